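test_that("axis normalization preserves incompressibility", {
  ns <- normalize_shape(8, 8)
  expect_equal(c(ns$a_n, ns$b_n, ns$c_n), c(1, 1, 1))
  expect_equal(ns$r0, 8)

  ns2 <- normalize_shape(16, 8)
  expect_equal(ns2$a_n, sqrt(2))
  expect_equal(ns2$b_n, 1 / sqrt(2))
  expect_equal(ns2$a_n * ns2$b_n * ns2$c_n, 1, tolerance = 1e-14)
  expect_equal(ns2$r0, sqrt(16 * 8))

  ns3 <- normalize_shape(5, 9)  # swapped inputs are exchanged, not an error
  expect_true(ns3$swapped)
  expect_equal(ns3$a_n, sqrt(9 / 5))
  expect_error(normalize_shape(0, 1), "> 0")
})

test_that("sphere shape integrals match their closed forms", {
  gi <- shearcyte:::.shape_integrals_quad(1, 1)
  expect_equal(gi$g1pp, 4 / 15, tolerance = 1e-6)
  expect_equal(gi$g2pp, 4 / 15, tolerance = 1e-6)
  expect_equal(gi$g3pp, 4 / 15, tolerance = 1e-6)
  expect_equal(gi$g3p, 2 / 5, tolerance = 1e-6)
  fc <- shape_factors(normalize_shape(1, 1), method = "quadrature")
  expect_equal(fc$I, 1, tolerance = 1e-6)
  expect_equal(fc$K, 4 / 25, tolerance = 1e-6)
})

test_that("lookup table agrees with direct quadrature and is scale-free", {
  for (q in c(1, 1.31, 2.7, 5.5, 9.93, 10)) {
    sh <- normalize_shape(q, 1)
    ft <- shape_factors(sh, method = "table")
    fq <- shape_factors(sh, method = "quadrature")
    expect_lt(abs(ft$I / fq$I - 1), 1e-3)
    expect_lt(abs(ft$K / fq$K - 1), 1e-3)
    expect_lt(abs(ft$g3p / fq$g3p - 1), 1e-3)
    # only the axis ratio matters (same ratio, different absolute axes)
    sh2 <- normalize_shape(3 * q, 3)
    f2 <- shape_factors(sh2, method = "table")
    expect_equal(f2$I, ft$I, tolerance = 1e-12)
  }
  tb <- shape_factor_table()
  expect_named(tb, c("axis_ratio", "I", "K", "g3p"))
  expect_equal(nrow(tb), 400)
})

test_that("strain vanishes for a sphere and grows with elongation", {
  expect_equal(cell_strain(normalize_shape(1, 1)), 0)
  # small-deformation limit: a_n = 1 + e, b_n = 1/(1 + e) -> strain -> 2e
  for (e in c(1e-4, 1e-3, 1e-2)) {
    sh <- structure(list(a_n = 1 + e, b_n = 1 / (1 + e), c_n = 1),
                    class = "normalized_shape")
    expect_equal(cell_strain(sh), 2 * e, tolerance = 2e-2)
  }
  eps <- vapply(seq(1, 8, length.out = 30),
                function(q) cell_strain(normalize_shape(q, 1)), numeric(1))
  expect_true(all(diff(eps) > 0))
  # self-consistency at ratio 2 against the quadrature oracle
  sh <- normalize_shape(2, 1)
  fq <- shape_factors(sh, method = "quadrature")
  expect_equal(cell_strain(sh, fq), (2 - 1 / 2) / (2 * fq$I),
               tolerance = 1e-12)
})

test_that("storage modulus follows the stress-strain-angle relation", {
  expect_equal(storage_modulus(100, pi / 4, 1), 250)
  expect_equal(storage_modulus(200, pi / 4, 1), 2 * storage_modulus(100, pi / 4, 1))
  expect_true(is.na(storage_modulus(100, pi / 4, 0)))      # zero strain
  expect_true(is.na(storage_modulus(100, -0.1, 0.5)))      # sin(2b) <= 0
})

test_that("loss modulus inverts the alignment relation exactly", {
  # round trip: G'' -> x -> cos(2 beta) reproduces the input angle
  for (q in c(1.2, 1.8, 3, 6)) for (beta in c(0.25, 0.6, pi / 4, 1.0)) {
    for (eta in c(0.2, 1, 3)) for (gd in c(5, 50, 500)) {
      sh <- normalize_shape(q, 1)
      fc <- shape_factors(sh)
      gpp <- loss_modulus(sh, fc, beta, eta, gd)
      if (is.na(gpp)) next
      om_d <- deformation_frequency(sh, gd)
      x <- (eta - gpp / om_d) / eta
      expect_equal(shearcyte:::.cos2beta_from_x(sh, fc, x), cos(2 * beta),
                   tolerance = 1e-10)
    }
  }
  # cos(2 beta) = A exactly corresponds to x = 0, G'' = omega_d * eta
  sh <- normalize_shape(2, 1)
  fc <- shape_factors(sh)
  A <- (sh$a_n^2 - sh$b_n^2) / (sh$a_n^2 + sh$b_n^2)
  beta_A <- acos(A) / 2
  gpp <- loss_modulus(sh, fc, beta_A, eta = 0.5, gamma_dot = 100)
  expect_equal(gpp, deformation_frequency(sh, 100) * 0.5, tolerance = 1e-10)
  # guards
  expect_true(is.na(loss_modulus(normalize_shape(1, 1), fc, 0.5, 1, 10)))
  expect_true(is.na(loss_modulus(sh, fc, 0.5, -1, 10)))
})

test_that("deformation frequency reduces to the shear rate for a sphere", {
  expect_equal(deformation_frequency(normalize_shape(1, 1), 120), 120)
  # slows down for elongated shapes
  expect_lt(deformation_frequency(normalize_shape(3, 1), 120), 120)
})
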