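test_that("population sampling is seeded and matches its moments", {
  geom <- ref_geometry()
  p0 <- population_params(log10_k_sd = 0, alpha_sd = 0, radius_sd = 0,
                          k_alpha_coupling = 0, n_cells = 5)
  cells0 <- sample_population(p0, geom)
  expect_equal(length(unique(cells0$k_pa)), 1)
  expect_equal(length(unique(cells0$alpha)), 1)

  p <- population_params(n_cells = 200, seed = 77)
  expect_equal(sample_population(p, geom), sample_population(p, geom))

  pbig <- population_params(n_cells = 1e4, seed = 8)
  cells <- sample_population(pbig, geom)
  se_l10k <- pbig$log10_k_sd / sqrt(1e4)
  expect_lt(abs(mean(log10(cells$k_pa)) - pbig$log10_k_mean), 3 * se_l10k)
  expect_lt(abs(mean(cells$alpha) - pbig$alpha_mean),
            3 * sqrt(pbig$alpha_sd^2 +
                     (pbig$k_alpha_coupling * pbig$log10_k_sd)^2) / sqrt(1e4))
  expect_true(all(abs(cells$y_um) <= 100 - cells$r0_um))
})

test_that("forward deformation solves the steady-state shape consistently", {
  st <- ref_state()
  # quasi-rigid limit: shape stays a sphere
  fd_rigid <- forward_deform(1e6, 0.05, 8, 50e-6, st)
  expect_true(fd_rigid$resolved)
  expect_lt(fd_rigid$a_um / fd_rigid$b_um, 1.001)
  expect_equal(fd_rigid$beta_rad, pi / 4, tolerance = 1e-2)

  # closed-loop identity: the emitted shape reproduces (G', G'') via the
  # inverse analysis to better than 0.5%
  for (y in c(20, 45, 80) * 1e-6) for (k in c(60, 150)) {
    fd <- forward_deform(k, 0.35, 8, y, st)
    expect_true(fd$resolved)
    sh <- normalize_shape(fd$a_um, fd$b_um)
    fc <- shape_factors(sh)
    eps <- cell_strain(sh, fc)
    expect_lt(abs(storage_modulus(fd$sigma, fd$beta_rad, eps) / fd$Gp - 1),
              0.005)
    expect_lt(abs(loss_modulus(sh, fc, fd$beta_rad, fd$eta, fd$gamma_dot) /
                  fd$Gpp - 1), 0.005)
  }

  # small-strain linearity: at a fixed position (fixed stress, shear rate
  # and frequency), halving the moduli doubles the strain of a stiff cell
  e_of <- function(k) {
    fd <- forward_deform(k, 0.2, 8, 40e-6, st)
    cell_strain(normalize_shape(fd$a_um, fd$b_um))
  }
  expect_lt(abs(e_of(2500) / e_of(5000) - 2), 0.1)
})

test_that("simulated tables follow the CSV schema with plausible content", {
  st <- ref_state()
  tab <- suppressWarnings(
    simulate_cytometry(population_params(n_cells = 60, seed = 14), st))
  expect_true(all(c("frame", "time_s", "x_um", "y_um", "a_um", "b_um",
                    "beta_deg", "solidity", "circumference_um",
                    "velocity_mm_s", "ftt_hz") %in% names(tab)))
  expect_true(all(tab$a_um >= tab$b_um))
  expect_true(all(abs(tab$beta_deg) <= 90))
  # alignment angle flips sign across the channel half-planes
  truth <- attr(tab, "truth")
  expect_true(all(sign(tab$beta_deg[abs(truth$y_um) > 20]) ==
                  sign(truth$y_um[abs(truth$y_um) > 20])))
  # speeds decrease towards the walls
  ord <- order(abs(truth$y_um))
  expect_gt(mean(tab$velocity_mm_s[head(ord, 10)]),
            mean(tab$velocity_mm_s[tail(ord, 10)]))
})

test_that("rendered frames advect and are re-detectable", {
  acq <- acquisition_config(frame_rate = 500, pixel_size = 0.5)
  det <- data.frame(x_um = 40, y_um = -20, a_um = 10, b_um = 7,
                    beta_deg = 25, velocity_mm_s = 5, ftt_hz = 2)
  stack <- render_frames(det, acq, width_um = 100, n_frames = 3, seed = 6)
  cfg <- default_config()
  cfg$acquisition$pixel_size_um <- 0.5
  found <- detect_cells(stack, cfg)
  expect_gte(nrow(found), 2)
  expect_lt(abs(mean(found$a_um) / 10 - 1), 0.03)
  expect_lt(abs(mean(found$b_um) / 7 - 1), 0.03)
  expect_lt(abs(found$velocity_mm_s[1] / 5 - 1), 0.02)

  # a static cell without rotation renders identical frames up to noise
  det0 <- data.frame(x_um = 40, y_um = 0, a_um = 8, b_um = 8, beta_deg = 0,
                     velocity_mm_s = 0, ftt_hz = 0)
  s0 <- render_frames(det0, acq, width_um = 60, n_frames = 2, noise_sd = 0.01,
                      seed = 7)
  expect_lt(max(abs(s0[, , 1] - s0[, , 2])), 0.1)
})
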