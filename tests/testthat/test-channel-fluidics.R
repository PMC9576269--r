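test_that("shear stress series has the expected symmetries and scaling", {
  st <- ref_state(1e5)
  W <- st$geometry$width

  expect_equal(shear_stress(st, 0), 0)
  # even in y
  y <- c(20, 50, 90) * 1e-6
  expect_equal(shear_stress(st, y), shear_stress(st, -y))
  # linear in the driving pressure
  st3 <- ref_state(2.7e5)
  expect_equal(shear_stress(st3, y), 2.7 * shear_stress(st, y),
               tolerance = 1e-12)
  # monotone from the center to the wall
  prof <- shear_stress(st, seq(0, W / 2, length.out = 50))
  expect_true(all(diff(prof) > 0))
  # series converged: 100 vs 400 odd terms differ by < 0.1% near the wall
  yw <- 0.99 * W / 2
  expect_lt(abs(shear_stress(st, yw, n_terms = 400) /
                shear_stress(st, yw, n_terms = 100) - 1), 1e-3)
  expect_error(shear_stress(st, W), "outside")
  expect_error(shear_stress(st, 0, z = st$geometry$height), "outside")
})

test_that("centerline fit recovers its own model and tolerates noise", {
  W <- 200e-6
  gen <- function(y, vmax, yc, zeta) vmax * (1 - abs((y - yc) / (W / 2))^zeta)
  y <- seq(-95e-6, 95e-6, length.out = 40)
  v <- gen(y, vmax = 10e-3, yc = 5e-6, zeta = 3)
  fit <- fit_centerline(y, v, W)
  expect_equal(fit$vmax, 10e-3, tolerance = 1e-6)
  expect_equal(fit$yc, 5e-6, tolerance = 1e-4)
  expect_equal(fit$zeta, 3, tolerance = 1e-5)

  set.seed(11)
  y2 <- runif(300, -95e-6, 95e-6)
  v2 <- gen(y2, 10e-3, 5e-6, 3) * (1 + rnorm(300, 0, 0.02))
  fit2 <- fit_centerline(y2, v2, W)
  expect_lt(abs(fit2$yc - 5e-6), 2e-6)

  expect_error(fit_centerline(y[1:3], v[1:3], W), "4 distinct")
  one_sided <- y > 10e-6
  expect_error(fit_centerline(y[one_sided], v[one_sided], W), "both sides")
})

test_that("Cross-model viscosity follows the defining equation", {
  expect_equal(viscosity(cross_model(2.5, 0, 0.6), c(0, 1, 100)),
               rep(2.5, 3))
  expect_equal(viscosity(cross_model(2, 0.1, 0.7), 10), 1)  # tau*gd = 1
  expect_equal(viscosity(cross_model(1, 0.1, 0.6), 100),
               1 / (1 + 10^0.6), tolerance = 1e-12)
  g <- seq(0, 1000, length.out = 200)
  expect_true(all(diff(viscosity(ref_fluid(), g)) <= 0))
  expect_error(viscosity(ref_fluid(), -1), "non-negative")
})

test_that("shear-rate solver satisfies the constitutive identity", {
  fl <- ref_fluid()
  # Newtonian limit
  expect_equal(solve_shear_rate(cross_model(2, 0, 0.5), c(0, 10, 50)),
               c(0, 5, 25))
  # identity eta(gd) * gd = sigma over a wide stress range
  sig <- c(0.01, 0.5, 5, 50, 250, 1000)
  g <- solve_shear_rate(fl, sig)
  expect_equal(viscosity(fl, g) * g, sig, tolerance = 1e-9)
  # against a brute-force bisection oracle on the residual equation
  fl2 <- cross_model(1, 0.1, 0.6)
  s <- 50
  oracle <- uniroot(function(gd) s / fl2$eta0 - gd +
                      s / fl2$eta0 * fl2$tau^fl2$delta * gd^fl2$delta,
                    c(1e-6, 10 * s / fl2$eta0 *
                        (1 + (fl2$tau * 10 * s / fl2$eta0)^fl2$delta)),
                    tol = 1e-12)$root
  expect_equal(solve_shear_rate(fl2, s), oracle, tolerance = 1e-8)
  expect_error(solve_shear_rate(fl, -5), "non-negative")
})

test_that("velocity profile matches the analytic Newtonian duct solution", {
  mu <- 2
  st <- channel_state(ref_geometry(), 1e5, cross_model(mu, 0, 0))
  W <- st$geometry$width
  y <- seq(0, W / 2, length.out = 41)
  v <- velocity_profile(st, y)
  v_oracle <- duct_velocity_oracle(y, W, st$geometry$height,
                                   st$geometry$length, 1e5, mu)
  expect_equal(v[length(v)], 0)
  expect_lt(max(abs(v[-41] / v_oracle[-41] - 1)), 0.005)
  # monotone decrease in |y|
  st2 <- ref_state()
  vv <- velocity_profile(st2, c(0, W / 4, W / 2))
  expect_true(vv[1] > vv[2] && vv[2] > vv[3] && vv[3] == 0)
})

test_that("fluid rheology fit recovers known Cross parameters", {
  geom <- ref_geometry()
  truth <- cross_model(2.0, 0.2, 0.6)
  st <- channel_state(geom, 2e5, truth)
  set.seed(3)
  y <- runif(200, -98e-6, 98e-6)
  v <- velocity_profile(st, y)
  fit <- fit_fluid_rheology(y, v, geom, 2e5)
  expect_lt(abs(fit$eta0 / truth$eta0 - 1), 0.01)
  expect_lt(abs(fit$tau / truth$tau - 1), 0.01)
  expect_lt(abs(fit$delta / truth$delta - 1), 0.01)

  expect_error(fit_fluid_rheology(y[1:5], v[1:5], geom, 2e5), "at least 20")
  y_narrow <- runif(30, -5e-6, 5e-6)
  expect_error(fit_fluid_rheology(y_narrow, velocity_profile(st, y_narrow),
                                  geom, 2e5), "ill-conditioned")

  js <- jsonlite::fromJSON(fluid_fit_json(fit))
  expect_named(js, c("eta0_pa_s", "tau_s", "delta", "rms_residual_mm_s"))
})

test_that("frame-rate constraint warns but does not error", {
  expect_warning(check_frame_rate(500, 41e-3, 124e-6), "frame rate")
  expect_silent(check_frame_rate(500, 20e-3, 248e-6))
})
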