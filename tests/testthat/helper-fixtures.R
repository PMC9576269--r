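# shared fixtures: the reference channel (200 x 200 um, 5.8 cm) with a
# 2%-alginate-like Cross fluid, driven at 200 kPa unless stated otherwise
ref_geometry <- function() channel_geometry(200e-6, 200e-6, 0.058)

ref_fluid <- function() cross_model(eta0 = 4, tau = 0.1, delta = 0.55)

ref_state <- function(pressure = 2e5, fluid = ref_fluid())
  channel_state(ref_geometry(), pressure, fluid)

# analytic mid-plane velocity of a Newtonian square duct (double series
# truncated at n_terms odd terms) — independent oracle for the integrated
# shear-rate profile
duct_velocity_oracle <- function(y, W, H, L, dP, mu, n_terms = 100) {
  n <- seq(1, by = 2, length.out = n_terms)
  vapply(y, function(yy) {
    4 * H^2 * dP / (pi^3 * L * mu) *
      sum((-1)^((n - 1) / 2) / n^3 *
          (1 - cosh(n * pi * yy / H) / cosh(n * pi * W / (2 * H))))
  }, numeric(1))
}

# draw a filled ellipse mask (rows = y, cols = x) for detector tests
ellipse_mask <- function(nr, nc, cy, cx, a, b, beta_deg) {
  beta <- beta_deg * pi / 180
  dy <- matrix(seq_len(nr) - cy, nr, nc)
  dx <- matrix(seq_len(nc) - cx, nr, nc, byrow = TRUE)
  xr <- cos(beta) * dx + sin(beta) * dy
  yr <- -sin(beta) * dx + cos(beta) * dy
  (xr / a)^2 + (yr / b)^2 <= 1
}
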