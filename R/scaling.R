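#' Complex modulus of a power-law (structural damping) material
#'
#' G(omega) = k * (i omega / omega0)^alpha * Gamma(1 - alpha) + i omega mu,
#' i.e. G' = k (omega/omega0)^alpha Gamma(1-alpha) cos(pi alpha / 2) and
#' G'' = k (omega/omega0)^alpha Gamma(1-alpha) sin(pi alpha / 2) + omega mu.
#' The stiffness k is referenced to omega0 = 2 pi rad/s (1 Hz); alpha = 0
#' is a Hookean solid, alpha = 1 a Newtonian fluid. The optional Newtonian
#' viscosity term mu matters only at high frequency (used for the
#' polyacrylamide-bead global fit, not for per-cell scaling).
#'
#' @param k Stiffness at the reference frequency, Pa.
#' @param alpha Fluidity, in `[0, 1)`.
#' @param omega Angular frequency(ies), rad/s, > 0.
#' @param mu Newtonian viscosity, Pa s.
#' @param omega0 Reference angular frequency, rad/s (default 2 pi).
#' @return A list with numeric vectors `Gp` and `Gpp` (Pa).
#' @export
complex_modulus <- function(k, alpha, omega, mu = 0, omega0 = 2 * pi) {
  .check_scalar(k, "k", positive = TRUE)
  .check_scalar(alpha, "alpha")
  if (alpha < 0 || alpha >= 1)
    stop("'alpha' must lie in [0, 1) (Gamma pole at alpha = 1)", call. = FALSE)
  .check_scalar(mu, "mu", nonneg = TRUE)
  if (any(omega <= 0)) stop("'omega' must be > 0", call. = FALSE)
  amp <- k * (omega / omega0)^alpha * gamma(1 - alpha)
  list(Gp = amp * cos(pi * alpha / 2),
       Gpp = amp * sin(pi * alpha / 2) + omega * mu)
}

#' Scale measured moduli to the 1 Hz reference
#'
#' Inverts the single-frequency power-law relation (mu = 0): the fluidity
#' follows from the structural-damping ratio,
#' alpha = (2/pi) * atan(G''/G'), and the stiffness from
#' k = G' / ((omega/omega0)^alpha Gamma(1-alpha) cos(pi alpha / 2)).
#' Round-trips exactly with [complex_modulus()] for mu = 0.
#'
#' @param Gp Storage modulus, Pa (> 0; else the record is flagged `NA`).
#' @param Gpp Loss modulus, Pa (>= 0).
#' @param omega Angular measurement frequency, rad/s.
#' @param omega0 Reference angular frequency, rad/s (default 2 pi).
#' @return A list with vectors `k` (Pa) and `alpha`.
#' @export
scale_to_reference <- function(Gp, Gpp, omega, omega0 = 2 * pi) {
  n <- max(length(Gp), length(Gpp), length(omega))
  Gp <- rep_len(Gp, n); Gpp <- rep_len(Gpp, n); omega <- rep_len(omega, n)
  bad <- !is.finite(Gp) | Gp <= 0 | !is.finite(Gpp) | Gpp < 0 |
    !is.finite(omega) | omega <= 0
  alpha <- (2 / pi) * atan(Gpp / Gp)
  k <- Gp / ((omega / omega0)^alpha * gamma(1 - alpha) * cos(pi * alpha / 2))
  alpha[bad] <- NA_real_
  k[bad] <- NA_real_
  list(k = k, alpha = alpha)
}

#' Global power-law fit to a population of (omega, G', G'') records
#'
#' Least-squares fit of the structural-damping model with a common
#' Newtonian viscosity mu to all records jointly, on log-magnitude
#' residuals of both components. Requires at least 3 records spanning more
#' than one octave in omega.
#'
#' @param omega Angular frequencies, rad/s.
#' @param Gp,Gpp Storage and loss moduli, Pa.
#' @param omega0 Reference angular frequency, rad/s.
#' @return A list of class `powerlaw_fit` with `k`, `alpha`, `mu`,
#'   `omega0`, and `objective`.
#' @export
fit_population_powerlaw <- function(omega, Gp, Gpp, omega0 = 2 * pi) {
  keep <- is.finite(omega) & is.finite(Gp) & is.finite(Gpp) &
    omega > 0 & Gp > 0 & Gpp > 0
  omega <- omega[keep]; Gp <- Gp[keep]; Gpp <- Gpp[keep]
  if (length(omega) < 3)
    stop("power-law fit needs at least 3 valid records", call. = FALSE)
  if (max(omega) / min(omega) < 2)
    stop("power-law fit needs records spanning more than one octave in omega",
         call. = FALSE)
  obj <- function(p) {
    k <- exp(p[1]); alpha <- stats::plogis(p[2]); mu <- exp(p[3])
    m <- complex_modulus(k, alpha, omega, mu = mu, omega0 = omega0)
    sum(log(m$Gp / Gp)^2 + log(m$Gpp / Gpp)^2)
  }
  # starts: alpha from the median damping ratio, k from the median modulus
  a0 <- min(max((2 / pi) * atan(median(Gpp / Gp)), 0.02), 0.9)
  k0 <- median(Gp / ((omega / omega0)^a0 * gamma(1 - a0) * cos(pi * a0 / 2)))
  best <- NULL
  for (mu0 in c(1e-6 * k0 / max(omega), 0.1 * k0 / max(omega))) {
    p0 <- c(log(k0), stats::qlogis(a0), log(mu0))
    fit <- stats::optim(p0, obj, method = "Nelder-Mead",
                        control = list(maxit = 5000, reltol = 1e-14))
    fit <- stats::optim(fit$par, obj, method = "Nelder-Mead",
                        control = list(maxit = 5000, reltol = 1e-14))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  structure(list(k = exp(best$par[1]), alpha = stats::plogis(best$par[2]),
                 mu = exp(best$par[3]), omega0 = omega0,
                 objective = best$value),
            class = "powerlaw_fit")
}

# Gaussian KDE consistent with MASS::kde2d (kernel sd = bandwidth / 4)
.kde2d_eval <- function(x0, y0, x, y, hx, hy) {
  mean(dnorm(x0, x, hx / 4) * dnorm(y0, y, hy / 4))
}

#' Mode of the 2-D (stiffness, fluidity) population distribution
#'
#' Gaussian kernel density estimation on (log10 k, alpha) — k is
#' log-normal across cells while alpha is normal — with Scott's
#' rule-of-thumb bandwidth for two dimensions (kernel sd =
#' sigma_hat * n^(-1/6) per axis, robust sigma_hat), evaluated on a
#' 201 x 201 grid; the grid argmax is refined by local ascent on the
#' exact KDE. The mode is the most common (k, alpha) combination and is
#' robust to the skew of k.
#'
#' @param k Per-cell stiffness values, Pa.
#' @param alpha Per-cell fluidity values.
#' @param n_grid Grid resolution per axis.
#' @return A list of class `population_summary` with `mode_k` (Pa, linear
#'   scale), `mode_alpha`, and `n_valid`.
#' @export
population_mode <- function(k, alpha, n_grid = 201) {
  keep <- is.finite(k) & is.finite(alpha) & k > 0
  k <- k[keep]; alpha <- alpha[keep]
  if (length(k) < 10)
    stop("population mode needs at least 10 valid (k, alpha) pairs",
         call. = FALSE)
  x <- log10(k); y <- alpha
  n <- length(x)
  # Scott's rule for d = 2; kde2d kernel sd is h/4
  sx <- max(min(sd(x), stats::IQR(x) / 1.34), 1e-3)
  sy <- max(min(sd(y), stats::IQR(y) / 1.34), 1e-3)
  hx <- 4 * sx * n^(-1 / 6)
  hy <- 4 * sy * n^(-1 / 6)
  lims <- c(range(x) + c(-1, 1) * hx / 2, range(y) + c(-1, 1) * hy / 2)
  dens <- MASS::kde2d(x, y, h = c(hx, hy), n = n_grid, lims = lims)
  idx <- which(dens$z == max(dens$z), arr.ind = TRUE)[1, ]
  start <- c(dens$x[idx[1]], dens$y[idx[2]])
  ref <- stats::optim(start,
                      function(p) -.kde2d_eval(p[1], p[2], x, y, hx, hy),
                      method = "Nelder-Mead",
                      control = list(maxit = 500, reltol = 1e-12))
  structure(list(mode_k = 10^ref$par[1], mode_alpha = ref$par[2],
                 n_valid = length(k)),
            class = "population_summary")
}
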