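#' Rectangular microchannel geometry
#'
#' All dimensions in meters. The channel is assumed long compared to its
#' width so that entrance and exit effects can be neglected.
#'
#' @param width Channel width W along the imaged (y) direction, m.
#' @param height Channel height H along the optical (z) axis, m.
#' @param length Channel length L along the flow (x) direction, m.
#' @return An object of class `channel_geometry`.
#' @export
#' @examples
#' channel_geometry(200e-6, 200e-6, 0.058)
channel_geometry <- function(width = 200e-6, height = 200e-6, length = 0.058) {
  .check_scalar(width, "width", positive = TRUE)
  .check_scalar(height, "height", positive = TRUE)
  .check_scalar(length, "length", positive = TRUE)
  if (length < 10 * width)
    warning("channel length is not large compared to its width; ",
            "entrance effects are neglected by the stress series")
  structure(list(width = width, height = height, length = length),
            class = "channel_geometry")
}

#' Cross shear-thinning viscosity model
#'
#' eta(gamma_dot) = eta0 / (1 + (tau * gamma_dot)^delta), with zero-shear
#' viscosity eta0 (Pa s), relaxation time tau (s) and shear-thinning
#' exponent delta (dimensionless, 0 <= delta < 1).
#'
#' @param eta0 Zero-shear viscosity, Pa s.
#' @param tau Relaxation time, s.
#' @param delta Shear-thinning exponent in `[0, 1)`.
#' @return An object of class `cross_model`.
#' @export
cross_model <- function(eta0, tau, delta) {
  .check_scalar(eta0, "eta0", positive = TRUE)
  .check_scalar(tau, "tau", nonneg = TRUE)
  .check_scalar(delta, "delta")
  if (delta < 0 || delta >= 1) stop("'delta' must lie in [0, 1)", call. = FALSE)
  structure(list(eta0 = eta0, tau = tau, delta = delta), class = "cross_model")
}

#' Channel state: geometry, driving pressure, and suspension-fluid rheology
#'
#' @param geometry A [channel_geometry()].
#' @param pressure Total driving pressure drop over the channel, Pa.
#' @param fluid A [cross_model()] describing the suspension fluid.
#' @return An object of class `channel_state`.
#' @export
channel_state <- function(geometry, pressure, fluid) {
  stopifnot(inherits(geometry, "channel_geometry"))
  .check_scalar(pressure, "pressure", positive = TRUE)
  stopifnot(inherits(fluid, "cross_model"))
  structure(list(geometry = geometry, pressure = pressure, fluid = fluid),
            class = "channel_state")
}

#' Fluid shear stress in a square-cross-section channel
#'
#' Magnitude of the shear stress at position (y, z) in the channel
#' mid-plane, from the series solution for laminar uniaxial flow in a
#' rectangular duct. The stress field depends only on geometry and driving
#' pressure, not on the fluid viscosity, and remains approximately valid
#' for shear-thinning fluids. It vanishes at the channel center and grows
#' monotonically towards the walls.
#'
#' The infinite series runs over odd indices n = 1, 3, 5, ...; `n_terms`
#' odd terms are summed (default 100, i.e. n up to 199), which is
#' converged to well below 0.1% everywhere in the channel.
#'
#' @param state A [channel_state()] (only geometry and pressure are used).
#' @param y Lateral position(s) measured from the channel center, m.
#' @param z Position along the optical axis from the mid-plane, m.
#' @param n_terms Number of odd series terms.
#' @return Shear stress magnitude(s), Pa (same length as `y`).
#' @export
#' @examples
#' st <- channel_state(channel_geometry(), 1e5, cross_model(4, 0.1, 0.55))
#' shear_stress(st, y = 100e-6)  # at the wall, ~116 Pa
shear_stress <- function(state, y, z = 0, n_terms = 100) {
  stopifnot(inherits(state, "channel_state"))
  W <- state$geometry$width
  H <- state$geometry$height
  L <- state$geometry$length
  dP <- state$pressure
  if (any(!is.finite(y)) || any(abs(y) > W / 2 * (1 + 1e-12)))
    stop("position y outside channel (|y| must be <= W/2)", call. = FALSE)
  .check_scalar(z, "z")
  if (abs(z) > H / 2 * (1 + 1e-12))
    stop("position z outside channel (|z| must be <= H/2)", call. = FALSE)

  n <- seq(1, by = 2, length.out = n_terms)
  # sinh(n pi y / H) / cosh(n pi W / (2 H)), computed in log space to avoid
  # overflow of the hyperbolic functions at large n
  u <- outer(n, y, function(n, y) n * pi * y / H)         # n_terms x ny
  v <- n * pi * W / (2 * H)
  ratio <- sign(u) * exp(abs(u) - v) * (1 - exp(-2 * abs(u))) / (1 + exp(-2 * v))
  coef <- (-1)^((n - 1) / 2) * (pi / (n^2 * H)) * cos(n * pi * z / H)
  pref <- 4 * H^2 * dP / (pi^3 * L)
  abs(pref * colSums(coef * ratio))
}

#' Fit the approximate centerline velocity profile
#'
#' Fits v(y) = vmax * (1 - |(y - yc) / (W/2)|^zeta) to per-cell speed
#' observations in raw (image) y-coordinates. The fitted center `yc` is
#' used downstream to shift all y-coordinates so that the channel center
#' sits at y = 0. This polynomial form is an approximation used only for
#' centering; the precise profile is obtained from [velocity_profile()].
#'
#' @param y Raw lateral positions, m (or any consistent unit shared with
#'   `width`).
#' @param v Observed speeds, m/s.
#' @param width Channel width W in the same unit as `y`.
#' @return An object of class `centerline_fit` with elements `vmax`, `yc`,
#'   `zeta`, and `rms_residual`.
#' @export
fit_centerline <- function(y, v, width) {
  if (length(y) != length(v)) stop("'y' and 'v' must have equal length")
  keep <- is.finite(y) & is.finite(v)
  y <- y[keep]; v <- v[keep]
  if (length(unique(y)) < 4)
    stop("centerline fit needs at least 4 distinct samples", call. = FALSE)
  y_peak <- y[which.max(v)]
  if (!any(y < y_peak) || !any(y > y_peak))
    stop("centerline fit needs samples on both sides of the channel center",
         call. = FALSE)
  dat <- data.frame(y = y, v = v)
  fit <- minpack.lm::nlsLM(
    v ~ vmax * (1 - abs((y - yc) / (width / 2))^zeta),
    data = dat,
    start = list(vmax = max(v), yc = y_peak, zeta = 2),
    lower = c(vmax = 1e-12, yc = min(y), zeta = 1.0001),
    upper = c(vmax = Inf, yc = max(y), zeta = 50),
    control = minpack.lm::nls.lm.control(maxiter = 500))
  cf <- coef(fit)
  structure(list(vmax = unname(cf["vmax"]), yc = unname(cf["yc"]),
                 zeta = unname(cf["zeta"]),
                 rms_residual = sqrt(mean(stats::resid(fit)^2))),
            class = "centerline_fit")
}

#' Cross-model viscosity at a given shear rate
#'
#' @param fluid A [cross_model()].
#' @param gamma_dot Shear rate(s), 1/s, non-negative.
#' @return Viscosity, Pa s.
#' @export
viscosity <- function(fluid, gamma_dot) {
  stopifnot(inherits(fluid, "cross_model"))
  if (any(!is.finite(gamma_dot)) || any(gamma_dot < 0))
    stop("'gamma_dot' must be non-negative", call. = FALSE)
  fluid$eta0 / (1 + (fluid$tau * gamma_dot)^fluid$delta)
}

#' Solve for the shear rate at a given shear stress
#'
#' Inverts sigma = eta(gamma_dot) * gamma_dot for the Cross model by
#' root-finding on
#' 0 = sigma/eta0 - gamma_dot + (sigma/eta0) * tau^delta * gamma_dot^delta
#' with the Newton-Raphson method. Iteration starts at the argmax of the
#' right-hand side plus a small offset (1e-6 * sigma/eta0), which
#' guarantees monotone convergence onto the unique physical root; on
#' non-convergence a bisection fallback is used.
#'
#' @param fluid A [cross_model()].
#' @param sigma Shear stress(es), Pa, non-negative.
#' @param tol Relative residual tolerance.
#' @param max_iter Maximum Newton iterations.
#' @return Shear rate(s), 1/s.
#' @export
solve_shear_rate <- function(fluid, sigma, tol = 1e-12, max_iter = 100) {
  stopifnot(inherits(fluid, "cross_model"))
  if (any(!is.finite(sigma)) || any(sigma < 0))
    stop("'sigma' must be non-negative", call. = FALSE)
  s <- sigma / fluid$eta0
  delta <- fluid$delta
  cc <- s * fluid$tau^delta
  g <- s
  if (fluid$tau > 0 && delta > 0) {
    gm <- (cc * delta)^(1 / (1 - delta))        # argmax of the residual
    g <- gm + 1e-6 * s
    f <- s - g + cc * g^delta
    converged <- s == 0
    g[s == 0] <- 0
    for (i in seq_len(max_iter)) {
      if (all(converged)) break
      fp <- -1 + cc * delta * g^(delta - 1)
      gn <- g - f / fp
      bad <- !is.finite(gn) | gn <= 0
      gn[bad] <- g[bad] / 2
      g <- ifelse(converged, g, gn)
      f <- s - g + cc * g^delta
      converged <- converged | abs(f) <= tol * pmax(s, .Machine$double.xmin)
    }
    if (!all(converged)) {
      # bisection fallback on the elements that did not converge
      idx <- which(!converged)
      for (j in idx) {
        lo <- gm[j]
        hi <- max(2 * gm[j], 2 * s[j] * (1 + cc[j] * (10 * s[j])^delta), 1)
        while (s[j] - hi + cc[j] * hi^delta > 0) hi <- hi * 2
        r <- tryCatch(
          stats::uniroot(function(x) s[j] - x + cc[j] * x^delta,
                         c(lo, hi), tol = tol * max(s[j], 1))$root,
          error = function(e)
            stop(sprintf("shear-rate solver failed (sigma = %g Pa, residual %g)",
                         sigma[j], abs(s[j] - g[j] + cc[j] * g[j]^delta)),
                 call. = FALSE))
        g[j] <- r
      }
    }
  }
  g
}

# composite 5-point Gauss-Legendre quadrature layout for integrating the
# shear rate from each |y| out to the wall W/2; shared by velocity_profile
# and fit_fluid_rheology so the stress at the nodes can be precomputed.
.velocity_quadrature <- function(y_abs, W, min_sub = 8) {
  panel_w <- W / 80
  nodes <- list(); weights <- list(); group <- list()
  for (i in seq_along(y_abs)) {
    a <- y_abs[i]; b <- W / 2
    if (b - a <= 0) { nodes[[i]] <- numeric(0); weights[[i]] <- numeric(0)
                      group[[i]] <- integer(0); next }
    nsub <- max(min_sub, ceiling((b - a) / panel_w))
    brk <- seq(a, b, length.out = nsub + 1)
    mid <- (brk[-1] + brk[-length(brk)]) / 2
    half <- diff(brk) / 2
    nodes[[i]] <- as.vector(outer(.gl5_nodes, half) +
                            matrix(mid, 5, nsub, byrow = TRUE))
    weights[[i]] <- as.vector(outer(.gl5_weights, half))
    group[[i]] <- rep.int(i, 5 * nsub)
  }
  list(nodes = unlist(nodes), weights = unlist(weights),
       group = unlist(group), n = length(y_abs))
}

#' Velocity profile in the channel mid-plane
#'
#' Integrates the shear rate from the wall (no-slip, v(W/2) = 0) to |y|
#' with composite 5-point Gauss-Legendre quadrature:
#' v(y) = integral over y' in (|y|, W/2) of gamma_dot(y').
#'
#' @param state A [channel_state()].
#' @param y Lateral position(s) from the channel center, m.
#' @param n_terms Series terms passed to [shear_stress()].
#' @return Speed(s), m/s.
#' @export
velocity_profile <- function(state, y, n_terms = 100) {
  stopifnot(inherits(state, "channel_state"))
  W <- state$geometry$width
  ya <- abs(y)
  if (any(!is.finite(ya)) || any(ya > W / 2 * (1 + 1e-12)))
    stop("position y outside channel", call. = FALSE)
  ya <- pmin(ya, W / 2)
  q <- .velocity_quadrature(ya, W)
  if (!length(q$nodes)) return(rep(0, length(y)))
  sig <- shear_stress(state, q$nodes, n_terms = n_terms)
  g <- solve_shear_rate(state$fluid, sig)
  v <- rep(0, length(y))
  agg <- rowsum(q$weights * g, q$group)
  v[as.integer(rownames(agg))] <- agg[, 1]
  v
}

#' Fit the suspension-fluid rheology from cell speeds
#'
#' Finds the Cross-model parameters (eta0, tau, delta) whose predicted
#' mid-plane velocity profile best matches observed per-cell speeds, by
#' minimizing the sum of squared relative speed residuals (cell-speed
#' measurement error is multiplicative, and relative weighting keeps the
#' slow near-wall cells — which carry the shear-thinning information —
#' from being swamped by the fast center cells). The optimizer is a
#' multi-start Nelder-Mead simplex on (log eta0, log tau, logit delta),
#' which enforces the parameter bounds eta0 > 0, tau >= 0, 0 <= delta < 1.
#'
#' The shear-thinning exponent delta is tightly constrained by a single
#' velocity profile; the zero-shear plateau parameters (eta0, tau) are
#' extrapolations beyond the sampled shear-rate range whenever
#' tau * gamma_dot >> 1 over most of the channel, and then carry a
#' sampling variability of tens of percent.
#'
#' @param y Lateral positions from the channel center, m.
#' @param v Observed speeds, m/s.
#' @param geometry A [channel_geometry()].
#' @param pressure Driving pressure, Pa.
#' @param starts Optional list of numeric `c(eta0, tau, delta)` start points.
#' @return A [cross_model()] with attributes `rms_residual` (m/s) and
#'   `objective` (sum of squares).
#' @export
fit_fluid_rheology <- function(y, v, geometry, pressure, starts = NULL) {
  stopifnot(inherits(geometry, "channel_geometry"))
  if (length(y) != length(v)) stop("'y' and 'v' must have equal length")
  keep <- is.finite(y) & is.finite(v)
  y <- y[keep]; v <- v[keep]
  if (length(y) < 20)
    stop("fluid fit needs at least 20 (y, v) samples", call. = FALSE)
  W <- geometry$width
  ya <- pmin(abs(y), W / 2)
  if (min(ya) > 0.25 * W / 2 || max(ya) < 0.7 * W / 2)
    stop("ill-conditioned fluid fit: samples must span |y| from near the ",
         "channel center to near the wall", call. = FALSE)

  # cumulative quadrature grid from the wall to the center: 5-point
  # Gauss-Legendre panels between 129 grid points, integrated once per
  # parameter set and spline-interpolated to the sample positions
  grid <- seq(0, W / 2, length.out = 129)
  mid <- (grid[-1] + grid[-length(grid)]) / 2
  half <- diff(grid) / 2
  nodes <- as.vector(outer(.gl5_nodes, half) +
                     matrix(mid, 5, length(mid), byrow = TRUE))
  wts <- as.vector(outer(.gl5_weights, half))
  panel <- rep(seq_along(mid), each = 5)
  # stress at the quadrature nodes is independent of the fluid parameters
  dummy <- channel_state(geometry, pressure, cross_model(1, 0, 0))
  sig <- shear_stress(dummy, nodes)

  model_v <- function(fluid) {
    g <- solve_shear_rate(fluid, sig)
    pint <- rowsum(wts * g, panel)[, 1]
    v_grid <- rev(cumsum(rev(c(pint, 0))))   # v at grid points (0 at wall)
    stats::spline(grid, v_grid, xout = ya)$y
  }
  decode <- function(p) cross_model(exp(p[1]), exp(p[2]), stats::plogis(p[3]))
  wts_v <- 1 / pmax(abs(v), 0.02 * max(abs(v)))^2
  obj <- function(p) {
    fl <- decode(p)
    sum(wts_v * (model_v(fl) - v)^2)
  }
  if (is.null(starts))
    starts <- list(c(1, 0.1, 0.5), c(3.5, 0.3, 0.65), c(8, 0.03, 0.3))
  best <- NULL
  for (s0 in starts) {
    p0 <- c(log(s0[1]), log(max(s0[2], 1e-8)), stats::qlogis(min(max(s0[3], 1e-6), 1 - 1e-6)))
    fit <- stats::optim(p0, obj, method = "Nelder-Mead",
                        control = list(maxit = 1000, reltol = 1e-12))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  # polish the overall best with a restarted simplex
  best <- stats::optim(best$par, obj, method = "Nelder-Mead",
                       control = list(maxit = 2000, reltol = 1e-14))
  fl <- decode(best$par)
  attr(fl, "rms_residual") <- sqrt(mean((model_v(fl) - v)^2))
  attr(fl, "objective") <- best$value
  fl
}

#' Export a fluid fit as JSON
#'
#' @param fluid A [cross_model()] as returned by [fit_fluid_rheology()].
#' @param path Output file path; if `NULL`, the JSON string is returned.
#' @return The JSON string, invisibly when written to a file.
#' @export
fluid_fit_json <- function(fluid, path = NULL) {
  stopifnot(inherits(fluid, "cross_model"))
  rms <- attr(fluid, "rms_residual")
  out <- list(eta0_pa_s = fluid$eta0, tau_s = fluid$tau, delta = fluid$delta,
              rms_residual_mm_s = if (is.null(rms)) NA_real_ else rms * 1e3)
  js <- jsonlite::toJSON(out, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' Check the frame-rate constraint for velocity tracking
#'
#' Each cell must appear in at least two consecutive frames, which requires
#' fr > vmax / (0.5 * ROIx). A violation is reported as a warning only.
#'
#' @param frame_rate Acquisition frame rate, 1/s.
#' @param vmax Maximum flow speed, m/s.
#' @param roi_x Width of the imaged region along the flow, m.
#' @return `TRUE` (invisibly) if the constraint holds, else `FALSE` with a
#'   warning.
#' @export
check_frame_rate <- function(frame_rate, vmax, roi_x) {
  ok <- frame_rate > vmax / (0.5 * roi_x)
  if (!ok)
    warning(sprintf(
      "frame rate %.0f Hz below vmax/(0.5 ROIx) = %.0f Hz; cells may not be trackable",
      frame_rate, vmax / (0.5 * roi_x)), call. = FALSE)
  invisible(ok)
}
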