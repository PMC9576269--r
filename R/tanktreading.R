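#' Predicted tank-treading frequency from the local shear rate
#'
#' Empirical master relationship
#' omega_tt(gamma_dot) = (gamma_dot / 2) / (1 + (0.113 * gamma_dot)^0.45)
#' with gamma_dot in 1/s. The rotation rate omega_tt/gamma_dot approaches
#' the Einstein limit of 1/2 as gamma_dot goes to 0 and decreases
#' monotonically with increasing shear rate. Used as a fallback when the
#' rotation cannot be measured from the images (poor contrast, no
#' trackable internal features). Calibrated for tank-treading cells in
#' viscous media; not valid for tumbling regimes (e.g. red blood cells at
#' low shear rates).
#'
#' @param gamma_dot Shear rate(s), 1/s, non-negative.
#' @return Angular tank-treading frequency(ies), rad/s.
#' @export
predict_tanktreading <- function(gamma_dot) {
  if (any(!is.finite(gamma_dot)) || any(gamma_dot < 0))
    stop("'gamma_dot' must be non-negative", call. = FALSE)
  gamma_dot / 2 / (1 + (0.113 * gamma_dot)^0.45)
}

# bilinear sampling of matrix `im` at fractional (row, col) positions;
# out-of-range positions return `fill`
.bilinear <- function(im, r, cl, fill = 0) {
  nr <- nrow(im); nc <- ncol(im)
  r0 <- floor(r); c0 <- floor(cl)
  fr <- r - r0; fc <- cl - c0
  ok <- r0 >= 1 & r0 < nr & c0 >= 1 & c0 < nc
  out <- rep(fill, length(r))
  if (!any(ok)) return(out)
  i00 <- cbind(r0[ok], c0[ok]); i10 <- cbind(r0[ok] + 1, c0[ok])
  i01 <- cbind(r0[ok], c0[ok] + 1); i11 <- cbind(r0[ok] + 1, c0[ok] + 1)
  out[ok] <- im[i00] * (1 - fr[ok]) * (1 - fc[ok]) +
    im[i10] * fr[ok] * (1 - fc[ok]) +
    im[i01] * (1 - fr[ok]) * fc[ok] +
    im[i11] * fr[ok] * fc[ok]
  out
}

# box-filter sums over a (2w+1)^2 window via a summed-area table
.window_sum <- function(m, w) {
  nr <- nrow(m); nc <- ncol(m)
  p <- matrix(0, nr + 1, nc + 1)
  cs <- apply(m, 2, cumsum)             # cumulative over rows
  cs <- t(apply(cs, 1, cumsum))         # then over columns
  p[-1, -1] <- cs
  r1 <- pmax(seq_len(nr) - w, 1); r2 <- pmin(seq_len(nr) + w, nr)
  c1 <- pmax(seq_len(nc) - w, 1); c2 <- pmin(seq_len(nc) + w, nc)
  p[r2 + 1, c2 + 1, drop = FALSE] - p[r1, c2 + 1, drop = FALSE] -
    p[r2 + 1, c1, drop = FALSE] + p[r1, c1, drop = FALSE]
}

#' Dense optical flow between two image patches
#'
#' Iterative dense Lucas-Kanade flow: spatial gradients by central
#' differences, per-pixel 2x2 normal equations accumulated over a square
#' window, refined over a few warp iterations with bilinear resampling.
#' Designed for the small (sub-pixel to few-pixel) displacements of
#' tank-treading cell texture between consecutive frames. The default
#' 7 x 7 window is a compromise: larger windows suppress noise but
#' oversmooth rotational fields near texture boundaries, biasing the
#' fitted rotation rate. This is the
#' default backend behind the dense-flow contract (two patches in,
#' per-pixel displacement out); alternative estimators with the same
#' signature can be substituted.
#'
#' @param im1,im2 Numeric matrices (grayscale patches, same size).
#' @param window Half-width of the integration window, px.
#' @param n_iter Warp/refinement iterations.
#' @param min_det Determinant threshold below which a pixel's flow is
#'   marked invalid (`NA`), e.g. in textureless regions.
#' @return A list with matrices `u` (column/x displacement, px) and `v`
#'   (row/y displacement, px); `NA` where the flow is undetermined.
#' @export
optical_flow <- function(im1, im2, window = 3, n_iter = 3, min_det = 1e-6) {
  stopifnot(is.matrix(im1), is.matrix(im2), all(dim(im1) == dim(im2)))
  nr <- nrow(im1); nc <- ncol(im1)
  # normalize contrast so min_det has a consistent scale
  s <- sd(im1); if (s > 0) { im1 <- (im1 - mean(im1)) / s; im2 <- (im2 - mean(im2)) / s }
  grad <- function(m) {
    gx <- matrix(0, nr, nc); gy <- matrix(0, nr, nc)
    gx[, 2:(nc - 1)] <- (m[, 3:nc] - m[, 1:(nc - 2)]) / 2
    gy[2:(nr - 1), ] <- (m[3:nr, ] - m[1:(nr - 2), ]) / 2
    list(gx = gx, gy = gy)
  }
  g1 <- grad(im1)
  Ix <- g1$gx; Iy <- g1$gy
  Sxx <- .window_sum(Ix * Ix, window)
  Sxy <- .window_sum(Ix * Iy, window)
  Syy <- .window_sum(Iy * Iy, window)
  det <- Sxx * Syy - Sxy^2
  u <- matrix(0, nr, nc); v <- matrix(0, nr, nc)
  rows <- matrix(seq_len(nr), nr, nc)
  cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  for (it in seq_len(n_iter)) {
    warped <- matrix(.bilinear(im2, as.vector(rows + v), as.vector(cols + u),
                               fill = NA), nr, nc)
    It <- warped - im1
    It[is.na(It)] <- 0
    Sxt <- .window_sum(Ix * It, window)
    Syt <- .window_sum(Iy * It, window)
    du <- -(Syy * Sxt - Sxy * Syt) / det
    dv <- -(Sxx * Syt - Sxy * Sxt) / det
    du[!is.finite(du)] <- 0; dv[!is.finite(dv)] <- 0
    u <- u + du; v <- v + dv
  }
  bad <- det < min_det * (2 * window + 1)^2
  u[bad] <- NA_real_; v[bad] <- NA_real_
  list(u = u, v = v)
}

#' Measure the tank-treading frequency of a cell from image crops
#'
#' Computes dense optical flow between consecutive crops centered on the
#' cell, maps every interior pixel to its ellipse-corrected radius r
#' (radial distance divided by the ellipse radius at that polar angle),
#' and regresses the ellipse-normalized tangential speed (1/s) through
#' the origin against r for r < `r_max`. Under rigid rotation the
#' normalized speed equals omega_tt * r, so the slope is the angular
#' tank-treading frequency in rad/s. Pixels near the cell boundary
#' (r >= `r_max`, default 0.7) are excluded to avoid boundary artefacts.
#'
#' @param crops List of >= 2 numeric matrices (consecutive crops of the
#'   same cell, cell centered).
#' @param detection A one-row data.frame (or list) with the cell's `a_um`,
#'   `b_um`, `beta_deg`.
#' @param frame_rate Acquisition frame rate, 1/s.
#' @param pixel_size Pixel size, um/px.
#' @param r_max Ellipse-corrected radius cutoff.
#' @param min_pixels Minimum usable pixels; below it the result is absent.
#' @param min_r2 Minimum through-origin fit R^2; below it the result is
#'   absent (caller falls back to [predict_tanktreading()]).
#' @return A list of class `tanktread_result` with `omega_tt` (rad/s,
#'   magnitude), `ftt` (Hz), `n_features`, `fit_r2`, `method =
#'   "measured"`, and `direction` (+1/-1); or `NULL` when no reliable
#'   measurement is possible.
#' @export
measure_tanktreading <- function(crops, detection, frame_rate, pixel_size,
                                 r_max = 0.7, min_pixels = 10, min_r2 = 0.2) {
  stopifnot(is.list(crops), length(crops) >= 2)
  a_px <- detection$a_um / pixel_size
  b_px <- detection$b_um / pixel_size
  beta <- detection$beta_deg * pi / 180
  # high-pass filter: remove the static shading of the cell body so the
  # flow responds to the rotating internal texture only
  hp <- function(m) {
    m - t(EBImage::imageData(EBImage::gblur(EBImage::Image(t(m)),
                                            sigma = 5)))
  }
  crops <- lapply(crops, hp)
  rt <- list(); st <- list()
  for (i in seq_len(length(crops) - 1)) {
    im1 <- crops[[i]]; im2 <- crops[[i + 1]]
    fl <- optical_flow(im1, im2)
    nr <- nrow(im1); nc <- ncol(im1)
    cy <- (nr + 1) / 2; cx <- (nc + 1) / 2
    dy <- matrix(seq_len(nr) - cy, nr, nc)
    dx <- matrix(seq_len(nc) - cx, nr, nc, byrow = TRUE)
    # rotate into the ellipse frame and form the ellipse-corrected radius
    xr <- cos(beta) * dx + sin(beta) * dy
    yr <- -sin(beta) * dx + cos(beta) * dy
    rtil <- sqrt((xr / a_px)^2 + (yr / b_px)^2)
    r <- sqrt(dx^2 + dy^2)
    # tangential flow component (px/frame), normalized by the ellipse
    # radius r/rtil at this angle, per second
    vt <- (-fl$u * dy + fl$v * dx) / r
    s_norm <- vt * rtil / r * frame_rate
    use <- is.finite(s_norm) & rtil < r_max & rtil > 0.05
    rt[[i]] <- rtil[use]; st[[i]] <- s_norm[use]
  }
  rt <- unlist(rt); st <- unlist(st)
  if (length(rt) < min_pixels) return(NULL)
  slope <- sum(rt * st) / sum(rt * rt)
  ss_res <- sum((st - slope * rt)^2)
  ss_tot <- sum(st^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
  # zero rotation: flow is pure noise around zero -> report 0 as measured
  if (ss_tot < 1e-12 * length(st)) {
    return(structure(list(omega_tt = 0, ftt = 0, n_features = length(rt),
                          fit_r2 = 1, method = "measured", direction = 1),
                     class = "tanktread_result"))
  }
  if (r2 < min_r2) return(NULL)
  structure(list(omega_tt = abs(slope), ftt = abs(slope) / (2 * pi),
                 n_features = length(rt), fit_r2 = r2,
                 method = "measured", direction = sign(slope)),
            class = "tanktread_result")
}
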