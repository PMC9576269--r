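#' Image acquisition configuration
#'
#' @param frame_rate Frames per second, 1/s.
#' @param pixel_size Pixel size in the object plane, um/px.
#' @param roi_x Width of the imaged region along the flow direction, um.
#' @param exposure Exposure time, s (metadata only).
#' @return An object of class `acquisition_config`.
#' @export
acquisition_config <- function(frame_rate = 500, pixel_size = 0.345,
                               roi_x = 248, exposure = 30e-6) {
  .check_scalar(frame_rate, "frame_rate", positive = TRUE)
  .check_scalar(pixel_size, "pixel_size", positive = TRUE)
  .check_scalar(roi_x, "roi_x", positive = TRUE)
  structure(list(frame_rate = frame_rate, pixel_size = pixel_size,
                 roi_x = roi_x, exposure = exposure),
            class = "acquisition_config")
}

#' Segment candidate cells in a grayscale frame
#'
#' Classical segmentation intended for images where cells stand out from a
#' homogeneous background (as produced by the package's renderer and by
#' in-focus bright-field frames after normalization): the frame is
#' z-score normalized (mean subtracted, divided by the standard
#' deviation), thresholded, morphologically closed, hole-filled, and
#' split into connected components. Pipelines with their own segmentation
#' (e.g. a trained network) can instead supply detection tables directly
#' to [evaluate_cytometry()].
#'
#' @param image Numeric matrix, rows indexing y and columns indexing x.
#' @param threshold_z Threshold on the z-scored intensity.
#' @param min_area_px Minimum component area in pixels.
#' @param brush_size Diameter of the closing brush, px (odd).
#' @return A list of logical mask matrices, one per candidate cell; empty
#'   list when nothing is found.
#' @export
segment_cells <- function(image, threshold_z = 3, min_area_px = 50,
                          brush_size = 5) {
  stopifnot(is.matrix(image))
  s <- sd(image)
  if (!is.finite(s) || s == 0) return(list())
  z <- (image - mean(image)) / s
  mask <- z > threshold_z
  if (!any(mask)) return(list())
  # EBImage uses [x, y] index order; transpose in and out
  img <- EBImage::Image(t(mask))
  img <- EBImage::closing(img, EBImage::makeBrush(brush_size, shape = "disc"))
  img <- EBImage::fillHull(img)
  lab <- EBImage::bwlabel(img)
  labm <- t(EBImage::imageData(lab))
  ids <- setdiff(unique(as.vector(labm)), 0)
  out <- list()
  for (id in ids) {
    m <- labm == id
    if (sum(m) >= min_area_px) out[[length(out) + 1]] <- m
  }
  out
}

# number of lattice pixels inside the convex hull of the pixel centers:
# Pick's theorem (interior + boundary lattice points = A + B/2 + 1) so that
# solidity matches the filled-pixel convention of regionprops-style tools
.hull_area <- function(px) {
  h <- grDevices::chull(px)
  hp <- px[h, , drop = FALSE]
  n <- nrow(hp)
  if (n < 3) return(nrow(px))
  i2 <- c(2:n, 1)
  A <- abs(sum(hp[, 1] * hp[i2, 2] - hp[i2, 1] * hp[, 2])) / 2
  d <- abs(hp - hp[i2, , drop = FALSE])
  B <- sum(mapply(function(a, b) if (a == 0 && b == 0) 0 else
    .gcd(a, b), d[, 1], d[, 2]))
  A + B / 2 + 1
}

.gcd <- function(a, b) if (b == 0) a else .gcd(b, a %% b)

# contour length of a mask (8-connected chain through EBImage::ocontour)
.mask_perimeter <- function(mask) {
  oc <- EBImage::ocontour(EBImage::Image(t(mask * 1)))
  if (!length(oc)) return(NA_real_)
  ct <- oc[[1]]
  d <- sqrt(rowSums((ct - ct[c(2:nrow(ct), 1), , drop = FALSE])^2))
  sum(d)
}

#' Fit an ellipse to a binary cell mask
#'
#' Moment-based fit: the ellipse with the same second central moments as
#' the pixel set has semi-axes 2*sqrt(eigenvalues) of the pixel covariance
#' and orientation along the principal eigenvector. The orientation beta
#' is reported relative to the flow (x/column) axis, folded into
#' (-90, 90] degrees; for a near-circular mask (axis ratio within 0.1%)
#' beta is 0 by convention. Solidity (area over convex-hull area) and the
#' contour circumference are attached for downstream shape-quality
#' filtering.
#'
#' @param mask Logical matrix (single connected component), rows = y,
#'   columns = x.
#' @param pixel_size Pixel size, um/px.
#' @return A one-row data.frame with columns `x_px`, `y_px`, `a_um`,
#'   `b_um`, `beta_deg`, `solidity`, `circumference_um`, `area_px`.
#' @export
fit_ellipse <- function(mask, pixel_size = 1) {
  stopifnot(is.logical(mask) || all(mask %in% c(0, 1)))
  px <- which(mask != 0, arr.ind = TRUE)  # (row = y, col = x)
  if (nrow(px) < 5)
    stop("mask too small for an ellipse fit (needs >= 5 pixels)",
         call. = FALSE)
  ys <- px[, 1]; xs <- px[, 2]
  cx <- mean(xs); cy <- mean(ys)
  # second central moments with the 1/12 variance of a unit pixel
  cxx <- mean((xs - cx)^2) + 1 / 12
  cyy <- mean((ys - cy)^2) + 1 / 12
  cxy <- mean((xs - cx) * (ys - cy))
  ev <- eigen(matrix(c(cxx, cxy, cxy, cyy), 2, 2), symmetric = TRUE)
  a_px <- 2 * sqrt(ev$values[1])
  b_px <- 2 * sqrt(ev$values[2])
  if ((a_px - b_px) / a_px < 1e-3) {
    beta <- 0
  } else {
    beta <- atan2(ev$vectors[2, 1], ev$vectors[1, 1])
    if (beta <= -pi / 2) beta <- beta + pi
    if (beta > pi / 2) beta <- beta - pi
  }
  sol <- min(nrow(px) / .hull_area(px), 1)
  data.frame(x_px = cx, y_px = cy,
             a_um = a_px * pixel_size, b_um = b_px * pixel_size,
             beta_deg = beta * 180 / pi,
             solidity = sol,
             circumference_um = .mask_perimeter(mask) * pixel_size,
             area_px = nrow(px))
}

#' Shape-quality and position filters for cell detections
#'
#' Keeps detections that (i) have solidity >= `s_min`, (ii) have a contour
#' circumference within `c_tol` relative deviation of the fitted-ellipse
#' perimeter (both criteria reject doublets and ragged segmentations),
#' and (iii) lie at least one equivalent cell radius r_eq = sqrt(a b)
#' away from the channel center, where the stress profile is
#' non-monotonic across the cell and deformations are too small for a
#' reliable modulus. The y-coordinates must already be centered. The
#' filter is idempotent; rejection counts are attached as attribute
#' `rejections`.
#'
#' @param detections Data.frame with at least `y_um`, `a_um`, `b_um`,
#'   `solidity`, `circumference_um`.
#' @param s_min Minimum solidity.
#' @param c_tol Relative circumference tolerance.
#' @param center_exclusion Apply the one-radius center exclusion.
#' @return The filtered data.frame.
#' @export
filter_detections <- function(detections, s_min = 0.95, c_tol = 0.10,
                              center_exclusion = TRUE) {
  d <- detections
  perim <- ellipse_perimeter(d$a_um, d$b_um)
  bad_sol <- !is.na(d$solidity) & d$solidity < s_min
  bad_circ <- !is.na(d$circumference_um) &
    abs(d$circumference_um / perim - 1) > c_tol
  r_eq <- sqrt(d$a_um * d$b_um)
  bad_center <- if (center_exclusion) abs(d$y_um) < r_eq else rep(FALSE, nrow(d))
  keep <- !(bad_sol | bad_circ | bad_center)
  out <- d[keep, , drop = FALSE]
  attr(out, "rejections") <- c(solidity = sum(bad_sol),
                               circumference = sum(bad_circ),
                               center_exclusion = sum(bad_center & !bad_sol & !bad_circ))
  out
}

#' Link per-frame detections into cell tracks
#'
#' Greedy nearest-neighbor linking between consecutive frames in a
#' weighted (predicted x, y, a, b) feature space (weights 1, 4, 2, 2 in
#' um), gated by |dy| < `y_gate` so that cells crossing paths at distinct
#' lateral positions stay separate. Each track's speed is the mean
#' frame-to-frame x-displacement divided by the frame interval.
#' Detections without a partner become single-frame tracks with undefined
#' velocity.
#'
#' @param frames List of per-frame detection data.frames (columns `x_um`,
#'   `y_um`, `a_um`, `b_um`, ...), in frame order.
#' @param acq An [acquisition_config()].
#' @param y_gate Maximum |dy| between linked detections, um.
#' @param max_dist Maximum weighted distance for a link.
#' @return A list of tracks, each a list with `detections` (data.frame
#'   with added `frame` if absent) and `velocity` (m/s, `NA` for
#'   single-frame tracks).
#' @export
track_cells <- function(frames, acq, y_gate = 5,
                        max_dist = 50) {
  stopifnot(length(frames) >= 2)
  dt <- 1 / acq$frame_rate
  w <- c(x = 1, y = 4, a = 2, b = 2)
  tracks <- list()
  active <- integer(0)   # track index of each detection in previous frame
  prev <- NULL
  for (fi in seq_along(frames)) {
    cur <- frames[[fi]]
    if (is.null(cur) || NROW(cur) == 0) { prev <- NULL; active <- integer(0); next }
    if (!"frame" %in% names(cur)) cur$frame <- fi
    cur <- cur[order(cur$x_um), , drop = FALSE]
    assigned <- rep(NA_integer_, nrow(cur))
    if (!is.null(prev) && nrow(prev)) {
      # predicted x of each previous detection
      predx <- prev$x_um + vapply(active, function(ti) {
        tv <- tracks[[ti]]$velocity_um_frame
        if (is.na(tv)) 0 else tv
      }, numeric(1))
      cand <- expand.grid(i = seq_len(nrow(prev)), j = seq_len(nrow(cur)))
      dy <- abs(prev$y_um[cand$i] - cur$y_um[cand$j])
      dxs <- cur$x_um[cand$j] - predx[cand$i]
      d <- sqrt(w["x"] * dxs^2 + w["y"] * dy^2 +
                w["a"] * (prev$a_um[cand$i] - cur$a_um[cand$j])^2 +
                w["b"] * (prev$b_um[cand$i] - cur$b_um[cand$j])^2)
      ok <- dy < y_gate & d < max_dist &
        cur$x_um[cand$j] >= prev$x_um[cand$i]   # cells advect downstream
      ord <- order(d)
      used_i <- logical(nrow(prev)); used_j <- logical(nrow(cur))
      for (kk in ord) {
        if (!ok[kk]) next
        i <- cand$i[kk]; j <- cand$j[kk]
        if (used_i[i] || used_j[j]) next
        used_i[i] <- TRUE; used_j[j] <- TRUE
        ti <- active[i]
        tracks[[ti]]$detections <- rbind(tracks[[ti]]$detections, cur[j, ])
        tracks[[ti]]$velocity_um_frame <- cur$x_um[j] - prev$x_um[i]
        assigned[j] <- ti
      }
    }
    for (j in which(is.na(assigned))) {
      tracks[[length(tracks) + 1]] <- list(detections = cur[j, , drop = FALSE],
                                           velocity_um_frame = NA_real_)
      assigned[j] <- length(tracks)
    }
    prev <- cur
    active <- assigned
  }
  lapply(tracks, function(tr) {
    det <- tr$detections
    n <- nrow(det)
    vel <- if (n >= 2) {
      mean(diff(det$x_um) / (diff(det$frame) * dt)) * 1e-6  # um/s -> m/s
    } else NA_real_
    list(detections = det, velocity = vel)
  })
}

#' Write a detection/track table to CSV
#'
#' Uses the fixed pipeline column contract
#' `frame,time_s,x_um,y_um,a_um,b_um,beta_deg,solidity,circumference_um,velocity_mm_s,ftt_hz`
#' (any further columns are appended after these).
#'
#' @param detections Data.frame containing at least the contract columns.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_detections_csv <- function(detections, path) {
  miss <- setdiff(.detection_columns, names(detections))
  if (length(miss))
    stop("detection table is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  extra <- setdiff(names(detections), .detection_columns)
  write.csv(detections[, c(.detection_columns, extra)], path,
            row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a detection/track table from CSV
#'
#' @param path CSV path written by [write_detections_csv()] (or produced
#'   by an external segmentation pipeline with the same column contract).
#' @return A data.frame.
#' @export
read_detections_csv <- function(path) {
  d <- read.csv(path, check.names = FALSE)
  miss <- setdiff(.detection_columns, names(d))
  if (length(miss))
    stop("detection CSV is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  d
}
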