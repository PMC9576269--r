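#' Default pipeline configuration
#'
#' Nested list of all tunable pipeline settings with units encoded in the
#' field names. Matches the reference experimental conditions: a 200 x
#' 200 um, 5.8 cm channel driven at 200 kPa, imaged at 500 Hz with
#' 0.345 um pixels over a 248 um wide region of interest.
#'
#' @return A nested configuration list.
#' @export
default_config <- function() {
  list(
    channel = list(width_um = 200, height_um = 200, length_um = 58000),
    pressure_pa = 2e5,
    acquisition = list(frame_rate_hz = 500, pixel_size_um = 0.345,
                       roi_x_um = 248, exposure_s = 30e-6),
    filters = list(solidity_min = 0.95, circumference_tol = 0.10,
                   center_exclusion = TRUE),
    segmentation = list(threshold_z = 3, min_area_px = 50),
    tanktreading = list(r_max = 0.7, min_pixels = 10, min_r2 = 0.2),
    seed = 1L
  )
}

#' Read a pipeline configuration from YAML
#'
#' Fields absent from the file fall back to [default_config()].
#'
#' @param path YAML file path.
#' @return A configuration list.
#' @export
read_config <- function(path) {
  utils::modifyList(default_config(), yaml::read_yaml(path))
}

.config_geometry <- function(config) {
  channel_geometry(config$channel$width_um * 1e-6,
                   config$channel$height_um * 1e-6,
                   config$channel$length_um * 1e-6)
}

.config_acq <- function(config) {
  acquisition_config(config$acquisition$frame_rate_hz,
                     config$acquisition$pixel_size_um,
                     config$acquisition$roi_x_um,
                     config$acquisition$exposure_s)
}

#' Detect and track cells in an image stack
#'
#' Runs segmentation, ellipse fitting, and frame-to-frame tracking on a
#' grayscale image stack and measures each track's tank-treading rotation
#' by optical flow on crops around the cell. Produces a detection table
#' in the pipeline CSV schema with raw (uncentered) y-coordinates.
#'
#' @param stack Numeric array `[rows, cols, frames]` or a multi-page TIFF
#'   path.
#' @param config Pipeline configuration, see [default_config()].
#' @return A detection-schema data.frame (one row per detection that
#'   belongs to a track; velocity and ftt are per-track values).
#' @export
detect_cells <- function(stack, config = default_config()) {
  if (is.character(stack)) {
    pages <- tiff::readTIFF(stack, all = TRUE)
    stack <- array(unlist(pages), c(dim(pages[[1]])[1], dim(pages[[1]])[2],
                                    length(pages)))
  }
  stopifnot(length(dim(stack)) == 3)
  acq <- .config_acq(config)
  ps <- acq$pixel_size
  nr <- dim(stack)[1]
  n_frames <- dim(stack)[3]
  frames <- vector("list", n_frames)
  for (fi in seq_len(n_frames)) {
    masks <- segment_cells(stack[, , fi],
                           threshold_z = config$segmentation$threshold_z,
                           min_area_px = config$segmentation$min_area_px)
    dets <- lapply(masks, function(m)
      tryCatch(fit_ellipse(m, ps), error = function(e) NULL))
    dets <- do.call(rbind, dets[!vapply(dets, is.null, logical(1))])
    if (!is.null(dets) && nrow(dets)) {
      dets$frame <- fi
      dets$time_s <- (fi - 1) / acq$frame_rate
      dets$x_um <- dets$x_px * ps
      dets$y_um <- (dets$y_px - nr / 2) * ps   # raw; centered later by the fit
    }
    frames[[fi]] <- dets
  }
  if (all(vapply(frames, function(f) is.null(f) || !nrow(f), logical(1))))
    stop("no cells detected in any frame", call. = FALSE)
  tracks <- track_cells(frames, acq)
  rows <- list()
  for (tr in tracks) {
    det <- tr$detections
    ftt <- NA_real_
    if (nrow(det) >= 2 && is.finite(tr$velocity)) {
      crops <- .extract_crops(stack, det, ps)
      tt <- tryCatch(
        measure_tanktreading(crops, det[1, ], acq$frame_rate, ps,
                             r_max = config$tanktreading$r_max,
                             min_pixels = config$tanktreading$min_pixels,
                             min_r2 = config$tanktreading$min_r2),
        error = function(e) NULL)
      if (!is.null(tt)) ftt <- tt$ftt
    }
    det$velocity_mm_s <- tr$velocity * 1e3
    det$ftt_hz <- ftt
    rows[[length(rows) + 1]] <- det
  }
  out <- do.call(rbind, rows)
  out[, c(.detection_columns, setdiff(names(out), .detection_columns))]
}

# square crops centered on a tracked cell, one per detection
.extract_crops <- function(stack, det, pixel_size) {
  half <- ceiling(1.3 * max(det$a_um) / pixel_size)
  nr <- dim(stack)[1]; nc <- dim(stack)[2]
  crops <- list()
  for (i in seq_len(nrow(det))) {
    cy <- round(det$y_px[i]); cx <- round(det$x_px[i])
    r <- (cy - half):(cy + half); cl <- (cx - half):(cx + half)
    if (min(r) < 1 || max(r) > nr || min(cl) < 1 || max(cl) > nc) next
    crops[[length(crops) + 1]] <- stack[r, cl, det$frame[i]]
  }
  crops
}

#' Run the full evaluation pipeline
#'
#' Executes, in order: load/detect cells; find the channel center line
#' from the speed profile; apply shape-quality and center-exclusion
#' filters; fit the suspension-fluid rheology (Cross model) to the speed
#' profile; compute per-cell shear stress, shear rate and viscosity;
#' take the measured tank-treading frequency or fall back to the
#' shear-rate prediction; compute strain, G' and G'' from the shape and
#' alignment angle; scale to stiffness k and fluidity alpha at 1 Hz; and
#' summarize the population by the 2-D kernel-density mode. Every input
#' row is retained in the output with a validity flag and, when invalid,
#' a machine-readable reason code.
#'
#' @param input A detection-schema data.frame, a detection CSV path, a
#'   TIFF path, or an image array `[rows, cols, frames]`.
#' @param config Pipeline configuration, see [default_config()].
#' @return A list of class `cytometry_result` with elements `cells`
#'   (per-cell table with appended result columns), `fluid`
#'   ([cross_model()] fit), `centerline` ([fit_centerline()] result),
#'   `summary` (list with `mode_k_pa`, `mode_alpha`, `n_valid`), and
#'   `counts` (named rejection counts).
#' @export
evaluate_cytometry <- function(input, config = default_config()) {
  if (is.character(input)) {
    input <- if (grepl("\\.(tif|tiff)$", input, ignore.case = TRUE))
      detect_cells(input, config) else read_detections_csv(input)
  } else if (is.array(input) && length(dim(input)) == 3) {
    input <- detect_cells(input, config)
  }
  det <- as.data.frame(input)
  if (!nrow(det)) stop("empty input: no detections to evaluate", call. = FALSE)
  miss <- setdiff(.detection_columns, names(det))
  if (length(miss))
    stop("detection table is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)

  geometry <- .config_geometry(config)
  W <- geometry$width
  acq <- .config_acq(config)

  # --- channel centering from the speed profile -------------------------
  hasv <- is.finite(det$velocity_mm_s)
  cl <- fit_centerline(det$y_um[hasv] * 1e-6, det$velocity_mm_s[hasv] * 1e-3,
                       W)
  det$y_um <- det$y_um - cl$yc * 1e6
  check_frame_rate(acq$frame_rate, cl$vmax, acq$roi_x * 1e-6)

  # --- shape-quality and position filters -------------------------------
  perim <- ellipse_perimeter(det$a_um, det$b_um)
  r_eq <- sqrt(det$a_um * det$b_um)
  reason <- rep("", nrow(det))
  fl <- config$filters
  reason[is.finite(det$solidity) & det$solidity < fl$solidity_min] <- "low_solidity"
  circ_bad <- is.finite(det$circumference_um) &
    abs(det$circumference_um / perim - 1) > fl$circumference_tol
  reason[reason == "" & circ_bad] <- "circumference_mismatch"
  if (isTRUE(fl$center_exclusion))
    reason[reason == "" & abs(det$y_um) < r_eq] <- "center_exclusion"

  # --- suspension-fluid rheology from the speed profile -----------------
  fit_rows <- hasv & reason == ""
  if (sum(fit_rows) < 20) fit_rows <- hasv
  fluid <- fit_fluid_rheology(det$y_um[fit_rows] * 1e-6,
                              det$velocity_mm_s[fit_rows] * 1e-3,
                              geometry, config$pressure_pa)
  state <- channel_state(geometry, config$pressure_pa, fluid)

  # --- per-cell fields and moduli ---------------------------------------
  y_m <- pmin(pmax(det$y_um * 1e-6, -W / 2), W / 2)
  sigma <- shear_stress(state, y_m)
  gdot <- solve_shear_rate(fluid, sigma)
  eta <- viscosity(fluid, gdot)
  ftt <- det$ftt_hz
  ftt_method <- ifelse(is.finite(ftt), "measured", "predicted")
  ftt[!is.finite(ftt)] <- predict_tanktreading(gdot[!is.finite(ftt)]) / (2 * pi)
  omega <- 2 * 2 * pi * ftt

  n <- nrow(det)
  strain <- Gp <- Gpp <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (reason[i] != "") next
    if (!is.finite(det$a_um[i]) || !is.finite(det$b_um[i]) ||
        det$a_um[i] <= 0 || det$b_um[i] <= 0) { reason[i] <- "bad_axes"; next }
    sh <- normalize_shape(det$a_um[i], det$b_um[i])
    beta <- abs(det$beta_deg[i]) * pi / 180
    if (sh$swapped) beta <- abs(pi / 2 - beta)
    fc <- shape_factors(sh)
    strain[i] <- cell_strain(sh, fc)
    Gp[i] <- storage_modulus(sigma[i], beta, strain[i])
    if (is.na(Gp[i])) { reason[i] <- "invalid_strain_or_angle"; next }
    Gpp[i] <- loss_modulus(sh, fc, beta, eta[i], gdot[i])
    if (is.na(Gpp[i])) { reason[i] <- "invalid_loss_modulus"; next }
  }
  sc <- scale_to_reference(Gp, Gpp, omega)
  valid <- reason == "" & is.finite(sc$k) & is.finite(sc$alpha)
  reason[reason == "" & !valid] <- "scaling_failed"

  det$stress_pa <- sigma
  det$shear_rate_1_s <- gdot
  det$viscosity_pa_s <- eta
  det$strain <- strain
  det$omega_rad_s <- omega
  det$Gp_pa <- Gp
  det$Gpp_pa <- Gpp
  det$k_pa <- sc$k
  det$alpha <- sc$alpha
  det$valid_flag <- valid
  det$ftt_method <- ftt_method
  det$invalid_reason <- reason

  if (!any(valid))
    stop("zero valid cells after filtering; cannot summarize the population",
         call. = FALSE)
  summary <- population_mode(det$k_pa[valid], det$alpha[valid])
  counts <- table(factor(reason[reason != ""]))
  message(sprintf("evaluated %d detections: %d valid, %d rejected (%s)",
                  n, sum(valid), sum(!valid),
                  paste(names(counts), as.integer(counts),
                        sep = "=", collapse = ", ")))
  structure(list(cells = det, fluid = fluid, centerline = cl,
                 summary = list(mode_k_pa = summary$mode_k,
                                mode_alpha = summary$mode_alpha,
                                n_valid = summary$n_valid),
                 counts = counts),
            class = "cytometry_result")
}

#' Fit the suspension-fluid rheology from a detection table
#'
#' Thin wrapper: centers the y-coordinates via the centerline fit, then
#' fits the Cross model to the (y, v) profile.
#'
#' @param input Detection-schema data.frame or CSV path (must contain
#'   `y_um` and `velocity_mm_s`).
#' @param config Pipeline configuration.
#' @return A [cross_model()] with fit attributes (see
#'   [fit_fluid_rheology()]).
#' @export
fit_fluid <- function(input, config = default_config()) {
  det <- if (is.character(input)) read.csv(input, check.names = FALSE) else
    as.data.frame(input)
  if (!all(c("y_um", "velocity_mm_s") %in% names(det)))
    stop("input must contain 'y_um' and 'velocity_mm_s' columns",
         call. = FALSE)
  keep <- is.finite(det$y_um) & is.finite(det$velocity_mm_s)
  geometry <- .config_geometry(config)
  cl <- fit_centerline(det$y_um[keep] * 1e-6, det$velocity_mm_s[keep] * 1e-3,
                       geometry$width)
  fit_fluid_rheology((det$y_um[keep] - cl$yc * 1e6) * 1e-6,
                     det$velocity_mm_s[keep] * 1e-3,
                     geometry, config$pressure_pa)
}

#' Write pipeline results to disk
#'
#' @param result A `cytometry_result` from [evaluate_cytometry()].
#' @param csv_path Per-cell results CSV path (detection schema plus the
#'   appended result columns).
#' @param json_path Summary JSON path
#'   (`{"mode_k_pa":..., "mode_alpha":..., "n_valid":...}`).
#' @return `result`, invisibly.
#' @export
write_results <- function(result, csv_path = NULL, json_path = NULL) {
  stopifnot(inherits(result, "cytometry_result"))
  if (!is.null(csv_path)) {
    cols <- c(.detection_columns, .result_columns, "ftt_method",
              "invalid_reason")
    write.csv(result$cells[, cols], csv_path, row.names = FALSE, quote = FALSE)
  }
  if (!is.null(json_path))
    writeLines(jsonlite::toJSON(result$summary, auto_unbox = TRUE,
                                digits = NA), json_path)
  invisible(result)
}

#' @export
print.cytometry_result <- function(x, ...) {
  cat("Shear flow deformation cytometry result\n")
  cat(sprintf("  cells: %d evaluated, %d valid\n", nrow(x$cells),
              x$summary$n_valid))
  cat(sprintf("  fluid: eta0 = %.3g Pa s, tau = %.3g s, delta = %.3g\n",
              x$fluid$eta0, x$fluid$tau, x$fluid$delta))
  cat(sprintf("  population mode: k = %.3g Pa, alpha = %.3g\n",
              x$summary$mode_k_pa, x$summary$mode_alpha))
  invisible(x)
}
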