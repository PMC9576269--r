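# 5-point Gauss-Legendre nodes/weights on [-1, 1]
.gl5_nodes <- c(-0.906179845938664, -0.538469310105683, 0,
                0.538469310105683, 0.906179845938664)
.gl5_weights <- c(0.236926885056189, 0.478628670499366, 0.568888888888889,
                  0.478628670499366, 0.236926885056189)

#' Perimeter of an ellipse
#'
#' Ramanujan's second approximation, accurate to better than 1e-6 relative
#' for axis ratios up to 20.
#'
#' @param a,b Semi-major and semi-minor axis (same length unit).
#' @return Perimeter in the same unit.
#' @export
ellipse_perimeter <- function(a, b) {
  h <- ((a - b) / (a + b))^2
  pi * (a + b) * (1 + 3 * h / (10 + sqrt(4 - 3 * h)))
}

# assert a single finite number
.check_scalar <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("'%s' must be > 0", name), call. = FALSE)
  if (nonneg && x < 0)
    stop(sprintf("'%s' must be >= 0", name), call. = FALSE)
  invisible(x)
}

# canonical detection-table column order (pipeline contract)
.detection_columns <- c("frame", "time_s", "x_um", "y_um", "a_um", "b_um",
                        "beta_deg", "solidity", "circumference_um",
                        "velocity_mm_s", "ftt_hz")

# per-cell result columns appended by the evaluation pipeline
.result_columns <- c("stress_pa", "shear_rate_1_s", "viscosity_pa_s",
                     "strain", "omega_rad_s", "Gp_pa", "Gpp_pa",
                     "k_pa", "alpha", "valid_flag")
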