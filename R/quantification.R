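# Population densities from endpoint serial-dilution cultivation and from
# filter microscopy counts.  The dilution estimator follows the documented
# convention for single-tube-per-step series: the sample slurry (about
# 0.5 g sediment in 5 mL, i.e. a 10x dilution assuming 1 g ~ 1 mL) is
# carried through transfers of 0.5 mL into 5 mL (an 11x step), and the
# density is read off the highest dilution step that still shows growth.

#' Population density from an endpoint serial-dilution series
#'
#' Under the documented convention the tube at step k holds the slurry
#' diluted by `step_factor^k`, and a step is positive when at least one
#' organism entered its inoculum volume.  The detection-limit density of
#' step k is therefore `step_factor^k * slurry_dilution / v_inoculum_mL`
#' (cells per mL of original sediment), and the estimate is that quantity at
#' the highest positive step.  An all-negative series is below detection;
#' the detection limit (the k = 0 value) is reported instead.
#'
#' @param positives logical vector, one entry per dilution step in order of
#'   increasing dilution.  Non-monotone patterns (a negative step followed
#'   by a positive one) raise a warning and the highest positive is used.
#' @param step_factor dilution per transfer (default 11: 0.5 mL into 5 mL).
#' @param v_inoculum_mL volume transferred per step (default 0.5 mL).
#' @param slurry_dilution sediment-to-slurry dilution (default 10: 0.5 g in
#'   5 mL, taking 1 g of sediment as 1 mL).
#' @return list with `density` (cells per mL sediment; `NA` when below
#'   detection), `below_detection` (logical), `detection_limit`, and
#'   `k` (highest positive step, 0 when none).
#' @examples
#' endpoint_dilution_density(c(TRUE, TRUE, TRUE, FALSE, FALSE))
#' @export
endpoint_dilution_density <- function(positives, step_factor = 11,
                                      v_inoculum_mL = 0.5,
                                      slurry_dilution = 10) {
  if (!is.logical(positives) || !length(positives)) {
    stop("positives must be a nonempty logical vector", call. = FALSE)
  }
  if (step_factor <= 1) stop("step_factor must exceed 1", call. = FALSE)
  if (v_inoculum_mL <= 0 || slurry_dilution <= 0) {
    stop("volumes and dilutions must be positive", call. = FALSE)
  }
  k <- if (any(positives)) max(which(positives)) else 0L
  if (k > 0 && any(!positives[seq_len(k)])) {
    warning("non-monotone positivity pattern; using the highest positive step")
  }
  density_at <- function(kk) step_factor^kk * slurry_dilution / v_inoculum_mL
  if (k == 0L) {
    list(density = NA_real_, below_detection = TRUE,
         detection_limit = density_at(0), k = 0L)
  } else {
    list(density = density_at(k), below_detection = FALSE,
         detection_limit = density_at(0), k = k)
  }
}

#' Cell density from filter microscopy counts
#'
#' density = mean count per field * (filtration area / field area) /
#' volume filtered * dilution factor.  Fewer than 100 counted fields raises
#' a warning, reflecting the usual precision convention for total counts.
#'
#' @param mean_count_per_field mean cells per microscopic field (>= 0).
#' @param field_area_mm2 area of one field (mm^2, > 0).
#' @param filtration_area_mm2 filtered membrane area (mm^2, > 0).
#' @param volume_mL sample volume filtered (mL, > 0).
#' @param dilution_factor dilution applied before filtration (default 1).
#' @param n_fields number of fields counted.
#' @return cells per mL.
#' @examples
#' cell_density_from_counts(20, 0.01, 200, 0.1, dilution_factor = 10,
#'                          n_fields = 120)
#' @export
cell_density_from_counts <- function(mean_count_per_field, field_area_mm2,
                                     filtration_area_mm2, volume_mL,
                                     dilution_factor = 1, n_fields = 100) {
  if (field_area_mm2 <= 0 || filtration_area_mm2 <= 0 || volume_mL <= 0 ||
      dilution_factor <= 0) {
    stop("areas, volume and dilution factor must be positive", call. = FALSE)
  }
  if (mean_count_per_field < 0) stop("count must be >= 0", call. = FALSE)
  if (n_fields < 1) stop("n_fields must be >= 1", call. = FALSE)
  if (n_fields < 100) {
    warning("fewer than 100 microscopic fields counted; estimate may be imprecise")
  }
  mean_count_per_field * (filtration_area_mm2 / field_area_mm2) /
    volume_mL * dilution_factor
}
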