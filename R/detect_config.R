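# Detector parameters. Every tunable lives here (a config object, not
# constants); the defaults were calibrated on the synthetic suite at the
# generator's default contrast — calibration runs are described in the
# methods vignette.

#' Detector parameters
#'
#' @param spot list: `diameters_um` (Laplacian-of-Gaussian scale ladder,
#'   matched to the 1-3 um punctuate class), `z_threshold` (detection
#'   threshold in robust response-noise units), `min_response` (absolute
#'   response floor in gray units, guarding noiseless frames where the
#'   robust noise estimate collapses to quantization ripple), `diameter_tol_px` (slack on
#'   the 1-3 um class bounds), `min_sep_factor` (non-maximum suppression
#'   radius as a fraction of the mean diameter), `highpass_sigma_px`
#'   (background-flattening high-pass composed with the LoG so diffuse
#'   autofluorescence and cell bodies stay out of the blob band).
#' @param cell list: `smooth_sigma_px`, `z_threshold` (robust units of the
#'   smoothed frame), `min_diameter_um` (components at or below this are
#'   punctuate, not cells), `boundary_um` (small/large split; >= goes to
#'   large), `max_aspect` (beyond this a component is fiber-like, not a
#'   cell), `granularity_floor` (minimum internal coefficient of variation
#'   for a large cell), `round_cv_max` and `round_contrast_max_sigma`
#'   (components more homogeneous and dimmer than this are round-structure
#'   candidates, not cells).
#' @param fiber list: `downsample`, `sigmas_px` (ridge scale ladder on the
#'   downsampled grid, matched to 1-4 um widths), `z_threshold`,
#'   `min_length_um`, `prune_um` (spurs shorter than this are ignored),
#'   `min_aspect`, `max_width_um`.
#' @param round list: `downsample`, `radii_um` (blob scale ladder for the
#'   10-60 um class), `z_threshold`, `cv_max` (homogeneity ceiling),
#'   `contrast_range_sigma` (mean intensity window, in background-noise
#'   units: above the noise floor, below cell-level brightness),
#'   `diameter_range_um`.
#' @param diffuse list: `downsample`, `smooth_sigma` (on the downsampled
#'   grid), `floor_quantile`, `threshold_frac_sigma` (threshold over the
#'   floor as a fraction of the pixel noise s.d.), `coverage_flag`
#'   (flag when coverage reaches this fraction of the field of view),
#'   `mask_dilate_um` (margin added around detected objects before
#'   computing the residual).
#' @param overrides optional named list of replacements (e.g. parsed from a
#'   JSON config file).
#' @return Nested list of detector parameters.
#' @export
detect_config <- function(
    spot = list(diameters_um = c(1, 1.7, 3),
                z_threshold = 10, min_response = 3, highpass_sigma_px = 12,
                diameter_tol_px = 1, min_sep_factor = 0.6),
    cell = list(smooth_sigma_px = 2, z_threshold = 12, min_diameter_um = 3,
                boundary_um = 25, max_aspect = 4, granularity_floor = 0.05,
                round_cv_max = 0.16, round_contrast_max_sigma = 6),
    fiber = list(downsample = 2L, sigmas_px = c(1.5, 2.5, 4),
                 z_threshold = 20, min_response = 1.5, min_length_um = 25,
                 prune_um = 10, min_aspect = 5, max_width_um = 5),
    round = list(downsample = 4L, radii_um = c(5, 7, 10, 14, 20, 25, 30),
                 z_threshold = 6, min_response = 3, cv_max = 0.16,
                 contrast_range_sigma = c(1.2, 6),
                 diameter_range_um = c(10, 60)),
    diffuse = list(downsample = 8L, smooth_sigma = 12, floor_quantile = 0.02,
                   threshold_frac_sigma = 0.08, coverage_flag = 0.5,
                   mask_dilate_um = 2),
    overrides = NULL) {
  cfg <- list(spot = spot, cell = cell, fiber = fiber, round = round,
              diffuse = diffuse)
  if (!is.null(overrides)) cfg <- utils::modifyList(cfg, overrides)
  cfg
}

# Empty detections table shared by all detectors.
empty_detections <- function() {
  data.frame(class = character(0), y_um = numeric(0), x_um = numeric(0),
             equivalent_diameter_um = numeric(0), length_um = numeric(0),
             width_um = numeric(0), mean_intensity = numeric(0),
             internal_cv = numeric(0), response = numeric(0),
             stringsAsFactors = FALSE)
}

detection_row <- function(class, y_um, x_um, diameter_um = NA_real_,
                          length_um = NA_real_, width_um = NA_real_,
                          mean_intensity = NA_real_, internal_cv = NA_real_,
                          response = NA_real_) {
  data.frame(class = class, y_um = y_um, x_um = x_um,
             equivalent_diameter_um = diameter_um, length_um = length_um,
             width_um = width_um, mean_intensity = mean_intensity,
             internal_cv = internal_cv, response = response,
             stringsAsFactors = FALSE)
}
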