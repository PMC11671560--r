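# Cells with fluorescent cytoplasm: intensity segmentation of the smoothed
# frame, connected components, hole filling, equivalent diameter from area.
# Components at or below 3 um belong to the punctuate class; (3, 25) um are
# small cells; >= 25 um with granular interiors are large cells (the
# boundary itself assigns to large). Fiber-like (elongated) and
# round-structure-like (homogeneous, weak) components are rejected here and
# left to their own detectors.

# Diameter routing at the small/large boundary: >= 25 um is a large cell
# (the boundary itself assigns to large).
cell_size_class <- function(eq_d_um, boundary_um = 25) {
  ifelse(eq_d_um >= boundary_um, "large_cell", "small_cell")
}

#' Detect cells with fluorescent cytoplasm
#'
#' @param image a `cle_field_image` (should have passed QC).
#' @param params a [detect_config()].
#' @return Detections data frame with classes `"small_cell"` /
#'   `"large_cell"`: centroid (um), equivalent diameter (um), mean
#'   intensity above background, internal coefficient of variation.
#' @export
detect_cells <- function(image, params = detect_config(), .ctx = NULL) {
  stopifnot(inherits(image, "cle_field_image"))
  p <- params$cell
  psz <- image$pixel_size_um
  px <- image$pixels
  rs <- if (is.null(.ctx)) robust_stats(px) else .ctx$rs
  x <- if (is.null(.ctx)) {
    matrix(as.numeric(px) - rs$median, nrow(px), ncol(px))
  } else .ctx$x
  xs <- fft_filter(x, otf_gaussian(nrow(x), ncol(x), p$smooth_sigma_px))
  # pixel noise from single-pixel differences (objects barely contribute),
  # propagated through the smoothing kernel; a quantile guard lifts the
  # threshold above any broad diffuse component without tracking the cells
  # themselves
  sigma_n <- robust_stats(x - shift_matrix(x, 0, 1))$sigma / sqrt(2)
  sigma_sn <- sigma_n / (2 * sqrt(pi) * p$smooth_sigma_px)
  thr <- max(p$z_threshold * sigma_sn,
             stats::quantile(xs[seq(1, length(xs), by = 7)], 0.95) +
               0.5 * p$z_threshold * sigma_sn)
  mask <- xs > thr
  mask <- EBImage::fillHull(mask)
  lab <- EBImage::bwlabel(mask)
  n_obj <- max(lab)
  if (n_obj == 0) return(empty_detections())
  shp <- EBImage::computeFeatures.shape(lab)
  mom <- EBImage::computeFeatures.moment(lab, x)
  idx <- which(lab > 0)
  vals_by_lab <- split(xs[idx], lab[idx])
  out <- empty_detections()
  for (i in seq_len(n_obj)) {
    area <- shp[i, "s.area"]
    eq_d <- 2 * sqrt(area / pi) * psz
    if (eq_d <= p$min_diameter_um + psz) next      # punctuate, not a cell
    major <- mom[i, "m.majoraxis"]
    ecc <- mom[i, "m.eccentricity"]
    minor <- major * sqrt(pmax(1 - ecc^2, 1e-6))
    if (major / max(minor, 1e-6) > p$max_aspect) next   # fiber-like
    vals <- vals_by_lab[[as.character(i)]]
    m <- mean(vals)
    cv <- stats::sd(vals) / max(abs(m), 1e-9)
    # homogeneous interior: round-structure candidate, not a cell (cells
    # are identified by granular/diffuse cytoplasmic texture)
    if (cv <= p$round_cv_max) next
    cls <- cell_size_class(eq_d, p$boundary_um)
    if (cls == "large_cell" && cv < p$granularity_floor) next
    # EBImage treats the first matrix dimension as x: m.cx is our row
    out <- rbind(out, detection_row(cls,
                                    y_um = px_to_um(mom[i, "m.cx"] + 0, psz),
                                    x_um = px_to_um(mom[i, "m.cy"] + 0, psz),
                                    diameter_um = eq_d,
                                    mean_intensity = m, internal_cv = cv))
  }
  out
}
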