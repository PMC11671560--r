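# Diffuse autofluorescence: low-spatial-frequency residual of the frame
# after masking detected discrete objects, compared against what pixel
# noise alone would produce at that smoothing scale.

#' Detect diffuse autofluorescence
#'
#' The frame (minus its robust background level) is heavily smoothed on a
#' downsampled grid using normalized convolution so that masked object
#' pixels do not contribute. The smoothed field is referenced to its own
#' robust floor (a low quantile); coverage is the fraction of the field of
#' view where the residual exceeds a threshold set well above the noise
#' level expected from pixel noise after this much averaging. The diffuse
#' flag is raised when coverage reaches `coverage_flag` (default half the
#' field of view).
#'
#' @param image a `cle_field_image` (should have passed QC).
#' @param params a [detect_config()].
#' @param object_mask optional logical matrix (frame-sized): pixels of
#'   detected discrete objects, excluded from the residual. Normally built
#'   by [detect_features()] from the other detectors' output.
#' @return List with `flag` (logical), `coverage` (fraction of FOV) and
#'   `threshold` (gray units over the floor).
#' @export
detect_diffuse <- function(image, params = detect_config(), object_mask = NULL,
                           .ctx = NULL) {
  stopifnot(inherits(image, "cle_field_image"))
  p <- params$diffuse
  px <- image$pixels
  rs <- if (is.null(.ctx)) robust_stats(px) else .ctx$rs
  x <- if (is.null(.ctx)) {
    matrix(as.numeric(px) - rs$median, nrow(px), ncol(px))
  } else .ctx$x
  f <- p$downsample
  w <- if (is.null(object_mask)) {
    matrix(1, nrow(x), ncol(x))
  } else {
    1 - (object_mask * 1)
  }
  xd <- downsample(x * w, f)
  wd <- downsample(w, f)
  otf <- otf_gaussian(nrow(xd), ncol(xd), p$smooth_sigma)
  num <- fft_filter(xd, otf)
  den <- pmax(fft_filter(wd, otf), 0.05)
  sm <- num / den
  # pixel noise -> smoothed-field noise: block mean over f^2 px, then a
  # Gaussian with effective area 4*pi*sigma^2
  sigma_sm <- rs$sigma / f / sqrt(4 * pi * p$smooth_sigma^2)
  floor_lvl <- stats::quantile(sm, p$floor_quantile)
  thr <- max(6 * sigma_sm, p$threshold_frac_sigma * rs$sigma)
  coverage <- mean(sm - floor_lvl > thr)
  list(flag = coverage >= p$coverage_flag, coverage = unname(coverage),
       threshold = unname(thr))
}
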