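# Scene specification for the synthetic CLE frame generator.
#
# The generator emulates the appearance of label-free CLE autofluorescence
# frames of brain tissue: punctuate granules (1-3 um), cells with fluorescent
# cytoplasm (small < 25 um, large >= 25 um), autofluorescent fibers, weakly
# fluorescent round structures (10-60 um, psammoma-body-like), diffuse
# low-spatial-frequency autofluorescence with negative-contrast silhouettes,
# and a filter-dependent background offset (longpass admits more background
# than bandpass). Noise is detector-dominated: gain-scaled Poisson shot noise
# plus Gaussian read noise.

#' CLE frame geometry constants
#'
#' The device scans a 267 x 475 um field of view onto 1920 x 1080 pixels;
#' the two printed axis ratios agree to < 0.1%, so square pixels of
#' 475/1920 um are used.
#'
#' @format A list with elements `nrow` (1080), `ncol` (1920),
#'   `pixel_size_um` (475/1920), `fov_um` (c(267.2, 475)).
#' @export
cle_geometry <- function() {
  px <- 475 / 1920
  list(nrow = 1080L, ncol = 1920L, pixel_size_um = px,
       fov_um = c(1080 * px, 475))
}

#' Specify a synthetic CLE scene
#'
#' All lengths are in micrometers, intensities in 16-bit gray units. Object
#' peak amplitudes are expressed in units of the bandpass background noise
#' standard deviation (`object_contrast`), so detectability is controlled
#' directly. Defaults describe a detector-noise-dominated acquisition: the
#' shot-noise gain is small relative to the read noise, matching the strong,
#' spatially white noise of high-gain clinical CLE autofluorescence frames.
#'
#' @param n_spots number of punctuate signals (diameters in `spot_diameter_um`).
#' @param spot_diameter_um length-2 range within \[1, 3\] um.
#' @param n_small_cells number of fluorescent-cytoplasm cells with diameters
#'   drawn in `small_cell_diameter_um` (inside (3, 25) um).
#' @param n_large_cells number of cells with diameters drawn in
#'   `large_cell_diameter_um` (>= 25 um).
#' @param small_cell_diameter_um,large_cell_diameter_um diameter ranges (um).
#' @param n_fibers number of curvilinear autofluorescent fibers.
#' @param fiber_length_um,fiber_width_um fiber geometry ranges (um).
#' @param n_round number of weakly fluorescent homogeneous round structures,
#'   diameters drawn in `round_diameter_um` (inside \[10, 60\] um).
#' @param round_diameter_um diameter range (um).
#' @param n_vessels number of dark (negative-contrast) curvilinear vessels.
#' @param diffuse_level mean diffuse autofluorescence level (gray units);
#'   0 disables the diffuse component.
#' @param bp_background bandpass background level (gray units).
#' @param lp_background_offset extra longpass background (gray units, >= 0).
#' @param object_contrast peak-above-background amplitude in units of the
#'   bandpass background noise s.d.
#' @param round_contrast_frac round structures render at this fraction of
#'   `object_contrast` (they are weakly fluorescent).
#' @param noise list with `poisson_scale` (shot-noise gain, gray units per
#'   photoelectron; 0 disables shot noise) and `read_sigma` (Gaussian read
#'   noise s.d., gray units).
#' @param autobrightness_target target frame mean for the autobrightness
#'   emulation ([emulate_autobrightness()]); `NA` (default) leaves renders on
#'   their physical scale.
#' @param seed integer scene seed; all object placement derives from it.
#' @return An object of class `cle_scene_spec`.
#' @seealso [render_scene()], [render_pair()], [random_scene_spec()]
#' @export
scene_spec <- function(n_spots = 0, spot_diameter_um = c(1, 3),
                       n_small_cells = 0, small_cell_diameter_um = c(8, 18),
                       n_large_cells = 0, large_cell_diameter_um = c(28, 45),
                       n_fibers = 0, fiber_length_um = c(60, 150),
                       fiber_width_um = c(1.5, 3.5),
                       n_round = 0, round_diameter_um = c(15, 50),
                       n_vessels = 0,
                       diffuse_level = 0,
                       bp_background = 500, lp_background_offset = 200,
                       object_contrast = 8, round_contrast_frac = 0.45,
                       noise = list(poisson_scale = 0.05, read_sigma = 30),
                       autobrightness_target = NA_real_,
                       seed = 1L) {
  spec <- list(
    n_spots = as.integer(n_spots), spot_diameter_um = spot_diameter_um,
    n_small_cells = as.integer(n_small_cells),
    small_cell_diameter_um = small_cell_diameter_um,
    n_large_cells = as.integer(n_large_cells),
    large_cell_diameter_um = large_cell_diameter_um,
    n_fibers = as.integer(n_fibers), fiber_length_um = fiber_length_um,
    fiber_width_um = fiber_width_um,
    n_round = as.integer(n_round), round_diameter_um = round_diameter_um,
    n_vessels = as.integer(n_vessels),
    diffuse_level = diffuse_level,
    bp_background = bp_background,
    lp_background_offset = lp_background_offset,
    object_contrast = object_contrast,
    round_contrast_frac = round_contrast_frac,
    noise = noise,
    autobrightness_target = autobrightness_target,
    seed = as.integer(seed))
  class(spec) <- "cle_scene_spec"
  validate_scene_spec(spec)
  spec
}

#' Validate a scene specification
#'
#' Checks counts, class-specific diameter bounds, non-negative background
#' offset, and that the requested object footprint fits the field of view
#' (a packing error otherwise).
#'
#' @param spec a `cle_scene_spec`.
#' @return `spec`, invisibly, if valid; otherwise an error is thrown.
#' @export
validate_scene_spec <- function(spec) {
  stopifnot(inherits(spec, "cle_scene_spec"))
  counts <- c(spec$n_spots, spec$n_small_cells, spec$n_large_cells,
              spec$n_fibers, spec$n_round, spec$n_vessels)
  if (any(counts < 0)) stop("object counts must be >= 0")
  chk_range <- function(r, lo, hi, what, lo_open = FALSE) {
    if (length(r) != 2 || r[1] > r[2]) stop(what, ": invalid range")
    bad_lo <- if (lo_open) r[1] <= lo else r[1] < lo
    if (bad_lo || r[2] > hi) {
      stop(sprintf("%s range [%g, %g] outside class bounds (%g, %g]",
                   what, r[1], r[2], lo, hi))
    }
  }
  chk_range(spec$spot_diameter_um, 1, 3, "spot diameter")
  chk_range(spec$small_cell_diameter_um, 3, 25 - 1e-9, "small cell diameter",
            lo_open = TRUE)
  if (spec$large_cell_diameter_um[1] < 25) stop("large cells must be >= 25 um")
  chk_range(spec$round_diameter_um, 10, 60, "round structure diameter")
  if (spec$lp_background_offset < 0) stop("lp_background_offset must be >= 0")
  if (spec$bp_background < 0) stop("bp_background must be >= 0")
  if (is.null(spec$noise$poisson_scale) || is.null(spec$noise$read_sigma))
    stop("noise must contain poisson_scale and read_sigma")
  if (spec$noise$poisson_scale < 0 || spec$noise$read_sigma < 0)
    stop("noise parameters must be >= 0")
  geom <- cle_geometry()
  fov_area <- prod(geom$fov_um)
  area <- function(n, d) n * pi * (mean(d) / 2)^2
  footprint <- area(spec$n_spots, spec$spot_diameter_um) +
    area(spec$n_small_cells, spec$small_cell_diameter_um) +
    area(spec$n_large_cells, spec$large_cell_diameter_um) +
    area(spec$n_round, spec$round_diameter_um) +
    spec$n_fibers * mean(spec$fiber_length_um) * mean(spec$fiber_width_um)
  if (footprint > 0.75 * fov_area) {
    stop("packing error: requested object footprint (", round(footprint),
         " um^2) exceeds the usable field of view")
  }
  invisible(spec)
}

# Expected background noise s.d. (gray units) of a filter's object-free
# frame under the spec's noise model.
background_sigma <- function(spec, filter = "BP") {
  bg <- spec$bp_background +
    if (identical(filter, "LP")) spec$lp_background_offset else 0
  sqrt(spec$noise$poisson_scale * bg + spec$noise$read_sigma^2)
}

#' Draw a random scene specification from tissue-like archetypes
#'
#' Samples one of five scene archetypes patterned on the autofluorescence
#' phenotypes seen in label-free CLE of brain tissue: glioblastoma-like
#' (dense punctuate signals, some cells), meningioma-like (fibers, round
#' psammoma-body-like structures, diffuse autofluorescence), metastasis-like
#' (sparse punctuate plus patchy diffuse signal), adenoma-like (sparse
#' punctuate, occasional bright cell agglomerates), and non-tumor-like
#' (dense small cells, some large cells). Counts are drawn within regimes
#' that are visually unambiguous for their class, mirroring how sparse and
#' dense patterns present as distinct phenotypes.
#'
#' @param seed integer seed controlling archetype choice and all counts.
#' @param archetype optional archetype name to force
#'   (`"glioblastoma"`, `"meningioma"`, `"metastasis"`, `"adenoma"`,
#'   `"non_tumor"`).
#' @param ... overrides forwarded to [scene_spec()].
#' @return A `cle_scene_spec` with attribute `archetype`.
#' @export
random_scene_spec <- function(seed, archetype = NULL, ...) {
  types <- c("glioblastoma", "meningioma", "metastasis", "adenoma", "non_tumor")
  spec <- with_stream(seed, "archetype", {
    type <- if (is.null(archetype)) sample(types, 1) else match.arg(archetype, types)
    ri <- function(lo, hi) sample(seq(lo, hi), 1)
    args <- switch(type,
      glioblastoma = list(n_spots = ri(60, 120), n_small_cells = ri(0, 6),
                          n_large_cells = ri(0, 2),
                          diffuse_level = if (runif(1) < 0.3) 90 else 0),
      meningioma = list(n_spots = ri(5, 35), n_fibers = ri(1, 3),
                        n_round = ri(1, 6),
                        diffuse_level = if (runif(1) < 0.6) 90 else 0),
      metastasis = list(n_spots = ri(5, 35), n_small_cells = ri(0, 6),
                        n_large_cells = ri(0, 2),
                        diffuse_level = if (runif(1) < 0.4) 90 else 0),
      adenoma = list(n_spots = ri(10, 40), n_small_cells = ri(0, 6)),
      non_tumor = list(n_spots = ri(10, 40), n_small_cells = ri(5, 12),
                       n_large_cells = ri(0, 4)))
    args$seed <- stream_seed(seed, "scene")
    spec <- do.call(scene_spec, utils::modifyList(args, list(...)))
    attr(spec, "archetype") <- type
    spec
  })
  spec
}
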