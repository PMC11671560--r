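# FieldImage: one CLE frame (1080 x 1920, 16-bit gray) with calibration and
# acquisition metadata, plus TIFF + JSON-sidecar I/O.

#' Construct a CLE field image
#'
#' @param pixels integer matrix, 1080 rows x 1920 columns, values in
#'   \[0, 65535\] (rows = the 267 um axis, columns = the 475 um axis).
#' @param filter emission filter, `"BP"` (bandpass 518-573 nm) or `"LP"`
#'   (longpass > 515 nm).
#' @param case_id,image_id identifiers.
#' @param acquisition `"ex_vivo"` or `"in_situ"`.
#' @param pixel_size_um pixel pitch; must be within 1% of 475/1920 um unless
#'   `check_size = FALSE`.
#' @param acq_index acquisition order within the case (used by duplicate QC).
#' @param meta optional list of extra metadata (render parameters etc.).
#' @param check_size set `FALSE` to accept frames of other sizes (the true
#'   `pixel_size_um` must then be supplied).
#' @return An object of class `cle_field_image`: a list with elements
#'   `pixels`, `filter`, `case_id`, `image_id`, `acquisition`,
#'   `pixel_size_um`, `acq_index`, `meta`.
#' @export
field_image <- function(pixels, filter = c("BP", "LP"), case_id = "case1",
                        image_id = "img1", acquisition = c("ex_vivo", "in_situ"),
                        pixel_size_um = cle_geometry()$pixel_size_um,
                        acq_index = 1L, meta = list(), check_size = TRUE) {
  filter <- match.arg(filter)
  acquisition <- match.arg(acquisition)
  if (!is.matrix(pixels)) stop("pixels must be a matrix")
  geom <- cle_geometry()
  if (check_size) {
    if (nrow(pixels) != geom$nrow || ncol(pixels) != geom$ncol) {
      stop(sprintf(
        "dimension error: expected %d x %d frame, got %d x %d (use check_size = FALSE to override)",
        geom$nrow, geom$ncol, nrow(pixels), ncol(pixels)))
    }
    if (abs(pixel_size_um / geom$pixel_size_um - 1) > 0.01)
      stop("pixel_size_um deviates more than 1% from 475/1920 um")
  }
  if (min(pixels) < 0 || max(pixels) > 65535)
    stop("pixel values must lie in [0, 65535]")
  storage.mode(pixels) <- "integer"
  structure(list(pixels = pixels, filter = filter, case_id = case_id,
                 image_id = image_id, acquisition = acquisition,
                 pixel_size_um = pixel_size_um, acq_index = as.integer(acq_index),
                 meta = meta),
            class = "cle_field_image")
}

#' @export
print.cle_field_image <- function(x, ...) {
  cat(sprintf("<cle_field_image %s> case %s, %s filter, %s, %d x %d px (%.4f um/px)\n",
              x$image_id, x$case_id, x$filter, x$acquisition,
              nrow(x$pixels), ncol(x$pixels), x$pixel_size_um))
  invisible(x)
}

#' Emulate the device autobrightness
#'
#' The clinical device rescales display intensity automatically; its
#' algorithm is unpublished, so a linear rescale of the frame to a target
#' mean is used as a configurable emulation (off in default renders so that
#' the noise model stays on its physical scale).
#'
#' @param image a `cle_field_image`.
#' @param target target frame mean in gray units (default 5% of the 16-bit
#'   dynamic range).
#' @return The rescaled `cle_field_image`.
#' @export
emulate_autobrightness <- function(image, target = 0.05 * 65535) {
  stopifnot(inherits(image, "cle_field_image"))
  m <- mean(image$pixels)
  if (m <= 0) return(image)
  px <- matrix(.quantize_u16_cpp(as.numeric(image$pixels) * (target / m)),
               nrow(image$pixels), ncol(image$pixels))
  image$pixels <- px
  image$meta$autobrightness <- list(target = target, gain = target / m)
  image
}

#' Write a field image as 16-bit TIFF plus JSON sidecar
#'
#' The sidecar (same basename, extension `.json`) holds the frame metadata,
#' the scene specification and ground-truth annotations when present, and a
#' schema version.
#'
#' @param image a `cle_field_image`.
#' @param path output TIFF path.
#' @param truth optional ground-truth annotation (from [render_scene()]).
#' @param spec optional `cle_scene_spec` to embed.
#' @return `path`, invisibly.
#' @export
write_field_image <- function(image, path, truth = NULL, spec = NULL) {
  stopifnot(inherits(image, "cle_field_image"))
  tiff::writeTIFF(image$pixels / 65535, path, bits.per.sample = 16L,
                  compression = "none")
  side <- list(
    schema = "cleaf-frame/1",
    image_id = image$image_id, case_id = image$case_id,
    filter = image$filter, acquisition = image$acquisition,
    pixel_size_um = image$pixel_size_um, acq_index = image$acq_index,
    meta = image$meta)
  if (!is.null(spec)) side$scene_spec <- unclass(spec)
  if (!is.null(truth)) {
    side$ground_truth <- list(objects = truth$objects,
                              diffuse = truth$diffuse,
                              artifact = truth$artifact,
                              seed = truth$seed)
  }
  jsonlite::write_json(side, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}

sidecar_path <- function(path) sub("\\.[^.]+$", ".json", path)

#' Read a field image written by [write_field_image()]
#'
#' @param path TIFF path; a single-channel image of the expected frame size
#'   is required unless `check_size = FALSE`.
#' @param check_size forwarded to [field_image()].
#' @param ... metadata defaults used when no sidecar exists (passed to
#'   [field_image()]).
#' @return A `cle_field_image`; if the sidecar carried ground truth it is
#'   attached as attribute `"truth"`, and a scene spec as attribute `"spec"`.
#' @export
read_field_image <- function(path, check_size = TRUE, ...) {
  if (!file.exists(path)) stop("file not found: ", path)
  px <- tiff::readTIFF(path, as.is = FALSE)
  if (length(dim(px)) == 3 && dim(px)[3] > 1)
    stop("dimension error: multi-channel TIFF; expected single-channel grayscale")
  if (length(dim(px)) == 3) px <- px[, , 1]
  px <- matrix(as.integer(round(px * 65535)), nrow(px), ncol(px))
  side <- sidecar_path(path)
  if (file.exists(side)) {
    s <- jsonlite::read_json(side, simplifyVector = TRUE)
    img <- field_image(px, filter = s$filter, case_id = s$case_id,
                       image_id = s$image_id, acquisition = s$acquisition,
                       pixel_size_um = s$pixel_size_um,
                       acq_index = s$acq_index %||% 1L,
                       meta = as.list(s$meta), check_size = check_size)
    if (!is.null(s$ground_truth)) {
      truth <- list(objects = as.data.frame(s$ground_truth$objects),
                    diffuse = isTRUE(s$ground_truth$diffuse),
                    artifact = s$ground_truth$artifact,
                    seed = s$ground_truth$seed)
      attr(img, "truth") <- truth
    }
    if (!is.null(s$scene_spec)) attr(img, "spec") <- s$scene_spec
    img
  } else {
    field_image(px, check_size = check_size, ...)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a
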