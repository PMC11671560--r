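# Chernoff-face glyphs. The feature-to-face mapping follows the cohort
# visualization convention used for these nine features:
#   size of face                <- sparse punctuate autofluorescence
#   forehead/jaw relative arc   <- diffuse autofluorescence
#   shape of forehead           <- fibers
#   shape of jaw                <- dense punctuate autofluorescence
#   angle of eyes               <- round structures
#   direction of pupils         <- sparse small cells
#   length of nose              <- dense large cells
#   shape of mouth              <- dense small cells
#   mouth arc length            <- sparse large cells
# All other facial parameters sit at their default (0.5). The geometric
# construction itself is this package's own (documented below); only the
# assignment of features to face slots is fixed.

glyph_param_names <- function() {
  c("face_size", "forehead_jaw_arc", "forehead_shape", "jaw_shape",
    "eye_angle", "pupil_direction", "nose_length", "mouth_shape",
    "mouth_arc")
}

# feature flag -> face parameter slot
glyph_mapping <- function() {
  c(sparse_punctuate = "face_size",
    diffuse = "forehead_jaw_arc",
    fibers = "forehead_shape",
    dense_punctuate = "jaw_shape",
    round_structures = "eye_angle",
    sparse_small_cells = "pupil_direction",
    dense_large_cells = "nose_length",
    dense_small_cells = "mouth_shape",
    sparse_large_cells = "mouth_arc")
}

#' Encode a case summary as Chernoff-face parameters
#'
#' Each mapped parameter is the corresponding feature percentage divided by
#' 100 (componentwise linear map, no winsorizing — percentages are bounded
#' by construction); every unmapped facial parameter is exactly 0.5.
#'
#' @param summary a `cle_case_summary` (or a named vector of nine
#'   percentages over [feature_names()]).
#' @return A `cle_glyph_spec`: named list of the nine parameters in
#'   \[0, 1\] plus the `label`.
#' @export
glyph_spec <- function(summary) {
  pct <- if (inherits(summary, "cle_case_summary")) summary$pct else summary
  stopifnot(all(feature_names() %in% names(pct)))
  if (any(pct < 0 | pct > 100)) stop("percentages must lie in [0, 100]")
  map <- glyph_mapping()
  par <- stats::setNames(rep(0.5, length(glyph_param_names())),
                         glyph_param_names())
  par[map] <- pct[names(map)] / 100
  structure(list(params = par,
                 label = if (inherits(summary, "cle_case_summary"))
                   summary$case_id else NA_character_),
            class = "cle_glyph_spec")
}

#' Recover feature percentages from a glyph specification
#'
#' Inverse of [glyph_spec()] (the mapping is a bijection between the nine
#' percentages and the nine mapped parameters).
#'
#' @param spec a `cle_glyph_spec`.
#' @return Named percentage vector over [feature_names()].
#' @export
glyph_pct <- function(spec) {
  stopifnot(inherits(spec, "cle_glyph_spec"))
  map <- glyph_mapping()
  out <- 100 * spec$params[map]
  stats::setNames(as.numeric(out), names(map))[feature_names()]
}

# SVG path fragments for one face centred at (cx, cy) in a cell of size
# `cell`. The construction: an elliptical face whose half-axes scale with
# face_size; forehead and jaw drawn as quadratic Béziers whose vertical
# reach splits according to forehead_jaw_arc and whose curvature follows
# the two shape parameters; slanted elliptical eyes with displaced pupils;
# a vertical nose; a mouth Bézier whose half-width, curvature and vertical
# position encode the three mouth/nose-adjacent parameters.
glyph_svg_elements <- function(spec, cx, cy, cell) {
  p <- spec$params
  fmt <- function(x) sprintf("%.3f", x)
  a <- cell * 0.30 * (0.6 + 0.4 * p[["face_size"]])   # half width
  b <- cell * 0.36 * (0.6 + 0.4 * p[["face_size"]])   # half height
  b_top <- b * (0.5 + 0.9 * p[["forehead_jaw_arc"]])
  b_bot <- b * (1.4 - 0.9 * p[["forehead_jaw_arc"]])
  fh <- b_top * (0.6 + 1.2 * p[["forehead_shape"]])
  jw <- b_bot * (0.6 + 1.2 * p[["jaw_shape"]])
  el <- c(
    sprintf('<path d="M %s %s Q %s %s %s %s" fill="none" stroke="black" stroke-width="1.2"/>',
            fmt(cx - a), fmt(cy), fmt(cx), fmt(cy - 2 * fh), fmt(cx + a), fmt(cy)),
    sprintf('<path d="M %s %s Q %s %s %s %s" fill="none" stroke="black" stroke-width="1.2"/>',
            fmt(cx - a), fmt(cy), fmt(cx), fmt(cy + 2 * jw), fmt(cx + a), fmt(cy)))
  # eyes: ellipses slanted by eye_angle in [-30, 30] degrees (mirrored)
  ang <- (p[["eye_angle"]] - 0.5) * 60
  ex <- 0.45 * a; ey <- 0.35 * b_top
  rx <- 0.22 * a; ry <- 0.10 * a
  for (s in c(-1, 1)) {
    el <- c(el, sprintf(
      '<ellipse cx="%s" cy="%s" rx="%s" ry="%s" transform="rotate(%s %s %s)" fill="none" stroke="black" stroke-width="1"/>',
      fmt(cx + s * ex), fmt(cy - ey), fmt(rx), fmt(ry), fmt(-s * ang),
      fmt(cx + s * ex), fmt(cy - ey)))
    # pupil displaced along the eye axis by pupil_direction
    off <- (p[["pupil_direction"]] - 0.5) * 1.2 * rx
    th <- -s * ang * pi / 180
    el <- c(el, sprintf('<circle cx="%s" cy="%s" r="%s" fill="black"/>',
                        fmt(cx + s * ex + off * cos(th)),
                        fmt(cy - ey + off * sin(th)), fmt(0.35 * ry)))
  }
  # nose
  nl <- (0.12 + 0.5 * p[["nose_length"]]) * b_bot
  el <- c(el, sprintf('<line x1="%s" y1="%s" x2="%s" y2="%s" stroke="black" stroke-width="1"/>',
                      fmt(cx), fmt(cy - 0.05 * b), fmt(cx), fmt(cy - 0.05 * b + nl)))
  # mouth: arc half-width from mouth_arc, curvature from mouth_shape
  mw <- (0.18 + 0.6 * p[["mouth_arc"]]) * a
  my <- cy + 0.62 * b_bot
  curve <- (p[["mouth_shape"]] - 0.5) * 0.9 * b_bot
  el <- c(el, sprintf('<path d="M %s %s Q %s %s %s %s" fill="none" stroke="black" stroke-width="1.2"/>',
                      fmt(cx - mw), fmt(my), fmt(cx), fmt(my + curve),
                      fmt(cx + mw), fmt(my)))
  if (!is.na(spec$label)) {
    el <- c(el, sprintf('<text x="%s" y="%s" font-size="%s" text-anchor="middle" font-family="sans-serif">%s</text>',
                        fmt(cx), fmt(cy + cell * 0.46), fmt(cell * 0.09),
                        spec$label))
  }
  el
}

#' Render a single Chernoff-face glyph as SVG
#'
#' Deterministic vector output: identical specs give byte-identical files,
#' and any change in one parameter changes the drawing.
#'
#' @param spec a `cle_glyph_spec`.
#' @param out_path output `.svg` path.
#' @param size canvas size in px.
#' @return `out_path`, invisibly.
#' @export
render_glyph <- function(spec, out_path, size = 220) {
  stopifnot(inherits(spec, "cle_glyph_spec"))
  el <- glyph_svg_elements(spec, size / 2, size / 2 * 0.94, size)
  svg <- c(sprintf('<svg xmlns="http://www.w3.org/2000/svg" width="%d" height="%d" viewBox="0 0 %d %d">',
                   size, size, size, size),
           el, "</svg>")
  con <- file(out_path, open = "wb")
  on.exit(close(con))
  writeLines(svg, con)
  invisible(out_path)
}

#' Render a grid of glyphs (one face per case) as a single SVG
#'
#' @param specs list of `cle_glyph_spec`.
#' @param labels character labels drawn under each face (default: the
#'   specs' own labels).
#' @param out_path output `.svg` path.
#' @param cell per-face cell size in px.
#' @param ncol faces per row.
#' @return `out_path`, invisibly.
#' @export
render_glyph_grid <- function(specs, labels = NULL, out_path, cell = 180,
                              ncol = 6) {
  n <- length(specs)
  if (!is.null(labels)) {
    specs <- lapply(seq_len(n), function(i) {
      s <- specs[[i]]; s$label <- labels[i]; s
    })
  }
  nrow <- ceiling(n / ncol)
  w <- cell * min(n, ncol); h <- cell * nrow
  el <- character(0)
  for (i in seq_len(n)) {
    r <- (i - 1) %/% ncol; c <- (i - 1) %% ncol
    el <- c(el, glyph_svg_elements(specs[[i]], c * cell + cell / 2,
                                   r * cell + cell / 2 * 0.94, cell))
  }
  svg <- c(sprintf('<svg xmlns="http://www.w3.org/2000/svg" width="%d" height="%d" viewBox="0 0 %d %d">',
                   w, h, w, h), el, "</svg>")
  con <- file(out_path, open = "wb")
  on.exit(close(con))
  writeLines(svg, con)
  invisible(out_path)
}
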