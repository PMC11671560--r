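# Per-case aggregation of frame-level feature vectors and the in situ
# QC category arithmetic.

#' Aggregate per-frame feature flags into a case summary
#'
#' For each of the nine features, the percentage of analyzable frames of
#' the case in which the feature was detected. Frames excluded by QC must
#' not be passed in.
#'
#' @param feature_rows data frame with one row per analyzable frame: a
#'   `case_id` column and one logical column per [feature_names()] entry
#'   (the format written by [cohort_feature_table()]).
#' @param tumor_type free-text label attached to the summary (e.g.
#'   `"glioblastoma"`, `"meningioma"`, `"metastasis"`, `"pituitary_adenoma"`,
#'   `"non_tumor"`).
#' @return A `cle_case_summary`: list with `case_id`, `tumor_type`,
#'   `n_images` and `pct` (named percentages in \[0, 100\]).
#' @export
aggregate_case <- function(feature_rows, tumor_type = NA_character_) {
  if (nrow(feature_rows) < 1) stop("zero analyzable frames for this case")
  cid <- unique(feature_rows$case_id)
  if (length(cid) != 1) stop("feature rows span multiple cases: ",
                             paste(cid, collapse = ", "))
  miss <- setdiff(feature_names(), names(feature_rows))
  if (length(miss)) stop("missing feature columns: ", paste(miss, collapse = ", "))
  pct <- vapply(feature_names(),
                function(f) 100 * mean(as.logical(feature_rows[[f]])),
                numeric(1))
  structure(list(case_id = cid, tumor_type = tumor_type,
                 n_images = nrow(feature_rows), pct = pct),
            class = "cle_case_summary")
}

#' @export
print.cle_case_summary <- function(x, ...) {
  cat(sprintf("<cle_case_summary> %s (%s), %d analyzable frames\n",
              x$case_id, x$tumor_type, x$n_images))
  print(round(x$pct, 1))
  invisible(x)
}

#' Flatten per-frame feature vectors into a cohort table
#'
#' @param feature_vectors list of `cle_feature_vector` (one per frame).
#' @param image_ids,case_ids identifiers, recycled along the list.
#' @return Data frame: image_id, case_id, the five counts, diffuse
#'   coverage, and the nine logical flags.
#' @export
cohort_feature_table <- function(feature_vectors, image_ids, case_ids) {
  stopifnot(length(feature_vectors) == length(image_ids))
  rows <- lapply(seq_along(feature_vectors), function(i) {
    fv <- feature_vectors[[i]]
    data.frame(image_id = image_ids[i], case_id = case_ids[i],
               t(fv$counts), diffuse_coverage = fv$diffuse_coverage,
               t(as.logical(fv$flags)) |>
                 as.data.frame() |> stats::setNames(feature_names()),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' In situ QC category percentages
#'
#' Reported-category arithmetic for an in situ acquisition series: each
#' category percentage is its count over the total, rounded half away from
#' zero to integer; the remainder is the count of frames in none of the
#' listed categories.
#'
#' @param total total number of acquired frames.
#' @param category_counts vector of per-category counts (their sum must
#'   not exceed `total`).
#' @return List with `percent` (integer percentages per category) and
#'   `remainder` (frame count).
#' @export
situ_category_summary <- function(total, category_counts) {
  stopifnot(total >= 0, all(category_counts >= 0))
  if (sum(category_counts) > total)
    stop("category counts exceed the total number of frames")
  pct <- as.integer(round_half_away(100 * category_counts / total))
  list(percent = pct, remainder = as.integer(total - sum(category_counts)))
}

#' Cohort report: per-case bar data, glyph grid, per-type medians
#'
#' Writes the standard report bundle for a cohort of case summaries: a
#' long-format CSV of per-case feature percentages (bar-chart data), one
#' Chernoff-face glyph per case arranged in a grid SVG, and a per-tumor-type
#' table of median percentages. Output is deterministic: regenerating from
#' the same summaries is byte-identical.
#'
#' @param summaries list of `cle_case_summary`.
#' @param outdir output directory (created if needed).
#' @return Invisible list of written paths (`bars_csv`, `glyph_svg`,
#'   `type_medians_csv`).
#' @export
cohort_report <- function(summaries, outdir) {
  stopifnot(length(summaries) >= 1)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  bars <- do.call(rbind, lapply(summaries, function(s) {
    data.frame(case_id = s$case_id, tumor_type = s$tumor_type,
               n_images = s$n_images, feature = feature_names(),
               pct = unname(s$pct), stringsAsFactors = FALSE)
  }))
  bars_csv <- file.path(outdir, "case_feature_pct.csv")
  write.csv(bars, bars_csv, row.names = FALSE)

  specs <- lapply(summaries, glyph_spec)
  labels <- vapply(summaries, function(s) s$case_id, character(1))
  glyph_svg <- file.path(outdir, "glyph_grid.svg")
  render_glyph_grid(specs, labels, glyph_svg)

  med <- stats::aggregate(pct ~ tumor_type + feature, data = bars, FUN = stats::median)
  type_csv <- file.path(outdir, "tumor_type_median_pct.csv")
  write.csv(med[order(med$tumor_type, med$feature), ], type_csv, row.names = FALSE)
  invisible(list(bars_csv = bars_csv, glyph_svg = glyph_svg,
                 type_medians_csv = type_csv))
}
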