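# End-to-end demo pipeline: simulate a small cohort, QC it, compare the
# detection filters on paired acquisitions, detect and classify features,
# aggregate per case, and write the report bundle. All stages run from one
# root seed; per-stage counters are logged as JSON lines.

demo_case_plan <- function(n_cases) {
  types <- c("glioblastoma", "meningioma", "metastasis", "adenoma",
             "non_tumor", "non_tumor")
  plan <- data.frame(
    case_id = sprintf("P%d", seq_len(n_cases)),
    archetype = rep_len(types, n_cases),
    stringsAsFactors = FALSE)
  plan$tumor_type <- ifelse(plan$archetype == "adenoma", "pituitary_adenoma",
                            plan$archetype)
  plan
}

log_line <- function(con, stage, ...) {
  rec <- c(list(stage = stage), list(...))
  writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE), con)
}

#' Run the end-to-end demo on a synthetic cohort
#'
#' Generates a cohort of cases with tumor-type-like scene archetypes and
#' injected acquisition artifacts, runs QC, a paired BP/LP SNR comparison,
#' feature detection on all kept frames, per-case aggregation, and the
#' glyph/report bundle. Deterministic: the same `seed` reproduces every
#' output byte-for-byte.
#'
#' @param outdir output directory.
#' @param seed root seed for the whole run.
#' @param n_cases number of cases.
#' @param frames_per_case frames acquired per case.
#' @param artifact_frac fraction of frames carrying an injected artifact
#'   (split evenly between blank, motion and duplicate).
#' @param n_snr_pairs BP/LP pairs for the filter comparison.
#' @param qc_cfg,det_cfg configuration objects.
#' @return Invisibly, a list with the per-stage outputs (`qc`, `snr`,
#'   `features`, `summaries`, `paths`); status is signalled by errors.
#' @export
run_demo <- function(outdir, seed = 1, n_cases = 6, frames_per_case = 8,
                     artifact_frac = 0.25, n_snr_pairs = 12,
                     qc_cfg = qc_config(), det_cfg = detect_config()) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  logcon <- file(file.path(outdir, "run_log.jsonl"), open = "wt")
  on.exit(close(logcon))
  plan <- demo_case_plan(n_cases)

  # --- simulate ---------------------------------------------------------
  scenes <- list(); k <- 0
  for (ci in seq_len(n_cases)) {
    last_clean <- NULL
    for (fi in seq_len(frames_per_case)) {
      k <- k + 1
      si <- stream_seed(seed, sprintf("demo_c%d_f%d", ci, fi))
      spec <- random_scene_spec(si, archetype = plan$archetype[ci])
      sc <- render_scene(spec, "BP", seed = si, case_id = plan$case_id[ci],
                         image_id = sprintf("%s_f%02d", plan$case_id[ci], fi),
                         acq_index = fi)
      art <- with_stream(si, "artifact_choice", {
        if (runif(1) < artifact_frac) {
          sample(c("blank", "motion", "duplicate"), 1)
        } else "none"
      })
      if (art == "duplicate" && !is.null(last_clean)) {
        sc <- inject_artifact(last_clean, "duplicate", strength = 8, seed = si,
                              image_id = sprintf("%s_f%02d", plan$case_id[ci], fi))
        sc$image$acq_index <- fi
      } else if (art %in% c("blank", "motion")) {
        sc <- inject_artifact(sc, art, strength = 50, seed = si,
                              image_id = sprintf("%s_f%02d", plan$case_id[ci], fi))
        sc$image$acq_index <- fi
      } else {
        last_clean <- sc
      }
      scenes[[k]] <- sc
    }
  }
  log_line(logcon, "simulate", n_cases = n_cases,
           n_frames = length(scenes))

  # --- qc ---------------------------------------------------------------
  images <- lapply(scenes, `[[`, "image")
  qc <- qc_pipeline(images, qc_cfg)
  write_qc_report(qc, csv_path = file.path(outdir, "qc_report.csv"),
                  json_path = file.path(outdir, "qc_report.json"))
  tally <- situ_category_summary(nrow(qc$frames),
                                 unname(qc$tally[c("no_signal", "motion",
                                                   "duplicate")]))
  jsonlite::write_json(
    list(total = nrow(qc$frames),
         counts = as.list(qc$tally),
         percent_categories = tally$percent,
         remainder = tally$remainder,
         percent_reconciled = as.list(qc$percent)),
    file.path(outdir, "qc_tally.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  log_line(logcon, "qc", acquired = nrow(qc$frames),
           excluded = sum(qc$frames$decision == "excluded"),
           kept = unname(qc$tally[["kept"]]))

  # --- snr filter comparison -------------------------------------------
  pairs <- snr_pair_study(n_snr_pairs, stream_seed(seed, "snr"))
  cmp <- compare_filters(pairs)
  write.csv(pairs, file.path(outdir, "snr_pairs.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(n_pairs = cmp$n_pairs, median_bp = cmp$median_bp,
         median_lp = cmp$median_lp, median_diff = cmp$median_diff,
         W = cmp$W, p_value = cmp$p_value, method = cmp$method),
    file.path(outdir, "snr_comparison.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  log_line(logcon, "snr", n_pairs = cmp$n_pairs, p_value = cmp$p_value)

  # --- feature detection on kept frames --------------------------------
  kept_idx <- which(qc$frames$decision == "kept")
  fvs <- list(); ids <- character(0); cids <- character(0)
  for (i in kept_idx) {
    fv <- detect_features(images[[i]], det_cfg)$feature_vector
    fvs[[length(fvs) + 1]] <- fv
    ids <- c(ids, images[[i]]$image_id)
    cids <- c(cids, images[[i]]$case_id)
  }
  features <- cohort_feature_table(fvs, ids, cids)
  write.csv(features, file.path(outdir, "features.csv"), row.names = FALSE)
  log_line(logcon, "detect", analyzed = length(kept_idx))

  # --- per-case aggregation + glyphs -----------------------------------
  summaries <- lapply(seq_len(n_cases), function(ci) {
    rows <- features[features$case_id == plan$case_id[ci], , drop = FALSE]
    if (nrow(rows) == 0) return(NULL)
    aggregate_case(rows, tumor_type = plan$tumor_type[ci])
  })
  summaries <- Filter(Negate(is.null), summaries)
  summary_df <- do.call(rbind, lapply(summaries, function(s) {
    data.frame(case_id = s$case_id, tumor_type = s$tumor_type,
               n_images = s$n_images, t(s$pct), stringsAsFactors = FALSE)
  }))
  write.csv(summary_df, file.path(outdir, "summary.csv"), row.names = FALSE)
  paths <- cohort_report(summaries, outdir)
  log_line(logcon, "summarize", n_cases = length(summaries))

  invisible(list(qc = qc, snr = cmp, features = features,
                 summaries = summaries,
                 paths = c(paths, outdir = outdir)))
}
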