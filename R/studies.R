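# Reusable synthetic studies: the paired-filter SNR comparison, detector
# recovery, and QC flag accuracy. The analysis scripts, the test suite and
# the acceptance script all run these same functions (at stated sizes), so
# every reported number comes from one code path.

#' Render BP/LP pairs and measure profile SNR in both
#'
#' Each pair is a scene holding one fluorescent-cytoplasm cell; a line
#' profile crossing the cell (length `profile_um`, centred on the planted
#' centroid) is extracted from both frames, allocated automatically, and
#' the SNR computed. Signal amplitude is identical in both frames; the
#' frames differ by the longpass background offset and independent noise.
#'
#' @param n_pairs number of image pairs.
#' @param seed root seed (pair i uses substream seed + i).
#' @param cell_diameter_um,object_contrast,profile_um study geometry.
#' @param spec_args extra overrides forwarded to [scene_spec()].
#' @return Data frame with one row per pair: `snr_bp`, `snr_lp`.
#' @export
snr_pair_study <- function(n_pairs, seed, cell_diameter_um = 15,
                           object_contrast = 5, profile_um = 45,
                           spec_args = list()) {
  out <- data.frame(snr_bp = numeric(n_pairs), snr_lp = numeric(n_pairs))
  psz <- cle_geometry()$pixel_size_um
  for (i in seq_len(n_pairs)) {
    si <- stream_seed(seed, paste0("pair", i))
    spec <- do.call(scene_spec, c(list(
      n_small_cells = 1,
      small_cell_diameter_um = rep(cell_diameter_um, 2),
      object_contrast = object_contrast, seed = si), spec_args))
    pair <- render_pair(spec, seed = si)
    obj <- pair$bp$truth$objects
    r0 <- um_to_px(obj$y_um[1], psz)
    c0 <- um_to_px(obj$x_um[1], psz)
    half <- profile_um / 2 / psz
    p0 <- c(r0, max(1, c0 - half)); p1 <- c(r0, min(1920, c0 + half))
    snr_of <- function(img) {
      prof <- allocate_profile(extract_profile(img, p0, p1), "otsu")
      compute_snr(prof)$snr
    }
    out$snr_bp[i] <- snr_of(pair$bp$image)
    out$snr_lp[i] <- snr_of(pair$lp$image)
  }
  out
}

#' Replicated paired-filter null study
#'
#' Runs [snr_pair_study()] for several independent cohorts and summarizes
#' each with [compare_filters()]: the expectation under matched signal
#' amplitudes is a median SNR difference near zero and a non-significant
#' Wilcoxon signed-rank test.
#'
#' @param n_cohorts number of replicate cohorts.
#' @param n_pairs pairs per cohort.
#' @param seed root seed.
#' @param ... forwarded to [snr_pair_study()].
#' @return Data frame per cohort: `median_bp`, `median_lp`, `median_diff`,
#'   `p_value`.
#' @export
paired_null_study <- function(n_cohorts = 20, n_pairs = 50, seed = 1, ...) {
  res <- lapply(seq_len(n_cohorts), function(k) {
    pairs <- snr_pair_study(n_pairs, stream_seed(seed, paste0("cohort", k)), ...)
    cmp <- compare_filters(pairs)
    data.frame(median_bp = cmp$median_bp, median_lp = cmp$median_lp,
               median_diff = cmp$median_diff, p_value = cmp$p_value)
  })
  do.call(rbind, res)
}

#' Detector recovery study on randomized scenes
#'
#' Renders `n_frames` frames from archetype-randomized scene
#' specifications ([random_scene_spec()]) at the default contrast, runs
#' [detect_features()] on each, and scores the nine-flag feature vector
#' against the ground-truth-implied vector.
#'
#' @param n_frames number of frames.
#' @param seed root seed.
#' @return List with `flag_matrix` (frames x 9 logical agreement),
#'   `flag_agreement` (overall fraction of agreeing (frame, flag) cells),
#'   `punctuate_agreement` (over the two punctuate flags), and the
#'   per-frame table `frames`.
#' @export
feature_recovery_study <- function(n_frames = 100, seed = 1) {
  agree <- matrix(NA, n_frames, length(feature_names()),
                  dimnames = list(NULL, feature_names()))
  rows <- vector("list", n_frames)
  for (i in seq_len(n_frames)) {
    si <- stream_seed(seed, paste0("frame", i))
    spec <- random_scene_spec(si)
    sc <- render_scene(spec, "BP", seed = si)
    det <- detect_features(sc$image)$feature_vector
    tv <- truth_feature_vector(sc$truth)
    agree[i, ] <- det$flags == tv$flags
    rows[[i]] <- data.frame(frame = i, archetype = attr(spec, "archetype"),
                            t(det$counts),
                            truth_spots = tv$counts[["n_spots"]],
                            flags_ok = sum(det$flags == tv$flags))
  }
  punct <- c("sparse_punctuate", "dense_punctuate")
  list(flag_matrix = agree,
       flag_agreement = mean(agree),
       punctuate_agreement = mean(agree[, punct]),
       frames = do.call(rbind, rows))
}

#' Spot detection accuracy at fixed contrast
#'
#' Frames with `n_spots` planted 2 um spots at the stated contrast;
#' detections match ground truth when centroids agree within 1 um.
#'
#' @param n_frames number of frames.
#' @param n_spots spots per frame.
#' @param contrast peak amplitude in background-noise s.d. units.
#' @param seed root seed.
#' @return List with `recall`, `precision`, `n_true`, `n_detected`.
#' @export
spot_accuracy_study <- function(n_frames = 5, n_spots = 30, contrast = 8,
                                seed = 1) {
  tp <- fp <- fn <- 0
  for (i in seq_len(n_frames)) {
    si <- stream_seed(seed, paste0("spots", i))
    spec <- scene_spec(n_spots = n_spots, spot_diameter_um = c(2, 2),
                       object_contrast = contrast, seed = si)
    sc <- render_scene(spec, "BP", seed = si)
    det <- detect_spots(sc$image)
    tr <- sc$truth$objects
    if (nrow(det) == 0) { fn <- fn + nrow(tr); next }
    dmat <- outer(tr$y_um, det$y_um, `-`)^2 + outer(tr$x_um, det$x_um, `-`)^2
    matched_truth <- apply(dmat, 1, min) <= 1
    matched_det <- apply(dmat, 2, min) <= 1
    tp <- tp + sum(matched_truth)
    fn <- fn + sum(!matched_truth)
    fp <- fp + sum(!matched_det)
  }
  list(recall = tp / (tp + fn), precision = tp / (tp + fp),
       n_true = tp + fn, n_detected = tp + fp)
}

#' QC flag accuracy on a labeled synthetic set
#'
#' Builds a frame set with known artifact labels — clean frames,
#' blank frames, motion-smeared frames (default 50 px) and duplicated
#' fields of view (shift at most 10 px) — grouped into cases, runs
#' [qc_pipeline()], and reports per-artifact sensitivity and specificity.
#' Scenes carry cells and punctuate signals so that a smeared frame still
#' has discernible (smeared) signal, as real motion artifacts do.
#'
#' @param n_frames total frames across all cases.
#' @param seed root seed.
#' @param frac_blank,frac_motion,frac_duplicate artifact fractions.
#' @param motion_strength smear length (px).
#' @param duplicate_shift maximum duplicate shift (px).
#' @param cfg a [qc_config()].
#' @return List with `table` (per-frame labels and flags) and `metrics`
#'   (sensitivity/specificity per artifact class).
#' @export
qc_flag_study <- function(n_frames = 300, seed = 1, frac_blank = 0.2,
                          frac_motion = 0.2, frac_duplicate = 0.2,
                          motion_strength = 50, duplicate_shift = 10,
                          cfg = qc_config()) {
  n_cases <- max(1L, n_frames %/% 30L)
  label <- with_stream(seed, "qc_labels",
    sample(c("blank", "motion", "duplicate", "clean"), n_frames,
           replace = TRUE,
           prob = c(frac_blank, frac_motion, frac_duplicate,
                    1 - frac_blank - frac_motion - frac_duplicate)))
  case_of <- rep(seq_len(n_cases), length.out = n_frames)
  # build and QC one case at a time so at most ~30 frames are in memory
  frames <- NULL
  tally <- c(no_signal = 0L, motion = 0L, duplicate = 0L, kept = 0L)
  for (ci in seq_len(n_cases)) {
    idx <- which(case_of == ci)
    images <- vector("list", length(idx))
    last_clean <- NULL
    for (k in seq_along(idx)) {
      i <- idx[k]
      si <- stream_seed(seed, paste0("qcframe", i))
      cid <- sprintf("case%02d", ci)
      spec <- scene_spec(n_spots = 25, n_small_cells = 4, seed = si)
      sc <- render_scene(spec, "BP", seed = si, case_id = cid,
                         image_id = sprintf("img%04d", i), acq_index = i)
      if (label[i] == "duplicate" && !is.null(last_clean)) {
        sc <- inject_artifact(last_clean, "duplicate",
                              strength = duplicate_shift, seed = si,
                              image_id = sprintf("img%04d", i))
        sc$image$acq_index <- i
      } else if (label[i] == "duplicate") {
        label[i] <- "clean"
      }
      if (label[i] == "blank") {
        sc <- inject_artifact(sc, "blank", seed = si,
                              image_id = sprintf("img%04d", i))
        sc$image$acq_index <- i
      } else if (label[i] == "motion") {
        sc <- inject_artifact(sc, "motion", strength = motion_strength,
                              seed = si, image_id = sprintf("img%04d", i))
        sc$image$acq_index <- i
      }
      if (label[i] == "clean") last_clean <- sc
      images[[k]] <- sc$image
    }
    rep <- qc_pipeline(images, cfg)
    fr <- rep$frames
    fr$label <- label[idx]
    frames <- rbind(frames, fr)
    tally <- tally + rep$tally
  }
  met <- function(truth, flagged) {
    c(sensitivity = if (any(truth)) mean(flagged[truth]) else NA_real_,
      specificity = if (any(!truth)) mean(!flagged[!truth]) else NA_real_)
  }
  metrics <- rbind(
    blank = met(frames$label == "blank", frames$no_signal),
    motion = met(frames$label == "motion", frames$motion),
    duplicate = met(frames$label == "duplicate", !is.na(frames$duplicate_of)))
  list(table = frames, metrics = metrics, tally = tally,
       percent = stats::setNames(reconcile_percentages(tally), names(tally)))
}
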