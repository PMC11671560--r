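# Frame quality control: automated surrogates for the exclusion of frames
# with no discernible signal, obvious motion artifacts, or an identical /
# very similar field of view. Flags are applied with total precedence
# no_signal > motion > duplicate; thresholds live in qc_config() so they are
# data, not constants.

#' QC thresholds
#'
#' Default thresholds for the automated exclusion flags. `anisotropy` was
#' calibrated on the synthetic suite (clean frames score close to 1, frames
#' smeared over 50 px score far above; see the methods vignette).
#'
#' @param k_sigma bright-pixel criterion: a pixel counts as signal when it
#'   exceeds median + `k_sigma` * 1.4826 * MAD.
#' @param min_frac minimum fraction of bright pixels for a frame to count as
#'   having discernible signal.
#' @param anisotropy gradient-energy anisotropy ratio above which a frame is
#'   flagged as motion-smeared.
#' @param motion_smooth_sigma Gaussian presmoothing (px) before gradients.
#' @param ncc normalized cross-correlation threshold for duplicates.
#' @param ncc_downsample block-mean factor before correlation.
#' @param ncc_smooth_sigma extra smoothing (downsampled px) suppressing the
#'   uncorrelated pixel noise between re-acquisitions.
#' @param max_shift_frac maximum relative field-of-view shift searched.
#' @param overrides optional named list (e.g. parsed from a JSON config
#'   file) replacing individual defaults.
#' @return A named list of thresholds.
#' @export
qc_config <- function(k_sigma = 4, min_frac = 1e-4, anisotropy = 2.3,
                      motion_smooth_sigma = 2, ncc = 0.95,
                      ncc_downsample = 8L, ncc_smooth_sigma = 2,
                      max_shift_frac = 0.1, overrides = NULL) {
  cfg <- list(k_sigma = k_sigma, min_frac = min_frac, anisotropy = anisotropy,
              motion_smooth_sigma = motion_smooth_sigma, ncc = ncc,
              ncc_downsample = as.integer(ncc_downsample),
              ncc_smooth_sigma = ncc_smooth_sigma,
              max_shift_frac = max_shift_frac)
  if (!is.null(overrides)) cfg <- utils::modifyList(cfg, overrides)
  cfg
}

#' Flag a frame without discernible signal
#'
#' A frame is "blank" when fewer than `min_frac` of its pixels exceed the
#' robust background level (median) by `k_sigma` robust standard deviations
#' (1.4826 * MAD). Robust statistics are used because bright objects bias
#' mean and s.d.
#'
#' @param image a `cle_field_image`.
#' @param k_sigma,min_frac see [qc_config()].
#' @return `TRUE` if the frame has no discernible signal. A constant frame
#'   is `TRUE` by definition.
#' @export
flag_no_signal <- function(image, k_sigma = 4, min_frac = 1e-4) {
  stopifnot(inherits(image, "cle_field_image"))
  px <- image$pixels
  rs <- robust_stats(px)
  if (rs$sigma == 0) return(TRUE)
  mean(px > rs$median + k_sigma * rs$sigma) < min_frac
}

# Gradient-energy anisotropy: ratio of the structure-tensor eigenvalues of
# the presmoothed frame, computed over the strongest-gradient pixels so that
# object edges rather than residual noise carry the statistic.
gradient_anisotropy <- function(px, smooth_sigma = 2, grad_quantile = 0.9,
                                ds = 2L) {
  x <- downsample(matrix(as.numeric(px), nrow(px), ncol(px)), ds)
  if (smooth_sigma > 0) {
    x <- fft_filter(x, otf_gaussian(nrow(x), ncol(x), smooth_sigma / ds))
  }
  gr <- (shift_matrix(x, -1, 0) - shift_matrix(x, 1, 0)) / 2
  gc <- (shift_matrix(x, 0, -1) - shift_matrix(x, 0, 1)) / 2
  mag2 <- gr^2 + gc^2
  keep <- mag2 >= stats::quantile(mag2, grad_quantile)
  jrr <- mean(gr[keep]^2); jcc <- mean(gc[keep]^2); jrc <- mean((gr * gc)[keep])
  tr <- (jrr + jcc) / 2
  s <- sqrt(((jrr - jcc) / 2)^2 + jrc^2)
  (tr + s) / max(tr - s, .Machine$double.eps)
}

#' Flag a motion-smeared frame
#'
#' Computes the gradient-energy anisotropy of the frame: the ratio of the
#' largest to smallest eigenvalue of the structure tensor (mean outer
#' product of the intensity gradient) over the strongest-gradient pixels of
#' the presmoothed frame. Directional smear drives the ratio far above the
#' near-isotropic value of clean frames.
#'
#' @param image a `cle_field_image`.
#' @param anisotropy_threshold flag when the ratio exceeds this value.
#' @param smooth_sigma presmoothing (px).
#' @return `TRUE` if the frame looks motion-smeared.
#' @export
flag_motion <- function(image, anisotropy_threshold = qc_config()$anisotropy,
                        smooth_sigma = qc_config()$motion_smooth_sigma) {
  stopifnot(inherits(image, "cle_field_image"))
  gradient_anisotropy(image$pixels, smooth_sigma) > anisotropy_threshold
}

# Downsampled, smoothed, standardized copy used for duplicate detection.
ncc_thumbnail <- function(px, cfg) {
  x <- downsample(matrix(as.numeric(px), nrow(px), ncol(px)), cfg$ncc_downsample)
  if (cfg$ncc_smooth_sigma > 0) {
    x <- fft_filter(x, otf_gaussian(nrow(x), ncol(x), cfg$ncc_smooth_sigma))
  }
  x <- x - mean(x)
  s <- sqrt(mean(x^2))
  if (s > 0) x <- x / s
  x
}

# Maximum normalized cross-correlation between two standardized thumbnails
# over translations up to max_shift_frac of each dimension (FFT-based,
# circular; shifts are small so wrap-around is negligible).
ncc_max <- function(a, b, max_shift_frac = 0.1) {
  d1 <- nrow(a); d2 <- ncol(a)
  cc <- Re(stats::fft(stats::fft(a) * Conj(stats::fft(b)), inverse = TRUE)) /
    (d1 * d2) / (d1 * d2)
  m1 <- ceiling(d1 * max_shift_frac); m2 <- ceiling(d2 * max_shift_frac)
  win_r <- c(seq_len(m1 + 1), seq(d1 - m1 + 1, d1))
  win_c <- c(seq_len(m2 + 1), seq(d2 - m2 + 1, d2))
  max(cc[win_r, win_c])
}

#' Flag duplicated fields of view within a case
#'
#' For each frame (in acquisition order) the maximum normalized
#' cross-correlation against every earlier non-duplicate frame of the same
#' case is computed on downsampled, smoothed, standardized copies, searching
#' translations up to `max_shift_frac` of the field of view. A frame whose
#' best match reaches `ncc` is marked `duplicate_of` that frame, so the
#' duplicate graph always points backwards in time (acyclic).
#'
#' @param images list of `cle_field_image` (one or more cases).
#' @param ncc_threshold correlation threshold.
#' @param cfg a [qc_config()].
#' @return Character vector along `images`: the `image_id` of the earlier
#'   frame each duplicate matches, or `NA` for originals.
#' @export
flag_duplicates <- function(images, ncc_threshold = qc_config()$ncc,
                            cfg = qc_config()) {
  n <- length(images)
  dup_of <- rep(NA_character_, n)
  if (n < 2) return(dup_of)
  case <- vapply(images, function(i) i$case_id, character(1))
  ord <- order(case, vapply(images, function(i) i$acq_index, integer(1)))
  thumbs <- vector("list", n)
  for (ci in split(ord, case[ord])) {
    kept <- integer(0)
    for (i in ci) {
      if (is.null(thumbs[[i]])) thumbs[[i]] <- ncc_thumbnail(images[[i]]$pixels, cfg)
      best <- -Inf; best_j <- NA_integer_
      for (j in kept) {
        v <- ncc_max(thumbs[[i]], thumbs[[j]], cfg$max_shift_frac)
        if (v > best) { best <- v; best_j <- j }
      }
      if (!is.na(best_j) && best >= ncc_threshold) {
        dup_of[i] <- images[[best_j]]$image_id
      } else {
        kept <- c(kept, i)
      }
    }
  }
  dup_of
}

#' Run the full QC pipeline over a set of frames
#'
#' Applies the exclusion flags with precedence no_signal > motion >
#' duplicate (a frame without signal is not evaluated for motion; duplicate
#' comparison only involves frames that survived the earlier flags) and
#' tallies the cohort per category with largest-remainder-reconciled
#' percentages.
#'
#' @param images list of `cle_field_image`.
#' @param cfg a [qc_config()].
#' @return A `cle_qc_report`: list with `frames` (data frame: image_id,
#'   case_id, no_signal, motion, duplicate_of, decision, reason), `tally`
#'   (named counts: no_signal, motion, duplicate, kept) and `percent`
#'   (reconciled integer percentages). Blood contamination and out-of-focus
#'   areas are listed in `unsupported` (no operational criteria).
#' @export
qc_pipeline <- function(images, cfg = qc_config()) {
  if (length(images) == 0) {
    rep <- list(frames = data.frame(image_id = character(0),
                                    case_id = character(0),
                                    no_signal = logical(0), motion = logical(0),
                                    duplicate_of = character(0),
                                    decision = character(0),
                                    reason = character(0)),
                tally = c(no_signal = 0L, motion = 0L, duplicate = 0L, kept = 0L),
                percent = c(no_signal = 0L, motion = 0L, duplicate = 0L, kept = 0L),
                unsupported = c("blood_contamination", "out_of_focus"))
    class(rep) <- "cle_qc_report"
    return(rep)
  }
  n <- length(images)
  no_sig <- vapply(images, flag_no_signal, logical(1),
                   k_sigma = cfg$k_sigma, min_frac = cfg$min_frac)
  motion <- rep(FALSE, n)
  for (i in which(!no_sig)) {
    motion[i] <- flag_motion(images[[i]], cfg$anisotropy, cfg$motion_smooth_sigma)
  }
  dup_of <- rep(NA_character_, n)
  cand <- which(!no_sig & !motion)
  if (length(cand) >= 2) dup_of[cand] <- flag_duplicates(images[cand], cfg$ncc, cfg)
  decision <- ifelse(no_sig | motion | !is.na(dup_of), "excluded", "kept")
  reason <- rep("", n)
  reason[!is.na(dup_of)] <- "duplicate"
  reason[motion] <- "motion"
  reason[no_sig] <- "no_signal"
  frames <- data.frame(
    image_id = vapply(images, function(i) i$image_id, character(1)),
    case_id = vapply(images, function(i) i$case_id, character(1)),
    no_signal = no_sig, motion = motion, duplicate_of = dup_of,
    decision = decision, reason = reason, stringsAsFactors = FALSE)
  tally <- c(no_signal = sum(no_sig),
             motion = sum(motion),
             duplicate = sum(!is.na(dup_of)),
             kept = sum(decision == "kept"))
  rep <- list(frames = frames, tally = tally,
              percent = stats::setNames(reconcile_percentages(tally), names(tally)),
              unsupported = c("blood_contamination", "out_of_focus"))
  class(rep) <- "cle_qc_report"
  rep
}

#' @export
print.cle_qc_report <- function(x, ...) {
  cat("<cle_qc_report>", nrow(x$frames), "frames\n")
  print(rbind(count = x$tally, percent = x$percent))
  invisible(x)
}

#' Serialize a QC report
#'
#' Writes the per-frame table as CSV (one row per image) and the report
#' (frames + tallies) as JSON.
#'
#' @param report a `cle_qc_report`.
#' @param csv_path,json_path output paths (`NULL` to skip either).
#' @return invisible list of written paths.
#' @export
write_qc_report <- function(report, csv_path = NULL, json_path = NULL) {
  stopifnot(inherits(report, "cle_qc_report"))
  if (!is.null(csv_path)) write.csv(report$frames, csv_path, row.names = FALSE)
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(frames = report$frames,
           tally = as.list(report$tally),
           percent = as.list(report$percent),
           unsupported = report$unsupported),
      json_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(list(csv = csv_path, json = json_path))
}
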