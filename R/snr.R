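# Line-profile SNR: gray values are extracted along a line crossing a
# fluorescent object, allocated to signal or background, and the
# signal-to-noise ratio computed as delta-mu / sigma — the difference of the
# mean gray values of signal and background divided by the standard
# deviation of the background.

#' Extract a line profile from a frame
#'
#' Samples the image along the segment from `p0` to `p1` at unit-pixel
#' spacing by bilinear interpolation. Endpoints are inclusive when the
#' segment length is an integer number of pixels (a 50 px segment yields 51
#' samples).
#'
#' @param image a `cle_field_image`.
#' @param p0,p1 endpoints as `c(row, col)` in pixel coordinates (1-based
#'   matrix convention); both must lie inside the frame.
#' @return A `cle_line_profile`: data frame with columns `position`
#'   (distance along the line, px), `value` (interpolated gray value) and
#'   `label` (`NA` until allocated), plus attributes `p0`, `p1`,
#'   `pixel_size_um`.
#' @export
extract_profile <- function(image, p0, p1) {
  stopifnot(inherits(image, "cle_field_image"))
  px <- image$pixels
  d1 <- nrow(px); d2 <- ncol(px)
  chk <- function(p) {
    if (p[1] < 1 || p[1] > d1 || p[2] < 1 || p[2] > d2)
      stop("profile endpoint outside the image")
  }
  chk(p0); chk(p1)
  L <- sqrt(sum((p1 - p0)^2))
  if (L == 0) stop("zero-length profile segment")
  t <- seq(0, floor(L)) / L
  if (max(t) < 1) t <- c(t, 1)
  rr <- p0[1] + t * (p1[1] - p0[1])
  cc <- p0[2] + t * (p1[2] - p0[2])
  r0 <- pmin(floor(rr), d1 - 1L); c0 <- pmin(floor(cc), d2 - 1L)
  fr <- rr - r0; fc <- cc - c0
  v <- (1 - fr) * (1 - fc) * px[cbind(r0, c0)] +
    (1 - fr) * fc * px[cbind(r0, c0 + 1L)] +
    fr * (1 - fc) * px[cbind(r0 + 1L, c0)] +
    fr * fc * px[cbind(r0 + 1L, c0 + 1L)]
  prof <- data.frame(position = t * L, value = v, label = NA_character_)
  attr(prof, "p0") <- p0; attr(prof, "p1") <- p1
  attr(prof, "pixel_size_um") <- image$pixel_size_um
  class(prof) <- c("cle_line_profile", "data.frame")
  prof
}

#' Construct a labeled profile from raw values
#'
#' Convenience constructor for curated or simulated profiles that never
#' came from an image.
#'
#' @param values gray values along the line.
#' @param labels optional character vector (`"signal"`/`"background"`).
#' @return A `cle_line_profile`.
#' @export
line_profile <- function(values, labels = NULL) {
  if (is.null(labels)) labels <- rep(NA_character_, length(values))
  stopifnot(length(labels) == length(values))
  prof <- data.frame(position = seq_along(values) - 1, value = as.numeric(values),
                     label = labels)
  class(prof) <- c("cle_line_profile", "data.frame")
  prof
}

#' Allocate profile samples to signal or background
#'
#' The original allocation was manual; `method = "otsu"` provides a
#' reproducible automatic surrogate: the threshold maximizing the
#' between-class variance of the profile values (exhaustive search over
#' midpoints between consecutive sorted unique values). Samples at or above
#' the threshold become `"signal"`, the rest `"background"`. Manual labels
#' remain first-class via `method = "manual"`.
#'
#' @param profile a `cle_line_profile`.
#' @param method `"otsu"` or `"manual"`.
#' @param manual_labels character vector of `"signal"`/`"background"` used
#'   verbatim when `method = "manual"`.
#' @return The labeled profile (attribute `"threshold"` records the Otsu
#'   cut).
#' @export
allocate_profile <- function(profile, method = c("otsu", "manual"),
                             manual_labels = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(profile, "cle_line_profile"))
  if (method == "manual") {
    if (is.null(manual_labels) || length(manual_labels) != nrow(profile))
      stop("manual allocation requires one label per sample")
    bad <- setdiff(unique(manual_labels), c("signal", "background"))
    if (length(bad)) stop("labels must be 'signal' or 'background'")
    profile$label <- manual_labels
    return(profile)
  }
  v <- profile$value
  if (length(v) < 4) stop("otsu allocation needs at least 4 samples")
  u <- sort(unique(v))
  if (length(u) < 2) stop("allocation error: profile has no contrast")
  cuts <- (u[-1] + u[-length(u)]) / 2
  best <- -Inf; thr <- NA_real_
  for (ct in cuts) {
    hi <- v >= ct
    w1 <- mean(hi); w0 <- 1 - w1
    bc <- w0 * w1 * (mean(v[hi]) - mean(v[!hi]))^2
    if (bc > best) { best <- bc; thr <- ct }
  }
  profile$label <- ifelse(v >= thr, "signal", "background")
  attr(profile, "threshold") <- thr
  profile
}

#' Compute the line-profile signal-to-noise ratio
#'
#' SNR = delta-mu / sigma: the difference between the mean gray value of
#' the signal samples and the mean of the background samples, divided by
#' the standard deviation of the background samples.
#'
#' @param profile a labeled `cle_line_profile` with at least 1 signal and
#'   2 background samples.
#' @param sd_denominator `"n-1"` (sample s.d., default — safer for the
#'   short background segments of line profiles) or `"n"` (population).
#' @return A list of class `cle_snr` with `delta_mu`, `sigma_bg`, `snr`,
#'   `n_signal`, `n_background`.
#' @export
compute_snr <- function(profile, sd_denominator = c("n-1", "n")) {
  sd_denominator <- match.arg(sd_denominator)
  stopifnot(inherits(profile, "cle_line_profile"))
  lab <- profile$label
  if (anyNA(lab)) stop("profile is not fully allocated")
  sig <- profile$value[lab == "signal"]
  bg <- profile$value[lab == "background"]
  if (length(sig) < 1) stop("missing label class: no signal samples")
  if (length(bg) < 2) stop("missing label class: need >= 2 background samples")
  sigma <- stats::sd(bg)
  if (sd_denominator == "n") sigma <- sigma * sqrt((length(bg) - 1) / length(bg))
  if (!is.finite(sigma) || sigma == 0)
    stop("degenerate-background error: background standard deviation is zero")
  delta <- mean(sig) - mean(bg)
  structure(list(delta_mu = delta, sigma_bg = sigma, snr = delta / sigma,
                 n_signal = length(sig), n_background = length(bg)),
            class = "cle_snr")
}

#' @export
print.cle_snr <- function(x, ...) {
  cat(sprintf("SNR = %.4f (delta-mu = %.3f, sigma_bg = %.3f; n_sig = %d, n_bg = %d)\n",
              x$snr, x$delta_mu, x$sigma_bg, x$n_signal, x$n_background))
  invisible(x)
}

#' Compare SNR between the bandpass and longpass filters
#'
#' Two-sided Wilcoxon signed-rank test on the paired SNR differences
#' (BP - LP). Zero differences are dropped (signed-rank convention). The
#' null tail is exact — computed from the full distribution of the
#' signed-rank sum under random sign assignment, with average ranks for
#' tied absolute differences — for up to `exact_n` effective pairs, and a
#' normal approximation with tie correction and continuity correction
#' above. The two-sided p doubles the smaller one-sided tail, capped at 1.
#'
#' @param pairs data frame (or matrix) with columns `snr_bp`, `snr_lp`
#'   (or two unnamed columns in that order); incomplete pairs are dropped.
#' @param exact_n exact-enumeration cutoff (default 25).
#' @return A `cle_paired_comparison`: list with `n_pairs`, `n_effective`,
#'   `median_bp`, `median_lp`, `median_diff`, `W` (sum of positive ranks),
#'   `p_value`, `method`, `degenerate`.
#' @export
compare_filters <- function(pairs, exact_n = 25L) {
  pairs <- as.data.frame(pairs)
  if (!all(c("snr_bp", "snr_lp") %in% names(pairs))) {
    stopifnot(ncol(pairs) >= 2)
    names(pairs)[1:2] <- c("snr_bp", "snr_lp")
  }
  pairs <- pairs[stats::complete.cases(pairs[, c("snr_bp", "snr_lp")]), ]
  n <- nrow(pairs)
  if (n < 1) stop("need at least one complete pair")
  d <- pairs$snr_bp - pairs$snr_lp
  dd <- d[d != 0]
  res <- list(n_pairs = n, n_effective = length(dd),
              median_bp = stats::median(pairs$snr_bp),
              median_lp = stats::median(pairs$snr_lp),
              median_diff = stats::median(d))
  if (length(dd) == 0) {
    res <- c(res, list(W = 0, p_value = 1, method = "degenerate",
                       degenerate = TRUE))
    class(res) <- "cle_paired_comparison"
    return(res)
  }
  r <- rank(abs(dd))
  W <- sum(r[dd > 0])
  if (length(dd) <= exact_n) {
    p <- signed_rank_exact_p(r, W)
    method <- "exact"
  } else {
    p <- signed_rank_normal_p(r, W)
    method <- "normal approximation"
  }
  res <- c(res, list(W = W, p_value = p, method = method, degenerate = FALSE))
  class(res) <- "cle_paired_comparison"
  res
}

#' @export
print.cle_paired_comparison <- function(x, ...) {
  cat(sprintf("Paired filter comparison: n = %d pairs\n", x$n_pairs))
  cat(sprintf("  median SNR BP: %.3f, median SNR LP: %.3f (diff %.3f)\n",
              x$median_bp, x$median_lp, x$median_diff))
  cat(sprintf("  Wilcoxon signed-rank: W = %.1f, p = %.4f (%s)\n",
              x$W, x$p_value, x$method))
  invisible(x)
}

# Exact two-sided signed-rank p via the distribution of the rank sum over
# all sign assignments: generating function prod_i (1 + x^(2 r_i)) on
# doubled ranks (average ranks of ties are half-integers, doubling makes
# them integral). Equivalent to full 2^n enumeration.
signed_rank_exact_p <- function(ranks, W) {
  r2 <- as.integer(round(2 * ranks))
  total <- sum(r2)
  cnt <- numeric(total + 1)  # counts over doubled rank sums 0..total
  cnt[1] <- 1
  for (ri in r2) {
    shifted <- c(numeric(ri), cnt[seq_len(total + 1 - ri)])
    cnt <- cnt + shifted
  }
  w2 <- round(2 * W)
  p_le <- sum(cnt[seq_len(w2 + 1)]) / sum(cnt)
  p_ge <- sum(cnt[seq(w2 + 1, total + 1)]) / sum(cnt)
  min(1, 2 * min(p_le, p_ge))
}

# Normal approximation with tie correction and continuity correction.
signed_rank_normal_p <- function(ranks, W) {
  n <- length(ranks)
  mu <- n * (n + 1) / 4
  ties <- table(ranks)
  sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
  z <- (W - mu - sign(W - mu) * 0.5) / sqrt(sig2)
  min(1, 2 * stats::pnorm(-abs(z)))
}
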