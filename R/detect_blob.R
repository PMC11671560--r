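# Blob detectors: punctuate autofluorescence spots (1-3 um, multiscale
# Laplacian of Gaussian at full resolution) and weakly fluorescent round
# structures (10-60 um, LoG on a downsampled copy with homogeneity and
# contrast gates).

#' Detect punctuate autofluorescence signals
#'
#' Multiscale scale-normalized Laplacian-of-Gaussian blob detection over
#' scales matched to 1-3 um diameters. Responses are standardized per scale
#' by their robust spread so the threshold is expressed in background-noise
#' units; overlapping candidates are greedily suppressed keeping the
#' strongest response; estimated diameters outside 1-3 um (plus a one-pixel
#' tolerance) are discarded.
#'
#' @param image a `cle_field_image` (should have passed QC).
#' @param params a [detect_config()].
#' @return Detections data frame (class `"spot"`): centroid (um),
#'   equivalent diameter (um), response (in noise units).
#' @export
detect_spots <- function(image, params = detect_config(), .ctx = NULL) {
  stopifnot(inherits(image, "cle_field_image"))
  p <- params$spot
  psz <- image$pixel_size_um
  px <- image$pixels
  rs <- if (is.null(.ctx)) robust_stats(px) else .ctx$rs
  x <- if (is.null(.ctx)) {
    matrix(as.numeric(px) - rs$median, nrow(px), ncol(px))
  } else .ctx$x
  sigmas <- p$diameters_um / psz / 2.3548
  # compose a high-pass (1 - broad Gaussian) with each LoG so diffuse
  # autofluorescence and cell bodies do not leak into the blob band
  hp <- 1 - otf_gaussian(nrow(x), ncol(x), p$highpass_sigma_px)
  otfs <- lapply(sigmas, function(s) otf_log(nrow(x), ncol(x), s) * hp)
  resp <- fft_filter(x, otfs)
  z <- NULL; scale_idx <- NULL
  for (k in seq_along(resp)) {
    zk <- resp[[k]] / max(robust_stats(resp[[k]])$sigma,
                          p$min_response / p$z_threshold)
    if (is.null(z)) {
      z <- zk; scale_idx <- matrix(1L, nrow(zk), ncol(zk))
    } else {
      upd <- zk > z
      z[upd] <- zk[upd]; scale_idx[upd] <- k
    }
  }
  # circular FFT filtering wraps content across frame borders; exclude a
  # band as wide as the largest kernel support
  band <- ceiling(3 * max(sigmas)) + 2L
  z[c(seq_len(band), seq(nrow(z) - band + 1, nrow(z))), ] <- 0
  z[, c(seq_len(band), seq(ncol(z) - band + 1, ncol(z)))] <- 0
  cand <- local_maxima_above(z, p$z_threshold)
  if (nrow(cand) == 0) return(empty_detections())
  zc <- z[cand]
  ord <- order(zc, decreasing = TRUE)
  cand <- cand[ord, , drop = FALSE]; zc <- zc[ord]
  d_est <- p$diameters_um[scale_idx[cand]]
  # greedy non-maximum suppression by centre distance
  keep <- logical(nrow(cand))
  kr <- numeric(0); kc <- numeric(0); kd <- numeric(0)
  for (i in seq_len(nrow(cand))) {
    if (length(kr)) {
      lim <- p$min_sep_factor * (d_est[i] + kd) / 2 / psz
      if (any((kr - cand[i, 1])^2 + (kc - cand[i, 2])^2 < lim^2)) next
    }
    keep[i] <- TRUE
    kr <- c(kr, cand[i, 1]); kc <- c(kc, cand[i, 2]); kd <- c(kd, d_est[i])
  }
  cand <- cand[keep, , drop = FALSE]; zc <- zc[keep]; d_est <- d_est[keep]
  # sub-pixel refinement: quadratic interpolation of the response peak
  off <- function(a, b, c) {
    den <- a - 2 * b + c
    if (abs(den) < 1e-12) 0 else pmin(pmax(0.5 * (a - c) / den, -1), 1)
  }
  rr <- cand[, 1]; cc <- cand[, 2]
  dr <- dc <- numeric(length(rr))
  d1 <- nrow(z); d2 <- ncol(z)
  inner <- rr > 1 & rr < d1 & cc > 1 & cc < d2
  for (i in which(inner)) {
    dr[i] <- off(z[rr[i] - 1, cc[i]], z[rr[i], cc[i]], z[rr[i] + 1, cc[i]])
    dc[i] <- off(z[rr[i], cc[i] - 1], z[rr[i], cc[i]], z[rr[i], cc[i] + 1])
  }
  tol_um <- p$diameter_tol_px * psz
  ok <- d_est >= min(p$diameters_um) - tol_um & d_est <= max(p$diameters_um) + tol_um
  det <- detection_row("spot",
                       y_um = px_to_um(rr + dr, psz)[ok],
                       x_um = px_to_um(cc + dc, psz)[ok],
                       diameter_um = d_est[ok], response = zc[ok])
  det
}

#' Detect weakly fluorescent round structures
#'
#' Blob detection (scale-normalized LoG) on a downsampled copy at scales
#' matched to 10-60 um diameters. Candidates are kept only when the
#' interior is homogeneous (coefficient of variation below `cv_max`) and
#' the mean intensity sits between the background noise floor and
#' cell-level brightness — the morphology of psammoma-body-like structures.
#'
#' @inheritParams detect_spots
#' @return Detections data frame (class `"round"`).
#' @export
detect_round <- function(image, params = detect_config(), .ctx = NULL) {
  stopifnot(inherits(image, "cle_field_image"))
  p <- params$round
  psz <- image$pixel_size_um
  px <- image$pixels
  rs <- if (is.null(.ctx)) robust_stats(px) else .ctx$rs
  x <- if (is.null(.ctx)) {
    matrix(as.numeric(px) - rs$median, nrow(px), ncol(px))
  } else .ctx$x
  f <- p$downsample
  xd <- downsample(x, f)
  psz_d <- psz * f
  sigma_n <- rs$sigma
  sigmas <- p$radii_um / psz_d / sqrt(2)   # LoG optimum for a disk: sigma = R/sqrt(2)
  otfs <- lapply(sigmas, function(s) otf_log(nrow(xd), ncol(xd), s))
  resp <- fft_filter(xd, otfs)
  z <- NULL; scale_idx <- NULL
  for (k in seq_along(resp)) {
    zk <- resp[[k]] / max(robust_stats(resp[[k]])$sigma,
                          p$min_response / p$z_threshold)
    if (is.null(z)) {
      z <- zk; scale_idx <- matrix(1L, nrow(zk), ncol(zk))
    } else {
      upd <- zk > z
      z[upd] <- zk[upd]; scale_idx[upd] <- k
    }
  }
  cand <- local_maxima_above(z, p$z_threshold)
  if (nrow(cand) == 0) return(empty_detections())
  zc <- z[cand]
  d_um <- 2 * p$radii_um[scale_idx[cand]]
  # containment-aware NMS: larger disks first so small-scale maxima inside
  # a homogeneous disk (edge rings) are absorbed by it
  ord <- order(d_um, zc, decreasing = TRUE)
  cand <- cand[ord, , drop = FALSE]; zc <- zc[ord]; d_um <- d_um[ord]
  keep <- logical(nrow(cand))
  kr <- kc <- kd <- numeric(0)
  for (i in seq_len(nrow(cand))) {
    if (length(kr)) {
      lim <- pmax(0.6 * (d_um[i] + kd) / 2, kd / 2 + 0.25 * d_um[i]) / psz_d
      if (any((kr - cand[i, 1])^2 + (kc - cand[i, 2])^2 < lim^2)) next
    }
    keep[i] <- TRUE
    kr <- c(kr, cand[i, 1]); kc <- c(kc, cand[i, 2]); kd <- c(kd, d_um[i])
  }
  cand <- cand[keep, , drop = FALSE]; zc <- zc[keep]; d_um <- d_um[keep]
  # interior statistics on a lightly smoothed half-resolution copy
  x2 <- downsample(x, 2)
  xs <- fft_filter(x2, otf_gaussian(nrow(x2), ncol(x2), 1.5))
  out <- empty_detections()
  for (i in seq_len(nrow(cand))) {
    r0 <- (cand[i, 1] - 0.5) * f + 0.5
    c0 <- (cand[i, 2] - 0.5) * f + 0.5
    r2 <- (r0 - 0.5) / 2 + 0.5; c2 <- (c0 - 0.5) / 2 + 0.5
    R_px <- d_um[i] / 2 / psz / 2
    rr <- max(1, floor(r2 - 0.7 * R_px)):min(nrow(xs), ceiling(r2 + 0.7 * R_px))
    cc <- max(1, floor(c2 - 0.7 * R_px)):min(ncol(xs), ceiling(c2 + 0.7 * R_px))
    sub <- xs[rr, cc]
    dmask <- outer((rr - r2)^2, (cc - c2)^2, `+`) <= (0.7 * R_px)^2
    vals <- sub[dmask]
    if (length(vals) < 5) next
    m <- mean(vals)
    cv <- stats::sd(vals) / max(abs(m), 1e-9)
    if (m < p$contrast_range_sigma[1] * sigma_n ||
        m > p$contrast_range_sigma[2] * sigma_n) next
    if (cv > p$cv_max) next
    if (d_um[i] < p$diameter_range_um[1] || d_um[i] > p$diameter_range_um[2]) next
    out <- rbind(out, detection_row("round",
                                    y_um = px_to_um(r0, psz),
                                    x_um = px_to_um(c0, psz),
                                    diameter_um = d_um[i],
                                    mean_intensity = m, internal_cv = cv,
                                    response = zc[i]))
  }
  out
}
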