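# Shared numerical helpers: seed substreams, rounding, robust statistics,
# cached-OTF FFT filtering. All frame filtering in the package goes through
# fft_filter()/otf_*() so kernels are built and transformed once per session.

# Deterministic substream seed from a root seed and a stream label, so each
# object class / noise channel consumes its own RNG stream and adding one
# class never perturbs the draws of another. Plain 31-bit string hash.
stream_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  h <- as.double(seed %% 2147483647)
  for (k in utf8ToInt(label)) h <- (h * 31 + k) %% 2147483647
  as.integer(h)
}

# Streams use the Kinderman-Ramage normal generator (several times faster
# than inversion for the 2-Mpx noise fields, equally deterministic); the
# caller's RNG state, including its generator kinds, is restored on exit
# (.Random.seed encodes the kinds).
with_stream <- function(seed, label, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  suppressWarnings(set.seed(stream_seed(seed, label),
                            normal.kind = "Kinderman-Ramage"))
  force(code)
}

#' Round half away from zero
#'
#' Commercial rounding used for reported percentages (contrast with R's
#' banker's [round()]).
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_away <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Reconcile rounded percentages to sum to 100
#'
#' Largest-remainder reconciliation: percentages are floored, then the
#' remaining integer points are assigned to the categories with the largest
#' fractional remainders (ties broken by category order).
#'
#' @param counts non-negative integer counts covering the whole cohort.
#' @return integer percentages summing to exactly 100 (when `sum(counts) > 0`).
#' @export
reconcile_percentages <- function(counts) {
  stopifnot(all(counts >= 0))
  total <- sum(counts)
  if (total == 0) return(rep(0L, length(counts)))
  raw <- 100 * counts / total
  base <- floor(raw)
  short <- 100L - as.integer(sum(base))
  rem <- raw - base
  add <- integer(length(counts))
  if (short > 0) {
    idx <- order(rem, decreasing = TRUE)[seq_len(short)]
    add[idx] <- 1L
  }
  as.integer(base) + add
}

# Robust location/scale (median, 1.4826*MAD). For 2-Mpx frames a fixed-stride
# subsample keeps the sort cheap without touching the RNG.
robust_stats <- function(x, max_n = 300000L) {
  x <- as.numeric(x)
  n <- length(x)
  if (n > max_n) x <- x[seq(1L, n, by = ceiling(n / max_n))]
  m <- stats::median(x)
  s <- stats::mad(x, center = m)
  list(median = m, sigma = s)
}

# ---- cached-OTF FFT filtering --------------------------------------------

.otf_cache <- new.env(parent = emptyenv())

# The cache holds full-frame transfer functions (16-32 MB each); cap the
# entry count so long sessions cannot accumulate gigabytes. Frequency
# grids are kept (cheap to hold, expensive to rebuild).
otf_cache_put <- function(key, value) {
  keys <- ls(.otf_cache)
  if (length(keys) > 48) {
    drop <- setdiff(keys, grep("^freq_", keys, value = TRUE))
    rm(list = drop, envir = .otf_cache)
  }
  .otf_cache[[key]] <- value
  value
}

# Frequency grids (cycles per pixel) for a d1 x d2 frame.
freq_grid <- function(d1, d2) {
  key <- sprintf("freq_%d_%d", d1, d2)
  if (!is.null(.otf_cache[[key]])) return(.otf_cache[[key]])
  f1 <- c(seq(0, floor(d1 / 2)), seq(-ceiling(d1 / 2) + 1, -1)) / d1
  f2 <- c(seq(0, floor(d2 / 2)), seq(-ceiling(d2 / 2) + 1, -1)) / d2
  g <- list(u = matrix(f1, d1, d2), v = matrix(f2, d1, d2, byrow = TRUE))
  .otf_cache[[key]] <- g
  g
}

# OTF of an isotropic Gaussian (unit DC gain). Closed form in frequency
# space, so no spatial kernel is ever built.
otf_gaussian <- function(d1, d2, sigma) {
  key <- sprintf("gauss_%d_%d_%.6g", d1, d2, sigma)
  if (!is.null(.otf_cache[[key]])) return(.otf_cache[[key]])
  g <- freq_grid(d1, d2)
  otf_cache_put(key, exp(-2 * pi^2 * sigma^2 * (g$u^2 + g$v^2)))
}

# OTF of the scale-normalized Laplacian-of-Gaussian, sign-flipped so bright
# blobs give positive responses: sigma^2 * (4 pi^2 |f|^2) * Gaussian OTF.
otf_log <- function(d1, d2, sigma) {
  key <- sprintf("log_%d_%d_%.6g", d1, d2, sigma)
  if (!is.null(.otf_cache[[key]])) return(.otf_cache[[key]])
  g <- freq_grid(d1, d2)
  w2 <- 4 * pi^2 * (g$u^2 + g$v^2)
  otf_cache_put(key, sigma^2 * w2 * exp(-sigma^2 * w2 / 2))
}

# Second-derivative-of-Gaussian OTFs for the Hessian (ridge detection).
# which: "11" = d2/drow2, "22" = d2/dcol2, "12" = cross term.
otf_gauss_deriv2 <- function(d1, d2, sigma, which) {
  key <- sprintf("d2_%s_%d_%d_%.6g", which, d1, d2, sigma)
  if (!is.null(.otf_cache[[key]])) return(.otf_cache[[key]])
  g <- freq_grid(d1, d2)
  base <- exp(-2 * pi^2 * sigma^2 * (g$u^2 + g$v^2))
  otf_cache_put(key, switch(which,
    "11" = -(2 * pi * g$u)^2 * base,
    "22" = -(2 * pi * g$v)^2 * base,
    "12" = -(2 * pi * g$u) * (2 * pi * g$v) * base,
    stop("unknown derivative")))
}

# Filter a matrix with one or more precomputed OTFs, sharing one forward FFT.
# Circular (periodic) boundary handling. Returns a matrix, or a list if
# `otfs` is a list.
fft_filter <- function(x, otfs) {
  single <- !is.list(otfs)
  if (single) otfs <- list(otfs)
  fx <- fftwtools::fftw2d(x)
  n <- length(x)
  out <- lapply(otfs, function(o) Re(fftwtools::fftw2d(fx * o, inverse = 1)) / n)
  if (single) out[[1]] else out
}

# Block-mean downsample by integer factor (trims remainder rows/cols).
downsample <- function(x, f) {
  if (!is.double(x)) storage.mode(x) <- "double"
  .downsample_cpp(x, as.integer(f))
}

# 2-D shift with edge replication (integer offsets).
shift_matrix <- function(x, dr, dc) {
  d1 <- nrow(x); d2 <- ncol(x)
  ri <- pmin(pmax(seq_len(d1) - dr, 1L), d1)
  ci <- pmin(pmax(seq_len(d2) - dc, 1L), d2)
  x[ri, ci]
}

# Indices (arr.ind) of local maxima of x over a 3x3 neighborhood among
# pixels exceeding `thr`; ties keep the raster-last pixel (strict
# comparison against earlier neighbors). Border pixels are excluded.
local_maxima_above <- function(x, thr) {
  d1 <- nrow(x); d2 <- ncol(x)
  idx <- which(x > thr)
  if (!length(idx)) return(matrix(integer(0), 0, 2))
  r <- ((idx - 1L) %% d1) + 1L
  c <- ((idx - 1L) %/% d1) + 1L
  inner <- r > 1L & r < d1 & c > 1L & c < d2
  idx <- idx[inner]; r <- r[inner]; c <- c[inner]
  if (!length(idx)) return(matrix(integer(0), 0, 2))
  keep <- rep(TRUE, length(idx))
  v <- x[idx]
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    nb <- x[idx + dr + dc * d1]
    if (dr < 0 || (dr == 0 && dc < 0)) keep <- keep & (v > nb)
    else keep <- keep & (v >= nb)
  }
  cbind(r[keep], c[keep])
}

# Local maxima of a matrix over a 3x3 neighborhood (strict vs ties broken by
# raster order not needed: >= current against shifted copies with > on the
# "earlier" neighbors keeps exactly one pixel of a flat peak).
local_maxima <- function(x) {
  ge <- matrix(TRUE, nrow(x), ncol(x))
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    nb <- shift_matrix(x, dr, dc)
    if (dr < 0 || (dr == 0 && dc < 0)) ge <- ge & (x > nb) else ge <- ge & (x >= nb)
  }
  ge
}
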