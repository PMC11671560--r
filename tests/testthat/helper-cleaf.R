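# Shared fixtures: small scene builders used across test files. Everything
# is generated in code at test time; no stored fixtures.

spots_spec <- function(n = 30, d = c(2, 2), seed = 21, ...) {
  scene_spec(n_spots = n, spot_diameter_um = d, seed = seed, ...)
}

# A frame with no planted objects (background + noise only).
background_scene <- function(seed = 101, ...) {
  render_scene(scene_spec(seed = seed, ...), "BP", seed = seed)
}

# Brute-force two-sided signed-rank p over all 2^n sign assignments:
# the enumeration oracle for the exact Wilcoxon implementation.
brute_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
  Ws <- apply(signs, 1, function(s) sum(r[s > 0]))
  p_le <- mean(Ws <= W + 1e-9)
  p_ge <- mean(Ws >= W - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}

# Half-peak equivalent diameter of the single brightest object in a
# noiseless render (hole-filled), in um.
halfpeak_diameter <- function(scene) {
  img <- scene$image$pixels
  bg <- scene$image$meta$bg_level
  peak <- scene$truth$objects$peak[1]
  mask <- EBImage::fillHull(img > bg + peak / 2)
  lab <- EBImage::bwlabel(mask)
  area <- max(tabulate(lab[lab > 0]))
  2 * sqrt(area / pi) * scene$image$pixel_size_um
}
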