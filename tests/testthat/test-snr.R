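# Line-profile extraction, signal/background allocation, and the
# delta-mu / sigma statistic.

test_that("profile extraction samples at unit spacing with bilinear interpolation", {
  img <- field_image(matrix(100L, 1080, 1920))
  prof <- extract_profile(img, c(10, 10), c(10, 60))
  expect_equal(nrow(prof), 51)   # 50 px segment, inclusive endpoints
  expect_true(all(prof$value == 100))
  expect_error(extract_profile(img, c(10, 10), c(10, 10)), "zero-length")
  expect_error(extract_profile(img, c(0, 10), c(10, 60)), "outside")
})

test_that("a profile through a planted spot reaches the rendered peak", {
  spec <- scene_spec(n_spots = 1, spot_diameter_um = c(2, 2), seed = 401)
  sc <- render_scene(spec, "BP", seed = 401, noiseless = TRUE)
  psz <- sc$image$pixel_size_um
  r0 <- sc$truth$objects$y_um / psz + 1
  c0 <- sc$truth$objects$x_um / psz + 1
  prof <- extract_profile(sc$image, c(r0, c0 - 40), c(r0, c0 + 40))
  peak_expected <- sc$image$meta$bg_level + sc$truth$objects$peak
  expect_lt(abs(max(prof$value) - peak_expected) / peak_expected, 0.02)
})

test_that("otsu allocation matches an exhaustive between-class-variance search", {
  vals <- c(10, 11, 9, 10, 30, 31, 30, 10, 9)
  prof <- allocate_profile(line_profile(vals), "otsu")
  expect_equal(prof$label == "signal", vals >= 30)

  # independent oracle: try every threshold, maximize between-class variance
  oracle_threshold <- function(v) {
    cand <- sort(unique(v))
    best <- -Inf; thr <- NA
    for (ct in (cand[-1] + cand[-length(cand)]) / 2) {
      hi <- v >= ct
      bc <- mean(hi) * mean(!hi) * (mean(v[hi]) - mean(v[!hi]))^2
      if (bc > best) { best <- bc; thr <- ct }
    }
    thr
  }
  set.seed(42)
  for (i in 1:20) {
    v <- c(rnorm(15, 10, 2), rnorm(sample(3:10, 1), 30, 2))
    p <- allocate_profile(line_profile(v), "otsu")
    expect_equal(p$label == "signal", v >= oracle_threshold(v))
  }

  expect_error(allocate_profile(line_profile(rep(5, 9)), "otsu"),
               "no contrast")
  manual <- allocate_profile(line_profile(vals), "manual",
                             manual_labels = rep(c("background", "signal"),
                                                 c(4, 5)))
  expect_equal(manual$label, rep(c("background", "signal"), c(4, 5)))
})

test_that("compute_snr reproduces the worked example and its edge cases", {
  prof <- line_profile(c(10, 12, 8, 10, 11, 9, 24, 26, 25),
                       rep(c("background", "signal"), c(6, 3)))
  res <- compute_snr(prof)
  expect_equal(res$delta_mu, 15)
  expect_equal(res$sigma_bg, 1.41421, tolerance = 1e-5)
  expect_equal(res$snr, 10.6066, tolerance = 1e-4)

  # population-s.d. variant
  res_n <- compute_snr(prof, sd_denominator = "n")
  expect_equal(res_n$sigma_bg, sd(c(10, 12, 8, 10, 11, 9)) * sqrt(5 / 6))

  flat <- line_profile(c(10, 12, 8, 10, 10, 10),
                       rep(c("background", "signal"), c(4, 2)))
  expect_equal(compute_snr(flat)$snr, 0)

  const_bg <- line_profile(c(10, 10, 10, 25),
                           rep(c("background", "signal"), c(3, 1)))
  expect_error(compute_snr(const_bg), "degenerate-background")
  no_sig <- line_profile(c(10, 11, 9), rep("background", 3))
  expect_error(compute_snr(no_sig), "missing label")
})

test_that("SNR is invariant to intensity shift and positive scaling", {
  set.seed(7)
  vals <- c(rnorm(20, 10, 2), rnorm(5, 30, 2))
  labs <- rep(c("background", "signal"), c(20, 5))
  base <- compute_snr(line_profile(vals, labs))$snr
  expect_equal(compute_snr(line_profile(vals + 57, labs))$snr, base)
  expect_equal(compute_snr(line_profile(vals * 3.7, labs))$snr, base)
})

test_that("the SNR estimator converges to the true delta over sigma", {
  set.seed(11)
  true_snr <- 4
  err <- replicate(100, {
    bg <- rnorm(200, 100, 5)
    sig <- rnorm(20, 100 + true_snr * 5, 5)
    prof <- line_profile(c(bg, sig), rep(c("background", "signal"), c(200, 20)))
    abs(compute_snr(prof)$snr - true_snr)
  })
  expect_lt(mean(err), 0.1 * true_snr)
})
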