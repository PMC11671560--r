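# Paired filter comparison: exact signed-rank null (with ties) against the
# brute-force enumeration oracle, plus the large-n approximation.

test_that("worked signed-rank examples give their enumerated p-values", {
  r <- compare_filters(data.frame(snr_bp = c(2, 3, 4, 5, 6),
                                  snr_lp = c(1, 1, 1, 1, 1)))
  expect_equal(r$p_value, 0.0625)  # 2 * 1/32, all differences positive

  r2 <- compare_filters(data.frame(snr_bp = c(3, 4, 5), snr_lp = c(1, 2, 3)))
  expect_equal(r2$median_bp, 4)
  expect_equal(r2$median_lp, 2)
  expect_equal(r2$p_value, 0.25)   # ties in |d|: 2 * 1/8
})

test_that("identical pairs degenerate to p = 1 with W = 0", {
  r <- compare_filters(data.frame(snr_bp = c(2, 3, 4), snr_lp = c(2, 3, 4)))
  expect_true(r$degenerate)
  expect_equal(r$p_value, 1)
  expect_equal(r$W, 0)
})

test_that("exact p equals full sign enumeration for n <= 10, ties included", {
  set.seed(99)
  for (i in 1:60) {
    n <- sample(2:10, 1)
    d <- sample(c(-3, -2, -1, 1, 2, 3, 4), n, replace = TRUE) +
      sample(c(0, 0, 0.5), n, replace = TRUE)
    d <- d[d != 0]
    if (length(d) < 1) next
    p_impl <- compare_filters(data.frame(snr_bp = d, snr_lp = 0))$p_value
    expect_equal(p_impl, brute_signed_rank_p(d), tolerance = 1e-12)
  }
})

test_that("tie-free exact p matches stats::wilcox.test", {
  set.seed(4)
  for (i in 1:10) {
    n <- sample(6:15, 1)
    d <- sample(seq(0.1, 9.9, by = 0.1), n) * sample(c(-1, 1), n, TRUE)
    p_impl <- compare_filters(data.frame(snr_bp = d, snr_lp = 0))$p_value
    p_ref <- stats::wilcox.test(d, exact = TRUE)$p.value
    expect_equal(p_impl, p_ref, tolerance = 1e-12)
  }
})

test_that("above the exact cutoff the normal approximation with continuity matches", {
  set.seed(12)
  d <- rnorm(40, 0.3, 1)
  r <- compare_filters(data.frame(snr_bp = d, snr_lp = 0))
  expect_equal(r$method, "normal approximation")
  p_ref <- suppressWarnings(
    stats::wilcox.test(d, exact = FALSE, correct = TRUE)$p.value)
  expect_equal(r$p_value, p_ref, tolerance = 1e-10)
})
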