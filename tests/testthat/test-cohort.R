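# Case aggregation, the in situ category arithmetic, and Chernoff glyphs.

fake_rows <- function(case_id, n, true_features = list()) {
  df <- data.frame(case_id = rep(case_id, n))
  for (f in feature_names()) {
    k <- true_features[[f]] %||% 0
    df[[f]] <- rep(c(TRUE, FALSE), c(k, n - k))
  }
  df
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("case aggregation turns flag tables into percentages exactly", {
  s <- aggregate_case(fake_rows("P1", 10, list(fibers = 4)), "meningioma")
  expect_equal(unname(s$pct[["fibers"]]), 40)
  expect_equal(s$n_images, 10)

  s2 <- aggregate_case(fake_rows("P2", 26, list(dense_punctuate = 13)))
  expect_equal(unname(s2$pct[["dense_punctuate"]]), 50)

  s3 <- aggregate_case(fake_rows("P3", 7))
  expect_true(all(s3$pct == 0))

  expect_error(aggregate_case(fake_rows("P4", 0)), "zero analyzable")
  two <- rbind(fake_rows("A", 2), fake_rows("B", 2))
  expect_error(aggregate_case(two), "multiple cases")
})

test_that("percentage identity: pct times n over 100 recovers the flag count", {
  set.seed(31)
  for (i in 1:20) {
    n <- sample(3:40, 1)
    k <- sample(0:n, 1)
    s <- aggregate_case(fake_rows("P", n, list(diffuse = k)))
    expect_equal(s$pct[["diffuse"]] * s$n_images / 100, k)
  }
})

test_that("in situ category arithmetic reproduces the printed tally", {
  s <- situ_category_summary(338, c(53, 141, 73))
  expect_equal(s$percent, c(16L, 42L, 22L))
  expect_equal(s$remainder, 71L)

  expect_equal(situ_category_summary(100, c(100))$percent, 100L)
  expect_equal(situ_category_summary(100, c(100))$remainder, 0L)

  s3 <- situ_category_summary(7, c(1, 2))
  expect_equal(s3$percent, c(14L, 29L))
  expect_equal(s3$remainder, 4L)

  expect_error(situ_category_summary(5, c(4, 2)), "exceed")
})

test_that("rounding is half away from zero, not banker's", {
  expect_equal(round_half_away(0.5), 1)
  expect_equal(round_half_away(2.5), 3)
  expect_equal(round_half_away(-0.5), -1)
  expect_equal(round_half_away(14.285), 14, tolerance = 1e-9)
})

test_that("glyph mapping is an exact componentwise bijection", {
  zeros <- stats::setNames(rep(0, 9), feature_names())
  gz <- glyph_spec(zeros)
  mapped <- unname(cleaf:::glyph_mapping())
  expect_true(all(gz$params[mapped] == 0))
  unmapped <- setdiff(names(gz$params), mapped)
  expect_true(all(gz$params[unmapped] == 0.5))

  full <- stats::setNames(rep(100, 9), feature_names())
  expect_true(all(glyph_spec(full)$params[mapped] == 1))

  one <- zeros; one[["sparse_punctuate"]] <- 80
  g1 <- glyph_spec(one)
  expect_equal(unname(g1$params[["face_size"]]), 0.8)
  expect_true(all(g1$params[setdiff(mapped, "face_size")] == 0))

  set.seed(5)
  for (i in 1:10) {
    pct <- stats::setNames(runif(9, 0, 100), feature_names())
    expect_equal(glyph_pct(glyph_spec(pct)), pct)
  }
})

test_that("glyph rendering is deterministic and injective per parameter", {
  pct <- stats::setNames(seq(5, 85, by = 10), feature_names())
  spec <- glyph_spec(pct)
  f1 <- file.path(tempdir(), "g1.svg"); f2 <- file.path(tempdir(), "g2.svg")
  render_glyph(spec, f1); render_glyph(spec, f2)
  expect_identical(readBin(f1, "raw", 1e6), readBin(f2, "raw", 1e6))
  base <- readBin(f1, "raw", 1e6)
  for (par in names(spec$params)) {
    sp2 <- spec; sp2$params[[par]] <- sp2$params[[par]] + 0.07
    render_glyph(sp2, f2)
    expect_false(identical(readBin(f2, "raw", 1e6), base))
  }
  # default face renders without error
  def <- glyph_spec(stats::setNames(rep(50, 9), feature_names()))
  expect_silent(render_glyph(def, f2))
  unlink(c(f1, f2))
})

test_that("cohort report emits one glyph per case and regenerates identically", {
  s1 <- aggregate_case(fake_rows("P1", 10, list(fibers = 4, diffuse = 9)),
                       "meningioma")
  s2 <- aggregate_case(fake_rows("P2", 12, list(dense_small_cells = 11)),
                       "non_tumor")
  out1 <- file.path(tempdir(), "rep1"); out2 <- file.path(tempdir(), "rep2")
  p1 <- cohort_report(list(s1, s2), out1)
  p2 <- cohort_report(list(s1, s2), out2)
  svg <- readLines(p1$glyph_svg)
  expect_equal(sum(grepl("<text", svg)), 2)  # one label per case
  expect_identical(readLines(p1$glyph_svg), readLines(p2$glyph_svg))
  expect_identical(readLines(p1$bars_csv), readLines(p2$bars_csv))
  med <- read.csv(p1$type_medians_csv)
  expect_true(all(c("tumor_type", "feature", "pct") %in% names(med)))
  unlink(c(out1, out2), recursive = TRUE)
})

test_that("per-type medians follow the median of case percentages", {
  s1 <- aggregate_case(fake_rows("P1", 100, list(dense_small_cells = 43)), "glioma")
  s2 <- aggregate_case(fake_rows("P2", 100, list(dense_small_cells = 4)), "glioma")
  out <- file.path(tempdir(), "repm")
  p <- cohort_report(list(s1, s2), out)
  med <- read.csv(p$type_medians_csv)
  v <- med$pct[med$feature == "dense_small_cells" & med$tumor_type == "glioma"]
  expect_equal(v, 23.5)
  unlink(out, recursive = TRUE)
})
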