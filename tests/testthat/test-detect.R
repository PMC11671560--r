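# Feature detectors and the nine-flag classification layer.

test_that("classification thresholds are exact at every boundary", {
  fv <- function(...) classify_features(list(...))$flags
  # punctuate: 1-49 sparse, >= 50 dense
  expect_false(fv(n_spots = 0)[["sparse_punctuate"]])
  expect_true(fv(n_spots = 1)[["sparse_punctuate"]])
  expect_true(fv(n_spots = 49)[["sparse_punctuate"]])
  expect_false(fv(n_spots = 49)[["dense_punctuate"]])
  expect_false(fv(n_spots = 50)[["sparse_punctuate"]])
  expect_true(fv(n_spots = 50)[["dense_punctuate"]])
  # cells: 1-4 sparse, >= 5 dense
  for (cls in c("n_small_cells", "n_large_cells")) {
    nm <- if (cls == "n_small_cells") "small_cells" else "large_cells"
    args0 <- stats::setNames(list(0), cls)
    expect_false(do.call(fv, args0)[[paste0("sparse_", nm)]])
    expect_true(do.call(fv, stats::setNames(list(1), cls))[[paste0("sparse_", nm)]])
    expect_true(do.call(fv, stats::setNames(list(4), cls))[[paste0("sparse_", nm)]])
    expect_false(do.call(fv, stats::setNames(list(4), cls))[[paste0("dense_", nm)]])
    expect_true(do.call(fv, stats::setNames(list(5), cls))[[paste0("dense_", nm)]])
    expect_false(do.call(fv, stats::setNames(list(5), cls))[[paste0("sparse_", nm)]])
  }
  # presence flags and the all-absent frame
  expect_true(fv(n_fibers = 1)[["fibers"]])
  expect_true(fv(n_round = 1)[["round_structures"]])
  expect_false(any(classify_features(list())$flags))
  # sparse and dense flags of one class can never co-occur
  for (n in c(0, 1, 4, 5, 49, 50, 120)) {
    f <- fv(n_spots = n)
    expect_false(f[["sparse_punctuate"]] && f[["dense_punctuate"]])
  }
})

test_that("the 25 um diameter boundary assigns to the large-cell class", {
  expect_equal(cleaf:::cell_size_class(24.9), "small_cell")
  expect_equal(cleaf:::cell_size_class(25.0), "large_cell")
  expect_equal(cleaf:::cell_size_class(25.1), "large_cell")
})

test_that("spot detection recovers planted spots accurately", {
  sc <- render_scene(spots_spec(30, seed = 501), "BP", seed = 501)
  det <- detect_spots(sc$image)
  tr <- sc$truth$objects
  dmat <- outer(tr$y_um, det$y_um, `-`)^2 + outer(tr$x_um, det$x_um, `-`)^2
  recall <- mean(apply(dmat, 1, min) <= 1)
  precision <- mean(apply(dmat, 2, min) <= 1)
  expect_gte(recall, 0.9)
  expect_gte(precision, 0.9)
  expect_true(all(det$equivalent_diameter_um >= 1 - 0.25 &
                    det$equivalent_diameter_um <= 3 + 0.25))
})

test_that("background-only frames stay free of spot detections", {
  fps <- vapply(1:5, function(i) {
    nrow(detect_spots(background_scene(510 + i)$image))
  }, numeric(1))
  expect_lte(mean(fps), 1)
})

test_that("a noiseless spot is localized to within a pixel", {
  spec <- scene_spec(n_spots = 1, spot_diameter_um = c(2, 2), seed = 521)
  sc <- render_scene(spec, "BP", seed = 521, noiseless = TRUE)
  det <- detect_spots(sc$image)
  expect_equal(nrow(det), 1)
  err_px <- sqrt((det$y_um - sc$truth$objects$y_um)^2 +
                   (det$x_um - sc$truth$objects$x_um)^2) /
    sc$image$pixel_size_um
  expect_lte(err_px, 1)
})

test_that("detected spot count never decreases with planted count (noiseless)", {
  counts <- c(5, 15, 40)
  detected <- vapply(seq_along(counts), function(i) {
    sc <- render_scene(spots_spec(counts[i], seed = 530), "BP", seed = 530,
                       noiseless = TRUE)
    nrow(detect_spots(sc$image))
  }, numeric(1))
  expect_true(all(diff(detected) >= 0))
})

test_that("cell detection counts and sizes planted cells", {
  sc <- render_scene(scene_spec(n_small_cells = 6,
                                small_cell_diameter_um = c(15, 15),
                                seed = 541), "BP", seed = 541)
  det <- detect_cells(sc$image)
  small <- det[det$class == "small_cell", ]
  expect_gte(nrow(small), 5)
  expect_lte(abs(nrow(small) - 6), 1)
  expect_true(all(abs(small$equivalent_diameter_um - 15) < 4))

  sc2 <- render_scene(scene_spec(n_large_cells = 1,
                                 large_cell_diameter_um = c(30, 30),
                                 seed = 542), "BP", seed = 542)
  det2 <- detect_cells(sc2$image)
  expect_equal(sum(det2$class == "large_cell"), 1)
})

test_that("fiber detection measures skeleton length and ignores non-fibers", {
  spec <- scene_spec(n_fibers = 1, fiber_length_um = c(100, 100),
                     fiber_width_um = c(2, 2), seed = 551)
  sc <- render_scene(spec, "BP", seed = 551)
  det <- detect_fibers(sc$image)
  expect_equal(nrow(det), 1)
  expect_lt(abs(det$length_um - 100) / 100, 0.2)

  expect_equal(nrow(detect_fibers(background_scene(552)$image)), 0)
  spots_frame <- render_scene(spots_spec(30, seed = 553), "BP", seed = 553)
  expect_equal(nrow(detect_fibers(spots_frame$image)), 0)
})

test_that("round structures are detected with homogeneity and size gates", {
  sc <- render_scene(scene_spec(n_round = 1, round_diameter_um = c(40, 40),
                                seed = 561), "BP", seed = 561)
  det <- detect_round(sc$image)
  expect_equal(nrow(det), 1)
  expect_lt(abs(det$equivalent_diameter_um - 40) / 40, 0.10)

  # below the 10 um class bound: not reported
  tiny <- render_scene(scene_spec(n_spots = 1, spot_diameter_um = c(3, 3),
                                  seed = 562), "BP", seed = 562)
  expect_equal(nrow(detect_round(tiny$image)), 0)
  expect_equal(nrow(detect_round(background_scene(563)$image)), 0)
})

test_that("diffuse criterion responds to a full-field diffuse component only", {
  diffuse <- render_scene(scene_spec(diffuse_level = 90, seed = 571), "BP",
                          seed = 571)
  r <- detect_diffuse(diffuse$image)
  expect_true(r$flag)
  expect_gte(r$coverage, 0.9)

  base <- detect_diffuse(background_scene(572)$image)
  expect_false(base$flag)
  expect_lt(base$coverage, 0.05)

  spots_only <- render_scene(spots_spec(30, seed = 573), "BP", seed = 573)
  expect_false(detect_features(spots_only$image)$diffuse$flag)
})

test_that("no detection is assigned to two classes in a mixed frame", {
  spec <- scene_spec(n_spots = 25, n_small_cells = 4, n_fibers = 1,
                     n_round = 2, seed = 581)
  sc <- render_scene(spec, "BP", seed = 581)
  out <- detect_features(sc$image)
  det <- out$detections
  # every pair of detections of different classes is spatially distinct
  if (nrow(det) > 1) {
    for (i in seq_len(nrow(det) - 1)) {
      for (j in seq((i + 1), nrow(det))) {
        if (det$class[i] == det$class[j]) next
        d <- sqrt((det$y_um[i] - det$y_um[j])^2 + (det$x_um[i] - det$x_um[j])^2)
        expect_gt(d, 0.5)
      }
    }
  }
  expect_equal(sum(out$feature_vector$counts), nrow(det))
})
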