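# Synthetic CLE frame generator: determinism, count conservation, noise
# calibration, rendered geometry, paired acquisitions, artifacts, I/O.

test_that("rendering is deterministic and conserves annotation counts", {
  spec <- scene_spec(n_spots = 12, n_small_cells = 2, n_fibers = 1,
                     n_round = 2, seed = 7)
  a <- render_scene(spec, "BP", seed = 7)
  b <- render_scene(spec, "BP", seed = 7)
  expect_identical(a$image$pixels, b$image$pixels)
  expect_identical(a$truth$objects, b$truth$objects)

  cnt <- table(a$truth$objects$class)
  expect_equal(unname(cnt[["spot"]]), 12)
  expect_equal(unname(cnt[["small_cell"]]), 2)
  expect_equal(unname(cnt[["fiber"]]), 1)
  expect_equal(unname(cnt[["round"]]), 2)

  only_spots <- render_scene(scene_spec(n_spots = 30, seed = 3), "BP", seed = 3)
  expect_equal(nrow(only_spots$truth$objects), 30)
  expect_true(all(only_spots$truth$objects$class == "spot"))
})

test_that("frame geometry follows the device calibration", {
  g <- cle_geometry()
  expect_equal(g$pixel_size_um, 475 / 1920)
  sc <- background_scene(11)
  expect_equal(dim(sc$image$pixels), c(1080L, 1920L))
  # the two printed FOV axes agree through one square pixel size
  expect_lt(abs(g$nrow * g$pixel_size_um - 267) / 267, 0.002)
  expect_error(field_image(matrix(0L, 100, 100)), "dimension error")
  img <- field_image(matrix(0L, 100, 100), check_size = FALSE,
                     pixel_size_um = 1)
  expect_equal(dim(img$pixels), c(100L, 100L))
})

test_that("object-free frame statistics match the noise model", {
  spec <- scene_spec(bp_background = 500,
                     noise = list(poisson_scale = 1, read_sigma = 10),
                     seed = 16)
  v <- as.numeric(render_scene(spec, "BP", seed = 16)$image$pixels)
  expect_lt(abs(mean(v) - 500) / 500, 0.02)
  expect_lt(abs(var(v) - (500 + 100)) / 600, 0.05)

  # Poisson-only frame: variance ~ poisson_scale * mean (>= 1e6 pixels)
  spec2 <- scene_spec(bp_background = 500,
                      noise = list(poisson_scale = 2, read_sigma = 0),
                      seed = 17)
  v2 <- as.numeric(render_scene(spec2, "BP", seed = 17)$image$pixels)
  expect_lt(abs(var(v2) / mean(v2) - 2) / 2, 0.05)
})

test_that("paired BP/LP frames share geometry and differ by the offset", {
  spec <- scene_spec(n_spots = 5, lp_background_offset = 200, seed = 23)
  pair <- render_pair(spec, seed = 23)
  expect_identical(pair$bp$truth$objects[, c("class", "x_um", "y_um")],
                   pair$lp$truth$objects[, c("class", "x_um", "y_um")])
  expect_false(identical(pair$bp$image$pixels, pair$lp$image$pixels))
  # background-pixel averaging on an object-free pair
  bgpair <- render_pair(scene_spec(lp_background_offset = 200, seed = 24),
                        seed = 24)
  diff <- mean(bgpair$lp$image$pixels) - mean(bgpair$bp$image$pixels)
  expect_lt(abs(diff - 200) / 200, 0.05)
})

test_that("rendered object diameters measured at half peak match annotations", {
  cases <- list(
    scene_spec(n_spots = 1, spot_diameter_um = c(1.5, 1.5), seed = 31),
    scene_spec(n_spots = 1, spot_diameter_um = c(2.5, 2.5), seed = 32),
    scene_spec(n_small_cells = 1, small_cell_diameter_um = c(12, 12), seed = 33),
    scene_spec(n_large_cells = 1, large_cell_diameter_um = c(35, 35), seed = 34),
    scene_spec(n_round = 1, round_diameter_um = c(40, 40), seed = 35))
  for (spec in cases) {
    sc <- render_scene(spec, "BP", seed = spec$seed, noiseless = TRUE)
    d_true <- sc$truth$objects$equivalent_diameter_um[1]
    expect_lt(abs(halfpeak_diameter(sc) - d_true) / d_true, 0.15)
  }
})

test_that("scene validation rejects out-of-class geometry and over-packing", {
  expect_error(scene_spec(n_spots = -1), "counts")
  expect_error(scene_spec(spot_diameter_um = c(0.5, 3)), "spot")
  expect_error(scene_spec(small_cell_diameter_um = c(5, 30)), "small cell")
  expect_error(scene_spec(large_cell_diameter_um = c(20, 30)), ">= 25")
  expect_error(scene_spec(round_diameter_um = c(5, 40)), "round")
  expect_error(scene_spec(lp_background_offset = -5), "lp_background_offset")
  expect_error(scene_spec(n_large_cells = 600), "packing")
})

test_that("artifact injection behaves per class and rejects unknown kinds", {
  sc <- render_scene(spots_spec(10, seed = 41), "BP", seed = 41)
  blank <- inject_artifact(sc, "blank", seed = 5)
  expect_equal(nrow(blank$truth$objects), 0)
  expect_equal(blank$truth$artifact, "blank")
  expect_lt(abs(mean(blank$image$pixels) - 500) / 500, 0.02)

  mot <- inject_artifact(sc, "motion", strength = 50, seed = 5)
  expect_equal(mot$truth$artifact, "motion")
  # directional smear raises the gradient-energy anisotropy
  expect_gt(cleaf:::gradient_anisotropy(mot$image$pixels),
            cleaf:::gradient_anisotropy(sc$image$pixels))
  expect_error(inject_artifact(sc, "motion", strength = 0), "strength")

  dup <- inject_artifact(sc, "duplicate", strength = 5, seed = 5)
  expect_match(dup$truth$artifact, "^duplicate_of:")
  expect_error(inject_artifact(sc, "smudge"), "unknown artifact")
})

test_that("autobrightness emulation rescales to the target mean", {
  sc <- background_scene(51)
  ab <- emulate_autobrightness(sc$image, target = 3000)
  expect_lt(abs(mean(ab$pixels) - 3000) / 3000, 0.01)
})

test_that("TIFF + sidecar round trip preserves pixels, metadata and truth", {
  sc <- render_scene(spots_spec(5, seed = 61), "BP", seed = 61,
                     case_id = "caseX")
  path <- file.path(tempdir(), "frame61.tif")
  write_field_image(sc$image, path, truth = sc$truth)
  back <- read_field_image(path)
  expect_identical(back$pixels, sc$image$pixels)
  expect_equal(back$case_id, "caseX")
  expect_equal(back$filter, "BP")
  tr <- attr(back, "truth")
  expect_equal(nrow(tr$objects), 5)
  expect_equal(tr$objects$x_um, sc$truth$objects$x_um, tolerance = 1e-8)

  # multi-channel input is a dimension error
  rgb <- array(runif(30), dim = c(5, 2, 3))
  rgb_path <- file.path(tempdir(), "rgb.tif")
  tiff::writeTIFF(rgb, rgb_path)
  expect_error(read_field_image(rgb_path), "multi-channel")
  unlink(c(path, sub("tif$", "json", path), rgb_path))
})
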