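# Quality-control flags: no-signal, motion, duplicate; precedence and
# cohort tallies.

test_that("no-signal flag fires on blank and constant frames only", {
  sc <- render_scene(spots_spec(30, seed = 201, object_contrast = 8), "BP",
                     seed = 201)
  expect_false(flag_no_signal(sc$image))
  blank <- inject_artifact(sc, "blank", seed = 1)
  expect_true(flag_no_signal(blank$image))
  zero <- field_image(matrix(0L, 1080, 1920))
  expect_true(flag_no_signal(zero))
})

test_that("motion flag separates smeared from clean frames at the default threshold", {
  sc <- render_scene(scene_spec(n_spots = 20, n_small_cells = 4, seed = 211),
                     "BP", seed = 211)
  expect_false(flag_motion(sc$image))
  mot <- inject_artifact(sc, "motion", strength = 50, seed = 2)
  expect_true(flag_motion(mot$image))
})

test_that("duplicate detection pairs copies and spares independent frames", {
  spec <- scene_spec(n_spots = 25, n_small_cells = 3, seed = 221)
  a <- render_scene(spec, "BP", seed = 221, image_id = "a", acq_index = 1L)
  ident <- a$image; ident$image_id <- "ident"; ident$acq_index <- 2L
  shifted <- inject_artifact(a, "duplicate", strength = 5, seed = 3,
                             image_id = "shifted")$image
  shifted$acq_index <- 3L
  indep <- render_scene(spec, "BP", seed = 222, image_id = "indep",
                        acq_index = 4L)$image
  dup <- flag_duplicates(list(a$image, ident, shifted, indep))
  expect_equal(dup, c(NA, "a", "a", NA))
})

test_that("qc pipeline applies precedence, tallies every frame, and is idempotent", {
  spec_of <- function(seed) scene_spec(n_spots = 25, n_small_cells = 4,
                                       seed = seed)
  scenes <- list()
  mk <- function(seed, id, idx) {
    render_scene(spec_of(seed), "BP", seed = seed, image_id = id,
                 acq_index = idx)
  }
  clean <- lapply(1:4, function(i) mk(300 + i, paste0("c", i), i))
  blanks <- lapply(1:2, function(i) {
    s <- inject_artifact(clean[[1]], "blank", seed = i,
                         image_id = paste0("b", i))
    s$image$acq_index <- 4L + i; s
  })
  motions <- lapply(1:3, function(i) {
    s <- inject_artifact(clean[[(i %% 4) + 1]], "motion", strength = 50,
                         seed = 10 + i, image_id = paste0("m", i))
    s$image$acq_index <- 6L + i; s
  })
  dup <- inject_artifact(clean[[2]], "duplicate", strength = 5, seed = 20,
                         image_id = "d1")
  dup$image$acq_index <- 10L
  images <- c(lapply(clean, `[[`, "image"), lapply(blanks, `[[`, "image"),
              lapply(motions, `[[`, "image"), list(dup$image))
  rep <- qc_pipeline(images)
  expect_equal(unname(rep$tally),
               c(2L, 3L, 1L, 4L))  # no_signal, motion, duplicate, kept
  expect_equal(sum(rep$percent), 100L)
  # blank frames carry no motion evaluation (precedence)
  expect_false(any(rep$frames$motion[rep$frames$no_signal]))
  # duplicate graph points backwards in acquisition order
  dup_rows <- rep$frames[!is.na(rep$frames$duplicate_of), ]
  for (i in seq_len(nrow(dup_rows))) {
    src_idx <- match(dup_rows$duplicate_of[i], rep$frames$image_id)
    expect_lt(src_idx, match(dup_rows$image_id[i], rep$frames$image_id))
  }
  # idempotence on the kept set
  kept <- images[rep$frames$decision == "kept"]
  rep2 <- qc_pipeline(kept)
  expect_equal(unname(rep2$tally[["kept"]]), length(kept))
})

test_that("empty input yields an empty report", {
  rep <- qc_pipeline(list())
  expect_equal(nrow(rep$frames), 0)
  expect_equal(sum(rep$tally), 0)
})

test_that("reconciled category percentages always sum to 100", {
  for (counts in list(c(53, 141, 73, 71), c(1, 1, 1), c(7, 0, 0, 3),
                      c(2, 3, 1, 4))) {
    expect_equal(sum(reconcile_percentages(counts)), 100L)
  }
})
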