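#!/usr/bin/env Rscript
# Stage 1 — simulate a synthetic CLE cohort.
#
# Renders a small ex-vivo-style cohort (6 cases spanning the tissue
# archetypes, 8 frames each) with acquisition artifacts injected into a
# quarter of the frames, and writes the frames as 16-bit TIFFs with JSON
# sidecars under scratch/frames (binary data stays out of results/).
# Everything downstream (QC, detection, aggregation) re-reads these files,
# so the workflow also exercises the on-disk interchange format.

suppressMessages(library(cleaf))

seed <- 20240901
outdir <- "scratch/frames"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

plan <- data.frame(
  case_id = sprintf("P%d", 1:6),
  archetype = c("glioblastoma", "meningioma", "metastasis",
                "adenoma", "non_tumor", "non_tumor"))
plan$tumor_type <- ifelse(plan$archetype == "adenoma", "pituitary_adenoma",
                          plan$archetype)
frames_per_case <- 8
artifact_frac <- 0.25

manifest <- NULL
for (ci in seq_len(nrow(plan))) {
  last_clean <- NULL
  for (fi in seq_len(frames_per_case)) {
    si <- cleaf:::stream_seed(seed, sprintf("sim_c%d_f%d", ci, fi))
    spec <- random_scene_spec(si, archetype = plan$archetype[ci])
    sc <- render_scene(spec, "BP", seed = si, case_id = plan$case_id[ci],
                       image_id = sprintf("%s_f%02d", plan$case_id[ci], fi),
                       acq_index = fi)
    art <- cleaf:::with_stream(si, "artifact_choice", {
      if (runif(1) < artifact_frac) sample(c("blank", "motion", "duplicate"), 1)
      else "none"
    })
    if (art == "duplicate" && !is.null(last_clean)) {
      sc <- inject_artifact(last_clean, "duplicate", strength = 8, seed = si,
                            image_id = sprintf("%s_f%02d", plan$case_id[ci], fi))
      sc$image$acq_index <- fi
    } else if (art %in% c("blank", "motion")) {
      sc <- inject_artifact(sc, art, strength = 50, seed = si,
                            image_id = sprintf("%s_f%02d", plan$case_id[ci], fi))
      sc$image$acq_index <- fi
    } else {
      art <- "none"
      last_clean <- sc
    }
    path <- file.path(outdir, paste0(sc$image$image_id, ".tif"))
    write_field_image(sc$image, path, truth = sc$truth, spec = spec)
    manifest <- rbind(manifest, data.frame(
      image_id = sc$image$image_id, case_id = sc$image$case_id,
      tumor_type = plan$tumor_type[ci], archetype = plan$archetype[ci],
      artifact = sc$truth$artifact, path = path))
  }
}
dir.create("results", showWarnings = FALSE)
write.csv(manifest, "results/cohort_manifest.csv", row.names = FALSE)
cat(sprintf("Simulated %d frames over %d cases (%d with artifacts) -> %s\n",
            nrow(manifest), nrow(plan),
            sum(manifest$artifact != "none"), outdir))
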