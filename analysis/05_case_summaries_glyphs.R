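#!/usr/bin/env Rscript
# Stage 5 — per-case abundance and Chernoff-face glyphs.
#
# Aggregates the per-frame feature flags into per-case percentages (the
# fraction of analyzable frames showing each feature), encodes each case as
# a Chernoff face with the fixed feature-to-face mapping, and writes the
# report bundle: bar-chart data, the glyph grid SVG and per-tumor-type
# median percentages.

suppressMessages(library(cleaf))

features <- read.csv("results/features.csv")
manifest <- read.csv("results/cohort_manifest.csv")
types <- unique(manifest[, c("case_id", "tumor_type")])

summaries <- list()
for (cid in unique(features$case_id)) {
  rows <- features[features$case_id == cid, ]
  summaries[[cid]] <- aggregate_case(
    rows, tumor_type = types$tumor_type[types$case_id == cid])
}
paths <- cohort_report(summaries, "results")

summary_df <- do.call(rbind, lapply(summaries, function(s) {
  data.frame(case_id = s$case_id, tumor_type = s$tumor_type,
             n_images = s$n_images, t(s$pct))
}))
write.csv(summary_df, "results/summary.csv", row.names = FALSE)
cat("Case summaries (percentage of frames with each feature):\n")
print(summary_df[, 1:6], row.names = FALSE)
cat(sprintf("Glyph grid: %s\n", paths$glyph_svg))
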