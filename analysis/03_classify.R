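#!/usr/bin/env Rscript
# Step 3 — intrinsic subtype calls and risk of recurrence on both arms.
#
# Nearest-centroid classification by Spearman correlation with the
# ambiguity rule (second centroid within 0.10), the 11-gene Proliferation
# Score, ROR / ROR+PS on the 0-100 scale and low/med/high risk groups.

suppressPackageStartupMessages(library(pamconcord))

fx <- "results/fixtures"
nm <- "results/normalized"
out <- "results/calls"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

centroids <- read_centroids(file.path(fx, "centroids.tsv"))
cfg <- pam50_config()

for (arm in c("nanostring", "rnaseq")) {
  m <- read_expression_matrix(file.path(nm, sprintf("%s_log2.tsv", arm)),
                              platform = arm, scale = "log2_normalized")
  calls <- classify_cohort(m, centroids, cfg)
  write_pam50_calls(calls, file.path(out, sprintf("calls_%s.tsv", arm)))
  freq <- attr(calls, "subtype_frequencies")
  cat(sprintf("%s subtype frequencies (%%): %s\n", arm,
              paste(sprintf("%s %.1f", names(freq), freq), collapse = ", ")))
  cat(sprintf("%s ambiguous calls: %d; risk groups: %s\n", arm,
              sum(calls$ambiguous),
              paste(names(table(calls$ror_s_group)),
                    table(calls$ror_s_group), collapse = ", ")))
}
cat("call tables written to", out, "\n")
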