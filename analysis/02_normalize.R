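#!/usr/bin/env Rscript
# Step 2 — platform-specific normalization.
#
# Digital arm: negative-probe background subtraction (mean - 2 SD, clamped,
# floored at 1 count) then per-sample division by the housekeeper geometric
# mean and log2; a platform-matched reference-median centering is applied
# so the proliferation score is on the same scale as the RNA-Seq arm.
# RNA-Seq arm: symbol harmonization onto the signature's legacy names,
# per-sample rescaling of the upper-quartile statistic to 1000 followed by
# log2(x + 1), then subtraction of the receptor-balanced per-gene
# reference medians.

suppressPackageStartupMessages(library(pamconcord))

fx <- "results/fixtures"
out <- "results/normalized"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

probes <- read_probe_counts(file.path(fx, "probe_counts.tsv"))
rnaseq <- read_expression_matrix(file.path(fx, "rnaseq_counts.tsv"),
                                 platform = "rnaseq", scale = "raw")
ref_medians <- read_reference_medians(file.path(fx, "reference_medians.tsv"))
cfg <- read_sim_config(file.path(fx, "sim_config.json"))
centroids <- read_centroids(file.path(fx, "centroids.tsv"))
ns_medians <- generate_reference_medians(centroids, cfg,
                                         platform = "nanostring")

ns <- normalize_nanostring_arm(probes, reference_medians = ns_medians)
rs <- normalize_rnaseq_arm(rnaseq, ref_medians)

write_expression_matrix(ns, file.path(out, "nanostring_log2.tsv"))
write_expression_matrix(rs, file.path(out, "rnaseq_log2.tsv"))

cat("digital arm:", nrow(ns$values), "genes x", ncol(ns$values), "samples",
    "(housekeepers:", paste(ns$housekeepers, collapse = ", "), ")\n")
cat("RNA-Seq arm:", nrow(rs$values), "genes x", ncol(rs$values), "samples\n")
cat("normalized matrices written to", out, "\n")
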