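#!/usr/bin/env Rscript
# Step 4 — cross-platform agreement.
#
# Pairs the two call tables and assembles the full concordance report:
# 5x5 call cross-table with Cohen's kappa, raw and ambiguity-adjusted
# concordance with per-sample discordance records, risk-group discordance,
# ROR / ROR+PS / proliferation agreement (Spearman, ICC with 95% CI,
# Bland-Altman limits) and per-gene Spearman + ICC with the binned summary.

suppressPackageStartupMessages(library(pamconcord))

fx <- "results/fixtures"
out <- "results/concordance"

centroids <- read_centroids(file.path(fx, "centroids.tsv"))
calls_ns <- read_pam50_calls("results/calls/calls_nanostring.tsv")
calls_rs <- read_pam50_calls("results/calls/calls_rnaseq.tsv")
ns <- read_expression_matrix("results/normalized/nanostring_log2.tsv",
                             platform = "nanostring", scale = "log2_normalized")
rs <- read_expression_matrix("results/normalized/rnaseq_log2.tsv",
                             platform = "rnaseq", scale = "log2_normalized")

paired <- pair_calls(calls_ns, calls_rs, platforms = c("nanostring", "rnaseq"))
keep50 <- function(m) expression_matrix(
  m$values[rownames(centroids), , drop = FALSE],
  platform = m$platform, scale = "log2_normalized")
report <- concordance_report(paired, keep50(ns), keep50(rs))

print(report)
cat(sprintf("risk-group discordance: ROR %d, ROR+PS %d\n",
            report$risk_groups$n_discordant_ror,
            report$risk_groups$n_discordant_ror_ps))
cat(sprintf("ROR ICC %.3f [%.3f-%.3f]; ROR+PS ICC %.3f [%.3f-%.3f]\n",
            report$ror_agreement$ror_s$icc,
            report$ror_agreement$ror_s$icc_ci_low,
            report$ror_agreement$ror_s$icc_ci_high,
            report$ror_agreement$ror_ps$icc,
            report$ror_agreement$ror_ps$icc_ci_low,
            report$ror_agreement$ror_ps$icc_ci_high))
cat("per-gene rho bins:",
    paste(names(report$per_gene$bins), report$per_gene$bins, collapse = ", "),
    "\n")

write_concordance_report(report, out)
cat("report written to", out, "\n")

# compare against simulated ground truth
truth <- utils::read.delim(file.path(fx, "truth.tsv"))
disc <- report$discordance_records
if (!is.null(disc))
  cat(sprintf("discordant samples with an injected flip: %d of %d\n",
              sum(disc$sample_id %in% truth$sample_id[truth$flipped]),
              nrow(disc)))
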