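#' @title Platform-specific normalization
#' @name normalization
#' @description The two preprocessing recipes that turn raw platform output
#'   into classifier-ready log2 expression. Digital counts: negative-probe
#'   background subtraction (mean minus a multiple of the SD, clamped at
#'   zero), a positive floor, then per-sample scaling by the geometric mean
#'   of the housekeeper genes and log2. RNA-Seq: per-sample rescaling of
#'   the upper-quartile statistic to a fixed target, log2(x + 1), then
#'   per-gene subtraction of externally supplied reference medians. The
#'   pipeline order is fixed; each step validates the scale of its input.
NULL

#' Digital-count normalization settings
#'
#' @param sd_multiplier Non-negative multiplier on the negative-probe SD in
#'   the background estimate `mean - sd_multiplier * SD` (default 2).
#' @param floor_value Positive floor applied after background subtraction
#'   (default 1 count) so log2 is always defined.
#' @return A `NanoStringNormConfig` list.
#' @export
nanostring_norm_config <- function(sd_multiplier = 2, floor_value = 1) {
  if (sd_multiplier < 0) .stopf("sd_multiplier must be >= 0")
  if (floor_value <= 0) .stopf("floor_value must be > 0")
  structure(list(sd_multiplier = sd_multiplier, floor_value = floor_value,
                 log_base = 2),
            class = "NanoStringNormConfig")
}

#' RNA-Seq normalization settings
#'
#' @param uq_target Positive target value the per-sample upper-quartile
#'   statistic is rescaled to (default 1000).
#' @param uq_min_frac Fraction of samples in which a gene must have a
#'   nonzero count to enter the upper-quartile computation (default 0.7).
#' @param reference_medians Optional named numeric vector of per-gene
#'   reference medians (an externally determined, receptor-balanced set)
#'   subtracted on the log2 scale by [median_center_genes()].
#' @return An `RnaSeqNormConfig` list.
#' @export
rnaseq_norm_config <- function(uq_target = 1000, uq_min_frac = 0.7,
                               reference_medians = NULL) {
  if (uq_target <= 0) .stopf("uq_target must be > 0")
  if (uq_min_frac < 0 || uq_min_frac > 1) .stopf("uq_min_frac must be in [0, 1]")
  structure(list(uq_target = uq_target, uq_min_frac = uq_min_frac,
                 log_base = 2, reference_medians = reference_medians),
            class = "RnaSeqNormConfig")
}

#' Background-correct digital counts with negative-control probes
#'
#' Per sample, the background is estimated from the negative-control probes
#' as `b = mean - sd_multiplier * SD`, clamped at 0, and subtracted from
#' every endogenous and housekeeping count; results are floored at
#' `floor_value`. Negative probes are dropped from the output; positive
#' probes, if present, pass through unchanged.
#'
#' @param table A `ProbeCountTable` with at least 2 negative probes.
#' @param cfg A [nanostring_norm_config()].
#' @return A background-corrected `ProbeCountTable` without negative probes.
#' @export
nanostring_background_correct <- function(table, cfg = nanostring_norm_config()) {
  stopifnot(inherits(table, "ProbeCountTable"))
  neg <- table$probes$probe_class == "negative"
  if (sum(neg) < 2L)
    .stopf("need >= 2 negative probes to estimate background (found %d)", sum(neg))
  target <- table$probes$probe_class %in% c("endogenous", "housekeeping")
  zero_samples <- colSums(table$counts) == 0
  if (any(zero_samples))
    warning(sprintf("all-zero sample(s): %s; output floored",
                    paste(table$sample_ids[zero_samples], collapse = ", ")))
  negm <- table$counts[neg, , drop = FALSE]
  b <- pmax(colMeans(negm) - cfg$sd_multiplier * apply(negm, 2L, stats::sd), 0)
  corrected <- table$counts
  corrected[target, ] <- pmax(sweep(table$counts[target, , drop = FALSE], 2L, b),
                              cfg$floor_value)
  probe_count_table(corrected[!neg, , drop = FALSE],
                    table$probes[!neg, , drop = FALSE])
}

#' Housekeeper geometric-mean normalization to log2 expression
#'
#' Per sample, every count is divided by the geometric mean of the named
#' housekeeper genes in that sample, then log2-transformed (equivalently:
#' log2(count) minus the mean log2 housekeeper count). Housekeeper rows are
#' retained in the output and flagged via the matrix's `housekeepers` field.
#'
#' @param table A background-corrected `ProbeCountTable` (all relevant
#'   counts strictly positive; the floor in
#'   [nanostring_background_correct()] guarantees this).
#' @param housekeepers Character vector of housekeeper gene symbols; every
#'   one must be present in the table.
#' @param cfg A [nanostring_norm_config()] (only carried for provenance).
#' @return An `ExpressionMatrix` (platform `nanostring`, scale
#'   `log2_normalized`) with one row per endogenous or housekeeping gene.
#' @export
nanostring_housekeeper_normalize <- function(table,
                                             housekeepers = default_housekeepers(),
                                             cfg = nanostring_norm_config()) {
  stopifnot(inherits(table, "ProbeCountTable"))
  keep <- table$probes$probe_class %in% c("endogenous", "housekeeping")
  genes <- table$probes$gene_symbol[keep]
  counts <- table$counts[keep, , drop = FALSE]
  rownames(counts) <- genes
  missing <- setdiff(housekeepers, genes)
  if (length(missing))
    .stopf("housekeeper gene(s) not in table: %s", paste(missing, collapse = ", "))
  hk <- counts[match(housekeepers, genes), , drop = FALSE]
  if (any(hk <= 0)) {
    bad <- which(hk <= 0, arr.ind = TRUE)[1L, ]
    .stopf("non-positive housekeeper count (gene '%s', sample '%s')",
           housekeepers[bad[1L]], colnames(hk)[bad[2L]])
  }
  if (any(counts <= 0)) .stopf("all counts must be positive before log2")
  logv <- log2(counts)
  log_gm <- colMeans(log2(hk))
  values <- sweep(logv, 2L, log_gm)
  expression_matrix(values, platform = "nanostring", scale = "log2_normalized",
                    housekeepers = housekeepers)
}

#' Upper-quartile normalize RNA-Seq counts to a fixed target
#'
#' Genes entering the quantile computation are those with a nonzero count
#' in at least `uq_min_frac` of samples. Per sample, the 75th percentile of
#' those genes' counts is computed (type-7 quantile) and the whole sample
#' rescaled so that statistic equals `uq_target`; then log2(x + 1).
#'
#' @param matrix A raw (`scale = "raw"`), non-negative `ExpressionMatrix`.
#' @param cfg An [rnaseq_norm_config()].
#' @return An `ExpressionMatrix` with scale `log2_normalized`.
#' @export
rnaseq_upper_quartile_normalize <- function(matrix, cfg = rnaseq_norm_config()) {
  stopifnot(inherits(matrix, "ExpressionMatrix"))
  if (matrix$scale != "raw")
    .stopf("upper-quartile normalization expects raw counts, got scale '%s'",
           matrix$scale)
  v <- matrix$values
  if (any(v < 0)) .stopf("negative counts in raw matrix")
  subset <- rowMeans(v > 0) >= cfg$uq_min_frac
  if (!any(subset)) .stopf("no gene passes the upper-quartile subset rule")
  uq <- apply(v[subset, , drop = FALSE], 2L, stats::quantile,
              probs = 0.75, names = FALSE)
  if (any(uq == 0))
    .stopf("upper quartile is 0 for sample(s): %s",
           paste(matrix$sample_ids[uq == 0], collapse = ", "))
  scaled <- sweep(v, 2L, cfg$uq_target / uq, `*`)
  expression_matrix(log2(scaled + 1), platform = matrix$platform,
                    scale = "log2_normalized",
                    housekeepers = matrix$housekeepers)
}

#' Subtract per-gene reference medians on the log2 scale
#'
#' Aligns a log2-normalized matrix to the classifier's training
#' distribution by subtracting an externally determined per-gene median
#' (for this assay, a median from an estrogen-receptor-balanced reference
#' set). Every gene in the matrix must have a reference value.
#'
#' @param matrix A log2-scale `ExpressionMatrix`.
#' @param reference_medians Named numeric vector of per-gene medians.
#' @return The centered `ExpressionMatrix`.
#' @export
median_center_genes <- function(matrix, reference_medians) {
  stopifnot(inherits(matrix, "ExpressionMatrix"))
  if (matrix$scale != "log2_normalized")
    .stopf("median centering expects log2-normalized input")
  missing <- setdiff(matrix$gene_ids, names(reference_medians))
  if (length(missing))
    .stopf("no reference median for gene(s): %s", paste(missing, collapse = ", "))
  v <- matrix$values - reference_medians[matrix$gene_ids]
  expression_matrix(v, platform = matrix$platform, scale = matrix$scale,
                    housekeepers = matrix$housekeepers)
}
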