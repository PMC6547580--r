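#' @title End-to-end platform arms
#' @name pipeline
#' @description Convenience wrappers composing the fixed per-platform
#'   preprocessing orders (digital: background correction then housekeeper
#'   geometric-mean normalization; RNA-Seq: alias harmonization, fixed
#'   upper-quartile normalization with log2, then reference-median
#'   centering) and a one-call paired-cohort analysis used by the analysis
#'   scripts and the acceptance run.
NULL

#' Normalize the digital (NanoString-style) arm
#'
#' Gene centering is off by default (the housekeeper-normalized profile is
#' used as-is, which is all a rank-based subtype call needs); supplying
#' `reference_medians` switches on per-gene centering, which puts the
#' proliferation score — and hence ROR+PS — on a scale comparable with the
#' centered RNA-Seq arm.
#'
#' @param table Raw `ProbeCountTable`.
#' @param housekeepers Housekeeper gene symbols.
#' @param cfg A [nanostring_norm_config()].
#' @param reference_medians Optional named per-gene medians; when given,
#'   [median_center_genes()] is applied after normalization.
#' @return Classifier-ready `ExpressionMatrix` (log2-normalized).
#' @export
normalize_nanostring_arm <- function(table,
                                     housekeepers = default_housekeepers(),
                                     cfg = nanostring_norm_config(),
                                     reference_medians = NULL) {
  out <- nanostring_housekeeper_normalize(
    nanostring_background_correct(table, cfg), housekeepers, cfg)
  if (!is.null(reference_medians))
    out <- median_center_genes(out, reference_medians)
  out
}

#' Normalize the RNA-Seq arm
#'
#' @param matrix Raw RNA-Seq `ExpressionMatrix`.
#' @param reference_medians Named per-gene reference medians (canonical
#'   symbols), subtracted after log2; `NULL` skips centering.
#' @param cfg An [rnaseq_norm_config()].
#' @param aliases Alias map applied before normalization (default
#'   [default_alias_map()]).
#' @return Classifier-ready `ExpressionMatrix` (log2-normalized).
#' @export
normalize_rnaseq_arm <- function(matrix, reference_medians = NULL,
                                 cfg = rnaseq_norm_config(),
                                 aliases = default_alias_map()) {
  out <- rnaseq_upper_quartile_normalize(
    harmonize_gene_ids(matrix, aliases), cfg)
  if (!is.null(reference_medians))
    out <- median_center_genes(out, reference_medians)
  out
}

#' Analyze a simulated paired cohort end to end
#'
#' Normalizes both arms, classifies both, and assembles the concordance
#' report. Used by the analysis drivers and the acceptance run; real data
#' follows the same calls with files read via the io functions.
#'
#' @param sim Output of [simulate_cohort()].
#' @param centroids A `CentroidMatrix`.
#' @param reference_medians Per-gene reference medians for the RNA-Seq arm
#'   (`NULL` skips centering).
#' @param cfg A [pam50_config()].
#' @param housekeepers Housekeeper genes for the digital arm.
#' @param ns_reference_medians Optional per-gene medians for the digital
#'   arm (makes ROR+PS comparable across platforms; see
#'   [normalize_nanostring_arm()]).
#' @return List with `calls_nanostring`, `calls_rnaseq`, `paired`,
#'   `report`, and the two normalized matrices.
#' @export
analyze_paired_cohort <- function(sim, centroids, reference_medians = NULL,
                                  cfg = pam50_config(),
                                  housekeepers = default_housekeepers(),
                                  ns_reference_medians = NULL) {
  ns <- normalize_nanostring_arm(sim$nanostring, housekeepers,
                                 reference_medians = ns_reference_medians)
  rs <- normalize_rnaseq_arm(sim$rnaseq, reference_medians)
  calls_ns <- classify_cohort(ns, centroids, cfg)
  calls_rs <- classify_cohort(rs, centroids, cfg)
  paired <- pair_calls(calls_ns, calls_rs,
                       platforms = c("nanostring", "rnaseq"))
  ns50 <- expression_matrix(ns$values[rownames(centroids), , drop = FALSE],
                            platform = "nanostring", scale = "log2_normalized")
  rs50 <- expression_matrix(rs$values[rownames(centroids), , drop = FALSE],
                            platform = "rnaseq", scale = "log2_normalized")
  report <- concordance_report(paired, ns50, rs50,
                               threshold = cfg$ambiguity_threshold)
  list(calls_nanostring = calls_ns, calls_rnaseq = calls_rs,
       paired = paired, report = report,
       normalized = list(nanostring = ns, rnaseq = rs))
}
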