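#' @title Nearest-centroid intrinsic subtyping and risk of recurrence
#' @name pam50
#' @description Correlation of each sample's 50-gene profile to the five
#'   subtype centroids (Spearman by default), subtype assignment with a
#'   confidence value and an explicit ambiguity rule (second centroid
#'   within 0.10 of the top), the Proliferation Score (mean log2 expression
#'   of 11 proliferation genes), risk-of-recurrence scores ROR and ROR+PS
#'   on a 0-100 scale, and low/med/high risk groups. Score coefficients,
#'   rescaling bounds and group cutoffs are configuration data, not code.
NULL

.CONF_EPS <- 1e-8

#' Classifier configuration
#'
#' All tunables of the subtype caller and risk scoring in one object. The
#' risk-score weights, rescaling bounds and group cutoffs are this
#' package's defaults (the standard published subtype weights plus a
#' documented stand-in proliferation weight); override any piece, or load
#' a config from JSON with [read_pam50_config()].
#'
#' @param correlation_method `"spearman"` (default) or `"pearson"`.
#' @param ambiguity_threshold Non-negative gap below which the top-two
#'   centroid correlations make a call ambiguous (default 0.10).
#' @param proliferation_genes Character vector of proliferation genes
#'   (default the 11-gene set of [proliferation_genes()]).
#' @param ror_coefficients Named list with elements `ror_s` and `ror_ps`,
#'   each a list `weights` (named over subtypes), `proliferation_weight`,
#'   and `bounds` (length-2: raw-score values mapped to 0 and 100).
#' @param risk_cutoffs Named list with elements `ror_s` and `ror_ps`, each
#'   `c(low_med, med_high)`; scores are binned half-open, the boundary
#'   value falling in the upper class.
#' @param tie_break Subtype order used to break exact correlation ties.
#' @return A `Pam50Config` list.
#' @export
pam50_config <- function(correlation_method = c("spearman", "pearson"),
                         ambiguity_threshold = 0.10,
                         proliferation_genes = pamconcord::proliferation_genes(),
                         ror_coefficients = default_ror_coefficients(),
                         risk_cutoffs = default_risk_cutoffs(),
                         tie_break = pam50_subtypes()) {
  correlation_method <- match.arg(correlation_method)
  if (ambiguity_threshold < 0) .stopf("ambiguity_threshold must be >= 0")
  if (!length(proliferation_genes)) .stopf("proliferation gene list is empty")
  if (!setequal(tie_break, pam50_subtypes()))
    .stopf("tie_break must be a permutation of the five subtypes")
  for (sc in c("ror_s", "ror_ps")) {
    co <- ror_coefficients[[sc]]
    if (is.null(co) || is.null(co$weights) || is.null(co$bounds))
      .stopf("ror_coefficients$%s must provide weights and bounds", sc)
    cut <- risk_cutoffs[[sc]]
    if (is.null(cut) || length(cut) != 2L || diff(cut) <= 0)
      .stopf("risk_cutoffs$%s must be an increasing pair", sc)
  }
  structure(list(correlation_method = correlation_method,
                 ambiguity_threshold = ambiguity_threshold,
                 proliferation_genes = proliferation_genes,
                 ror_coefficients = ror_coefficients,
                 risk_cutoffs = risk_cutoffs,
                 tie_break = tie_break),
            class = "Pam50Config")
}

#' Default risk-of-recurrence coefficients
#'
#' Subtype weights are the standard published ones for the
#' correlation-based risk score (0.05 Basal, 0.12 Her2, -0.34 LumA,
#' 0.23 LumB, Normal-like excluded via weight 0). The proliferation weight
#' for ROR+PS (0.17) and the linear rescaling bounds are this package's
#' stand-ins, chosen so the raw score range maps onto 0-100; they are
#' configuration, not a claim about any external implementation.
#'
#' @return Named list with `ror_s` and `ror_ps` coefficient sets.
#' @export
default_ror_coefficients <- function() {
  w <- c(Basal = 0.05, Her2 = 0.12, LumA = -0.34, LumB = 0.23, Normal = 0)
  list(
    ror_s = list(weights = w, proliferation_weight = 0,
                 bounds = c(-0.74, 0.74)),
    ror_ps = list(weights = w, proliferation_weight = 0.17,
                  bounds = c(-1.08, 1.08))
  )
}

#' Default risk-group cutoffs
#'
#' Low/med and med/high boundaries on the 0-100 scale: 29/52 for ROR and
#' 23/52 for ROR+PS. Binning is half-open (a score exactly at a boundary
#' falls in the upper class).
#'
#' @return Named list with `ror_s` and `ror_ps` cutoff pairs.
#' @export
default_risk_cutoffs <- function() {
  list(ror_s = c(low_med = 29, med_high = 52),
       ror_ps = c(low_med = 23, med_high = 52))
}

#' Read a classifier configuration from JSON
#'
#' Any field absent from the file keeps its [pam50_config()] default.
#'
#' @param path JSON file path.
#' @return A `Pam50Config`.
#' @export
read_pam50_config <- function(path) {
  if (!file.exists(path)) .stopf("file not found: %s", path)
  js <- jsonlite::read_json(path, simplifyVector = TRUE)
  args <- list()
  for (f in c("correlation_method", "ambiguity_threshold",
              "proliferation_genes", "tie_break"))
    if (!is.null(js[[f]])) args[[f]] <- js[[f]]
  if (!is.null(js$ror_coefficients)) {
    rc <- lapply(js$ror_coefficients, function(co) {
      co$weights <- unlist(co$weights)
      co$bounds <- as.numeric(unlist(co$bounds))
      co
    })
    args$ror_coefficients <- rc
  }
  if (!is.null(js$risk_cutoffs))
    args$risk_cutoffs <- lapply(js$risk_cutoffs, function(x) as.numeric(unlist(x)))
  do.call(pam50_config, args)
}

#' Correlate one sample profile to every subtype centroid
#'
#' @param profile Named numeric vector of log2, median-adjusted expression
#'   covering every centroid gene (extra genes are ignored).
#' @param centroids A `CentroidMatrix`.
#' @param method `"spearman"` or `"pearson"`.
#' @return Named numeric vector of 5 correlations in [-1, 1], in subtype
#'   order.
#' @export
centroid_correlations <- function(profile, centroids,
                                  method = c("spearman", "pearson")) {
  method <- match.arg(method)
  stopifnot(inherits(centroids, "CentroidMatrix"))
  genes <- rownames(centroids)
  missing <- setdiff(genes, names(profile))
  if (length(missing))
    .stopf("profile is missing centroid gene(s): %s",
           paste(missing, collapse = ", "))
  x <- as.numeric(profile[genes])
  if (anyNA(x) || any(!is.finite(x))) .stopf("profile contains non-finite values")
  if (diff(range(x)) == 0)
    .stopf("constant profile: correlation undefined")
  vapply(pam50_subtypes(),
         function(st) stats::cor(x, unclass(centroids)[, st], method = method),
         numeric(1))
}

#' Assign a subtype from centroid correlations
#'
#' The call is the subtype with the highest correlation; the second call is
#' the runner-up. The call is ambiguous when the top-two gap is less than
#' or equal to `ambiguity_threshold` (exact ties are broken by the fixed
#' `tie_break` order and always flagged ambiguous). Confidence is
#' `(top - second) / max(top, eps)` clipped to [0, 1] — this package's own
#' convention, since the assay's confidence formula is not public.
#'
#' @param correlations Named numeric vector of 5 finite correlations.
#' @param cfg A [pam50_config()].
#' @return List with `call`, `second_call`, `confidence`, `ambiguous`.
#' @export
assign_subtype <- function(correlations, cfg = pam50_config()) {
  if (!all(pam50_subtypes() %in% names(correlations)))
    .stopf("correlations must be named over the five subtypes")
  r <- correlations[cfg$tie_break]
  if (anyNA(r) || any(!is.finite(r))) .stopf("non-finite correlation")
  ord <- order(-r)              # stable: ties keep tie_break order
  top <- names(r)[ord[1L]]
  second <- names(r)[ord[2L]]
  gap <- unname(r[ord[1L]] - r[ord[2L]])
  conf <- gap / max(r[ord[1L]], .CONF_EPS)
  list(call = top, second_call = second,
       confidence = unname(min(max(conf, 0), 1)),
       ambiguous = gap <= cfg$ambiguity_threshold)
}

#' Proliferation score
#'
#' Arithmetic mean of the log2 expression of the configured proliferation
#' genes (default: the 11-gene set).
#'
#' @param profile Named numeric vector of log2 expression.
#' @param cfg A [pam50_config()].
#' @return A single number, in log2 units.
#' @export
proliferation_score <- function(profile, cfg = pam50_config()) {
  missing <- setdiff(cfg$proliferation_genes, names(profile))
  if (length(missing))
    .stopf("profile is missing proliferation gene(s): %s",
           paste(missing, collapse = ", "))
  mean(as.numeric(profile[cfg$proliferation_genes]))
}

#' Risk-of-recurrence score on the 0-100 scale
#'
#' Raw score = sum over subtypes of weight x correlation, plus
#' proliferation_weight x proliferation score for ROR+PS; linearly rescaled
#' so the configured bounds map to 0 and 100, then clipped to [0, 100].
#'
#' @param correlations Named numeric vector of 5 centroid correlations.
#' @param proliferation Proliferation score; required for `score = "ror_ps"`.
#' @param cfg A [pam50_config()].
#' @param score `"ror_s"` (subtype-only) or `"ror_ps"` (with proliferation).
#' @return A number in [0, 100].
#' @export
ror_score <- function(correlations, proliferation = NULL,
                      cfg = pam50_config(), score = c("ror_s", "ror_ps")) {
  score <- match.arg(score)
  co <- cfg$ror_coefficients[[score]]
  if (is.null(co)) .stopf("no coefficient set configured for %s", score)
  w <- co$weights
  missing <- setdiff(names(w)[w != 0], names(correlations))
  if (length(missing))
    .stopf("correlations missing for weighted subtype(s): %s",
           paste(missing, collapse = ", "))
  raw <- sum(w * as.numeric(correlations[names(w)]))
  pw <- if (is.null(co$proliferation_weight)) 0 else co$proliferation_weight
  if (pw != 0) {
    if (is.null(proliferation))
      .stopf("%s requires a proliferation score", score)
    raw <- raw + pw * proliferation
  }
  scaled <- 100 * (raw - co$bounds[1L]) / (co$bounds[2L] - co$bounds[1L])
  min(max(scaled, 0), 100)
}

#' Risk group from a 0-100 risk score
#'
#' Half-open binning: `low` below the low/med boundary, `med` from the
#' low/med boundary up to (not including) the med/high boundary, `high`
#' at or above the med/high boundary.
#'
#' @param score Numeric score(s) in [0, 100].
#' @param cfg A [pam50_config()].
#' @param which `"ror_s"` or `"ror_ps"` cutoff set.
#' @return Character vector over `{"low", "med", "high"}`.
#' @export
risk_group <- function(score, cfg = pam50_config(),
                       which = c("ror_s", "ror_ps")) {
  which <- match.arg(which)
  cut <- unname(cfg$risk_cutoffs[[which]])
  ifelse(score < cut[1L], "low", ifelse(score < cut[2L], "med", "high"))
}

#' Classify a cohort and score risk of recurrence
#'
#' Runs the full per-sample pipeline — centroid correlations, subtype call
#' with confidence and ambiguity, proliferation score, ROR and ROR+PS with
#' risk groups — over every column of a log2-normalized expression matrix.
#' A per-sample failure is rethrown with the sample id; samples are never
#' silently dropped. The subtype frequency table (percentages) is attached
#' as attribute `"subtype_frequencies"`.
#'
#' @param matrix An `ExpressionMatrix` with scale `log2_normalized`.
#' @param centroids A `CentroidMatrix`.
#' @param cfg A [pam50_config()].
#' @return A `data.frame` with one row per sample: `sample_id`, the five
#'   `cor_<subtype>` columns, `call`, `second_call`, `confidence`,
#'   `ambiguous`, `proliferation_score`, `ror_s`, `ror_s_group`, `ror_ps`,
#'   `ror_ps_group`.
#' @export
classify_cohort <- function(matrix, centroids, cfg = pam50_config()) {
  stopifnot(inherits(matrix, "ExpressionMatrix"))
  if (matrix$scale != "log2_normalized")
    .stopf("classifier requires log2-normalized input, got scale '%s'", matrix$scale)
  rows <- lapply(matrix$sample_ids, function(sid) {
    res <- tryCatch({
      profile <- matrix$values[, sid]
      names(profile) <- matrix$gene_ids
      r <- centroid_correlations(profile, centroids,
                                 method = cfg$correlation_method)
      a <- assign_subtype(r, cfg)
      p <- proliferation_score(profile, cfg)
      rs <- ror_score(r, p, cfg, "ror_s")
      rp <- ror_score(r, p, cfg, "ror_ps")
      data.frame(sample_id = sid,
                 cor_Basal = r[["Basal"]], cor_Her2 = r[["Her2"]],
                 cor_LumA = r[["LumA"]], cor_LumB = r[["LumB"]],
                 cor_Normal = r[["Normal"]],
                 call = a$call, second_call = a$second_call,
                 confidence = a$confidence, ambiguous = a$ambiguous,
                 proliferation_score = p,
                 ror_s = rs, ror_s_group = risk_group(rs, cfg, "ror_s"),
                 ror_ps = rp, ror_ps_group = risk_group(rp, cfg, "ror_ps"),
                 stringsAsFactors = FALSE)
    }, error = function(e) .stopf("sample '%s': %s", sid, conditionMessage(e)))
    res
  })
  calls <- do.call(rbind, rows)
  rownames(calls) <- NULL
  freq <- table(factor(calls$call, levels = pam50_subtypes()))
  attr(calls, "subtype_frequencies") <- 100 * as.numeric(freq) / nrow(calls)
  names(attr(calls, "subtype_frequencies")) <- pam50_subtypes()
  calls
}

#' Write / read a cohort call table as TSV
#'
#' @param calls A call table from [classify_cohort()].
#' @param path File path.
#' @return `path` (writer) or the call table (reader).
#' @export
write_pam50_calls <- function(calls, path) {
  out <- calls
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], .fmt_num)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pam50_calls
#' @export
read_pam50_calls <- function(path) {
  if (!file.exists(path)) .stopf("file not found: %s", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  num <- c("cor_Basal", "cor_Her2", "cor_LumA", "cor_LumB", "cor_Normal",
           "confidence", "proliferation_score", "ror_s", "ror_ps")
  for (cn in intersect(num, names(df))) df[[cn]] <- as.numeric(df[[cn]])
  if ("ambiguous" %in% names(df)) df$ambiguous <- as.logical(df$ambiguous)
  df
}
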