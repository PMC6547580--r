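#' @title Paired-platform agreement statistics
#' @name concordance
#' @description Everything needed to compare two platforms run on the same
#'   cohort: Spearman correlation with a large-sample p-value, the two-way
#'   mixed-effects single-measures ICC (consistency and absolute-agreement
#'   variants, F-based confidence intervals), Cohen's kappa on subtype
#'   calls, Bland-Altman limits of agreement, raw and ambiguity-adjusted
#'   call concordance with per-sample discordance records, risk-group
#'   discordance counts, per-gene agreement with the binned summary, and
#'   t-based mean/CI summaries.
NULL

#' Spearman rank correlation with large-sample p-value
#'
#' Average ranks for ties; p from the t approximation
#' `t = rho * sqrt((n-2)/(1-rho^2))` on n-2 degrees of freedom.
#'
#' @param x,y Paired numeric vectors, length >= 3.
#' @return List with `rho` and `p_value`.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) .stopf("x and y must have equal length")
  n <- length(x)
  if (n < 3L) .stopf("need n >= 3 pairs")
  if (diff(range(x)) == 0 || diff(range(y)) == 0)
    .stopf("constant vector: rank correlation undefined")
  rho <- stats::cor(rank(x), rank(y))
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  list(rho = rho, p_value = p)
}

# two-way ANOVA mean squares for an n x 2 paired layout
.paired_mean_squares <- function(x, y) {
  m <- cbind(x, y)
  n <- nrow(m); k <- ncol(m)
  grand <- mean(m)
  row_m <- rowMeans(m); col_m <- colMeans(m)
  msr <- k * sum((row_m - grand)^2) / (n - 1)
  msc <- n * sum((col_m - grand)^2) / (k - 1)
  resid <- m - outer(row_m, rep(1, k)) - outer(rep(1, n), col_m) + grand
  mse <- sum(resid^2) / ((n - 1) * (k - 1))
  list(n = n, k = k, msr = msr, msc = msc, mse = mse)
}

#' Two-way mixed-effects, single-measures ICC with 95% CI
#'
#' `consistency` is ICC(3,1): (MSR - MSE) / (MSR + (k-1) MSE), with the
#' exact F-based interval. `absolute_agreement` is the single-measures
#' absolute-agreement form, which also charges the platform (column) mean
#' square, with the Satterthwaite-approximated F interval.
#'
#' @param x,y Paired numeric vectors, length >= 5.
#' @param variant `"consistency"` (default) or `"absolute_agreement"`.
#' @param conf_level Confidence level (default 0.95).
#' @return List with `icc`, `ci_low`, `ci_high`, `variant`.
#' @export
icc_single_measures <- function(x, y,
                                variant = c("consistency", "absolute_agreement"),
                                conf_level = 0.95) {
  variant <- match.arg(variant)
  if (length(x) != length(y)) .stopf("x and y must have equal length")
  if (length(x) < 5L) .stopf("need n >= 5 pairs")
  ms <- .paired_mean_squares(x, y)
  n <- ms$n; k <- ms$k
  if (stats::var(rowMeans(cbind(x, y))) == 0) {
    warning("zero between-subject variance: ICC defined as 0")
    return(list(icc = 0, ci_low = NA_real_, ci_high = NA_real_,
                variant = variant))
  }
  alpha <- 1 - conf_level
  if (variant == "consistency") {
    icc <- (ms$msr - ms$mse) / (ms$msr + (k - 1) * ms$mse)
    if (ms$mse == 0) {
      ci <- c(1, 1)
    } else {
      fobs <- ms$msr / ms$mse
      df1 <- n - 1; df2 <- (n - 1) * (k - 1)
      fl <- fobs / stats::qf(1 - alpha / 2, df1, df2)
      fu <- fobs * stats::qf(1 - alpha / 2, df2, df1)
      ci <- c((fl - 1) / (fl + k - 1), (fu - 1) / (fu + k - 1))
    }
  } else {
    icc <- (ms$msr - ms$mse) /
      (ms$msr + (k - 1) * ms$mse + (k / n) * (ms$msc - ms$mse))
    if (ms$mse == 0) {
      ci <- c(icc, icc)   # degenerate: no residual variance
    } else {
      fj <- ms$msc / ms$mse
      a <- (k * icc) / (n * (1 - icc))
      b <- 1 + (k * icc * (n - 1)) / (n * (1 - icc))
      v <- ((a * fj + b)^2) /
        ((a^2 * fj^2) / (k - 1) + b^2 / (n - 1))
      fl <- stats::qf(1 - alpha / 2, n - 1, v)
      fu <- stats::qf(1 - alpha / 2, v, n - 1)
      lo <- n * (ms$msr - fl * ms$mse) /
        (fl * (k * ms$msc + (k * n - k - n) * ms$mse) + n * ms$msr)
      hi <- n * (fu * ms$msr - ms$mse) /
        (k * ms$msc + (k * n - k - n) * ms$mse + n * fu * ms$msr)
      ci <- c(lo, hi)
    }
  }
  list(icc = icc, ci_low = min(ci), ci_high = max(ci), variant = variant)
}

#' Cohen's kappa for paired categorical calls
#'
#' Chance-corrected agreement `(p_obs - p_exp) / (1 - p_exp)` from the
#' cross-table over the shared category universe.
#'
#' @param calls_a,calls_b Equal-length character/factor vectors.
#' @param levels Category universe; defaults to the union of observed
#'   categories.
#' @return A single number.
#' @export
cohen_kappa <- function(calls_a, calls_b, levels = NULL) {
  if (length(calls_a) != length(calls_b))
    .stopf("call vectors must have equal length")
  if (is.null(levels)) levels <- sort(unique(c(as.character(calls_a),
                                               as.character(calls_b))))
  a <- factor(calls_a, levels = levels)
  b <- factor(calls_b, levels = levels)
  tab <- table(a, b)
  n <- sum(tab)
  p_obs <- sum(diag(tab)) / n
  p_exp <- sum(rowSums(tab) * colSums(tab)) / n^2
  if (p_exp >= 1) {
    warning("both raters constant and equal: kappa defined as 1")
    return(1)
  }
  (p_obs - p_exp) / (1 - p_exp)
}

#' Bland-Altman agreement statistics
#'
#' Differences d = x - y; limits of agreement are the mean difference
#' +/- 1.96 standard deviations.
#'
#' @param x,y Paired numeric vectors, length >= 2.
#' @return A `BlandAltmanStats` list: `mean_difference`, `sd_difference`,
#'   `lower_limit`, `upper_limit`, and the per-sample `pairs` data frame
#'   (columns `mean`, `difference`).
#' @export
bland_altman <- function(x, y) {
  if (length(x) != length(y)) .stopf("x and y must have equal length")
  if (length(x) < 2L) .stopf("need n >= 2 pairs")
  d <- x - y
  md <- mean(d)
  sdd <- stats::sd(d)
  structure(list(mean_difference = md, sd_difference = sdd,
                 lower_limit = md - 1.96 * sdd,
                 upper_limit = md + 1.96 * sdd,
                 pairs = data.frame(mean = (x + y) / 2, difference = d)),
            class = "BlandAltmanStats")
}

#' Pair two platforms' call tables
#'
#' Validates that both tables cover the same samples and aligns the second
#' to the first's order.
#'
#' @param calls_a,calls_b Call tables from [classify_cohort()].
#' @param platforms Length-2 character vector naming the two platforms.
#' @return A `PairedCalls` list with elements `a`, `b`, `platforms`.
#' @export
pair_calls <- function(calls_a, calls_b, platforms = c("a", "b")) {
  if (!setequal(calls_a$sample_id, calls_b$sample_id))
    .stopf("platforms cover different sample sets")
  if (anyDuplicated(calls_a$sample_id) || anyDuplicated(calls_b$sample_id))
    .stopf("duplicate sample ids in a call table")
  b <- calls_b[match(calls_a$sample_id, calls_b$sample_id), , drop = FALSE]
  rownames(b) <- NULL
  structure(list(a = calls_a, b = b, platforms = platforms),
            class = "PairedCalls")
}

.cor_gap <- function(row) {
  r <- sort(as.numeric(row[paste0("cor_", pam50_subtypes())]),
            decreasing = TRUE)
  r[1L] - r[2L]
}

#' Raw and ambiguity-adjusted subtype concordance
#'
#' `raw` is the fraction of samples with identical calls. A raw-discordant
#' sample is *rescued* when either platform's call is a near-tie (top-two
#' gap <= `threshold`) and that platform's second call equals the other
#' platform's call. Near-ties whose second call does not match are tallied
#' separately as `near_tie_unresolved`; with `count_any_near_tie = TRUE`
#' (default) they are also discounted from discordance, so `adjusted`
#' counts a sample as concordance-eligible whenever its discordance is
#' explainable by an ambiguous call on either platform. Both tallies are
#' always reported.
#'
#' @param paired A [pair_calls()] object.
#' @param threshold Near-tie gap threshold (default 0.10).
#' @param count_any_near_tie Logical; see above.
#' @return List with `raw`, `adjusted`, `n`, `n_raw_discordant`,
#'   `n_rescued_matching`, `n_near_tie_unresolved`, and a
#'   `discordance_records` data frame (one row per raw-discordant sample:
#'   both calls and second calls, both top-two gaps, `rescued_by` and
#'   `rescue_type`).
#' @export
raw_and_adjusted_concordance <- function(paired, threshold = 0.10,
                                         count_any_near_tie = TRUE) {
  stopifnot(inherits(paired, "PairedCalls"))
  a <- paired$a; b <- paired$b
  n <- nrow(a)
  disc <- which(a$call != b$call)
  records <- NULL
  n_match <- 0L; n_near <- 0L; n_adjusted_ok <- 0L
  if (length(disc)) {
    recs <- lapply(disc, function(i) {
      gap_a <- .cor_gap(a[i, ]); gap_b <- .cor_gap(b[i, ])
      near_a <- gap_a <= threshold; near_b <- gap_b <= threshold
      match_a <- near_a && a$second_call[i] == b$call[i]
      match_b <- near_b && b$second_call[i] == a$call[i]
      rescue_type <- if (match_a || match_b) "second_call_match"
        else if (near_a || near_b) "near_tie_unresolved"
        else "real_discordance"
      rescued_by <- paste(c(if (near_a) paired$platforms[1L],
                            if (near_b) paired$platforms[2L]), collapse = "+")
      data.frame(sample_id = a$sample_id[i],
                 call_a = a$call[i], call_b = b$call[i],
                 second_call_a = a$second_call[i],
                 second_call_b = b$second_call[i],
                 gap_a = gap_a, gap_b = gap_b,
                 rescue_type = rescue_type,
                 rescued_by = ifelse(rescued_by == "", NA, rescued_by),
                 stringsAsFactors = FALSE)
    })
    records <- do.call(rbind, recs)
    n_match <- sum(records$rescue_type == "second_call_match")
    n_near <- sum(records$rescue_type == "near_tie_unresolved")
  }
  n_rescued <- if (count_any_near_tie) n_match + n_near else n_match
  raw <- (n - length(disc)) / n
  adjusted <- (n - length(disc) + n_rescued) / n
  list(raw = raw, adjusted = adjusted, n = n,
       n_raw_discordant = length(disc),
       n_rescued_matching = n_match,
       n_near_tie_unresolved = n_near,
       discordance_records = records)
}

#' Risk-group discordance between platforms
#'
#' @param paired A [pair_calls()] object whose call tables carry
#'   `ror_s_group` and `ror_ps_group` columns.
#' @return List with `n_discordant_ror`, `n_discordant_ror_ps`, and a
#'   per-sample `records` data frame for every sample discordant on either
#'   score.
#' @export
risk_group_discordance <- function(paired) {
  stopifnot(inherits(paired, "PairedCalls"))
  a <- paired$a; b <- paired$b
  d_s <- a$ror_s_group != b$ror_s_group
  d_p <- a$ror_ps_group != b$ror_ps_group
  any_d <- d_s | d_p
  records <- data.frame(sample_id = a$sample_id[any_d],
                        ror_s_group_a = a$ror_s_group[any_d],
                        ror_s_group_b = b$ror_s_group[any_d],
                        ror_ps_group_a = a$ror_ps_group[any_d],
                        ror_ps_group_b = b$ror_ps_group[any_d],
                        stringsAsFactors = FALSE)
  list(n_discordant_ror = sum(d_s), n_discordant_ror_ps = sum(d_p),
       records = records)
}

#' Per-gene cross-platform agreement
#'
#' For every shared gene: Spearman rho with p-value and the consistency
#' ICC across platforms; plus the binned rho counts (> 0.9, 0.8-0.9,
#' 0.7-0.8, < 0.7), the fraction above 0.8, and the median/mean ICC.
#' A gene constant on either platform gets NA statistics with a reason.
#'
#' @param matrix_a,matrix_b Log2-scale `ExpressionMatrix` objects with
#'   harmonized gene ids and the same samples.
#' @return List with `per_gene` (data frame: gene, rho, p_value, icc,
#'   reason), `bins` (named counts), `fraction_above_0.8`, `median_icc`,
#'   `mean_icc`.
#' @export
per_gene_agreement <- function(matrix_a, matrix_b) {
  stopifnot(inherits(matrix_a, "ExpressionMatrix"),
            inherits(matrix_b, "ExpressionMatrix"))
  genes <- intersect(matrix_a$gene_ids, matrix_b$gene_ids)
  if (!length(genes)) .stopf("no shared genes")
  if (!setequal(matrix_a$sample_ids, matrix_b$sample_ids))
    .stopf("platforms cover different samples")
  samples <- matrix_a$sample_ids
  rows <- lapply(genes, function(g) {
    x <- matrix_a$values[g, samples]
    y <- matrix_b$values[g, samples]
    if (diff(range(x)) == 0 || diff(range(y)) == 0)
      return(data.frame(gene = g, rho = NA_real_, p_value = NA_real_,
                        icc = NA_real_, reason = "constant gene",
                        stringsAsFactors = FALSE))
    sp <- spearman_rho(x, y)
    ic <- icc_single_measures(x, y, "consistency")
    data.frame(gene = g, rho = sp$rho, p_value = sp$p_value, icc = ic$icc,
               reason = NA_character_, stringsAsFactors = FALSE)
  })
  per_gene <- do.call(rbind, rows)
  list(per_gene = per_gene,
       bins = bin_correlations(per_gene$rho[!is.na(per_gene$rho)]),
       fraction_above_0.8 = mean(per_gene$rho > 0.8, na.rm = TRUE),
       median_icc = stats::median(per_gene$icc, na.rm = TRUE),
       mean_icc = mean(per_gene$icc, na.rm = TRUE))
}

#' Bin a vector of correlation coefficients
#'
#' The standard reporting bins for per-gene agreement: above 0.9,
#' (0.8, 0.9], (0.7, 0.8], and 0.7 or below.
#'
#' @param rho Numeric vector of correlations.
#' @return Named integer vector `gt_0.9`, `0.8_to_0.9`, `0.7_to_0.8`,
#'   `le_0.7`.
#' @export
bin_correlations <- function(rho) {
  c(`gt_0.9` = sum(rho > 0.9),
    `0.8_to_0.9` = sum(rho > 0.8 & rho <= 0.9),
    `0.7_to_0.8` = sum(rho > 0.7 & rho <= 0.8),
    `le_0.7` = sum(rho <= 0.7))
}

#' Mean with extrema and t-based 95% CI
#'
#' @param values Numeric vector, length >= 2, all finite.
#' @param conf_level Confidence level (default 0.95).
#' @return List with `mean`, `min`, `max`, `ci_low`, `ci_high`.
#' @export
summary_stats <- function(values, conf_level = 0.95) {
  if (length(values) < 2L) .stopf("need n >= 2 values")
  if (any(!is.finite(values))) .stopf("values must be finite")
  n <- length(values)
  m <- mean(values)
  se <- stats::sd(values) / sqrt(n)
  tq <- stats::qt(1 - (1 - conf_level) / 2, df = n - 1)
  list(mean = m, min = min(values), max = max(values),
       ci_low = m - tq * se, ci_high = m + tq * se)
}

#' Full paired-platform concordance report
#'
#' Assembles the complete agreement picture between two platforms: the 5x5
#' call cross-table with Cohen's kappa, raw and ambiguity-adjusted
#' concordance with discordance records, risk-group discordance, ROR /
#' ROR+PS and proliferation-score agreement (Spearman rho, consistency and
#' absolute-agreement ICC with CIs, Bland-Altman), per-subtype
#' cross-platform correlation of the centroid correlations, and — when the
#' expression matrices are supplied — per-gene agreement. Per-gene p-values
#' are reported without multiple-testing correction (raw correlations are
#' the report's contract); the report records that choice in its `notes`.
#'
#' @param paired A [pair_calls()] object.
#' @param matrix_a,matrix_b Optional log2 `ExpressionMatrix` pair for
#'   per-gene agreement.
#' @param threshold Near-tie threshold for adjusted concordance.
#' @param count_any_near_tie Passed to [raw_and_adjusted_concordance()].
#' @return A `ConcordanceReport` list.
#' @export
concordance_report <- function(paired, matrix_a = NULL, matrix_b = NULL,
                               threshold = 0.10, count_any_near_tie = TRUE) {
  stopifnot(inherits(paired, "PairedCalls"))
  a <- paired$a; b <- paired$b
  lv <- pam50_subtypes()
  crosstab <- table(factor(a$call, lv), factor(b$call, lv),
                    dnn = paired$platforms)
  conc <- raw_and_adjusted_concordance(paired, threshold, count_any_near_tie)
  score_agreement <- function(x, y) {
    sp <- spearman_rho(x, y)
    icc_c <- icc_single_measures(x, y, "consistency")
    icc_a <- icc_single_measures(x, y, "absolute_agreement")
    list(spearman_rho = sp$rho, p_value = sp$p_value,
         icc = icc_c$icc, icc_ci_low = icc_c$ci_low,
         icc_ci_high = icc_c$ci_high,
         icc_absolute = icc_a$icc, icc_absolute_ci_low = icc_a$ci_low,
         icc_absolute_ci_high = icc_a$ci_high,
         bland_altman = bland_altman(x, y))
  }
  centroidwise <- vapply(lv, function(st) {
    spearman_rho(a[[paste0("cor_", st)]], b[[paste0("cor_", st)]])$rho
  }, numeric(1))
  report <- list(
    platforms = paired$platforms,
    n = nrow(a),
    crosstab = crosstab,
    kappa = cohen_kappa(a$call, b$call, levels = lv),
    raw_concordance = conc$raw,
    adjusted_concordance = conc$adjusted,
    n_raw_discordant = conc$n_raw_discordant,
    n_rescued_matching = conc$n_rescued_matching,
    n_near_tie_unresolved = conc$n_near_tie_unresolved,
    discordance_records = conc$discordance_records,
    risk_groups = risk_group_discordance(paired),
    ror_agreement = list(ror_s = score_agreement(a$ror_s, b$ror_s),
                         ror_ps = score_agreement(a$ror_ps, b$ror_ps),
                         proliferation = score_agreement(a$proliferation_score,
                                                         b$proliferation_score)),
    centroidwise_rho = centroidwise,
    per_gene = if (!is.null(matrix_a) && !is.null(matrix_b))
      per_gene_agreement(matrix_a, matrix_b),
    notes = "per-gene p-values are uncorrected for multiple testing"
  )
  structure(report, class = "ConcordanceReport")
}

#' @export
print.ConcordanceReport <- function(x, ...) {
  cat(sprintf("ConcordanceReport (%s vs %s, n = %d)\n",
              x$platforms[1L], x$platforms[2L], x$n))
  cat(sprintf("  raw concordance:      %d/%d = %.1f%%\n",
              x$n - x$n_raw_discordant, x$n, 100 * x$raw_concordance))
  cat(sprintf("  adjusted concordance: %.1f%% (kappa %.3f)\n",
              100 * x$adjusted_concordance, x$kappa))
  cat(sprintf("  ROR rho %.3f, ROR+PS rho %.3f, proliferation rho %.3f\n",
              x$ror_agreement$ror_s$spearman_rho,
              x$ror_agreement$ror_ps$spearman_rho,
              x$ror_agreement$proliferation$spearman_rho))
  if (!is.null(x$per_gene))
    cat(sprintf("  per-gene median ICC %.3f; %.0f%% of genes rho > 0.8\n",
                x$per_gene$median_icc, 100 * x$per_gene$fraction_above_0.8))
  invisible(x)
}

#' Write a concordance report to a directory
#'
#' Emits `report.json` (scalar summaries), plus TSV tables: `crosstab.tsv`,
#' `discordance_records.tsv`, `risk_group_records.tsv`, `per_gene.tsv`
#' (when present) and `bland_altman_<score>.tsv` pair tables.
#'
#' @param report A `ConcordanceReport`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_concordance_report <- function(report, dir) {
  stopifnot(inherits(report, "ConcordanceReport"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  scalars <- report[c("platforms", "n", "kappa", "raw_concordance",
                      "adjusted_concordance", "n_raw_discordant",
                      "n_rescued_matching", "n_near_tie_unresolved",
                      "centroidwise_rho", "notes")]
  scalars$ror_agreement <- lapply(report$ror_agreement, function(sa) {
    ba <- sa$bland_altman
    sa$bland_altman <- ba[c("mean_difference", "sd_difference",
                            "lower_limit", "upper_limit")]
    sa
  })
  scalars$risk_groups <- report$risk_groups[c("n_discordant_ror",
                                              "n_discordant_ror_ps")]
  if (!is.null(report$per_gene))
    scalars$per_gene_summary <- report$per_gene[c("bins", "fraction_above_0.8",
                                                  "median_icc", "mean_icc")]
  jsonlite::write_json(scalars, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  utils::write.table(as.data.frame.matrix(report$crosstab),
                     file.path(dir, "crosstab.tsv"),
                     sep = "\t", quote = FALSE)
  if (!is.null(report$discordance_records))
    utils::write.table(report$discordance_records,
                       file.path(dir, "discordance_records.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  if (nrow(report$risk_groups$records))
    utils::write.table(report$risk_groups$records,
                       file.path(dir, "risk_group_records.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(report$per_gene))
    utils::write.table(report$per_gene$per_gene,
                       file.path(dir, "per_gene.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  for (sc in names(report$ror_agreement))
    utils::write.table(report$ror_agreement[[sc]]$bland_altman$pairs,
                       file.path(dir, sprintf("bland_altman_%s.tsv", sc)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
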