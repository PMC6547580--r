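# small in-code fixtures shared across test files

# 3 endogenous genes, 2 housekeepers, 2 negatives, n samples
tiny_probe_table <- function(n_samples = 2, seed = 42) {
  set.seed(seed)
  genes <- c("ESR1", "ERBB2", "MKI67")
  hk <- c("ACTB", "PUM1")
  neg <- c("NEG_01", "NEG_02")
  counts <- rbind(
    matrix(round(runif(3 * n_samples, 50, 500)), 3, n_samples),
    matrix(round(runif(2 * n_samples, 100, 200)), 2, n_samples),
    matrix(rpois(2 * n_samples, 10), 2, n_samples))
  rownames(counts) <- c(genes, hk, neg)
  colnames(counts) <- sprintf("S%02d", seq_len(n_samples))
  probe_count_table(counts, data.frame(
    probe_name = rownames(counts),
    gene_symbol = rownames(counts),
    probe_class = c(rep("endogenous", 3), rep("housekeeping", 2),
                    rep("negative", 2)),
    stringsAsFactors = FALSE))
}

tiny_expr <- function(values, platform = "other", scale = "log2_normalized") {
  expression_matrix(values, platform = platform, scale = scale)
}

rand_expr <- function(n_genes = 10, n_samples = 4, seed = 1,
                      scale = "log2_normalized") {
  set.seed(seed)
  m <- matrix(rnorm(n_genes * n_samples), n_genes, n_samples,
              dimnames = list(sprintf("G%02d", seq_len(n_genes)),
                              sprintf("S%02d", seq_len(n_samples))))
  tiny_expr(m, scale = scale)
}

# minimal call table rows for concordance tests
make_calls <- function(sample_ids, calls, second = NULL, gaps = NULL,
                       ror_s = 50, ror_s_group = "med",
                       ror_ps = 50, ror_ps_group = "med") {
  n <- length(sample_ids)
  if (is.null(second)) second <- rep("Normal", n)
  if (is.null(gaps)) gaps <- rep(0.5, n)
  # encode the desired top-two gap into the correlation columns
  cors <- matrix(-0.5, n, 5,
                 dimnames = list(NULL, paste0("cor_", pam50_subtypes())))
  for (i in seq_len(n)) {
    cors[i, paste0("cor_", calls[i])] <- 0.8
    cors[i, paste0("cor_", second[i])] <- 0.8 - gaps[i]
  }
  data.frame(sample_id = sample_ids, cors,
             call = calls, second_call = second,
             confidence = gaps, ambiguous = gaps <= 0.1,
             proliferation_score = 0,
             ror_s = rep_len(ror_s, n), ror_s_group = rep_len(ror_s_group, n),
             ror_ps = rep_len(ror_ps, n), ror_ps_group = rep_len(ror_ps_group, n),
             stringsAsFactors = FALSE)
}

# type-7 quantile computed by explicit sorting (independent of stats::quantile)
sort_quantile75 <- function(x) {
  x <- unname(sort(x))
  h <- (length(x) - 1) * 0.75 + 1
  lo <- floor(h)
  x[lo] + (h - lo) * (if (lo < length(x)) x[lo + 1] - x[lo] else 0)
}
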