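test_that("spearman rho handles perfect order, reversal, and ties", {
  x <- c(1.2, 3.4, 2.2, 5.0, 4.1)
  expect_equal(spearman_rho(x, x)$rho, 1.0)
  expect_equal(spearman_rho(x, -x)$rho, -1.0)
  expect_equal(spearman_rho(x, x)$p_value, 0)
  # tie case against an explicit average-rank oracle
  y <- c(2, 2, 3, 5, 4)
  got <- spearman_rho(x, y)
  rx <- rank(x); ry <- c(1.5, 1.5, 3, 5, 4)
  oracle <- sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  expect_equal(got$rho, oracle, tolerance = 1e-12)
  # large-sample p matches the t transform
  tstat <- got$rho * sqrt(3 / (1 - got$rho^2))
  expect_equal(got$p_value, 2 * pt(-abs(tstat), 3), tolerance = 1e-12)
  expect_error(spearman_rho(rep(1, 5), y), "constant")
  expect_error(spearman_rho(1:2, 2:1), "n >= 3")
})

test_that("ICC variants behave on exact and shifted agreement", {
  x <- c(1, 2, 3, 4, 5, 6)
  expect_equal(icc_single_measures(x, x, "consistency")$icc, 1.0)
  shifted <- icc_single_measures(x, x + 2, "consistency")
  expect_equal(shifted$icc, 1.0)
  abs_agree <- icc_single_measures(x, x + 2, "absolute_agreement")
  expect_lt(abs_agree$icc, 1.0)
  expect_gt(abs_agree$icc, 0)
})

test_that("ICC matches the two-way ANOVA mean-squares oracle", {
  x <- c(9, 6, 8, 7, 10, 6)
  y <- c(2, 1, 4, 1, 5, 2)
  got_c <- icc_single_measures(x, y, "consistency")
  got_a <- icc_single_measures(x, y, "absolute_agreement")
  # oracle: explicit ANOVA table via aov on the long layout
  d <- data.frame(val = c(x, y),
                  subj = factor(rep(1:6, 2)),
                  rater = factor(rep(1:2, each = 6)))
  ms <- summary(aov(val ~ subj + rater, data = d))[[1]][["Mean Sq"]]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  expect_equal(got_c$icc, (msr - mse) / (msr + mse), tolerance = 1e-10)
  expect_equal(got_a$icc,
               (msr - mse) / (msr + mse + (2 / 6) * (msc - mse)),
               tolerance = 1e-10)
  # F-based CI brackets the estimate
  expect_true(got_c$ci_low <= got_c$icc && got_c$icc <= got_c$ci_high)
  expect_true(got_a$ci_low <= got_a$icc && got_a$icc <= got_a$ci_high)
})

test_that("ICC degenerate input yields 0 with a warning", {
  expect_warning(res <- icc_single_measures(rep(3, 6), rep(3, 6)),
                 "zero between-subject")
  expect_equal(res$icc, 0)
})

test_that("Cohen's kappa: identity, closed form, independence limit", {
  a <- c("Basal", "Her2", "LumA", "Basal", "Her2")
  expect_equal(cohen_kappa(a, a), 1)
  # 2x2 table a=45, b=5, c=5, d=45 -> p_obs .9, p_exp .5, kappa .8
  x <- rep(c("P", "P", "N", "N"), c(45, 5, 5, 45))
  y <- rep(c("P", "N", "P", "N"), c(45, 5, 5, 45))
  expect_equal(cohen_kappa(x, y), (0.9 - 0.5) / (1 - 0.5), tolerance = 1e-12)
  # independent raters: kappa near zero
  set.seed(2024)
  n <- 1e4
  r1 <- sample(pam50_subtypes(), n, TRUE, prob = c(.5, .2, .15, .1, .05))
  r2 <- sample(pam50_subtypes(), n, TRUE, prob = c(.5, .2, .15, .1, .05))
  expect_lt(abs(cohen_kappa(r1, r2)), 0.05)
  expect_warning(k <- cohen_kappa(rep("Basal", 4), rep("Basal", 4)),
                 "constant")
  expect_equal(k, 1)
})

test_that("Bland-Altman statistics match hand computation and antisymmetry", {
  x <- c(10, 12, 15)
  y <- c(11, 11, 13)
  ba <- bland_altman(x, y)
  d <- c(-1, 1, 2)
  expect_equal(ba$mean_difference, mean(d))
  expect_equal(ba$sd_difference, sd(d))
  expect_equal(ba$lower_limit, mean(d) - 1.96 * sd(d))
  expect_equal(ba$upper_limit, mean(d) + 1.96 * sd(d))
  expect_equal(ba$pairs$mean, (x + y) / 2)
  z <- bland_altman(x, x)
  expect_equal(z$mean_difference, 0)
  expect_equal(z$lower_limit, 0)
  expect_equal(z$upper_limit, 0)
  expect_equal(bland_altman(y, x)$mean_difference, -ba$mean_difference)
})

test_that("raw/adjusted concordance implements the rescue rule", {
  ids <- sprintf("S%02d", 1:4)
  a <- make_calls(ids, c("Basal", "Basal", "Her2", "LumA"),
                  second = c("Her2", "Her2", "Basal", "LumB"),
                  gaps = c(0.5, 0.05, 0.5, 0.5))
  b <- make_calls(ids, c("Basal", "Her2", "Her2", "LumB"),
                  second = c("Her2", "Basal", "Basal", "LumA"),
                  gaps = c(0.5, 0.5, 0.5, 0.5))
  paired <- pair_calls(a, b)
  res <- raw_and_adjusted_concordance(paired, threshold = 0.10)
  # S02: platform A near-tie (gap .05) and its second call matches B -> rescued
  expect_equal(res$raw, 2 / 4)
  expect_equal(res$adjusted, 3 / 4)
  expect_equal(res$n_rescued_matching, 1)
  rec <- res$discordance_records
  expect_identical(rec$rescue_type[rec$sample_id == "S02"], "second_call_match")
  expect_identical(rec$rescue_type[rec$sample_id == "S04"], "real_discordance")
  # identical calls: raw = adjusted = 1
  same <- raw_and_adjusted_concordance(pair_calls(a, a))
  expect_equal(same$raw, 1)
  expect_equal(same$adjusted, 1)
  expect_null(same$discordance_records)
})

test_that("adjusted >= raw and both are non-decreasing in the threshold", {
  set.seed(61)
  ids <- sprintf("S%02d", 1:30)
  a <- make_calls(ids, sample(pam50_subtypes(), 30, TRUE),
                  second = sample(pam50_subtypes()[-1], 30, TRUE),
                  gaps = runif(30, 0, 0.4))
  b <- make_calls(ids, sample(pam50_subtypes(), 30, TRUE),
                  second = sample(pam50_subtypes()[-1], 30, TRUE),
                  gaps = runif(30, 0, 0.4))
  # keep call != second_call
  a$second_call[a$second_call == a$call] <-
    ifelse(a$call[a$second_call == a$call] == "Normal", "LumA", "Normal")
  b$second_call[b$second_call == b$call] <-
    ifelse(b$call[b$second_call == b$call] == "Normal", "LumA", "Normal")
  paired <- pair_calls(a, b)
  prev <- 0
  for (th in c(0, 0.05, 0.1, 0.2, 0.5)) {
    res <- raw_and_adjusted_concordance(paired, th)
    expect_gte(res$adjusted, res$raw)
    expect_gte(res$adjusted, prev)
    prev <- res$adjusted
  }
})

test_that("concordance statistics are permutation-equivariant", {
  set.seed(62)
  ids <- sprintf("S%02d", 1:20)
  a <- make_calls(ids, sample(pam50_subtypes(), 20, TRUE),
                  ror_s = runif(20, 0, 100))
  b <- make_calls(ids, sample(pam50_subtypes(), 20, TRUE),
                  ror_s = runif(20, 0, 100))
  perm <- sample(20)
  p1 <- pair_calls(a, b)
  p2 <- pair_calls(a[perm, ], b[perm, ])
  expect_equal(raw_and_adjusted_concordance(p1)$raw,
               raw_and_adjusted_concordance(p2)$raw)
  expect_equal(cohen_kappa(a$call, b$call),
               cohen_kappa(a$call[perm], b$call[perm]))
  expect_equal(spearman_rho(p1$a$ror_s, p1$b$ror_s)$rho,
               spearman_rho(p2$a$ror_s, p2$b$ror_s)$rho)
})

test_that("risk-group discordance counts injected flips exactly", {
  ids <- sprintf("S%02d", 1:10)
  a <- make_calls(ids, rep("Basal", 10))
  same <- risk_group_discordance(pair_calls(a, a))
  expect_equal(same$n_discordant_ror, 0)
  expect_equal(same$n_discordant_ror_ps, 0)
  for (k in c(1, 3, 5)) {
    b <- a
    b$ror_s_group[seq_len(k)] <- "high"
    res <- risk_group_discordance(pair_calls(a, b))
    expect_equal(res$n_discordant_ror, k)
    expect_equal(res$n_discordant_ror_ps, 0)
    expect_identical(res$records$sample_id, ids[seq_len(k)])
  }
})

test_that("per-gene agreement: identity, shift invariance, constant genes", {
  m <- rand_expr(n_genes = 6, n_samples = 8, seed = 71)
  res <- per_gene_agreement(m, m)
  expect_true(all(res$per_gene$rho == 1))
  expect_true(all(abs(res$per_gene$icc - 1) < 1e-12))
  expect_equal(res$median_icc, 1)
  # per-gene constant shifts leave rank correlation at 1
  shifted <- tiny_expr(m$values + seq_len(6))
  res2 <- per_gene_agreement(m, shifted)
  expect_true(all(res2$per_gene$rho == 1))
  # a constant gene is recorded as missing with a reason, not dropped
  v <- m$values; v["G03", ] <- 7
  res3 <- per_gene_agreement(tiny_expr(v), m)
  row <- res3$per_gene[res3$per_gene$gene == "G03", ]
  expect_true(is.na(row$rho))
  expect_identical(row$reason, "constant gene")
})

test_that("summary statistics match the t-interval oracle", {
  v <- c(2.1, 1.9, 2.3, 2.0, 1.8, 2.2, 2.4, 1.7, 2.05, 1.95)
  s <- summary_stats(v)
  m <- mean(v); se <- sd(v) / sqrt(10); tq <- qt(0.975, 9)
  expect_equal(s$mean, m)
  expect_equal(s$ci_low, m - tq * se, tolerance = 1e-12)
  expect_equal(s$ci_high, m + tq * se, tolerance = 1e-12)
  expect_true(s$min <= s$mean && s$mean <= s$max)
  const <- summary_stats(rep(5, 4))
  expect_equal(const$ci_low, 5)
  expect_equal(const$ci_high, 5)
  expect_error(summary_stats(3), "n >= 2")
})

test_that("the assembled report is coherent and writes its artifact set", {
  set.seed(81)
  cen <- generate_centroids(50, 81)
  cfg <- sim_config(n_samples = 24, seed = 81, injected_discordance = 2)
  sim <- simulate_cohort(cfg, cen)
  res <- analyze_paired_cohort(sim, cen,
                               generate_reference_medians(cen, cfg))
  rep <- res$report
  expect_equal(sum(rep$crosstab), rep$n)
  expect_gte(rep$adjusted_concordance, rep$raw_concordance)
  expect_lte(rep$kappa, 1)
  expect_true(all(rep$centroidwise_rho >= -1 & rep$centroidwise_rho <= 1))
  ba <- rep$ror_agreement$ror_s$bland_altman
  expect_true(ba$lower_limit <= ba$mean_difference &&
              ba$mean_difference <= ba$upper_limit)
  out <- withr::local_tempdir()
  write_concordance_report(rep, out)
  expect_true(file.exists(file.path(out, "report.json")))
  expect_true(file.exists(file.path(out, "crosstab.tsv")))
  expect_true(file.exists(file.path(out, "per_gene.tsv")))
  js <- jsonlite::read_json(file.path(out, "report.json"))
  expect_equal(js$n, rep$n)
  expect_equal(js$raw_concordance, rep$raw_concordance)
})
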