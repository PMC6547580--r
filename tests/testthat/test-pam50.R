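centroids <- generate_centroids(50, seed = 123)

test_that("centroid correlations: self-correlation, rank invariance, oracle", {
  prof <- unclass(centroids)[, "Basal"]
  r <- centroid_correlations(prof, centroids, "spearman")
  expect_equal(unname(r["Basal"]), 1.0)
  expect_true(all(r >= -1 & r <= 1))
  # a strictly increasing transform leaves Spearman untouched
  r2 <- centroid_correlations(2^unclass(centroids)[, "LumA"], centroids,
                              "spearman")
  expect_equal(unname(r2["LumA"]), 1.0)
  # brute-force rank-then-Pearson oracle on a random profile
  set.seed(77)
  prof3 <- rnorm(50); names(prof3) <- rownames(centroids)
  r3 <- centroid_correlations(prof3, centroids, "spearman")
  for (st in pam50_subtypes()) {
    rx <- rank(prof3[rownames(centroids)])
    ry <- rank(unclass(centroids)[, st])
    oracle <- sum((rx - mean(rx)) * (ry - mean(ry))) /
      sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
    expect_equal(unname(r3[st]), oracle, tolerance = 1e-12)
  }
})

test_that("centroid correlations validate their input", {
  prof <- unclass(centroids)[, "Basal"]
  expect_error(centroid_correlations(prof[-1], centroids),
               rownames(centroids)[1])
  const <- rep(1, 50); names(const) <- rownames(centroids)
  expect_error(centroid_correlations(const, centroids), "constant profile")
})

test_that("subtype assignment applies the ambiguity rule at the 0.10 gap", {
  r <- c(Basal = 0.80, Her2 = 0.30, LumA = -0.40, LumB = -0.20, Normal = 0.00)
  a <- assign_subtype(r)
  expect_identical(a$call, "Basal")
  expect_identical(a$second_call, "Her2")
  expect_false(a$ambiguous)
  expect_equal(a$confidence, (0.80 - 0.30) / 0.80)
  # gap exactly 0.10 is ambiguous ("less or equal")
  r2 <- c(Basal = 0.60, Her2 = 0.50, LumA = 0, LumB = 0, Normal = 0)
  expect_true(assign_subtype(r2)$ambiguous)
  r3 <- c(Basal = 0.60, Her2 = 0.4999, LumA = 0, LumB = 0, Normal = 0)
  expect_false(assign_subtype(r3)$ambiguous)
})

test_that("exact ties resolve by the fixed subtype order, flagged ambiguous", {
  r <- c(Basal = 0.3, Her2 = 0.3, LumA = 0.3, LumB = 0.3, Normal = 0.3)
  for (i in 1:3) {
    a <- assign_subtype(r)
    expect_identical(a$call, "Basal")
    expect_identical(a$second_call, "Her2")
    expect_true(a$ambiguous)
    expect_equal(a$confidence, 0)
  }
  # at threshold 0 the rule reduces to plain argmax; only exact ties flag
  cfg0 <- pam50_config(ambiguity_threshold = 0)
  set.seed(15)
  for (i in 1:50) {
    rr <- runif(5, -1, 1); names(rr) <- pam50_subtypes()
    a0 <- assign_subtype(rr, cfg0)
    expect_identical(a0$call, names(which.max(rr)))
    expect_identical(a0$ambiguous, sum(rr == max(rr)) > 1)
  }
})

test_that("proliferation score is the mean log2 of the 11-gene set", {
  expect_length(proliferation_genes(), 11)
  prof <- rep(2.5, 11); names(prof) <- proliferation_genes()
  expect_equal(proliferation_score(prof), 2.5)
  set.seed(31)
  prof2 <- rnorm(50); names(prof2) <- pam50_genes()
  oracle <- sum(prof2[proliferation_genes()]) / 11
  expect_equal(proliferation_score(prof2), oracle, tolerance = 1e-12)
  expect_error(proliferation_score(prof2[-match("MKI67", names(prof2))]),
               "MKI67")
})

test_that("risk scores are affine in the correlations and bounded", {
  cfg <- pam50_config()
  r <- c(Basal = 0.5, Her2 = -0.2, LumA = 0.1, LumB = 0.3, Normal = 0)
  # all-zero weights: every sample lands on the rescaling intercept
  co0 <- default_ror_coefficients()
  co0$ror_s$weights[] <- 0
  cfg0 <- pam50_config(ror_coefficients = co0)
  s0 <- ror_score(r, cfg = cfg0, score = "ror_s")
  expect_equal(s0, 100 * (0 - -0.74) / 1.48)
  expect_equal(ror_score(r * 0 + c(Basal = 1, Her2 = -1, LumA = 0, LumB = 0,
                                   Normal = 0), cfg = cfg0, score = "ror_s"), s0)
  # determinism
  expect_identical(ror_score(r, 1.2, cfg, "ror_ps"),
                   ror_score(r, 1.2, cfg, "ror_ps"))
  # single nonzero weight: affine in that correlation (two-point oracle)
  co1 <- default_ror_coefficients()
  co1$ror_s$weights[] <- 0; co1$ror_s$weights["LumB"] <- 0.4
  cfg1 <- pam50_config(ror_coefficients = co1)
  f <- function(x) ror_score(c(Basal = 0, Her2 = 0, LumA = 0, LumB = x,
                               Normal = 0), cfg = cfg1, score = "ror_s")
  x1 <- -0.5; x2 <- 0.75; slope <- (f(x2) - f(x1)) / (x2 - x1)
  expect_equal(f(0.2), f(x1) + slope * (0.2 - x1), tolerance = 1e-12)
  # bounds and error contracts
  set.seed(41)
  for (i in 1:25) {
    rr <- runif(5, -1, 1); names(rr) <- pam50_subtypes()
    s <- ror_score(rr, runif(1, -3, 3), cfg, "ror_ps")
    expect_true(s >= 0 && s <= 100)
  }
  expect_error(ror_score(r, NULL, cfg, "ror_ps"), "proliferation")
})

test_that("risk groups use half-open cutoffs", {
  cfg <- pam50_config()
  expect_identical(risk_group(16.87, cfg, "ror_s"), "low")
  expect_identical(risk_group(43.57, cfg, "ror_s"), "med")
  # boundary value falls in the upper class
  expect_identical(risk_group(29, cfg, "ror_s"), "med")
  expect_identical(risk_group(52, cfg, "ror_s"), "high")
  expect_identical(risk_group(28.999, cfg, "ror_s"), "low")
  expect_identical(risk_group(c(0, 30, 99), cfg, "ror_s"),
                   c("low", "med", "high"))
})

test_that("classifying the centroid profiles recovers each subtype", {
  m <- unclass(centroids)
  colnames(m) <- paste0("sample_", pam50_subtypes())
  calls <- classify_cohort(tiny_expr(m), centroids)
  expect_identical(calls$call, pam50_subtypes())
  expect_false(any(calls$ambiguous))
  # self-correlation tops out at 1, so confidence is the gap itself
  expect_true(all(calls$confidence > 0.1))
  freq <- attr(calls, "subtype_frequencies")
  expect_equal(unname(freq), rep(20, 5))
})

test_that("cohort classification is order-equivariant and spearman-invariant", {
  set.seed(55)
  v <- matrix(rnorm(50 * 8), 50, 8,
              dimnames = list(rownames(centroids), sprintf("S%d", 1:8)))
  calls <- classify_cohort(tiny_expr(v), centroids)
  perm <- c(5, 3, 8, 1, 2, 7, 4, 6)
  calls_p <- classify_cohort(tiny_expr(v[, perm]), centroids)
  reordered <- calls[perm, ]; rownames(reordered) <- NULL
  attr(reordered, "subtype_frequencies") <- attr(calls_p, "subtype_frequencies")
  expect_equal(calls_p, reordered)
  # strictly increasing per-sample transform changes nothing (spearman)
  calls_t <- classify_cohort(tiny_expr(v^3), centroids)
  expect_identical(calls_t$call, calls$call)
  expect_equal(calls_t[paste0("cor_", pam50_subtypes())],
               calls[paste0("cor_", pam50_subtypes())], tolerance = 1e-12)
})

test_that("per-sample failures carry the sample id and nothing is dropped", {
  v <- matrix(rnorm(100), 50, 2,
              dimnames = list(rownames(centroids), c("ok", "broken")))
  v[, 2] <- 1  # constant profile
  expect_error(classify_cohort(tiny_expr(v), centroids), "broken")
})

test_that("subtype recovery does not improve as platform noise grows", {
  rates <- vapply(c(0, 0.2, 0.5), function(ns) {
    cfg <- sim_config(n_samples = 200, bio_sd = 0,
                      platform_noise_sd = c(nanostring = ns, rnaseq = ns),
                      seed = 99)
    sim <- simulate_cohort(cfg, centroids)
    norm <- normalize_nanostring_arm(sim$nanostring)
    calls <- classify_cohort(norm, centroids)
    mean(calls$call == sim$truth$true_subtype)
  }, numeric(1))
  expect_true(all(diff(rates) <= 0))
  expect_equal(rates[1], 1)
})

test_that("the JSON config round-trips through read_pam50_config", {
  path <- system.file("extdata", "pam50_config.json", package = "pamconcord")
  cfg <- read_pam50_config(path)
  ref <- pam50_config()
  expect_equal(cfg$ambiguity_threshold, ref$ambiguity_threshold)
  expect_identical(cfg$proliferation_genes, ref$proliferation_genes)
  expect_equal(cfg$ror_coefficients$ror_s$weights,
               ref$ror_coefficients$ror_s$weights)
  expect_equal(unname(cfg$risk_cutoffs$ror_ps),
               unname(ref$risk_cutoffs$ror_ps))
})
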