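#' @title Paired-platform cohort simulation with ground truth
#' @name synthetic-data
#' @description Generates everything the pipeline consumes — a centroid
#'   matrix with the field's known correlation structure, a digital probe
#'   count table (endogenous + housekeeping + negative-control probes), a
#'   raw RNA-Seq count matrix, receptor-balanced reference medians and a
#'   ground-truth table — for a cohort with a configurable subtype mixture,
#'   biological and platform noise, and optionally injected between-platform
#'   call flips. Defaults emulate a 96-sample triple-negative cohort
#'   dominated by Basal-like tumors. Noise is additive Gaussian on the log2
#'   scale before count generation; when the biological and platform SDs
#'   are zero the generator emits deterministic expected counts, so the
#'   noiseless limit is exact by construction.
NULL

#' Simulation settings
#'
#' @param n_samples Cohort size (default 96).
#' @param subtype_mixture Named probabilities over the five subtypes
#'   (default Basal .82, Her2 .13, LumA .04, LumB .01, Normal 0 — a
#'   Basal-dominated triple-negative call distribution).
#' @param n_genes Signature size (default 50).
#' @param n_housekeepers Housekeeper probes (default 5).
#' @param n_negative_probes Negative-control probes (default 8).
#' @param bio_sd Within-subtype biological SD, log2 units (default 0.5).
#' @param platform_noise_sd Named pair `c(nanostring=, rnaseq=)` of
#'   platform measurement SDs, log2 units (default 0.2 each).
#' @param nanostring_scale Count magnitude of the digital platform
#'   (default 500 counts at log2 expression 0).
#' @param rnaseq_library_size_range Range the per-sample RNA-Seq library
#'   size is drawn from (default 1e5 to 3e5 over the 50-gene panel).
#' @param negative_mean Poisson mean of negative-control probes (default 10).
#' @param injected_discordance Number of samples whose RNA-Seq profile is
#'   resampled from a different subtype's centroid (default 0).
#' @param seed Integer seed; fixed seed gives bit-reproducible output.
#' @return A `SimulationConfig` list.
#' @export
sim_config <- function(n_samples = 96,
                       subtype_mixture = c(Basal = 0.82, Her2 = 0.13,
                                           LumA = 0.04, LumB = 0.01,
                                           Normal = 0),
                       n_genes = 50, n_housekeepers = 5,
                       n_negative_probes = 8,
                       bio_sd = 0.5,
                       platform_noise_sd = c(nanostring = 0.2, rnaseq = 0.2),
                       nanostring_scale = 500,
                       rnaseq_library_size_range = c(1e5, 3e5),
                       negative_mean = 10,
                       injected_discordance = 0,
                       seed = 1) {
  if (!setequal(names(subtype_mixture), pam50_subtypes()))
    .stopf("subtype_mixture must be named over the five subtypes")
  subtype_mixture <- subtype_mixture[pam50_subtypes()]
  if (any(subtype_mixture < 0) || abs(sum(subtype_mixture) - 1) > 1e-8)
    .stopf("subtype_mixture must be non-negative and sum to 1")
  if (bio_sd < 0 || any(platform_noise_sd < 0))
    .stopf("all SDs must be >= 0")
  if (!all(c("nanostring", "rnaseq") %in% names(platform_noise_sd)))
    .stopf("platform_noise_sd must name nanostring and rnaseq")
  if (injected_discordance < 0 || injected_discordance > n_samples)
    .stopf("injected_discordance must be in [0, n_samples]")
  structure(list(n_samples = n_samples, subtype_mixture = subtype_mixture,
                 n_genes = n_genes, n_housekeepers = n_housekeepers,
                 n_negative_probes = n_negative_probes, bio_sd = bio_sd,
                 platform_noise_sd = platform_noise_sd,
                 nanostring_scale = nanostring_scale,
                 rnaseq_library_size_range = rnaseq_library_size_range,
                 negative_mean = negative_mean,
                 injected_discordance = injected_discordance,
                 seed = as.integer(seed)),
            class = "SimulationConfig")
}

.sim_gene_names <- function(n_genes) {
  base <- pam50_genes()
  if (n_genes <= length(base)) base[seq_len(n_genes)]
  else c(base, sprintf("G%03d", seq_len(n_genes - length(base))))
}

# legacy -> modern renaming used for the RNA-Seq arm's gene ids
.modernize <- function(ids) {
  legacy <- unclass(default_alias_map())         # modern -> legacy
  rev_map <- structure(names(legacy), names = legacy)
  hit <- ids %in% names(rev_map)
  ids[hit] <- rev_map[ids[hit]]
  ids
}

#' Generate a synthetic centroid matrix
#'
#' Five prototype profiles with the correlation structure seen in real
#' centroid sets: Basal-like strongly anti-correlated with LumA, and
#' HER2-enriched positively correlated with LumB; Normal-like independent.
#' Proliferation genes get a subtype-dependent offset (high in Basal,
#' HER2-enriched and LumB; low in LumA and Normal-like) so risk scores
#' separate the subtypes the way the assay intends. Values are on the
#' log2, median-centered scale the classifier expects.
#'
#' @param n_genes Number of genes, >= 10 (default 50; the first 50 names
#'   are the signature's legacy symbols).
#' @param seed Integer seed.
#' @return A `CentroidMatrix`.
#' @export
generate_centroids <- function(n_genes = 50, seed = 1) {
  if (n_genes < 10) .stopf("need n_genes >= 10")
  set.seed(seed)
  z1 <- stats::rnorm(n_genes); z2 <- stats::rnorm(n_genes)
  z3 <- stats::rnorm(n_genes)
  e1 <- stats::rnorm(n_genes); e2 <- stats::rnorm(n_genes)
  m <- cbind(Basal = z1,
             Her2 = z2,
             LumA = -0.7 * z1 + sqrt(1 - 0.7^2) * e1,
             LumB = 0.7 * z2 + sqrt(1 - 0.7^2) * e2,
             Normal = z3)
  genes <- .sim_gene_names(n_genes)
  rownames(m) <- genes
  prolif <- intersect(proliferation_genes(), genes)
  offset <- c(Basal = 0.7, Her2 = 0.5, LumA = -0.7, LumB = 0.5, Normal = -0.7)
  m[prolif, ] <- sweep(m[prolif, , drop = FALSE], 2L, offset, `+`)
  centroid_matrix(m)
}

#' Simulate a paired-platform cohort
#'
#' Per sample: a subtype is drawn from the mixture; the biological profile
#' is that subtype's centroid plus Gaussian log2 noise (`bio_sd`). The
#' digital arm observes `round(scale * 2^(profile + noise) * library
#' factor)` counts with near-constant housekeepers and Poisson
#' negative-control probes; the RNA-Seq arm draws a library size and
#' multinomial counts proportional to `2^(profile + noise)` (modern gene
#' symbols, exercising alias harmonization). Samples selected for injected
#' discordance have their RNA-Seq profile resampled from a different
#' subtype's centroid. With all SDs zero, counts are deterministic expected
#' values.
#'
#' @param cfg A [sim_config()].
#' @param centroids A `CentroidMatrix`; defaults to
#'   [generate_centroids()] at the config's seed.
#' @return List with `nanostring` (`ProbeCountTable`), `rnaseq` (raw
#'   `ExpressionMatrix`), `truth` (data frame: `sample_id`,
#'   `true_subtype`, `flipped`, `flip_target`), and `profiles` (pre-noise
#'   log2 profile matrices per platform).
#' @export
simulate_cohort <- function(cfg = sim_config(),
                            centroids = generate_centroids(cfg$n_genes, cfg$seed)) {
  stopifnot(inherits(cfg, "SimulationConfig"),
            inherits(centroids, "CentroidMatrix"))
  set.seed(cfg$seed + 1L)
  n <- cfg$n_samples
  genes <- rownames(centroids)
  n_genes <- length(genes)
  sample_ids <- sprintf("S%03d", seq_len(n))
  mix <- cfg$subtype_mixture
  labels <- sample(pam50_subtypes(), n, replace = TRUE, prob = mix)

  flip_idx <- integer(0)
  flip_target <- rep(NA_character_, n)
  if (cfg$injected_discordance > 0) {
    flip_idx <- sort(sample.int(n, cfg$injected_discordance))
    for (i in flip_idx) {
      alt <- setdiff(pam50_subtypes()[mix > 0], labels[i])
      if (!length(alt))
        .stopf("cannot inject discordance: mixture supports a single subtype")
      p_alt <- mix[alt] / sum(mix[alt])
      flip_target[i] <- if (length(alt) == 1L) alt
        else sample(alt, 1L, prob = p_alt)
    }
  }

  noise_ns <- cfg$platform_noise_sd[["nanostring"]]
  noise_rs <- cfg$platform_noise_sd[["rnaseq"]]
  deterministic <- cfg$bio_sd == 0 && noise_ns == 0 && noise_rs == 0

  # one biological profile per tumor, shared by both platforms; flipped
  # samples get an independently drawn profile on the RNA-Seq arm only
  bio <- function() if (cfg$bio_sd == 0) 0 else stats::rnorm(n_genes, 0, cfg$bio_sd)
  p_ns <- vapply(seq_len(n),
                 function(i) unclass(centroids)[, labels[i]] + bio(),
                 numeric(n_genes))
  p_rs <- p_ns
  for (i in flip_idx)
    p_rs[, i] <- unclass(centroids)[, flip_target[i]] + bio()
  dimnames(p_ns) <- dimnames(p_rs) <- list(genes, sample_ids)

  add_noise <- function(p, sd) if (sd == 0) p
    else p + matrix(stats::rnorm(length(p), 0, sd), nrow(p))

  # --- digital arm -----------------------------------------------------
  lib_ns <- if (deterministic) rep(1, n) else 2^stats::rnorm(n, 0, 0.15)
  endo <- sweep(cfg$nanostring_scale * 2^add_noise(p_ns, noise_ns),
                2L, lib_ns, `*`)
  hk_names <- default_housekeepers()[seq_len(min(cfg$n_housekeepers, 5L))]
  if (cfg$n_housekeepers > 5L)
    hk_names <- c(hk_names, sprintf("HK%02d", seq_len(cfg$n_housekeepers - 5L)))
  hk_base <- seq(3, 5, length.out = cfg$n_housekeepers)
  hk_sd <- 0.25 * noise_ns
  hk_log <- matrix(hk_base, cfg$n_housekeepers, n)
  hk <- sweep(cfg$nanostring_scale * 2^add_noise(hk_log, hk_sd), 2L, lib_ns, `*`)
  neg_names <- sprintf("NEG_%02d", seq_len(cfg$n_negative_probes))
  neg <- matrix(stats::rpois(cfg$n_negative_probes * n, cfg$negative_mean),
                cfg$n_negative_probes, n)
  counts <- rbind(if (deterministic) rbind(endo, hk) else round(rbind(endo, hk)),
                  neg)
  rownames(counts) <- c(genes, hk_names, neg_names)
  colnames(counts) <- sample_ids
  probes <- data.frame(
    probe_name = rownames(counts),
    gene_symbol = c(genes, hk_names, neg_names),
    probe_class = c(rep("endogenous", n_genes),
                    rep("housekeeping", cfg$n_housekeepers),
                    rep("negative", cfg$n_negative_probes)),
    stringsAsFactors = FALSE)
  ns_table <- probe_count_table(counts, probes)

  # --- RNA-Seq arm -----------------------------------------------------
  rs_expr <- 2^add_noise(p_rs, noise_rs)
  lib_range <- cfg$rnaseq_library_size_range
  lib_rs <- round(stats::runif(n, lib_range[1L], lib_range[2L]))
  rs_counts <- vapply(seq_len(n), function(i) {
    p <- rs_expr[, i] / sum(rs_expr[, i])
    if (deterministic) lib_rs[i] * p
    else as.numeric(stats::rmultinom(1L, lib_rs[i], p))
  }, numeric(n_genes))
  rownames(rs_counts) <- .modernize(genes)
  colnames(rs_counts) <- sample_ids
  rs_matrix <- expression_matrix(rs_counts, platform = "rnaseq", scale = "raw")

  truth <- data.frame(sample_id = sample_ids, true_subtype = labels,
                      flipped = seq_len(n) %in% flip_idx,
                      flip_target = flip_target, stringsAsFactors = FALSE)
  list(nanostring = ns_table, rnaseq = rs_matrix, truth = truth,
       profiles = list(nanostring = p_ns, rnaseq = p_rs))
}

#' Reference medians from a balanced pseudo-reference cohort
#'
#' Emulates the externally determined receptor-balanced median set: a
#' cohort balanced over the five subtypes is simulated, normalized with
#' the requested platform's recipe, and per-gene medians taken (on
#' canonical legacy symbols).
#'
#' @param centroids A `CentroidMatrix`.
#' @param cfg A [sim_config()] (noise settings and seed are reused; the
#'   reference cohort uses an offset seed and 10 samples per subtype).
#' @param per_subtype Samples per subtype in the reference (default 10).
#' @param platform `"rnaseq"` (default) or `"nanostring"`: which arm's
#'   normalization recipe the medians are taken on.
#' @return Named numeric vector of per-gene medians.
#' @export
generate_reference_medians <- function(centroids, cfg = sim_config(),
                                       per_subtype = 10,
                                       platform = c("rnaseq", "nanostring")) {
  platform <- match.arg(platform)
  ref_cfg <- sim_config(
    n_samples = 5L * per_subtype,
    subtype_mixture = c(Basal = .2, Her2 = .2, LumA = .2, LumB = .2,
                        Normal = .2),
    n_genes = nrow(centroids),
    n_housekeepers = cfg$n_housekeepers,
    n_negative_probes = cfg$n_negative_probes,
    bio_sd = cfg$bio_sd,
    platform_noise_sd = cfg$platform_noise_sd,
    rnaseq_library_size_range = cfg$rnaseq_library_size_range,
    negative_mean = cfg$negative_mean,
    seed = cfg$seed + 1000L)
  sim <- simulate_cohort(ref_cfg, centroids)
  norm <- if (platform == "rnaseq") {
    rnaseq_upper_quartile_normalize(
      harmonize_gene_ids(sim$rnaseq, default_alias_map()))
  } else {
    nanostring_housekeeper_normalize(
      nanostring_background_correct(sim$nanostring))
  }
  apply(norm$values, 1L, stats::median)
}

#' Read a simulation-config snapshot written by [emit_fixture_set()]
#'
#' @param path `sim_config.json` file path.
#' @return A `SimulationConfig`.
#' @export
read_sim_config <- function(path) {
  if (!file.exists(path)) .stopf("file not found: %s", path)
  js <- jsonlite::read_json(path, simplifyVector = TRUE)
  sim_config(n_samples = js$n_samples,
             subtype_mixture = unlist(js$subtype_mixture),
             n_genes = js$n_genes, n_housekeepers = js$n_housekeepers,
             n_negative_probes = js$n_negative_probes, bio_sd = js$bio_sd,
             platform_noise_sd = unlist(js$platform_noise_sd),
             nanostring_scale = js$nanostring_scale,
             rnaseq_library_size_range = as.numeric(js$rnaseq_library_size_range),
             negative_mean = js$negative_mean,
             injected_discordance = js$injected_discordance,
             seed = js$seed)
}

#' Write a complete fixture set to a directory
#'
#' Emits six files — `centroids.tsv`, `probe_counts.tsv`,
#' `rnaseq_counts.tsv`, `reference_medians.tsv`, `truth.tsv`,
#' `sim_config.json` — plus `manifest.json` listing them with the seed.
#' Same seed, same bytes.
#'
#' @param out_dir Output directory (created if needed).
#' @param cfg A [sim_config()].
#' @return The manifest list (files, seed), invisibly.
#' @export
emit_fixture_set <- function(out_dir, cfg = sim_config()) {
  ok <- dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) .stopf("cannot create directory: %s", out_dir)
  centroids <- generate_centroids(cfg$n_genes, cfg$seed)
  sim <- simulate_cohort(cfg, centroids)
  ref_med <- generate_reference_medians(centroids, cfg)
  files <- c(centroids = "centroids.tsv", probe_counts = "probe_counts.tsv",
             rnaseq_counts = "rnaseq_counts.tsv",
             reference_medians = "reference_medians.tsv",
             truth = "truth.tsv", config = "sim_config.json")
  write_centroids(centroids, file.path(out_dir, files["centroids"]))
  write_probe_counts(sim$nanostring, file.path(out_dir, files["probe_counts"]))
  write_expression_matrix(sim$rnaseq, file.path(out_dir, files["rnaseq_counts"]))
  utils::write.table(
    data.frame(gene_id = names(ref_med), median = .fmt_num(ref_med),
               stringsAsFactors = FALSE),
    file.path(out_dir, files["reference_medians"]),
    sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$truth, file.path(out_dir, files["truth"]),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  cfg_out <- unclass(cfg)
  # named vectors as JSON objects, not nameless arrays
  cfg_out$subtype_mixture <- as.list(cfg_out$subtype_mixture)
  cfg_out$platform_noise_sd <- as.list(cfg_out$platform_noise_sd)
  jsonlite::write_json(cfg_out, file.path(out_dir, files["config"]),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest <- list(files = as.list(files), seed = cfg$seed)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Read a reference-median table written by [emit_fixture_set()]
#'
#' @param path TSV with columns `gene_id`, `median`.
#' @return Named numeric vector.
#' @export
read_reference_medians <- function(path) {
  if (!file.exists(path)) .stopf("file not found: %s", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (!all(c("gene_id", "median") %in% names(df)))
    .stopf("malformed reference median file")
  structure(as.numeric(df$median), names = df$gene_id)
}
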