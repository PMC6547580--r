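#' @title Tabular I/O and gene-identifier harmonization
#' @name io-formats
#' @description Readers and writers for the pipeline's plain-text artifacts
#'   (probe count tables, expression matrices, centroid matrices, alias
#'   maps) plus cross-platform gene symbol harmonization. All files are
#'   UTF-8 TSV with '.' decimal; numbers are written with 17 significant
#'   digits so every writer/reader pair is a lossless round trip.
NULL

PROBE_CLASSES <- c("endogenous", "housekeeping", "negative", "positive")

# full-precision numeric formatting: round-trips doubles exactly
.fmt_num <- function(x) sprintf("%.17g", x)

.stopf <- function(...) stop(sprintf(...), call. = FALSE)

#' Construct a validated probe count table
#'
#' @param counts Numeric matrix, probes in rows, samples in columns; row
#'   names are probe names, column names are sample ids.
#' @param probes `data.frame` with columns `probe_name`, `gene_symbol`,
#'   `probe_class` (one of endogenous, housekeeping, negative, positive),
#'   one row per row of `counts`, in the same order.
#' @return An object of class `ProbeCountTable`.
#' @export
probe_count_table <- function(counts, probes) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  req <- c("probe_name", "gene_symbol", "probe_class")
  if (!all(req %in% names(probes)))
    .stopf("probe annotation must have columns: %s", paste(req, collapse = ", "))
  probes <- data.frame(probes[req], stringsAsFactors = FALSE)
  if (nrow(probes) != nrow(counts))
    .stopf("probe annotation has %d rows but counts has %d", nrow(probes), nrow(counts))
  if (anyDuplicated(probes$probe_name))
    .stopf("duplicate probe names: %s",
           paste(unique(probes$probe_name[duplicated(probes$probe_name)]), collapse = ", "))
  bad <- setdiff(unique(probes$probe_class), PROBE_CLASSES)
  if (length(bad))
    .stopf("unknown probe_class: %s", paste(bad, collapse = ", "))
  if (anyNA(counts) || any(counts < 0))
    .stopf("probe counts must be non-negative and complete")
  if (is.null(colnames(counts)))
    .stopf("counts must have sample ids as column names")
  rownames(counts) <- probes$probe_name
  structure(list(counts = counts, probes = probes,
                 sample_ids = colnames(counts)),
            class = "ProbeCountTable")
}

#' @export
print.ProbeCountTable <- function(x, ...) {
  cat(sprintf("ProbeCountTable: %d probes x %d samples (%s)\n",
              nrow(x$counts), ncol(x$counts),
              paste(sprintf("%s=%d", names(table(x$probes$probe_class)),
                            as.integer(table(x$probes$probe_class))),
                    collapse = ", ")))
  invisible(x)
}

#' Read a probe count table
#'
#' Two dialects are accepted. `tsv` is the canonical format: a header line
#' `probe_name  gene_symbol  probe_class  <sample...>` followed by one row
#' per probe. `rcc_like` accepts the CSV CodeSummary section of digital
#' count exports: lines between `<CodeSummary>` and `</CodeSummary>` with
#' header `CodeClass,Name,Accession,<sample...>`; CodeClass values are
#' mapped case-insensitively onto the canonical probe classes and the
#' Accession column is ignored.
#'
#' @param path File path.
#' @param dialect `"tsv"` (default) or `"rcc_like"`.
#' @return A `ProbeCountTable`.
#' @export
read_probe_counts <- function(path, dialect = c("tsv", "rcc_like")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) .stopf("file not found: %s", path)
  if (dialect == "tsv") {
    df <- utils::read.delim(path, header = TRUE, sep = "\t",
                            check.names = FALSE, stringsAsFactors = FALSE)
    req <- c("probe_name", "gene_symbol", "probe_class")
    if (ncol(df) < 4L || !identical(names(df)[1:3], req))
      .stopf("malformed header: expected columns %s then sample columns",
             paste(req, collapse = ", "))
    ann <- df[req]
    cnt <- df[-(1:3)]
  } else {
    lines <- readLines(path, warn = FALSE)
    open <- grep("^\\s*<CodeSummary>\\s*$", lines)
    close <- grep("^\\s*</CodeSummary>\\s*$", lines)
    if (length(open) != 1L || length(close) != 1L || close <= open + 1L)
      .stopf("malformed rcc_like file: need one <CodeSummary>...</CodeSummary> block")
    block <- lines[(open + 1L):(close - 1L)]
    df <- utils::read.csv(text = paste(block, collapse = "\n"), header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
    if (ncol(df) < 4L || !identical(tolower(names(df)[1:3]),
                                    c("codeclass", "name", "accession")))
      .stopf("malformed CodeSummary header: expected CodeClass,Name,Accession,<samples>")
    cls <- tolower(df[[1L]])
    cls[cls == "endogenous1"] <- "endogenous"
    ann <- data.frame(probe_name = df[[2L]], gene_symbol = df[[2L]],
                      probe_class = cls, stringsAsFactors = FALSE)
    cnt <- df[-(1:3)]
  }
  for (j in seq_along(cnt)) {
    v <- suppressWarnings(as.numeric(cnt[[j]]))
    if (anyNA(v) && !anyNA(cnt[[j]]))
      .stopf("non-numeric count in sample column '%s'", names(cnt)[j])
    cnt[[j]] <- v
  }
  m <- as.matrix(cnt)
  colnames(m) <- names(cnt)
  probe_count_table(m, ann)
}

#' Write a probe count table (canonical TSV dialect)
#'
#' @param table A `ProbeCountTable`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_probe_counts <- function(table, path) {
  stopifnot(inherits(table, "ProbeCountTable"))
  num <- apply(table$counts, 2L, .fmt_num)
  if (is.null(dim(num))) num <- matrix(num, nrow = nrow(table$counts))
  out <- data.frame(table$probes, num, check.names = FALSE,
                    stringsAsFactors = FALSE)
  names(out) <- c(names(table$probes), colnames(table$counts))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a validated expression matrix
#'
#' @param values Numeric matrix, genes in rows (row names = gene ids),
#'   samples in columns (column names = sample ids).
#' @param platform `"nanostring"`, `"rnaseq"` or `"other"`.
#' @param scale `"raw"` or `"log2_normalized"`. The classifier accepts only
#'   `log2_normalized` input.
#' @param housekeepers Optional character vector flagging housekeeper rows
#'   retained in the matrix.
#' @return An object of class `ExpressionMatrix`.
#' @export
expression_matrix <- function(values,
                              platform = c("other", "nanostring", "rnaseq"),
                              scale = c("raw", "log2_normalized"),
                              housekeepers = character()) {
  platform <- match.arg(platform)
  scale <- match.arg(scale)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(rownames(values)) || is.null(colnames(values)))
    .stopf("expression matrix needs gene row names and sample column names")
  dup <- unique(rownames(values)[duplicated(rownames(values))])
  if (length(dup))
    .stopf("duplicate gene ids: %s", paste(dup, collapse = ", "))
  if (anyNA(values) || any(!is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1L, ]
    .stopf("non-finite value at gene '%s', sample '%s'",
           rownames(values)[bad[1L]], colnames(values)[bad[2L]])
  }
  structure(list(gene_ids = rownames(values), sample_ids = colnames(values),
                 values = values, platform = platform, scale = scale,
                 housekeepers = as.character(housekeepers)),
            class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d genes x %d samples [%s, %s]\n",
              nrow(x$values), ncol(x$values), x$platform, x$scale))
  invisible(x)
}

#' Read a gene x sample expression matrix from TSV
#'
#' First column `gene_id`, then one numeric column per sample.
#'
#' @inheritParams expression_matrix
#' @param path File path.
#' @return An `ExpressionMatrix` with the declared platform and scale.
#' @export
read_expression_matrix <- function(path,
                                   platform = c("other", "nanostring", "rnaseq"),
                                   scale = c("raw", "log2_normalized")) {
  if (!file.exists(path)) .stopf("file not found: %s", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L || names(df)[1L] != "gene_id")
    .stopf("malformed header: expected 'gene_id' then sample columns")
  genes <- df[[1L]]
  cnt <- df[-1L]
  for (j in seq_along(cnt)) {
    v <- suppressWarnings(as.numeric(cnt[[j]]))
    if (anyNA(v) && !anyNA(cnt[[j]])) {
      i <- which(is.na(v) & !is.na(cnt[[j]]))[1L]
      .stopf("non-numeric cell at gene '%s', sample '%s'", genes[i], names(cnt)[j])
    }
    cnt[[j]] <- v
  }
  m <- as.matrix(cnt)
  rownames(m) <- genes
  colnames(m) <- names(cnt)
  expression_matrix(m, platform = platform, scale = scale)
}

#' Write an expression matrix to TSV
#'
#' @param matrix An `ExpressionMatrix`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(matrix, path) {
  stopifnot(inherits(matrix, "ExpressionMatrix"))
  num <- apply(matrix$values, 2L, .fmt_num)
  if (is.null(dim(num))) num <- base::matrix(num, nrow = nrow(matrix$values))
  out <- data.frame(gene_id = matrix$gene_ids, num, check.names = FALSE,
                    stringsAsFactors = FALSE)
  names(out) <- c("gene_id", matrix$sample_ids)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a validated centroid matrix
#'
#' @param values Numeric matrix, genes in rows, exactly the five subtype
#'   columns Basal, Her2, LumA, LumB, Normal.
#' @return A matrix of class `CentroidMatrix`.
#' @export
centroid_matrix <- function(values) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  missing <- setdiff(pam50_subtypes(), colnames(values))
  if (length(missing))
    .stopf("missing subtype column(s): %s", paste(missing, collapse = ", "))
  values <- values[, pam50_subtypes(), drop = FALSE]
  if (nrow(values) < 2L) .stopf("centroid matrix needs at least 2 genes")
  if (is.null(rownames(values))) .stopf("centroid matrix needs gene row names")
  if (anyDuplicated(rownames(values)))
    .stopf("duplicate genes in centroid matrix")
  const <- colnames(values)[apply(values, 2L, function(v) diff(range(v)) == 0)]
  if (length(const))
    .stopf("constant centroid column(s): %s", paste(const, collapse = ", "))
  structure(values, class = c("CentroidMatrix", "matrix"))
}

#' Read a centroid matrix from TSV
#'
#' Header `gene_id  Basal  Her2  LumA  LumB  Normal`; one row per gene.
#'
#' @param path File path.
#' @return A `CentroidMatrix`.
#' @export
read_centroids <- function(path) {
  if (!file.exists(path)) .stopf("file not found: %s", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1L] != "gene_id")
    .stopf("malformed header: expected 'gene_id' then subtype columns")
  m <- as.matrix(df[-1L])
  rownames(m) <- df[[1L]]
  centroid_matrix(m)
}

#' Write a centroid matrix to TSV
#'
#' @param centroids A `CentroidMatrix`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_centroids <- function(centroids, path) {
  stopifnot(inherits(centroids, "CentroidMatrix"))
  num <- apply(unclass(centroids), 2L, .fmt_num)
  out <- data.frame(gene_id = rownames(centroids), num, check.names = FALSE,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a gene alias map
#'
#' A functional alias -> canonical mapping. The map must be idempotent:
#' no canonical symbol may itself appear as an alias of a different symbol,
#' so applying the map twice equals applying it once.
#'
#' @param pairs Named character vector; names are aliases, values the
#'   canonical symbols.
#' @return An object of class `GeneAliasMap`.
#' @export
gene_alias_map <- function(pairs) {
  pairs <- unlist(pairs)
  if (length(pairs) && (is.null(names(pairs)) || any(names(pairs) == "")))
    .stopf("alias map entries must be named (alias = canonical)")
  if (anyDuplicated(names(pairs)))
    .stopf("alias mapped to more than one canonical symbol: %s",
           paste(unique(names(pairs)[duplicated(names(pairs))]), collapse = ", "))
  chained <- intersect(pairs, names(pairs))
  chained <- chained[pairs[chained] != chained]
  if (length(chained))
    .stopf("alias map is not idempotent; canonical symbol(s) also aliased: %s",
           paste(chained, collapse = ", "))
  structure(as.character(pairs), names = names(pairs), class = "GeneAliasMap")
}

#' Read a gene alias map from JSON
#'
#' The file is a single JSON object `{ "alias": "canonical", ... }`.
#'
#' @param path File path.
#' @return A `GeneAliasMap`.
#' @export
read_alias_map <- function(path) {
  if (!file.exists(path)) .stopf("file not found: %s", path)
  gene_alias_map(unlist(jsonlite::read_json(path)))
}

#' Harmonize gene identifiers across platforms
#'
#' Replaces alias symbols in an expression matrix by their canonical
#' symbols; genes absent from the map are unchanged and row order is
#' preserved. Two input genes collapsing onto one canonical symbol is an
#' error, never a silent merge.
#'
#' @param matrix An `ExpressionMatrix`.
#' @param aliases A `GeneAliasMap`.
#' @return The matrix with canonical gene ids.
#' @export
harmonize_gene_ids <- function(matrix, aliases) {
  stopifnot(inherits(matrix, "ExpressionMatrix"), inherits(aliases, "GeneAliasMap"))
  ids <- matrix$gene_ids
  hit <- ids %in% names(aliases)
  new_ids <- ids
  new_ids[hit] <- unclass(aliases)[ids[hit]]
  dup <- unique(new_ids[duplicated(new_ids)])
  if (length(dup))
    .stopf("ambiguous merge: multiple input genes map to %s",
           paste(dup, collapse = ", "))
  v <- matrix$values
  rownames(v) <- new_ids
  expression_matrix(v, platform = matrix$platform, scale = matrix$scale,
                    housekeepers = matrix$housekeepers)
}
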