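#' @title Gene sets and subtype constants
#' @name gene-sets
#' @description Fixed vocabularies used throughout the pipeline: the five
#'   intrinsic subtypes in their deterministic tie-break order, the 50-gene
#'   signature (legacy symbols, as used by the classifier's centroid files),
#'   the 11 proliferation genes, the default housekeeper panel for digital
#'   count normalization, and the modern-to-legacy symbol alias map.
NULL

#' Intrinsic subtype labels in tie-break order
#'
#' The fixed order Basal < Her2 < LumA < LumB < Normal is also the
#' deterministic tie-break order used by [assign_subtype()].
#'
#' @return Character vector of the five subtype labels.
#' @export
pam50_subtypes <- function() {
  c("Basal", "Her2", "LumA", "LumB", "Normal")
}

#' The 50-gene intrinsic signature (legacy symbols)
#'
#' Legacy symbols (KNTC2, CDCA1, ORC6L) are kept because published centroid
#' files use them; [default_alias_map()] maps current symbols onto these.
#'
#' @return Character vector of 50 gene symbols.
#' @export
pam50_genes <- function() {
  c("ACTR3B", "ANLN", "BAG1", "BCL2", "BIRC5", "BLVRA", "CCNB1", "CCNE1",
    "CDC20", "CDC6", "CDCA1", "CDH3", "CENPF", "CEP55", "CXXC5", "EGFR",
    "ERBB2", "ESR1", "EXO1", "FGFR4", "FOXA1", "FOXC1", "GPR160", "GRB7",
    "KIF2C", "KNTC2", "KRT14", "KRT17", "KRT5", "MAPT", "MDM2", "MELK",
    "MIA", "MKI67", "MLPH", "MMP11", "MYBL2", "MYC", "NAT1", "ORC6L",
    "PGR", "PHGDH", "PTTG1", "RRM2", "SFRP1", "SLC39A6", "TMEM45B",
    "TYMS", "UBE2C", "UBE2T")
}

#' The 11 proliferation genes
#'
#' Mean log2 expression over this set defines the Proliferation Score.
#'
#' @return Character vector of 11 gene symbols (legacy names).
#' @export
proliferation_genes <- function() {
  c("CCNB1", "UBE2C", "BIRC5", "KNTC2", "CDC20", "PTTG1", "RRM2",
    "MKI67", "TYMS", "CEP55", "CDCA1")
}

#' Default housekeeper panel for digital-count normalization
#'
#' Five stably expressed genes commonly run alongside the 50-gene panel.
#' The set is configuration, not a contract: any housekeeper list present
#' in the probe table may be passed to [nanostring_housekeeper_normalize()].
#'
#' @return Character vector of 5 gene symbols.
#' @export
default_housekeepers <- function() {
  c("ACTB", "MRPL19", "PSMC4", "PUM1", "SF3A1")
}

#' Default modern-to-legacy gene alias map
#'
#' Maps current HGNC symbols to the legacy symbols used by the signature
#' (e.g. NDC80 -> KNTC2), so RNA-Seq quantifications with up-to-date
#' annotation can be matched against the centroids.
#'
#' @return A [gene_alias_map()] object.
#' @export
default_alias_map <- function() {
  gene_alias_map(c(NDC80 = "KNTC2", NUF2 = "CDCA1", ORC6 = "ORC6L"))
}
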