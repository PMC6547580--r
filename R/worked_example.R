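#' Bundled risk-of-recurrence worked example
#'
#' Paired ROR / ROR+PS scores and published risk groups for seven samples
#' that received different subtype calls on the two platforms in a
#' published two-platform triple-negative cohort comparison. The table is
#' the package's reference worked example: re-deriving the printed risk
#' groups from the printed scores checks the default cutoff configuration,
#' and pairing the two platform blocks exercises the risk-group
#' discordance operation (exactly one sample, HLPR-002, changes group).
#'
#' @return Data frame with columns `sample_id`, `platform`, `ror`,
#'   `ror_group`, `ror_ps`, `ror_ps_group`.
#' @export
ror_worked_example <- function() {
  path <- system.file("extdata", "ror_worked_example.tsv",
                      package = "pamconcord", mustWork = TRUE)
  utils::read.delim(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}

#' Pair the worked example's two platform blocks as minimal call tables
#'
#' Builds a [pair_calls()] object carrying only the risk-group fields, as
#' needed by [risk_group_discordance()].
#'
#' @return A `PairedCalls` object.
#' @export
ror_worked_example_paired <- function() {
  df <- ror_worked_example()
  mk <- function(platform) {
    sub <- df[df$platform == platform, ]
    data.frame(sample_id = sub$sample_id,
               ror_s = sub$ror, ror_s_group = sub$ror_group,
               ror_ps = sub$ror_ps, ror_ps_group = sub$ror_ps_group,
               stringsAsFactors = FALSE)
  }
  pair_calls(mk("nanostring"), mk("rnaseq"),
             platforms = c("nanostring", "rnaseq"))
}
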