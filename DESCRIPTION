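Package: pamconcord
Title: Cross-Platform PAM50 Subtyping and Platform Concordance
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Normalizes digital multiplexed (NanoString nCounter-style)
    probe counts and RNA-Seq gene quantifications into classifier-ready
    log2 expression, calls PAM50 intrinsic breast-cancer subtypes by
    nearest-centroid correlation with an explicit ambiguity rule,
    computes risk-of-recurrence scores (ROR and ROR+PS) with risk
    groups, and quantifies between-platform agreement (per-gene Spearman
    correlation and ICC, Cohen's kappa on subtype calls, adjusted
    concordance under the ambiguity rule, Bland-Altman limits of
    agreement). Includes a paired-platform cohort simulator with known
    ground truth so every stage is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
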