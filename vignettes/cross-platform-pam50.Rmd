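---
title: "Cross-platform PAM50 subtyping: models, conventions and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-platform PAM50 subtyping: models, conventions and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pamconcord)
```

`pamconcord` reimplements a complete two-platform PAM50 workflow — digital
multiplexed counts and RNA-Seq quantifications in, subtype calls, risk
scores and a full agreement report out. This vignette records the models
it assumes, the conventions it had to choose where the assay's published
descriptions are silent, and what its tests do and do not establish.

## The classification model

PAM50 is a nearest-centroid classifier. Each intrinsic subtype
(Basal-like, HER2-enriched, LumA, LumB, Normal-like) is represented by a
prototype profile over 50 genes; a sample is assigned the subtype whose
centroid its profile correlates with most. `pamconcord` uses Spearman
correlation by default (Pearson is available for sensitivity checks):
nearest-centroid calls should not depend on the monotone details of each
platform's intensity scale, and rank correlation makes that invariance
exact — the test suite verifies that any strictly increasing per-sample
transform leaves every call, correlation and risk score untouched.

Three conventions around the argmax are this package's own:

* **Ambiguity.** A call is flagged ambiguous when the runner-up centroid
  correlation is within 0.1 of the top one (inclusive: a gap of exactly
  0.10 is ambiguous). At threshold 0 the rule degenerates to plain argmax
  with only exact ties flagged.
* **Ties.** Exact ties are broken by the fixed order Basal < Her2 < LumA <
  LumB < Normal, deterministically, and always flagged ambiguous.
* **Confidence.** The assay's commercial implementations report a
  confidence score whose formula is not public. We define confidence =
  (ρ₁ − ρ₂)/max(ρ₁, 10⁻⁸), clipped to [0, 1]. It is monotone in the gap,
  0 at a tie and 1 when the runner-up is at 0 or below while the top is
  positive. It is *not* claimed to match any vendor's confidence value.

## Risk of recurrence as configuration

The correlation-weighted risk score raw = Σ_k w_k ρ_k (+ w_P·P for
ROR+PS, with P the mean log2 expression of the 11 proliferation genes) is
linearly mapped to 0–100 and binned low/med/high. The subtype weights in
the default configuration are the standard published ones (0.05, 0.12,
−0.34, 0.23 for Basal/Her2/LumA/LumB; Normal-like excluded via weight 0).
The proliferation weight (0.17), the rescaling bounds (symmetric about 0,
spanning the raw score's attainable range) and the group cutoffs (29/52
for ROR, 23/52 for ROR+PS, half-open so a boundary score falls in the
upper group) are this package's defaults: the original per-platform
scripts and constants are not publicly deposited, so these numbers are
declared as data (`inst/extdata/pam50_config.json`), overridable, and
validated against the one external anchor available — a published table of
paired ROR/ROR+PS scores with printed risk groups for seven samples, whose
14 + 14 labels the defaults reproduce exactly (`ror_worked_example()`,
`analysis/05_worked_example.R`). Any cutoff pair with the low/med boundary
in (16.87, 35.25] and the med/high boundary in (51.60, 62.68] (ROR), or
(10.68, 23.44] and (43.42, 52.98] (ROR+PS), would reproduce that table;
the defaults were fixed once inside those intervals and are not tuned
further.

## Normalization recipes

**Digital counts.** Per sample, the background estimate is
b = mean − 2·SD over the negative-control probes. Two readings of
"corrected with mean minus 2 SD" are possible — subtraction or
thresholding; we subtract, clamping b at 0 first, because correction
suggests removing an additive background component. Counts are floored at
1 count after subtraction so log2 is always defined (the source
descriptions are silent on negative post-subtraction counts). Each
endogenous count is then divided by the sample's housekeeper geometric
mean and log2-transformed; the output is invariant to any whole-sample
scaling, which is the property the housekeepers exist to provide. The
five housekeeper genes are configuration (default ACTB, MRPL19, PSMC4,
PUM1, SF3A1), not a contract.

**RNA-Seq.** "Normalized to a fixed upper quartile (1000 genes)" is
ambiguous between a target value of 1000 and a 1000-gene computation set.
We implement the fixed-target reading: the 75th percentile (type-7
quantile) of the counts of genes expressed in ≥ 70% of samples is rescaled
to `uq_target = 1000` per sample; the gene-subset rule and the target are
both configurable, so the other reading is reproducible. log2(x + 1)
follows (the conventional count pseudocount), then per-gene subtraction of
*externally supplied* reference medians — in the real assay a median set
determined on an estrogen-receptor-balanced FFPE reference, never
recomputed from the study cohort itself, because a triple-negative cohort
is maximally unbalanced in exactly the receptor-driven genes the medians
are meant to calibrate.

**Centering the digital arm.** The published descriptions state median
adjustment only for RNA-Seq. Subtype calls do not care (per-gene shifts
change nothing about a rank correlation's per-sample input only per-gene;
empirically calls are stable under it), but the proliferation score is an
*absolute* mean of log2 values, so leaving one arm uncentered puts ROR+PS
on incomparable scales — in a full simulated run every sample's ROR+PS
group disagreed between platforms purely through that offset. The default
therefore stays "use the normalized profile as-is", and
`normalize_nanostring_arm(reference_medians =)` provides the centering
switch, which the analysis drivers and the acceptance run turn on with
platform-matched pseudo-reference medians.

Pipeline order is fixed and enforced through scale tags: raw matrices are
rejected by the classifier and by median centering; upper-quartile
normalization rejects already-log2 input.

## Gene identifiers

The signature's centroid files use legacy symbols (KNTC2, CDCA1, ORC6L);
current annotation uses NDC80, NUF2, ORC6. Matching across platforms is
by canonical symbol after an explicit alias map, applied before
normalization of the RNA-Seq arm. The map must be idempotent (no
alias chains), and two input genes collapsing onto one canonical symbol is
an error, never a silent merge or average — the 50-gene centroids need
exactly one row per gene, and silent imputation or averaging would corrupt
calls undetectably.

## Agreement statistics

* **Spearman ρ** with average ranks for ties and the large-sample t
  approximation for p-values.
* **ICC**: two-way mixed-effects, single measures. The consistency form
  ICC(3,1) = (MSR − MSE)/(MSR + MSE) is the default (platforms are the
  fixed factor); the absolute-agreement form, which also charges the
  platform mean square, is computed alongside, since the variant family is
  usually cited without fixing the agreement definition. 95% CIs are
  F-based (exact for consistency, Satterthwaite-approximated for absolute
  agreement). Zero between-subject variance yields ICC 0 with a warning.
* **Cohen's kappa** from the 5×5 call cross-table.
* **Bland-Altman**: differences x − y, limits mean ± 1.96·SD.
* **Adjusted concordance.** Raw concordance is the fraction of identical
  calls. A discordant pair is *rescued* when either platform's call was
  ambiguous (gap ≤ 0.1); rescues whose second call matches the other
  platform's call are tallied separately from unresolved near-ties, and by
  default (`count_any_near_tie = TRUE`) both are discounted from
  discordance — the reading under which a 7-discordant, 3-near-tie cohort
  of 96 yields 92/96 ≈ 96% adjusted concordance. Both tallies always
  appear in the report, so the stricter reading is available at a glance.
* Per-gene p-values are reported without multiple-testing correction;
  the per-gene contract is the raw correlations, and the report carries a
  note saying so.

## The simulated world

The generator's defaults describe one fixed cohort: n = 96; subtype
mixture Basal .82 / Her2 .13 / LumA .04 / LumB .01 / Normal 0 (a
Basal-dominated triple-negative call distribution, so cohort-level outputs
are comparable with such series); 50 signature genes + 5 housekeepers + 8
negative-control probes; within-subtype biological SD 0.5 log2 units;
platform noise SD 0.2 log2 units per arm; digital scale 500 counts,
RNA-Seq library 1–3 × 10⁵ over the 50-gene panel; negative probes Poisson
with mean 10. Biological SD 0.5 and platform SD 0.2 were chosen once as
values a bulk-expression analyst would call realistic for FFPE material on
these panels (within-subtype spread visibly larger than measurement
error); they are not tuned to any reported statistic.

Structure the generator does emulate: one shared biological profile per
tumor observed twice with platform-specific noise; centroids with the
field's known correlation pattern (Basal anti-correlated with LumA, Her2
positively correlated with LumB) and proliferation genes elevated in the
proliferative subtypes; near-constant housekeepers making geometric-mean
normalization identifiable; count-generation through rounding (digital)
and multinomial sampling at a drawn library size (RNA-Seq); optional
injected call flips with recorded ground truth. Structure it deliberately
does not emulate: FFPE degradation, GC/length bias, probe affinity
differences, batch effects, or any read-level process. A green test on
this world therefore establishes the *statistical machinery* — that the
pipeline recovers known truth, that every statistic matches its
independent oracle, that agreement decays monotonically with injected
noise — not that any particular real cohort will show any particular
concordance level.

Two simulator conventions matter for exactness: when all SDs are zero the
generator emits deterministic expected counts rather than sampled ones, so
the noiseless-limit checks (100% recovery, concordance exactly 1, exactly
92/96 under 4 injected flips) are sharp; and the reference-median
pseudo-cohort is balanced across all five subtypes, mimicking how the
real calibration set differs in composition from a test cohort.

## Numerical choices

* Floor after background subtraction: 1 count. Pseudocount for RNA-Seq:
  +1 before log2. Quantiles: type 7 (R's default), checked against a
  sort-based oracle.
* Risk scores are clipped to [0, 100] after rescaling; risk-group bins are
  half-open with the boundary in the upper class.
* Confidence denominator guarded by ε = 10⁻⁸; with a non-positive top
  correlation the clip returns 1, documented behavior for profiles that
  match no centroid.
* TSV writers emit 17 significant digits, making every write/read pair a
  bitwise round trip; this is load-bearing for the byte-reproducibility
  guarantee of the fixture emitter.
* Degenerate inputs fail loudly and by name: missing centroid or
  proliferation genes, constant profiles under Spearman, zero upper
  quartiles, non-positive housekeepers, ambiguous gene merges all raise
  errors carrying the offending gene/sample identifier; per-sample
  classification failures are rethrown with the sample id and never
  silently dropped.

## Known limitations

* The ROR rescaling bounds and the ROR+PS proliferation weight are
  stand-ins constrained only by the seven-sample worked example; absolute
  ROR values from this package are internally consistent but not
  comparable to vendor-reported scores.
* The confidence value is a package convention (see above).
* The rcc_like reader accepts only the CodeSummary section of digital
  count exports — no lanes, fields of view or binding-density QC.
* No survival or prognosis modeling: risk groups are reported, their
  clinical meaning is out of scope.
* Single-measures ICC assumes one measurement per platform per sample;
  technical replicates are not modeled.
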