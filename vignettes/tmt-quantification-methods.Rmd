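---
title: "Quantification and inference methods in tmtpipe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantification and inference methods in tmtpipe}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tmtpipe)
```

`tmtpipe` turns PSM-level reporter-ion tables from multi-plex TMT
experiments into protein abundance matrices and runs the downstream
inference a tumor-proteomics study typically needs. This vignette is the
package's own account of the methods: the model at each stage, the
parameters that matter, the numerical conventions, and what the synthetic
cohort generator does and does not emulate.

## Quantification model

### PSM filtering

A PSM contributes to quantification only if all of the following hold: the
reference-channel reporter is present and positive; peptide probability
≥ 0.9; precursor isolation purity ≥ 0.5; MS1 precursor intensity at least
0.05% of the largest MS1 intensity in its plex; summed reporter intensity
at least 5% of the per-plex median of that sum; and the protein is not a
contaminant (IDs prefixed `contam_`). Rejections are attributed to the
first failing criterion in a fixed order (reference, probability, purity,
MS1, MS2, contaminant) so filter reports are deterministic. Redundant PSMs
sharing a spectrum ID are resolved by keeping the one with the highest
summed reporter intensity, ties to the earliest record.

Two of these thresholds are percentages without an obvious denominator.
We anchor the MS1 floor to the per-plex maximum MS1 intensity and the MS2
floor to the per-plex median reporter sum: both anchors are scale-free, so
the filter behaves identically if a run is globally rescaled. Both choices
are isolated in `filter_criteria()` and can be reconfigured.

### Ratios, outliers, roll-up

Reporter intensities are log2-transformed and the reference channel
(channel 131, the pooled master mix) is subtracted, giving ratios on a
common scale across plexes. For a single-plex design without a master mix,
`to_log_ratios(..., pooled_reference = TRUE)` instead subtracts the
per-PSM mean of all log2 channels, emulating a pooled reference
constructed from the samples themselves.

Within each protein × sample group of PSM ratios we apply one pass of the
1.5 × IQR fence rule and then take the median. Quartiles use linear
interpolation (the `stats::quantile` type-7 convention), and the rule is
applied only to groups of at least 4 values — quartiles of fewer points
over-trim. Both conventions are fixed for bit-reproducibility and verified
in the tests against an independently coded quantile routine.

### Median/MAD normalization

With rows = proteins and columns = samples (the package uses this
orientation everywhere), each sample is median-centered, scaled by its MAD
(median absolute deviation of the centered values, no consistency
constant), and rescaled by the global MAD across samples:
`R^N = (R − M) / MAD × MAD_0`. After normalization every sample has median
0 and MAD equal to `MAD_0` exactly; the tests assert this to 1e-9 on
random matrices, and the transformation is idempotent. A sample whose
values are all equal has MAD 0 and is returned centered but unscaled with
a warning; with more than one distinct value a zero MAD cannot occur for
continuous data, though it can arise in degenerate noise-free synthetic
input.

### Reference intensities and abundances

Per protein and plex, the reference intensity is the sum of the three
largest MS1 precursor intensities among the protein's PSMs (all of them if
fewer than three). The literature describes this summary as a weighted
sum but states no weights; we use weights of 1 and expose a configurable
weight vector. `REF_i` is the mean over plexes, with plexes lacking the
protein contributing the global minimum reference intensity — a
conservative floor for sporadically observed proteins. Abundances are then
`A = R^N + log2(REF)`, so between-sample differences are exactly the
normalized ratio differences; the REF term only restores an absolute
scale.

In the full pipeline the per-plex ratio matrices are first integrated
(union of proteins, concatenated samples) and normalization runs once on
the combined matrix. This makes `MAD_0` a cohort-level scale and the
"median 0 / common MAD" invariant holds across all samples of all plexes,
which per-plex normalization would not give.

## Imputation and batch correction

Missing abundances are imputed by chained equations with predictive mean
matching. Columns (samples) are visited in order of decreasing
missingness; each column with missing cells is regressed by ordinary least
squares on the current completions of the other columns, and each missing
cell receives the observed value of a donor drawn uniformly from the 5
observed rows with nearest predicted mean. Each of the m = 5 chains starts
from a random draw of observed column values and runs maxit = 50 sweeps by
default. This is type-0 matching (no posterior draw of the regression
coefficients), which slightly understates between-imputation variance for
small m but keeps every imputed value an observed value of its column and
the whole procedure deterministic given the seed. Rows with fewer than 3
observed values cannot support the regression and are dropped with a
warning; a rank-deficient regression falls back to column-median
predictions with a warning.

Per-imputation estimates are pooled by Rubin's rules: pooled point = mean,
within-variance W = mean variance, between-variance B = sample variance of
the estimates, total T = W + (1 + 1/m)·B. Degrees of freedom use the
Barnard–Rubin small-sample formula when a complete-data df is supplied
(the DE path passes the t-test df) and reduce to the classic
(m − 1)/λ² otherwise. A median-pooled p-value is also reported as a
simpler, more conservative summary.

Batch correction is per-protein batch-mean centering: subtract each
batch's mean, add back the protein's grand mean. Within-batch contrasts
are preserved exactly, and additive batch offsets are removed exactly; an
empirical-Bayes variant is deliberately out of scope. Batch labels default
to plex provenance. Correction runs after imputation, matching the stated
order of the workflow the package implements.

## Differential expression, clustering, ordination

Fold change is the difference of group means on log2 data (so "FC > 1"
means |log2 FC| > 1 — the volcano cut lines are symmetric at ±1), tested
with the equal-variance Student t-test (Welch available via
`var.equal = FALSE`); q-values are Benjamini–Hochberg. Degenerate rows
(zero pooled variance) return t = 0, p = 1 when the means agree and p = 0
otherwise, documented conventions rather than NaNs. Proteins with fewer
than two observations in a group are reported untested rather than
silently dropped. Multi-group comparisons use classical one-way ANOVA.

Hierarchical clustering follows the Cluster 3.0 recipe: per-protein median
centering, uncentered-correlation distance
`d = 1 − Σxy / (‖x‖‖y‖)` over pairwise-complete positions, complete
linkage via `stats::hclust`. Item pairs sharing fewer than 3 positions get
the maximum observed distance, with a warning. PCA is the column-centered
SVD with samples as observations and requires a complete (imputed) matrix.

## Preranked GSEA

The ranked list is ordered by fold change, descending, ties broken
lexicographically by symbol. The enrichment score is the weighted
running-sum statistic (hit increments proportional to |stat|^1, classic
exponent 0 by flag). Because the input is a preranked list, the only
available null is gene-label permutation: for each set size, `n_perm`
random same-size sets are drawn from the universe (the measured protein
list — the "background"), and

* NES = ES / mean(|null ES| with matching sign),
* nominal p = add-one-corrected fraction of same-sign null scores at least
  as extreme,
* BH adjustment across sets; the single BH procedure serves as both the
  adjusted-p and FDR criterion.

Null ensembles are shared across sets of equal size, and the running-sum
implementation is cross-checked in the tests against both a hand-coded
walk and `fgsea::calcGseaStat`. GMT collections apply 5–500 size bounds
after intersection with the universe.

## Signatures and cross-species overlap

Significant proteins are called at p < 0.05, q < 0.1 and |log2FC| > 1 —
all strict inequalities, as the cutoffs are conventionally printed. Mouse
symbols are mapped to human through a user-supplied two-column table
(case-insensitive; one-to-many mappings expand, since the subsequent
intersection removes spurious targets and silent collapse loses
information; unmapped symbols are always reported). The cross-species
signature is the per-direction intersection, with full Venn-region counts.

## The synthetic cohort generator

The generator emulates a 27-sample cohort measured in three TMT 10-plexes:
five groups (normal = 9, TNBC = 6, and three tumor subtypes of 4 — the
split is our choice of a realistic cohort of this size), one reference
channel per plex carrying the pooled mean of all samples' true log2
abundances, and per-plex missingness defaulting to 18/14/12% — rates
typical of consecutive multi-plex experiments. Reporter intensities are
multiplicative: `2^(truth + batch shift + PSM effect + noise)`, where the
PSM effect (ionization efficiency, sd 1) is shared across a PSM's channels
and cancels in ratio space, noise is per-channel (`psm_noise_sd`, default
0.3 log2 units), and batch shifts are per protein × plex (sd 0.3).
Differential proteins (10% by default) carry a ±1.5 log2 effect in all
tumor groups. Per-protein PSM counts are shifted Poisson (minimum 1) so
every protein is quantifiable. Samples are assigned to plexes round-robin
within the group ordering so batch is never confounded with group.
Contaminant PSMs (`contam_` IDs) and low-quality PSMs (each violating one
named filter criterion, with a hidden truth label) are injected so the
filter stage is genuinely exercised.

Missingness is cell-level (a channel within a PSM), blanked by exact count
so the realized per-plex rate always matches the request; the mechanism is
a switch: `"mnar"` (default) draws cells with logistic weights decreasing
in observed log2 intensity, emulating intensity-dependent dropout, and
`"mcar"` draws uniformly. The real missingness mechanism of instrument
data is unknown, which is why both are exposed rather than asserting one.

What the generator does **not** emulate: peptide-level effects shared
across plexes (each PSM's effect is independent), within-group biological
variance (group means are exact, so statistical power on synthetic data is
optimistic), isotope-impurity crosstalk between channels, retention-time
or spectral structure, and razor-peptide ambiguity (the protein assignment
is taken as given). Passing recovery tests therefore demonstrates the
correctness of the computational chain, not instrument-level realism.

## Pipeline, determinism, problem sizes

`run_pipeline()` chains quantify → integrate → normalize → impute →
batch-correct → DE (Rubin-pooled across imputations — DE on a single
completed matrix is possible by passing one matrix, but pooling is the
default) → GSEA → signatures → clustering/PCA, writing every output with a
manifest. All stochastic stages derive their seeds from the global seed by
a fixed affine map (`derive_seed`), so any stage can be rerun in isolation
and full reruns are byte-identical: numeric output is printed at 17
significant digits, which round-trips doubles exactly. The package's
interface is R functions; the orchestration layer is `pipeline_config()` /
`validate_pipeline_config()` / `run_pipeline()` rather than a shell
executable, which suits an audience scripting in R.

The test and acceptance workloads use cohorts of 200 proteins × 27
samples, m = 5 imputations with 10–20 sweeps, 400–1000 GSEA permutations
and 5 seeds per stochastic claim — sizes chosen so the full suite documents
the pipeline's statistical behavior (sensitivity, FDR, calibration) while
remaining quick to run routinely; the underlying claims are
size-independent properties.

## Known limitations

* The MS1/MS2 percentage filter anchors are package conventions (per-plex
  maximum and median); other implementations may anchor differently.
* PMM here is type-0; with very small m the total variance from Rubin's
  rules can be mildly optimistic.
* Batch correction assumes additive protein-wise batch shifts and balanced
  group allocation across batches; strong confounding of batch with group
  is not detectable from the data alone.
* The gene-permutation GSEA null ignores inter-gene correlation, as all
  preranked GSEA variants do; p-values on correlated proteomics data are
  anti-conservative in the same way.
* Protein inference, search-engine FDR and reporter isotope correction are
  upstream of this package's scope: the PSM table's assignments and scores
  are trusted as given.
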