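---
title: "Deriving and using drug-sensitivity signatures with iraps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deriving and using drug-sensitivity signatures with iraps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iraps)
```

# The problem

Cell-line pharmacogenomic panels pair genome-wide expression with drug
sensitivity (IC50 or dose-response AUC) for hundreds of lines across many
tissues. A *drug-sensitivity signature* is a small set of genes with signed
weights whose correlation with a sample's expression predicts response. The
difficulty is that any single differential-expression contrast between
"sensitive" and "resistant" lines is unstable: it depends on where the
class boundary is drawn and on which lines happen to be in the panel.
`iraps` addresses this with resampling: the contrast is recomputed on many
random half-panels, and only genes that recur — that are *conserved* across
iterations — can enter the signature.

# The model and its stages

## Normalization

`log2_transform()` (offset default 1, for raw intensities containing
zeros), `quantile_normalize()`, and `preprocess_per_tissue()` implement the
standard chain for heterogeneous panels. Quantile normalization forces
every sample onto the across-sample mean of order statistics; tied values
within a sample receive the mean of the reference values at their tied
ranks, which makes the map deterministic and idempotent. Per tissue,
`median_polish()` (Tukey's alternating row/column median sweeps; defaults
`max_iter = 10`, relative `tol = 1e-6`) decomposes expression into
overall + gene + sample effects + residuals; the gene and overall effects
are then *removed*, so each gene is centered within its tissue. The point
of this choice is that cross-tissue baseline differences — which dominate
pan-cancer expression — cannot masquerade as drug-sensitivity signal in the
downstream contrasts. Tissues with a single sample pass through centered at
zero. Whether quantile normalization should act within tissue or across the
whole panel is genuinely ambiguous for this pipeline; within-tissue is the
default and `quantile_within = FALSE` gives the other order.

## Responder classification

Sensitivity values are z-scored per drug over the lines with data
(`zscore_sensitivity()`), with IC50s log-transformed first (concentration
scales are multiplicative). `call_single()` labels z < −1 responders,
z > 0 non-responders, everything else (boundaries included) neither — for
roughly Gaussian sensitivity this yields about 16% / 50% / 34%. For a
dual-inhibitor pair `call_dual()` averages the two z-scores and requires
each z ≤ −0.5 for responders (so that one strongly sensitive drug cannot
carry a line) and both z > 0 for non-responders. The boundary z = −0.5 is
included as satisfying the guard; the choice is arbitrary at a
measure-zero boundary and is documented here rather than load-bearing.

By default z-scores are computed once on the full candidate pool and the
resulting labels held fixed across resampling iterations — this keeps a
line's class from flickering with the resample and matches classification
preceding iteration. `rescore_per_iteration = TRUE` re-standardizes within
each half-panel instead; both readings of the protocol are available.

## Iterative resampling

`run_resampling()` draws `floor(fraction * n)` lines (default fraction
0.5) without replacement from the lines having both expression and
response data, classifies them, and computes per-gene Welch
unequal-variance t-tests with `log2_fc` = mean(responders) −
mean(non-responders) on the log2 scale. Welch's test is the appropriate
default for the unbalanced group sizes the rule produces (roughly 1:3
responder:non-responder); no variance moderation or per-gene FDR is
applied — the conservation filter below is the multiplicity control, and
within-iteration FDR would change what "conserved at p < t" means.
Iterations with fewer than `min_group_size` (default 5) members in either
class are skipped and counted, not padded. Samples are canonically sorted
before seeding, so archives are reproducible regardless of input file
order. Held-out test samples are excluded from the pool *before* any
sampling via `exclude_samples`.

## Signature optimization

For thresholds (p, fc, c), a gene's `conservation_fraction()` is the share
of iterations with p-value < p and |log2 fold change| > log2(fc). Two
refinements matter:

* **Direction consistency.** A gene can pass the magnitude thresholds in
  both directions across iterations; a signed weight for such a gene is
  meaningless. Only iterations matching the gene's majority sign among
  qualifying iterations are counted (ties resolve toward up; a sign-split
  gene therefore at best halves its conservation). This is switchable off
  (`direction_consistent = FALSE`).
* **One-standard-error selection.** `optimize_signature()` sweeps the grid
  (defaults p ∈ {1e−2 … 1e−5}, fc ∈ {1.1, 1.25, 1.5, 2.0}, c ∈ {0.5 …
  0.95}, bracketing the conventional working point p = 1e−4, fc = 1.25,
  c = 0.8), scores the training samples with each candidate, and measures
  the ROC AUC for responder prediction. On a cleanly separated training
  set, many grid points reach AUCs differing by a single concordant pair;
  the raw argmax then selects among nested candidate gene sets by sampling
  noise. All candidates within one Hanley-McNeil standard error of the
  maximal AUC are therefore treated as equivalent, and the choice among
  them falls to the largest gene set, then the larger conservation
  threshold, then the smaller p threshold. The most inclusive conserved
  set gives the lowest-variance correlation score; parsimony is already
  enforced by the conservation filter, which at these grids admits
  essentially no unconserved genes. Candidates below `min_genes`
  (default 5) are skipped — a one- or two-gene "signature" can win a small
  grid by chance.

Weights are the mean signed log2 fold change over the iterations in which
the gene qualified. Fold-change thresholds are interpreted on the ratio
scale against the log2 difference (a threshold of 1.25 passes when
|log2_fc| > log2 1.25); whether the original protocol thresholded the
ratio or the anti-logged group-mean ratio is unstated, and the log2
difference is the scale on which the statistics are computed.

## Scoring and evaluation

`score_samples()` correlates (Pearson; Spearman by flag) the weight vector
with the sample's expression over the signature genes after centering each
gene at its cohort median. Centering is the single largest interpretive
choice in the scoring convention: without it, absolute expression level —
essentially gene GC content, probe affinity, and baseline abundance —
dominates the correlation and every sample scores alike. `center = FALSE`
exposes the raw variant. Signature genes missing from the matrix are
dropped symmetrically (at least `min_overlap = 3` must remain).

`evaluate_scores()` builds the ROC over responders vs non-responders
("neither" excluded) with tied scores grouped, integrates AUC by the
trapezoid rule (equal to the Mann-Whitney U statistic with half credit for
ties — the suite asserts this identity on random fixtures), and reports
accuracy at a threshold policy: the training Youden point by default, to
be frozen (`threshold_policy = "fixed"`) for test cohorts.

`stratified_drug_screen()` compares drug sensitivity between
signature-high (score > mean + 1 SD) and signature-low (score < mean)
lines with Welch tests, after dropping drugs whose mean response AUC in
the high stratum exceeds `exclude_auc_above` — a toxicity filter keeping
only drugs genuinely active in the high-score group. The source protocol
prints both 10 and 9 for this dataset-specific cutoff, so it is an
explicit parameter with default 10.

## Survival

`optimal_cutpoint()` reads "maximizing the statistical difference between
the groups" as the minimum-p-value split: every midpoint between
consecutive distinct scores leaving at least `min_group_frac` (default
0.2) of patients on each side is evaluated with the bespoke two-group
log-rank statistic (`logrank_test()`, simultaneous-event tie convention,
hypergeometric variance), and the maximizing cutpoint is returned. The
selected p-value is *not* adjusted for the scan and is therefore
optimistic; the result carries `p_value_unadjusted_for_scan = TRUE` and
the full candidate table so users can see the landscape. Hazard ratios
with covariates (`cox_adjusted()`) are delegated to `survival::coxph()` —
off-the-shelf proportional-hazards machinery, not re-derived.

## Synergy

`fit_median_effect()` fits the median-effect equation fa/fu = (D/Dm)^m by
a least-squares line on logit(fa) vs log D. Assay noise is additive on fa,
so the logit-scale variance inflates by 1/(fa(1−fa))² at the floor and
ceiling; the default fit weights points by (fa(1−fa))², without which the
lowest-dose point's leverage can move Dm by tens of percent at realistic
noise. Unweighted fitting (`weighted = FALSE`) reproduces the plain
textbook regression; on noiseless model data both are exact. Fractions at
the assay limits are clamped into (0.005, 0.995) with a warning.

`combination_index()` evaluates CI = d_A/D_A(fa) + d_B/D_B(fa) for a
fixed-molar-ratio combination, the mutually exclusive two-term form by
default (the common CompuSyn default); `mutually_exclusive = FALSE` adds
the product term. At fa = 0.5 the CI reduces to d_A/Dm_A + d_B/Dm_B
exactly. `isobologram_points()` returns the equi-effect axis intercepts
and the combination point; the point lies under the additivity line
exactly when CI < 1.

# The synthetic generator

`generate_panel()` encodes the coupling the method assumes: a single
latent sensitivity factor s ~ N(0,1) per cell line drives both drug
response (z-scores sqrt(ρ)s + sqrt(1−ρ)ε per drug, pairwise correlation ρ,
default 0.8, exponentiated to IC50-like values) and the expression of
`n_planted` genes (baseline + sign·effect_size·s + N(0,1), half positive
half negative sign). Defaults — 2,000 genes × 200 samples, 60 planted
genes, effect size 1.2 SD — are large enough to exercise the grid search
while keeping a full pipeline run in seconds. Because responders are the
low-z lines, the expected weight sign of a planted gene is minus its
expression sign; the truth object records both. What the generator does
*not* emulate: real covariance among genes (all noise is independent),
batch effects, tissue-specific biology (tissue labels are round-robin),
mutation data, or heavy-tailed response distributions. Passing tests
therefore demonstrate the machinery is correct under the model's own
assumptions, not that real CCLE/GDSC data will yield signatures of any
particular quality.

`generate_survival()` draws exponential event times with hazard
λ₀·hr^score and independent uniform censoring whose upper bound is solved
numerically to hit the requested censoring fraction in expectation.
`generate_dose_response()` follows the median-effect equation over a
three-fold serial dilution of seven doses (the usual plate layout) with
truncated Gaussian noise.

# Numerical choices and degenerate inputs

* Duplicate gene ids on input are collapsed by the mean (deterministic and
  symmetric); readers reject non-finite cells unless `allow_missing`.
* Zero-variance drugs, one-class evaluation sets, all-equal scores,
  all-skipped resampling runs, and empty grid sweeps raise typed errors
  (the optimizer's is catchable as `iraps_optimize_failed`) rather than
  returning silently degenerate objects.
* Welch rows with zero pooled variance give p = 1 when the mean difference
  is zero and the smallest representable p otherwise; p-values are kept in
  (0, 1].
* `median_polish()` folds residual medians of the effect vectors into the
  overall term on exit, so median(row effects) = median(column effects) = 0
  holds exactly along with the exact reconstruction identity.
* All generators and the resampling engine take explicit integer seeds and
  restore the caller's RNG state.

# Problem sizes in the shipped tests

The suite runs the full pipeline at 2,000 genes × 300 samples (200
training, 100 held out) × 200 iterations for the recovery and null-safety
checks, 100 iterations × 2,000 genes for the null p-value calibration, 200
random fixtures for the AUC/U-statistic identity, a 10,000-rep permutation
oracle for the Welch test, 50 simulated cohorts for Cox coverage, and
n = 500 cohorts for hazard-ratio recovery — sizes chosen so the whole
suite completes in well under a minute while keeping Monte-Carlo error
small relative to the asserted tolerances.

# Known limitations

* The per-gene test is unmoderated; with very few responders per
  iteration, variance estimation is noisy and `min_group_size` is the only
  guard. A moderated-variance option is deliberately out of scope.
* The cutpoint scan's p-value optimism is flagged but not corrected; if an
  honest p-value is needed, validate the cutpoint on an independent
  cohort.
* GCT support is read-only (version 1.2) and probe-level summarization is
  out of scope: gene identifiers are opaque strings.
* The screen's toxicity threshold and the IC50/AUC units are
  dataset-specific and must be set by the user for anything other than
  CTRPv2-like inputs.
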