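---
title: "Methods: pairwise mixed-type correlation scanning and redundancy mapping"
author: "pairscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pairwise mixed-type correlation scanning and redundancy mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pairscan)
```

## The problem

Large observational cohorts in dementia research combine clinical and
biomarker tables, blood expression microarrays, and structural MRI for
the same patients. Feeding all of these features into machine-learning
models invites trouble: many features are highly correlated — or outright
duplicated under different column headers — which inflates training cost
and degrades generalisation. `pairscan` implements the full pipeline for
quantifying that redundancy: it assembles the three domains into one
mixed-type feature table, tests the association of *every* unordered
feature pair with a test chosen automatically from the pair's data types
and normality, controls the family-wise error rate by Bonferroni
correction at the full comparison count, and summarises the retained
pairs as per-feature correlate frequencies, feature-to-correlates
mappings, representative-feature reductions, and stratified subgroup
revalidations.

At full cohort scale the numbers are extreme: 1,131 clinical features,
48,157 expression probes and 124 × 6,400 = 793,600 image-derived latent
features give m = 842,888 features, hence m(m−1)/2 = 355,229,668,828
comparisons and a corrected threshold of 0.05/355,229,668,828 ≈
1.40754 × 10⁻¹³. The package reproduces this arithmetic exactly and runs
the same machinery at desk scale on synthetic data with known planted
structure.

## Preprocessing model

**Typing.** Every column is classed `numeric` or `nominal` before
testing. Number-valued columns with fewer than ten distinct observed
values are treated as nominal (low-cardinality codes behave like
categories); text columns with more than 20 distinct values are dropped
as identifier-like. Unknown markers never count toward the distinct
tally: missingness is a state, not a category. Columns mixing text and
numbers follow the text rules — the conservative reading.

**Longitudinal collapse.** Visit-level rows are reduced to one row per
patient, keeping for each feature independently the value from the
latest dated visit at which that feature is *known*; a known value from
an earlier visit beats a later unknown. Ties in date, and rows with no
usable date, resolve to the first occurrence in stable input order,
which makes the otherwise arbitrary choice reproducible.

**Merging.** Headers are capitalised before collision detection, so the
same feature spelled differently across tables merges. When two tables
carry an identically named column, each patient takes the value from the
table whose record for that patient is most recent; with no dates, the
earlier table in input order wins. Tables without a recognisable
patient-ID column (the configurable candidate list defaults to `RID`,
`PTID`, `PATIENT_ID`) are skipped with a warning — a data dictionary has
no patient rows.

**Filtering.** Features are dropped, in a fixed order and with exactly
one logged reason each: fewer than two distinct observed values; known
fraction below 0.80; any nominal category with fewer than 20 patients
(too small for the contingency and group tests). Filtering precedes
imputation, and is idempotent.

**Imputation.** Nominal unknowns take the modal category, ties broken
lexicographically. Numeric unknowns are filled by an iterative
regression imputer: starting from column means, each incomplete numeric
feature is regressed on all others with a ridge-regularised linear model
and its missing entries replaced by the fit, cycling in a seeded random
order for 10 rounds (the round count and penalty are configurable; the
defaults settle well before 10 rounds on the synthetic regime). Known
values are never modified.

## The image domain

Slice stacks are turned into tabular features by a compact symmetric
convolutional autoencoder, one model per slice index: pixel values are
min-max normalised to [0, 1]; the encoder applies stride-2 3×3
convolutions (ReLU) until the spatial grid is at most 8×8, then a dense
linear map to the latent space; the decoder mirrors this with dense,
nearest-neighbour upsampling and 3×3 convolutions, ending in a sigmoid.
Training minimises mean-squared reconstruction error with Adam. This is
the smallest standard design that is genuinely convolutional and
symmetric; the latent layer is linear so latent features do not die the
way ReLU units can. Backpropagation is verified against finite
differences in the test suite.

Per patient, the per-slice latent vectors are concatenated slice-major
into `SLICE{i}_L{j}` columns: `nSlices × latentDim` features. The
package's desk defaults are 16×16 pixels, 4–8 slices and latent 16–64,
which train in seconds on one core; the full-scale configuration
(128×128, latent 6,400, 124 slices) is expressible through the same
spec and is validated as a shape contract rather than trained in tests.
All randomness (weight initialisation, batch order) is seeded, so runs
are bit-reproducible.

## Test dispatch and the scan

Each pair's test follows its types and normality:

| pair | condition | test |
|---|---|---|
| numeric / numeric | both normal | Pearson correlation |
| numeric / numeric | otherwise | Spearman correlation |
| nominal / nominal | all contingency cells ≥ 5 | chi-squared |
| nominal / nominal | any cell < 5 | skipped |
| numeric / nominal | every category normal | one-way ANOVA |
| numeric / nominal | otherwise | Kruskal–Wallis |

Normality is the D'Agostino–Pearson omnibus skew/kurtosis test at
α = 0.05, implemented from the published transformations and verified
against an independent reference implementation; samples smaller than 8
(where the kurtosis transformation is undefined) and constant samples
are deemed non-normal, routing them to the non-parametric branch.
Numeric-feature normality is assessed once per feature and cached;
per-category normality depends on the partner and is assessed per pair.

Numerical conventions, chosen once: the chi-squared statistic carries no
continuity correction, and the cells checked against the < 5 rule are
the *observed* counts — the plain reading of a frequency rule. Spearman
uses average ranks for ties with the large-sample t approximation for
the p-value. ANOVA assumes equal variances (the classical F); a
degenerate zero within-group variance yields p = 0 when group means
differ and p = 1 otherwise. p-values that underflow the smallest
positive double are stored as an explicit underflow marker, written to
CSV as `0.0E0_UNDERFLOW`, and interpreted as p ≤ 5 × 10⁻³²⁴ ("maximally
significant").

`scanAll()` evaluates every unordered pair once, in canonical
lexicographic order of feature IDs, and retains pairs with p ≤ α where
α divides the base level by the *planned* family size m(m−1)/2 — pairs
later skipped by the contingency rule still count in the divisor, since
they were planned comparisons. The scan can fork across workers; chunk
boundaries and worker count never affect the result, which is emitted
sorted for bit-reproducible output.

## Redundancy summaries and reduction

Every stored pair increments both endpoints' correlate counters in the
partner's domain column, so each feature's total equals its stored pair
count and column sums obey handshake conservation (within-domain sums
double-count; cross-domain sums are exact). Domain-level summaries
report mean, *population* standard deviation, minimum and maximum per
(feature-domain, correlate-domain) cell; population SD is a
convention choice, recorded here, and printed output rounds half away
from zero (3 decimals for percentages, 2 for summary statistics) to
match conventional table precision.

The feature-to-correlates mapping is restricted to the clinical and
expression domains — latent image features carry no direct biological
reading — and lists each feature's sorted significant partners;
symmetry holds by construction. Representative selection is a greedy
cover: repeatedly keep the feature with the most not-yet-covered
correlates (ties lexicographic) until everything is covered. Greedy is
a deliberate trade: minimum set cover is NP-hard and the greedy
solution is within a logarithmic factor, which is ample for a
redundancy reduction whose point is engineering, not optimality.

## Stratified revalidation

Five standard subsets — female, male, and dementia-rating strata 0, 0.5
and ≥ 1 — are row-filtered copies in which every feature's testability
is re-checked (fewer than two distinct observed values flags it
untestable rather than dropping it). The maximally significant pairs
from the full scan are then re-dispatched and re-tested inside each
subset — normality is reassessed there, since sample properties change
under sub-setting — and classified as retained, lost to untestability
(flagged feature, or the chosen test's preconditions fail in the
subset), or lost to reduced significance. The accounting is exact:
full = retained + lost_untestable + lost_significance, per feature and
in aggregate. Revalidating against the identity subset reproduces the
original classifications, and shrinking a subset never makes an
untestable feature testable.

## What the synthetic generator emulates — and what it does not

The generator produces every input the pipeline consumes, with ground
truth recorded: compound-symmetric multivariate-normal feature blocks
(a shared latent factor gives exact expected within-block correlation
ρ); independent numeric noise; nominal features, optionally with a
numeric partner whose mean shifts per category (what ANOVA and
Kruskal–Wallis detect); bit-identical duplicate columns under distinct
names; identifier-like metadata text; per-feature missingness at
declared fractions; longitudinal visit rows with integer-day dates
(earlier visits perturbed, the latest carrying the generated value,
with deliberate date ties exercised in tests); sex and three-level
dementia-rating strata; and image stacks containing smooth elliptical
blobs whose size and position vary per patient and drift across slices
— structured content an autoencoder can compress, where pure noise
would give it nothing to learn.

Default study conditions used by the validation suite: planted blocks
of 4 features at ρ = 0.95 among independent noise with n = 500
patients, under which a Bonferroni-corrected scan recovers exactly the
planted pairs in ≥ 95% of seeds; and 40 mutually independent features
at n = 100, under which the store is empty in ≥ 95% of seeds at
family-wise α = 0.05. End-to-end determinism is checked at 16×16
pixels, 4 slices, latent 16, with 16–200 patients; these sizes are the
package's validation regime, chosen so the full pipeline exercises
every stage in seconds.

What passing these tests does *not* show: the generator draws numeric
features from (mixtures of) Gaussians, so it says nothing about heavy
tails or monotone-but-nonlinear dependence beyond what the Spearman
branch sees; its missingness is completely at random, while real
cohort missingness is informative; its images are far simpler than
MRI anatomy, so autoencoder reconstruction quality on real scans is
not established — only the mechanics and reproducibility of the
embedding are.

## Known limitations

- The scan is O(n·m²); the package parallelises across forked workers
  but is not engineered for the third-of-a-trillion-comparison regime —
  that is a cluster job, and the package's contribution is the exact
  same logic at testable scale.
- Bonferroni control is deliberately conservative; no FDR alternative
  is offered because the redundancy question ("is this pair certainly
  associated?") wants family-wise control.
- The chi-squared branch's < 5 observed-cell rule skips rather than
  falling back to an exact test; skipped pairs are reported with
  reasons and still count in the α divisor.
- Effect sizes are not estimated; the pipeline asks whether features
  are redundant, not how strongly.
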