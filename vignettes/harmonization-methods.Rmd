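---
title: "Harmonizing multi-study vaccine transcriptomics: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Harmonizing multi-study vaccine transcriptomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(immunoharmonize)
```

## The problem

Vaccination cohorts profile blood transcriptomes longitudinally around a
vaccine dose, across many studies, platform vendors (Affymetrix, Illumina,
RNA-seq, two-color arrays) and specimen types (whole blood, PBMC). Pooled
naively, the dominant axes of variation are technical: each study/platform
pair imprints per-gene offsets and a platform-specific intensity
distribution that dwarf vaccination biology. This package implements the
stages needed to make such a compendium analyzable — array QC, alias
resolution and probe collapsing, within-study and cross-study quantile
normalization, baseline-anchored batch correction with PVCA diagnostics,
sex/age imputation, and titer endpoints — and pairs every stage with a
synthetic generator whose injected effects are recorded, so each stage is
testable against ground truth without downloading any archive.

## Array quality control

Within one cohort matrix (one cohort × specimen type, hence one platform),
three statistics are computed per array: the mean absolute pairwise
difference `d_a`, the Kolmogorov–Smirnov distance `K_a` between the array's
intensity distribution and the pooled distribution of all arrays of the
matrix, and Hoeffding's `D_a` measuring dependence between A (average) and
M (difference) values against a feature-wise **median pseudo-array** — the
standard MA construction for single-channel data, which the underlying method
leaves unspecified. An array is an outlier only if it fails **all three**
statistics; one aberrant statistic alone (e.g. a brightness shift) is not
disqualifying.

Thresholds are tunable: the boxplot upper fence (Q3 + 1.5·IQR across the
arrays of the matrix) for `d_a` and `K_a`, a fixed 0.15 for `D_a`. These are
the conventions of established array-QC practice; they are parameters, not
constants, because cohort sizes in real compendia range from 4 to hundreds of
arrays and the boxplot rule degrades below ~5 arrays (the distance statistic
therefore requires at least 3). QC runs per cohort matrix rather than per
study because intensity distributions differ across platforms; this is
configurable.

Note one subtlety the tests encode: independence of A and M for a clean
array requires that per-gene baselines vary much more than the within-array
noise. A matrix of genes with identical means exhibits A–M dependence for
*every* array; that is a property of the MA construction, not a QC failure
mode of the data.

## Annotation and gene collapsing

Alias resolution is a total function with three outcomes: an alias whose
candidate symbol set contains itself resolves to itself; several candidates
none of which is the alias → dropped; exactly one candidate → that symbol;
none → unmapped. Matching is case-insensitive after trimming because vendor
tables mix cases. Collapsing keeps, per symbol, the probe with the highest
mean across all samples of the cohort matrix — never an average, so every
gene-level row equals some probe-level row exactly. Exact mean ties break to
the lexicographically smallest probe id (the source method is silent; any
deterministic rule works, this one is stable across platforms). The alias
table itself is user-supplied with a mandatory version tag, since symbol
assignments drift between nomenclature releases.

## Normalization

Within-study quantile normalization (order statistics replaced by their
across-sample mean, ties averaged) uses the standard limma implementation.
Cross-study normalization maps every sample onto a **target distribution
built from the Affymetrix samples**, which have the best-behaved intensity
distributions in mixed compendia: per Affymetrix sample the empirical
quantile function is evaluated at `L` midpoint probabilities `(r − 0.5)/L`
(quantile type 5) and averaged. Each sample's value at average rank `r` of
`n` is then mapped to the target quantile at probability `(r − 0.5)/n` by
linear interpolation, clamped at the ends. The midpoint convention is
symmetric and makes a sample equal to the target quantiles map to itself.
`L` defaults to the gene count — one quantile per gene avoids interpolation
bias. The target is built from within-study-normalized Affymetrix samples
(the alternative, raw-scale targets, is supported by supplying an explicit
target). RNA-seq counts enter via median-of-ratios size factors and
`log2(count/sf + 1)` — a deliberately simple, pluggable library-size
normalization that makes counts mergeable with log-scale array data; it does
not attempt full variance stabilization (dispersion-trend modeling is out of
scope and the transform is replaceable).

## Batch model and PVCA

Technical effects are estimated **only on pre-vaccination samples**
(`time_days ≤ 0`, counting day −7 and day 0 both as baseline): baseline
biology is unaffected by which vaccine a study later administers, so study
terms estimated there are purely technical. Per gene, OLS with treatment
coding on: intercept, age (centered), Y-presence (three-level factor:
present/absent/unknown), batch key, platform vendor, specimen type. The
batch key is study × cohort — multi-cohort studies are separate batches,
since cohorts were often assayed years apart. Platform is almost always
nested in study; rank analysis drops aliased columns greedily in block order
(batch first), so a fully confounded platform column is absorbed into the
batch-key coefficients — the *removal* is identical either way, only the
labeling of the combined effect changes. The estimated batch + platform +
specimen terms are subtracted from **every** timepoint; age and Y-presence
terms are biological and stay. Consequences the tests verify: correction is
idempotent; within-participant longitudinal contrasts (day d − day 0) are
numerically unchanged, because a participant's offsets cancel.

PVCA takes the leading PCs up to a cumulative-variance threshold (default
0.6 — enough to capture dominant structure without flooding the mixed models
with noise PCs; configurable), fits per PC a random-intercept model per
factor (REML via lme4; a method-of-moments one-way fall-back is used with a
warning if the mixed model fails), converts each PC's variance components to
proportions and averages them weighted by eigenvalue share. Factor
interactions are off: the batch model is additive, and with few studies an
interaction term is unidentifiable anyway. With a handful of studies,
nested factors (specimen constant within study) are statistically
confounded with the batch factor, and the decomposition attributes their
shared variance arbitrarily; the package therefore reports the batch factor
as "study (including platform)" in such designs, which is also how the
variance should be interpreted.

## Sex and age imputation

Sex: per study, classical MDS of Euclidean distances on the Y-panel
expression (13 genes by default; the panel is a parameter — the default list
covers the commonly used blood-detectable Y genes: RPS4Y1, RPS4Y2, KDM5D,
DDX3Y, UTY, USP9Y, EIF1AY, NLGN4Y, ZFY, TMSB4Y, PRKY, TXLNGY, SRY), then
k-means with k = 2 and 25 restarts under a fixed seed. The higher-mean
cluster is male. A standardized separation score (between-cluster gap of
mean Y expression over pooled within-cluster SD) below 2 triggers
abstention — k = 2 on a single-sex cohort would otherwise fabricate a split.
Reconciliation per participant: unanimous calls win; conflicts defer to
reported sex; otherwise strict majority, with exact ties unknown.

Age: a reference is interpolated from known-age baseline samples — per gene,
a natural cubic spline in age (4 df; exact on linear trends, flexible enough
for sigmoidal aging trajectories at the 20-sample minimum) plus additive
covariates, evaluated on a fine grid with covariates at reference level. A
sample's age estimate is the grid age maximizing the Spearman correlation
between its profile and the reference column; a bootstrap over random gene
subsets (default 30 draws of half the genes) gives the CI. Two estimator
details matter in practice and are defaults here: staging is restricted to
genes whose reference profile actually moves (dynamic range ≥ 2× the median
range, minimum 50 genes) — flat genes carry no age information and dilute
the rank correlation — and the reference should be built with sex (or
Y-presence) as a covariate, otherwise the Y genes' sex bimodality masquerades
as an age trend and corrupts staging. That is exactly the kind of covariate
the model-selection step (leave-one-study-out RMSE, young <50 / old ≥50
pools, R² reported alongside) is meant to find: on synthetic data it selects
the sex covariate over the covariate-free model in both pools. Age staging
presumes batch-corrected (or single-study) input; per-gene study offsets
several times larger than the aging signal make cross-study staging
meaningless. This estimator is a deliberate simplification of full
interpolation-staging machinery: no optimal-transport interpolation, no
per-component staging.

## Endpoints

Fold change uses the latest baseline titer and, within the post-vaccination
window (default 21–35 days), the measurement closest to day 28 — schedules
vary and "day 28–30" is the common anchor. MFC is the maximum log2 fold
change across strains (log2 is monotone in the raw ratio, so the argmax
strain is the same either way). maxRBA regresses, per strain, log2 fold
change on log2 baseline across participants (≥3 complete participants per
strain, else the strain is skipped) and takes each participant's maximum
residual; a zero-variance baseline degenerates to centered fold changes.
Residuals are invariant to rescaling raw titers by a positive constant — the
regression absorbs affine shifts of log baseline. Titer values at or below
detection limits are taken as reported; no censoring model. Assay
preference: HAI, then NAb, then ELISA for influenza; NAb then ELISA
otherwise. Responder/non-responder discretization is intentionally not
computed.

## The synthetic generator

`generate()` emulates, additively on the log2 scale: per-gene batch
(study × cohort) offsets (SD 3 by default — strong, platform-scale
separation, with the first batch as zero reference so corrected output is
directly comparable to the recorded batch-free truth), scalar platform
location shifts (0 / +1.5 / −1 for Affymetrix / Illumina / RNA-seq; optional
non-unit scale factors emulate the distribution-shape differences that the
additive model cannot fix and cross-study quantile normalization can),
per-gene whole-blood-vs-PBMC offsets (SD 0.5, an order of magnitude below
study effects, matching the small specimen fractions seen in real
decompositions), a +4 log2 Y-panel shift in males, gene-specific sigmoidal
aging trajectories (random direction, onset and width, ~0.3 log2/decade
typical magnitude — concentrated in 50 of 200 genes, so stronger per gene
than real aging signatures, which spread over thousands of genes; trajectory
*diversity* is deliberate, because a uniform linear trend makes all
reference columns rank-equivalent and correlation staging unidentifiable),
a day-7-peaking response kernel scaled by a participant responder score, and
Gaussian noise (SD 0.3). Titers follow
`log2(post) = log2(base) + a − b·log2(base) + r + ε` per strain with the
responder score `r` shared across strains and assays, which induces the
positive HAI–NAb endpoint correlation the acceptance script measures.
Corrupt-array injection (partial rank scrambling, 2× variance inflation,
+3 shift) fails all three QC statistics by construction.

What the generator does **not** emulate: probe-level array physics,
count-level RNA-seq sampling (beyond what the count-transform test needs),
heavy-tailed biological outliers, correlated gene modules, or missing data.
Passing tests therefore demonstrate the pipeline's correctness and its
behavior under the stated effect structure, not robustness to every real-data
pathology.

## Problem sizes and numerical choices

Default test and acceptance problem sizes — 3 studies × 20 participants ×
200 genes (1000 samples for the sex check, 120 participants for model
selection) — were chosen so the full suite runs in well under a minute per
module while leaving every statistic far from its decision boundary.
Numerical conventions: quantile type 5 everywhere a quantile function is
evaluated; `(r − 0.5)/n` rank-to-probability mapping; average ranks for
ties; interpolation clamped at target ends; boxplot fences with type-7
quartiles; treatment coding with alphabetically first reference levels;
greedy rank filtering in design-block order; REML with singular fits allowed
(a zero variance component is a valid estimate); curation order irrelevant →
schedule → baseline → age with provenance counts at each step
(`in = out + removed`). The bundle container is R serialization with a
fixed logical layout (expression / samples / titers / provenance). Stage
wall time is logged to the message stream, not stored in provenance, so two
runs from the same seed serialize to identical bytes.

## Known limitations

Platform scale differences are only removable by the quantile stages, not by
the additive batch model. PVCA attribution between nested factors is
arbitrary in few-study designs (see above). The age estimator's CI is a
gene-subset bootstrap, not a full resampling of the reference; its coverage
is approximate. maxRBA assumes a linear log–log baseline relationship;
alternative curve forms are out of scope. Exclusion rules for "irrelevant"
participants are a caller-supplied predicate, since no operational
definition is universal.
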