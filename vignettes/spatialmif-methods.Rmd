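---
title: "Methods: spatial cell-interaction features and the immune-related risk score"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatial cell-interaction features and the immune-related risk score}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spatialmif)
```

# Overview

`spatialmif` implements a complete analysis chain for two-panel multiplex
immunofluorescence (mIF) studies of the tumour microenvironment:

1. **Cell detection and phenotyping** — from an RGB fluorescence scene
   (DAPI-like nuclear signal in blue, marker stains in red/green) to a table
   of typed, region-assigned cells with staining-intensity bins and
   H-scores.
2. **Spatial graph features** — Delaunay triangulation of the cells of each
   panel, classification of every edge into one of 30 marker-pair
   categories, and a fixed 60-feature descriptor (30 connection counts + 30
   mean connection lengths) with two relative normalisations and
   per-patient averaging.
3. **Segmentation evaluation** — IoU-matched scoring of a nucleus
   segmentation against ground truth (detection coverage, precision,
   recall, F1, pixel accuracy).
4. **Association statistics** — Spearman rank correlations and
   group-difference tests over the resulting feature tables.
5. **The immune-related risk score (IRRS)** — univariate Cox screening,
   cross-validated LASSO-Cox selection, log-hazard-ratio weighting, an
   optimal log-rank cutpoint, and validation by Kaplan-Meier/log-rank,
   covariate-adjusted Cox models and time-dependent AUC.
6. **Synthetic data** — point-process scene simulation and survival-cohort
   simulation with known truth, so every stage above is testable without
   imaging data.

This vignette records the modelling choices, the tunable parameters, the
numerical conventions, and what the synthetic data do and do not establish.

# The imaging model and its conventions

## Coordinates

Positions are real-valued pixel coordinates, 0-based, origin at the
top-left pixel centre, `x` indexing columns and `y` indexing rows. A matrix
cell `[r, c]` (1-based) has centre `(x, y) = (c - 1, r - 1)`, and the image
frame extends half a pixel beyond the outermost centres. All spatial
features are reported in pixel units; physical units enter only through the
`microns_per_pixel` parameter (default 0.5 µm/px, a typical 20×
whole-slide scan) used for cell densities per mm².

## Panels and channels

The design assumes two 5-marker panels stained on serial sections of the
same block: panel 1 (CD38, CD20, CD4, FOXP3, CD66b) and panel 2 (PD-L1,
CD163, CD8, CD68, CD133). Each marker is read in either the red or the
green channel (CD4, CD20, CD38, CD66b, CD133, CD163 in G; CD8, CD68,
PD-L1, FOXP3 in R); blue is reserved for the nuclear counterstain. Because
several markers of one panel share an optical channel, marker identity is
carried by the per-marker *component* images produced by spectral unmixing,
not by a single composite. The scene simulator therefore returns both: a
composite RGB (`image`) for display and channel-arithmetic checks, and a
named list of per-marker channel maps (`marker_maps`) that the detection
module consumes. Spectral unmixing itself, autofluorescence, and
multi-colour TSA chemistry are out of scope: component maps are taken as
given.

## Intensity bins and the H-score

Each marker has a positivity threshold X on the channel scale (in practice
set by pathologists; here a configuration value, default 0.2 on [0, 1]).
Staining strength is binned at exactly `[X, 2X)` = "+", `[2X, 3X)` = "++",
`[3X, ∞)` = "+++". A relative tolerance of 1e-9 is applied at the
boundaries so that values constructed as multiples of X land in their
intended bin despite binary floating-point rounding. The H-score of a
phenotype within a region is

$$\mathrm{H} = 1 \cdot \%_{low} + 2 \cdot \%_{median} + 3 \cdot \%_{high}
\in [0, 300],$$

with percentages taken over all cells of the region.

## Detection and typing

Nucleus detection is a pluggable interface. The default classical detector
smooths the nuclear channel (Gaussian, `smooth_sigma = 1` px), thresholds
it (Otsu by default), separates touching nuclei with a distance-transform
watershed, removes fragments below `min_nucleus_px = 9` px, and reports one
centroid per label. It is deterministic for a fixed input. A learned
detector (e.g. a star-convex polygon model) can be dropped in via
`config$method = "custom"` without touching the rest of the pipeline; the
package deliberately treats the detector as exchangeable because the
pipeline around it is the contribution.

Marker positivity uses the minimal faithful reading of "intersecting cell
coordinates with the stained area": a cell is positive for marker m iff its
centroid pixel lies inside m's denoised positivity mask (threshold at X,
then removal of connected components below `min_object_px = 10` px). The
intensity used for binning is read at the centroid pixel by default; a
`"mean"` read-out over the nucleus mask is available as a configuration
switch. Cells may be positive for several markers (e.g. CD8+CD133+), and
region assignment (tumour nest TN / tumour stroma TS / none) is a strict
partition by centroid membership in the two disjoint region masks, which
are inputs.

# The spatial feature layer

## Edge categories

Cells of one panel in one image are connected by Delaunay triangulation
(computed with `deldir`; lengths are Euclidean, in px). Degenerate inputs
return defined results: one point or none gives an empty edge table, two
points the single segment, and a fully collinear set the chain of
consecutive segments. Exactly coincident points are collapsed beforehand
into one node carrying the union of the marker sets — a double-positive
nucleus would otherwise appear as duplicated points and degenerate the
triangulation. This collapse rule is an interpretation (the alternative,
concatenating per-marker coordinate lists, creates zero-length artefacts)
and each edge then contributes one count to *every distinct unordered
marker pair* formed from its two endpoints' label sets.

An edge category is an unordered within-panel marker pair, self-pairs
included: `choose(5,2) + 5 = 15` per panel, 30 overall. Cross-panel
categories cannot exist because the panels live on different serial
sections. The raw descriptor per image pair is therefore 60 numbers: a
connection count `n_c` and a mean connection length `len_c` (total length /
count, `NA` when the category is empty) for each of the 30 slots. Edges
with a marker-negative endpoint are skipped and counted in an attribute.

## Normalisation and aggregation

Two relative forms are computed *within one image*, over all 30 categories
of both panels' graphs:

$$\mathrm{pct\_len}_c = \frac{\bar L_c}{\sum_i n_i \bar L_i / \sum_i n_i},
\qquad
\mathrm{pct\_num}_c = \frac{n_c}{\sum_i n_i}.$$

By construction `sum(pct_num) = 1` and the edge-weighted mean of `pct_len`
is 1; both identities are asserted to machine precision in the test suite
and make the features comparable across images of different cellularity.
With zero classified edges all relative values are `NA`.

Patient-level vectors average each feature across a patient's slides,
missing-aware: a slide lacking a category is ignored for that feature, and
the patient value is `NA` only if every slide misses it. Whether empty
categories should instead be zero-filled is not determined by the source
material; missing-aware averaging was chosen because a category absent
from a sparse field is unobserved, not observed-zero, for lengths (counts,
by contrast, are genuinely zero and enter the mean as zero).

# Segmentation evaluation

Predicted and ground-truth label masks are compared by pairwise
intersection-over-union. Matching is one-to-one and greedy in descending
IoU (ties broken by the smaller ground-truth label), keeping pairs with
IoU strictly greater than the threshold (default 0.6). Matched pairs are
TP; remaining ground-truth objects FN; remaining predictions FP. The suite
verifies on every feasible fixture that this greedy procedure coincides
with an optimal-assignment oracle. Pixel accuracy is binary
foreground/background agreement — with background-dominated microscopy
fields it is expectedly close to 1 even for imperfect segmentations, which
is why object-level F1 is the primary quality number.

# The IRRS model

Let `z = 1..k` index the selected prognostic variables. The score is

$$\mathrm{IRRS} = \sum_z \ln(\mathrm{HR}_z) \cdot \mathrm{proportion}_z,$$

where `HR_z` is the variable's *univariate* Cox hazard ratio estimated on
the training cohort only and `proportion_z` the patient's value of the
variable on its proportion scale (percentages/100 for abundance variables;
normalised spatial features as computed). The construction is:

1. **Split.** Stratified 70/30 split by event status; the training size is
   exactly `round(0.7 n)` and each stratum's proportion is within one
   patient of 0.7.
2. **Screen.** Univariate Cox (Efron ties) per candidate; variables with
   two-sided p < 0.05 advance. Constant variables and non-converging or
   monotone-likelihood fits are flagged and excluded rather than carried.
3. **Select.** LASSO-Cox over a log-spaced path of 100 λ values spanning
   four decades below the full-shrinkage λ; λ* minimises the mean 10-fold
   cross-validated partial-likelihood deviance (the λ.min rule, not λ.1se);
   selected = non-zero coefficients at λ*. With fewer events than folds
   the fold count is reduced with a warning.
4. **Weight.** The LASSO coefficients are used only for selection; the
   score weights are the selected variables' univariate training ln(HR).
   Whether these weights should be refit on the full cohort is ambiguous
   in principle; training-only estimation is used so that the identical
   frozen formula transfers to validation data.
5. **Cut.** The optimal cutpoint maximises the two-group log-rank
   chi-square over candidate cutoffs at the distinct training scores
   between the 10th and 90th percentiles (thinned to at most 100
   quantile-spaced values), requiring both groups to hold at least 10% of
   the cohort. This emulates X-tile-style scanning; the scan's maximised
   chi-square makes the training p-value optimistic, which is why the
   cutoff is applied *unchanged* to the testing and entire cohorts.
6. **Validate.** Kaplan-Meier curves and log-rank tests per cohort; a
   multivariable Cox model of the high/low group adjusted for sex, age, T
   stage, N stage, vascular cancer embolus and dissected lymph-node count
   (collinear terms are refused, and fewer than ten events per variable
   triggers a warning); and cumulative/dynamic time-dependent AUC at 365,
   1095 and 1825 days with inverse-probability-of-censoring weights (cases
   `1/G(T_i^-)`, controls `1/G(t)`, G the Kaplan-Meier estimate of the
   censoring distribution).

# The synthetic data: what it emulates, and what it does not

## Scenes

`simulate_point_pattern` supports complete spatial randomness (Poisson),
clustering (Thomas process: Poisson parents, Gaussian offspring
displacement), and regular spacing (simple sequential inhibition). These
reproduce the qualitative regimes the spatial features are meant to
separate — clustered cells have shorter nearest-neighbour distances and
more same-type connections; inhibited cells the opposite — and the suite
verifies those orderings against brute-force nearest-neighbour
computations. `assign_markers` draws at most one primary marker per cell
from a probability vector and then applies co-expression rules (a stated
probability that a cell positive for marker A is also positive for B),
producing the multi-positive phenotypes (e.g. CD8+CD133+) the typing layer
must handle. `render_scene` stamps nuclei as discs (default radius 5 px on
a default 1024×1024 frame, configurable; tests run smaller fields) and
markers as discs at `1.1X / 2.1X / 3.1X` for "+"/"++"/"+++", so rendered
levels land in their intended bins by construction; speckle noise (1–3 px
objects, above X) exercises the small-object denoising; an optional
Gaussian blur emulates a point-spread function.

Cell densities per phenotype are configurable, not calibrated: where the
underlying study reports only that abundant phenotypes exceed
2000 cells/mm², the simulator defaults are chosen to be desk-scale
realistic (hundreds of cells per field) and the density round-trip is
tested at 2000/mm² explicitly.

The scenes do **not** model optical spectral overlap, autofluorescence,
uneven illumination, tissue folds, or non-disc nuclear morphology. Passing
the round-trip tests therefore shows the pipeline's logic is correct on
well-posed inputs; it does not certify detector performance on real tissue,
which is exactly why the detector is pluggable and separately evaluable
via the segmentation-evaluation module.

## Cohorts

`simulate_cohort` draws event times from an exponential proportional-
hazards model: rate `exp(lp - mean(lp)) / baseline_hazard_scale`, with `lp`
the stated log-linear predictor. The defaults mirror the target study's
structure — 553 patients, censoring calibrated to an expected 56.6%
censored fraction (43.4% events), and a baseline scale of 2421 days so the
median disease-free survival sits near 1678 days. Censoring is an
independent exponential whose rate is solved numerically (`uniroot`) so
the *expected* censored fraction equals `censoring_rate`; this preserves
independent censoring, unlike schemes that censor a fixed subset at a
fraction of their event time. The default feature generator produces
standard-normal columns: unit variance makes per-unit log hazard ratios
directly interpretable as per-SD effects, which is what gives stated
effect sizes (|ln HR| between 0.4 and 1.0) their intended detectability at
the study's sample size. Proportion-scale features can be supplied through
a custom generator; the score formula itself is agnostic.

The cohort generator does not model competing risks, time-varying effects,
cohort heterogeneity between centres, or informative censoring; the
parameter-recovery guarantees in the test suite are statements about the
implementation under its own assumptions, not about clinical data.

# Numerical choices and degenerate inputs

- **Delaunay degeneracy.** Exact duplicates are collapsed with a 1e-6 px
  tolerance before triangulation; co-circular ties resolve
  deterministically inside `deldir`; collinear inputs return the segment
  chain.
- **Empty structures.** Empty masks raise errors where the operation is
  meaningless (point simulation), and return empty-but-typed results where
  emptiness is informative (blank image → zero nuclei; zero edges → all
  relative features `NA`).
- **Metric edge cases.** Precision/recall/F1 are defined as 0 when their
  denominators vanish (with a warning for the all-zero case); detection
  coverage with zero ground-truth nuclei is `NA`, flagged.
- **Test sizes.** The test and acceptance workloads are sized for a
  single-CPU desk run: fields of 200–500 px, cohorts of 300–2000
  patients, 100-replicate geometry sweeps and 1000-replicate null
  calibrations; the full suite completes in well under a minute.

# Known limitations

- The centroid-in-mask positivity rule is the minimal reading of
  coordinate/stain intersection; alternatives (fractional nucleus overlap)
  would need a definition of overlap the source design does not provide.
- The enumeration of quantitative "cell amounts" variables in the original
  design (reported as 66) is not reconstructible from the available
  description; the quantitative module emits every computable phenotype ×
  region × (count, density, percentage, H-score) summary instead.
- The optimal-cutpoint scan is optimistic on the cohort it is fit on; all
  conclusions should rest on the transferred cutoff in held-out data.
- Pixel accuracy is near-saturated for background-dominated fields and is
  reported for completeness, not as a discriminative quality metric.
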