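---
title: "Methods: soil antibiotic risk, upscaling, and risk-yield thresholds"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: soil antibiotic risk, upscaling, and risk-yield thresholds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

agrorisk chains four analyses that together link antibiotic pollution in
agricultural soil to crop production across nested spatial scales:
ecotoxicological risk quotients for antibiotic mixtures, ensemble
random-forest upscaling of site risks to grids with Monte-Carlo
uncertainty, scale-dependent watershed regressions with AICc model
averaging, and inverted-U threshold estimation for the tradeoff between
risk and yield under land system intensification. A seeded synthetic-data
generator with planted ground truth makes every stage testable by
parameter recovery. This vignette documents the models, the tunable
parameters, and the design decisions taken where the methodology left
genuine choices open.

## Risk quotients for antibiotic mixtures

Exposure is a measured environmental concentration (MEC, ug antibiotic
per kg dry soil). Effect levels are predicted no-effect concentrations
(PNECs) derived from standard endpoints by the assessment-factor
approach:

* PNEC = EC50 / 1000 (or LC50 / 1000) for acute endpoints;
* PNEC = NOEC / 100 for the chronic no-observed-effect concentration.

Endpoints reported in water (ug/L) are converted to soil via the
equilibrium partitioning method, PNEC_soil = PNEC_water x Kd, with Kd
the soil-water partition coefficient (L/kg). Within each compound, the
minimum PNEC across species and endpoints is retained (a worst-case
assumption; the package deliberately keeps no species-specific output).
The risk quotient is RQ = MEC / PNEC, and mixture risk follows
concentration addition: the cumulative RQ at a site is the sum over
compounds of each compound's highest RQ there. Duplicate measurements of
one compound at a site therefore contribute their maximum, and compounds
not reported at a site are treated as absent (RQ 0). RQ > 1 is read as a
serious risk in the EU assessment convention.

Record-level filters remove experimentally treated samples and samples
from seriously polluted sites (hospitals, livestock farms) before any
risk arithmetic; rejections are counted per rule. The bundled toxicity
table (`load_toxicity_table()`) is synthetic and schema-compatible —
clearly labelled illustrative values, not curated ecotoxicology — so the
pipeline runs without any literature compilation.

Global Moran's I (expectation -1/(n-1) under the null) serves as the
spatial-autocorrelation diagnostic for the sampling network. Inference
uses the normal approximation by default, with a permutation test as an
option; the implementation is checked in the tests against a brute-force
double sum and against an independent implementation.

## Ensemble upscaling

Site RQs are upscaled to the full grid by random-forest regression on
the covariate stack (climate, soil properties, land-use proportions,
socioeconomic pressure, management intensity). Choices that matter:

* **Harmonization.** `regrid()` aggregates finer grids by block means and
  upsamples coarser grids by plain replication (no interpolation).
* **Standardization.** Predictors are Z-scored with the training-site
  means and SDs; grid cells reuse the training parameters.
* **Targets.** log10(RQ + delta). delta is 0 when all RQs are positive,
  otherwise half the smallest nonzero RQ; this keeps zero RQs finite,
  preserves ordering, and maps RQ = 1 to exactly 0 when no zeros occur.
  delta is recorded with the fit.
* **Ensemble.** `n_members` forests (default 500; desk-scale runs use
  25), each trained on an independent bootstrap resample of the training
  rows (a random 70% subset is available by configuration), with up to
  `max_trees` trees each (default 1000) and the regression convention
  mtry = p/3. Per-member back-transformation (10^pred - delta, clipped
  at 0) precedes averaging, so the mean, SD and relative-uncertainty
  (SD/mean) maps live on the RQ scale; averaging in log space is a
  configuration switch.
* **Mixtures.** The cumulative map sums per-compound means; its SD is
  taken over member-wise cumulative sums, aligned by member index.
* **Masking.** Non-soil cells (bare land, water) are NA in every output;
  relative uncertainty is additionally NA where the mean is 0.

Validation is a random 70/30 hold-out: RMSE and Pearson's r between
observed and ensemble-mean predicted targets on the held-out rows. The
hold-out requires at least 20 training rows, so fewer than 29
observations cannot be validated this way.

## Watershed scales and model averaging

Risk and land-system indicators are averaged over the soil cells of each
watershed at four nested levels (level 1 coarsest). Land use is
reclassified into arable, built-up and natural (grassland plus forest)
proportions; management intensity is the manure nitrogen application
rate (kg N/km^2/yr) and the irrigated-area proportion. Land system
intensification is the sum of min-max standardized arable proportion,
manure rate and irrigated proportion (each component in [0, 1], score in
[0, 3]); a constant component carries no information and contributes 0.

To probe the extent of scale, watersheds are ranked by a human-footprint
index (ties broken by watershed ID for determinism) and 20 subdatasets
are formed: omitting the ceiling(f * n) highest-footprint watersheds for
f = 0, 0.1, ..., 0.9, and likewise the lowest. Each subdataset is
regressed with all-subsets OLS over seven standardized candidate
predictors (three land-use proportions, two management intensities,
population, GDP — one joint candidate set, since they are reported
together; separating the socioeconomic pair is a configuration choice).
Models are ranked by the small-sample Akaike criterion

AICc = AIC + 2k(k+1)/(n - k - 1),

with k counting intercept, slopes and the residual variance. The
best-model set (delta AICc < 2 by default, extendable to 5) is averaged
with Akaike weights. Full averaging is the default: a predictor absent
from a model contributes a zero coefficient, and its unconditional
standard error combines within-model variance with between-model spread;
conditional averaging is available. Significance is a two-sided z test
on the averaged coefficient.

Two consequences are documented deliberately. First, exact collinearity
among the land proportions (arable + built + natural close to 1) is
handled by a rank check that drops `natural_prop` first, with a log
entry. Second, full-model averaging is *conservative* under the null:
shrinkage toward zero from low-weight models pushes the realized
significance rate well below the nominal 5% (the test suite measures
about 1% across null simulations). The calibration test therefore checks
the direction that matters for inference — no type-I inflation — rather
than exact attainment of the nominal level.

Contributions to explained variance are |beta_i| / sum_j |beta_j| x 100.
The literal alternative reading (|beta_i / sum_j beta_j|) explodes when
coefficients cancel; the implemented form is nonnegative and sums to
100% by construction. Contributions are grouped into land use (arable,
built, natural) versus management (manure, irrigated), with population
and GDP reported as "other".

At desk scale the omission battery necessarily leaves some analyses
unfit: a subdataset must keep at least predictors + 5 rows, so with 54
level-4 watersheds the 80% and 90% omissions fail and are logged and
counted rather than silently skipped.

## Risk-yield tradeoffs and thresholds

**Breakpoints.** The yield response to cumulative RQ is summarized two
ways: a generalized additive model with a thin-plate smoother of basis
dimension 5 (adjusted R^2 and smoother p-value), and a two-segment
continuous hinge search for the risk threshold of yield reduction — a
grid of candidate breakpoints over the central 90% of the RQ range,
two-segment least squares at each, and local refinement of the best
candidate. The slope change is retained only when the hinge improves
significantly on a straight line (F test with 2 numerator degrees of
freedom, p < 0.05); strictly linear data return an explicit
no-breakpoint result. The breakpoint search is implemented natively;
agreement on planted breakpoints — not numeric agreement with any
particular segmented-regression package — is the contract.

**Improvement and tradeoff.** Each objective is scaled as
P = (A_i - A_min) / (A_max - A_min) over watersheds (undefined, hence an
error, for constant objectives). The risk-yield tradeoff is
P_yield - P_risk, the signed distance from the 1:1 line; positive values
mean yield benefits exceed risks. The scores are invariant under
positive affine transformations of the raw objective.

**Constraint lines.** The constraint-variable axis is split into 50
equal-width bins (10 at watershed level 1) and each nonempty bin
contributes its y-quantile as a boundary point: the 99% upper boundary
for yields and tradeoffs, the 1% lower boundary for risk. Quantiles use
linear interpolation (R type 7); the bin representative is the midpoint;
empty bins are reported with NA and listed, never interpolated over.

**Moving windows.** Watersheds are ordered by the constraint variable
(manure rate, irrigated proportion, or arable proportion) and summarized
in contiguous sliding windows of w watersheds with step 1. Candidate
sizes default to {2, 3, 5, 8, 12, 20, 0.05n, 0.1n}. The relative range
of a candidate is the range of its windowed mean RQs divided by the raw
(size-1) range — the maximum over all window sizes, since windowed-mean
ranges shrink as windows grow — and the chosen w is the smallest whose
relative range exceeds 0.6, i.e. the finest resolution meeting the
stability constraint. Window geometry is attribute-space, not spatial:
the ordering variable defines contiguity, and spatially contiguous
windows are an explicit non-goal.

**Inverted U and thresholds.** Windowed tradeoffs are regressed on the
windowed constraint variable as y = a x^2 + b x + c by OLS. When a < 0
the intensification threshold is the vertex t = -b/(2a), with a
delta-method standard error from the (a, b) covariance
(dt/da = b/(2a^2), dt/db = -1/(2a)); fits with a >= 0 return an explicit
no-threshold result. The battery runs every level x crop x constraint
variable combination, propagating failures (e.g. too few watersheds at
coarse levels) into a status column; when several fits are pooled at one
level the spread across fits is the reported error, with per-fit
delta-method SEs retained.

## The synthetic-data generator

The generator emulates the study's data geometry, not any real
geography:

* **Watersheds** come from recursive k-means on cell coordinates —
  level 1 has `n_level1` watersheds, each split into `branching`
  children per level (so 2, 6, 18, 54 at the default 2 x 3^3) — because
  only the nesting and aggregation structure matters to the analyses;
  hydrological realism is a non-goal. A smooth random field thresholded
  at its 5% quantile provides the non-soil mask.
* **Covariates** are transformed Gaussian random fields
  (Gaussian-filtered white noise, autocorrelation range in cells;
  near-zero ranges recover white noise). Land proportions come from a
  softmax with a slack class, so each lies in [0, 1] and their sum stays
  below 1. Manure rate and irrigated proportion are positively coupled
  to arable land and livestock so that a land-system signal exists for
  the watershed regressions to find. Temperature and precipitation carry
  small linear annual trends to exercise year-matched extraction.
* **Concentrations** follow planted linear models of the covariates with
  Gaussian noise, truncated at zero; values below the detection limit
  are emitted as exactly 0, mirroring the non-detect-as-zero convention
  (not half the detection limit). Sampling years are uniform on
  2000-2020. The planted coefficient scale was fixed at design time so
  that site cumulative RQs average about 6 and span the planted yield
  breakpoint at RQ = 9 — the regime the downstream analyses are meant to
  operate in.
* **Yields** for maize, rice, wheat and vegetables are built so the
  scaled tradeoff peaks at a planted, crop-specific intensification
  vertex (0.35, 0.42, 0.55, 0.68 by default). Naive planting fails: the
  min-max scaling of yields forces the scaled yield to span exactly
  [0, 1], which over-constrains "scaled risk plus parabola"
  constructions (two earlier attempts failed vertex recovery and were
  discarded). The working construction sets scaled yield to the isotonic
  trend of scaled risk on intensification plus a concave parabola
  centred on the vertex, with the parabola amplitude solved (by
  root-finding) so the curve spans exactly [0, 1]; such curves pass
  through min-max rescaling unchanged, so subtracting scaled risk
  downstream recovers the planted parabola in expectation. When the risk
  trend alone already spans the scale the parabola is added at a fixed
  amplitude and the overflow clipped at 1, which leaves the vertex the
  argmax. Yields decline beyond the planted cumulative-RQ breakpoint
  (a multiplicative hinge), and a constant risk grid degenerates,
  by design, to yields monotone nondecreasing in intensification.

What the generator does **not** emulate: real coordinate systems or
hydrology, measurement-method differences between laboratories, spatial
sampling bias of monitoring networks, temporal persistence or
degradation kinetics, and real toxicity values. Passing recovery tests
on these landscapes therefore demonstrates that the estimators are
correct and well-calibrated under the stated generating assumptions —
not that field-scale effect sizes or national maps would be reproduced
from real monitoring data.

## Numerical choices and problem sizes

* Sub-seeds are derived per stage from one root seed
  (`derive_seed(seed, tag)`), so toggling stages never perturbs other
  stages' streams; all generators are bitwise-reproducible given
  (configuration, seed).
* Footprint ties break by watershed ID; omission counts use ceiling(fn)
  so every positive fraction removes at least one watershed; quantiles
  are type 7; k-means partitions relabel children by centroid order for
  determinism.
* The test suite and the acceptance script run desk-scale problems
  chosen as the package's standard study: a 32 x 32 grid (2 level-1
  watersheds, branching 3), 120-500 sampling sites (484 in the
  acceptance script), 6-25 forest members with 100-400 trees, 100-seed
  Monte-Carlo calibrations, and 50-seed null batteries. These sizes
  exercise every code path while keeping full runs in minutes.

## Known limitations

* Full-model averaging is conservative under the null (documented
  above); users wanting strictly nominal error rates should use the
  conditional-averaging switch with care or single-model inference.
* The planted-vertex construction is exact in expectation only where the
  isotonic risk trend is adequate; strongly non-monotone risk-
  intensification relations would bias recovered vertices.
* Random forests do not extrapolate beyond the convex hull of training
  covariates; grid cells far from any sampling site inherit that
  limitation, which the relative-uncertainty map only partially reveals.
* Hold-out validation shares the spatial autocorrelation of the sites;
  Moran's I is reported as a diagnostic, but no spatially blocked
  cross-validation is implemented.
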