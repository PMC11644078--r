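---
title: "Methods: time-course metabolomics of batch cell cultures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: time-course metabolomics of batch cell cultures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`metabatch` analyses GC-MS metabolite profiles sampled along the growth cycle
of a plant suspension batch culture — the kind of design used for
heterotrophic tobacco BY-2 cells: ten sampling days spread over lag,
proliferation, elongation, stationary and death phases, with five biological
replicates per day and a few hundred annotated compounds. The package covers
the full analysis chain (preprocessing, ordination, supervised contrasts,
set enrichment, correlation mapping, variability fingerprints) and ships a
synthetic-data generator with known ground truth so that every stage can be
validated end to end. This vignette records the models, the defaults, the
numerical choices, and the design decisions that were genuinely open.

# The preprocessing chain

Raw peak areas pass through a fixed, order-enforced state machine:

1. **Sample-median normalization.** Each sample is divided by its median
   over observed metabolites and re-multiplied by the grand median of all
   sample medians. The re-multiplication is a pure scale convention — it
   keeps values in the original units; plain division would be an
   equivalent alternative. A zero sample median is an error.
2. **Natural log.** The base is a convention only (autoscaling removes it);
   natural log matches common metabolomics practice. Zeros are floored to
   half the metabolite's smallest positive value before the log — the
   standard half-minimum floor for below-detection values.
3. **Autoscaling.** Per-metabolite standardization to zero mean and unit
   sample SD over observed cells. Constant metabolites cannot be scaled;
   they are zeroed and flagged rather than dropped.
4. **KNN imputation.** A cell missing in one replicate but observed in the
   others is treated as a technical dropout and filled with the mean of the
   `k = 10` nearest *metabolite* rows (Euclidean distance over co-observed
   samples, normalized by their number), with `k` capped at the number of
   complete rows. Imputation never changes an observed value.

Whether standardization should precede or follow imputation is not fixed by
the field; this package imputes **after** scaling, which makes the
neighbour distances comparable across metabolites of very different
abundance. The choice is declared in the stage machine rather than hidden.

`unscale_to_normalized()` maps a scaled (possibly imputed) table back to
positive normalized abundances by inverting steps 2–3 exactly; analyses
that need positive values after imputation (the positive-scale fingerprint
below) use it.

# Ordination and supervised contrasts

**PCA** is a plain SVD of the column-centered matrix, with the sign of each
component fixed so its largest-magnitude loading is positive. Group
confidence ellipses use the Gaussian approximation: squared Mahalanobis
radius equal to the chi-square(2) quantile at the chosen level (4.605 at
90%, semi-axis 2.146 for unit covariance).

**OPLS-DA** is a single-response PLS1 with orthogonal signal correction.
For a two-group day contrast (response coded -1/+1), class-orthogonal
components — directions of X-variation uncorrelated with the response —
are estimated and removed iteratively; one predictive component is then
fitted on the filtered matrix. The model reports the fraction of *total*
X-variance carried by the predictive component (`r2x_pred`), by each
orthogonal component, and by the residual; orthogonality of the score
vectors makes these three sum to one exactly, which the tests assert.
Defaults: one orthogonal component; in `"auto"` mode components are added
(up to five) while each explains at least 1% of the X-variance — the
small-variance stopping rule conventional in OPLS implementations. The predictive loading is oriented so the
second day-set of the contrast (the later one) has positive mean score,
making "up" unambiguous in all outputs.

**VIP** is computed from the single predictive component:
`VIP_j = sqrt(J * w_j^2 / sum(w^2))`, so the mean squared VIP is exactly 1
and `VIP > 1` marks influential metabolites, with a weak band at
`0.9 < VIP <= 1`.

**Univariate testing** offers the exact-when-feasible two-sided
Mann-Whitney test and the Welch t test per metabolite, with
Benjamini-Hochberg adjustment across metabolites (the conventional choice
where only "adjusted p-values" is specified) and star bands at adjusted
p < 0.001 / 0.01 / 0.05 / 0.1. All-tied metabolites are reported with p = 1
and flagged rather than dropped.

# Metabolite-set enrichment

Enrichment uses the preranked running-sum (weighted Kolmogorov-Smirnov)
statistic on a list ranked by OPLS-DA predictive loadings: hits increment
by `|score|^weight` normalized over the set, misses decrement by
`1/(N - n_members)`, and the enrichment score is the signed extremum. The
hit-weight exponent defaults to 1 (the common preranked default; nothing in
the analysis pins it down) and the ranking input is a parameter, since
either raw loadings or VIP-signed loadings are defensible.

The null distribution is built from random member sets of the same size
drawn from the profile — a metabolite-label permutation. Sample-label
permutation is out of reach here because the ranking comes from one fitted
model; this limitation is deliberate and declared. NES is the enrichment
score divided by the mean |ES| of same-signed null draws; p-values come
from the signed tail with a +1 smoothing term; BH adjustment is applied
across pathways. Sets smaller than `min_size = 3` after intersection with
the profile are skipped (smaller sets give degenerate nulls). The
implementation is cross-checked against an independent reference
implementation of the statistic in the test suite, and its null p-values
are verified to be approximately uniform (KS < 0.1 over 200 random sets).

Hand-curated pathway membership is supported by an override table
(`add`/`remove` rows) merged onto the base GMT-style annotation, so
class-annotated compounds can be placed into class-level pathways.

# Correlation mapping and the inside/outside contrast

Mean temporal profiles (replicate means per day, on the scaled table) are
correlated metabolite-against-metabolite. The map uses Pearson correlation
by default — consistent with the use of Pearson distance elsewhere in the
workflow — while the pathway contrast uses Spearman; both are available
everywhere and the method tag travels with every output. Edges connect
pairs with `|r| > 0.85`, keeping the sign: the threshold is interpreted on
the absolute value, since negative (anti-correlated) edges are part of the
map's semantics.

The layout places nodes by a signed force model: positive edges attract
proportionally to `r` (normalized by node degree, so hubs do not collapse
the embedding), all pairs repel, and negative edges repel three times more
strongly. Positions start from the two leading eigenvectors of the
correlation matrix — a spectral sketch of the block structure — plus a
small seeded jitter, and a cooling schedule caps per-iteration movement.
The spectral start matters: a random start lets genuine cross-cluster
edges slowly merge well-separated groups, while refining an already
sensible embedding keeps them apart. Everything is deterministic given the
seed.

Nodes are then clustered by k-means on the 2-D coordinates (`k = 4`
following the standard four-phase reading of batch-culture dynamics;
50 restarts; labels renumbered by decreasing size for determinism), and
per-cluster median trajectories, inter-quartile bands and chemical-class
compositions are reported.

The **inside/outside contrast** partitions unordered metabolite pairs into
those sharing at least one pathway ("inside"), annotated pairs sharing none
("outside"), and pairs with an unannotated member (kept only in "all").
The summary statistic is the median shift `median(inside) − median(outside)`
of Spearman correlations: positive when pathway co-membership constrains
co-accumulation.

# Canberra variability fingerprints

For each day and each metabolite pair, the fingerprint is the Canberra
distance `sum |u_i - v_i| / (|u_i| + |v_i|)` between the two metabolites'
replicate vectors at that day, with 0/0 terms contributing zero. Days are
then clustered by the Canberra distance between their pair-distance rows
(average linkage by default — a robust choice for a non-Euclidean
distance; the linkage is configurable).

Two value spaces are exposed, and the choice matters more than it may
seem. On **standardized** data (the default, matching the rest of the
pipeline) the statistic is dominated by the day's mean configuration: for
any pair whose members sit on opposite sides of their own means the term
is exactly 1 regardless of magnitudes, so a day and the day with the
negated configuration are nearly indistinguishable — the statistic is
blind to a global sign flip of the mean profile, and mid-culture days can
pair with early ones through that symmetry. On **normalized** (positive)
data the terms are smooth functions of log-ratios, no saturation occurs,
and differences in replicate dispersion and covariation between days
become legible. The replicate-variability analysis therefore reads more
cleanly in the positive space; both paths are tagged in the output
metadata (`space` attribute) and either can be selected in the pipeline.

# The synthetic-data generator

The generator is first-class, tested code: it defines the study conditions
under which the pipeline's claims are validated.

* **Design**: 360 metabolites, days 1, 2, 3, 4, 7, 14, 18, 21, 23, 26
  after inoculation, 5 biological replicates — the standard batch-culture
  time-course design.
* **Chemical classes** are drawn with proportions matching a GC-MS plant
  profile of this size: 7.5% amino acids, 16.5% sugars, 8.5% carboxylates,
  3.5% free fatty acids, 3% sterols, 8.5% glycosides, the rest unassigned.
* **Temporal archetypes.** Each metabolite follows one of four planted
  shapes on the day axis, standardized across sampling days: (1) early
  high then declining (logistic decline, midpoint ~7.5 d), (2) humps at
  the start, the elongation phase and the end (three Gaussian bumps), (3)
  monotone rise (logistic, midpoint ~11.5 d), (4) a transient mid-culture
  peak within days 7–14 (Gaussian at ~9 d). The fourth shape is a design
  completion — it makes the shape basis near-orthogonal. Assignment
  probabilities are 35/25/30/10% with class bias: amino acids and sterols
  lean to shape 1, sugars to shape 3, FFAs and carboxylates to shape 2.
  Each metabolite additionally shifts its curve by a random offset
  (SD 1 day), so zero crossings are not synchronized within an archetype —
  real compounds do not switch phase on the same day.
* **Amplitudes and baselines** are metabolite-specific (log-scale
  amplitude uniform on [1, 1.8]; log-normal baselines), giving positive,
  heteroscedastic peak-area-like values.
* **Pathways** are disjoint random sets (25 sets of 5–15 members) drawn
  independently of archetype; members share a smooth profile perturbation
  at strength `within_pathway_coupling` (default 0.6). Independence from
  archetype is what makes the inside/outside shift a clean readout of the
  coupling: at coupling 0 the inside and outside pair populations are
  exchangeable and the shift is ~0.
* **Replicate noise** is multiplicative log-normal (peak areas are
  positive and heteroscedastic). Part of each replicate's noise is a
  flask-level factor shared by all metabolites of that biological
  replicate, with a fixed ±1 loading per metabolite — the signs prevent
  sample-median normalization from cancelling it. The noise regime is
  phase-specific: days up to 7 (lag/proliferation) have SD 0.35 and
  coupling 0.8; later days have SD 0.15 and coupling 0.1. This encodes the
  observation that freshly subcultured flasks are heterogeneous and
  strongly co-fluctuating while aged cultures converge, and it is the
  structure the Canberra fingerprint is designed to detect: the expected
  top split of the day dendrogram is lag/proliferation (1–7) versus
  elongation-to-death (14–26).
* **Missingness** is injected uniformly at random (default 2%), with the
  guarantee that no (metabolite, day) group loses all replicates, so the
  KNN-imputation precondition holds by construction.

What the generator does **not** emulate: chromatographic artifacts,
retention-index errors and co-elution, non-detections correlated with
abundance (missingness here is completely at random), drift between
batches, and any real biochemical stoichiometry — pathway coupling is a
correlation statement, not a flux model. Passing the recovery tests
therefore shows the pipeline is sound under its own assumptions, not that
real data will be as kind.

# The medium-kinetics model

A deliberately small daily-step (Euler) model of the incubation medium
with three fluxes: direct sucrose uptake (Monod in sucrose, proportional
to biomass), extracellular hydrolysis of sucrose to hexose (first order,
with the 1.053 g/g water-gain factor so mass bookkeeping is testable), and
hexose uptake feeding logistic dry-biomass growth. Outflows are scaled
within a step so a pool empties exactly instead of overshooting; a
genuinely negative pool (pathological parameters) is clipped at zero with
a warning. pH is phenomenological: a linear dip from 5.8 to 5.1 over the
first two days, then a saturating rise to 6.3.

The default rate constants were calibrated once against the classic
batch-culture milestones — medium sucrose halves in the first two days,
falls below 10% of its start by day 7 and is exhausted around day 10;
hexoses accumulate to ~20 g/L and fall to near zero at culture death; dry
biomass follows an S-curve to ~10–11 mg/mL; pH 5.1 at day 2 and 6.3 at
day 26 — and then frozen. The tests assert exactly these milestones.

# Pipeline defaults and problem sizes

`run_pipeline()` executes: simulate or ingest → preprocess → PCA with 90%
day ellipses → the seven-step contrast schedule (subculture vs lag 21,23
vs 1,2; lag vs proliferation 1,2 vs 4,7; then 7v14, 14v18, 18v21, 21v23,
23v26) with OPLS-DA, differential calls and MSEA per contrast → the
correlation map with k-means clusters and dynamics → the inside/outside
contrast → the fingerprint. Defaults: KNN `k = 10`; `n_ortho = 1`;
`n_perm = 500`; network threshold 0.85, Pearson map / Spearman contrast,
`k = 4`, 300 layout iterations, 50 k-means restarts; fingerprint on the
standardized space with average linkage. Every stage failure aborts with a
stage-named error; seeds and the package version are recorded in the JSON
report.

The validation suite and the acceptance script run the recovery studies at
150 metabolites (cluster recovery, pathway shift) and 120 metabolites
(fingerprint), 20 seeds each, and the full pipeline at the default 360 —
sizes chosen so the whole validation is a desk-scale computation while the
estimates (ARI, detection rates, split rates) are stable across seeds.

# Known limitations

* The OPLS-DA variance fractions depend mildly on the number of orthogonal
  components; reported fractions should always be read together with
  `n_ortho`.
* The enrichment null permutes metabolite labels, not samples; p-values are
  calibrated against that null only.
* Canberra on standardized data is scale-sensitive by construction and
  blind to global sign flips of a day's mean configuration (see above);
  the positive-space variant avoids this but changes the units of the
  fingerprint.
* k-means on 2-D layout coordinates inherits the layout's information
  loss; the test suite shows the spectral-plus-forces embedding preserves
  planted cluster structure, but k-means directly on profiles is the
  stronger clustering when a map is not needed.
* The pipeline imputes after scaling; with heavy missingness (far above
  the few-percent technical-dropout regime) the order of scaling and
  imputation would start to matter.
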