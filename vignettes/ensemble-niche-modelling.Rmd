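---
title: "Ensemble niche modelling: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ensemble niche modelling: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ensdm)
```

# The modelling problem

`ensdm` estimates a species' potential niche — the set of grid cells
whose environmental conditions the species could occupy — from
presence/absence records and a stack of environmental layers, and then
asks how that niche moves under climate scenarios. The central
assumptions are the standard ones of correlative distribution modelling:
occurrence is driven by the mapped environmental covariates (or their
proxies), the realized distribution samples the potential one without
systematic spatial bias, and the fitted occurrence–environment
relationship is transferable to the shifted covariate values of a future
scenario. None of these is testable from the data alone; the package's
synthetic generator exists precisely to check the machinery under
conditions where they hold by construction.

## Data preparation

Coordinates are reduced to two decimal places and within-species
duplicate (lon, lat, presence) rows dropped, so each species keeps at
most one record per roughly 1 km². Rounding is half-away-from-zero
rather than banker's rounding: it is platform-stable and makes the
filter idempotent. When one rounded location carries both a presence and
an absence of the same species, the presence wins — a confirmed
detection overrides a non-detection. This conflict rule is a documented
choice; nothing in the data forces it, but any alternative (keep both,
absence wins) either breaks the one-record-per-cell contract or discards
detections.

Absences for a target species are derived from the compilation itself:
every grid cell holding a record of another species (or an explicit
target absence) is a surveyed site, and becomes one absence unless the
target was detected in that cell. This "target-group absence" scheme is
what makes multi-species compilations more informative than
presence-only data, and it is why the synthetic sampler records all
species at all sites.

## Collinearity screening

`vif_filter()` iterates: find the variable pair with the largest |r|;
if it exceeds the threshold (default 0.85, strictly), drop the member
with the larger VIF = 1/(1 − R²) and recompute. Ties in VIF drop the
later variable in input order, making the procedure deterministic. The
threshold is on the correlation scale, so `max |r| = 0.85` exactly
removes nothing. By default screening uses the covariate values at the
occurrence records; an all-raster-cells scope is available via
`vif_design(stack)` — the two scopes can disagree when occurrences
sample the environment unevenly, and the point scope was chosen as the
default because it matches the data the models are actually fitted to.

## Candidate models

Ten learners are fitted per species across `n_runs = 3` stratified
calibration splits (80% calibration / 20% evaluation, per-class test
counts `round(0.2 * n_class)` clamped to leave both classes on both
sides). One split per run is shared by all methods, so methods are
compared on identical data. Case weights make total presence weight
equal total absence weight (prevalence 0.5) while summing to *n*.

GLM (weighted logistic regression) and SRE are implemented in the
package. SRE is the classical surface range envelope: per continuous
variable the central 95% presence interval (quantiles q = 0.025 and
1 − q, type-7), per categorical variable the levels observed among
training presences; prediction is the 0/1 indicator of falling inside
every envelope. The remaining methods delegate to established
implementations behind a uniform adapter that emits probabilities and
honours case weights where the backend supports them:

| id | backend | pinned settings |
|----|---------|-----------------|
| GAM | `mgcv::gam` | thin-plate smooths, k ≤ 9, REML |
| CTA | `rpart::rpart` | method `"class"`, defaults |
| ANN | `nnet::nnet` | 8 hidden units, decay 0.01, maxit 500, entropy fit, standardized inputs |
| RF | `randomForest` | 500 trees, defaults (no case weights) |
| GBM | `xgboost` | `binary:logistic`, depth 2, eta 0.1, 100 rounds |
| FDA | `MASS::lda` | equal class priors (0.5/0.5) |
| MARS | native | forward-selected reflected hinge pairs (5 quantile knots/variable, ≤ 10 pairs, deviance gain ≥ 1e−3), weighted logistic fit |
| MAXENT | `glmnet` | lasso logistic on linear + quadratic features, deterministic 5-fold CV for λ |

Two of these deserve a note. FDA with the default linear basis on a
binary response is equivalent to linear discriminant analysis with
optimal scoring, so `MASS::lda` with equal priors is used directly. The
MARS adapter is a compact native implementation — forward selection of
reflected hinge-function pairs by weighted binomial deviance — rather
than the full backward-pruning algorithm; on the smooth logistic
response surfaces this package targets the forward pass captures the
same piecewise-linear structure. All settings are fixed constants, never
data-dependent, so a seed fully determines a fit.

Fit or evaluation failures (e.g. a degenerate split) are recorded and
excluded; they never abort the species.

## Evaluation

ROC is the Mann–Whitney estimator: the probability a random presence
outranks a random absence, ties counted ½ — computed from ranks, and
tested against an O(n²) pairwise count. TSS is maximized by scanning
cutoffs at all midpoints between distinct predicted values plus the two
degenerate cutoffs (everything predicted present / absent); a record is
"predicted present" when its suitability strictly exceeds the cutoff.
Including the degenerate cutoffs floors TSS at 0 — a useless model
scores 0, not a small negative number. Ties in TSS select the smallest
cutoff. TSS is reported at this maximizing cutoff rather than at a fixed
0.5 because the cutoff is reused downstream to binarize maps, and a
fixed 0.5 is meaningless for learners (SRE, weighted fits) whose output
is not calibrated prevalence. Constant predictions short-circuit to
ROC 0.5, TSS 0.

Permutation importance is the mean over 3 permutations of
1 − max(0, cor(p, p_shuffled)): negative correlations are floored so
importance stays in [0, 1], and a model with constant predictions gets
all-zero importance. Three permutations is noisy by design — it matches
the reference analysis setting — and the noise averages out in the
ensemble aggregation.

## Ensemble

Members are candidates with ROC > 0.9; when a species has none the gate
falls back to 0.8, and a species with no candidate above 0.8 gets no
ensemble (reported, skipped). Weights are member ROC scores normalized
to sum 1. The ensemble map is the pointwise weighted mean.

The ensemble is evaluated on the full dataset rather than any single
held-out split: members were calibrated on different splits, so no one
split is held out from the whole ensemble, and the combined map needs a
common reference. These scores are therefore optimistic relative to the
members' held-out scores and should be read as descriptive.

Ensemble variable importance applies the member weights to the *full*
candidate importance set: per method, importances are averaged over all
of its runs (whether or not each run is a member), multiplied by the
method's summed member weight (zero for gated-out methods), summed per
variable, divided by the fixed number of methods (10), and rescaled to
percentages. Keeping the denominator at the method count rather than the
member count follows the reference formulation; since the final rescaling
normalizes to 100%, the choice affects nothing downstream.

## Consensus maps, transitions, dispersal

The binary consensus map marks a pixel suitable when strictly more than
50% of the evaluated candidates (not only ensemble members — the vote is
over the whole 30-model set, configurable) predict suitability strictly
above their own cutoff. With 30 models, exactly 15 votes is *not*
suitable; both strict inequalities are contractual and tested.

Current/future map pairs classify pixels as never (0,0), always (1,1),
lost (1,0), gained (0,1); the four classes partition the masked-in
pixels, asserted on every call. Range change is relative to the current
range (always + lost). Full dispersal counts every gained pixel. No
dispersal counts a gained pixel only when its patch in the *future*
binary map contains at least one always-occupied pixel — habitat
connectivity is the only dispersal constraint, so a "gained" fragment
touching retained habitat counts and an offshore fragment does not.
Island boundaries are enforced purely by this connectivity rule (the sea
is masked out, so patches cannot cross it). Connectivity defaults to
8-neighbour (queen), the common landscape default, configurable to 4.

## Fragmentation metrics

Patches are connected components of habitat at queen connectivity,
labelled in deterministic row-major order. Patches below 0.1 km² are
removed from the patch set and all metric denominators. At a 30
arc-second resolution cells are ~0.6–0.9 km², so the filter removes
nothing; it is retained so the metrics are resolution-independent.
SPLIT = A²/Σaᵢ² uses the total masked-in landscape area A; the
aggregation index counts like rook adjacencies (patch labelling and AI
deliberately use different adjacency rules — that is how the standard
metrics are defined). A single habitat pixel has g_max = 0 and AI is
defined as 0.

Geodesic cell areas use the spherical formula
R²·Δλ·(sin φ_top − sin φ_bottom), R = 6371 km, at each row's
cell-centre latitude; summed over a latitude band this telescopes to the
exact band area. A Cartesian mode (unit areas) exists so fragmentation
oracles in tests are exact integer arithmetic.

## Grid conventions and degenerate inputs

Grids are row-major from the NW corner. A point maps to cell
⌊(lon − lon_min)/res⌋, ⌊(lat_max − lat)/res⌋ with half-open
[edge, edge + res) intervals; points exactly on the max edge belong to
the last cell, so the extent is covered without gaps. Crops snap
requested bounds outward to source-grid cell edges. Exact collinearity
in VIF is reported as `Inf` (never a crash); zero-variance columns,
single-class labels, empty current ranges and empty habitat all raise
typed errors or return documented sentinels (`NA` for SPLIT/AI of empty
habitat) rather than propagating `NaN`.

## The synthetic generator

`generate_world()` emulates the structure of a gridded climate dataset:
a strictly monotone latitudinal gradient (temperature analogue),
Gaussian random fields with ~8-cell correlation length (precipitation
analogues; separable Gaussian-kernel smoothing of white noise),
a quantile-binned categorical layer (soil analogue), and a two-island
mask (vertical sea channel) that exercises the disconnected-gain rule.
Continuous layers are standardized to mean 0, sd 1 over land. True
niches are logistic in the layers, so suitability, binary range, and
range change under any scenario have closed forms. Scenarios add a
constant to the temperature analogue (+1.0 and +3.7 in layer units as
the two warming analogues) and optionally scale precipitation;
categorical layers are static.

Default test conditions are a 100×100 world with 400 survey sites and a
dominant coefficient |β| = 3; recovery tests require ensemble-vs-truth
Pearson r > 0.8 and consensus-vs-truth Jaccard > 0.6, and a scenario
constructed so the true net range change is exactly −50% (a 25-row shift
of a cold-adapted niche) must be estimated within ±15 percentage points
across 5 seeds. Smaller worlds (40×40, 200 sites, 2–3 methods) are used
where only plumbing is under test.

What passing these tests shows: the pipeline recovers niche structure,
ranking, and range arithmetic when its assumptions hold. What it does
not show: robustness to sampling bias, spatially autocorrelated
detection error, niche–covariate mismatch, or non-equilibrium
occupancy — real-data failure modes the generator deliberately omits
(it emulates none of the observation process beyond Bernoulli sampling
at true suitability).

## Known limitations

- Raster I/O is plain-text ESRI ASCII only, single CRS (geographic
  WGS84); there is no reprojection.
- Dispersal is all-or-nothing by patch connectivity; finite dispersal
  kernels are out of scope.
- The ensemble evaluation is in-sample (see above).
- RF ignores case weights (backend limitation); its candidates still
  compete through the same ROC gate.
- Only the reported fragmentation metrics are implemented, not the full
  landscape-metric catalogue.
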