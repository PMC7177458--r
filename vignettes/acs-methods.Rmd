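---
title: "Methods: street-network exposures and active school commuting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: street-network exposures and active school commuting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(acsroutes)
```

## The question and the measurement model

Active commuting to school (ACS) — walking the home–school journey — is a
health behaviour with well-documented built-environment correlates. This
package implements a GIS-style measurement-and-analysis protocol on a street
network: it quantifies the *school-built environment* inside a catchment
buffer, quantifies the *home–school route*, and relates both to a
dichotomised commuting outcome.

The outcome comes from a weekly travel questionnaire: the number of active
one-way trips per week, 0–10. Participants reporting 4–10 trips are coded
active (1), 0–3 non-active (0). Cyclists are excluded rather than recoded,
and so are participants with a missing trip count or an unusable home
location; every exclusion carries a logged reason.

Five exposures are computed per participant:

* **Resident density** — residents per hectare of the school's catchment
  footprint.
* **Intersection density** — street nodes of graph degree ≥ 3 per hectare.
  Degree ≥ 3 is the standard GIS convention for an intersection; it excludes
  dead ends and mid-block bends, which are connectivity-neutral.
* **Mixed-use diversity** — normalised Shannon entropy of floor-area shares
  across six land-use classes (residential, industrial, retail, office,
  public service, recreational):
  \(H = -\sum_i p_i \ln p_i / \ln k\) over classes with \(p_i > 0\). The
  class count \(k\) is fixed at 6, so an absent class lowers the index —
  the index reads as *evenness across the named uses*. (A `k = "present"`
  switch normalises by the number of observed classes for sensitivity
  analysis.) Because the raw entropy is school-level, it is standardised to
  a z-value across schools, with the population-SD convention (n
  denominator).
* **Distance** — shortest street-network distance home→school, in km.
* **PRD (pedestrian route directness)** — network distance divided by
  straight-line distance. 1 is a perfectly direct route; values ≤ 1.5 are
  conventionally "direct", > 1.5 "indirect".

Both legs of the PRD ratio are measured between the *snapped* endpoints
(each point orthogonally projected onto its nearest street segment). This
makes PRD ≥ 1 a theorem rather than an aspiration: a shortest network path
between two points on the network can never undercut their straight line.
Real geocoded data violate this only through address errors; such records
are retained and flagged `prd_lt_1` (a strict mode drops them).

## Catchment buffers on the network

The school-built environment is the sub-network within a threshold network
distance of the school, walked in every direction: 1250 m for children and
1350 m for adolescents (published walking-threshold estimates for these age
groups; both are configurable). An edge reached from one end with residual
budget *r* contributes its first *r* metres; reaches from both ends merge.

The footprint of a buffer is the set of points within a pedestrian-access
margin (default 25 m) of any reached edge portion. With no
polygon-clipping library in the dependency stack, the footprint is handled
numerically rather than as an explicit polygon union: area is counted on a
deterministic grid of cell centres (default resolution 10 m, globally
aligned so results do not depend on the bounding box), and
parcel areal weighting asks, for each grid cell centre inside a parcel,
whether that cell is covered. Partially covered parcels therefore
contribute residents and floor area proportionally to their intersected
fraction. At the default resolution the measured area of a dilated 1 km
street differs from the closed-form capsule area by under 5%; halving the
resolution quarters that error, at four times the cost. The GeoJSON writer
emits the footprint as per-segment capsule polygons.

Snapping ties (a point equidistant from two edges) break to the lowest edge
id, then the lowest offset, so every run of the pipeline is deterministic.
Participants whose home cannot reach their school on the network
(disconnected components) are excluded with reason `unroutable` — the
analogue of a study's lost-case funnel, surfaced rather than silently
dropped.

## The modelling protocol

School-level measures take only as many values as there are schools, so the
three buffer measures are recoded to 0/1 dummies at the median before
entering the models. The median is taken over the participant-level column
(each participant carrying their school's value) — the regression's unit of
analysis — with ties coding to 0; a school-level alternative is available.
Route measures stay numeric.

1. **Model 1** — pooled binomial logit of ACS on all five predictors plus
   an age-group adjustment, all variables entered in one step (no stepwise
   selection). Its crude counterpart (without the age term) feeds a
   confounding check: the percent change in each predictor's OR, flagged at
   the conventional 10%.
2. **Collinearity** — pairwise Pearson correlations (screen: |r| < 0.80),
   logistic coefficient SEs (screen: < 2.0), per-predictor VIF from
   regressing each predictor on the others, and condition indices of the
   scaled, intercept-included cross-product matrix (screen: < 20). The VIF
   drop threshold defaults to 2.0: VIFs in the low 2s are where school-level
   measures start borrowing each other's variance, and a predictor is
   dropped only when it is *both* non-significant in model 1 (p > 0.05) and
   VIF-flagged — neither symptom alone justifies removal.
3. **Model 2** — the remaining predictors refit separately for children and
   adolescents. Strata with fewer than 10 events per class refuse to fit.

Coefficients are reported SPSS-style: B, SE, Wald p, OR = exp(B) with the
95% Wald interval exp(B ± 1.96·SE) (profile-likelihood intervals are an
option), and classification accuracy at probability cutoff 0.50. The IRLS
fit runs to a relative log-likelihood tolerance of 1e-8 (max 100
iterations); coefficient magnitudes beyond |B| > 15 — odds ratios above
three million — only arise under (quasi-)perfect separation, which is
reported as an error naming the offending predictor rather than returned as
a pseudo-estimate.

## Cut-points: ROC and the Youden index

Four threshold analyses relate route measures to the outcome: PRD for all
participants and per age group (active *above* the cutoff), and distance
for all participants (active *below*). The ROC is empirical — no smoothing
— with candidate thresholds midway between consecutive distinct scores. AUC
is the trapezoidal area, which equals the Mann–Whitney concordance
probability with half-credit for ties; its 95% CI uses the Hanley–McNeil
variance, chosen for closed-form desk-scale computation (DeLong is the
usual alternative and is unnecessary at these sample sizes). The cutoff
maximises J = sensitivity + specificity − 1; J-ties break towards the
cutoff that classifies more participants active. A model is *valid* when
AUC ≥ 0.5 with 0.5 outside the CI, *valid-exploratory* when additionally
AUC < 0.75, otherwise *invalid*.

Finally, a cross-table of commuting status by PRD ranges uses bins
[min–1.212], (1.212–1.30], (1.30–1.40], (1.40–1.50], (1.50–max]: the first
edge is the ROC-derived all-participant PRD cutoff of the original study,
the last is the conventional direct/indirect boundary. Interval membership
is (a, b] with a closed first bin; percentages are kept at full precision
internally and rounded to one decimal only when printed. Independence is
tested with Pearson's chi-square (no continuity correction).

## The synthetic city

The questionnaire data behind this design are not publicly deposited, so
the package ships a generator that emulates every input with controllable
structure; the analysis scripts and all stochastic tests run on it.

* **Streets** — a `blocks × blocks` grid (default 16 blocks of 120 m), with
  a fraction of edges removed as cul-de-sacs (default 12%) and
  `superblocks` non-crossable areas (default two 3×3-block areas with
  interior nodes removed, so routes must go around — the classic
  directness-killing morphology). The largest connected component is kept;
  a draw that fragments the grid is re-drawn, at most five times.
* **Land use** — one parcel per block; each of four districts draws its
  class mix from a Dirichlet distribution (concentration 1.0), parcels
  sample a class from their district's mix, floor areas are log-normal, and
  residents follow a negative binomial on residential parcels.
* **Population** — 826 children and 2142 adolescents across 24 schools (8
  primary, 14 secondary, 2 both), mirroring the study scale this design
  derives from. Homes sit at a log-normal straight-line distance from the
  assigned school (median 800 m, sdlog 0.55) at a uniform bearing.
* **Behaviour** — the active indicator is Bernoulli with logit
  β₀ + β₁·int_dummy + β₂·mix_dummy + β₃·distance + β₄·PRD, computed from
  the pipeline's own exposure values, so recovery tests isolate estimation
  error from exposure-measurement error. Trip counts are drawn uniformly
  from 4–10 for actives and 0–3 otherwise: *active ⟺ trips ≥ 4* holds by
  construction. Small fractions of missing outcomes (5%), cyclists (2%) and
  corrupted addresses (2%) exercise the exclusion funnel.

The default slope presets reproduce the qualitative age-group contrast of
the study this design follows — children −, −, −, + and adolescents
+, +, −, + over (intersections, mixed uses, distance, PRD) — with published
magnitudes where those are usable (children −0.369, −0.420, +2.428;
adolescents +0.495, +0.711, −0.144, +1.257). The one exception is the
children's distance slope: the published per-km value (−0.021) is so small
that no simulation at the package's n = 5000 scale could distinguish its
sign from noise (one-sided power ≈ 0.7), so the default is −0.18/km —
between the two published age-group values and sized, by an a-priori power
calculation, to make the sign-recovery study informative. Intercepts
(−2.13 children, −1.62 adolescents) were calibrated once, on the default
city, to land near the study's observed active shares (≈68% and ≈71%);
realised shares vary by a few points across seeds because exposures are
school-clustered. Residents enter the behaviour model with coefficient
zero: the generator plants a genuinely null school-level predictor.

All randomness flows through one seeded generator; identical config and
seed give byte-identical output files.

### What the generator does and does not emulate

It reproduces the *statistical structure* the analysis assumes — clustered
school-level exposures, route measures derived from real shortest paths on
a morphologically varied network, a logistic outcome with known
coefficients, and a defect funnel. It does not attempt realistic city
statistics (no calibration to cadastral data or OSM), socio-economic
covariates, route choice beyond shortest paths, or measurement error in
exposures (an optional noisy-exposure mode would be the place for
robustness studies). Passing recovery tests therefore demonstrates that
the estimation machinery is faithful, not that the published effect
estimates would replicate in new field data.

## Numerical and design choices worth knowing

* Coordinates must be projected metres; inputs that look like lon/lat
  degrees (all coordinates within ±180/±90 *and* sub-metre edge spans) are
  rejected with instructions to re-project.
* Edges are treated as straight segments; an edge's stated `length_m` may
  exceed its chord (curvy streets), and offsets scale proportionally.
* Problem sizes in the test suite: oracle-equivalence fixtures stay ≤ 500
  nodes so brute-force Dijkstra and exhaustive pair enumeration remain
  exact and fast; the stochastic recovery study uses 20 replicates of a
  5000-participant city, the scale at which all eight stratified
  coefficient signs are recoverable with high probability.
* Text serialisation (GeoJSON/CSV) carries ~10 significant digits; two
  runs through files agree to that precision, while in-memory reruns are
  bit-identical.
* Degenerate inputs fail loudly and early: empty networks, unroutable
  schools, all-zero land-use areas, constant predictors, single-class
  outcomes, zero chi-square margins.

## Limitations

School-level clustering is deliberately *not* modelled (no random effects),
matching the design this package implements; with ~24 schools the
school-level dummies can occasionally go constant within one age stratum
on an unlucky synthetic draw, which the model sequence reports as an
explicit error — re-draw the city or widen the school mix. The footprint
grid is a numerical approximation with a stated resolution. The ROC
validity classes depend on the Hanley–McNeil variance, which is slightly
conservative for very large AUC. Published numeric cut-offs from the
original field study (PRD 1.212/1.269/1.213, distance 1.262 km) depend on
data that were never deposited and are treated as bin-edge conventions,
not as reproduction targets.
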