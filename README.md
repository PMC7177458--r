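# acsroutes

Street-network exposures and active school commuting analysis in R.

Urban-health studies of **active commuting to school (ACS)** ask how the
built environment around a school and the geometry of each child's
home–school route relate to whether that child walks to school. This
package implements the full measurement-and-analysis chain for that
question, for epidemiologists and urban analysts who have (or want to
simulate) a street network, a school roster, land-use parcels and a travel
questionnaire:

* **Network geometry** — snapping points to streets, shortest network paths
  with partial-edge offsets, and network-distance catchment buffers
  (service areas) with footprint area and intersection counts.
* **Exposures** — resident density and intersection density per hectare of
  buffer, a mixed-use diversity index
  `H = -Σ pᵢ ln pᵢ / ln k` over six land-use classes (z-scored across
  schools), home–school network distance, and **PRD**, the pedestrian route
  directness: network distance ÷ straight-line distance (1 = perfectly
  direct; > 1.5 conventionally "indirect").
* **Outcome coding** — weekly active-trip counts 0–10 dichotomised at
  4–10 = active; exclusion funnel (missing outcome, cyclists, ungeocodable
  or unroutable homes) with per-reason logs.
* **Association** — a two-model binary logistic protocol: pooled fit with
  age-group adjustment and confounding check (OR change > 10%),
  collinearity diagnostics (correlations, SEs, VIF, condition indices),
  then age-stratified refits; OR = exp(B) with Wald 95% CIs and
  classification accuracy at p = 0.50.
* **Cut-points** — empirical ROC curves with trapezoidal AUC
  (= Mann–Whitney concordance), Hanley–McNeil CIs, and Youden-index
  (J = sensitivity + specificity − 1) optimal thresholds for PRD and
  distance, each with a validity class.
* **Cross-table** — ACS status by PRD ranges with row percentages and
  Pearson's chi-square.
* **Synthetic city** — a seeded generator for all inputs (grid morphology
  with cul-de-sacs and non-crossable superblocks, Dirichlet land-use
  mixing, log-normal home placement) plus a logistic behaviour model with
  known coefficients, so the whole pipeline is testable end to end.

Everything is exact-format compatible with plain GeoJSON (network, parcels,
service areas) and CSV (rosters, schools, exposure tables).

## Worked example

The `analysis/` directory is a five-stage workflow over a simulated study
(2968 participants, 24 schools). Run the stages in order from the package
root:

```sh
Rscript analysis/01_simulate.R     # city + roster -> results/city/
Rscript analysis/02_exposures.R    # exclusions + exposure table
Rscript analysis/03_associate.R    # two-model logistic protocol
Rscript analysis/04_thresholds.R   # ROC/Youden cut-points
Rscript analysis/05_crosstab.R     # ACS x PRD cross-table
```

Stage 2 prints the funnel and the sample's shape:

```
exclusions: 148 missing ACS, 59 cyclists, 59 ungeocodable
analysed n = 2699 of 2968 enrolled
active share: 64.5% (children 66.2%, adolescents 63.8%)
median distance 0.85 km, median PRD 1.351; 0 records flagged PRD < 1
```

Stage 3 fits the stratified models. The generating truth behind this run
(recorded in `results/city/truth.json`) sets children's PRD log-odds at
+2.428 (OR 11.3) and adolescents' mixed-use dummy at +0.711 (OR 2.04);
both are recovered within their intervals, with the age-group sign
contrast intact:

```
model 2 (child): n = 758, accuracy 67.2%
  res_d        OR =  0.860 (0.567- 1.306)  p = 0.48
  int_d        OR =  0.630 (0.369- 1.076)  p = 0.0905
  mix_d        OR =  0.758 (0.516- 1.113)  p = 0.158
  distance_km  OR =  0.802 (0.585- 1.100)  p = 0.171
  prd          OR = 12.379 (4.752-32.243)  p = 2.59e-07
model 2 (adolescent): n = 1941, accuracy 64.1%
  res_d        OR =  0.852 (0.668- 1.087)  p = 0.197
  int_d        OR =  1.342 (1.083- 1.664)  p = 0.00728
  mix_d        OR =  1.935 (1.544- 2.424)  p = 9.53e-09
  distance_km  OR =  0.896 (0.743- 1.082)  p = 0.254
  prd          OR =  3.811 (2.470- 5.882)  p = 1.51e-09
```

An OR above 1 means higher odds of walking: for this simulated city, a less
direct route (higher PRD) strongly predicts walking in both groups, and
mixed land use encourages adolescents but not children — the qualitative
pattern the generator plants. Stage 4 then locates the PRD cut-point that
best separates active from non-active commuters:

```
prd_all          AUC = 0.585 (95% CI 0.563-0.607)  J = 0.132  cutoff = 1.383  [valid-exploratory]
prd_children     AUC = 0.611 (95% CI 0.570-0.652)  J = 0.189  cutoff = 1.357  [valid-exploratory]
prd_adolescents  AUC = 0.575 (95% CI 0.549-0.601)  J = 0.122  cutoff = 1.324  [valid-exploratory]
distance_all     AUC = 0.486 (95% CI 0.463-0.509)  J = 0.010  cutoff = 1.080  [invalid]
```

and stage 5 cross-tabulates status by PRD range (chi-square p = 1.5e-10 for
this run). All stage outputs land under `results/` as CSV/JSON/GeoJSON.

The same pipeline runs fused, in memory:

```r
library(acsroutes)
report <- run_pipeline(run_config(seed = 1803, output_dir = "results/run"))
```

or on your own files by passing `network=`, `parcels=`, `schools=`,
`participants=` paths to `run_config()`.

## Method vignette

`vignettes/acs-methods.Rmd` documents the measurement model (buffers,
entropy index, PRD), the modelling protocol and its diagnostics, the
ROC/Youden conventions, the synthetic city's design and defaults, and the
package's numerical choices and limitations.
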