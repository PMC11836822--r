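---
title: "Classifying cattle farms into production types from linked registry data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying cattle farms into production types from linked registry data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

National cattle registries record individual animals, their movements
between holdings, bulk-milk quality tests and veterinary antibiotic
prescriptions — but they rarely record what a farm *does*. For disease
surveillance and antibiotic-use benchmarking it matters greatly whether a
holding fattens calves, milks cows, fattens older cattle, rears heifers
for dairy herds, or keeps suckler cows. `cattletype` implements a
supervised pipeline that infers the predominant production type of a farm
from one year of registry events, using five classes:

* **calf fattening** — buys young calves from many farms, slaughters at
  roughly 5–8 months;
* **dairy** — milking herd of adult cows, frequent calvings, bull calves
  sold on;
* **cattle fattening** — buys cattle at 6–24 months, predominantly male,
  slaughters them as young stock;
* **rearing** — raises heifers off-site for dairy farms, with a high
  share of animals returning to their herd of birth;
* **suckler cow** — beef-breeding cows raising their own calves, usually
  with a bull.

Because the underlying national data are confidential, the package ships
an event-level simulator for these five types so that every stage —
feature extraction, model training, attribution, calibration — can be
developed, tested and benchmarked end to end on data with known truth.

## Farm-year features

Each eligible farm-year is summarised by 24 features. A farm is eligible
in a year when it has at least 10 cattle stays overlapping that year and
is a standard holding (alpine pasture facilities, veterinary clinics and
cattle markets are excluded).

The demographic features are built on **animal days**: one calendar day
of one animal's presence. Presence intervals are half-open, `[entry,
exit)`, clipped to the calendar year, so a within-year transfer never
counts a day twice and a same-day entry/exit contributes nothing. Age
classes partition all ages by *completed calendar months*: calf =
completed months 0–6, young = 7–24, adult = 25 and above. An animal
changes class on the monthly anniversary of its birth date, with
month-end clamping (born January 31, one month is completed on February
28/29). This convention is enforced by an exact day-by-day oracle in the
test suite.

The feature set, with zero denominators always mapping to 0:

| Group | Features | Definition |
|---|---|---|
| Milk | `hasMilk` | at least one bulk-milk test in the year |
| Age & sex | `pFemaleCalves` … `pMaleAdults` (6) | class animal-days / total animal-days |
| Breed | `pDairyBreed`, `pBeefBreed`, `pDoubleBreed` | breed-category days / total days |
| Calving | `pCalvedAnimals` | days contributed by animals on or after their first calving / total days |
| Births | `pBirths` | calvings (incl. stillbirths) on the farm in the year / distinct animals with ≥ 1 day |
| Slaughter | `pOutMovesToSLCalves/Young/Adults` | direct slaughter exits in the age class at exit / all direct slaughter exits |
| Movement | `pOutMovesToBirthHerd`, `pAnimals10Days` | among sales (slaughter excluded): share returning to the birth farm; share present ≤ 10 days |
| Movement | `inDegree`, `outDegree` | `log(1 + distinct origin farms)`, `log(1 + distinct destination farms)` in the year |
| Antibiotics | `pABRearing` … `pABSuckling` (5) | prescriptions of the usage category / all prescriptions in the year |

Several definitional choices deserve a note because the source registers
leave them open:

* **Degree transform.** The published per-type degree medians lie on a
  `log(small integer)` grid, so the degrees are log-transformed;
  `log(1 + k)` is used so that farms with no movement partners stay
  finite. `log(k)` would fit the same grid for `k ≥ 1`; the two differ
  only additively for the typical range and the classifier is indifferent.
* **Out-degree counts destination farms.** The symmetric reading of the
  in/out pair; sales to slaughter carry no destination and are excluded.
* **Herd size for `pBirths`** is the number of distinct animals with at
  least one animal-day in the year, not the average daily herd size.
  Under realistic turnover the distinct-animal count is larger, which
  keeps the dairy birth ratio in the published range; an average-daily
  denominator overshoots it.
* **`pCalvedAnimals` is lifetime-based**: an animal counts as "calved"
  from its first recorded calving onward, also when that calving predates
  the year.
* **Slaughter ratios use direct exits only** (animals leaving the farm
  for slaughter), in both numerator and denominator.
* **Extreme-value exclusion.** Labeled farm observations are dropped when
  any numeric feature falls outside `[Q1 − 3·IQR, Q3 + 3·IQR]` computed
  within the observation's class. Features whose within-class IQR is zero
  are not fenced: most ratio features are exactly 0 for most farms of a
  class, a degenerate fence would flag any nonzero value, and the
  exclusion is meant to catch single-farm anomalies (management changes),
  not the ordinary sparsity of the feature space. On the default
  benchmark this removes roughly 5–10% of observations, dominated by
  farms carrying a sideline herd component whose class-atypical shares
  (male calves on a dairy farm, say) fall outside their class's fence —
  exactly the mixed-management cases the exclusion is meant to catch.

## The synthetic registry generator

The simulator is event-level by design: it never samples feature vectors.
It emits animals, stays, calvings, milk tests and prescriptions, and the
features used for the benchmark are obtained by running the *same*
extraction code a real registry extract would pass through.

Each production type is described by a `type_profile`: a herd-size
law (log-normal, national median herd size around 35–40 cattle), a target
day-share mix over the six sex×age classes, breed composition, milk-test
probability, calving rate (calvings per adult-female-year), per-class
residency patterns, exit-mode mixes, movement-pool sizes, a
return-to-birth-farm probability, and prescription behaviour. Per-farm
heterogeneity is introduced by drawing every farm's share vectors from
Dirichlet distributions centred on the profile (concentration parameters
control the published interquartile spread) and scalar probabilities from
Beta distributions.

Demography is static within the simulation window:

* **Resident classes** (adult cows, bulls) are renewal processes on herd
  "slots": successive occupants arrive, stay for a tenure of a few years
  and are culled or sold; fractional slots become part-year animals,
  which is how a shared bull produces the small but nonzero adult-male
  day share typical of suckler herds.
* **Throughput classes** (fattening calves, reared heifers) are yearly
  entry cohorts with entry-age and exit-age laws; cohorts are also
  generated for the years immediately before the window so that stays
  overhanging the window start appear at their steady-state rate.

Counterpart holdings (origins, destinations, external birth farms) are
synthetic identifiers drawn from per-farm pools whose sizes set the
network degrees; they are never simulated as farms. Animals moved in are
flagged as born at their origin farm with high probability, which is what
makes "return to birth herd" a meaningful event for rearing farms.

The default profiles are a **versioned calibration file**
(`inst/extdata/default_profiles.yaml`). Their constants were fitted once
so that, with 500 farm-years per type pushed through the full
simulate→extract path, the extracted feature medians match the published
per-type summary statistics (checked for eight anchor features in the
test suite, each within ±0.05 or ±5 percentage points, ±0.01 for the
suckler adult-male share). The default benchmark
(`benchmark_config()`) mirrors the reference dataset's composition — 64
calf-fattening, 264 dairy, 76 cattle-fattening, 63 rearing and 151
suckler farms over 2020–2022, dairy ≈ 43% of observations — and emits a
small fraction of farms whose first year falls below the 10-stay
eligibility threshold, reproducing "missing farm observations" in early
years.

What the generator deliberately does **not** emulate: seasonal alpine
grazing movements, within-year management changes, spatial structure,
breed-specific biology, and the long tail of truly mixed enterprises
(only a modest share of farms carries a secondary "sideline" herd
component). Classification on simulated data is therefore an *easier*
problem than on real registries; passing the benchmark shows the pipeline
is correct and that the published performance is attainable when the
class signal is as described, not that the model would reach the same
accuracy on any particular country's data.

## Models and evaluation

The labeled matrix (one row per farm-year, grouped by farm) is split
70/30 by a stratified **group** split: all observations of a farm stay on
one side, and per-class shares are preserved within a few percentage
points. Hyperparameters are tuned by group-aware 10-fold cross-validation
(no farm spans folds) optimising macro-averaged F1: a random draw of
candidates from the search space (`inst/extdata/default_search.yaml`) is
followed by a coordinate grid refinement around the incumbent. Three
families are supported: a probability random forest (ranger), an
RBF-kernel SVM and a single-hidden-layer perceptron; SVM and MLP consume
z-scored features (statistics fitted on the training partition only),
the forest consumes raw features. Ties anywhere are broken by the fixed
alphabetical class order, and every stochastic step is seeded, so a
configuration reproduces byte-identical outputs.

Metrics follow the one-vs-rest formulas: per-class precision
`TP/(TP+FP)`, sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)` and
`F1 = TP/(TP + (FP+FN)/2)`; overall metrics are unweighted macro means,
and **multiclass balanced accuracy is defined as macro sensitivity**
(mean per-class recall) — the definition under which the published
sensitivity and balanced-accuracy columns coincide. Per-class "accuracy"
is class recall. Confidence intervals resample whole farms of the
training partition with replacement (B replicates), refit with the chosen
hyperparameters — re-searching 1,000 times would be computationally
indefensible and is not implied by a bootstrap of the training data — and
re-evaluate on the untouched holdout; the CI is the 2.5/97.5 percentile.

A one-vs-rest random-forest stage with SMOTE up-sampling (k = 5
neighbours, synthetic points on segments between minority neighbours,
up-sampled to balance) is provided as `train_ovr_smote()`; it mirrors the
screening stage used to produce preliminary labels and its outputs are
never fed back into training.

## Attribution and calibration

Random-forest predictions are explained with the exact path-dependent
TreeSHAP algorithm, implemented in C++ over the fitted ranger trees, with
node covers recomputed by routing a background sample through each tree.
For SVM/MLP a permutation-sampling Shapley estimator is used (fixed seed,
≥ 2,048 evaluations per row); both estimators satisfy local accuracy —
attributions plus the per-row base value reproduce the model output — to
numerical precision, which the tests assert at 1e-6. Importance is
summarised as the mean absolute attribution per class and feature, and
features are ranked by the sum over classes.

Calibration fits per-class one-vs-rest monotone maps from raw scores to
probabilities — Platt's logistic fit or isotonic regression — on
out-of-fold predictions obtained by refitting the model on group-aware
folds of the training partition (the holdout never touches calibration),
then renormalises to sum to 1. Agreement is scored by multiclass Brier
(sum-over-classes quadratic form, so a 5-class uniform prediction scores
0.8) and log loss with probabilities floored at 1e-15. Isotonic steps are
linearly interpolated between observed scores and clamped outside the
observed range; a class with fewer than two distinct scores keeps the
identity map.

## Numerical and design choices

* Simulation ages use a 213/761-day approximation of the 7/25-month
  boundaries; extraction always uses exact calendar-month anniversaries.
* Zero-denominator ratios are 0 everywhere, matching the many published
  medians of 0.00 and keeping the feature space complete.
* Antibiotic ratios are clipped to `[0, 1]` (the published table contains
  an IQR bound above 1 for one of them, impossible for a proportion; the
  stated definition is kept and the anomaly ignored).
* `exit_mode = death` is representable and simulated but feeds no feature,
  mirroring the registers' ambiguity about non-slaughter deaths.
* Mixed farms (`inject_mixed_farm()`) blend two profiles' composition,
  movement and prescription behaviour with a weight; weight 1 or 0
  reproduces the pure profile in law. They are for robustness
  experiments only and never enter the default benchmark.
* Problem sizes: the shipped tests simulate 500 farm-years per type for
  calibration recovery and the full ~1,850-observation benchmark for
  model performance; the analysis scripts use the same benchmark with
  B = 50 bootstrap replicates by default.

## Known limitations

* The calibration file targets the published medians/IQRs; joint
  dependence between features beyond what the event model induces (e.g.
  breed–milk correlations within mixed herds) is not separately
  calibrated.
* The simulator's class signal is cleaner than reality; holdout accuracy
  on simulated data should be read as an upper bound and a correctness
  check, not a forecast for real registries.
* SMOTE operates on raw feature scales; with features on [0,1] and log
  degrees this is adequate, but heavily skewed custom features would
  warrant scaling first.
* The bootstrap treats the holdout as fixed and quantifies training
  variability only, as in the reference procedure.
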