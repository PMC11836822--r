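# cattletype

Classification of cattle farms into their predominant production type —
**calf fattening, dairy, cattle fattening, rearing, or suckler cow** —
from the event streams national registries already collect: per-animal
identification and movement records, bulk-milk quality tests, and
veterinary antibiotic prescriptions. Knowing a farm's production type is
what lets veterinary services target disease surveillance and compare
antibiotic use fairly; registries typically record only "milk" vs
"non-milk".

The package is aimed at veterinary epidemiologists and surveillance
analysts. It provides, as one tested pipeline:

* an **event-level simulator** of the five production types (herd
  demography, movements, births, slaughter, milk testing, prescriptions),
  calibrated so that features extracted from simulations reproduce
  published per-type summary statistics — so every downstream stage can
  be developed and benchmarked without access to confidential registry
  data;
* **feature engineering**: eligibility filtering (≥ 10 cattle stays per
  year, standard holdings only) and 24 farm-year features built on exact
  animal-day accounting, where an animal's age class (calf 0–6, young
  7–24, adult ≥ 25 completed months) switches on the monthly anniversary
  of its birth date and presence is counted over half-open `[entry,
  exit)` intervals — e.g.

  `pFemaleYoung = FemaleYoungDays / TotalAnimalDays`,
  `pBirths = Births / TotalHerdSize`,
  `inDegree = log(1 + #origin farms)`;

* **models**: stratified group 70/30 split (no farm on both sides),
  group-aware 10-fold cross-validated hyperparameter search optimising
  macro F1, for a probability random forest, an RBF SVM and a multi-layer
  perceptron, plus a one-vs-rest random forest stage with SMOTE
  up-sampling;
* **evaluation**: one-vs-rest precision/sensitivity/specificity/F1 with
  `F1 = TP / (TP + (FP + FN)/2)`, balanced accuracy as macro recall, and
  grouped-bootstrap 95% confidence intervals (farms resampled, model
  refit, untouched holdout);
* **interpretation & calibration**: exact path-dependent TreeSHAP (C++)
  for the forest with a permutation-sampling Shapley fallback for the
  other families, and Platt-sigmoid / isotonic probability calibration
  scored by multiclass Brier and log loss.

## Worked example

```r
library(cattletype)

# simulate a small labeled benchmark: ~120 farms, two years
cfg <- benchmark_config(seed = 42, years = 2020:2021, scale = 0.2)
sim <- simulate_dataset(cfg)
sim$registry
#> <linked_registry>
#>   animals          19484 rows
#>   stays            19484 rows
#>   calvings          4915 rows
#>   milk_tests         566 rows
#>   prescriptions      737 rows
#>   farms              124 rows

# eligibility filter + 24-feature extraction + extreme-value exclusion
fx <- build_dataset(sim$registry, sim$labels, 2020:2021)
fx[1:3, .(farm_id, year, hasMilk, pFemaleAdults, pBirths, inDegree,
          production_type)]
#>    farm_id  year hasMilk pFemaleAdults     pBirths inDegree production_type
#> 1: CF00001  2020       0    0.05832312 0.000000000 4.127134  calf_fattening
#> 2: CF00002  2020       0    0.01995952 0.000000000 4.615121  calf_fattening
#> 3: CF00003  2020       0    0.02893662 0.005154639 3.871201  calf_fattening

# grouped 70/30 split, tuned random forest, holdout evaluation
sp <- stratified_group_split(fx, split_spec(seed = 42))
rf <- tune_and_train(sp$train, model_spec("random_forest", n_random = 4),
                     split_spec(n_folds = 5, seed = 42), seed = 42)
evaluate_model(rf, sp$holdout)
#> <evaluation_report>
#>   n=66 accuracy=1.000 balanced_accuracy=1.000 precision=1.000
#>   sensitivity=1.000 F1=1.000

# per-class Shapley attribution of the fitted forest
shap_importance(rf, sp$holdout, background = sp$train)
#> <shap_summary> top features by summed mean |SHAP|:
#>   pCalvedAnimals         0.2322
#>   pBirths                0.1776
#>   outDegree              0.1731
#>   pBeefBreed             0.1465
#>   hasMilk                0.1380
#>   ...
```

The first rows are calf-fattening farm-years and read exactly as a
practitioner would expect: no milk tests, almost no adult-female days,
essentially no births, and a high in-degree (`log(1 + k)` of roughly
50–100 source farms). On this small, well-separated benchmark the tuned
forest classifies the holdout perfectly; calving- and birth-related
features together with the milk indicator dominate the attribution,
mirroring what separates dairy and suckler herds from the fattening and
rearing types.

The complete analysis — simulation of the full 618-farm benchmark,
feature extraction, PCA overview, training and bootstrap evaluation of
all three families, SHAP summaries, calibration comparison and the
per-farm classification report — is organised as numbered drivers in
`analysis/01_simulate.R` … `analysis/06_classify.R`, which write their
tables under `results/`. The methods vignette
(`vignettes/cattle-farm-classification.Rmd`) documents the model,
conventions and design decisions.

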