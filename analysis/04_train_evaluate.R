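#!/usr/bin/env Rscript
# Trains the three classifier families on a 70/30 stratified group split
# with group 10-fold cross-validated hyperparameter search, evaluates on
# the holdout and attaches grouped-bootstrap 95% confidence intervals to
# the overall metrics of each model. B is kept moderate so the script
# finishes in minutes; raise it for tighter intervals.

suppressMessages(library(cattletype))
suppressMessages(library(data.table))

seed <- 1L
B <- 50L

fx <- fread("scratch/features.csv")
sp <- stratified_group_split(fx, split_spec(train_fraction = 0.7,
                                            n_folds = 10, seed = seed))
cat("Split:", nrow(sp$train), "training /", nrow(sp$holdout),
    "holdout observations;", length(sp$train_groups), "/",
    length(sp$holdout_groups), "farms.\n")
fwrite(rbind(data.table(farm_id = sp$train_groups, partition = "train"),
             data.table(farm_id = sp$holdout_groups, partition = "holdout")),
       "results/split_manifest.csv")

rows <- list()
models <- list()
for (fam in c("random_forest", "svm", "mlp")) {
  cat("\n==", fam, "==\n")
  model <- tune_and_train(sp$train, model_spec(fam, n_random = 6),
                          split_spec(n_folds = 10, seed = seed),
                          seed = seed)
  cat("  chosen:", paste(names(model$hyper), unlist(model$hyper),
                         sep = "=", collapse = " "), "\n")
  rep <- evaluate_model(model, sp$holdout)
  bs <- bootstrap_ci(sp$train, sp$holdout, fam, model$hyper, B = B,
                     seed = seed)
  fmt <- function(m) sprintf("%.3f (%.3f, %.3f)", rep[[m]],
                             bs$ci[[m]][1], bs$ci[[m]][2])
  cat(sprintf("  accuracy %s | balanced acc %s | F1 %s\n",
              fmt("accuracy"), fmt("balanced_accuracy"), fmt("macro_F1")))
  rows[[fam]] <- data.table(
    model = fam,
    accuracy = rep$accuracy,
    accuracy_lo = bs$ci$accuracy[1], accuracy_hi = bs$ci$accuracy[2],
    balanced_accuracy = rep$balanced_accuracy,
    balanced_lo = bs$ci$balanced_accuracy[1],
    balanced_hi = bs$ci$balanced_accuracy[2],
    precision = rep$macro_precision,
    precision_lo = bs$ci$macro_precision[1],
    precision_hi = bs$ci$macro_precision[2],
    sensitivity = rep$macro_sensitivity,
    sensitivity_lo = bs$ci$macro_sensitivity[1],
    sensitivity_hi = bs$ci$macro_sensitivity[2],
    F1 = rep$macro_F1, F1_lo = bs$ci$macro_F1[1], F1_hi = bs$ci$macro_F1[2],
    B = B)
  models[[fam]] <- model
  if (fam == "random_forest") {
    fwrite(as.data.table(rep$confusion, keep.rownames = "true"),
           "results/confusion_rf.csv")
    fwrite(rep$per_class, "results/per_class_rf.csv")
  }
}
fwrite(rbindlist(rows), "results/model_scores.csv")
saveRDS(models, "scratch/models.rds")
saveRDS(sp, "scratch/split.rds")
cat("\nModel comparison written to results/model_scores.csv\n")
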