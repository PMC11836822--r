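# Evaluation: confusion matrix, one-vs-rest classification metrics with
# macro averaging, grouped bootstrap confidence intervals, and a PCA
# overview of the numerical features.
#
# Multiclass balanced accuracy is defined as the unweighted mean of the
# per-class sensitivities (macro recall); per-class metrics additionally
# report specificity and the balanced accuracy of the one-vs-rest binary
# problem.

#' Confusion matrix
#'
#' @param y_true,y_pred Label vectors (values from [production_types()]).
#' @param classes Class order (default the fixed order).
#' @return Integer matrix, rows = true class, columns = predicted class.
#' @export
confusion <- function(y_true, y_pred, classes = production_types()) {
  stopifnot(length(y_true) == length(y_pred))
  bad <- setdiff(unique(c(y_true, y_pred)), classes)
  if (length(bad)) {
    stop("confusion: unknown label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  tab <- table(factor(y_true, classes), factor(y_pred, classes))
  m <- matrix(as.integer(tab), nrow = length(classes),
              dimnames = list(true = classes, predicted = classes))
  m
}

#' Classification metrics from a confusion matrix
#'
#' Computes overall accuracy, per-class one-vs-rest precision, sensitivity
#' (recall), specificity and F1 (`TP / (TP + (FP + FN) / 2)`), and their
#' unweighted macro averages. Balanced accuracy is the macro mean of the
#' per-class sensitivities. Classes absent from the true labels yield
#' undefined (NA) per-class metrics and are excluded from the macro means
#' with a warning.
#'
#' @param cm Confusion matrix from [confusion()].
#' @return An `evaluation_report` list with overall and per-class metrics.
#' @export
metrics <- function(cm) {
  stopifnot(is.matrix(cm), nrow(cm) == ncol(cm), sum(cm) > 0)
  classes <- rownames(cm)
  total <- sum(cm)
  tp <- diag(cm)
  fn <- rowSums(cm) - tp
  fp <- colSums(cm) - tp
  tn <- total - tp - fn - fp
  present <- rowSums(cm) > 0
  if (any(!present)) {
    warning("metrics: class(es) absent from true labels: ",
            paste(classes[!present], collapse = ", "),
            "; excluded from macro averages")
  }
  safe_div <- function(a, b) ifelse(b > 0, a / b, NA_real_)
  precision <- safe_div(tp, tp + fp)
  sensitivity <- safe_div(tp, tp + fn)
  specificity <- safe_div(tn, tn + fp)
  f1 <- safe_div(tp, tp + (fp + fn) / 2)
  per_class <- data.table(
    class = classes,
    accuracy = sensitivity,           # label-specific accuracy = class recall
    precision = precision,
    sensitivity = sensitivity,
    specificity = specificity,
    balanced_accuracy = (sensitivity + specificity) / 2,
    F1 = f1,
    support = rowSums(cm))
  per_class[!present, c("accuracy", "precision", "sensitivity",
                        "specificity", "balanced_accuracy", "F1") := NA_real_]
  mac <- function(v) mean(v[present], na.rm = TRUE)
  structure(list(
    accuracy = sum(tp) / total,
    balanced_accuracy = mac(sensitivity),
    macro_precision = mac(precision),
    macro_sensitivity = mac(sensitivity),
    macro_F1 = mac(f1),
    per_class = per_class,
    confusion = cm,
    n = total), class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("<evaluation_report>\n")
  cat(sprintf(
    "  n=%d accuracy=%.3f balanced_accuracy=%.3f precision=%.3f sensitivity=%.3f F1=%.3f\n",
    x$n, x$accuracy, x$balanced_accuracy, x$macro_precision,
    x$macro_sensitivity, x$macro_F1))
  if (!is.null(x$ci)) {
    for (m in names(x$ci)) {
      cat(sprintf("  %s 95%% CI: (%.3f, %.3f)\n", m, x$ci[[m]][1],
                  x$ci[[m]][2]))
    }
  }
  invisible(x)
}

overall_metric_vector <- function(rep) {
  c(accuracy = rep$accuracy, balanced_accuracy = rep$balanced_accuracy,
    macro_precision = rep$macro_precision,
    macro_sensitivity = rep$macro_sensitivity, macro_F1 = rep$macro_F1)
}

#' Evaluate a model on holdout rows
#'
#' @param model A fitted classifier.
#' @param holdout Holdout feature rows with `production_type`.
#' @return An `evaluation_report`.
#' @export
evaluate_model <- function(model, holdout) {
  p <- predict_proba(model, holdout)
  metrics(confusion(holdout$production_type, predict_label(p)))
}

#' Bootstrap confidence intervals for the overall metrics
#'
#' For each replicate, whole farms (groups) of the training partition are
#' resampled with replacement, the model is refit with the already-chosen
#' hyperparameters (no re-search) and evaluated on the untouched holdout;
#' the CI is the 2.5/97.5 percentile of the replicate metrics.
#'
#' @param train,holdout Feature partitions.
#' @param family Model family.
#' @param hyper Chosen hyperparameters.
#' @param B Number of bootstrap replicates (default 1000).
#' @param seed Integer seed.
#' @return List with `ci` (per-metric lower/upper), `replicates` (B x 5
#'   matrix).
#' @export
bootstrap_ci <- function(train, holdout, family, hyper = list(), B = 1000L,
                         seed = 1L) {
  if (B < 1) stop("bootstrap_ci: B must be >= 1", call. = FALSE)
  train <- as.data.table(train)
  groups <- unique(train$farm_id)
  reps <- matrix(NA_real_, nrow = B, ncol = 5,
                 dimnames = list(NULL, c("accuracy", "balanced_accuracy",
                                         "macro_precision",
                                         "macro_sensitivity", "macro_F1")))
  for (b in seq_len(B)) {
    set.seed((seed + 7919L * b) %% 2147483647L)
    gs <- sample(groups, length(groups), replace = TRUE)
    idx <- unlist(lapply(gs, function(g) which(train$farm_id == g)))
    boot <- train[idx]
    if (length(unique(boot$production_type)) < 2L) next
    m <- train_model(boot, family, hyper, seed = seed + b)
    rep_b <- suppressWarnings(evaluate_model(m, holdout))
    reps[b, ] <- overall_metric_vector(rep_b)
  }
  ci <- apply(reps, 2, quantile, probs = c(0.025, 0.975), na.rm = TRUE)
  list(ci = as.list(as.data.frame(ci)), replicates = reps)
}

#' PCA overview of the numerical features
#'
#' Centers and scales the 23 numerical features (the binary milk indicator
#' is excluded) and computes principal components; zero-variance features
#' are dropped with a warning. Loadings are sign-fixed so that each
#' column's largest-magnitude entry is positive.
#'
#' @param rows Feature rows.
#' @param n_components Number of components to keep (default all).
#' @return A `pca_overview` list: `variance_fraction`, `loadings`,
#'   `scores`, `labels` (when `production_type` present), `dropped`.
#' @export
pca_overview <- function(rows, n_components = NULL) {
  dt <- as.data.table(rows)
  feats <- intersect(feature_names(numeric_only = TRUE), names(dt))
  x <- as.matrix(dt[, feats, with = FALSE])
  stopifnot(nrow(x) >= 2)
  v <- apply(x, 2, var)
  dropped <- colnames(x)[v == 0 | !is.finite(v)]
  if (length(dropped)) {
    warning("pca_overview: dropping zero-variance feature(s): ",
            paste(dropped, collapse = ", "))
    x <- x[, setdiff(colnames(x), dropped), drop = FALSE]
  }
  pc <- prcomp(x, center = TRUE, scale. = TRUE)
  if (!is.null(n_components)) {
    k <- min(n_components, ncol(pc$rotation))
    pc$rotation <- pc$rotation[, seq_len(k), drop = FALSE]
    pc$x <- pc$x[, seq_len(k), drop = FALSE]
    pc$sdev_kept <- pc$sdev[seq_len(k)]
  }
  # sign convention: largest |loading| in each component is positive
  for (j in seq_len(ncol(pc$rotation))) {
    i <- which.max(abs(pc$rotation[, j]))
    if (pc$rotation[i, j] < 0) {
      pc$rotation[, j] <- -pc$rotation[, j]
      pc$x[, j] <- -pc$x[, j]
    }
  }
  structure(list(
    variance_fraction = pc$sdev^2 / sum(pc$sdev^2),
    loadings = pc$rotation,
    scores = pc$x,
    labels = if ("production_type" %in% names(dt)) dt$production_type else NULL,
    dropped = dropped), class = "pca_overview")
}
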