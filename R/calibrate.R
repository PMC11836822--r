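# Probability calibration: per-class one-vs-rest monotone mappings of raw
# classifier scores to probabilities, fitted on out-of-fold predictions of
# the training partition (fit-then-calibrate on held-out group folds), and
# agreement metrics (multiclass Brier score and log loss).

platt_fit <- function(score, y) {
  fit <- suppressWarnings(glm(y ~ score, family = binomial()))
  co <- coef(fit)
  function(s) 1 / (1 + exp(-(co[1] + co[2] * s)))
}

isotonic_fit <- function(score, y) {
  o <- order(score)
  ir <- isoreg(score[o], y[o])
  xs <- ir$x
  ys <- ir$yf
  agg <- tapply(ys, xs, mean)
  ux <- as.numeric(names(agg))
  uy <- as.numeric(agg)
  if (length(ux) == 1L) return(function(s) rep(uy, length(s)))
  function(s) approx(ux, uy, xout = s, rule = 2, ties = "ordered")$y
}

#' Calibrate a classifier
#'
#' Fits per-class one-vs-rest monotone mappings from raw scores to
#' probabilities — a logistic (Platt sigmoid) fit or an isotonic step
#' regression — on out-of-fold predictions obtained by refitting the model
#' (with its chosen hyperparameters) on group-aware folds of the training
#' rows, then renormalises mapped scores to sum to 1. Classes with fewer
#' than 2 distinct raw scores keep the identity mapping with a warning.
#'
#' @param model A fitted `farm_classifier`.
#' @param train Training rows (must be disjoint from any holdout used for
#'   evaluation).
#' @param method `"sigmoid"` or `"isotonic"`.
#' @param n_folds Internal folds for out-of-fold scores (default 5).
#' @param seed Integer seed.
#' @return A `calibrated_classifier` wrapping the base model.
#' @export
calibrate <- function(model, train, method = c("sigmoid", "isotonic"),
                      n_folds = 5L, seed = 1L) {
  method <- match.arg(method)
  stopifnot(inherits(model, "farm_classifier"))
  train <- as.data.table(train)
  folds <- group_folds(train, n_folds = n_folds, seed = seed)
  oof <- matrix(NA_real_, nrow(train), length(model$classes),
                dimnames = list(NULL, model$classes))
  for (f in sort(unique(folds))) {
    m <- train_model(train[folds != f], model$family, model$hyper,
                     seed = seed + f)
    oof[folds == f, ] <- predict_proba(m, train[folds == f])
  }
  maps <- list()
  for (cls in model$classes) {
    s <- oof[, cls]
    y <- as.numeric(train$production_type == cls)
    if (length(unique(s)) < 2L) {
      warning("calibrate: fewer than 2 distinct scores for class ", cls,
              "; keeping identity mapping")
      maps[[cls]] <- identity
    } else {
      maps[[cls]] <- if (method == "sigmoid") platt_fit(s, y)
                     else isotonic_fit(s, y)
    }
  }
  structure(list(base = model, method = method, maps = maps,
                 classes = model$classes), class = "calibrated_classifier")
}

#' @export
predict_proba.calibrated_classifier <- function(model, rows) {
  raw <- predict_proba(model$base, rows)
  out <- raw
  for (cls in model$classes) {
    out[, cls] <- pmin(pmax(model$maps[[cls]](raw[, cls]), 0), 1)
  }
  rs <- rowSums(out)
  zero <- rs <= 1e-12
  if (any(zero)) out[zero, ] <- 1 / ncol(out)   # fully flattened row
  out[!zero, ] <- out[!zero, , drop = FALSE] / rs[!zero]
  out
}

#' @export
print.calibrated_classifier <- function(x, ...) {
  cat(sprintf("<calibrated_classifier: %s + %s calibration>\n",
              x$base$family, x$method))
  invisible(x)
}

#' Probability-quality metrics
#'
#' Multiclass Brier score (mean over rows of the summed squared
#' differences between the one-hot outcome and the predicted probability
#' vector) and log loss (mean negative log predicted probability of the
#' true class, probabilities floored at 1e-15), together with the
#' classification metrics of the argmax predictions.
#'
#' @param y_true True labels.
#' @param proba Probability matrix with class columns summing to 1.
#' @return A `calibration_report` list: `brier`, `log_loss`, `accuracy`,
#'   `precision`, `recall`, `F1`.
#' @export
calibration_metrics <- function(y_true, proba) {
  stopifnot(length(y_true) == nrow(proba))
  classes <- colnames(proba)
  onehot <- outer(y_true, classes, `==`) * 1
  brier <- mean(rowSums((onehot - proba)^2))
  p_true <- proba[cbind(seq_along(y_true), match(y_true, classes))]
  log_loss <- mean(-log(pmax(p_true, 1e-15)))
  rep <- suppressWarnings(metrics(confusion(y_true, predict_label(proba),
                                            classes)))
  structure(list(brier = brier, log_loss = log_loss,
                 accuracy = rep$accuracy,
                 precision = rep$macro_precision,
                 recall = rep$macro_sensitivity,
                 F1 = rep$macro_F1), class = "calibration_report")
}

#' @export
print.calibration_report <- function(x, ...) {
  cat(sprintf(
    "<calibration_report> brier=%.4f log_loss=%.4f accuracy=%.3f precision=%.3f recall=%.3f F1=%.3f\n",
    x$brier, x$log_loss, x$accuracy, x$precision, x$recall, x$F1))
  invisible(x)
}
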