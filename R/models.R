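# Classifier training: grouped splitting, group-aware cross-validated
# hyperparameter search (random stage then coordinate grid refinement),
# and the three model families (random forest, RBF-kernel SVM, single
# hidden layer perceptron). All repeated observations of one farm share a
# group key and never cross a partition or fold boundary.

#' Split specification
#'
#' @param train_fraction Fraction of observations targeted for the training
#'   partition (default 0.7).
#' @param n_folds Number of cross-validation folds (default 10).
#' @param seed Integer seed.
#' @return A `split_spec` object.
#' @export
split_spec <- function(train_fraction = 0.7, n_folds = 10L, seed = 1L) {
  stopifnot(train_fraction > 0, train_fraction < 1, n_folds >= 2)
  structure(list(train_fraction = train_fraction,
                 n_folds = as.integer(n_folds), seed = as.integer(seed)),
            class = "split_spec")
}

#' Model specification
#'
#' @param family One of `"random_forest"`, `"svm"`, `"mlp"`.
#' @param search_space Named list of candidate hyperparameter values; when
#'   `NULL` the default search space for the family
#'   ([default_search_space()]) is used. An empty list trains with family
#'   defaults.
#' @param n_random Number of candidates drawn in the initial random-search
#'   stage before grid refinement (default 8).
#' @return A `model_spec` object.
#' @export
model_spec <- function(family = c("random_forest", "svm", "mlp"),
                       search_space = NULL, n_random = 8L) {
  family <- match.arg(family)
  if (is.null(search_space)) search_space <- default_search_space(family)
  structure(list(family = family, search_space = search_space,
                 tuning = "random_then_grid", scoring = "macro_F1",
                 n_random = as.integer(n_random)),
            class = "model_spec")
}

#' Default hyperparameter search spaces
#'
#' Conventional ranges for the three families, read from the configuration
#' file shipped with the package (`inst/extdata/default_search.yaml`).
#'
#' @param family Model family.
#' @return Named list of candidate values.
#' @export
default_search_space <- function(family) {
  path <- system.file("extdata", "default_search.yaml",
                      package = "cattletype", mustWork = TRUE)
  sp <- yaml::read_yaml(path)
  if (!family %in% names(sp)) stop("no search space for family ", family)
  sp[[family]]
}

#' Stratified group split
#'
#' Partitions a labeled feature matrix into training and holdout rows such
#' that no farm (group) appears in both partitions and the per-class
#' observation shares of each partition stay close to the full matrix.
#'
#' @param matrix Feature matrix with `farm_id` and `production_type`.
#' @param spec A [split_spec()].
#' @return List with `train` and `holdout` (data.tables) and the group id
#'   vectors `train_groups`, `holdout_groups`.
#' @export
stratified_group_split <- function(matrix, spec = split_spec()) {
  dt <- as.data.table(matrix)
  stopifnot(all(c("farm_id", "production_type") %in% names(dt)))
  grp <- dt[, .(n = .N), by = .(farm_id, production_type)]
  cls_groups <- grp[, .(g = .N), by = production_type]
  few <- cls_groups[g < 2]
  if (nrow(few)) {
    stop("stratified_group_split: class present in fewer than 2 groups: ",
         paste(few$production_type, collapse = ", "), call. = FALSE)
  }
  set.seed(spec$seed)
  holdout_groups <- character()
  carry <- 0   # rounding deficit carried across classes
  for (cls in sort(unique(grp$production_type))) {
    g <- grp[production_type == cls]
    g <- g[sample(.N)]
    target <- (1 - spec$train_fraction) * sum(g$n) + carry
    csum <- cumsum(g$n)
    take <- which(csum <= target + 1e-9)
    if (!length(take) && g$n[1] < 2 * target) take <- 1L
    taken <- if (length(take)) csum[max(take)] else 0
    carry <- target - taken
    holdout_groups <- c(holdout_groups, g$farm_id[take])
  }
  hold <- dt[farm_id %chin% holdout_groups]
  train <- dt[!(farm_id %chin% holdout_groups)]
  list(train = train, holdout = hold,
       train_groups = sort(unique(train$farm_id)),
       holdout_groups = sort(unique(hold$farm_id)))
}

#' Group-aware stratified fold assignment
#'
#' Assigns every group (farm) to one of `n_folds` folds, stratified by
#' class and balanced by observation count, so that no farm spans folds.
#'
#' @param matrix Feature matrix with `farm_id` and `production_type`.
#' @param n_folds Number of folds.
#' @param seed Integer seed.
#' @return Integer vector of fold ids, one per row of `matrix`.
#' @export
group_folds <- function(matrix, n_folds = 10L, seed = 1L) {
  dt <- as.data.table(matrix)
  grp <- dt[, .(n = .N), by = .(farm_id, production_type)]
  set.seed(seed)
  fold_of <- setNames(integer(nrow(grp)), grp$farm_id)
  fold_load <- integer(n_folds)
  for (cls in sort(unique(grp$production_type))) {
    g <- grp[production_type == cls]
    g <- g[sample(.N)][order(-n)]
    load_cls <- integer(n_folds)
    for (i in seq_len(nrow(g))) {
      f <- which.min(load_cls * n_folds + fold_load)  # balance within class first
      fold_of[g$farm_id[i]] <- f
      load_cls[f] <- load_cls[f] + g$n[i]
      fold_load[f] <- fold_load[f] + g$n[i]
    }
  }
  unname(fold_of[dt$farm_id])
}

feature_matrix_of <- function(rows) {
  feats <- feature_names()
  missing <- setdiff(feats, names(rows))
  if (length(missing)) {
    stop("missing feature column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  m <- as.matrix(as.data.table(rows)[, feats, with = FALSE])
  storage.mode(m) <- "double"
  m
}

fit_scaler <- function(x) {
  ctr <- colMeans(x)
  scl <- apply(x, 2, sd)
  scl[scl == 0 | !is.finite(scl)] <- 1
  list(center = ctr, scale = scl)
}

apply_scaler <- function(x, scaler) {
  if (is.null(scaler)) return(x)
  sweep(sweep(x, 2, scaler$center, "-"), 2, scaler$scale, "/")
}

# fit one family with given hyperparameters; x is the raw feature matrix
fit_family <- function(family, x, y, hyper, seed) {
  y <- factor(y, levels = production_types())
  if (family == "random_forest") {
    fit <- ranger::ranger(
      x = x, y = y, probability = TRUE,
      num.trees = hyper$num_trees %||% 500L,
      mtry = min(ncol(x), hyper$mtry %||% floor(sqrt(ncol(x)))),
      min.node.size = hyper$min_node_size %||% 1L,
      max.depth = hyper$max_depth %||% 0L,
      seed = seed, num.threads = 1L)
    list(fit = fit, scaler = NULL)
  } else if (family == "svm") {
    scaler <- fit_scaler(x)
    set.seed(seed)
    fit <- e1071::svm(x = apply_scaler(x, scaler), y = y, kernel = "radial",
                      cost = hyper$cost %||% 1,
                      gamma = hyper$gamma %||% (1 / ncol(x)),
                      probability = TRUE)
    list(fit = fit, scaler = scaler)
  } else if (family == "mlp") {
    scaler <- fit_scaler(x)
    set.seed(seed)
    ycls <- nnet::class.ind(y)
    fit <- nnet::nnet(x = apply_scaler(x, scaler), y = ycls,
                      size = hyper$size %||% 32L,
                      decay = hyper$decay %||% 1e-3,
                      softmax = TRUE, maxit = hyper$maxit %||% 300L,
                      MaxNWts = 20000L, trace = FALSE)
    list(fit = fit, scaler = scaler)
  } else stop("unknown family: ", family)
}

predict_family <- function(family, fitted, x) {
  xs <- apply_scaler(x, fitted$scaler)
  classes <- production_types()
  if (family == "random_forest") {
    p <- predict(fitted$fit, data = xs, num.threads = 1L)$predictions
  } else if (family == "svm") {
    pr <- predict(fitted$fit, xs, probability = TRUE)
    p <- attr(pr, "probabilities")
  } else {
    p <- predict(fitted$fit, xs)
    if (is.null(dim(p))) p <- matrix(p, nrow = nrow(xs))
  }
  p <- p[, classes, drop = FALSE]
  p <- p / pmax(rowSums(p), 1e-12)
  dimnames(p) <- list(NULL, classes)
  p
}

`%||%` <- function(a, b) if (is.null(a)) b else a

macro_f1_of <- function(y_true, y_pred) {
  cm <- confusion(y_true, y_pred)
  suppressWarnings(metrics(cm)$macro_F1)
}

cv_score_candidate <- function(family, hyper, train, folds, seed) {
  x <- feature_matrix_of(train)
  y <- train$production_type
  scores <- numeric(max(folds))
  for (f in sort(unique(folds))) {
    tr <- folds != f
    fitted <- fit_family(family, x[tr, , drop = FALSE], y[tr], hyper,
                         seed = seed + f)
    p <- predict_family(family, fitted, x[!tr, , drop = FALSE])
    pred <- colnames(p)[max.col(p, ties.method = "first")]
    scores[f] <- macro_f1_of(y[!tr], pred)
  }
  scores
}

#' Tune and train a classifier with group-aware cross-validation
#'
#' Hyperparameters are selected by macro-averaged F1 over group-aware
#' folds: an initial random draw of candidates from the search space is
#' followed by a coordinate grid refinement around the best candidate
#' (each hyperparameter swept over its full candidate list with the others
#' held at the incumbent). The final model is refit on all training rows
#' with the chosen hyperparameters.
#'
#' @param train Training rows (feature matrix with `farm_id`,
#'   `production_type`).
#' @param spec A [model_spec()].
#' @param split A [split_spec()] providing `n_folds`.
#' @param seed Integer seed.
#' @return A `farm_classifier` object.
#' @export
tune_and_train <- function(train, spec = model_spec("random_forest"),
                           split = split_spec(), seed = 1L) {
  train <- as.data.table(train)
  folds <- group_folds(train, n_folds = split$n_folds, seed = seed)
  space <- spec$search_space
  if (length(space) == 0L) {
    warning("empty search space: training ", spec$family,
            " with family defaults")
    candidates <- list(list())
  } else {
    grid <- expand.grid(space, stringsAsFactors = FALSE,
                        KEEP.OUT.ATTRS = FALSE)
    set.seed(seed)
    n_rand <- min(spec$n_random, nrow(grid))
    cand_idx <- sort(sample.int(nrow(grid), n_rand))
    candidates <- lapply(cand_idx, function(i) as.list(grid[i, , drop = FALSE]))
  }
  eval_one <- function(h) mean(cv_score_candidate(spec$family, h, train,
                                                  folds, seed))
  scores <- vapply(candidates, eval_one, numeric(1))
  best <- candidates[[which.max(scores)]]
  if (length(space) > 0L) {
    # coordinate grid refinement around the random-stage incumbent
    refine <- list()
    for (hp in names(space)) {
      for (v in space[[hp]]) {
        cand <- best
        cand[[hp]] <- v
        if (!any(vapply(c(candidates, refine), identical, logical(1), cand))) {
          refine[[length(refine) + 1L]] <- cand
        }
      }
    }
    if (length(refine)) {
      r_scores <- vapply(refine, eval_one, numeric(1))
      candidates <- c(candidates, refine)
      scores <- c(scores, r_scores)
      best <- candidates[[which.max(scores)]]
    }
  }
  cv_scores <- cv_score_candidate(spec$family, best, train, folds, seed)
  x <- feature_matrix_of(train)
  fitted <- fit_family(spec$family, x, train$production_type, best,
                       seed = seed)
  structure(list(family = spec$family, fit = fitted$fit,
                 scaler = fitted$scaler, classes = production_types(),
                 hyper = best, cv_scores = cv_scores,
                 feature_names = feature_names(), seed = seed),
            class = "farm_classifier")
}

#' Train a classifier without tuning
#'
#' Fits one family on the given rows with fixed hyperparameters (used for
#' bootstrap refits and calibration folds).
#'
#' @param train Training rows.
#' @param family Model family.
#' @param hyper Named list of hyperparameters (possibly empty).
#' @param seed Integer seed.
#' @return A `farm_classifier`.
#' @export
train_model <- function(train, family, hyper = list(), seed = 1L) {
  train <- as.data.table(train)
  x <- feature_matrix_of(train)
  fitted <- fit_family(family, x, train$production_type, hyper, seed = seed)
  structure(list(family = family, fit = fitted$fit, scaler = fitted$scaler,
                 classes = production_types(), hyper = hyper,
                 cv_scores = NULL, feature_names = feature_names(),
                 seed = seed),
            class = "farm_classifier")
}

#' Class-probability predictions
#'
#' @param model A fitted classifier.
#' @param rows Feature rows (must contain all 24 feature columns).
#' @return Matrix of class probabilities (rows sum to 1), columns in the
#'   fixed class order.
#' @export
predict_proba <- function(model, rows) UseMethod("predict_proba")

#' @export
predict_proba.farm_classifier <- function(model, rows) {
  x <- feature_matrix_of(rows)
  predict_family(model$family, list(fit = model$fit, scaler = model$scaler), x)
}

#' Predicted labels from probabilities
#'
#' Argmax with ties broken by the fixed class order.
#'
#' @param proba Probability matrix with class columns.
#' @return Character vector of predicted production types.
#' @export
predict_label <- function(proba) {
  colnames(proba)[max.col(proba, ties.method = "first")]
}

#' @export
print.farm_classifier <- function(x, ...) {
  cat(sprintf("<farm_classifier: %s>\n", x$family))
  if (length(x$hyper)) {
    cat("  hyperparameters:",
        paste(sprintf("%s=%s", names(x$hyper), unlist(x$hyper)),
              collapse = " "), "\n")
  }
  if (!is.null(x$cv_scores)) {
    cat(sprintf("  CV macro-F1: %.3f (%d folds)\n", mean(x$cv_scores),
                length(x$cv_scores)))
  }
  invisible(x)
}

#' SMOTE synthetic minority over-sampling
#'
#' Generates synthetic minority-class rows by convex interpolation between
#' a random minority row and one of its `k` nearest minority neighbours.
#'
#' @param x Numeric matrix of minority-class rows.
#' @param n_new Number of synthetic rows to generate.
#' @param k Number of nearest neighbours (default 5; reduced with a warning
#'   when fewer rows are available).
#' @return Matrix with `n_new` synthetic rows.
#' @export
smote_sample <- function(x, n_new, k = 5L) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 2L) stop("smote_sample: need at least 2 rows", call. = FALSE)
  if (n < k + 1L) {
    warning(sprintf("smote_sample: reducing k from %d to %d", k, n - 1L))
    k <- n - 1L
  }
  d <- as.matrix(dist(x))
  diag(d) <- Inf
  nn <- t(apply(d, 1, function(r) order(r)[seq_len(k)]))
  i <- sample.int(n, n_new, replace = TRUE)
  j <- nn[cbind(i, sample.int(k, n_new, replace = TRUE))]
  u <- runif(n_new)
  x[i, , drop = FALSE] + u * (x[j, , drop = FALSE] - x[i, , drop = FALSE])
}

#' One-vs-rest random forests with SMOTE up-sampling
#'
#' For each production type, the positive class is synthetically
#' up-sampled to balance with SMOTE and a binary random forest is fitted.
#' This reproduces the two-class screening stage used to produce
#' preliminary farm tags; its outputs are never fed back into the main
#' multiclass training.
#'
#' @param matrix Labeled feature matrix.
#' @param seed Integer seed.
#' @param k SMOTE neighbourhood size.
#' @param num_trees Trees per binary forest.
#' @return Named list of per-class bundles (`fit`, `n_synthetic`,
#'   `class_counts`).
#' @export
train_ovr_smote <- function(matrix, seed = 1L, k = 5L, num_trees = 300L) {
  dt <- as.data.table(matrix)
  x <- feature_matrix_of(dt)
  set.seed(seed)
  out <- list()
  for (cls in production_types()) {
    pos <- dt$production_type == cls
    n_pos <- sum(pos); n_neg <- sum(!pos)
    xs <- x
    ys <- ifelse(pos, "positive", "rest")
    n_new <- 0L
    if (n_pos < n_neg && n_pos >= 2L) {
      n_new <- n_neg - n_pos
      synth <- smote_sample(x[pos, , drop = FALSE], n_new, k = k)
      xs <- rbind(x, synth)
      ys <- c(ys, rep("positive", n_new))
    }
    fit <- ranger::ranger(x = xs, y = factor(ys, c("positive", "rest")),
                          probability = TRUE, num.trees = num_trees,
                          seed = seed, num.threads = 1L)
    out[[cls]] <- list(fit = fit, n_synthetic = n_new,
                       class_counts = table(ys))
  }
  out
}
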