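# Shapley-value feature attribution.
#
# Random forests are explained with the exact path-dependent TreeSHAP
# algorithm (implemented in src/treeshap.cpp) over the fitted trees, with
# node covers recomputed by routing the supplied background data through
# every tree. Other families are explained with a permutation-sampling
# Shapley estimator that preserves local accuracy exactly (for every
# sampled permutation the contributions telescope to the difference
# between the prediction and the background mean).

# Extract one ranger tree as flat arrays, with covers computed from the
# background matrix and per-class leaf values.
ranger_tree_arrays <- function(rf, tree, xb, classes) {
  ti <- ranger::treeInfo(rf, tree)
  nn <- nrow(ti)
  left <- ifelse(is.na(ti$leftChild), -1L, ti$leftChild)
  right <- ifelse(is.na(ti$rightChild), -1L, ti$rightChild)
  feat <- ifelse(ti$terminal, -1L, ti$splitvarID)  # 0-based var index
  thr <- ifelse(ti$terminal, 0, ti$splitval)
  # route the background through the tree to obtain node covers
  cover <- numeric(nn)
  node_rows <- vector("list", nn)
  node_rows[[1]] <- seq_len(nrow(xb))
  for (i in seq_len(nn)) {
    rows <- node_rows[[i]]
    cover[i] <- length(rows)
    if (feat[i] >= 0L && length(rows)) {
      goleft <- xb[rows, feat[i] + 1L] <= thr[i]
      node_rows[[left[i] + 1L]] <- c(node_rows[[left[i] + 1L]], rows[goleft])
      node_rows[[right[i] + 1L]] <- c(node_rows[[right[i] + 1L]],
                                      rows[!goleft])
    }
  }
  # nodes unreached by this background get a nominal cover so that cover
  # ratios stay finite
  cover[cover == 0] <- 1e-8
  vals <- as.matrix(ti[, paste0("pred.", classes), drop = FALSE])
  vals[is.na(vals)] <- 0
  list(left = as.integer(left), right = as.integer(right),
       feature = as.integer(feat), threshold = as.numeric(thr),
       cover = as.numeric(cover), values = vals)
}

shap_tree <- function(model, x, background) {
  rf <- model$fit
  classes <- model$classes
  xb <- background
  trees <- lapply(seq_len(rf$num.trees), ranger_tree_arrays, rf = rf,
                  xb = xb, classes = classes)
  p <- ncol(x)
  out <- array(0, dim = c(nrow(x), p, length(classes)),
               dimnames = list(NULL, colnames(x), classes))
  base <- numeric(length(classes))
  for (k in seq_along(classes)) {
    trees_k <- lapply(trees, function(tr) {
      tr$value <- tr$values[, k]
      tr
    })
    out[, , k] <- treeshap_cpp(trees_k, x)
    base[k] <- mean(vapply(trees_k, function(tr) {
      leaves <- tr$feature < 0L
      sum(tr$cover[leaves] * tr$value[leaves]) / tr$cover[1]
    }, numeric(1)))
  }
  base_m <- matrix(base, nrow(x), length(classes), byrow = TRUE,
                   dimnames = list(NULL, classes))
  list(shap = out, base = base_m)
}

shap_sampling <- function(model, x, background, n_samples = 2048L,
                          seed = 1L) {
  classes <- model$classes
  p <- ncol(x)
  n_perm <- max(2L, ceiling(n_samples / (p + 1L)))
  out <- array(0, dim = c(nrow(x), p, length(classes)),
               dimnames = list(NULL, colnames(x), classes))
  pred_fun <- function(m) {
    colnames(m) <- colnames(x)
    predict_family(model$family, list(fit = model$fit, scaler = model$scaler),
                   m)
  }
  base_acc <- matrix(0, nrow(x), length(classes))
  for (i in seq_len(nrow(x))) {
    set.seed((seed + 104729L * i) %% 2147483647L)
    bg_idx <- sample.int(nrow(background), n_perm, replace = TRUE)
    # build all hybrid instances for this row in one batch
    hyb <- matrix(0, n_perm * (p + 1L), p)
    orders <- matrix(0L, n_perm, p)
    for (r in seq_len(n_perm)) {
      ord <- sample.int(p)
      orders[r, ] <- ord
      cur <- background[bg_idx[r], ]
      hyb[(r - 1L) * (p + 1L) + 1L, ] <- cur
      for (s in seq_len(p)) {
        cur[ord[s]] <- x[i, ord[s]]
        hyb[(r - 1L) * (p + 1L) + 1L + s, ] <- cur
      }
    }
    pr <- pred_fun(hyb)
    for (r in seq_len(n_perm)) {
      off <- (r - 1L) * (p + 1L)
      d <- pr[off + 2L:(p + 1L), , drop = FALSE] -
        pr[off + 1L:p, , drop = FALSE]
      out[i, orders[r, ], ] <- out[i, orders[r, ], ] + d / n_perm
      base_acc[i, ] <- base_acc[i, ] + pr[off + 1L, ] / n_perm
    }
  }
  colnames(base_acc) <- classes
  list(shap = out, base = base_acc)
}

#' Shapley-value attributions for a classifier
#'
#' Returns per-row, per-class additive attributions satisfying local
#' accuracy: attributions plus the base value reproduce the model output
#' for that class. Random forests use the exact tree-path algorithm;
#' other families a permutation-sampling estimator with a fixed seed.
#'
#' @param model A `farm_classifier`.
#' @param rows Rows to explain.
#' @param background Background rows (defaults to `rows`) used for node
#'   covers / marginalisation.
#' @param n_samples Sampling budget per row for the non-tree estimator.
#' @param seed Integer seed (non-tree estimator only).
#' @return A `shap_values` list: `shap` (rows x features x classes array),
#'   `base` (rows x classes matrix of base values; identical rows for the
#'   tree backend), `pred` (model probabilities). For every row and class,
#'   `rowSums` of the attributions plus the base value equals the model
#'   output (local accuracy).
#' @export
shap_values <- function(model, rows, background = NULL, n_samples = 2048L,
                        seed = 1L) {
  stopifnot(inherits(model, "farm_classifier"))
  x <- feature_matrix_of(rows)
  xb <- if (is.null(background)) x else feature_matrix_of(background)
  res <- if (model$family == "random_forest") {
    shap_tree(model, x, xb)
  } else {
    shap_sampling(model, x, xb, n_samples = n_samples, seed = seed)
  }
  res$pred <- predict_proba(model, rows)
  class(res) <- "shap_values"
  res
}

#' Mean-absolute SHAP importance summary
#'
#' Per (class, feature) mean absolute attribution over the evaluated rows,
#' plus a global feature ranking by the sum over classes.
#'
#' @param model A `farm_classifier`.
#' @param rows Rows to explain.
#' @param ... Passed to [shap_values()].
#' @return A `shap_summary` list: `table` (class, feature, mean_abs_shap),
#'   `ranking` (features ordered by summed importance), `values` (the
#'   underlying `shap_values`).
#' @export
shap_importance <- function(model, rows, ...) {
  sv <- shap_values(model, rows, ...)
  mas <- apply(abs(sv$shap), c(2, 3), mean)   # feature x class
  tab <- data.table(
    class = rep(colnames(mas), each = nrow(mas)),
    feature = rep(rownames(mas), times = ncol(mas)),
    mean_abs_shap = as.vector(mas))
  ranking <- names(sort(rowSums(mas), decreasing = TRUE))
  structure(list(table = tab, ranking = ranking, values = sv),
            class = "shap_summary")
}

#' @export
print.shap_summary <- function(x, ...) {
  cat("<shap_summary> top features by summed mean |SHAP|:\n")
  tot <- x$table[, .(total = sum(mean_abs_shap)), by = feature][
    order(-total)][1:min(8, .N)]
  for (i in seq_len(nrow(tot))) {
    cat(sprintf("  %-22s %.4f\n", tot$feature[i], tot$total[i]))
  }
  invisible(x)
}
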