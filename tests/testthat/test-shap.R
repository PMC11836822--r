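# build a hand-specified stump (one split) in the flat-array layout
stump <- function(feature, threshold, v_left, v_right, cov_left, cov_right) {
  list(left = c(1L, -1L, -1L), right = c(2L, -1L, -1L),
       feature = c(feature, -1L, -1L), threshold = c(threshold, 0, 0),
       cover = c(cov_left + cov_right, cov_left, cov_right),
       value = c(0, v_left, v_right))
}

test_that("a depth-1 tree has the closed-form Shapley attribution", {
  # split on feature 1 at 0.5; 30% of cover goes left
  tr <- stump(0L, 0.5, v_left = 1, v_right = 0, cov_left = 30,
              cov_right = 70)
  x <- matrix(c(0.2, 9, 9, 0.9, 9, 9), 2, 3, byrow = TRUE)
  phi <- treeshap_cpp(list(tr), x)
  base <- 0.3 * 1 + 0.7 * 0
  # only the split feature receives attribution
  expect_equal(phi[, 2:3], matrix(0, 2, 2))
  expect_equal(phi[1, 1], 1 - base, tolerance = 1e-12)
  expect_equal(phi[2, 1], 0 - base, tolerance = 1e-12)
})

test_that("constant trees attribute nothing", {
  tr <- stump(0L, 0.5, v_left = 0.4, v_right = 0.4, cov_left = 10,
              cov_right = 90)
  x <- matrix(runif(12), 4, 3)
  expect_equal(treeshap_cpp(list(tr), x), matrix(0, 4, 3),
               tolerance = 1e-12)
})

test_that("two-feature depth-2 tree matches exact subset enumeration", {
  # root splits f1 at 0.5; left child splits f2 at 0.5; leaf values chosen
  # asymmetric. Oracle: enumerate all feature subsets and compute the
  # path-dependent expectation recursively in R.
  tree <- list(left = c(1L, 3L, -1L, -1L, -1L),
               right = c(2L, 4L, -1L, -1L, -1L),
               feature = c(0L, 1L, -1L, -1L, -1L),
               threshold = c(0.5, 0.5, 0, 0, 0),
               cover = c(100, 60, 40, 20, 40),
               value = c(0, 0, 0.9, 0.1, 0.5))
  cond_exp <- function(node, S, x) {
    f <- tree$feature[node + 1]
    if (f < 0) return(tree$value[node + 1])
    l <- tree$left[node + 1]; r <- tree$right[node + 1]
    if ((f + 1) %in% S) {
      nxt <- if (x[f + 1] <= tree$threshold[node + 1]) l else r
      return(cond_exp(nxt, S, x))
    }
    (tree$cover[l + 1] * cond_exp(l, S, x) +
       tree$cover[r + 1] * cond_exp(r, S, x)) / tree$cover[node + 1]
  }
  shapley_oracle <- function(x, p) {
    phi <- numeric(p)
    feats <- seq_len(p)
    for (i in feats) {
      others <- setdiff(feats, i)
      for (k in 0:length(others)) {
        combs <- if (k == 0) list(integer(0)) else
          asplit(utils::combn(others, k), 2)
        w <- factorial(k) * factorial(p - k - 1) / factorial(p)
        for (S in combs) {
          phi[i] <- phi[i] + w * (cond_exp(0, c(S, i), x) - cond_exp(0, S, x))
        }
      }
    }
    phi
  }
  xs <- rbind(c(0.2, 0.3, 0.7), c(0.2, 0.9, 0.1), c(0.8, 0.2, 0.6))
  phi <- treeshap_cpp(list(tree), xs)
  for (i in 1:3) {
    expect_equal(phi[i, ], shapley_oracle(xs[i, ], 3), tolerance = 1e-10,
                 label = paste("row", i))
  }
})

test_that("tree SHAP satisfies local accuracy on a trained forest", {
  fx <- get_bench()$fx
  sp <- stratified_group_split(fx, split_spec(seed = 8))
  m <- train_model(sp$train, "random_forest", list(num_trees = 150),
                   seed = 2)
  rows <- sp$holdout[1:30]
  sv <- shap_values(m, rows, background = sp$train[1:200])
  recon <- apply(sv$shap, c(1, 3), sum) + sv$base
  expect_lt(max(abs(recon - predict_proba(m, rows))), 1e-6)
})

test_that("sampling SHAP satisfies local accuracy for SVM and MLP", {
  fx <- get_bench()$fx
  sp <- stratified_group_split(fx, split_spec(seed = 8))
  for (fam in c("svm", "mlp")) {
    m <- train_model(sp$train, fam,
                     list(cost = 4, gamma = 0.04, size = 8, decay = 1e-3,
                          maxit = 80), seed = 2)
    rows <- sp$holdout[1:3]
    sv <- shap_values(m, rows, background = sp$train[1:15],
                      n_samples = 300, seed = 5)
    recon <- apply(sv$shap, c(1, 3), sum) + sv$base
    expect_lt(max(abs(recon - predict_proba(m, rows))), 1e-6)
  }
})

test_that("importance summary ranks features and is a permutation", {
  fx <- get_bench()$fx
  sp <- stratified_group_split(fx, split_spec(seed = 8))
  m <- train_model(sp$train, "random_forest", list(num_trees = 150),
                   seed = 2)
  si <- shap_importance(m, sp$holdout[1:50], background = sp$train[1:200])
  expect_setequal(si$ranking, feature_names())
  expect_true(all(si$table$mean_abs_shap >= 0))
  expect_equal(nrow(si$table), 24 * 5)
  # the milk indicator is a dominant marker for the dairy class
  dairy <- si$table[class == "dairy_cow"][order(-mean_abs_shap)]
  expect_true("hasMilk" %in% dairy$feature[1:3])
})
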