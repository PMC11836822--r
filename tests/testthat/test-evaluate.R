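test_that("confusion counts are exact", {
  y <- sample(production_types(), 200, replace = TRUE)
  expect_equal(sum(confusion(y, y)), 200)
  expect_equal(confusion(y, y), diag(table(factor(y, production_types()))),
               ignore_attr = TRUE)
  yp <- sample(production_types(), 200, replace = TRUE)
  cm <- confusion(y, yp)
  expect_equal(sum(cm), 200)
  for (a in production_types()[1:2]) {
    for (b in production_types()[1:2]) {
      expect_equal(cm[a, b], sum(y == a & yp == b))
    }
  }
  one <- confusion("dairy_cow", "suckler_cow")
  expect_equal(sum(one), 1)
  expect_equal(one["dairy_cow", "suckler_cow"], 1)
  expect_error(confusion("dairy_cow", "goat"), "unknown label")
})

test_that("metric formulas match hand-computed values", {
  # binary: TP=8 FN=2 FP=1 TN=9
  cm <- matrix(c(8L, 2L, 1L, 9L), 2, 2, byrow = TRUE,
               dimnames = list(c("pos", "neg"), c("pos", "neg")))
  rep <- metrics(cm)
  expect_equal(rep$accuracy, 0.85)
  pc <- rep$per_class
  expect_equal(pc[class == "pos"]$sensitivity, 0.8)
  expect_equal(pc[class == "pos"]$specificity, 0.9)
  expect_equal(pc[class == "pos"]$balanced_accuracy, 0.85)
  expect_equal(pc[class == "pos"]$F1, 8 / 9.5, tolerance = 1e-12)

  perfect <- diag(c(3L, 4L, 5L, 6L, 7L))
  dimnames(perfect) <- list(production_types(), production_types())
  repp <- metrics(perfect)
  expect_equal(repp$accuracy, 1)
  expect_equal(repp$macro_F1, 1)
  expect_equal(repp$balanced_accuracy, 1)

  # everything predicted as one class under a balanced 5-class truth
  allone <- matrix(0L, 5, 5, dimnames = list(production_types(),
                                             production_types()))
  allone[, 1] <- 10L
  repa <- metrics(allone)
  expect_equal(repa$accuracy, 0.2)
  expect_equal(repa$macro_sensitivity, 0.2)
  expect_equal(repa$balanced_accuracy, repa$macro_sensitivity)
})

test_that("perfect self-prediction scores 1 and balanced accuracy is macro recall", {
  for (s in 1:5) {
    set.seed(s)
    y <- sample(production_types(), 60, replace = TRUE)
    yp <- sample(production_types(), 60, replace = TRUE)
    expect_equal(suppressWarnings(metrics(confusion(y, y))$macro_F1), 1)
    rep <- suppressWarnings(metrics(confusion(y, yp)))
    pc <- rep$per_class
    expect_equal(rep$balanced_accuracy,
                 mean(pc$sensitivity[!is.na(pc$sensitivity)]))
  }
})

test_that("absent classes are excluded from macro means with a warning", {
  y <- rep(c("dairy_cow", "suckler_cow"), 10)
  yp <- rep(c("dairy_cow", "rearing_cattle"), 10)
  expect_warning(rep <- metrics(confusion(y, yp)), "absent")
  expect_true(is.na(rep$per_class[class == "calf_fattening"]$F1))
  expect_equal(rep$macro_sensitivity, mean(c(1, 0)))
})

test_that("bootstrap replicates are deterministic and CIs match a sort oracle", {
  dt <- separable_matrix(n_groups_per_class = 10, rows_per_group = 2)
  sp <- stratified_group_split(dt, split_spec(seed = 1))
  b1 <- bootstrap_ci(sp$train, sp$holdout, "random_forest",
                     list(num_trees = 30), B = 4, seed = 10)
  b2 <- bootstrap_ci(sp$train, sp$holdout, "random_forest",
                     list(num_trees = 30), B = 4, seed = 10)
  expect_identical(b1$replicates, b2$replicates)
  expect_equal(nrow(b1$replicates), 4)
  # separable data: every replicate is perfect
  expect_equal(unname(b1$ci$accuracy), c(1, 1))
  # percentile bounds equal an independent sort-based interpolation
  r <- b1$replicates[, "macro_F1"]
  sorted <- sort(r)
  manual <- function(p) {
    h <- (length(sorted) - 1) * p + 1
    lo <- floor(h); hi <- ceiling(h)
    sorted[lo] + (h - lo) * (sorted[hi] - sorted[lo])
  }
  expect_equal(unname(b1$ci$macro_F1), c(manual(0.025), manual(0.975)))
  expect_error(bootstrap_ci(sp$train, sp$holdout, "random_forest",
                            B = 0), "B must be")
})

test_that("PCA overview matches closed-form eigenstructure", {
  # perfectly collinear rows: one component explains everything
  n <- 40
  base <- seq(0, 1, length.out = n)
  dt <- data.table(farm_id = sprintf("f%d", 1:n), year = 2020L)
  for (f in feature_names()) dt[[f]] <- base * runif(1, 0.5, 2)
  pv <- suppressWarnings(pca_overview(dt))
  expect_equal(pv$variance_fraction[1], 1, tolerance = 1e-9)

  # 2-feature toy with known correlation: eigenvalues of the correlation
  # matrix are 1 +- r
  set.seed(4)
  x1 <- rnorm(4000)
  x2 <- 0.6 * x1 + sqrt(1 - 0.36) * rnorm(4000)
  dt2 <- data.table(farm_id = as.character(1:4000), year = 2020L,
                    pBirths = x1, inDegree = x2)
  for (f in setdiff(feature_names(numeric_only = TRUE),
                    c("pBirths", "inDegree"))) dt2[[f]] <- 0
  pv2 <- suppressWarnings(pca_overview(dt2))
  expect_identical(pv2$dropped,
                   setdiff(feature_names(numeric_only = TRUE),
                           c("pBirths", "inDegree")))
  r <- cor(x1, x2)
  ev <- pv2$variance_fraction * 2
  expect_equal(ev, c(1 + r, 1 - r), tolerance = 1e-9)
  expect_equal(sum(pv2$variance_fraction), 1, tolerance = 1e-9)
  # unit-norm loadings, largest entry positive
  expect_equal(colSums(pv2$loadings^2), c(PC1 = 1, PC2 = 1))
  for (j in 1:2) {
    expect_gt(pv2$loadings[which.max(abs(pv2$loadings[, j])), j], 0)
  }
})

test_that("hasMilk is excluded from the PCA feature set", {
  fx <- get_bench()$fx
  pv <- pca_overview(fx)
  expect_false("hasMilk" %in% rownames(pv$loadings))
  expect_equal(nrow(pv$loadings), 23)
  expect_equal(sum(pv$variance_fraction), 1, tolerance = 1e-9)
})
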