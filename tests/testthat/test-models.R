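test_that("stratified group split keeps farms whole and classes balanced", {
  # 10 single-row groups, 2 classes -> 7 train / 3 holdout, disjoint
  dt <- separable_matrix(n_groups_per_class = 5, rows_per_group = 1)
  dt <- dt[production_type %in% production_types()[1:2]]
  sp <- stratified_group_split(dt, split_spec(seed = 4))
  expect_equal(nrow(sp$train), 7)
  expect_equal(nrow(sp$holdout), 3)
  expect_length(intersect(sp$train_groups, sp$holdout_groups), 0)

  fx <- get_bench()$fx
  sp2 <- stratified_group_split(fx, split_spec(seed = 11))
  expect_length(intersect(sp2$train_groups, sp2$holdout_groups), 0)
  overall <- prop.table(table(fx$production_type))
  for (part in list(sp2$train, sp2$holdout)) {
    shares <- prop.table(table(part$production_type))
    expect_true(all(abs(shares[names(overall)] - overall) <= 0.05))
  }
  # a class confined to one group cannot be split
  one <- data.table::copy(dt)[production_type == production_types()[1],
                              farm_id := "only_group"]
  expect_error(stratified_group_split(one), "fewer than 2 groups")
})

test_that("fold assignment never separates rows of one farm", {
  fx <- get_bench()$fx
  folds <- group_folds(fx, n_folds = 10, seed = 2)
  expect_length(folds, nrow(fx))
  per_farm <- tapply(folds, fx$farm_id, function(x) length(unique(x)))
  expect_true(all(per_farm == 1))
  expect_equal(sort(unique(folds)), 1:10)
})

test_that("a single-candidate space is chosen; two candidates match a brute-force re-run", {
  dt <- separable_matrix(n_groups_per_class = 8, rows_per_group = 2)
  single <- model_spec("random_forest",
                       search_space = list(num_trees = 50, mtry = 3))
  m <- tune_and_train(dt, single, split_spec(n_folds = 3), seed = 6)
  expect_equal(m$hyper$num_trees, 50)
  expect_equal(m$hyper$mtry, 3)

  two <- model_spec("random_forest",
                    search_space = list(num_trees = c(10, 100)),
                    n_random = 2)
  m2 <- tune_and_train(dt, two, split_spec(n_folds = 3), seed = 6)
  folds <- group_folds(dt, n_folds = 3, seed = 6)
  scores <- vapply(c(10, 100), function(nt) {
    mean(cattletype:::cv_score_candidate("random_forest",
                                         list(num_trees = nt), dt, folds,
                                         seed = 6))
  }, numeric(1))
  expect_equal(m2$hyper$num_trees, c(10, 100)[which.max(scores)])
})

test_that("probability rows sum to one and argmax follows the fixed class order", {
  proba <- rbind(
    c(calf_fattening = 0.00, cattle_fattening = 0.06, dairy_cow = 0.91,
      rearing_cattle = 0.00, suckler_cow = 0.03),
    c(calf_fattening = 0.10, cattle_fattening = 0.12, dairy_cow = 0.37,
      rearing_cattle = 0.39, suckler_cow = 0.02),
    rep(0.2, 5))
  colnames(proba) <- production_types()
  expect_equal(predict_label(proba),
               c("dairy_cow", "rearing_cattle", "calf_fattening"))

  fx <- get_bench()$fx
  sp <- stratified_group_split(fx, split_spec(seed = 3))
  for (fam in c("random_forest", "svm", "mlp")) {
    m <- train_model(sp$train, fam,
                     list(num_trees = 100, cost = 4, gamma = 0.04,
                          size = 16, decay = 1e-3, maxit = 150), seed = 4)
    p <- predict_proba(m, sp$holdout)
    expect_equal(rowSums(p), rep(1, nrow(p)), tolerance = 1e-9)
    expect_identical(colnames(p), production_types())
  }
  m <- train_model(sp$train, "random_forest", list(num_trees = 50), seed = 1)
  expect_error(predict_proba(m, sp$holdout[, -"hasMilk"]), "hasMilk")
})

test_that("fixed seeds make split, folds and predictions reproducible", {
  fx <- get_bench()$fx
  s1 <- stratified_group_split(fx, split_spec(seed = 21))
  s2 <- stratified_group_split(fx, split_spec(seed = 21))
  expect_identical(s1$holdout_groups, s2$holdout_groups)
  expect_identical(group_folds(fx, 10, seed = 5), group_folds(fx, 10, seed = 5))
  for (fam in c("random_forest", "svm", "mlp")) {
    m1 <- train_model(s1$train, fam,
                      list(num_trees = 60, cost = 2, gamma = 0.05,
                           size = 8, decay = 1e-3, maxit = 80), seed = 9)
    m2 <- train_model(s1$train, fam,
                      list(num_trees = 60, cost = 2, gamma = 0.05,
                           size = 8, decay = 1e-3, maxit = 80), seed = 9)
    expect_equal(predict_proba(m1, s1$holdout), predict_proba(m2, s1$holdout),
                 label = fam)
  }
})

test_that("all three families master linearly separable data", {
  dt <- separable_matrix(n_groups_per_class = 20, rows_per_group = 2)
  sp <- stratified_group_split(dt, split_spec(seed = 2))
  for (fam in c("random_forest", "svm", "mlp")) {
    m <- train_model(sp$train, fam,
                     list(num_trees = 200, cost = 4, gamma = 0.05,
                          size = 16, decay = 1e-4, maxit = 300), seed = 3)
    rep <- evaluate_model(m, sp$holdout)
    expect_gte(rep$macro_F1, 0.99)
  }
})

test_that("SMOTE points are convex combinations of same-class neighbours", {
  set.seed(12)
  x <- matrix(runif(15 * 6), 15, 6)
  synth <- smote_sample(x, n_new = 40, k = 5)
  expect_equal(dim(synth), c(40, 6))
  on_segment <- function(s) {
    for (i in seq_len(nrow(x))) {
      for (j in seq_len(nrow(x))) {
        if (i == j) next
        dir <- x[j, ] - x[i, ]
        rel <- s - x[i, ]
        nz <- which(abs(dir) > 1e-12)
        if (!length(nz)) next
        u <- rel[nz[1]] / dir[nz[1]]
        if (u >= -1e-9 && u <= 1 + 1e-9 &&
            max(abs(rel - u * dir)) < 1e-8) return(TRUE)
      }
    }
    FALSE
  }
  expect_true(all(apply(synth, 1, on_segment)))
  # duplicated identical rows interpolate to themselves
  dup <- matrix(rep(c(1, 2, 3), each = 6), 6, 3)
  sd <- smote_sample(dup, n_new = 10, k = 2)
  expect_true(all(apply(sd, 1, function(r) all(r == c(1, 2, 3)))))
})

test_that("one-vs-rest SMOTE models balance the binary classes", {
  fx <- get_bench()$fx
  ovr <- train_ovr_smote(fx, seed = 5, num_trees = 50)
  expect_setequal(names(ovr), production_types())
  for (cls in production_types()) {
    cc <- ovr[[cls]]$class_counts
    expect_equal(unname(cc["positive"]), unname(cc["rest"]))
  }
})

test_that("small classes reduce the SMOTE neighbourhood with a warning", {
  x <- matrix(runif(4 * 5), 4, 5)
  expect_warning(smote_sample(x, n_new = 5, k = 5), "reducing k")
})
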