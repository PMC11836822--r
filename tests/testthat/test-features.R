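test_that("eligibility requires 10 overlapping stays and a standard facility", {
  mk <- function(n_stays) {
    an <- data.table(animal_id = sprintf("a%02d", 1:n_stays),
                     birth_date = as.Date("2018-01-01"), sex = "female",
                     breed_category = "dairy", birth_farm_id = "fx")
    st <- data.table(animal_id = an$animal_id, farm_id = "fx",
                     entry_date = as.Date("2020-02-01"),
                     exit_date = as.Date("2020-10-01"),
                     entry_mode = "move_in", exit_mode = "death",
                     origin_farm_id = "ext",
                     destination_farm_id = NA_character_)
    fm <- data.table(farm_id = "fx", facility_type = "standard")
    linked_registry(animals = an, stays = st, farms = fm)
  }
  expect_identical(filter_eligible(mk(9), 2020), character(0))
  expect_identical(filter_eligible(mk(10), 2020), "fx")
  # a busy cattle market is still excluded
  reg <- tiny_registry()
  expect_identical(filter_eligible(reg, 2020), "FARM1")
})

test_that("hand-built farm-year reproduces every event-based feature", {
  reg <- tiny_registry()
  fx <- extract_features(reg, "FARM1", 2020)
  expect_equal(fx$hasMilk, 1)
  # slaughter exits 2020: one adult cow, one newborn calf, one young animal
  expect_equal(fx$pOutMovesToSLCalves, 1 / 3)
  expect_equal(fx$pOutMovesToSLYoung, 1 / 3)
  expect_equal(fx$pOutMovesToSLAdults, 1 / 3)
  # 4 move-outs, 1 of them back to the animal's birth farm, none <= 10 days
  expect_equal(fx$pOutMovesToBirthHerd, 0.25)
  expect_equal(fx$pAnimals10Days, 0)
  # no arrivals dated within 2020; 3 distinct destinations
  expect_equal(fx$inDegree, 0)
  expect_equal(fx$outDegree, log(4))
  # one calving among 12 animals present
  expect_equal(fx$pBirths, 1 / 12)
  # prescriptions: 2 milk_cow, 1 rearing, 1 other
  expect_equal(fx$pABMilkCow, 0.5)
  expect_equal(fx$pABRearing, 0.25)
  expect_equal(fx$pABFatteningCalves + fx$pABFatteningYoung +
                 fx$pABSuckling, 0)
})

test_that("zero denominators yield zeros, never NaN", {
  reg <- make_single_stay("2015-06-01", "2019-01-01", NA)
  fx <- extract_features(reg, "f1", 2021)
  expect_equal(fx$pOutMovesToSLCalves + fx$pOutMovesToSLYoung +
                 fx$pOutMovesToSLAdults, 0)
  expect_equal(fx$pOutMovesToBirthHerd, 0)
  expect_equal(fx$pAnimals10Days, 0)
  expect_equal(fx$pABMilkCow, 0)
  expect_false(any(is.na(as.numeric(fx[, feature_names(), with = FALSE]))))
})

test_that("in-degree is the log of one plus the distinct origin farms", {
  an <- data.table(animal_id = sprintf("a%d", 1:6),
                   birth_date = as.Date("2019-05-01"), sex = "male",
                   breed_category = "beef", birth_farm_id = "ext1")
  st <- data.table(animal_id = an$animal_id, farm_id = "fx",
                   entry_date = as.Date("2020-03-01") + 0:5,
                   exit_date = as.Date(NA),
                   entry_mode = "move_in", exit_mode = "none",
                   origin_farm_id = c("o1", "o2", "o3", "o4", "o1", "o2"),
                   destination_farm_id = NA_character_)
  fm <- data.table(farm_id = "fx", facility_type = "standard")
  reg <- linked_registry(animals = an, stays = st, farms = fm)
  fx <- extract_features(reg, "fx", 2020)
  expect_equal(fx$inDegree, log(5), tolerance = 1e-12)
})

test_that("adding a milk test changes only hasMilk; a prescription only its ratios", {
  reg <- tiny_registry()
  base <- extract_features(reg, "FARM1", 2020)
  no_milk <- linked_registry(
    animals = reg$animals, stays = reg$stays, calvings = reg$calvings,
    milk_tests = NULL, prescriptions = reg$prescriptions, farms = reg$farms)
  fx0 <- extract_features(no_milk, "FARM1", 2020)
  expect_equal(fx0$hasMilk, 0)
  others <- setdiff(feature_names(), "hasMilk")
  expect_equal(as.numeric(fx0[, others, with = FALSE]),
               as.numeric(base[, others, with = FALSE]))
  # one more suckling prescription weakly raises pABSuckling, lowers others
  rx <- rbind(reg$prescriptions,
              data.table(farm_id = "FARM1", date = as.Date("2020-07-07"),
                         usage_category = "suckling"))
  more <- extract_features(linked_registry(
    animals = reg$animals, stays = reg$stays, calvings = reg$calvings,
    milk_tests = reg$milk_tests, prescriptions = rx, farms = reg$farms),
    "FARM1", 2020)
  expect_gt(more$pABSuckling, base$pABSuckling)
  expect_lte(more$pABMilkCow, base$pABMilkCow)
  expect_lte(more$pABRearing, base$pABRearing)
})

test_that("row order of input tables never changes the features", {
  reg <- tiny_registry()
  base <- extract_features(reg, "FARM1", 2020)
  set.seed(1)
  shuf <- linked_registry(
    animals = reg$animals[sample(.N)], stays = reg$stays[sample(.N)],
    calvings = reg$calvings[sample(.N)],
    milk_tests = reg$milk_tests[sample(.N)],
    prescriptions = reg$prescriptions[sample(.N)], farms = reg$farms)
  expect_equal(as.data.frame(extract_features(shuf, "FARM1", 2020)),
               as.data.frame(base))
})

test_that("class-wise extreme fences match a brute-force oracle", {
  set.seed(7)
  n <- 120
  dt <- data.table(farm_id = sprintf("f%03d", 1:n), year = 2020L)
  for (f in feature_names()) dt[[f]] <- runif(n)
  dt$production_type <- rep(production_types(), length.out = n)
  dt$pBirths[5] <- 100   # single gross outlier
  res <- exclude_extreme(dt)
  expect_true("f005" %in% res$flagged$farm_id)
  # independent re-computation of the fence flags
  flagged_oracle <- character()
  for (cls in unique(dt$production_type)) {
    sub <- dt[production_type == cls]
    bad <- rep(FALSE, nrow(sub))
    for (f in feature_names(numeric_only = TRUE)) {
      q <- unname(quantile(sub[[f]], c(.25, .75)))
      iqr <- q[2] - q[1]
      if (iqr > 0) bad <- bad | sub[[f]] < q[1] - 3 * iqr |
          sub[[f]] > q[2] + 3 * iqr
    }
    flagged_oracle <- c(flagged_oracle, sub$farm_id[bad])
  }
  expect_setequal(res$flagged$farm_id, flagged_oracle)
  # constant features per class flag nothing
  cst <- data.table::copy(dt)
  for (f in feature_names()) cst[[f]] <- as.numeric(
    match(cst$production_type, production_types()))
  expect_equal(nrow(exclude_extreme(cst)$flagged), 0)
})

test_that("build_dataset keeps eligible farm-years and groups by farm", {
  bench <- get_bench()
  fx <- bench$fx
  expect_true(all(fx$production_type %in% production_types()))
  expect_equal(anyDuplicated(fx[, .(farm_id, year)]), 0)
  # labels for unknown farms are skipped with a warning
  labs <- rbind(bench$sim$labels,
                data.table(farm_id = "NOSUCH", production_type = "dairy_cow"))
  expect_warning(build_dataset(bench$sim$registry, labs, 2020),
                 "unknown farm")
  # empty labels produce an empty matrix
  empty <- build_dataset(bench$sim$registry,
                         bench$sim$labels[0], 2020)
  expect_equal(nrow(empty), 0)
})

test_that("feature invariants hold on every simulated farm-year", {
  fx <- get_bench()$fx
  feats <- as.matrix(fx[, setdiff(feature_names(), c("inDegree", "outDegree")),
                        with = FALSE])
  expect_true(all(feats >= 0 & feats <= 1))
  expect_true(all(fx$inDegree >= 0 & fx$outDegree >= 0))
  sexage <- fx$pFemaleCalves + fx$pMaleCalves + fx$pFemaleYoung +
    fx$pMaleYoung + fx$pFemaleAdults + fx$pMaleAdults
  expect_true(all(abs(sexage - 1) < 1e-9))
  sl <- fx$pOutMovesToSLCalves + fx$pOutMovesToSLYoung +
    fx$pOutMovesToSLAdults
  expect_true(all(abs(sl - 1) < 1e-9 | sl == 0))
  breeds <- fx$pDairyBreed + fx$pBeefBreed + fx$pDoubleBreed
  expect_true(all(breeds <= 1 + 1e-9))
  ab <- fx$pABRearing + fx$pABFatteningCalves + fx$pABFatteningYoung +
    fx$pABMilkCow + fx$pABSuckling
  expect_true(all(ab <= 1 + 1e-9))
})
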