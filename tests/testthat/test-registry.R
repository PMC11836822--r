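test_that("empty registry round-trips through header-only files", {
  reg <- linked_registry()
  dir <- withr::local_tempdir()
  paths <- write_registry(reg, dir)
  expect_length(paths, 6)
  for (p in paths) {
    expect_true(file.exists(p))
    expect_length(readLines(p), 1)   # header only
  }
  back <- read_registry(dir)
  for (tab in names(paths)) expect_equal(nrow(back[[tab]]), 0)
})

test_that("stay invariant violations are reported with the offending row", {
  reg <- tiny_registry()
  bad <- data.table::copy(reg$stays)
  bad$destination_farm_id[5] <- NA   # row 5 is a move_out
  expect_error(
    linked_registry(animals = reg$animals, stays = bad,
                    calvings = reg$calvings, milk_tests = reg$milk_tests,
                    prescriptions = reg$prescriptions, farms = reg$farms),
    "row 5.*destination", ignore.case = TRUE)
  bad2 <- data.table::copy(reg$stays)
  bad2$exit_date[5] <- as.Date("2019-01-01")   # before entry
  expect_error(
    linked_registry(animals = reg$animals, stays = bad2,
                    calvings = reg$calvings, milk_tests = reg$milk_tests,
                    prescriptions = reg$prescriptions, farms = reg$farms),
    "entry_date after exit_date")
})

test_that("overlapping stays of one animal are rejected", {
  an <- data.table(animal_id = "a1", birth_date = as.Date("2019-01-01"),
                   sex = "female", breed_category = "dairy",
                   birth_farm_id = "f1")
  st <- data.table(
    animal_id = "a1", farm_id = c("f1", "f2"),
    entry_date = as.Date(c("2020-01-01", "2020-03-01")),
    exit_date = as.Date(c("2020-06-01", "2020-09-01")),
    entry_mode = "birth", exit_mode = "death",
    origin_farm_id = NA_character_, destination_farm_id = NA_character_)
  fm <- data.table(farm_id = c("f1", "f2"), facility_type = "standard")
  expect_error(linked_registry(animals = an, stays = st, farms = fm),
               "overlapping stays")
  # back-to-back stays (shared endpoint) are fine under half-open intervals
  st$exit_date[1] <- as.Date("2020-03-01")
  expect_s3_class(linked_registry(animals = an, stays = st, farms = fm),
                  "linked_registry")
})

test_that("write -> read -> write is byte-identical on a simulated registry", {
  reg <- simulate_farm_year(default_profiles()$suckler_cow, "S01", 2021,
                            seed = 4)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_registry(reg, d1)
  back <- read_registry(d1)
  write_registry(back, d2)
  for (tab in c("animals", "stays", "calvings", "milk_tests",
                "prescriptions", "farms")) {
    expect_identical(readLines(file.path(d1, paste0(tab, ".csv"))),
                     readLines(file.path(d2, paste0(tab, ".csv"))),
                     label = tab)
    expect_equal(back[[tab]], reg[[tab]], label = tab)
  }
})

test_that("anonymization preserves structure, is seeded, and inverts", {
  reg <- simulate_farm_year(default_profiles()$rearing_cattle, "R01", 2021,
                            seed = 11)
  a1 <- anonymize(reg, seed = 42)
  a2 <- anonymize(reg, seed = 42)
  expect_identical(a1$mapping, a2$mapping)
  # relational structure: the movement edge multiset is preserved
  fmap <- setNames(a1$mapping$farms$token, a1$mapping$farms$original)
  orig_edges <- sort(paste(reg$stays$farm_id, reg$stays$origin_farm_id))
  anon_edges <- sort(paste(a1$registry$stays$farm_id,
                           a1$registry$stays$origin_farm_id))
  expect_identical(anon_edges,
                   sort(paste(fmap[reg$stays$farm_id],
                              ifelse(is.na(reg$stays$origin_farm_id), NA,
                                     fmap[reg$stays$origin_farm_id]))))
  # composing with the inverse restores the original tables
  inv_f <- setNames(a1$mapping$farms$original, a1$mapping$farms$token)
  inv_a <- setNames(a1$mapping$animals$original, a1$mapping$animals$token)
  restored <- data.table::copy(a1$registry$stays)
  restored[, `:=`(animal_id = inv_a[animal_id], farm_id = inv_f[farm_id],
                  origin_farm_id = ifelse(is.na(origin_farm_id), NA,
                                          inv_f[origin_farm_id]),
                  destination_farm_id = ifelse(is.na(destination_farm_id),
                                               NA,
                                               inv_f[destination_farm_id]))]
  expect_equal(as.data.frame(restored), as.data.frame(reg$stays))
})

test_that("referential integrity violations are caught", {
  reg <- tiny_registry()
  orphan <- data.table::copy(reg$stays)
  orphan$animal_id[1] <- "GHOST"
  expect_error(
    linked_registry(animals = reg$animals, stays = orphan,
                    farms = reg$farms),
    "not in animals table")
  expect_error(read_registry(withr::local_tempdir()), "not found")
})
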