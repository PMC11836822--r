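# Shared fixtures and independent oracles, built in code at test time.

suppressMessages({
  library(data.table)
  library(lubridate)
})

# Day-by-day oracle for animal-day partitioning: iterates every calendar
# day of the year, derives the completed-months age from the monthly
# anniversary sequence of the birth date (month-end clamped), and counts
# presence under the half-open [entry, exit) convention. Independent of
# the split-interval arithmetic used by the implementation.
oracle_stay_days <- function(entry, exit, birth, year) {
  y0 <- as.Date(sprintf("%d-01-01", year))
  y1 <- as.Date(sprintf("%d-01-01", year + 1L))
  days <- seq(y0, y1 - 1, by = "day")
  present <- days >= entry & (is.na(exit) | days < exit)
  out <- c(calf = 0L, young = 0L, adult = 0L)
  if (!any(present)) return(out)
  n_m <- as.integer(ceiling(as.numeric(y1 - birth) / 28)) + 2L
  anniv <- birth %m+% months(0:n_m)
  m <- findInterval(days, anniv) - 1L   # completed months per day
  cls <- ifelse(m <= 6L, "calf", ifelse(m <= 24L, "young", "adult"))
  for (g in names(out)) out[g] <- sum(present & cls == g)
  out
}

# Random single-farm registries for oracle comparisons: each farm gets a
# handful of stays with varied birth dates (including month-end edge
# cases), open exits and zero-length stays.
random_stay_registry <- function(n_farms, stays_per_farm, year, seed) {
  set.seed(seed)
  y0 <- as.Date(sprintf("%d-01-01", year))
  rows <- list()
  k <- 0L
  for (f in seq_len(n_farms)) {
    for (s in seq_len(stays_per_farm)) {
      k <- k + 1L
      birth <- y0 - sample(0:2200, 1)
      if (runif(1) < 0.15) {
        # force month-end births to exercise anniversary clamping
        birth <- as.Date(sprintf("%d-%02d-%02d", sample(2015:2020, 1),
                                 sample(c(1, 3, 5, 7, 8, 10, 12), 1), 31))
      }
      entry <- max(birth, y0 + sample(-400:360, 1))
      len <- sample(c(0, 1, 5, 30, 100, 400, 900), 1)
      exit <- entry + len
      open <- runif(1) < 0.15
      rows[[k]] <- data.table(
        animal_id = sprintf("a%05d", k), farm_id = sprintf("f%03d", f),
        birth_date = birth, entry_date = entry,
        exit_date = if (open) as.Date(NA) else exit,
        sex = sample(c("female", "male"), 1))
    }
  }
  dt <- rbindlist(rows)
  animals <- dt[, .(animal_id, birth_date, sex,
                    breed_category = "dual_purpose",
                    birth_farm_id = farm_id)]
  stays <- dt[, .(animal_id, farm_id, entry_date, exit_date,
                  entry_mode = "birth",
                  exit_mode = fifelse(is.na(exit_date), "none", "death"),
                  origin_farm_id = NA_character_,
                  destination_farm_id = NA_character_)]
  farms <- data.table(farm_id = unique(dt$farm_id),
                      facility_type = "standard")
  list(registry = linked_registry(animals = animals, stays = stays,
                                  farms = farms),
       detail = dt)
}

make_single_stay <- function(birth, entry, exit, sex = "female") {
  an <- data.table(animal_id = "a1", birth_date = as.Date(birth), sex = sex,
                   breed_category = "dairy", birth_farm_id = "f1")
  st <- data.table(animal_id = "a1", farm_id = "f1",
                   entry_date = as.Date(entry),
                   exit_date = as.Date(exit),
                   entry_mode = "birth",
                   exit_mode = if (is.na(exit)) "none" else "death",
                   origin_farm_id = NA_character_,
                   destination_farm_id = NA_character_)
  fm <- data.table(farm_id = "f1", facility_type = "standard")
  linked_registry(animals = an, stays = st, farms = fm)
}

# A small hand-checkable registry: one standard farm with crafted events,
# one under-threshold farm, one cattle market.
tiny_registry <- function() {
  d <- function(x) as.Date(x)
  animals <- data.table(
    animal_id = sprintf("A%02d", 1:14),
    birth_date = c(rep(d("2016-03-10"), 4),      # adults (cows)
                   rep(d("2020-03-01"), 4),      # calves born in-year
                   rep(d("2019-01-15"), 4),      # young
                   d("2016-06-01"), d("2017-01-01")),
    sex = c("female", "female", "female", "female",
            "male", "male", "female", "female",
            "female", "female", "male", "male",
            "male", "female"),
    breed_category = c(rep("dairy", 4), rep("dual_purpose", 4),
                       rep("beef", 4), "other", "dairy"),
    birth_farm_id = c("EXT1", "EXT1", "EXT2", "EXT2",
                      rep("FARM1", 4), "EXT3", "EXT3", "EXT4", "EXT5",
                      "EXT6", "EXT7"))
  stays <- data.table(
    animal_id = sprintf("A%02d", 1:14),
    farm_id = c(rep("FARM1", 12), "FARM2", "MKT1"),
    entry_date = c(rep(d("2018-05-01"), 4),
                   rep(d("2020-03-01"), 4),
                   rep(d("2019-11-20"), 4),
                   d("2020-02-01"), d("2020-01-10")),
    exit_date = as.Date(c(NA, NA, "2020-09-15", NA,
                          "2020-04-10", "2020-04-12", NA, "2020-12-01",
                          "2020-06-30", "2020-07-15", NA, "2020-05-20",
                          NA, "2020-03-01")),
    entry_mode = c(rep("move_in", 4), rep("birth", 4), rep("move_in", 4),
                   "move_in", "move_in"),
    exit_mode = c("none", "none", "slaughter", "none",
                  "move_out", "slaughter", "none", "move_out",
                  "move_out", "slaughter", "none", "move_out",
                  "none", "move_out"),
    origin_farm_id = c("EXT1", "EXT1", "EXT2", "EXT2",
                       NA, NA, NA, NA, "EXT3", "EXT3", "EXT4", "EXT5",
                       "EXT6", "EXT7"),
    destination_farm_id = c(NA, NA, NA, NA,
                            "EXT9", NA, NA, "EXT9",
                            "EXT3", NA, NA, "EXT8",
                            NA, "EXT9"))
  calvings <- data.table(
    animal_id = c("A01", "A02", "A03"),
    date = c(d("2019-04-01"), d("2020-05-15"), d("2018-12-01")),
    stillbirth = c(FALSE, FALSE, TRUE))
  milk_tests <- data.table(farm_id = "FARM1",
                           date = c(d("2020-02-11"), d("2020-08-03")))
  prescriptions <- data.table(
    farm_id = rep("FARM1", 4),
    date = c(d("2020-01-20"), d("2020-03-05"), d("2020-06-30"),
             d("2020-11-11")),
    usage_category = c("milk_cow", "milk_cow", "rearing", "other"))
  farms <- data.table(farm_id = c("FARM1", "FARM2", "MKT1"),
                      facility_type = c("standard", "standard",
                                        "cattle_market"))
  linked_registry(animals = animals, stays = stays, calvings = calvings,
                  milk_tests = milk_tests, prescriptions = prescriptions,
                  farms = farms)
}

# Cached medium benchmark shared across test files (simulate once).
.bench_cache <- new.env(parent = emptyenv())
get_bench <- function() {
  if (is.null(.bench_cache$fx)) {
    cfg <- benchmark_config(seed = 99, years = 2020:2021, scale = 0.35)
    sim <- simulate_dataset(cfg)
    fx <- build_dataset(sim$registry, sim$labels, 2020:2021)
    .bench_cache$sim <- sim
    .bench_cache$fx <- fx
  }
  list(sim = .bench_cache$sim, fx = .bench_cache$fx)
}

# Well-separated synthetic feature matrix (5 Gaussian blobs) for model
# sanity checks independent of the farm simulator.
separable_matrix <- function(n_groups_per_class = 30, rows_per_group = 2,
                             seed = 5) {
  set.seed(seed)
  feats <- feature_names()
  classes <- production_types()
  rows <- list()
  gid <- 0L
  for (k in seq_along(classes)) {
    center <- rep(0, length(feats))
    center[((k - 1) * 4 + 1):(k * 4)] <- 1  # distinct active block
    for (g in seq_len(n_groups_per_class)) {
      gid <- gid + 1L
      for (r in seq_len(rows_per_group)) {
        v <- pmin(pmax(center + rnorm(length(feats), 0, 0.05), 0), 1)
        row <- as.list(v)
        names(row) <- feats
        rows[[length(rows) + 1L]] <- c(
          list(farm_id = sprintf("g%04d", gid), year = 2020L + r),
          row, list(production_type = classes[k]))
      }
    }
  }
  rbindlist(rows)
}
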