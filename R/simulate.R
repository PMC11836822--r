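# Event-level synthetic registry generator.
#
# Farms are simulated animal by animal and stay by stay, never by sampling
# feature vectors directly, so the full feature-extraction path is
# exercised. Demography is static within the simulation window: resident
# classes (typically adults) are realized as renewal processes on "slots"
# whose successive occupants arrive, stay for a tenure and are culled or
# sold, while throughput classes (fattening calves, reared heifers, ...)
# are realized as yearly entry cohorts with entry/exit age laws. Cohorts
# are also generated for the years immediately before the window so that
# stays overhanging the window start are present at their steady-state
# rate.

AGE_YOUNG_D <- 213L   # approx day the 7th month completes (simulation only)
AGE_ADULT_D <- 761L   # approx day the 25th month completes

rdirichlet1 <- function(alpha) {
  g <- rgamma(length(alpha), shape = pmax(alpha, 1e-8))
  if (sum(g) <= 0) g <- alpha
  g / sum(g)
}

runif_int <- function(n, lo, hi) as.integer(lo + floor(runif(n) * (hi - lo + 1)))

rbeta_mean <- function(n, mean, conc) {
  if (mean <= 0) return(rep(0, n))
  if (mean >= 1) return(rep(1, n))
  rbeta(n, mean * conc, (1 - mean) * conc)
}

age_group_d <- function(age_days) {
  fifelse(age_days < AGE_YOUNG_D, "calf",
          fifelse(age_days < AGE_ADULT_D, "young", "adult"))
}

year_len <- function(year) {
  as.integer(as.Date(sprintf("%d-01-01", year + 1L)) -
               as.Date(sprintf("%d-01-01", year)))
}

# Simulate all events of one farm over a span of calendar years.
# Returns raw tables with integer dates; not exported (wrapped by
# simulate_farm_year / simulate_dataset).
simulate_farm_events <- function(profile, farm_id, years, seed) {
  stopifnot(inherits(profile, "type_profile"))
  set.seed(as.integer(seed) %% 2147483647L)
  years <- sort(as.integer(years))
  w0 <- as.integer(as.Date(sprintf("%d-01-01", years[1])))
  w1 <- as.integer(as.Date(sprintf("%d-01-01", years[length(years)] + 1L)))

  hs <- profile$herd_size
  H <- min(max(rlnorm(1, hs$meanlog, hs$sdlog), hs$min), hs$max)
  base_mix <- unlist(profile$sexage_mix)
  if (!is.null(profile$sideline) && runif(1) < profile$sideline$prob) {
    base_mix <- unlist(profile$sideline$mix)
  }
  mix <- rdirichlet1(profile$mix_concentration * base_mix)
  names(mix) <- SEXAGE_CLASSES
  breed_p <- rdirichlet1(profile$breed_concentration *
                           unlist(profile$breed_mix))
  has_milk <- runif(1) < profile$milk_test_prob
  ret_p <- rbeta_mean(1, profile$return_to_birth_prob,
                      profile$return_concentration)
  rx_mix <- rdirichlet1(profile$rx$concentration * unlist(profile$rx$mix))
  K_src <- max(1L, as.integer(round(rlnorm(1, profile$n_source_farms$meanlog,
                                           profile$n_source_farms$sdlog))))
  K_dst <- max(1L, as.integer(round(rlnorm(1, profile$n_dest_farms$meanlog,
                                           profile$n_dest_farms$sdlog))))
  src_ids <- sprintf("ES%s_%03d", farm_id, seq_len(K_src))
  dst_ids <- sprintf("ED%s_%03d", farm_id, seq_len(K_dst))
  exit_mix_farm <- lapply(profile$exit_mix, function(m) {
    rdirichlet1(12 * unlist(m)[c("slaughter", "move_out", "death")])
  })

  batches <- list()
  for (cls in SEXAGE_CLASSES) {
    rc <- profile$residency[[cls]]
    if (is.null(rc) || identical(rc$mode, "none")) next
    sex <- if (startsWith(cls, "female")) "female" else "male"
    days_py <- H * 365 * mix[[cls]]
    if (days_py < 1) next
    if (identical(rc$mode, "resident")) {
      batches[[cls]] <- gen_resident(rc, sex, days_py, years, w0, w1)
    } else {
      batches[[cls]] <- gen_throughput(rc, sex, days_py, years, w0, w1,
                                       profile)
    }
  }
  ani <- rbindlist(batches, use.names = TRUE)
  if (!nrow(ani)) {
    ani <- data.table(entry = integer(), exit = integer(), birth = integer(),
                      sex = character(), is_birth_entry = logical(),
                      resident = logical())
  }
  # keep only stays overlapping the window
  keep <- (is.na(ani$exit) | ani$exit > w0) & ani$entry < w1
  ani <- ani[keep]
  n <- nrow(ani)

  if (n) {
    ani[, animal_id := sprintf("%s_a%05d", farm_id, seq_len(n))]
    ani[, breed_category := sample(BREED_CATEGORIES, n, TRUE, prob = breed_p)]
    ani[, origin_farm_id := NA_character_]
    ani[!(is_birth_entry), origin_farm_id :=
          src_ids[runif_int(sum(!is_birth_entry), 1L, K_src)]]
    born_home <- ani$is_birth_entry
    at_origin <- !born_home & runif(n) < profile$born_at_origin_prob
    ani[, birth_farm_id := fifelse(born_home, farm_id,
                                   fifelse(at_origin, origin_farm_id,
                                           sprintf("EB%s_%04d", farm_id,
                                                   seq_len(n))))]
    # exit mode by age class at exit
    exit_age <- ani$exit - ani$birth
    grp <- age_group_d(exit_age)
    em <- rep("none", n)
    closed <- !is.na(ani$exit) & ani$exit < w1
    for (g in c("calf", "young", "adult")) {
      idx <- which(closed & grp == g)
      if (length(idx)) {
        em[idx] <- sample(c("slaughter", "move_out", "death"), length(idx),
                          TRUE, prob = exit_mix_farm[[g]])
      }
    }
    # some sold animals pass through in 10 days or fewer
    short <- which(em == "move_out" & !ani$resident &
                     runif(n) < profile$short_stay_prob)
    if (length(short)) {
      newex <- ani$entry[short] + runif_int(length(short), 1L, 10L)
      ani[short, exit := pmin(exit, newex)]
    }
    ani[, exit_mode := em]
    ani[exit_mode == "none", exit := NA_integer_]
    ani[, destination_farm_id := NA_character_]
    mo <- which(em == "move_out")
    if (length(mo)) {
      dest <- dst_ids[runif_int(length(mo), 1L, K_dst)]
      can_ret <- ani$birth_farm_id[mo] != farm_id
      ret <- can_ret & runif(length(mo)) < ret_p
      dest[ret] <- ani$birth_farm_id[mo][ret]
      ani[mo, destination_farm_id := dest]
    }
  }

  # calvings from adult females
  calvings <- data.table(animal_id = character(), date = integer(),
                         stillbirth = logical())
  if (n && profile$calving_rate > 0) {
    fa <- which(ani$sex == "female" &
                  (ifelse(is.na(ani$exit), w1, ani$exit) - ani$birth) >
                  AGE_ADULT_D)
    for (i in fa) {
      b <- ani$birth[i]; en <- ani$entry[i]
      ex <- if (is.na(ani$exit[i])) w1 else min(ani$exit[i], w1)
      adult_from <- max(en, b + 740L, w0)
      cdates <- integer()
      if (runif(1) < profile$calved_at_entry_prob) {
        hist_d <- max(b + 730L, en - runif_int(1, 30L, 400L))
        if (hist_d < en) cdates <- hist_d
      }
      span <- ex - adult_from
      if (span > 0) {
        k <- rpois(1, profile$calving_rate * span / 365)
        if (k > 0) {
          dts <- sort(adult_from + runif_int(k, 0L, span - 1L))
          # at least ~9 months between calvings
          dts <- dts[c(TRUE, diff(dts) > 270L)]
          cdates <- c(cdates, dts)
        }
      }
      if (length(cdates)) {
        calvings <- rbind(calvings, data.table(
          animal_id = ani$animal_id[i], date = as.integer(cdates),
          stillbirth = runif(length(cdates)) < profile$stillbirth_prob))
      }
    }
  }

  milk <- data.table(farm_id = character(), date = integer())
  if (has_milk) {
    for (y in years) {
      y0 <- as.integer(as.Date(sprintf("%d-01-01", y)))
      k <- 1L + rpois(1, max(profile$milk_tests_per_year - 1, 0))
      milk <- rbind(milk, data.table(
        farm_id = farm_id, date = y0 + sort(runif_int(k, 0L, year_len(y) - 1L))))
    }
  }

  rx <- data.table(farm_id = character(), date = integer(),
                   usage_category = character())
  for (y in years) {
    if (runif(1) < profile$rx$zero_prob) next
    k <- rpois(1, profile$rx$rate)
    if (k > 0) {
      y0 <- as.integer(as.Date(sprintf("%d-01-01", y)))
      rx <- rbind(rx, data.table(
        farm_id = farm_id, date = y0 + sort(runif_int(k, 0L, year_len(y) - 1L)),
        usage_category = sample(USAGE_CATEGORIES, k, TRUE, prob = rx_mix)))
    }
  }

  animals <- if (n) data.table(
    animal_id = ani$animal_id, birth_date = ani$birth, sex = ani$sex,
    breed_category = ani$breed_category, birth_farm_id = ani$birth_farm_id
  ) else data.table(animal_id = character(), birth_date = integer(),
                    sex = character(), breed_category = character(),
                    birth_farm_id = character())
  stays <- if (n) data.table(
    animal_id = ani$animal_id, farm_id = farm_id, entry_date = ani$entry,
    exit_date = ani$exit,
    entry_mode = fifelse(ani$is_birth_entry, "birth", "move_in"),
    exit_mode = ani$exit_mode, origin_farm_id = ani$origin_farm_id,
    destination_farm_id = ani$destination_farm_id
  ) else data.table(animal_id = character(), farm_id = character(),
                    entry_date = integer(), exit_date = integer(),
                    entry_mode = character(), exit_mode = character(),
                    origin_farm_id = character(),
                    destination_farm_id = character())
  list(animals = animals, stays = stays, calvings = calvings,
       milk_tests = milk, prescriptions = rx)
}

gen_resident <- function(rc, sex, days_py, years, w0, w1) {
  slots <- days_py / 365
  n_full <- floor(slots)
  frac <- slots - n_full
  ten <- unlist(rc$tenure_years)
  tmin <- as.integer(ten[1] * 365)
  tmax <- as.integer(ten[2] * 365)
  eam <- unlist(rc$entry_age_months)
  rows <- list()
  add <- function(entry, exit, birth) {
    rows[[length(rows) + 1L]] <<- data.table(
      entry = as.integer(entry), exit = as.integer(exit),
      birth = as.integer(birth), sex = sex,
      is_birth_entry = FALSE, resident = TRUE)
  }
  for (s in seq_len(n_full)) {
    t <- w0 - runif_int(1, 0L, tmax)
    while (t < w1) {
      ten <- runif_int(1, tmin, tmax)
      entry <- t
      exit <- entry + ten
      if (exit > w0 - 30L) {
        age_m <- runif(1, eam[1], eam[2])
        birth <- entry - as.integer(round(age_m * 30.437))
        add(entry, exit, birth)
      }
      t <- exit + runif_int(1, 5L, 60L)
    }
  }
  if (frac > 0.01) {
    for (y in years) {
      y0 <- as.integer(as.Date(sprintf("%d-01-01", y)))
      yl <- year_len(y)
      d <- as.integer(round(frac * yl))
      if (d >= 5L) {
        entry <- y0 + runif_int(1, 0L, yl - d)
        age_m <- runif(1, eam[1], eam[2])
        add(entry, entry + d, entry - as.integer(round(age_m * 30.437)))
      }
    }
  }
  rbindlist(rows)
}

gen_throughput <- function(rc, sex, days_py, years, w0, w1, profile) {
  ea <- as.integer(unlist(rc$entry_age))
  comps <- rc$exit_age
  base_w <- vapply(comps, function(cp) cp$w, numeric(1))
  wts <- if (length(base_w) > 1) rdirichlet1(6 * base_w) else 1
  lo <- vapply(comps, function(cp) unlist(cp$range)[1], numeric(1))
  hi <- vapply(comps, function(cp) unlist(cp$range)[2], numeric(1))
  mean_exit <- sum(wts * (lo + hi) / 2)
  mean_entry <- if (rc$birth_frac >= 1) 0 else mean(ea)
  mean_entry <- (1 - rc$birth_frac) * mean_entry
  mean_stay <- max(30, mean_exit - mean_entry)
  n_py <- days_py / mean_stay
  n_back <- min(2L, as.integer(ceiling((max(hi) - min(c(ea[1], 0))) / 365)))
  gen_years <- (years[1] - n_back):years[length(years)]
  rows <- list()
  for (g in gen_years) {
    g0 <- as.integer(as.Date(sprintf("%d-01-01", g)))
    yl <- year_len(g)
    ng <- floor(n_py) + (runif(1) < (n_py - floor(n_py)))
    if (ng < 1) next
    entry <- g0 + runif_int(ng, 0L, yl - 1L)
    is_birth <- runif(ng) < rc$birth_frac
    entry_age <- ifelse(is_birth, 0L, runif_int(ng, ea[1], ea[2]))
    comp <- if (length(wts) > 1) sample.int(length(wts), ng, TRUE, prob = wts)
            else rep(1L, ng)
    exit_age <- runif_int(ng, lo[comp], hi[comp])
    exit_age <- pmax(exit_age, entry_age + 7L)
    birth <- entry - as.integer(entry_age)
    rows[[length(rows) + 1L]] <- data.table(
      entry = entry, exit = as.integer(birth + exit_age), birth = birth,
      sex = sex, is_birth_entry = is_birth, resident = FALSE)
  }
  rbindlist(rows)
}

#' Simulate one farm-year as a partial registry
#'
#' Generates animals, stays, calvings, milk tests and prescriptions for a
#' single farm over one calendar year, consistent with the profile, and
#' returns them as a validated `linked_registry` (with a one-row farm
#' table).
#'
#' @param profile A `type_profile`.
#' @param farm_id Farm identifier.
#' @param year Calendar year.
#' @param seed Integer seed.
#' @return A `linked_registry`.
#' @export
simulate_farm_year <- function(profile, farm_id, year, seed = 1L) {
  ev <- simulate_farm_events(profile, farm_id, year, seed)
  assemble_registry(list(ev), farm_ids = farm_id)
}

# convert integer-date event tables to a validated linked_registry
assemble_registry <- function(event_list, farm_ids,
                              facility = "standard") {
  tabs <- list()
  date_cols <- list(animals = "birth_date",
                    stays = c("entry_date", "exit_date"),
                    calvings = "date", milk_tests = "date",
                    prescriptions = "date")
  for (tb in names(date_cols)) {
    dt <- rbindlist(lapply(event_list, `[[`, tb), use.names = TRUE)
    if (nrow(dt)) {
      for (cl in date_cols[[tb]]) {
        set(dt, j = cl, value = as.Date(dt[[cl]], origin = "1970-01-01"))
      }
      tabs[[tb]] <- dt
    } else {
      tabs[tb] <- list(NULL)
    }
  }
  farms <- data.table(farm_id = as.character(farm_ids))
  farms[, facility_type := rep(facility, length.out = .N)]
  linked_registry(animals = tabs$animals, stays = tabs$stays,
                  calvings = tabs$calvings, milk_tests = tabs$milk_tests,
                  prescriptions = tabs$prescriptions, farms = farms)
}

#' Simulate a labeled multi-farm dataset
#'
#' Unions per-farm simulations over farms and years for every production
#' type in the configuration and returns the registry together with one
#' label per farm. The same seed yields byte-identical output.
#'
#' @param config A [sim_config()].
#' @return A list with `registry` (a `linked_registry`) and `labels`
#'   (`data.table` with `farm_id`, `production_type`).
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  prefixes <- c(calf_fattening = "CF", dairy_cow = "DC",
                cattle_fattening = "CT", rearing_cattle = "RC",
                suckler_cow = "SC")
  events <- list()
  labels <- list()
  farm_ids <- character()
  gi <- 0L
  for (tp in production_types()) {
    n <- config$n_farms_per_type[[tp]]
    if (n == 0L) next
    profile <- config$profiles[[tp]]
    for (i in seq_len(n)) {
      gi <- gi + 1L
      fid <- sprintf("%s%05d", prefixes[[tp]], i)
      fseed <- (config$seed + 131071 * gi) %% 2147483647L
      yrs <- config$years
      ev <- NULL
      if (config$ineligible_first_year_prob > 0 && length(yrs) > 1) {
        set.seed((fseed + 7L) %% 2147483647L)
        if (runif(1) < config$ineligible_first_year_prob) {
          # marginal first year: a handful of stays below the eligibility
          # threshold, then full simulation from the second year on
          ev_small <- small_farm_year(fid, yrs[1], fseed)
          ev_main <- simulate_farm_events(profile, fid, yrs[-1], fseed)
          ev <- Map(rbind, ev_small, ev_main)
        }
      }
      if (is.null(ev)) ev <- simulate_farm_events(profile, fid, yrs, fseed)
      events[[gi]] <- ev
      labels[[gi]] <- data.table(farm_id = fid, production_type = tp)
      farm_ids <- c(farm_ids, fid)
    }
  }
  registry <- assemble_registry(events, farm_ids = farm_ids)
  list(registry = registry,
       labels = if (length(labels)) rbindlist(labels) else
         data.table(farm_id = character(), production_type = character()))
}

# fewer than 10 stays in one year, used to exercise the eligibility filter
small_farm_year <- function(farm_id, year, seed) {
  set.seed((seed + 13L) %% 2147483647L)
  y0 <- as.integer(as.Date(sprintf("%d-01-01", year)))
  yl <- year_len(year)
  k <- runif_int(1, 3L, 7L)
  entry <- y0 + runif_int(k, 0L, yl - 220L)
  stay <- runif_int(k, 30L, 200L)
  ids <- sprintf("%s_s%03d", farm_id, seq_len(k))
  list(
    animals = data.table(animal_id = ids, birth_date = entry - 500L,
                         sex = sample(SEXES, k, TRUE),
                         breed_category = sample(BREED_CATEGORIES, k, TRUE),
                         birth_farm_id = sprintf("EB%s_s%02d", farm_id,
                                                 seq_len(k))),
    stays = data.table(animal_id = ids, farm_id = farm_id,
                       entry_date = entry, exit_date = entry + stay,
                       entry_mode = "move_in", exit_mode = "move_out",
                       origin_farm_id = sprintf("ES%s_s%02d", farm_id,
                                                seq_len(k)),
                       destination_farm_id = sprintf("ED%s_s%02d", farm_id,
                                                     seq_len(k))),
    calvings = data.table(animal_id = character(), date = integer(),
                          stillbirth = logical()),
    milk_tests = data.table(farm_id = character(), date = integer()),
    prescriptions = data.table(farm_id = character(), date = integer(),
                               usage_category = character())
  )
}

#' Simulate a farm-year mixing two production types
#'
#' Emits a farm-year whose herd composition, movement and prescription
#' behaviour is a `weight`-mixture of two profiles (weight 1 reproduces
#' profile A in law, weight 0 profile B). Intended for robustness
#' experiments on mixed production types; not part of the default labeled
#' benchmark.
#'
#' @param profile_a,profile_b `type_profile`s.
#' @param weight Mixing weight in `[0, 1]` on `profile_a`.
#' @param farm_id,year,seed As in [simulate_farm_year()].
#' @return A `linked_registry`.
#' @export
inject_mixed_farm <- function(profile_a, profile_b, weight, farm_id, year,
                              seed = 1L) {
  stopifnot(weight >= 0, weight <= 1)
  simulate_farm_year(blend_profiles(profile_a, profile_b, weight),
                     farm_id, year, seed)
}

blend_profiles <- function(a, b, w) {
  mix_n <- function(x, y) w * x + (1 - w) * y
  p <- unclass(a)
  p$sideline <- NULL
  p$herd_size <- list(meanlog = mix_n(a$herd_size$meanlog, b$herd_size$meanlog),
                      sdlog = mix_n(a$herd_size$sdlog, b$herd_size$sdlog),
                      min = min(a$herd_size$min, b$herd_size$min),
                      max = max(a$herd_size$max, b$herd_size$max))
  am <- unlist(a$sexage_mix); bm <- unlist(b$sexage_mix)
  p$sexage_mix <- as.list(mix_n(am, bm))
  p$breed_mix <- as.list(mix_n(unlist(a$breed_mix), unlist(b$breed_mix)))
  p$rx <- a$rx
  p$rx$rate <- mix_n(a$rx$rate, b$rx$rate)
  p$rx$zero_prob <- mix_n(a$rx$zero_prob, b$rx$zero_prob)
  p$rx$concentration <- mix_n(a$rx$concentration, b$rx$concentration)
  p$rx$mix <- as.list(mix_n(unlist(a$rx$mix), unlist(b$rx$mix)))
  for (f in c("milk_test_prob", "calving_rate", "stillbirth_prob",
              "calved_at_entry_prob", "return_to_birth_prob",
              "short_stay_prob", "born_at_origin_prob",
              "mix_concentration", "breed_concentration",
              "return_concentration", "milk_tests_per_year")) {
    p[[f]] <- mix_n(a[[f]], b[[f]])
  }
  # each class keeps the residency pattern of the profile contributing the
  # larger share of its animal-days
  p$residency <- lapply(SEXAGE_CLASSES, function(cls) {
    if (w * am[[cls]] >= (1 - w) * bm[[cls]]) a$residency[[cls]]
    else b$residency[[cls]]
  })
  names(p$residency) <- SEXAGE_CLASSES
  p$exit_mix <- lapply(c(calf = "calf", young = "young", adult = "adult"),
                       function(g) as.list(mix_n(unlist(a$exit_mix[[g]]),
                                                 unlist(b$exit_mix[[g]]))))
  for (f in c("n_source_farms", "n_dest_farms")) {
    p[[f]] <- list(meanlog = mix_n(a[[f]]$meanlog, b[[f]]$meanlog),
                   sdlog = mix_n(a[[f]]$sdlog, b[[f]]$sdlog))
  }
  type_profile(a$production_type, p)
}
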