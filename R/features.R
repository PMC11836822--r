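# Farm-year feature extraction: eligibility filtering, the 24 features,
# dataset assembly and class-wise extreme-value exclusion.
#
# All ratio features use the convention that a zero denominator yields 0
# (never NaN), so the feature space is complete for farms without
# slaughter exits, out-moves or prescriptions.

year_bounds <- function(year) {
  c(as.Date(sprintf("%d-01-01", year)), as.Date(sprintf("%d-01-01", year + 1L)))
}

#' Eligible farms for a year
#'
#' A farm is eligible when it has at least 10 cattle stays overlapping the
#' year (regardless of stay length) and is registered as a standard
#' facility (alpine pasture facilities, veterinary clinics and cattle
#' markets are excluded).
#'
#' @param registry A `linked_registry`.
#' @param year Calendar year.
#' @param min_stays Minimum number of stays overlapping the year (default 10).
#' @return Character vector of eligible farm ids.
#' @export
filter_eligible <- function(registry, year, min_stays = 10L) {
  stopifnot(inherits(registry, "linked_registry"))
  yb <- year_bounds(year)
  st <- registry$stays
  overlap <- st$entry_date < yb[2] & (is.na(st$exit_date) | st$exit_date >= yb[1])
  cnt <- table(st$farm_id[overlap])
  ok <- names(cnt)[cnt >= min_stays]
  standard <- registry$farms$farm_id[registry$farms$facility_type == "standard"]
  sort(intersect(ok, standard))
}

# first calving date per animal (lifetime; an animal counts as "calved"
# from its first recorded calving onwards)
first_calving <- function(registry) {
  cv <- registry$calvings
  if (!nrow(cv)) {
    return(data.table(animal_id = character(), first_calving = as.Date(character())))
  }
  cv[, .(first_calving = min(date)), by = animal_id]
}

#' Extract the 24 features for every farm-year
#'
#' Bulk engine behind [extract_features()] and [build_dataset()]: computes
#' the full feature vector for each requested farm and year in one pass.
#'
#' @param registry A `linked_registry`.
#' @param years Integer vector of calendar years.
#' @param farm_ids Farms to evaluate; default all farms in the farm table.
#' @param check_eligible If `TRUE`, restrict to farms passing
#'   [filter_eligible()] in each year.
#' @return A `data.table` with `farm_id`, `year`, the 24 feature columns and
#'   `total_animal_days`.
#' @export
extract_features_all <- function(registry, years, farm_ids = NULL,
                                 check_eligible = TRUE) {
  stopifnot(inherits(registry, "linked_registry"))
  years <- as.integer(years)
  an <- registry$animals
  st <- copy(registry$stays)
  idx <- match(st$animal_id, an$animal_id)
  st[, `:=`(birth_date = an$birth_date[idx], sex = an$sex[idx],
            breed_category = an$breed_category[idx],
            birth_farm_id = an$birth_farm_id[idx])]
  fc <- first_calving(registry)
  st[, first_calving := fc$first_calving[match(animal_id, fc$animal_id)]]
  tr <- age_transition_dates(st$birth_date)
  st[, `:=`(t7 = as.integer(tr$young), t25 = as.integer(tr$adult))]

  res <- vector("list", length(years))
  for (k in seq_along(years)) {
    yr <- years[k]
    fids <- if (is.null(farm_ids)) sort(unique(registry$farms$farm_id)) else
      as.character(farm_ids)
    if (check_eligible) fids <- intersect(fids, filter_eligible(registry, yr))
    if (!length(fids)) next
    res[[k]] <- extract_year(registry, st, yr, fids)
  }
  out <- rbindlist(res, use.names = TRUE)
  if (!nrow(out)) {
    out <- data.table(farm_id = character(), year = integer())
    for (f in feature_names()) out[, (f) := numeric()]
    out[, total_animal_days := numeric()]
  }
  out[]
}

# one year, vectorized over farms
extract_year <- function(registry, st, yr, fids) {
  yb <- year_bounds(yr)
  y0 <- as.integer(yb[1]); y1 <- as.integer(yb[2])
  ss <- st[farm_id %chin% fids]
  en <- as.integer(ss$entry_date)
  ex <- as.integer(ss$exit_date)
  ex_open <- is.na(ex)
  ex_full <- ifelse(ex_open, .Machine$integer.max, ex)
  s <- pmax(en, y0); e <- pmin(ex_full, y1)
  keep <- e > s | (en < y1 & (ex_open | ex >= y0))  # day-contributing or overlapping
  ss <- ss[keep]; en <- en[keep]; ex <- ex[keep]; ex_full <- ex_full[keep]
  s <- s[keep]; e <- e[keep]

  tot <- pmax(0L, e - s)
  calf <- .days_in(s, e, -.Machine$integer.max, ss$t7)
  young <- .days_in(s, e, ss$t7, ss$t25)
  adult <- .days_in(s, e, ss$t25, .Machine$integer.max)
  fcal <- as.integer(ss$first_calving)
  fcal[is.na(fcal)] <- .Machine$integer.max
  calved <- .days_in(s, e, fcal, .Machine$integer.max)

  dd <- data.table(farm_id = ss$farm_id, animal_id = ss$animal_id,
                   sex = ss$sex, breed = ss$breed_category, tot = tot,
                   calf = calf, young = young, adult = adult, calved = calved)
  days <- dd[, .(
    female_calf = sum(calf[sex == "female"]),
    male_calf = sum(calf[sex == "male"]),
    female_young = sum(young[sex == "female"]),
    male_young = sum(young[sex == "male"]),
    female_adult = sum(adult[sex == "female"]),
    male_adult = sum(adult[sex == "male"]),
    dairy_days = sum(tot[breed == "dairy"]),
    beef_days = sum(tot[breed == "beef"]),
    dual_days = sum(tot[breed == "dual_purpose"]),
    calved_days = sum(calved),
    n_animals = uniqueN(animal_id[tot > 0L]),
    total_days = sum(tot)
  ), by = farm_id]

  # exits within the year
  exit_in_year <- !is.na(ss$exit_date) & ex >= y0 & ex < y1
  sl <- exit_in_year & ss$exit_mode == "slaughter"
  mo <- exit_in_year & ss$exit_mode == "move_out"
  exit_class <- fifelse(ex < ss$t7, "calf", fifelse(ex < ss$t25, "young", "adult"))
  stay_len <- ex - en
  ret <- mo & !is.na(ss$destination_farm_id) & !is.na(ss$birth_farm_id) &
    ss$destination_farm_id == ss$birth_farm_id
  ev <- data.table(farm_id = ss$farm_id, sl = sl, mo = mo,
                   exit_class = exit_class, stay_len = stay_len, ret = ret,
                   dest = ss$destination_farm_id)
  exits <- ev[, .(
    sl_total = sum(sl),
    sl_calves = sum(sl & exit_class == "calf"),
    sl_young = sum(sl & exit_class == "young"),
    sl_adults = sum(sl & exit_class == "adult"),
    out_moves = sum(mo),
    out_returns = sum(ret),
    out_short = sum(mo & stay_len <= 10L),
    out_degree = uniqueN(dest[mo])
  ), by = farm_id]

  # arrivals within the year
  arr <- ss$entry_mode == "move_in" & en >= y0 & en < y1
  av <- data.table(farm_id = ss$farm_id[arr], origin = ss$origin_farm_id[arr])
  arrivals <- av[, .(in_degree = uniqueN(origin)), by = farm_id]

  # calvings on the farm in the year: a calving belongs to the farm where
  # the dam was present on the calving date
  cv <- registry$calvings
  births <- NULL
  if (nrow(cv)) {
    cvd <- as.integer(cv$date)
    in_yr <- cvd >= y0 & cvd < y1
    if (any(in_yr)) {
      cvy <- data.table(animal_id = cv$animal_id[in_yr], d = cvd[in_yr])
      sty <- data.table(animal_id = ss$animal_id, farm_id = ss$farm_id,
                        en = en, ex = ex_full)
      m <- sty[cvy, on = .(animal_id, en <= d, ex > d), nomatch = NULL,
               .(farm_id = x.farm_id)]
      if (nrow(m)) births <- m[, .(n_births = .N), by = farm_id]
    }
  }

  mt <- registry$milk_tests
  milk_farms <- unique(mt$farm_id[as.integer(mt$date) >= y0 &
                                    as.integer(mt$date) < y1])
  rx <- registry$prescriptions
  rx_in <- as.integer(rx$date) >= y0 & as.integer(rx$date) < y1
  rxy <- data.table(farm_id = rx$farm_id[rx_in],
                    usage_category = rx$usage_category[rx_in])
  rx_tab <- rxy[, .(
    rx_total = .N,
    rx_rearing = sum(usage_category == "rearing"),
    rx_fat_calves = sum(usage_category == "fattening_calves"),
    rx_fat_young = sum(usage_category == "fattening_young"),
    rx_milk = sum(usage_category == "milk_cow"),
    rx_suckling = sum(usage_category == "suckling")
  ), by = farm_id]

  out <- data.table(farm_id = fids, year = yr)
  j <- function(tbl, col, default = 0) {
    if (is.null(tbl)) return(rep(default, length(fids)))
    v <- tbl[[col]][match(fids, tbl$farm_id)]
    v[is.na(v)] <- default
    v
  }
  td <- j(days, "total_days")
  ratio <- function(num, den) fifelse(den > 0, num / den, 0)
  out[, hasMilk := as.numeric(fids %chin% milk_farms)]
  out[, pFemaleCalves := ratio(j(days, "female_calf"), td)]
  out[, pMaleCalves := ratio(j(days, "male_calf"), td)]
  out[, pFemaleYoung := ratio(j(days, "female_young"), td)]
  out[, pMaleYoung := ratio(j(days, "male_young"), td)]
  out[, pFemaleAdults := ratio(j(days, "female_adult"), td)]
  out[, pMaleAdults := ratio(j(days, "male_adult"), td)]
  out[, pDairyBreed := ratio(j(days, "dairy_days"), td)]
  out[, pBeefBreed := ratio(j(days, "beef_days"), td)]
  out[, pDoubleBreed := ratio(j(days, "dual_days"), td)]
  out[, pCalvedAnimals := ratio(j(days, "calved_days"), td)]
  out[, pBirths := ratio(j(births, "n_births"), j(days, "n_animals"))]
  slt <- j(exits, "sl_total")
  out[, pOutMovesToSLCalves := ratio(j(exits, "sl_calves"), slt)]
  out[, pOutMovesToSLYoung := ratio(j(exits, "sl_young"), slt)]
  out[, pOutMovesToSLAdults := ratio(j(exits, "sl_adults"), slt)]
  om <- j(exits, "out_moves")
  out[, pOutMovesToBirthHerd := ratio(j(exits, "out_returns"), om)]
  out[, inDegree := log1p(j(arrivals, "in_degree"))]
  out[, outDegree := log1p(j(exits, "out_degree"))]
  out[, pAnimals10Days := ratio(j(exits, "out_short"), om)]
  rxt <- j(rx_tab, "rx_total")
  out[, pABRearing := pmin(1, ratio(j(rx_tab, "rx_rearing"), rxt))]
  out[, pABFatteningCalves := pmin(1, ratio(j(rx_tab, "rx_fat_calves"), rxt))]
  out[, pABFatteningYoung := pmin(1, ratio(j(rx_tab, "rx_fat_young"), rxt))]
  out[, pABMilkCow := pmin(1, ratio(j(rx_tab, "rx_milk"), rxt))]
  out[, pABSuckling := pmin(1, ratio(j(rx_tab, "rx_suckling"), rxt))]
  out[, total_animal_days := td]
  out
}

#' Extract the 24 features for one farm-year
#'
#' @param registry A `linked_registry`.
#' @param farm_id Single farm id (should have passed [filter_eligible()]).
#' @param year Calendar year.
#' @return One-row `data.table` of the 24 features plus `farm_id`, `year`
#'   and `total_animal_days`.
#' @export
extract_features <- function(registry, farm_id, year) {
  stopifnot(length(farm_id) == 1L)
  extract_features_all(registry, year, farm_ids = farm_id,
                       check_eligible = FALSE)
}

#' Flag and drop class-wise extreme farm observations
#'
#' Within each labeled production type, a row is flagged when any numeric
#' feature lies outside the fence `[Q1 - 3 IQR, Q3 + 3 IQR]` of that
#' feature's within-class distribution. Flagged rows are removed from the
#' returned matrix; the binary `hasMilk` indicator is not fenced.
#'
#' @param matrix A labeled feature matrix (column `production_type`).
#' @param k Fence multiplier (default 3).
#' @return A list with `matrix` (rows kept) and `flagged` (rows removed,
#'   with a `flag_reason` column naming the first offending feature).
#' @export
exclude_extreme <- function(matrix, k = 3) {
  dt <- as.data.table(matrix)
  stopifnot("production_type" %in% names(dt))
  feats <- intersect(feature_names(numeric_only = TRUE), names(dt))
  flagged <- rep(FALSE, nrow(dt))
  reason <- rep(NA_character_, nrow(dt))
  for (cls in unique(dt$production_type)) {
    rows <- which(dt$production_type == cls)
    for (f in feats) {
      v <- dt[[f]][rows]
      q <- quantile(v, c(0.25, 0.75), names = FALSE, type = 7)
      iqr <- q[2] - q[1]
      # a zero within-class IQR degenerates the fence to a point; such
      # features (typically all-zero ratios) are not fenced
      if (iqr <= 0) next
      bad <- v < q[1] - k * iqr | v > q[2] + k * iqr
      newly <- rows[bad & !flagged[rows]]
      reason[newly] <- f
      flagged[rows[bad]] <- TRUE
    }
  }
  list(matrix = dt[!flagged],
       flagged = cbind(dt[flagged], flag_reason = reason[flagged]))
}

#' Assemble the labeled feature matrix
#'
#' One row per labeled farm per year in which the farm is eligible and has
#' at least one animal-day; rows of the same farm share the group key
#' `farm_id`. Class-wise extreme-value exclusion is applied last.
#'
#' @param registry A `linked_registry`.
#' @param labels `data.table`/data.frame with columns `farm_id`,
#'   `production_type`.
#' @param years Integer vector of calendar years.
#' @param exclude_extremes Apply [exclude_extreme()] (default `TRUE`).
#' @return A `data.table` feature matrix with `farm_id`, `year`, the 24
#'   features and `production_type`. Attribute `"flagged"` carries the
#'   excluded rows.
#' @export
build_dataset <- function(registry, labels, years, exclude_extremes = TRUE) {
  labels <- as.data.table(labels)
  stopifnot(all(c("farm_id", "production_type") %in% names(labels)))
  bad <- !(labels$production_type %chin% production_types())
  if (any(bad)) {
    stop("build_dataset: unknown production_type: ",
         paste(unique(labels$production_type[bad]), collapse = ", "),
         call. = FALSE)
  }
  unknown <- setdiff(labels$farm_id, registry$farms$farm_id)
  if (length(unknown)) {
    warning("build_dataset: skipping label(s) for unknown farm(s): ",
            paste(head(unknown, 5), collapse = ", "),
            if (length(unknown) > 5) " ...")
    labels <- labels[!(farm_id %chin% unknown)]
  }
  fx <- extract_features_all(registry, years, farm_ids = labels$farm_id,
                             check_eligible = TRUE)
  fx <- fx[total_animal_days > 0]
  fx[, production_type := labels$production_type[match(farm_id, labels$farm_id)]]
  fx[, total_animal_days := NULL]
  flagged <- NULL
  if (exclude_extremes && nrow(fx)) {
    ex <- exclude_extreme(fx)
    fx <- ex$matrix
    flagged <- ex$flagged
  }
  setattr(fx, "flagged", flagged)
  fx[]
}
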