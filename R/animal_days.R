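# Animal-day accounting.
#
# Age classes are defined by completed calendar months: calf = completed
# months 0-6, young = 7-24, adult = >= 25. An animal changes class on the
# monthly anniversary of its birth date, with month-end clamping (an animal
# born on Jan 31 completes its first month on Feb 28/29). Presence is
# counted over half-open intervals [entry, exit) clipped to the calendar
# year, so a within-year transfer never double-counts a day and a stay with
# entry == exit contributes zero days.

#' Age-class transition dates for a birth date
#'
#' @param birth_date `Date` vector.
#' @return A list with `young` (date the animal completes month 7 and
#'   becomes young) and `adult` (date it completes month 25 and becomes
#'   adult), month-end clamped.
#' @export
age_transition_dates <- function(birth_date) {
  list(young = birth_date %m+% months(7),
       adult = birth_date %m+% months(25))
}

# number of days of [s, e) (integer dates, half-open) falling in [lo, hi)
.days_in <- function(s, e, lo, hi) {
  pmax(0L, pmin(e, hi) - pmax(s, lo))
}

# Internal engine: per-stay day counts split by age class for one year.
# stays_dt must carry entry_date, exit_date (Date, NA = open), birth_date,
# plus any id columns; returns integer columns calf_days, young_days,
# adult_days, total_days for the given year.
split_stay_days <- function(entry, exit, birth, year) {
  y0 <- as.integer(as.Date(sprintf("%d-01-01", year)))
  y1 <- as.integer(as.Date(sprintf("%d-01-01", year + 1L)))
  tr <- age_transition_dates(birth)
  t7 <- as.integer(tr$young)
  t25 <- as.integer(tr$adult)
  s <- pmax(as.integer(entry), y0)
  e_raw <- as.integer(exit)
  e_raw[is.na(e_raw)] <- .Machine$integer.max  # open stay: still present
  e <- pmin(e_raw, y1)
  tot <- pmax(0L, e - s)
  calf <- .days_in(s, e, -.Machine$integer.max, t7)
  young <- .days_in(s, e, t7, t25)
  adult <- .days_in(s, e, t25, .Machine$integer.max)
  list(calf = calf, young = young, adult = adult, total = tot)
}

#' Animal-day partition for one farm and year
#'
#' Clips every stay on the farm to the calendar year and partitions the
#' resulting presence days by the animal's sex and age class, with the age
#' class changing on the completed-month anniversaries of the birth date.
#'
#' @param registry A `linked_registry`.
#' @param farm_id Single farm identifier.
#' @param year Calendar year (integer).
#' @return A one-row `data.table` with columns `farm_id`, `year`, the six
#'   class day counts (`female_calf`, `male_calf`, `female_young`,
#'   `male_young`, `female_adult`, `male_adult`) and `total_animal_days`.
#'   The six class counts sum to `total_animal_days` exactly.
#' @export
animal_days <- function(registry, farm_id, year) {
  stopifnot(inherits(registry, "linked_registry"), length(farm_id) == 1L)
  sel <- registry$stays$farm_id == farm_id
  st <- registry$stays[sel]
  out <- data.table(farm_id = farm_id, year = as.integer(year))
  for (cl in SEXAGE_CLASSES) out[, (cl) := 0L]
  out[, total_animal_days := 0L]
  if (!nrow(st)) return(out)
  if (any(!is.na(st$exit_date) & st$entry_date > st$exit_date)) {
    stop("animal_days: stay with entry after exit", call. = FALSE)
  }
  an <- registry$animals
  idx <- match(st$animal_id, an$animal_id)
  sp <- split_stay_days(st$entry_date, st$exit_date, an$birth_date[idx],
                        as.integer(year))
  sex <- an$sex[idx]
  for (s in SEXES) {
    w <- sex == s
    out[[paste0(s, "_calf")]] <- sum(sp$calf[w])
    out[[paste0(s, "_young")]] <- sum(sp$young[w])
    out[[paste0(s, "_adult")]] <- sum(sp$adult[w])
  }
  out$total_animal_days <- sum(sp$total)
  out
}
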