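# Production-type profiles.
#
# A TypeProfile bundles every parameter the event-level simulator needs for
# one production type: the herd-size law, the target day-share mix over the
# six sex-by-age classes, breed composition, milk testing, calving,
# residency patterns (which classes are long-term residents vs throughput
# animals and their entry/exit age laws), exit-mode mixes, movement pools
# and antibiotic prescription behaviour. The shipped default profiles are a
# versioned calibration file: their constants were fitted so that feature
# distributions extracted from large simulations reproduce the published
# per-type summary statistics.

#' Load the default production-type profiles
#'
#' Reads the versioned calibration file shipped with the package
#' (`inst/extdata/default_profiles.yaml`) and returns one validated
#' `type_profile` per production type.
#'
#' @param path Optional path to an alternative profile YAML.
#' @return Named list of five `type_profile` objects.
#' @export
default_profiles <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "default_profiles.yaml",
                        package = "cattletype", mustWork = TRUE)
  }
  raw <- yaml::read_yaml(path)
  out <- lapply(names(raw), function(tp) type_profile(tp, raw[[tp]]))
  names(out) <- names(raw)
  stopifnot(setequal(names(out), production_types()))
  out[production_types()]
}

normalize_shares <- function(x, what) {
  v <- unlist(x)
  if (any(v < 0)) stop("negative share in ", what, call. = FALSE)
  s <- sum(v)
  if (s <= 0) stop("shares sum to zero in ", what, call. = FALSE)
  as.list(v / s)
}

#' Construct and validate a type profile
#'
#' @param production_type One of [production_types()].
#' @param params Named list of simulator parameters (see the shipped YAML
#'   for the schema).
#' @return A `type_profile` object.
#' @export
type_profile <- function(production_type, params) {
  stopifnot(production_type %in% production_types())
  p <- params
  p$production_type <- production_type
  p$sexage_mix <- normalize_shares(p$sexage_mix[SEXAGE_CLASSES], "sexage_mix")
  names(p$sexage_mix) <- SEXAGE_CLASSES
  p$breed_mix <- normalize_shares(p$breed_mix[BREED_CATEGORIES], "breed_mix")
  names(p$breed_mix) <- BREED_CATEGORIES
  p$rx$mix <- normalize_shares(p$rx$mix[USAGE_CATEGORIES], "rx$mix")
  names(p$rx$mix) <- USAGE_CATEGORIES
  if (!is.null(p$sideline)) {
    p$sideline$mix <- normalize_shares(p$sideline$mix[SEXAGE_CLASSES],
                                       "sideline$mix")
    names(p$sideline$mix) <- SEXAGE_CLASSES
  }
  # derived summary: share of slaughter exits expected per age class,
  # induced by the per-class exit-age mixtures (kept on the object so the
  # slaughter-age composition is inspectable)
  probs <- c(milk_test_prob = p$milk_test_prob,
             return_to_birth_prob = p$return_to_birth_prob,
             short_stay_prob = p$short_stay_prob,
             born_at_origin_prob = p$born_at_origin_prob)
  if (any(probs < 0 | probs > 1)) {
    stop("probability outside [0, 1] in profile ", production_type,
         call. = FALSE)
  }
  if (p$calving_rate < 0 || p$rx$rate < 0) {
    stop("negative rate in profile ", production_type, call. = FALSE)
  }
  structure(p, class = "type_profile")
}

#' @export
print.type_profile <- function(x, ...) {
  cat(sprintf("<type_profile: %s>\n", x$production_type))
  cat("  herd size: lognormal(meanlog=", round(x$herd_size$meanlog, 3),
      ", sdlog=", x$herd_size$sdlog, ")\n", sep = "")
  cat("  sexage mix:",
      paste(sprintf("%s=%.3f", names(x$sexage_mix), unlist(x$sexage_mix)),
            collapse = " "), "\n")
  cat(sprintf("  milk_test_prob=%.3f calving_rate=%.2f rx_rate=%.2f\n",
              x$milk_test_prob, x$calving_rate, x$rx$rate))
  invisible(x)
}

#' Simulation configuration
#'
#' @param n_farms_per_type Named integer vector (names from
#'   [production_types()]); types omitted default to 0.
#' @param years Integer vector of calendar years to simulate.
#' @param seed Integer master seed.
#' @param profiles Named list of `type_profile`s; defaults to
#'   [default_profiles()].
#' @param ineligible_first_year_prob Probability that a farm's first year is
#'   emitted as a marginal under-threshold year (fewer than 10 stays), to
#'   exercise the eligibility filter; default 0.
#' @return A `sim_config` object.
#' @export
sim_config <- function(n_farms_per_type, years, seed = 1L, profiles = NULL,
                       ineligible_first_year_prob = 0) {
  if (is.null(profiles)) profiles <- default_profiles()
  n <- setNames(integer(length(production_types())), production_types())
  n[names(n_farms_per_type)] <- as.integer(n_farms_per_type)
  stopifnot(all(n >= 0), length(years) >= 1)
  structure(list(n_farms_per_type = n, years = sort(as.integer(years)),
                 seed = as.integer(seed), profiles = profiles,
                 ineligible_first_year_prob = ineligible_first_year_prob),
            class = "sim_config")
}

#' Default benchmark configuration
#'
#' Farm counts per type mirror the class composition of the reference
#' dataset (dairy dominating at roughly 43% of farms), over three calendar
#' years.
#'
#' @param seed Integer master seed.
#' @param years Years to simulate (default 2020:2022).
#' @param scale Multiplier on the per-type farm counts (default 1).
#' @return A `sim_config`.
#' @export
benchmark_config <- function(seed = 1L, years = 2020:2022, scale = 1) {
  n <- round(c(calf_fattening = 64, dairy_cow = 264, cattle_fattening = 76,
               rearing_cattle = 63, suckler_cow = 151) * scale)
  sim_config(n, years = years, seed = seed,
             ineligible_first_year_prob = 0.05)
}
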