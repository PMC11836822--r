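#' @import data.table
#' @importFrom lubridate %m+%
#' @importFrom ranger ranger treeInfo
#' @importFrom e1071 svm
#' @importFrom nnet nnet class.ind
#' @importFrom stats predict quantile median rnorm runif rpois rbinom rlnorm
#'   rgamma rbeta rexp glm binomial coef isoreg approx prcomp sd var
#'   setNames rmultinom
#' @importFrom utils head tail
#' @useDynLib cattletype, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Production type labels
#'
#' The five primary cattle production types, in the fixed (alphabetical)
#' class order used throughout the package for probability columns and
#' tie-breaking.
#'
#' @return Character vector of the five production-type tokens.
#' @export
production_types <- function() {
  c("calf_fattening", "cattle_fattening", "dairy_cow",
    "rearing_cattle", "suckler_cow")
}

#' Production types in reporting order
#'
#' Order used in classification output files (calf fattening, dairy,
#' cattle fattening, rearing, suckler).
#' @return Character vector of the five production-type tokens.
#' @export
production_types_report_order <- function() {
  c("calf_fattening", "dairy_cow", "cattle_fattening",
    "rearing_cattle", "suckler_cow")
}

# closed categorical sets for registry validation
SEXES <- c("female", "male")
BREED_CATEGORIES <- c("dairy", "beef", "dual_purpose", "other")
ENTRY_MODES <- c("birth", "move_in")
EXIT_MODES <- c("slaughter", "move_out", "death", "none")
USAGE_CATEGORIES <- c("rearing", "fattening_calves", "fattening_young",
                      "milk_cow", "suckling", "other")
FACILITY_TYPES <- c("standard", "alpine_pasture", "veterinary_clinic",
                    "cattle_market")

# six sex-by-age animal-day classes
SEXAGE_CLASSES <- c("female_calf", "male_calf", "female_young", "male_young",
                    "female_adult", "male_adult")

#' Names of the 24 farm-year features
#'
#' @param numeric_only If `TRUE`, drop the binary `hasMilk` indicator and
#'   return the 23 numerical features (the set used for PCA).
#' @return Character vector of feature names.
#' @export
feature_names <- function(numeric_only = FALSE) {
  nm <- c("hasMilk",
          "pFemaleCalves", "pMaleCalves", "pFemaleYoung", "pMaleYoung",
          "pFemaleAdults", "pMaleAdults",
          "pDairyBreed", "pBeefBreed", "pDoubleBreed",
          "pCalvedAnimals", "pBirths",
          "pOutMovesToSLCalves", "pOutMovesToSLYoung", "pOutMovesToSLAdults",
          "pOutMovesToBirthHerd", "inDegree", "outDegree", "pAnimals10Days",
          "pABRearing", "pABFatteningCalves", "pABFatteningYoung",
          "pABMilkCow", "pABSuckling")
  if (numeric_only) nm[nm != "hasMilk"] else nm
}
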