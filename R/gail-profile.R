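# Risk-factor profile for the Gail model --------------------------------------

#' Construct a Gail-model risk-factor profile
#'
#' Bundles the six classical risk factors of the model: current age, age at
#' menarche, age at first live birth, number of breast biopsies, history of
#' atypical hyperplasia, and number of first-degree relatives with breast
#' cancer, plus the race/ethnicity group that selects the constant block.
#' Unknown values are accepted for every factor and score as the baseline
#' category.
#'
#' @param current_age Integer age in years, 18-90.
#' @param age_at_menarche `"ge14"` (baseline), `"12to13"`, `"lt12"`, or
#'   `"unknown"`.
#' @param age_at_first_birth `"lt20"` (baseline), `"20to24"`,
#'   `"25to29_or_nulliparous"`, `"ge30"`, or `"unknown"`.
#' @param n_biopsies `"0"` (baseline), `"1"`, `"2plus"`, or `"unknown"`.
#'   Integers 0, 1, 2, ... are also accepted and folded into those categories.
#' @param atypical_hyperplasia `"absent"`, `"present"`, or `"unknown"`.
#'   `"present"` requires at least one biopsy.
#' @param n_relatives Number of first-degree relatives with breast cancer:
#'   `"0"`, `"1"`, `"2plus"`, `"unknown"`, or an integer.
#' @param race_group `"white"`, `"black"`, `"hispanic"`,
#'   `"asian_pacific_islander"`, or `"other"`.
#' @return An object of class `risk_factor_profile`.
#' @examples
#' risk_factor_profile(45, "12to13", "25to29_or_nulliparous", 1, "absent", 1)
#' @export
risk_factor_profile <- function(current_age,
                                age_at_menarche = "unknown",
                                age_at_first_birth = "unknown",
                                n_biopsies = "unknown",
                                atypical_hyperplasia = "unknown",
                                n_relatives = "unknown",
                                race_group = "other") {
  current_age <- validate_age(current_age, "current_age")
  age_at_menarche <- match.arg(age_at_menarche, .menarche_levels)
  age_at_first_birth <- match.arg(age_at_first_birth, .first_birth_levels)
  n_biopsies <- as_count_category(n_biopsies, "n_biopsies")
  n_relatives <- as_count_category(n_relatives, "n_relatives")
  atypical_hyperplasia <- match.arg(atypical_hyperplasia, .hyperplasia_levels)
  race_group <- match.arg(race_group, .race_groups)
  if (atypical_hyperplasia == "present" && n_biopsies == "0") {
    stop("atypical_hyperplasia = 'present' requires n_biopsies >= 1")
  }
  structure(
    list(current_age = current_age,
         age_at_menarche = age_at_menarche,
         age_at_first_birth = age_at_first_birth,
         n_biopsies = n_biopsies,
         atypical_hyperplasia = atypical_hyperplasia,
         n_relatives = n_relatives,
         race_group = race_group),
    class = "risk_factor_profile")
}

validate_age <- function(age, field) {
  if (length(age) != 1L || !is.finite(age)) {
    stop("field '", field, "': age must be a single finite number")
  }
  if (age < 18 || age > 90) {
    stop("field '", field, "': age ", age, " outside the supported range [18, 90]")
  }
  as.numeric(age)
}

as_count_category <- function(x, field) {
  if (is.numeric(x)) {
    if (is.na(x) || x < 0 || x != trunc(x)) {
      stop("field '", field, "': expected a non-negative integer count")
    }
    return(if (x >= 2) "2plus" else as.character(x))
  }
  match.arg(as.character(x), .count_levels)
}

#' Map a risk-factor profile to the model's category indices
#'
#' Each factor maps to exactly one category index, 0 being the baseline
#' category; `"unknown"` always maps to 0. The returned vector drives the
#' relative-risk linear predictor.
#'
#' @param profile A [risk_factor_profile()].
#' @return A named integer vector with elements `menarche` (0-2),
#'   `first_birth` (0-3), `biopsies` (0-2), `relatives` (0-2), and
#'   `hyperplasia` (0 = unknown/none of concern, 1 = present, 2 = biopsy with
#'   hyperplasia ruled out; selects the multiplier, not a coefficient).
#' @examples
#' p <- risk_factor_profile(45, "lt12", "ge30", 1, "absent", 1)
#' categorize_risk_factors(p)
#' @export
categorize_risk_factors <- function(profile) {
  stopifnot(inherits(profile, "risk_factor_profile"))
  idx0 <- function(x, levels) {
    i <- match(x, levels) - 1L
    if (x == "unknown") 0L else i
  }
  hyp <- if (profile$atypical_hyperplasia == "present") {
    1L
  } else if (profile$atypical_hyperplasia == "absent" && profile$n_biopsies != "0") {
    2L
  } else 0L
  c(menarche = idx0(profile$age_at_menarche, .menarche_levels),
    first_birth = idx0(profile$age_at_first_birth, .first_birth_levels),
    biopsies = idx0(profile$n_biopsies, .count_levels),
    relatives = idx0(profile$n_relatives, .count_levels),
    hyperplasia = hyp)
}

#' @export
print.risk_factor_profile <- function(x, ...) {
  cat("Gail risk-factor profile\n")
  cat("  age ", x$current_age, ", race group ", x$race_group, "\n", sep = "")
  cat("  menarche ", x$age_at_menarche, ", first birth ", x$age_at_first_birth,
      "\n  biopsies ", x$n_biopsies, " (hyperplasia ", x$atypical_hyperplasia,
      "), first-degree relatives ", x$n_relatives, "\n", sep = "")
  invisible(x)
}
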