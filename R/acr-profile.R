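# Transgender patient profile used by the screening decision table ------------

#' Construct a transgender patient profile
#'
#' The decision table consumes four pieces of history: gender identity (which
#' selects the table arm), age, cumulative past-or-current gender-affirming
#' hormone therapy in years, and chest surgical history. Sex assigned at
#' birth is implied by the identity and checked for consistency when given.
#' Non-binary identities are routed by sex assigned at birth (AMAB with the
#' transfeminine arm, AFAB with the transmasculine arm) and the resulting
#' recommendation is flagged as an extrapolation.
#'
#' @param gender_identity `"transfeminine"`, `"transmasculine"`,
#'   `"nonbinary_AMAB"`, or `"nonbinary_AFAB"`.
#' @param age Age in years, 18-90.
#' @param hormone_years Cumulative hormone-therapy duration in years
#'   (past or current), non-negative.
#' @param chest_surgery `"none"`, `"breast_reduction"`, or
#'   `"bilateral_mastectomy"`.
#' @param sex_assigned_at_birth Optional `"female"` or `"male"`; must agree
#'   with the identity when supplied.
#' @return An object of class `trans_profile`.
#' @examples
#' trans_profile("transfeminine", age = 52, hormone_years = 8)
#' @export
trans_profile <- function(gender_identity, age, hormone_years = 0,
                          chest_surgery = "none",
                          sex_assigned_at_birth = NULL) {
  gender_identity <- match.arg(gender_identity, .identity_levels)
  chest_surgery <- match.arg(chest_surgery, .surgery_levels)
  age <- validate_age(age, "age")
  if (!is.finite(hormone_years) || hormone_years < 0) {
    stop("hormone_years must be a non-negative number of years")
  }
  implied <- if (gender_identity %in% c("transfeminine", "nonbinary_AMAB")) {
    "male"
  } else "female"
  if (!is.null(sex_assigned_at_birth)) {
    sex_assigned_at_birth <- match.arg(sex_assigned_at_birth, c("female", "male"))
    if (sex_assigned_at_birth != implied) {
      stop("gender_identity '", gender_identity, "' implies sex assigned at ",
           "birth '", implied, "', got '", sex_assigned_at_birth, "'")
    }
  }
  structure(
    list(gender_identity = gender_identity,
         sex_assigned_at_birth = implied,
         age = age,
         hormone_years = as.numeric(hormone_years),
         chest_surgery = chest_surgery),
    class = "trans_profile")
}

# Which arm of the decision table scores this profile.
table_arm <- function(identity) {
  ifelse(identity %in% c("transfeminine", "nonbinary_AMAB"),
         "transwoman", "transman")
}

#' @export
print.trans_profile <- function(x, ...) {
  cat("Patient profile: ", x$gender_identity, " (assigned ",
      x$sex_assigned_at_birth, " at birth), age ", x$age, "\n", sep = "")
  cat("  hormone therapy ", x$hormone_years, " years; chest surgery: ",
      x$chest_surgery, "\n", sep = "")
  invisible(x)
}
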