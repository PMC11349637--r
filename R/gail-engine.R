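# Gail-model relative and absolute risk ---------------------------------------

#' Age-stratum relative risk for a risk-factor profile
#'
#' The model is proportional-hazards in form: the relative risk versus the
#' all-baseline profile is the exponential of a linear predictor over the
#' category indices, with two interaction terms (biopsies x age stratum,
#' applied only at ages >= 50, and age-at-first-birth x relatives), times the
#' biopsy-pathology multiplier (1.82 when atypical hyperplasia was found,
#' 0.93 when biopsies were benign without hyperplasia, 1 otherwise). An
#' all-baseline profile returns exactly 1.
#'
#' @param profile A [risk_factor_profile()], or a named index vector as
#'   returned by [categorize_risk_factors()].
#' @param age_stratum `"lt50"` or `"ge50"`.
#' @param constants A [gail_constants()] block; defaults to the block for the
#'   profile's race group (index vectors default to `"white"`).
#' @return A single positive number.
#' @examples
#' p <- risk_factor_profile(45, "lt12", "ge30", 1, "absent", 1, "white")
#' relative_risk(p, "lt50")
#' @export
relative_risk <- function(profile, age_stratum = c("lt50", "ge50"),
                          constants = NULL) {
  age_stratum <- match.arg(age_stratum)
  if (inherits(profile, "risk_factor_profile")) {
    if (is.null(constants)) constants <- gail_constants(profile$race_group)
    idx <- categorize_risk_factors(profile)
  } else {
    idx <- profile
    need <- c("menarche", "first_birth", "biopsies", "relatives", "hyperplasia")
    if (!all(need %in% names(idx))) {
      stop("internal consistency: index vector must name ",
           paste(need, collapse = ", "))
    }
    if (is.null(constants)) constants <- gail_constants("white")
  }
  b <- constants$beta
  lp <- idx[["biopsies"]] * b[["n_biopsies"]] +
    idx[["menarche"]] * b[["age_at_menarche"]] +
    idx[["first_birth"]] * b[["age_at_first_birth"]] +
    idx[["relatives"]] * b[["n_relatives"]] +
    idx[["first_birth"]] * idx[["relatives"]] * b[["first_birth_x_relatives"]]
  if (age_stratum == "ge50") {
    lp <- lp + idx[["biopsies"]] * b[["biopsies_x_age_ge50"]]
  }
  mult <- switch(as.character(idx[["hyperplasia"]]),
                 "0" = constants$hyperplasia_rr[["unknown_or_no_biopsy"]],
                 "1" = constants$hyperplasia_rr[["present"]],
                 "2" = constants$hyperplasia_rr[["absent_with_biopsy"]])
  unname(exp(lp) * mult)
}

# Split [start, end) at every band edge and at the age-50 stratum switch.
# Returns a data frame of segments with their hazards for one person.
hazard_segments <- function(start_age, end_age, constants, rr_lt50, rr_ge50,
                            competing_scale = 1) {
  bands <- constants$age_bands
  cuts <- sort(unique(c(start_age, end_age, 50,
                        bands$start, bands$end)))
  cuts <- cuts[cuts >= start_age & cuts <= end_age]
  if (length(cuts) < 2) return(NULL)
  s <- cuts[-length(cuts)]
  e <- cuts[-1]
  band <- findInterval(s, bands$start)
  ar <- ifelse(s < 50, constants$one_minus_ar[["age_lt50"]],
               constants$one_minus_ar[["age_ge50"]])
  rr <- ifelse(s < 50, rr_lt50, rr_ge50)
  data.frame(start = s, end = e,
             h1 = bands$lambda1[band] * ar * rr,
             h2 = bands$lambda2[band] * competing_scale)
}

#' Absolute risk of invasive breast cancer over an age interval
#'
#' Combines the attributable-risk-adjusted composite baseline hazard, the
#' age-stratum-dependent relative risk, and competing (non-breast-cancer)
#' mortality. Hazards are piecewise constant on the 5-year bands of the
#' constant block; within each band the standard closed form for competing
#' piecewise-constant hazards is used:
#' \deqn{P = \sum_j \frac{h_{1j}}{h_{1j}+h_{2j}}
#'   \left(1 - e^{-(h_{1j}+h_{2j})\Delta_j}\right) S_j,}
#' where \eqn{S_j} is the probability of remaining alive and breast-cancer
#' free at the start of segment \eqn{j}. The relative risk and the 1-AR
#' factor switch at age 50, which is a band edge.
#'
#' @param profile A [risk_factor_profile()].
#' @param start_age,end_age Projection interval in years,
#'   `start_age <= end_age` and `start_age >= profile$current_age`. Portions
#'   outside \[20, 90) are clipped with a warning.
#' @param constants Optional [gail_constants()] block overriding the one
#'   implied by the profile's race group.
#' @param competing_scale Multiplier applied to the competing mortality
#'   hazards (1 = as published); exposed for sensitivity analysis.
#' @return A probability in \[0, 1).
#' @examples
#' p <- risk_factor_profile(45, "12to13", "25to29_or_nulliparous",
#'                          1, "absent", 1, "white")
#' absolute_risk(p, 45, 50)   # 5-year risk
#' absolute_risk(p, 45, 90)   # lifetime risk
#' @export
absolute_risk <- function(profile, start_age = profile$current_age,
                          end_age = 90, constants = NULL,
                          competing_scale = 1) {
  stopifnot(inherits(profile, "risk_factor_profile"))
  if (is.null(constants)) constants <- gail_constants(profile$race_group)
  if (!is.finite(start_age) || !is.finite(end_age)) {
    stop("projection ages must be finite")
  }
  if (end_age < start_age) {
    stop("reversed projection interval: end_age ", end_age,
         " < start_age ", start_age)
  }
  if (start_age < profile$current_age) {
    stop("start_age must not precede the profile's current age")
  }
  lo <- constants$age_bands$start[1]
  hi <- constants$age_bands$end[nrow(constants$age_bands)]
  if (start_age < lo || end_age > hi) {
    warning("projection interval [", start_age, ", ", end_age,
            ") clipped to [", lo, ", ", hi, ")")
    start_age <- max(start_age, lo)
    end_age <- min(end_age, hi)
    if (end_age < start_age) return(0)
  }
  if (end_age == start_age) return(0)
  seg <- hazard_segments(start_age, end_age, constants,
                         rr_lt50 = relative_risk(profile, "lt50", constants),
                         rr_ge50 = relative_risk(profile, "ge50", constants),
                         competing_scale = competing_scale)
  if (is.null(seg)) return(0)
  htot <- seg$h1 + seg$h2
  dt <- seg$end - seg$start
  surv <- c(1, cumprod(exp(-htot * dt)))[seq_len(nrow(seg))]
  frac <- ifelse(htot > 0, seg$h1 / htot, 0)
  p <- sum(frac * (1 - exp(-htot * dt)) * surv)
  min(p, 1 - .Machine$double.eps)
}

# Tier thresholds --------------------------------------------------------------

#' Risk-tier thresholds
#'
#' The decision table speaks in named tiers; the numeric cut points follow
#' screening convention: lifetime risk below 15% is average, 15-20%
#' intermediate, 20% and above high; a 5-year risk of 1.67% or more marks a
#' profile as higher than average on its own. All four numbers are
#' overridable; every boundary is closed on the lower side (a risk exactly at
#' a threshold falls in the upper tier).
#'
#' @param lifetime_low,lifetime_high Lifetime-risk cut points (probabilities,
#'   defaults 0.15 and 0.20), `lifetime_low < lifetime_high`.
#' @param five_year_elevated 5-year-risk cut point (default 0.0167).
#' @return An object of class `gail_thresholds`.
#' @export
gail_thresholds <- function(lifetime_low = 0.15, lifetime_high = 0.20,
                            five_year_elevated = 0.0167) {
  for (v in c(lifetime_low, lifetime_high, five_year_elevated)) {
    if (!is.finite(v) || v <= 0 || v >= 1) {
      stop("thresholds must be probabilities strictly inside (0, 1)")
    }
  }
  if (lifetime_low >= lifetime_high) {
    stop("malformed thresholds: lifetime_low (", lifetime_low,
         ") must be below lifetime_high (", lifetime_high, ")")
  }
  structure(list(lifetime_low = lifetime_low, lifetime_high = lifetime_high,
                 five_year_elevated = five_year_elevated),
            class = "gail_thresholds")
}

#' Categorical risk tiers from the two projected risks
#'
#' The three-tier label is a function of lifetime risk alone:
#' `average` below `lifetime_low`, `intermediate` in
#' \[`lifetime_low`, `lifetime_high`), `high` at or above `lifetime_high`.
#' The two-tier label is `higher_than_average` when the three-tier label is
#' not `average` or the 5-year risk reaches `five_year_elevated`. Both are
#' deterministic, total on \[0, 1) x \[0, 1).
#'
#' @param five_year_risk,lifetime_risk Probabilities in \[0, 1); vectorized.
#' @param thresholds A [gail_thresholds()] object.
#' @return A list with character vectors `three_tier` and `two_tier`.
#' @examples
#' classify_gail_category(0.005, 0.05)
#' classify_gail_category(0.02, 0.25)
#' @export
classify_gail_category <- function(five_year_risk, lifetime_risk,
                                   thresholds = gail_thresholds()) {
  stopifnot(inherits(thresholds, "gail_thresholds"))
  if (any(!is.finite(five_year_risk)) || any(!is.finite(lifetime_risk)) ||
      any(five_year_risk < 0) || any(five_year_risk >= 1) ||
      any(lifetime_risk < 0) || any(lifetime_risk >= 1)) {
    stop("risks must lie in [0, 1)")
  }
  three <- ifelse(lifetime_risk >= thresholds$lifetime_high, "high",
                  ifelse(lifetime_risk >= thresholds$lifetime_low,
                         "intermediate", "average"))
  two <- ifelse(three != "average" |
                  five_year_risk >= thresholds$five_year_elevated,
                "higher_than_average", "average")
  list(three_tier = three, two_tier = two)
}

#' Full Gail risk estimate for one profile
#'
#' Projects the 5-year risk (current age to current age + 5) and lifetime
#' risk (current age to 90) and attaches the categorical tiers.
#'
#' @param profile A [risk_factor_profile()].
#' @param thresholds A [gail_thresholds()] object.
#' @param constants Optional [gail_constants()] block override.
#' @return An object of class `gail_risk_estimate` with elements
#'   `five_year_risk`, `lifetime_risk`, `three_tier`, `two_tier`.
#' @examples
#' gail_risk(risk_factor_profile(45, "lt12", "ge30", "2plus",
#'                               "present", "2plus", "white"))
#' @export
gail_risk <- function(profile, thresholds = gail_thresholds(),
                      constants = NULL) {
  stopifnot(inherits(profile, "risk_factor_profile"))
  if (is.null(constants)) constants <- gail_constants(profile$race_group)
  a <- max(profile$current_age, constants$age_bands$start[1])
  hi <- constants$age_bands$end[nrow(constants$age_bands)]
  five <- absolute_risk(profile, a, min(a + 5, hi), constants)
  life <- absolute_risk(profile, a, hi, constants)
  tiers <- classify_gail_category(five, life, thresholds)
  structure(list(five_year_risk = five, lifetime_risk = life,
                 three_tier = tiers$three_tier, two_tier = tiers$two_tier),
            class = "gail_risk_estimate")
}

#' @export
print.gail_risk_estimate <- function(x, ...) {
  cat(sprintf("Gail risk estimate: 5-year %.2f%%, lifetime %.2f%%\n",
              100 * x$five_year_risk, 100 * x$lifetime_risk))
  cat("  tiers: ", x$three_tier, " (three-tier), ", x$two_tier,
      " (two-tier)\n", sep = "")
  invisible(x)
}
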