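# Appropriateness-criteria decision table -------------------------------------

#' Configuration for the screening decision table
#'
#' Age and hormone-duration thresholds of the eight table variants, plus the
#' Gail-tier thresholds. Every "at least" comparison is inclusive: hormone
#' exposure partitions at exactly `hormone_years` (5.0 years by default), and
#' a patient exactly at an age threshold qualifies.
#'
#' @param v1_age,v2_age,v4_age Age thresholds of the transwoman-arm variants
#'   (defaults 40, 25, 25).
#' @param v6_age,v7_age,v8_age Age thresholds of the transman-arm variants
#'   (defaults 40, 30, 25).
#' @param hormone_years Hormone-exposure cut in years (default 5).
#' @param gail A [gail_thresholds()] object.
#' @return An object of class `screening_config`.
#' @seealso [load_screening_config()] to read the same settings from YAML.
#' @export
screening_config <- function(v1_age = 40, v2_age = 25, v4_age = 25,
                             v6_age = 40, v7_age = 30, v8_age = 25,
                             hormone_years = 5,
                             gail = gail_thresholds()) {
  ages <- c(v1_age = v1_age, v2_age = v2_age, v4_age = v4_age,
            v6_age = v6_age, v7_age = v7_age, v8_age = v8_age)
  if (any(!is.finite(ages)) || any(ages < 18) || any(ages > 90)) {
    stop("variant age thresholds must lie in [18, 90]")
  }
  if (!is.finite(hormone_years) || hormone_years < 0) {
    stop("hormone_years threshold must be non-negative")
  }
  stopifnot(inherits(gail, "gail_thresholds"))
  structure(c(as.list(ages),
              list(hormone_years = hormone_years, gail = gail,
                   version = "1.0")),
            class = "screening_config")
}

#' Read a screening configuration from a YAML file
#'
#' The file may set any subset of the [screening_config()] arguments at top
#' level, with Gail-tier thresholds nested under `gail:` (keys
#' `lifetime_low`, `lifetime_high`, `five_year_elevated`). Omitted keys keep
#' their defaults.
#'
#' @param path Path to a YAML file.
#' @return An object of class `screening_config`.
#' @export
load_screening_config <- function(path) {
  raw <- yaml::read_yaml(path)
  gail_args <- raw$gail %||% list()
  raw$gail <- NULL
  known <- c("v1_age", "v2_age", "v4_age", "v6_age", "v7_age", "v8_age",
             "hormone_years")
  bad <- setdiff(names(raw), known)
  if (length(bad)) stop("unknown configuration keys: ", paste(bad, collapse = ", "))
  do.call(screening_config,
          c(raw, list(gail = do.call(gail_thresholds, gail_args))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# The declarative rule set: one row per printed variant, in match priority.
# Bilateral mastectomy (the first rule) dominates every other condition.
rule_set <- function(config = screening_config()) {
  data.frame(
    variant = c("V5", "V1", "V2", "V3", "V4", "V6", "V7", "V8"),
    arm = c("any", "transwoman", "transwoman", "transwoman", "transwoman",
            "transman", "transman", "transman"),
    age_min = c(NA, config$v1_age, config$v2_age, NA, config$v4_age,
                config$v6_age, config$v7_age, config$v8_age),
    hormone = c("any", "ge", "ge", "lt", "lt", "any", "any", "any"),
    surgery = c("mastectomy", "none_or_reduction", "none_or_reduction",
                "none_or_reduction", "none_or_reduction",
                "none_or_reduction", "none_or_reduction", "none_or_reduction"),
    tier = c("any", "average", "higher_than_average", "average",
             "higher_than_average", "average", "intermediate", "high"),
    stringsAsFactors = FALSE)
}

# Modality ratings printed for each variant (and the unmatched outcome).
variant_ratings <- function() {
  data.frame(
    variant = c("V1", "V2", "V3", "V4", "V5", "V6", "V7", "V8", "NO_MATCH"),
    mammography = c("may_be_appropriate", "usually_appropriate",
                    "usually_not_appropriate", "may_be_appropriate",
                    "usually_not_appropriate", "usually_appropriate",
                    "usually_appropriate", "usually_appropriate",
                    "not_indicated"),
    ultrasound = c("usually_not_appropriate", "usually_not_appropriate",
                   "usually_not_appropriate", "usually_not_appropriate",
                   "usually_not_appropriate", "usually_not_appropriate",
                   "may_be_appropriate", "may_be_appropriate",
                   "not_indicated"),
    stringsAsFactors = FALSE)
}

#' Rank of an appropriateness rating
#'
#' Ratings are ordered `usually_appropriate` (3) > `may_be_appropriate` (2)
#' > `usually_not_appropriate` (1) >= `not_indicated` (1). The two lowest
#' labels share a rank: both mean no screening is being recommended, and the
#' monotonicity guarantees of the table (raising age or risk tier never
#' lowers a rating) are stated over this ranking.
#'
#' @param rating Character vector of rating labels.
#' @return Integer vector of ranks.
#' @export
rating_rank <- function(rating) {
  r <- c(not_indicated = 1L, usually_not_appropriate = 1L,
         may_be_appropriate = 2L, usually_appropriate = 3L)
  out <- r[rating]
  if (anyNA(out)) stop("unknown rating label: ",
                       paste(unique(rating[is.na(out)]), collapse = ", "))
  unname(out)
}

# Vectorized matcher over parallel columns. tier2/tier3 are the tier labels
# consumed by the transwoman and transman arms respectively.
match_variant_vec <- function(arm, age, hormone_years, surgery, tier2, tier3,
                              config = screening_config()) {
  n <- length(age)
  id <- rep("NO_MATCH", n)
  surgery_class <- ifelse(surgery == "bilateral_mastectomy",
                          "mastectomy", "none_or_reduction")
  rules <- rule_set(config)
  for (i in seq_len(nrow(rules))) {
    r <- rules[i, ]
    tier <- if (r$arm == "transwoman") tier2 else tier3
    ok <- (r$arm == "any" | arm == r$arm) &
      (r$surgery == "any" | surgery_class == r$surgery) &
      (is.na(r$age_min) | age >= r$age_min) &
      switch(r$hormone,
             any = rep(TRUE, n),
             ge = hormone_years >= config$hormone_years,
             lt = hormone_years < config$hormone_years) &
      (r$tier == "any" | tier == r$tier)
    id[id == "NO_MATCH" & ok] <- r$variant
  }
  id
}

# Resolve a tier argument for one profile: accepts a gail_risk_estimate or a
# tier label; returns list(two, three). The transwoman arm consumes the
# two-tier vocabulary, the transman arm the three-tier vocabulary.
resolve_tier <- function(gail_tier, arm) {
  if (inherits(gail_tier, "gail_risk_estimate")) {
    return(list(two = gail_tier$two_tier, three = gail_tier$three_tier))
  }
  tier <- match.arg(as.character(gail_tier),
                    unique(c(.three_tier_levels, .two_tier_levels)))
  two <- if (tier == "average") "average" else "higher_than_average"
  three <- if (tier == "higher_than_average") {
    if (arm == "transman") {
      stop("the transman arm distinguishes intermediate from high risk; ",
           "pass a three-tier label or a gail_risk_estimate")
    }
    NA_character_
  } else tier
  list(two = two, three = three)
}

#' Match a patient profile to a screening variant
#'
#' Deterministic, total mapping from (profile, Gail tier) to one of the eight
#' table variants or an explicit `NO_MATCH` outcome. Bilateral mastectomy
#' dominates every other condition ("any risk"); the transwoman arm consumes
#' the two-tier risk vocabulary (average / higher than average), the
#' transman arm the three-tier vocabulary (average / intermediate / high).
#' Profiles the printed table does not cover (for example a 30-year-old
#' average-risk transfeminine patient with 5+ years of hormone exposure)
#' return `NO_MATCH` with a reason code rather than a silent default.
#'
#' @param profile A [trans_profile()].
#' @param gail_tier A [gail_risk_estimate] (preferred), or a tier label:
#'   `"average"` / `"higher_than_average"` for the transwoman arm,
#'   `"average"` / `"intermediate"` / `"high"` for the transman arm.
#' @param config A [screening_config()].
#' @return An object of class `screening_variant` with elements `id`
#'   (`"V1"`..`"V8"` or `"NO_MATCH"`), `arm`, `reason`
#'   (`"below_age_threshold"` or `"insufficient_hormone_exposure"`, `NA`
#'   when matched), `first_matching_age` (for age-related `NO_MATCH`), and
#'   `extrapolated` (non-binary routing, or mastectomy dominance applied on
#'   the transwoman arm).
#' @examples
#' classify_variant(trans_profile("transfeminine", 52, hormone_years = 8),
#'                  "average")
#' @export
classify_variant <- function(profile, gail_tier,
                             config = screening_config()) {
  stopifnot(inherits(profile, "trans_profile"),
            inherits(config, "screening_config"))
  arm <- table_arm(profile$gender_identity)
  tiers <- resolve_tier(gail_tier, arm)
  id <- match_variant_vec(arm, profile$age, profile$hormone_years,
                          profile$chest_surgery, tiers$two, tiers$three,
                          config)
  reason <- NA_character_
  first_age <- NA_real_
  if (id == "NO_MATCH") {
    ages <- seq(profile$age, 90)
    hit <- match_variant_vec(rep(arm, length(ages)), ages,
                             rep(profile$hormone_years, length(ages)),
                             rep(profile$chest_surgery, length(ages)),
                             rep(tiers$two, length(ages)),
                             rep(tiers$three, length(ages)), config)
    if (any(hit != "NO_MATCH")) {
      reason <- "below_age_threshold"
      first_age <- ages[which(hit != "NO_MATCH")[1]]
    } else {
      reason <- "insufficient_hormone_exposure"
    }
  }
  extrapolated <- profile$gender_identity %in%
    c("nonbinary_AMAB", "nonbinary_AFAB") ||
    (id == "V5" && arm == "transwoman")
  structure(list(id = id, arm = arm, reason = reason,
                 first_matching_age = first_age,
                 extrapolated = extrapolated,
                 tier_used = if (arm == "transwoman") tiers$two else tiers$three),
            class = "screening_variant")
}

variant_rationale <- function(id, arm, tier_used) {
  desc <- c(
    V1 = "age >= 40, past or current hormone use >= 5 years, average risk (Gail model)",
    V2 = "age >= 25, past or current hormone use >= 5 years, higher than average risk (Gail model)",
    V3 = "past or current hormone use < 5 years, average risk (Gail model)",
    V4 = "age >= 25, past or current hormone use < 5 years, higher than average risk (Gail model)",
    V5 = "double bilateral mastectomy, any risk (Gail model)",
    V6 = "age >= 40, no surgery or breast reduction surgery, average risk (Gail model)",
    V7 = "age >= 30, no surgery or breast reduction surgery, intermediate risk (Gail model)",
    V8 = "age >= 25, no surgery or breast reduction surgery, high risk (Gail model)")
  if (id == "NO_MATCH") {
    sprintf("No screening scenario covers this %s-arm profile (tier: %s).",
            arm, tier_used)
  } else {
    sprintf("Variant %s (%s arm): %s.", sub("^V", "", id), arm, desc[[id]])
  }
}

#' Imaging recommendation for a matched screening variant
#'
#' Maps a [classify_variant()] result to the printed modality ratings:
#' mammography "may be appropriate" (V1, V4) or "usually appropriate"
#' (V2, V6, V7, V8), "screening usually not appropriate" (V3, V5), with
#' ultrasound "may be appropriate" added for V7 and V8. Unmatched profiles
#' receive `not_indicated` for both modalities and a re-evaluation hint
#' (for age-related non-matches, the age at which the profile would first
#' qualify).
#'
#' @param variant A `screening_variant` from [classify_variant()].
#' @param config A [screening_config()] (recorded in the output).
#' @return An object of class `screening_recommendation` with elements
#'   `variant`, `mammography_rating`, `ultrasound_rating`, `rationale`,
#'   `reevaluation_hint` (or `NA`), and `extrapolated`.
#' @examples
#' v <- classify_variant(trans_profile("transmasculine", 45), "average")
#' recommend(v)
#' @export
recommend <- function(variant, config = screening_config()) {
  stopifnot(inherits(variant, "screening_variant"))
  rt <- variant_ratings()
  row <- rt[rt$variant == variant$id, ]
  hint <- NA_character_
  if (variant$id == "NO_MATCH") {
    hint <- if (!is.na(variant$first_matching_age)) {
      sprintf(paste("Re-evaluate at age %d, when this profile first matches a",
                    "screening scenario."), as.integer(variant$first_matching_age))
    } else {
      paste("No scenario matches at any age with this hormone exposure;",
            "re-evaluate if cumulative hormone-therapy duration increases.")
    }
  }
  structure(
    list(variant = variant,
         mammography_rating = row$mammography,
         ultrasound_rating = row$ultrasound,
         rationale = variant_rationale(variant$id, variant$arm,
                                       variant$tier_used),
         reevaluation_hint = hint,
         extrapolated = variant$extrapolated,
         config_version = config$version),
    class = "screening_recommendation")
}

#' @export
print.screening_variant <- function(x, ...) {
  cat("Screening variant: ", x$id, " (", x$arm, " arm)\n", sep = "")
  if (!is.na(x$reason)) cat("  no match: ", x$reason, "\n", sep = "")
  if (x$extrapolated) cat("  note: extrapolated beyond the printed table\n")
  invisible(x)
}

#' @export
print.screening_recommendation <- function(x, ...) {
  cat("Screening recommendation [variant ", x$variant$id, ", ",
      x$variant$arm, " arm]\n", sep = "")
  cat("  mammography: ", gsub("_", " ", x$mammography_rating), "\n", sep = "")
  cat("  ultrasound:  ", gsub("_", " ", x$ultrasound_rating), "\n", sep = "")
  cat("  ", x$rationale, "\n", sep = "")
  if (!is.na(x$reevaluation_hint)) cat("  ", x$reevaluation_hint, "\n", sep = "")
  if (x$extrapolated) {
    cat("  note: extrapolated beyond the printed table\n")
  }
  invisible(x)
}

#' Serialize a recommendation to a stable list/JSON record
#'
#' @param rec A `screening_recommendation`.
#' @return A named list with stable field names, suitable for
#'   `jsonlite::toJSON(..., auto_unbox = TRUE)`.
#' @export
recommendation_record <- function(rec) {
  stopifnot(inherits(rec, "screening_recommendation"))
  list(variant = rec$variant$id,
       arm = rec$variant$arm,
       tier_used = rec$variant$tier_used,
       mammography_rating = rec$mammography_rating,
       ultrasound_rating = rec$ultrasound_rating,
       no_match_reason = rec$variant$reason,
       first_matching_age = rec$variant$first_matching_age,
       extrapolated = rec$extrapolated,
       rationale = rec$rationale,
       reevaluation_hint = rec$reevaluation_hint,
       config_version = rec$config_version)
}

#' Enumerate the full decision table
#'
#' Renders every distinct rule cell of the configured table: the eight
#' variant rows plus the explicit `NO_MATCH` cells (condition combinations
#' the printed table does not cover). Used to regenerate a facsimile of the
#' published one-page table and as an exact-match test fixture.
#'
#' @param config A [screening_config()].
#' @return A data frame with one row per distinct cell: `arm`, `variant`,
#'   `age_condition`, `hormone_condition`, `surgery_condition`, `tier`,
#'   `mammography`, `ultrasound`.
#' @examples
#' decision_table()
#' @export
decision_table <- function(config = screening_config()) {
  stopifnot(inherits(config, "screening_config"))
  rt <- variant_ratings()
  rows <- list()
  add <- function(arm, variant, age_c, horm_c, surg_c, tier) {
    r <- rt[rt$variant == variant, ]
    rows[[length(rows) + 1L]] <<- data.frame(
      arm = arm, variant = variant, age_condition = age_c,
      hormone_condition = horm_c, surgery_condition = surg_c, tier = tier,
      mammography = r$mammography, ultrasound = r$ultrasound,
      stringsAsFactors = FALSE)
  }
  age_brackets <- function(cuts) {
    cuts <- sort(unique(c(18, cuts[cuts > 18])))
    lo <- cuts
    hi <- c(cuts[-1] - 1, 90)
    cond <- ifelse(lo == 18 & hi == 90, "any",
                   ifelse(hi == 90, paste0(">=", lo),
                          paste0(lo, "-", hi)))
    data.frame(lo = lo, cond = cond, stringsAsFactors = FALSE)
  }
  horm <- data.frame(
    val = c(config$hormone_years, max(config$hormone_years - 1, 0)),
    cond = c(paste0(">=", config$hormone_years, "y"),
             paste0("<", config$hormone_years, "y")),
    stringsAsFactors = FALSE)
  if (config$hormone_years == 0) horm <- horm[1, , drop = FALSE]

  # Merge adjacent age brackets that land on the same outcome.
  emit_age_runs <- function(arm, br, ids, horm_cond, tier) {
    runs <- rle(ids)
    stops <- cumsum(runs$lengths)
    starts <- stops - runs$lengths + 1L
    for (k in seq_along(runs$values)) {
      cond <- if (length(runs$values) == 1L) "any"
      else if (stops[k] == nrow(br)) paste0(">=", br$lo[starts[k]])
      else paste0(br$lo[starts[k]], "-", br$lo[stops[k] + 1L] - 1)
      add(arm, runs$values[k], cond, horm_cond,
          "none or breast reduction", tier)
    }
  }

  # Mastectomy dominates in both arms.
  for (arm in c("transwoman", "transman")) {
    add(arm, "V5", "any", "any", "bilateral mastectomy", "any")
  }
  # Transwoman arm, no mastectomy: hormone bracket x two-tier x age bracket.
  br_tw <- age_brackets(c(config$v1_age, config$v2_age, config$v4_age))
  for (h in seq_len(nrow(horm))) {
    for (tier in .two_tier_levels) {
      ids <- match_variant_vec(rep("transwoman", nrow(br_tw)), br_tw$lo,
                               rep(horm$val[h], nrow(br_tw)),
                               rep("none", nrow(br_tw)),
                               rep(tier, nrow(br_tw)),
                               rep(NA_character_, nrow(br_tw)), config)
      emit_age_runs("transwoman", br_tw, ids, horm$cond[h], tier)
    }
  }
  # Transman arm, no mastectomy: three-tier x age bracket.
  br_tm <- age_brackets(c(config$v6_age, config$v7_age, config$v8_age))
  for (tier in .three_tier_levels) {
    ids <- match_variant_vec(rep("transman", nrow(br_tm)), br_tm$lo,
                             rep(0, nrow(br_tm)), rep("none", nrow(br_tm)),
                             rep(NA_character_, nrow(br_tm)),
                             rep(tier, nrow(br_tm)), config)
    emit_age_runs("transman", br_tm, ids, "any", tier)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
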