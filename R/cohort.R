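# Seeded synthetic cohorts and the exhaustive profile grid --------------------

#' Configuration for the synthetic cohort generator
#'
#' The generator exists for coverage, not epidemiology: defaults give
#' uniform ages over 18-90, a zero-inflated uniform hormone-duration mixture
#' calibrated so roughly one in five records carries 5+ years of exposure,
#' every surgery state, and unremarkable-but-varied Gail factor prevalences.
#' Identical `(seed, config)` pairs reproduce identical cohorts.
#'
#' @param n Number of records (>= 1).
#' @param seed Integer RNG seed.
#' @param identity_mix Named proportions over the four identities; must sum
#'   to 1.
#' @param age_range Integer age range (inclusive), within 18-90.
#' @param hormone_zero_prob Probability of zero hormone exposure.
#' @param hormone_max_years Upper limit of the uniform duration component.
#' @param surgery_probs_afab,surgery_probs_amab Named proportions over
#'   `none`, `breast_reduction`, `bilateral_mastectomy` for each natal-sex
#'   arm; each must sum to 1.
#' @param relatives_probs,biopsies_probs Named proportions over counts
#'   `0`, `1`, `2plus`.
#' @param hyperplasia_prob Probability of atypical hyperplasia given at
#'   least one biopsy.
#' @param menarche_probs Named proportions over `ge14`, `12to13`, `lt12`.
#' @param first_birth_probs Named proportions over `lt20`, `20to24`,
#'   `25to29_or_nulliparous`, `ge30`.
#' @param race_probs Named proportions over the five race groups.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n = 100, seed = 1L,
                          identity_mix = c(transfeminine = 0.4,
                                           transmasculine = 0.4,
                                           nonbinary_AMAB = 0.1,
                                           nonbinary_AFAB = 0.1),
                          age_range = c(18L, 90L),
                          hormone_zero_prob = 0.6,
                          hormone_max_years = 10,
                          surgery_probs_afab = c(none = 0.5,
                                                 breast_reduction = 0.2,
                                                 bilateral_mastectomy = 0.3),
                          surgery_probs_amab = c(none = 0.95,
                                                 breast_reduction = 0.03,
                                                 bilateral_mastectomy = 0.02),
                          relatives_probs = c("0" = 0.70, "1" = 0.25,
                                              "2plus" = 0.05),
                          biopsies_probs = c("0" = 0.80, "1" = 0.15,
                                             "2plus" = 0.05),
                          hyperplasia_prob = 0.10,
                          menarche_probs = c(ge14 = 0.25, "12to13" = 0.50,
                                             lt12 = 0.25),
                          first_birth_probs = c(lt20 = 0.2, "20to24" = 0.3,
                                                "25to29_or_nulliparous" = 0.3,
                                                ge30 = 0.2),
                          race_probs = c(white = 0.60, black = 0.15,
                                         hispanic = 0.15,
                                         asian_pacific_islander = 0.08,
                                         other = 0.02)) {
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n != trunc(n)) {
    stop("n must be a positive integer")
  }
  check_probs <- function(p, levels, what) {
    if (!setequal(names(p), levels) || any(p < 0) ||
        abs(sum(p) - 1) > 1e-8) {
      stop(what, " must be named proportions over {",
           paste(levels, collapse = ", "), "} summing to 1")
    }
    p[levels]
  }
  cfg <- list(
    n = as.integer(n), seed = as.integer(seed),
    identity_mix = check_probs(identity_mix, .identity_levels, "identity_mix"),
    age_range = as.integer(age_range),
    hormone_zero_prob = hormone_zero_prob,
    hormone_max_years = hormone_max_years,
    surgery_probs_afab = check_probs(surgery_probs_afab, .surgery_levels,
                                     "surgery_probs_afab"),
    surgery_probs_amab = check_probs(surgery_probs_amab, .surgery_levels,
                                     "surgery_probs_amab"),
    relatives_probs = check_probs(relatives_probs, c("0", "1", "2plus"),
                                  "relatives_probs"),
    biopsies_probs = check_probs(biopsies_probs, c("0", "1", "2plus"),
                                 "biopsies_probs"),
    hyperplasia_prob = hyperplasia_prob,
    menarche_probs = check_probs(menarche_probs,
                                 setdiff(.menarche_levels, "unknown"),
                                 "menarche_probs"),
    first_birth_probs = check_probs(first_birth_probs,
                                    setdiff(.first_birth_levels, "unknown"),
                                    "first_birth_probs"),
    race_probs = check_probs(race_probs, .race_groups, "race_probs"))
  if (length(cfg$age_range) != 2L || cfg$age_range[1] < 18 ||
      cfg$age_range[2] > 90 || cfg$age_range[1] > cfg$age_range[2]) {
    stop("age_range must be an increasing pair within [18, 90]")
  }
  if (cfg$hormone_zero_prob < 0 || cfg$hormone_zero_prob > 1 ||
      cfg$hormone_max_years < 0) {
    stop("invalid hormone-duration mixture")
  }
  if (cfg$hyperplasia_prob < 0 || cfg$hyperplasia_prob > 1) {
    stop("hyperplasia_prob must be a probability")
  }
  structure(cfg, class = "cohort_config")
}

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE)) {
            rm(".Random.seed", envir = globalenv())
          })
  set.seed(seed)
  code
}

#' Sample a synthetic cohort
#'
#' Draws `config$n` records satisfying both profile types' invariants by
#' construction (identity implies sex assigned at birth; atypical
#' hyperplasia only ever accompanies a biopsy). The result doubles as the
#' batch CSV schema: [write_cohort_csv()] / [read_batch_csv()] round-trip
#' it.
#'
#' @param config A [cohort_config()].
#' @return A data frame with one row per subject and columns `patient_id`,
#'   `gender_identity`, `sex_assigned_at_birth`, `age`, `hormone_years`,
#'   `chest_surgery`, `age_at_menarche`, `age_at_first_birth`, `n_biopsies`,
#'   `atypical_hyperplasia`, `n_relatives`, `race_group`.
#' @examples
#' head(sample_cohort(cohort_config(n = 5, seed = 7)))
#' @export
sample_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n
  with_seed(config$seed, {
    identity <- sample(names(config$identity_mix), n, replace = TRUE,
                       prob = config$identity_mix)
    amab <- identity %in% c("transfeminine", "nonbinary_AMAB")
    age <- sample(seq(config$age_range[1], config$age_range[2]), n,
                  replace = TRUE)
    hormone <- ifelse(stats::runif(n) < config$hormone_zero_prob, 0,
                      round(stats::runif(n, 0, config$hormone_max_years), 1))
    surgery <- character(n)
    surgery[amab] <- sample(.surgery_levels, sum(amab), replace = TRUE,
                            prob = config$surgery_probs_amab)
    surgery[!amab] <- sample(.surgery_levels, sum(!amab), replace = TRUE,
                             prob = config$surgery_probs_afab)
    biopsies <- sample(names(config$biopsies_probs), n, replace = TRUE,
                       prob = config$biopsies_probs)
    hyper <- ifelse(biopsies != "0" &
                      stats::runif(n) < config$hyperplasia_prob,
                    "present", "absent")
    data.frame(
      patient_id = sprintf("S%05d", seq_len(n)),
      gender_identity = identity,
      sex_assigned_at_birth = ifelse(amab, "male", "female"),
      age = age,
      hormone_years = hormone,
      chest_surgery = surgery,
      age_at_menarche = sample(names(config$menarche_probs), n,
                               replace = TRUE, prob = config$menarche_probs),
      age_at_first_birth = sample(names(config$first_birth_probs), n,
                                  replace = TRUE,
                                  prob = config$first_birth_probs),
      n_biopsies = biopsies,
      atypical_hyperplasia = hyper,
      n_relatives = sample(names(config$relatives_probs), n, replace = TRUE,
                           prob = config$relatives_probs),
      race_group = sample(names(config$race_probs), n, replace = TRUE,
                          prob = config$race_probs),
      stringsAsFactors = FALSE)
  })
}

#' The exhaustive discretized profile grid
#'
#' Full cross-product of integer ages, whole-year hormone durations, the
#' three surgery states, the three-tier risk labels and the four gender
#' identities (sex assigned at birth is implied by identity, so no
#' combination needs filtering). Used by the totality and monotonicity
#' property suites.
#'
#' @param ages Integer ages (default 18:90).
#' @param hormone_years Whole-year durations (default 0:40).
#' @return A data frame with columns `gender_identity`, `age`,
#'   `hormone_years`, `chest_surgery`, `tier` plus the derived
#'   `sex_assigned_at_birth` and `arm`.
#' @export
exhaustive_grid <- function(ages = 18:90, hormone_years = 0:40) {
  g <- expand.grid(gender_identity = .identity_levels,
                   age = ages,
                   hormone_years = hormone_years,
                   chest_surgery = .surgery_levels,
                   tier = .three_tier_levels,
                   stringsAsFactors = FALSE,
                   KEEP.OUT.ATTRS = FALSE)
  g$sex_assigned_at_birth <- ifelse(
    g$gender_identity %in% c("transfeminine", "nonbinary_AMAB"),
    "male", "female")
  g$arm <- table_arm(g$gender_identity)
  g
}

#' Classify every row of a profile grid or cohort-like data frame
#'
#' Vectorized form of [classify_variant()] + [recommend()] over parallel
#' columns, used by the exhaustive property suites. A `tier` column (three-
#' tier vocabulary) supplies the Gail tier directly; the transwoman arm
#' consumes its two-tier projection (`average` vs anything else).
#'
#' @param grid A data frame with columns `gender_identity` (or `arm`),
#'   `age`, `hormone_years`, `chest_surgery`, `tier`.
#' @param config A [screening_config()].
#' @return The input with columns `variant`, `mammography`, `ultrasound`
#'   appended.
#' @export
classify_grid <- function(grid, config = screening_config()) {
  arm <- if ("arm" %in% names(grid)) grid$arm else table_arm(grid$gender_identity)
  tier2 <- ifelse(grid$tier == "average", "average", "higher_than_average")
  id <- match_variant_vec(arm, grid$age, grid$hormone_years,
                          grid$chest_surgery, tier2, grid$tier, config)
  rt <- variant_ratings()
  m <- match(id, rt$variant)
  grid$variant <- id
  grid$mammography <- rt$mammography[m]
  grid$ultrasound <- rt$ultrasound[m]
  grid
}
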