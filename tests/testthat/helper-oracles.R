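# Independent oracles used across the suite -----------------------------------

# Fine-grid midpoint Riemann integrator for the absolute-risk cause-specific
# integral. Deliberately does NOT reuse the package's closed form: it reads
# the hazards off the constant block, builds a numeric grid aligned to the
# band edges, and integrates h1(t) * exp(-H(t)) dt directly.
riemann_risk <- function(profile, start_age, end_age, step = 0.01,
                         competing_scale = 1) {
  constants <- gail_constants(profile$race_group)
  bands <- constants$age_bands
  rr_lt <- relative_risk(profile, "lt50", constants)
  rr_ge <- relative_risk(profile, "ge50", constants)
  nsteps <- round((end_age - start_age) / step)
  if (nsteps == 0) return(0)
  mid <- start_age + step * (seq_len(nsteps) - 0.5)
  band <- findInterval(mid, bands$start)
  ar <- ifelse(mid < 50, constants$one_minus_ar[["age_lt50"]],
               constants$one_minus_ar[["age_ge50"]])
  h1 <- bands$lambda1[band] * ar * ifelse(mid < 50, rr_lt, rr_ge)
  h2 <- bands$lambda2[band] * competing_scale
  htot <- h1 + h2
  cum_mid <- c(0, cumsum(htot * step))[seq_len(nsteps)] + htot * step / 2
  sum(h1 * exp(-cum_mid) * step)
}

# Relative-risk oracle that re-reads the shipped YAML coefficient table and
# accumulates the linear predictor in the reverse order of the engine.
yaml_rr_oracle <- function(profile, stratum) {
  file <- system.file("extdata", "gail_constants",
                      paste0(profile$race_group, ".yaml"),
                      package = "transcreen")
  raw <- yaml::read_yaml(file)
  if (!is.null(raw$alias)) {
    raw <- yaml::read_yaml(system.file("extdata", "gail_constants",
                                       paste0(raw$alias, ".yaml"),
                                       package = "transcreen"))
  }
  b <- raw$beta
  am <- switch(profile$age_at_menarche,
               ge14 = 0, "12to13" = 1, lt12 = 2, unknown = 0)
  af <- switch(profile$age_at_first_birth, lt20 = 0, "20to24" = 1,
               "25to29_or_nulliparous" = 2, ge30 = 3, unknown = 0)
  nb <- switch(profile$n_biopsies, "0" = 0, "1" = 1, "2plus" = 2, unknown = 0)
  nr <- switch(profile$n_relatives, "0" = 0, "1" = 1, "2plus" = 2, unknown = 0)
  terms <- c(if (stratum == "ge50") nb * b$biopsies_x_age_ge50 else 0,
             af * nr * b$first_birth_x_relatives,
             nr * b$n_relatives,
             af * b$age_at_first_birth,
             am * b$age_at_menarche,
             nb * b$n_biopsies)
  mult <- if (profile$atypical_hyperplasia == "present") {
    raw$hyperplasia_rr$present
  } else if (profile$atypical_hyperplasia == "absent" && nb > 0) {
    raw$hyperplasia_rr$absent_with_biopsy
  } else {
    raw$hyperplasia_rr$unknown_or_no_biopsy
  }
  exp(sum(terms)) * mult
}

# Random-but-seeded risk-factor profiles for property suites.
random_profiles <- function(n, seed) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    nb <- sample(c("0", "1", "2plus"), 1)
    risk_factor_profile(
      current_age = sample(18:90, 1),
      age_at_menarche = sample(c("ge14", "12to13", "lt12", "unknown"), 1),
      age_at_first_birth = sample(c("lt20", "20to24",
                                    "25to29_or_nulliparous", "ge30",
                                    "unknown"), 1),
      n_biopsies = nb,
      atypical_hyperplasia = if (nb == "0") {
        sample(c("absent", "unknown"), 1)
      } else sample(c("absent", "present", "unknown"), 1),
      n_relatives = sample(c("0", "1", "2plus", "unknown"), 1),
      race_group = sample(c("white", "black", "hispanic",
                            "asian_pacific_islander", "other"), 1))
  })
}

# The eight scenarios printed in the one-page table, with their verbatim
# modality ratings.
canonical_scenarios <- function() {
  data.frame(
    variant = paste0("V", 1:8),
    gender_identity = c(rep("transfeminine", 4), rep("transmasculine", 4)),
    age = c(45, 30, 35, 30, 50, 45, 33, 27),
    hormone_years = c(8, 6, 2, 0, 10, 0, 3, 1),
    chest_surgery = c(rep("none", 4), "bilateral_mastectomy",
                      "none", "breast_reduction", "none"),
    tier = c("average", "higher_than_average", "average",
             "higher_than_average", "high", "average", "intermediate",
             "high"),
    mammography = c("may_be_appropriate", "usually_appropriate",
                    "usually_not_appropriate", "may_be_appropriate",
                    "usually_not_appropriate", "usually_appropriate",
                    "usually_appropriate", "usually_appropriate"),
    ultrasound = c("usually_not_appropriate", "usually_not_appropriate",
                   "usually_not_appropriate", "usually_not_appropriate",
                   "usually_not_appropriate", "usually_not_appropriate",
                   "may_be_appropriate", "may_be_appropriate"),
    stringsAsFactors = FALSE)
}

scenario_recommendation <- function(row, config = screening_config()) {
  p <- trans_profile(row$gender_identity, row$age, row$hormone_years,
                     row$chest_surgery)
  recommend(classify_variant(p, row$tier, config), config)
}
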