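baseline_profile <- function(age = 40, race = "white") {
  risk_factor_profile(age, "ge14", "lt20", "0", "absent", "0", race)
}

test_that("risk factors map to category indices with unknown as baseline", {
  idx <- categorize_risk_factors(baseline_profile())
  expect_equal(idx[c("menarche", "first_birth", "biopsies", "relatives")],
               c(menarche = 0L, first_birth = 0L, biopsies = 0L,
                 relatives = 0L))
  idx_unk <- categorize_risk_factors(risk_factor_profile(40))
  expect_equal(unname(idx_unk), rep(0L, 5))

  idx2 <- categorize_risk_factors(
    risk_factor_profile(45, "lt12", "ge30", 1, "absent", 1, "white"))
  expect_equal(idx2[["menarche"]], 2L)
  expect_equal(idx2[["first_birth"]], 3L)
  expect_equal(idx2[["biopsies"]], 1L)
  expect_equal(idx2[["relatives"]], 1L)
  expect_equal(idx2[["hyperplasia"]], 2L)  # biopsy, hyperplasia ruled out
})

test_that("profile validation names the offending field", {
  expect_error(risk_factor_profile(95), "current_age")
  expect_error(risk_factor_profile(17), "current_age")
  expect_error(risk_factor_profile(40, atypical_hyperplasia = "present",
                                   n_biopsies = 0),
               "requires n_biopsies")
})

test_that("relative risk is 1 at baseline and exp(beta) for single factors", {
  k <- gail_constants("white")
  for (stratum in c("lt50", "ge50")) {
    expect_identical(relative_risk(baseline_profile(), stratum), 1)
  }
  one_rel <- risk_factor_profile(40, "ge14", "lt20", 0, "absent", 1, "white")
  expect_equal(relative_risk(one_rel, "lt50"),
               exp(k$beta[["n_relatives"]]))
  menarche <- risk_factor_profile(40, "lt12", "lt20", 0, "absent", 0, "white")
  expect_equal(relative_risk(menarche, "ge50"),
               exp(2 * k$beta[["age_at_menarche"]]))
  # the biopsy term interacts with the age stratum
  biop <- risk_factor_profile(40, "ge14", "lt20", 1, "unknown", 0, "white")
  expect_equal(relative_risk(biop, "lt50"), exp(k$beta[["n_biopsies"]]))
  expect_equal(relative_risk(biop, "ge50"),
               exp(k$beta[["n_biopsies"]] + k$beta[["biopsies_x_age_ge50"]]))
})

test_that("multi-factor relative risk matches the order-independent oracle", {
  for (p in random_profiles(40, seed = 101)) {
    for (stratum in c("lt50", "ge50")) {
      expect_equal(relative_risk(p, stratum), yaml_rr_oracle(p, stratum),
                   tolerance = 1e-12)
    }
  }
})

test_that("relative risk is multiplicative over non-interacting factors", {
  # menarche and relatives share no interaction term
  a <- risk_factor_profile(40, "lt12", "lt20", 0, "absent", 0, "white")
  b <- risk_factor_profile(40, "ge14", "lt20", 0, "absent", "2plus", "white")
  ab <- risk_factor_profile(40, "lt12", "lt20", 0, "absent", "2plus", "white")
  expect_equal(relative_risk(ab, "lt50"),
               relative_risk(a, "lt50") * relative_risk(b, "lt50"))
})

test_that("absolute risk handles degenerate and invalid intervals", {
  p <- baseline_profile(45)
  expect_identical(absolute_risk(p, 45, 45), 0)
  expect_error(absolute_risk(p, 50, 45), "reversed")
  expect_error(absolute_risk(p, 40, 60), "current age")
  expect_warning(r <- absolute_risk(baseline_profile(18), 18, 95), "clipped")
  expect_true(r > 0 && r < 1)
})

test_that("all-baseline absolute risk is the AR-adjusted cumulative risk", {
  # independent computation straight from the YAML table, RR identically 1
  raw <- yaml::read_yaml(system.file("extdata", "gail_constants",
                                     "white.yaml", package = "transcreen"))
  surv <- 1
  acc <- 0
  for (b in raw$age_bands) {
    ar <- if (b$start < 50) raw$one_minus_ar$age_lt50 else raw$one_minus_ar$age_ge50
    h1 <- b$lambda1 * ar
    htot <- h1 + b$lambda2
    width <- b$end - b$start
    acc <- acc + h1 / htot * (1 - exp(-htot * width)) * surv
    surv <- surv * exp(-htot * width)
  }
  p <- baseline_profile(20)
  expect_equal(absolute_risk(p, 20, 90), acc, tolerance = 1e-14)
})

test_that("absolute risk is monotone in the horizon and in competing hazards", {
  p <- risk_factor_profile(40, "12to13", "ge30", 1, "absent", 1, "white")
  risks <- vapply(41:90, function(e) absolute_risk(p, 40, e), numeric(1))
  expect_true(all(diff(risks) >= 0))
  # inflating competing mortality never increases the cancer risk
  for (s in c(2, 5, 10)) {
    expect_lte(absolute_risk(p, 40, 90, competing_scale = s),
               absolute_risk(p, 40, 90))
  }
})

test_that("absolute risk is 0 under zero hazards and bounded under huge RR", {
  raw <- yaml::read_yaml(system.file("extdata", "gail_constants",
                                     "white.yaml", package = "transcreen"))
  for (i in seq_along(raw$age_bands)) {
    raw$age_bands[[i]]$lambda1 <- 0
    raw$age_bands[[i]]$lambda2 <- 0
  }
  k0 <- validate_gail_constants(raw)
  p <- baseline_profile(20)
  expect_identical(absolute_risk(p, 20, 90, constants = k0), 0)

  # push the relative risk to an extreme: the probability stays below 1
  raw2 <- yaml::read_yaml(system.file("extdata", "gail_constants",
                                      "white.yaml", package = "transcreen"))
  raw2$beta$n_relatives <- 20   # e^40 with two relatives
  khuge <- validate_gail_constants(raw2)
  pmax <- risk_factor_profile(20, "ge14", "lt20", 0, "absent", "2plus",
                              "white")
  r <- absolute_risk(pmax, 20, 90, constants = khuge)
  expect_true(r < 1 && r > 0.99)
})

test_that("closed-form risk agrees with the numerical integrator", {
  # a fixed reference profile, 5-year horizon
  ref <- risk_factor_profile(45, "12to13", "25to29_or_nulliparous", 1,
                             "absent", 1, "white")
  expect_lt(abs(absolute_risk(ref, 45, 50) - riemann_risk(ref, 45, 50)),
            1e-6)
  # seeded random profiles over random whole-year intervals
  profiles <- random_profiles(25, seed = 202)
  set.seed(203)
  for (p in profiles) {
    a <- max(20, p$current_age)
    b <- seq(a, 90)[sample.int(91 - a, 1)]
    expect_lt(abs(absolute_risk(p, a, b) - riemann_risk(p, a, b)), 1e-6)
  }
})

test_that("tier classification honors closed lower bounds and is total", {
  th <- gail_thresholds()
  expect_equal(classify_gail_category(0.005, 0.05, th),
               list(three_tier = "average", two_tier = "average"))
  expect_equal(classify_gail_category(0.02, 0.25, th)$three_tier, "high")
  expect_equal(classify_gail_category(0.02, 0.25, th)$two_tier,
               "higher_than_average")
  # exactly at a threshold -> upper tier
  expect_equal(classify_gail_category(0.001, 0.15, th)$three_tier,
               "intermediate")
  expect_equal(classify_gail_category(0.001, 0.20, th)$three_tier, "high")
  expect_equal(classify_gail_category(0.0167, 0.01, th)$two_tier,
               "higher_than_average")

  # one category flip per threshold under a +/- 1 ulp scan
  ulp_scan <- function(x) x * (1 + c(-1, 0, 1) * .Machine$double.eps)
  for (t in c(th$lifetime_low, th$lifetime_high)) {
    labs <- classify_gail_category(rep(0.001, 3), ulp_scan(t), th)$three_tier
    expect_equal(length(unique(labs)), 2)
    expect_equal(labs[2], labs[3])  # boundary belongs to the upper tier
  }
  labs <- classify_gail_category(ulp_scan(th$five_year_elevated),
                                 rep(0.01, 3), th)$two_tier
  expect_equal(labs, c("average", "higher_than_average",
                       "higher_than_average"))
})

test_that("threshold configuration is validated", {
  expect_error(gail_thresholds(lifetime_low = 0.25, lifetime_high = 0.20),
               "malformed")
  expect_error(gail_thresholds(five_year_elevated = 1.5), "probabilities")
  expect_error(classify_gail_category(1.0, 0.5), "\\[0, 1\\)")
})

test_that("gail_risk bundles projections with tiers consistently", {
  p <- risk_factor_profile(45, "lt12", "ge30", "2plus", "present", "2plus",
                           "white")
  est <- gail_risk(p)
  expect_true(est$five_year_risk > 0)
  expect_lt(est$five_year_risk, est$lifetime_risk)
  expect_lt(est$lifetime_risk, 1)
  retier <- classify_gail_category(est$five_year_risk, est$lifetime_risk)
  expect_equal(est$three_tier, retier$three_tier)
  expect_equal(est$two_tier, retier$two_tier)
})
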