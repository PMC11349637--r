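test_that("the eight canonical scenarios reproduce the printed ratings", {
  sc <- canonical_scenarios()
  for (i in seq_len(nrow(sc))) {
    rec <- scenario_recommendation(sc[i, ])
    expect_equal(rec$variant$id, sc$variant[i])
    expect_equal(rec$mammography_rating, sc$mammography[i],
                 label = paste("mammography for", sc$variant[i]))
    expect_equal(rec$ultrasound_rating, sc$ultrasound[i],
                 label = paste("ultrasound for", sc$variant[i]))
  }
})

test_that("profiles outside the printed table get explicit NO_MATCH outcomes", {
  # 30-year-old average-risk transwoman with long hormone exposure
  v <- classify_variant(trans_profile("transfeminine", 30, 8), "average")
  expect_equal(v$id, "NO_MATCH")
  expect_equal(v$reason, "below_age_threshold")
  expect_equal(v$first_matching_age, 40)
  rec <- recommend(v)
  expect_equal(rec$mammography_rating, "not_indicated")
  expect_match(rec$reevaluation_hint, "age 40")

  # 35-year-old average-risk transman
  v2 <- classify_variant(trans_profile("transmasculine", 35), "average")
  expect_equal(v2$id, "NO_MATCH")
  expect_equal(v2$first_matching_age, 40)
})

test_that("bilateral mastectomy dominates every other condition", {
  for (tier in c("average", "intermediate", "high")) {
    v <- classify_variant(
      trans_profile("transmasculine", 60, 20, "bilateral_mastectomy"), tier)
    expect_equal(v$id, "V5")
    expect_equal(recommend(v)$mammography_rating, "usually_not_appropriate")
  }
  # the AMAB arm is extrapolated onto the same rule
  v <- classify_variant(
    trans_profile("transfeminine", 60, 20, "bilateral_mastectomy"),
    "higher_than_average")
  expect_equal(v$id, "V5")
  expect_true(v$extrapolated)
})

test_that("non-binary identities route by sex assigned at birth, flagged", {
  v <- classify_variant(trans_profile("nonbinary_AMAB", 52, 8), "average")
  expect_equal(v$id, "V1")
  expect_equal(v$arm, "transwoman")
  expect_true(v$extrapolated)
  v2 <- classify_variant(trans_profile("nonbinary_AFAB", 45), "average")
  expect_equal(v2$id, "V6")
  expect_equal(v2$arm, "transman")
})

test_that("patient profile invariants are enforced", {
  expect_error(trans_profile("transfeminine", 40,
                             sex_assigned_at_birth = "female"),
               "implies sex assigned at birth")
  expect_error(trans_profile("transmasculine", 40, hormone_years = -1),
               "non-negative")
  expect_error(trans_profile("transmasculine", 95), "age")
  # the transman arm needs the three-tier vocabulary
  expect_error(classify_variant(trans_profile("transmasculine", 45),
                                "higher_than_average"),
               "three-tier")
})

test_that("hormone exposure partitions at exactly the threshold", {
  at <- classify_variant(trans_profile("transfeminine", 45, 5.0), "average")
  below <- classify_variant(trans_profile("transfeminine", 45, 4.999),
                            "average")
  expect_equal(at$id, "V1")
  expect_equal(below$id, "V3")
})

test_that("rating labels are totally ordered with a shared bottom rank", {
  expect_equal(rating_rank(c("usually_appropriate", "may_be_appropriate",
                             "usually_not_appropriate", "not_indicated")),
               c(3L, 2L, 1L, 1L))
  expect_error(rating_rank("sometimes"), "unknown rating")
})

test_that("the rendered decision table matches a brute-force cell count", {
  dt <- decision_table()
  expect_setequal(unique(dt$variant[dt$variant != "NO_MATCH"]),
                  paste0("V", 1:8))

  # independent count: scan every (arm, surgery, hormone bracket, tier)
  # combination over all integer ages and count outcome runs
  cells <- 0L
  for (arm in c("transwoman", "transman")) {
    tiers <- if (arm == "transwoman") {
      c("average", "higher_than_average")
    } else c("average", "intermediate", "high")
    for (h in c(0, 10)) {
      if (arm == "transman" && h > 0) next  # hormone-free arm
      for (tier in tiers) {
        g <- data.frame(arm = arm, age = 18:90, hormone_years = h,
                        chest_surgery = "none",
                        tier = if (tier == "higher_than_average") "high" else tier)
        if (arm == "transwoman" && tier == "higher_than_average") {
          g$tier <- "intermediate"  # any non-average three-tier label
        }
        ids <- classify_grid(g)$variant
        cells <- cells + length(rle(ids)$values)
      }
    }
    cells <- cells + 1L  # the mastectomy cell of this arm
  }
  expect_equal(nrow(dt), cells)
})

test_that("a degenerate config with equal age thresholds stays total", {
  cfg <- screening_config(v1_age = 18, v2_age = 18, v4_age = 18,
                          v6_age = 18, v7_age = 18, v8_age = 18)
  dt <- decision_table(cfg)
  expect_lt(nrow(dt), nrow(decision_table()))
  g <- classify_grid(exhaustive_grid(ages = c(18, 25, 60),
                                     hormone_years = c(0, 10)), cfg)
  expect_false(anyNA(g$variant))
})

test_that("screening configuration validates and loads from YAML", {
  expect_error(screening_config(v1_age = 10), "\\[18, 90\\]")
  expect_error(screening_config(hormone_years = -2), "non-negative")
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("v1_age: 45", "gail:", "  lifetime_high: 0.25"), f)
  cfg <- load_screening_config(f)
  expect_equal(cfg$v1_age, 45)
  expect_equal(cfg$gail$lifetime_high, 0.25)
  expect_equal(cfg$v2_age, 25)  # untouched default
  v <- classify_variant(trans_profile("transfeminine", 43, 8), "average", cfg)
  expect_equal(v$id, "NO_MATCH")  # below the raised V1 age
  f2 <- withr::local_tempfile(fileext = ".yaml")
  writeLines("frobnicate: 1", f2)
  expect_error(load_screening_config(f2), "unknown configuration")
})

test_that("recommendation records serialize with stable field names", {
  rec <- scenario_recommendation(canonical_scenarios()[7, ])
  r <- recommendation_record(rec)
  expect_named(r, c("variant", "arm", "tier_used", "mammography_rating",
                    "ultrasound_rating", "no_match_reason",
                    "first_matching_age", "extrapolated", "rationale",
                    "reevaluation_hint", "config_version"))
  json <- jsonlite::toJSON(r, auto_unbox = TRUE, na = "null")
  expect_equal(jsonlite::fromJSON(json)$variant, "V7")
})
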