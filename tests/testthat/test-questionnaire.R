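# Independent path-count oracle: memoized recursion over the item table,
# counting distinct terminal paths of the pruned binary answer tree.
dp_path_count <- function(items = questionnaire_items()) {
  memo <- rep(NA_real_, nrow(items))
  count <- function(id) {
    if (id == 0L) return(1)
    i <- match(id, items$id)
    if (!is.na(memo[i])) return(memo[i])
    memo[i] <<- count(items$yes_next[i]) + count(items$no_next[i])
    memo[i]
  }
  count(items$id[1])
}

test_that("the flow has exactly 16 items and passes its structural self-check", {
  expect_equal(item_count(), 16)
  items <- questionnaire_items()
  expect_equal(sort(items$id), 1:16)
})

test_that("the self-check fails on broken flows", {
  items <- questionnaire_items()
  expect_error(item_count(items[-16, ]), "self-check")
  cyclic <- items
  cyclic$no_next[16] <- 1L
  expect_error(item_count(cyclic), "cycle|more than")
})

test_that("every item is reachable on some enumerated path", {
  ep <- enumerate_paths()
  seen <- sort(unique(as.integer(sub("[YN]$", "",
                                     unlist(strsplit(ep$path, " "))))))
  expect_equal(seen, 1:16)
  expect_lte(max(ep$n_items), 16)
})

test_that("path enumeration matches the independent tree-walk count", {
  ep <- enumerate_paths()
  expect_equal(nrow(ep), dp_path_count())
  expect_false(any(duplicated(ep$path)))
  # every terminal path agrees with the direct classifier
  expect_equal(sum(ep$divergent), 0)
})

test_that("replaying a recorded answer list reproduces the recommendation", {
  s1 <- run_answer_string("YYYYYYYNNNNNNNNN")
  s2 <- run_answer_string("YYYYYYYNNNNNNNNN")
  expect_identical(recommendation_record(s1$recommendation),
                   recommendation_record(s2$recommendation))
  expect_identical(attr(s1, "path"), attr(s2, "path"))
})

test_that("a transfeminine path with long hormone use and no risk factors lands on V1", {
  res <- run_answer_string("YYYYYYYNNNNNNNNN")
  expect_equal(res$trans_profile$gender_identity, "transfeminine")
  expect_equal(res$trans_profile$age, 40)  # lowest age consistent with >=40
  expect_equal(res$trans_profile$hormone_years, 5)
  expect_equal(res$recommendation$variant$id, "V1")
  expect_equal(res$recommendation$mammography_rating, "may_be_appropriate")
})

test_that("a mastectomy answer terminates early with screening not appropriate", {
  recs <- lapply(c("NNNNNNNYNNNNNNNN", "NYNYNYNYNYNYNYNY"), function(a) {
    run_answer_string(a)
  })
  for (res in recs) {
    expect_equal(res$recommendation$variant$id, "V5")
    expect_equal(res$recommendation$mammography_rating,
                 "usually_not_appropriate")
    # early exit leaves every other field at its default
    expect_equal(res$trans_profile$hormone_years, 0)
    expect_equal(res$trans_profile$age, 18)
  }
  # the two paths asked exactly two questions
  expect_equal(nrow(attr(recs[[1]], "path")), 2)
})

test_that("stepwise advancing validates usage", {
  s <- questionnaire_start()
  expect_equal(s$current, 1L)
  s <- questionnaire_advance(s, "no")
  s <- questionnaire_advance(s, "yes")
  expect_true(s$complete)
  expect_error(questionnaire_advance(s, "yes"), "terminal")
  expect_error(questionnaire_advance(questionnaire_start(), "maybe"),
               "yes or no")
  expect_error(run_answer_string("YY"), "16-character")
  expect_error(run_answer_string("YYYYYYYNNNNNNNNX"), "16-character")
})

test_that("age brackets map to the lowest consistent integer age", {
  # AFAB, no surgery, ages: item5 no -> 18; 5y 6n -> 25; 6y 7n -> 30; 7y -> 40
  res18 <- run_answer_string("NNNNNNNNNNNNNNNN")
  res25 <- run_answer_string("NNNNYNNNNNNNNNNN")
  res30 <- run_answer_string("NNNNYYNNNNNNNNNN")
  res40 <- run_answer_string("NNNNYYYNNNNNNNNN")
  expect_equal(vapply(list(res18, res25, res30, res40),
                      function(r) r$trans_profile$age, numeric(1)),
               c(18, 25, 30, 40))
  # 40-year-old average-risk transman with no surgery is V6
  expect_equal(res40$recommendation$variant$id, "V6")
  expect_equal(res40$recommendation$mammography_rating,
               "usually_appropriate")
})

test_that("risk-factor answers raise the Gail tier through the flow", {
  # transman, 30-34, two relatives, hyperplasia on two biopsies, early
  # menarche, late first birth: high tier -> V8 needs age >= 25 only
  hot <- run_answer_string("NNNNYYNNNYYYYYYY")
  expect_equal(hot$gail$three_tier, "high")
  expect_equal(hot$recommendation$variant$id, "V8")
  cold <- run_answer_string("NNNNYYNNNNNNNNNN")
  expect_equal(cold$gail$three_tier, "average")
  expect_equal(cold$recommendation$variant$id, "NO_MATCH")
})
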