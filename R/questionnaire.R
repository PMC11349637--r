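# 16-item yes/no questionnaire flow -------------------------------------------
#
# The flow is a fixed acyclic graph over 16 items. Each answer may write one
# or more profile fields; branch targets depend only on (item, answer), so a
# recorded answer list replays to the same terminal state. Ages enter as
# bracketed yes/no items and are mapped to the lowest consistent integer age
# (18 / 25 / 30 / 40), a documented coarsening relative to the direct API.
# The surgery item is asked immediately on the transmasculine arm so that a
# bilateral mastectomy terminates the flow early (its recommendation cannot
# be changed by any later answer).

questionnaire_graph <- function() {
  data.frame(
    id = 1:16,
    text = c(
      "Were you assigned male at birth?",
      "Do you identify on the transfeminine spectrum?",
      "Have you ever used gender-affirming hormone therapy?",
      "Has your hormone use totaled 5 or more years (past or current)?",
      "Are you 25 or older?",
      "Are you 30 or older?",
      "Are you 40 or older?",
      "Have you had a bilateral (\"top\") mastectomy?",
      "Have you had breast-reduction surgery?",
      "Has a first-degree relative (parent, sibling, child) had breast cancer?",
      "Have two or more first-degree relatives had breast cancer?",
      "Have you ever had a breast biopsy?",
      "Have you had two or more breast biopsies?",
      "Did any biopsy show atypical hyperplasia?",
      "Did your menstrual periods start before age 12?",
      "Was your first live birth after age 30, or have you had no live birth?"),
    # 0 marks a terminal edge.
    yes_next = c(2L, 3L, 4L, 5L, 6L, 7L, 10L, 0L, 5L, 11L, 12L, 13L, 14L,
                 15L, 16L, 0L),
    no_next = c(8L, 3L, 5L, 5L, 10L, 10L, 10L, 9L, 5L, 12L, 12L, 15L, 14L,
                15L, 16L, 0L),
    stringsAsFactors = FALSE)
}

# Field writes per (item, answer). The accumulator starts at the lowest
# consistent defaults, so skipped items leave baseline values behind.
qf_defaults <- function() {
  list(sex_assigned_at_birth = "male",
       gender_identity = "transfeminine",
       age = 18, hormone_years = 0, chest_surgery = "none",
       n_relatives = "0", n_biopsies = "0", atypical_hyperplasia = "absent",
       age_at_menarche = "ge14", age_at_first_birth = "lt20")
}

qf_apply_answer <- function(acc, id, yes) {
  if (id == 1L) {
    if (!yes) {
      acc$sex_assigned_at_birth <- "female"
      acc$gender_identity <- "transmasculine"
    }
  } else if (id == 2L) {
    acc$gender_identity <- if (yes) "transfeminine" else "nonbinary_AMAB"
  } else if (id == 3L) {
    if (!yes) acc$hormone_years <- 0
  } else if (id == 4L) {
    # Lowest whole-year duration consistent with the answer.
    acc$hormone_years <- if (yes) 5 else 1
  } else if (id == 5L) {
    if (yes) acc$age <- 25
  } else if (id == 6L) {
    if (yes) acc$age <- 30
  } else if (id == 7L) {
    if (yes) acc$age <- 40
  } else if (id == 8L) {
    if (yes) acc$chest_surgery <- "bilateral_mastectomy"
  } else if (id == 9L) {
    acc$chest_surgery <- if (yes) "breast_reduction" else "none"
  } else if (id == 10L) {
    if (yes) acc$n_relatives <- "1"
  } else if (id == 11L) {
    if (yes) acc$n_relatives <- "2plus"
  } else if (id == 12L) {
    if (yes) acc$n_biopsies <- "1"
  } else if (id == 13L) {
    if (yes) acc$n_biopsies <- "2plus"
  } else if (id == 14L) {
    acc$atypical_hyperplasia <- if (yes) "present" else "absent"
  } else if (id == 15L) {
    acc$age_at_menarche <- if (yes) "lt12" else "ge14"
  } else if (id == 16L) {
    acc$age_at_first_birth <- if (yes) "ge30" else "lt20"
  }
  acc
}

qf_finalize <- function(acc, config) {
  tp <- trans_profile(acc$gender_identity, acc$age, acc$hormone_years,
                      acc$chest_surgery)
  rfp <- risk_factor_profile(acc$age, acc$age_at_menarche,
                             acc$age_at_first_birth, acc$n_biopsies,
                             acc$atypical_hyperplasia, acc$n_relatives,
                             race_group = "other")
  est <- gail_risk(rfp, thresholds = config$gail)
  rec <- recommend(classify_variant(tp, est, config), config)
  list(trans_profile = tp, risk_profile = rfp, gail = est,
       recommendation = rec)
}

#' The 16 questionnaire items
#'
#' @return A data frame with columns `id`, `text`, `yes_next`, `no_next`
#'   (branch targets; 0 marks a terminal edge).
#' @export
questionnaire_items <- function() questionnaire_graph()

#' Number of items in the questionnaire flow
#'
#' Counts the distinct items and runs the flow's structural self-check: the
#' branch graph must be acyclic, every path from item 1 must reach a
#' terminal, every item must be reachable, and no path may visit more than
#' 16 items.
#'
#' @param items Item table (defaults to the built-in flow); exposed so that
#'   tests can verify the self-check rejects a broken flow.
#' @return The number of items (16 for the built-in flow).
#' @export
item_count <- function(items = questionnaire_graph()) {
  n <- nrow(items)
  targets <- c(items$yes_next, items$no_next)
  if (any(targets != 0L & !(targets %in% items$id))) {
    stop("flow self-check failed: branch target outside the item set")
  }
  # Longest path to terminal from each item; Inf signals a cycle.
  depth <- rep(NA_real_, n)
  longest <- function(id, stack = integer()) {
    if (id == 0L) return(0)
    if (id %in% stack) stop("flow self-check failed: cycle through item ", id)
    i <- match(id, items$id)
    if (!is.na(depth[i])) return(depth[i])
    d <- 1 + max(longest(items$yes_next[i], c(stack, id)),
                 longest(items$no_next[i], c(stack, id)))
    depth[i] <<- d
    d
  }
  if (longest(items$id[1]) > n) {
    stop("flow self-check failed: a path visits more than ", n, " items")
  }
  reach <- new.env(parent = emptyenv())
  visit <- function(id) {
    if (id == 0L || !is.null(reach[[as.character(id)]])) return(invisible())
    reach[[as.character(id)]] <- TRUE
    i <- match(id, items$id)
    visit(items$yes_next[i]); visit(items$no_next[i])
  }
  visit(items$id[1])
  if (length(ls(reach)) != n) {
    stop("flow self-check failed: unreachable item(s) ",
         paste(setdiff(items$id, as.integer(ls(reach))), collapse = ", "))
  }
  n
}

#' Start a questionnaire session
#'
#' @param config A [screening_config()].
#' @return An object of class `questionnaire_state` positioned at item 1.
#' @seealso [questionnaire_advance()], [run_answer_string()]
#' @export
questionnaire_start <- function(config = screening_config()) {
  structure(list(current = 1L,
                 answered = data.frame(id = integer(), answer = character(),
                                       stringsAsFactors = FALSE),
                 acc = qf_defaults(),
                 config = config,
                 complete = FALSE,
                 result = NULL),
            class = "questionnaire_state")
}

as_yes <- function(answer) {
  if (is.logical(answer) && length(answer) == 1L && !is.na(answer)) {
    return(answer)
  }
  a <- tolower(as.character(answer))
  if (a %in% c("y", "yes")) return(TRUE)
  if (a %in% c("n", "no")) return(FALSE)
  stop("answer must be yes or no (got '", answer, "')")
}

#' Advance the questionnaire by one answer
#'
#' Applies the current item's write-effect and moves along the answered
#' branch. When a terminal edge is crossed, both profiles are reconstructed
#' from the accumulated answers, the Gail engine is run on the risk-factor
#' profile, and the same [classify_variant()] + [recommend()] pipeline as
#' the direct API produces the recommendation, stored in `$result`.
#'
#' @param state A `questionnaire_state`.
#' @param answer `"yes"`/`"no"` (also accepts `"y"`/`"n"` or a logical).
#' @return The updated `questionnaire_state`; check `$complete`, and on
#'   completion read `$result$recommendation` (plus the reconstructed
#'   `$result$trans_profile`, `$result$risk_profile`, `$result$gail`).
#' @examples
#' s <- questionnaire_start()
#' s <- questionnaire_advance(s, "no")   # assigned female at birth
#' s <- questionnaire_advance(s, "yes")  # bilateral mastectomy: terminal
#' s$result$recommendation
#' @export
questionnaire_advance <- function(state, answer) {
  stopifnot(inherits(state, "questionnaire_state"))
  if (state$complete) {
    stop("the questionnaire is complete; answering a terminal state is an error")
  }
  yes <- as_yes(answer)
  items <- questionnaire_graph()
  i <- match(state$current, items$id)
  state$acc <- qf_apply_answer(state$acc, state$current, yes)
  state$answered <- rbind(state$answered,
                          data.frame(id = state$current,
                                     answer = if (yes) "yes" else "no",
                                     stringsAsFactors = FALSE))
  nxt <- if (yes) items$yes_next[i] else items$no_next[i]
  if (nxt == 0L) {
    state$result <- qf_finalize(state$acc, state$config)
    state$complete <- TRUE
    state$current <- NA_integer_
  } else {
    state$current <- nxt
  }
  state
}

#' Score a positional 16-character answer string
#'
#' Machine mode of the questionnaire: character *k* of `answers` is the
#' yes/no answer to item *k*. The flow consumes only the items it visits
#' (branching prunes the rest), but all 16 positions must be supplied.
#'
#' @param answers A 16-character string over `Y`/`N` (case-insensitive).
#' @param config A [screening_config()].
#' @return The terminal result list (as in [questionnaire_advance()]), with
#'   the visited path attached as attribute `"path"` (a data frame of
#'   `id`, `answer`).
#' @examples
#' # Transfeminine, 5+ years of hormones, age >= 40, no flagged risk factors:
#' res <- run_answer_string("YYYYYYYNNNNNNNNN")
#' res$recommendation
#' @export
run_answer_string <- function(answers, config = screening_config()) {
  answers <- toupper(as.character(answers))
  if (length(answers) != 1L || is.na(answers) || nchar(answers) != 16L ||
      grepl("[^YN]", answers)) {
    stop("answers must be a single 16-character string over Y/N")
  }
  ans <- strsplit(answers, "")[[1]] == "Y"
  state <- questionnaire_start(config)
  while (!state$complete) {
    state <- questionnaire_advance(state, ans[state$current])
  }
  res <- state$result
  attr(res, "path") <- state$answered
  res
}

#' Exhaustively enumerate all terminal paths of the flow
#'
#' Depth-first traversal of the branch graph. Each terminal path is scored
#' twice: once by the flow itself and once by calling the direct
#' classifier/recommender on the path's reconstructed profile; a mismatch
#' marks the path as divergent (the central flow-vs-classifier oracle).
#'
#' @param config A [screening_config()].
#' @return A data frame with one row per terminal path: `path` (for example
#'   `"1Y 8N 9Y ..."`), `n_items`, the reconstructed profile fields,
#'   `tier_used`, `variant`, `mammography`, `ultrasound`, and `divergent`.
#' @export
enumerate_paths <- function(config = screening_config()) {
  items <- questionnaire_graph()
  rows <- vector("list", 2048)
  n_rows <- 0L
  walk <- function(id, acc, trail) {
    i <- match(id, items$id)
    for (yes in c(TRUE, FALSE)) {
      acc2 <- qf_apply_answer(acc, id, yes)
      trail2 <- c(trail, paste0(id, if (yes) "Y" else "N"))
      nxt <- if (yes) items$yes_next[i] else items$no_next[i]
      if (nxt == 0L) {
        res <- qf_finalize(acc2, config)
        direct <- recommend(
          classify_variant(res$trans_profile, res$gail, config), config)
        flow_rec <- res$recommendation
        n_rows <<- n_rows + 1L
        rows[[n_rows]] <<- data.frame(
          path = paste(trail2, collapse = " "),
          n_items = length(trail2),
          gender_identity = acc2$gender_identity,
          age = acc2$age,
          hormone_years = acc2$hormone_years,
          chest_surgery = acc2$chest_surgery,
          tier_used = flow_rec$variant$tier_used,
          variant = flow_rec$variant$id,
          mammography = flow_rec$mammography_rating,
          ultrasound = flow_rec$ultrasound_rating,
          divergent = !identical(
            recommendation_record(flow_rec)[c("variant", "mammography_rating",
                                              "ultrasound_rating")],
            recommendation_record(direct)[c("variant", "mammography_rating",
                                            "ultrasound_rating")]),
          stringsAsFactors = FALSE)
      } else {
        walk(nxt, acc2, trail2)
      }
    }
  }
  walk(1L, qf_defaults(), character())
  out <- do.call(rbind, rows[seq_len(n_rows)])
  rownames(out) <- NULL
  if (any(out$divergent)) {
    warning("flow/classifier equivalence failure on path(s): ",
            paste(utils::head(out$path[out$divergent], 5), collapse = "; "))
  }
  out
}

#' @export
print.questionnaire_state <- function(x, ...) {
  if (x$complete) {
    cat("Questionnaire complete after", nrow(x$answered), "answers\n")
    print(x$result$recommendation)
  } else {
    items <- questionnaire_graph()
    cat("Questionnaire at item ", x$current, " of ", nrow(items), ":\n  ",
        items$text[match(x$current, items$id)], "\n", sep = "")
  }
  invisible(x)
}
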