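# Interactive questionnaire session -------------------------------------------

#' Run the questionnaire interactively
#'
#' Walks the 16-item yes/no flow one prompt at a time and prints the
#' resulting recommendation with its variant and rationale. Intended for a
#' terminal session (the shipped command-line front-end wraps it); `input`
#' is parameterizable so scripted sessions and tests can drive it.
#'
#' @param input A connection to read answers from (default `stdin()`).
#' @param output A connection for prompts and the report (default
#'   `stdout()`).
#' @param config A [screening_config()].
#' @return The terminal result list (see [questionnaire_advance()]),
#'   invisibly.
#' @export
run_interactive <- function(input = stdin(), output = stdout(),
                            config = screening_config()) {
  items <- questionnaire_graph()
  state <- questionnaire_start(config)
  writeLines(c("Transgender chest/breast cancer screening questionnaire",
               "Answer yes or no (y/n)."), output)
  while (!state$complete) {
    q <- items$text[match(state$current, items$id)]
    writeLines(paste0("[", state$current, "/16] ", q), output)
    ans <- readLines(input, n = 1)
    if (length(ans) == 0) {
      stop("input ended at item ", state$current, " before the ",
           "questionnaire completed; re-run and answer every prompt")
    }
    ans <- trimws(ans)
    if (!tolower(ans) %in% c("y", "n", "yes", "no")) {
      writeLines("Please answer yes or no.", output)
      next
    }
    state <- questionnaire_advance(state, ans)
  }
  rec <- state$result$recommendation
  writeLines("", output)
  writeLines(utils::capture.output(print(rec)), output)
  writeLines(sprintf(paste0("5-year Gail risk %.2f%%, lifetime %.2f%% ",
                            "(tiers: %s / %s)"),
                     100 * state$result$gail$five_year_risk,
                     100 * state$result$gail$lifetime_risk,
                     state$result$gail$three_tier,
                     state$result$gail$two_tier), output)
  writeLines(paste("Decision support, not a diagnosis; review with a",
                   "clinician. Config version", config$version), output)
  invisible(state$result)
}
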