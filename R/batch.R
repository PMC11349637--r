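# Batch CSV scoring ------------------------------------------------------------

batch_columns <- c("patient_id", "gender_identity", "sex_assigned_at_birth",
                   "age", "hormone_years", "chest_surgery", "age_at_menarche",
                   "age_at_first_birth", "n_biopsies", "atypical_hyperplasia",
                   "n_relatives", "race_group")

#' Write a cohort to the batch CSV schema
#'
#' @param cohort A data frame as produced by [sample_cohort()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  missing_cols <- setdiff(batch_columns, names(cohort))
  if (length(missing_cols)) {
    stop("cohort is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  utils::write.csv(cohort[batch_columns], path, row.names = FALSE,
                   quote = FALSE, na = "")
  invisible(path)
}

#' Read a batch CSV
#'
#' The header is validated before any row is scored: all twelve documented
#' columns must be present (`patient_id`, `gender_identity`,
#' `sex_assigned_at_birth`, `age`, `hormone_years`, `chest_surgery`,
#' `age_at_menarche`, `age_at_first_birth`, `n_biopsies`,
#' `atypical_hyperplasia`, `n_relatives`, `race_group`). Empty cells in
#' categorical fields read as `"unknown"` (surgery as `"none"`, hormone
#' years as 0); a missing age is a per-row error at scoring time, never an
#' abort.
#'
#' @param path Path to a CSV file.
#' @return A data frame in the batch schema.
#' @export
read_batch_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  missing_cols <- setdiff(batch_columns, names(df))
  if (length(missing_cols)) {
    stop("malformed batch header; missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  df <- df[batch_columns]
  blank <- function(x) is.na(x) | trimws(x) == ""
  for (col in c("age_at_menarche", "age_at_first_birth", "n_biopsies",
                "atypical_hyperplasia", "n_relatives")) {
    df[[col]][blank(df[[col]])] <- "unknown"
  }
  df$race_group[blank(df$race_group)] <- "other"
  df$chest_surgery[blank(df$chest_surgery)] <- "none"
  df$hormone_years[blank(df$hormone_years)] <- "0"
  df$age <- suppressWarnings(as.numeric(df$age))
  df$hormone_years <- suppressWarnings(as.numeric(df$hormone_years))
  df
}

score_one <- function(row, config) {
  tp <- trans_profile(row$gender_identity, row$age, row$hormone_years,
                      row$chest_surgery,
                      sex_assigned_at_birth =
                        if (!is.na(row$sex_assigned_at_birth) &&
                            nzchar(row$sex_assigned_at_birth)) {
                          row$sex_assigned_at_birth
                        } else NULL)
  rfp <- risk_factor_profile(row$age, row$age_at_menarche,
                             row$age_at_first_birth, row$n_biopsies,
                             row$atypical_hyperplasia, row$n_relatives,
                             row$race_group)
  est <- gail_risk(rfp, thresholds = config$gail)
  rec <- recommend(classify_variant(tp, est, config), config)
  data.frame(patient_id = row$patient_id,
             five_year_risk = est$five_year_risk,
             lifetime_risk = est$lifetime_risk,
             three_tier = est$three_tier,
             two_tier = est$two_tier,
             variant = rec$variant$id,
             mammography = rec$mammography_rating,
             ultrasound = rec$ultrasound_rating,
             no_match_reason = rec$variant$reason,
             extrapolated = rec$extrapolated,
             error = NA_character_,
             stringsAsFactors = FALSE)
}

#' Score a batch of patient records
#'
#' Runs the full pipeline (Gail projection, tier classification, variant
#' match, imaging recommendation) on every row of a batch table. Row-level
#' validation failures are reported in the `error` column of that row and
#' never abort the batch. No input data is persisted beyond the requested
#' output files.
#'
#' @param input A CSV path or a data frame in the batch schema.
#' @param output Optional path for the scored CSV.
#' @param json Optional path for the scored JSON records.
#' @param config A [screening_config()].
#' @param quiet Suppress the summary log (default `FALSE`).
#' @return The scored data frame (one row per input row), invisibly when
#'   `output` is given.
#' @examples
#' scored <- run_batch(sample_cohort(cohort_config(n = 5, seed = 1)),
#'                     quiet = TRUE)
#' scored[, c("patient_id", "variant", "mammography")]
#' @export
run_batch <- function(input, output = NULL, json = NULL,
                      config = screening_config(), quiet = FALSE) {
  df <- if (is.character(input)) read_batch_csv(input) else {
    missing_cols <- setdiff(batch_columns, names(input))
    if (length(missing_cols)) {
      stop("malformed batch header; missing column(s): ",
           paste(missing_cols, collapse = ", "))
    }
    input[batch_columns]
  }
  empty <- score_one(list(patient_id = "x", gender_identity = "transfeminine",
                          sex_assigned_at_birth = "male", age = 40,
                          hormone_years = 0, chest_surgery = "none",
                          age_at_menarche = "unknown",
                          age_at_first_birth = "unknown", n_biopsies = "unknown",
                          atypical_hyperplasia = "unknown",
                          n_relatives = "unknown", race_group = "other"),
                     config)[0, ]
  scored <- lapply(seq_len(nrow(df)), function(i) {
    row <- as.list(df[i, ])
    tryCatch(score_one(row, config),
             error = function(e) {
               out <- empty[NA_integer_, ]
               out$patient_id <- as.character(row$patient_id)
               out$error <- conditionMessage(e)
               out
             })
  })
  scored <- if (length(scored)) do.call(rbind, scored) else empty
  rownames(scored) <- NULL
  if (!quiet) {
    ok <- sum(is.na(scored$error))
    message("transcreen: decision support, not a diagnosis; review with a ",
            "clinician. Constants/config version ", config$version, ".")
    message(ok, " scored, ", nrow(scored) - ok, " row error(s).")
    if (ok > 0) {
      tab <- table(scored$variant[is.na(scored$error)])
      message("variants: ",
              paste(names(tab), tab, sep = "=", collapse = ", "))
    }
  }
  if (!is.null(output)) {
    utils::write.csv(scored, output, row.names = FALSE, na = "")
  }
  if (!is.null(json)) {
    jsonlite::write_json(scored, json, auto_unbox = FALSE, na = "null",
                         digits = NA)
  }
  if (is.null(output) && is.null(json)) scored else invisible(scored)
}
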