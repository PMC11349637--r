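#' @keywords internal
"_PACKAGE"

# Levels shared across the package ------------------------------------------

.race_groups <- c("white", "black", "hispanic", "asian_pacific_islander", "other")
.menarche_levels <- c("ge14", "12to13", "lt12", "unknown")
.first_birth_levels <- c("lt20", "20to24", "25to29_or_nulliparous", "ge30", "unknown")
.count_levels <- c("0", "1", "2plus", "unknown")
.hyperplasia_levels <- c("absent", "present", "unknown")
.identity_levels <- c("transfeminine", "transmasculine", "nonbinary_AMAB", "nonbinary_AFAB")
.surgery_levels <- c("none", "breast_reduction", "bilateral_mastectomy")
.three_tier_levels <- c("average", "intermediate", "high")
.two_tier_levels <- c("average", "higher_than_average")
.rating_levels <- c("not_indicated", "usually_not_appropriate",
                    "may_be_appropriate", "usually_appropriate")

.constants_cache <- new.env(parent = emptyenv())

#' Load a Gail-model constant block for one race/ethnicity group
#'
#' Constant blocks ship with the package as versioned, human-readable YAML
#' files (one per race group, under `extdata/gail_constants/`). Each block
#' holds the log relative-risk coefficients (including the two published
#' interaction terms), the atypical-hyperplasia multipliers, the
#' attributable-risk adjustment `1 - AR` per age stratum, and the composite
#' invasive breast-cancer incidence and competing (non-breast-cancer)
#' mortality hazards on 5-year age bands tiling \[20, 90). Blocks are
#' validated on load and cached for the session.
#'
#' @param race_group One of `"white"`, `"black"`, `"hispanic"`,
#'   `"asian_pacific_islander"`, `"other"`. The `"other"` block is an alias
#'   for the White block (the convention of the NCI risk tool for unknown
#'   race/ethnicity).
#' @param path Directory containing the YAML blocks; defaults to the copies
#'   installed with the package.
#' @return An object of class `gail_constants`: a list with elements
#'   `race_group`, `version`, `beta`, `hyperplasia_rr`, `one_minus_ar`, and
#'   `age_bands` (a data frame with columns `start`, `end`, `lambda1`,
#'   `lambda2`).
#' @examples
#' k <- gail_constants("white")
#' k$age_bands
#' @export
gail_constants <- function(race_group = "white", path = NULL) {
  race_group <- match.arg(race_group, .race_groups)
  default_path <- is.null(path)
  if (default_path) {
    key <- race_group
    if (!is.null(.constants_cache[[key]])) return(.constants_cache[[key]])
    path <- system.file("extdata", "gail_constants", package = "transcreen")
  }
  file <- file.path(path, paste0(race_group, ".yaml"))
  if (!file.exists(file)) {
    stop("no constant block for race group '", race_group, "' at ", file)
  }
  raw <- yaml::read_yaml(file)
  if (!is.null(raw$alias)) {
    base <- gail_constants(raw$alias, path = if (default_path) NULL else path)
    base$race_group <- race_group
    base$alias_of <- raw$alias
    if (default_path) .constants_cache[[race_group]] <- base
    return(base)
  }
  k <- validate_gail_constants(raw)
  if (default_path) .constants_cache[[race_group]] <- k
  k
}

#' Validate a Gail-model constant block
#'
#' Checks structural completeness (every coefficient named, both
#' attributable-risk strata present), that hazards are non-negative, and that
#' the age bands tile \[20, 90) without gaps or overlaps.
#'
#' @param raw A list as read from a constant-block YAML file.
#' @return The validated block, classed `gail_constants`.
#' @export
validate_gail_constants <- function(raw) {
  need_beta <- c("n_biopsies", "age_at_menarche", "age_at_first_birth",
                 "n_relatives", "biopsies_x_age_ge50", "first_birth_x_relatives")
  beta <- raw$beta
  if (!all(need_beta %in% names(beta))) {
    stop("constant block '", raw$race_group, "' is missing coefficients: ",
         paste(setdiff(need_beta, names(beta)), collapse = ", "))
  }
  beta <- vapply(beta[need_beta], as.numeric, numeric(1))
  if (anyNA(beta)) stop("non-numeric coefficient in block '", raw$race_group, "'")

  hyp <- raw$hyperplasia_rr
  need_hyp <- c("present", "absent_with_biopsy", "unknown_or_no_biopsy")
  if (!all(need_hyp %in% names(hyp))) {
    stop("incomplete hyperplasia multipliers in block '", raw$race_group, "'")
  }
  hyp <- vapply(hyp[need_hyp], as.numeric, numeric(1))
  if (any(hyp <= 0)) stop("hyperplasia multipliers must be positive")

  ar <- raw$one_minus_ar
  if (!all(c("age_lt50", "age_ge50") %in% names(ar))) {
    stop("incomplete attributable-risk adjustment in block '", raw$race_group, "'")
  }
  ar <- vapply(ar[c("age_lt50", "age_ge50")], as.numeric, numeric(1))
  if (any(ar <= 0 | ar > 1)) stop("1-AR factors must lie in (0, 1]")

  bands <- do.call(rbind, lapply(raw$age_bands, function(b) {
    data.frame(start = as.numeric(b$start), end = as.numeric(b$end),
               lambda1 = as.numeric(b$lambda1), lambda2 = as.numeric(b$lambda2))
  }))
  bands <- bands[order(bands$start), , drop = FALSE]
  rownames(bands) <- NULL
  if (any(bands$lambda1 < 0) || any(bands$lambda2 < 0)) {
    stop("hazards must be non-negative in block '", raw$race_group, "'")
  }
  if (bands$start[1] != 20 || bands$end[nrow(bands)] != 90 ||
      any(bands$end[-nrow(bands)] != bands$start[-1])) {
    stop("age bands must tile [20, 90) without gaps or overlaps in block '",
         raw$race_group, "'")
  }
  structure(
    list(race_group = raw$race_group,
         version = as.character(raw$version),
         provenance = raw$provenance,
         beta = beta, hyperplasia_rr = hyp, one_minus_ar = ar,
         age_bands = bands),
    class = "gail_constants")
}

#' @export
print.gail_constants <- function(x, ...) {
  cat("Gail-model constants: race group '", x$race_group, "' (version ",
      x$version, ")\n", sep = "")
  if (!is.null(x$alias_of)) cat("  alias of block '", x$alias_of, "'\n", sep = "")
  cat("  log relative risks:\n")
  for (nm in names(x$beta)) cat(sprintf("    %-24s % .10f\n", nm, x$beta[[nm]]))
  cat(sprintf("  1-AR: %.7f (<50), %.7f (>=50)\n",
              x$one_minus_ar[["age_lt50"]], x$one_minus_ar[["age_ge50"]]))
  cat("  age bands: ", nrow(x$age_bands), " x [",
      x$age_bands$start[1], ", ", x$age_bands$end[nrow(x$age_bands)], ")\n",
      sep = "")
  invisible(x)
}
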