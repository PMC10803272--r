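# Observation-level extraction tables: schema, validation, I/O, log transform.

#' @keywords internal
.obs_enums <- list(
  design = c("prospective_cohort", "case_control", "nested_case_control",
             "retrospective_cohort", "case_cohort", "case_crossover"),
  smoking_status = c("never", "former", "nonsmoker", "any_unspecified",
                     "adjusted_never"),
  exposure_location = c("home_or_work", "home", "work", "any_unspecified"),
  exposure_source = c("family", "parental", "maternal", "paternal", "spouse",
                      "any_unspecified"),
  exposure_timing = c("current", "ever"),
  sex_scope = c("both", "female", "male"),
  subgroup_level = c("whole_population", "sex_specific", "age_specific",
                     "other_subgroup"),
  endpoint_type = c("incidence", "mortality", "combined")
)

.obs_columns <- c("obs_id", "study_id", "outcome_id", "rr", "ci_lower",
                  "ci_upper", "se_log_rr", "design", "smoking_status",
                  "exposure_location", "exposure_source", "exposure_timing",
                  "sex_scope", "children_only", "subgroup_level",
                  "endpoint_type", "adjustment_rank", "group_key",
                  "mutually_exclusive")

#' Column dictionary for extraction tables
#'
#' Returns the canonical column set of the comma-separated extraction-table
#' dialect read by [read_extraction_table()]. Bias covariates travel as
#' additional 0/1 columns prefixed `"bc_"`; the gold-standard study has all
#' of them equal to 0.
#'
#' @return Character vector of required column names.
#' @export
extraction_columns <- function() .obs_columns

## Validate one parsed table; returns list(records, rejected).
## Each rejected row is reported with its 1-based data-row number and reason.
.validate_observations <- function(df) {
  n <- nrow(df)
  reasons <- character(n)
  flag <- function(bad, msg) {
    bad <- which(bad & !nzchar(reasons))
    reasons[bad] <<- msg
  }

  flag(is.na(df$rr) | df$rr <= 0, "rr must be a positive number")
  has_ci <- !is.na(df$ci_lower) & !is.na(df$ci_upper)
  has_se <- !is.na(df$se_log_rr)
  flag(has_ci & (df$ci_lower <= 0 | df$ci_lower > df$rr | df$ci_upper < df$rr),
       "CI must satisfy 0 < ci_lower <= rr <= ci_upper")
  flag(has_ci & has_se, "exactly one of CI pair and se_log_rr may be given")
  flag(!has_ci & !has_se, "no resolvable uncertainty (CI pair or se_log_rr)")
  flag(has_se & df$se_log_rr <= 0, "se_log_rr must be positive")
  flag(has_ci & df$ci_lower == df$ci_upper, "degenerate CI (zero width)")
  for (col in names(.obs_enums))
    flag(!(df[[col]] %in% .obs_enums[[col]]),
         sprintf("invalid %s value", col))
  flag(df$smoking_status == "adjusted_never" & !df$children_only,
       "adjusted_never smoking status requires children_only = TRUE")
  flag(is.na(df$adjustment_rank), "adjustment_rank must be an integer")
  flag(duplicated(df$obs_id), "duplicate obs_id")

  ok <- !nzchar(reasons)
  rejected <- data.frame(row = which(!ok), obs_id = df$obs_id[!ok],
                         reason = reasons[!ok], stringsAsFactors = FALSE)
  list(records = df[ok, , drop = FALSE], rejected = rejected)
}

#' Read an observation-level extraction table
#'
#' Reads a comma-separated extraction table (one row per reported effect
#' size) and validates every row against the observation-record invariants:
#' positive relative risk, a consistent 95% CI or a positive log-scale
#' standard error (exactly one of the two), admissible values for the
#' design/exposure/population descriptors, and the rule that the
#' `adjusted_never` smoking status is only admissible for children-only
#' samples. Rows violating an invariant are dropped and reported, with row
#' numbers, via a warning and the `"rejected"` attribute of the result.
#'
#' Unicode minus signs are normalized to ASCII before parsing so tables
#' pasted from publications read cleanly.
#'
#' @param path Path to a delimited text file with a header row.
#' @param schema Optional named character vector mapping canonical column
#'   names (see [extraction_columns()]) to the file's column names.
#' @return A `data.frame` of validated observation records, one row per
#'   valid input row, with bias-flag columns (`bc_*`) carried through.
#'   Attribute `"rejected"` holds a data frame of dropped rows and reasons.
#' @seealso [write_extraction_table()], [to_log_scale()]
#' @export
read_extraction_table <- function(path, schema = NULL) {
  raw <- readLines(path, encoding = "UTF-8", warn = FALSE)
  raw <- gsub("−|–", "-", raw)  # unicode minus/en-dash -> ASCII
  df <- utils::read.csv(text = raw, stringsAsFactors = FALSE)

  if (!is.null(schema)) {
    hit <- match(schema, names(df))
    if (anyNA(hit))
      stop("schema maps to columns absent from file: ",
           paste(schema[is.na(hit)], collapse = ", "))
    names(df)[hit] <- names(schema)
  }
  missing <- setdiff(.obs_columns, names(df))
  if (length(missing))
    stop("extraction table is missing required columns: ",
         paste(missing, collapse = ", "))

  for (col in c("rr", "ci_lower", "ci_upper", "se_log_rr"))
    df[[col]] <- as.numeric(df[[col]])
  df$adjustment_rank <- as.integer(df$adjustment_rank)
  df$children_only <- as.logical(df$children_only)
  df$mutually_exclusive <- as.logical(df$mutually_exclusive)
  bc <- grep("^bc_", names(df), value = TRUE)
  for (col in bc) {
    df[[col]] <- as.integer(df[[col]])
    if (!all(df[[col]] %in% c(0L, 1L)))
      stop("bias-flag column ", col, " must be 0/1")
  }

  out <- .validate_observations(df)
  if (nrow(out$rejected))
    warning(sprintf(
      "dropped %d invalid row(s): %s", nrow(out$rejected),
      paste(sprintf("row %d (%s)", out$rejected$row, out$rejected$reason),
            collapse = "; ")))
  records <- out$records
  rownames(records) <- NULL
  attr(records, "rejected") <- out$rejected
  records
}

#' Write an observation-level extraction table
#'
#' Writes records in the same comma-separated dialect read by
#' [read_extraction_table()], so that a write/read round trip is the
#' identity on valid records.
#'
#' @param records Data frame of observation records.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_extraction_table <- function(records, path) {
  cols <- c(.obs_columns, grep("^bc_", names(records), value = TRUE))
  if (nrow(records) == 0 && !all(cols %in% names(records)))
    cols <- .obs_columns
  utils::write.csv(records[, cols, drop = FALSE], path, row.names = FALSE,
                   quote = FALSE, na = "")
  invisible(path)
}

#' Transform effect sizes to the log scale
#'
#' Adds `log_rr` and, where absent, `se_log_rr` columns. The pooled model
#' works throughout in log relative-risk space; a reported 95% CI is
#' converted to a log-scale standard error under the lognormal sampling
#' model, `se = (log(ci_upper) - log(ci_lower)) / (2 * 1.96)`. A reported
#' `se_log_rr` is passed through unchanged.
#'
#' @param records Data frame of observation records.
#' @return `records` with `log_rr` and `se_log_rr` populated for every row.
#' @export
to_log_scale <- function(records) {
  has_ci <- !is.na(records$ci_lower) & !is.na(records$ci_upper)
  if (any(has_ci & records$ci_lower == records$ci_upper))
    stop("zero-variance observation: ci_lower equals ci_upper for ",
         paste(records$obs_id[has_ci & records$ci_lower == records$ci_upper],
               collapse = ", "))
  records$log_rr <- log(records$rr)
  fill <- has_ci & is.na(records$se_log_rr)
  records$se_log_rr[fill] <-
    (log(records$ci_upper[fill]) - log(records$ci_lower[fill])) / (2 * 1.96)
  if (any(records$se_log_rr <= 0, na.rm = TRUE))
    stop("non-positive se_log_rr after CI conversion")
  records
}
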