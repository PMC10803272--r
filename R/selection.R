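# Prioritization cascade and standard-error inflation for repeated
# non-mutually-exclusive exposure groups.

#' Selection-cascade configuration
#'
#' Priority lists mirror the GBD exposure definition for secondhand smoke
#' (current exposure among nonsmokers at home or work): the best-matching
#' smoking status is preferred first, then the location of exposure, then
#' the source, then the temporality (current before ever). Each list is a
#' permutation of the admissible values of its field, most preferred first.
#'
#' @param smoking_priority,location_priority,source_priority,timing_priority
#'   Character vectors ordering the admissible values of the corresponding
#'   observation field, most preferred first.
#' @param prefer_combined_endpoint Prefer combined incidence+mortality
#'   endpoints over either alone.
#' @param prefer_whole_population Prefer whole-population estimates over
#'   sex-, age- or otherwise subgroup-specific ones.
#' @param subtype_outcomes Named list mapping an aggregate outcome label to
#'   the subtype labels dropped when the aggregate is present in the same
#'   study (e.g. `list(stroke = c("ischemic_stroke", "hemorrhagic_stroke"))`).
#' @param break_ties If `TRUE` (default), ties surviving the full cascade
#'   within a study/outcome/group cell are broken to a single record by
#'   smallest `se_log_rr`, then lexicographic `obs_id`; if `FALSE` all
#'   tied-best records are retained (and should then be standard-error
#'   inflated via [adjust_se_for_repeats()]).
#' @return An object of class `"selection_config"`.
#' @export
selection_config <- function(
    smoking_priority = c("nonsmoker", "never", "adjusted_never", "former",
                         "any_unspecified"),
    location_priority = c("home_or_work", "home", "work", "any_unspecified"),
    source_priority = c("any_unspecified", "family", "spouse", "parental",
                        "maternal", "paternal"),
    timing_priority = c("current", "ever"),
    prefer_combined_endpoint = TRUE,
    prefer_whole_population = TRUE,
    subtype_outcomes = list(),
    break_ties = TRUE) {
  chk <- function(x, field) {
    if (!setequal(x, .obs_enums[[field]]))
      stop(field, " priority must be a permutation of: ",
           paste(.obs_enums[[field]], collapse = ", "))
    x
  }
  structure(list(
    smoking_priority = chk(smoking_priority, "smoking_status"),
    location_priority = chk(location_priority, "exposure_location"),
    source_priority = chk(source_priority, "exposure_source"),
    timing_priority = chk(timing_priority, "exposure_timing"),
    prefer_combined_endpoint = isTRUE(prefer_combined_endpoint),
    prefer_whole_population = isTRUE(prefer_whole_population),
    subtype_outcomes = subtype_outcomes,
    break_ties = isTRUE(break_ties)
  ), class = "selection_config")
}

## Keep the rows attaining the minimum of `rank`; log the rest under `rule`.
.keep_best <- function(df, rank, rule, log_env) {
  best <- rank == min(rank)
  if (any(!best))
    log_env$log <- rbind(log_env$log, data.frame(
      obs_id = df$obs_id[!best], eliminated_by_rule = rule,
      stringsAsFactors = FALSE))
  df[best, , drop = FALSE]
}

#' Apply the prioritization cascade to one study/outcome cell
#'
#' Reduces the observations each study reports for one outcome to the
#' analysis set, in three stages: (1) exposure-definition match against the
#' reference definition — smoking status, then exposure location, then
#' source, then timing; (2) least granular analysis — whole-population over
#' subgroup estimates, combined endpoints over incidence- or mortality-only,
#' aggregate outcomes over subtypes; (3) highest covariate-adjustment rank.
#' Remaining ties break to one record by smallest standard error, then
#' lexicographic `obs_id` (unless `config$break_ties` is `FALSE`).
#'
#' The cascade runs independently within each study x outcome x `group_key`
#' cell, so mutually exclusive population groups (e.g. sex- or age-specific
#' samples reported separately) each contribute their own selected record.
#'
#' @param records Data frame of observation records for a single outcome
#'   (aggregate plus any configured subtype labels).
#' @param config A [selection_config()].
#' @return The selected records, with attribute `"audit"`: a data frame
#'   (`obs_id`, `eliminated_by_rule`) recording the rule that eliminated
#'   each dropped observation.
#' @export
select_observations <- function(records, config = selection_config()) {
  stopifnot(inherits(config, "selection_config"))
  audit <- new.env()
  audit$log <- data.frame(obs_id = character(), eliminated_by_rule = character(),
                          stringsAsFactors = FALSE)
  if (nrow(records) == 0) {
    warning("select_observations: empty input")
    attr(records, "audit") <- audit$log
    return(records)
  }

  outcomes <- unique(records$outcome_id)
  agg <- intersect(names(config$subtype_outcomes), outcomes)
  if (length(setdiff(outcomes, c(agg, unlist(config$subtype_outcomes[agg])))) > 1 &&
      length(agg) == 0 && length(outcomes) > 1)
    stop("records span multiple outcomes with no subtype mapping")

  # aggregate-over-subtype: within a study, drop subtype rows when the
  # aggregate outcome is reported
  for (a in agg) {
    subs <- config$subtype_outcomes[[a]]
    for (s in unique(records$study_id)) {
      in_study <- records$study_id == s
      if (any(in_study & records$outcome_id == a)) {
        drop <- in_study & records$outcome_id %in% subs
        if (any(drop)) {
          audit$log <- rbind(audit$log, data.frame(
            obs_id = records$obs_id[drop],
            eliminated_by_rule = "subtype_dropped_for_aggregate",
            stringsAsFactors = FALSE))
          records <- records[!drop, , drop = FALSE]
        }
      }
    }
  }

  # stage 1: exposure-definition match, within each study x group cell so
  # that mutually exclusive population groups are each represented
  cell <- function(df) interaction(df$study_id, df$group_key, drop = TRUE)
  stage1 <- lapply(split(records, cell(records)), function(df) {
    df <- .keep_best(df, match(df$smoking_status, config$smoking_priority),
                     "smoking_status_priority", audit)
    df <- .keep_best(df, match(df$exposure_location, config$location_priority),
                     "exposure_location_priority", audit)
    df <- .keep_best(df, match(df$exposure_source, config$source_priority),
                     "exposure_source_priority", audit)
    .keep_best(df, match(df$exposure_timing, config$timing_priority),
               "exposure_timing_priority", audit)
  })
  records <- do.call(rbind, stage1)

  # stage 2: least granular analysis, study-wide and conditional on an
  # aggregate actually being present (subgroup rows are only dropped in
  # favor of an aggregate, never unconditionally)
  stage2 <- lapply(split(records, records$study_id), function(df) {
    if (config$prefer_whole_population &&
        any(df$subgroup_level == "whole_population"))
      df <- .keep_best(df, ifelse(df$subgroup_level == "whole_population",
                                  0L, 1L),
                       "subgroup_dropped_for_aggregate", audit)
    if (config$prefer_combined_endpoint &&
        any(df$endpoint_type == "combined"))
      df <- .keep_best(df, ifelse(df$endpoint_type == "combined", 0L, 1L),
                       "endpoint_dropped_for_combined", audit)
    df
  })
  records <- do.call(rbind, stage2)

  # stage 3: highest adjustment rank, then the deterministic tie-break,
  # within each remaining study x group cell
  stage3 <- lapply(split(records, cell(records)), function(df) {
    df <- .keep_best(df, -df$adjustment_rank, "adjustment_rank", audit)
    if (config$break_ties && nrow(df) > 1) {
      # tables may arrive before to_log_scale, so resolve se from the CI
      se <- ifelse(!is.na(df$se_log_rr), df$se_log_rr,
                   (log(df$ci_upper) - log(df$ci_lower)) / (2 * 1.96))
      df <- .keep_best(df, order(order(se, df$obs_id)) != 1L,
                       "tie_break_se_then_id", audit)
    }
    df
  })
  out <- do.call(rbind, stage3)
  out <- out[order(out$obs_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "audit") <- audit$log
  out
}

#' Inflate standard errors for repeated non-mutually-exclusive observations
#'
#' Multiple effect sizes reported for overlapping (non-mutually-exclusive)
#' exposure groups within the same age-sex-smoking-status group of a study
#' are not independent. To stop them from jointly over-weighting their
#' study, each of the k >= 2 such observations has its standard error
#' inflated so that the group as a whole carries the information of a
#' single observation.
#'
#' With `factor = "sqrt_k"` (default) the standard error is multiplied by
#' sqrt(k), i.e. the variance by k, so the sum of inverse variances of the
#' group equals one pre-inflation observation's. `factor = "k"` applies the
#' literal multiplier k.
#'
#' @param records Data frame of observation records with `se_log_rr`,
#'   `group_key` and `mutually_exclusive` populated.
#' @param factor `"sqrt_k"` (information-preserving, default) or `"k"`.
#' @return `records` with inflated `se_log_rr` (and widened CI columns kept
#'   `NA`-consistent: the CI columns are left untouched; downstream code
#'   works from `se_log_rr`).
#' @export
adjust_se_for_repeats <- function(records, factor = c("sqrt_k", "k")) {
  factor <- match.arg(factor)
  if (nrow(records) == 0) return(records)
  if (is.null(records$se_log_rr) || anyNA(records$se_log_rr))
    stop("se_log_rr must be populated (run to_log_scale first)")
  key <- paste(records$study_id, records$group_key, sep = "\r")
  k <- stats::ave(as.numeric(!records$mutually_exclusive), key, FUN = sum)
  hit <- !records$mutually_exclusive & k >= 2
  mult <- if (factor == "sqrt_k") sqrt(k) else k
  records$se_log_rr[hit] <- records$se_log_rr[hit] * mult[hit]
  records
}
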