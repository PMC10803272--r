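# End-to-end orchestration: read -> cascade -> SE inflation -> candidate
# matrix -> covariate selection -> trimmed fit -> scoring -> Egger, with
# the sensitivity restrictions used for model validation.

#' Pipeline run configuration
#'
#' @param input Path to an extraction table or a data frame of observation
#'   records.
#' @param outcome_id Outcome analyzed; records for other outcomes are
#'   dropped (subtype labels mapped by the selection config are kept).
#' @param selection A [selection_config()].
#' @param trim_fraction Trimming fraction, default 0.10 (applied only when
#'   at least 10 observations reach the fit).
#' @param alpha Significance threshold for covariate selection and the
#'   Egger test.
#' @param direction `"harmful"` or `"protective"`.
#' @param sensitivity Character vector drawn from `"prospective_only"`,
#'   `"never_smokers_only"`, `"both"`, `"children_only"`; each named
#'   restriction is rerun on the filtered input in addition to the primary
#'   analysis.
#' @param se_inflation `"sqrt_k"` or `"k"`, passed to
#'   [adjust_se_for_repeats()].
#' @param covariate_method Passed to [select_bias_covariates()].
#' @param seed Seed for the duplicate-covariate draw and any stochastic
#'   restart.
#' @param output_dir Optional directory; when given, the evidence summary,
#'   selected-covariate report, funnel table, audit log and a
#'   reproducibility manifest are written there as CSV/JSON.
#' @return An object of class `"run_config"`.
#' @export
run_config <- function(input, outcome_id = "outcome",
                       selection = selection_config(),
                       trim_fraction = 0.10, alpha = 0.05,
                       direction = c("harmful", "protective"),
                       sensitivity = character(0),
                       se_inflation = c("sqrt_k", "k"),
                       covariate_method = "stepwise_lasso",
                       seed = 1L, output_dir = NULL) {
  stopifnot(trim_fraction >= 0, trim_fraction < 0.5, alpha > 0, alpha < 1)
  bad <- setdiff(sensitivity, c("prospective_only", "never_smokers_only",
                                "both", "children_only"))
  if (length(bad)) stop("unknown sensitivity filter(s): ",
                        paste(bad, collapse = ", "))
  structure(list(input = input, outcome_id = outcome_id,
                 selection = selection, trim_fraction = trim_fraction,
                 alpha = alpha, direction = match.arg(direction),
                 sensitivity = sensitivity,
                 se_inflation = match.arg(se_inflation),
                 covariate_method = covariate_method,
                 seed = as.integer(seed), output_dir = output_dir),
            class = "run_config")
}

.sensitivity_filters <- list(
  prospective_only = function(r) r$design == "prospective_cohort",
  never_smokers_only = function(r) r$smoking_status %in% c("never",
                                                           "adjusted_never"),
  both = function(r) r$design == "prospective_cohort" &
    r$smoking_status %in% c("never", "adjusted_never"),
  children_only = function(r) r$children_only
)

.empty_report <- function(stage_counts) {
  list(score = NULL, fit = NULL, covariates = NULL, egger = NULL,
       funnel = NULL, audit = NULL, stage_counts = stage_counts,
       empty = TRUE)
}

.run_one <- function(records, config) {
  counts <- c(input = nrow(records))
  if (nrow(records) == 0) return(.empty_report(counts))

  selected <- select_observations(records, config$selection)
  audit <- attr(selected, "audit")
  counts["after_cascade"] <- nrow(selected)
  if (nrow(selected) == 0 || length(unique(selected$study_id)) < 2)
    return(.empty_report(counts))

  selected <- to_log_scale(selected)
  selected <- adjust_se_for_repeats(selected, factor = config$se_inflation)

  cand <- build_candidate_matrix(selected, seed = config$seed)
  sel <- select_bias_covariates(selected, cand, alpha = config$alpha,
                                method = config$covariate_method)
  design <- if (length(sel$selected))
    cand$matrix[, sel$selected, drop = FALSE] else NULL

  fit <- fit_trimmed(selected, design, trim_fraction = config$trim_fraction)
  counts["after_trimming"] <- fit$n_obs_used

  score <- evidence_score(fit, config$direction)
  funnel <- export_funnel(fit, selected, design = design)
  egger <- eggers_test(funnel, alpha = config$alpha)

  list(score = score, fit = fit, covariates = sel$coefficients,
       egger = egger, funnel = funnel, audit = audit,
       stage_counts = counts, empty = FALSE)
}

#' Run the full evidence-scoring pipeline
#'
#' Executes, for one risk-outcome pair: table read and validation, the
#' prioritization cascade, standard-error inflation for repeated
#' non-mutually-exclusive observations, candidate bias-covariate
#' construction and step-wise Lasso selection, the trimmed mixed-effects
#' fit, conservative intervals / BPRF / ROS / star rating, and Egger's
#' publication-bias test. Any requested sensitivity restrictions rerun the
#' same pipeline on the filtered input. The pipeline is a pure function of
#' the input table and configuration; identical inputs give identical
#' outputs.
#'
#' @param config A [run_config()].
#' @return List of class `"bprf_report"` with elements `primary` (score,
#'   fit, covariate report, Egger result, funnel table, audit log, stage
#'   counts) and `sensitivity` (named list of the same shape).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  records <- if (is.character(config$input))
    read_extraction_table(config$input) else config$input
  subtype <- unlist(config$selection$subtype_outcomes[config$outcome_id])
  records <- records[records$outcome_id %in% c(config$outcome_id, subtype), ,
                     drop = FALSE]

  out <- list(primary = .run_one(records, config),
              sensitivity = stats::setNames(
                lapply(config$sensitivity, function(nm) {
                  keep <- .sensitivity_filters[[nm]](records)
                  .run_one(records[keep, , drop = FALSE], config)
                }), config$sensitivity),
              config = config)
  class(out) <- "bprf_report"
  if (!is.null(config$output_dir)) .write_report(out, config)
  out
}

.write_report <- function(report, config) {
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(config$output_dir, ...)
  pr <- report$primary
  if (!pr$empty) {
    s <- pr$score
    summary_df <- data.frame(
      outcome_id = config$outcome_id, rr = s$rr,
      rr_lower_no_gamma = s$ui_no_gamma[1],
      rr_upper_no_gamma = s$ui_no_gamma[2],
      rr_lower_with_gamma = s$ui_with_gamma[1],
      rr_upper_with_gamma = s$ui_with_gamma[2],
      gamma = s$gamma, bprf = s$bprf, ros = s$ros, stars = s$stars,
      publication_bias = pr$egger$flagged, n_studies = s$n_studies,
      n_obs_used = s$n_obs_used, n_trimmed = s$n_trimmed,
      selected_covariates = paste(pr$covariates$name, collapse = ";"))
    utils::write.csv(summary_df, p("evidence_summary.csv"),
                     row.names = FALSE)
    utils::write.csv(pr$covariates, p("selected_covariates.csv"),
                     row.names = FALSE)
    utils::write.csv(pr$funnel, p("funnel.csv"), row.names = FALSE)
    utils::write.csv(pr$audit, p("audit_log.csv"), row.names = FALSE)
  }
  manifest <- list(
    outcome_id = config$outcome_id,
    trim_fraction = config$trim_fraction,
    alpha = config$alpha,
    direction = config$direction,
    se_inflation = config$se_inflation,
    covariate_method = config$covariate_method,
    seed = config$seed,
    sensitivity = config$sensitivity,
    stage_counts = as.list(report$primary$stage_counts),
    r_version = R.version.string,
    package_version = as.character(utils::packageVersion("bprf")))
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(report)
}

#' @export
print.bprf_report <- function(x, ...) {
  cat(sprintf("Evidence-scoring pipeline report: %s\n",
              x$config$outcome_id))
  if (x$primary$empty) {
    cat("  primary analysis: no usable records after filtering\n")
  } else {
    print(x$primary$score)
    eg <- x$primary$egger
    if (eg$evaluable)
      cat(sprintf("  Egger's test: slope %.3f, p = %.3g%s\n", eg$slope,
                  eg$p_value,
                  if (eg$flagged) "  [publication bias flagged]" else ""))
  }
  for (nm in names(x$sensitivity)) {
    s <- x$sensitivity[[nm]]
    cat(sprintf("  sensitivity %s: %s\n", nm,
                if (s$empty) "no usable records"
                else sprintf("RR %.2f, stars %d", s$score$rr,
                             s$score$stars)))
  }
  invisible(x)
}
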