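# Synthetic extraction-table generator with the generative structure the
# meta-regression assumes: study-level random effects, additive bias-
# covariate shifts, heteroskedastic sampling error, optional outlier
# contamination, repeated non-mutually-exclusive exposure groups, and a
# one-sided censoring mode emulating publication bias.

#' Configuration for the synthetic extraction-table generator
#'
#' Defaults echo the regime of the secondhand-smoke literature the package
#' targets: a pooled RR near 1.2, between-study variance around 0.01,
#' study counts within the 9-125 range seen across outcomes, and log-scale
#' standard errors drawn log-uniformly over 0.05-0.4 so that reported CI
#' widths resemble literature extractions.
#'
#' @param n_studies Number of studies.
#' @param obs_per_study Integer, or length-2 range sampled uniformly per
#'   study.
#' @param true_beta0 True pooled log RR at the gold standard.
#' @param true_gamma True between-study variance of the study random
#'   effect.
#' @param bias_effects Named numeric vector: additive log-RR shift when
#'   the corresponding `bc_*` covariate is 1.
#' @param covariate_prevalence Named numeric in `[0,1]`: probability a
#'   study carries each bias covariate (covariates are study-level).
#' @param se_min,se_max Log-uniform range for the observation-level
#'   log-scale standard error.
#' @param outlier_fraction Fraction of observations receiving an extra
#'   shift of `+/- outlier_shift` (random sign), in `[0, 0.5)`.
#' @param outlier_shift Magnitude of the outlier shift on the log scale.
#' @param outlier_sign `"both"` (default: random sign, symmetric
#'   contamination) or `"positive"` (all outliers shifted upward, the
#'   one-sided gross-error scenario used in robustness checks).
#' @param repeat_prob Probability that a study reports an extra
#'   non-mutually-exclusive duplicate pair within one group (same latent
#'   mean, independent sampling noise).
#' @param censor_small_negative Publication-bias mode: suppress
#'   observations whose effect falls below the true mean when their
#'   standard error lies in the upper half of the range (small studies with
#'   null/negative findings go unpublished).
#' @param report_ci Emit 95% CIs (default) rather than `se_log_rr`.
#' @param seed Master seed; per-study substreams are derived from it so
#'   adding studies does not perturb earlier ones.
#' @return An object of class `"synthetic_config"`.
#' @export
synthetic_config <- function(n_studies = 40L, obs_per_study = c(1L, 3L),
                             true_beta0 = log(1.2), true_gamma = 0.01,
                             bias_effects = c(bc_non_prospective = 0.1,
                                              bc_self_reported_outcome = 0.05),
                             covariate_prevalence = c(bc_non_prospective = 0.5,
                                                      bc_self_reported_outcome = 0.3),
                             se_min = 0.05, se_max = 0.4,
                             outlier_fraction = 0, outlier_shift = 2,
                             outlier_sign = c("both", "positive"),
                             repeat_prob = 0.1,
                             censor_small_negative = FALSE,
                             report_ci = TRUE, seed = 1L) {
  stopifnot(n_studies >= 1, se_min > 0, se_max >= se_min,
            outlier_fraction >= 0, outlier_fraction < 0.5,
            true_gamma >= 0, repeat_prob >= 0, repeat_prob <= 1,
            all(covariate_prevalence >= 0), all(covariate_prevalence <= 1),
            setequal(names(bias_effects), names(covariate_prevalence)))
  structure(list(
    n_studies = as.integer(n_studies), obs_per_study = obs_per_study,
    true_beta0 = true_beta0, true_gamma = true_gamma,
    bias_effects = bias_effects,
    covariate_prevalence = covariate_prevalence,
    se_min = se_min, se_max = se_max,
    outlier_fraction = outlier_fraction, outlier_shift = outlier_shift,
    outlier_sign = match.arg(outlier_sign),
    repeat_prob = repeat_prob,
    censor_small_negative = isTRUE(censor_small_negative),
    report_ci = isTRUE(report_ci), seed = as.integer(seed)
  ), class = "synthetic_config")
}

#' Generate a synthetic extraction table
#'
#' Draws, for each study s, a random effect `u_s ~ N(0, true_gamma)`; for
#' each observation, study-level bias-covariate indicators, a log-scale
#' standard error from the configured log-uniform law, and
#' `y = true_beta0 + X %*% bias_effects + u_s + N(0, se^2)`; outliers
#' receive an additional shift of `+/- outlier_shift`. Relative risks are
#' emitted as `exp(y)` with 95% CI `exp(y +/- 1.96 se)` (or `se_log_rr`
#' directly). A master seed fans out to per-study substreams so the table
#' is deterministic and stable under study-count extension.
#'
#' @param config A [synthetic_config()].
#' @return List with `data` (extraction table in the dialect of
#'   [read_extraction_table()]) and `truth` (latent values: per-study
#'   random effects, per-observation means, outlier flags, and the
#'   generating parameters).
#' @export
generate_synthetic <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  study_seeds <- sample.int(.Machine$integer.max - 1L, config$n_studies)
  covs <- names(config$bias_effects)

  rows <- vector("list", config$n_studies)
  u_all <- numeric(config$n_studies)
  for (s in seq_len(config$n_studies)) {
    set.seed(study_seeds[s])
    u_s <- stats::rnorm(1, 0, sqrt(config$true_gamma))
    u_all[s] <- u_s
    n_obs <- if (length(config$obs_per_study) == 2)
      sample(seq(config$obs_per_study[1], config$obs_per_study[2]), 1)
    else config$obs_per_study
    xs <- stats::setNames(
      as.integer(stats::runif(length(covs)) < config$covariate_prevalence[covs]),
      covs)
    df <- data.frame(group = seq_len(n_obs), dup = FALSE)
    if (stats::runif(1) < config$repeat_prob)
      df <- rbind(df, data.frame(group = 1L, dup = TRUE))
    m <- nrow(df)
    se <- exp(stats::runif(m, log(config$se_min), log(config$se_max)))
    mu <- config$true_beta0 + sum(config$bias_effects * xs) + u_s
    y <- mu + stats::rnorm(m, 0, se)
    is_out <- stats::runif(m) < config$outlier_fraction
    sign <- if (config$outlier_sign == "positive") rep(1, sum(is_out))
            else sample(c(-1, 1), sum(is_out), replace = TRUE)
    y[is_out] <- y[is_out] + sign * config$outlier_shift

    keep <- rep(TRUE, m)
    if (config$censor_small_negative)
      keep <- !(y < config$true_beta0 &
                  se > sqrt(config$se_min * config$se_max))
    if (!any(keep)) keep[which.max(y)] <- TRUE

    study <- data.frame(
      obs_id = sprintf("s%03d_o%02d", s, seq_len(m)),
      study_id = sprintf("s%03d", s),
      outcome_id = "outcome",
      rr = exp(y),
      ci_lower = if (config$report_ci) exp(y - 1.96 * se) else NA_real_,
      ci_upper = if (config$report_ci) exp(y + 1.96 * se) else NA_real_,
      se_log_rr = if (config$report_ci) NA_real_ else se,
      design = if (isTRUE(xs["bc_non_prospective"] == 1L)) "case_control"
               else "prospective_cohort",
      smoking_status = "never",
      exposure_location = "home_or_work",
      exposure_source = "any_unspecified",
      exposure_timing = "current",
      sex_scope = "both",
      children_only = FALSE,
      subgroup_level = "whole_population",
      endpoint_type = "combined",
      adjustment_rank = 1L,
      group_key = sprintf("g%02d", df$group),
      mutually_exclusive = !df$dup & !(df$group %in% df$group[df$dup]),
      stringsAsFactors = FALSE)
    for (cv in covs) study[[cv]] <- xs[[cv]]
    study$.y <- y; study$.se <- se; study$.outlier <- is_out
    rows[[s]] <- study[keep, , drop = FALSE]
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  truth <- list(beta0 = config$true_beta0, gamma = config$true_gamma,
                bias_effects = config$bias_effects,
                u_study = stats::setNames(u_all,
                                          sprintf("s%03d",
                                                  seq_len(config$n_studies))),
                y_latent = stats::setNames(tab$.y, tab$obs_id),
                se = stats::setNames(tab$.se, tab$obs_id),
                outlier = stats::setNames(tab$.outlier, tab$obs_id),
                seed = config$seed)
  tab$.y <- NULL; tab$.se <- NULL; tab$.outlier <- NULL
  list(data = tab, truth = truth)
}
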