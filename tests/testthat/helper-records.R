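# Builders for small observation tables used across tests.

make_records <- function(n = 3, study_id = sprintf("st%02d", seq_len(n)),
                         rr = rep(1.2, n), se_log_rr = rep(0.1, n), ...) {
  if (n == 0) return(make_records(1, ...)[0, , drop = FALSE])
  df <- data.frame(
    obs_id = sprintf("obs%02d", seq_len(n)),
    study_id = study_id,
    outcome_id = "outcome",
    rr = rr,
    ci_lower = NA_real_,
    ci_upper = NA_real_,
    se_log_rr = se_log_rr,
    design = "prospective_cohort",
    smoking_status = "never",
    exposure_location = "home_or_work",
    exposure_source = "any_unspecified",
    exposure_timing = "current",
    sex_scope = "both",
    children_only = FALSE,
    subgroup_level = "whole_population",
    endpoint_type = "combined",
    adjustment_rank = 1L,
    group_key = "all",
    mutually_exclusive = TRUE,
    stringsAsFactors = FALSE)
  extra <- list(...)
  for (nm in names(extra)) df[[nm]] <- extra[[nm]]
  df
}

.obs_levels <- function(field, drop = NULL)
  setdiff(bprf:::.obs_enums[[field]], drop)

# A hand-built meta_fit for scoring tests (fields as documented).
make_fit <- function(beta_mean, beta_se, gamma = 0, gamma_sd = 0,
                     n_studies = 10L, n_obs_used = 10L) {
  structure(list(beta_mean = beta_mean, beta_se = beta_se,
                 bias_coefs = stats::setNames(numeric(0), character(0)),
                 coef_se = stats::setNames(numeric(0), character(0)),
                 gamma = gamma, gamma_sd = gamma_sd,
                 trimmed_ids = character(0), n_obs_used = n_obs_used,
                 n_studies = n_studies, loglik = NA_real_,
                 converged = TRUE, obs_id = character(0),
                 data = NULL, design = NULL),
            class = "meta_fit")
}

# Independent marginal log-likelihood: dense per-study Gaussian blocks,
# no Woodbury shortcuts. Oracle for the optimizer-sanity property.
dense_loglik <- function(records, beta, gamma) {
  ll <- 0
  for (s in unique(records$study_id)) {
    d <- records[records$study_id == s, , drop = FALSE]
    V <- diag(d$se_log_rr^2, nrow(d)) + gamma
    r <- d$log_rr - beta
    ll <- ll - 0.5 * (nrow(d) * log(2 * pi) +
                        determinant(V, logarithm = TRUE)$modulus[1] +
                        drop(t(r) %*% solve(V, r)))
  }
  ll
}

# Independent selection-cascade oracle: explicit sequential filtering with
# plain loops, mirroring the rule book rather than the implementation.
oracle_select <- function(records, config) {
  keep_min <- function(df, vals) df[vals == min(vals), , drop = FALSE]
  out <- list()
  for (s in unique(records$study_id)) {
    st <- records[records$study_id == s, , drop = FALSE]
    cells <- list()
    for (g in unique(st$group_key)) {
      df <- st[st$group_key == g, , drop = FALSE]
      df <- keep_min(df, match(df$smoking_status, config$smoking_priority))
      df <- keep_min(df, match(df$exposure_location, config$location_priority))
      df <- keep_min(df, match(df$exposure_source, config$source_priority))
      df <- keep_min(df, match(df$exposure_timing, config$timing_priority))
      cells[[g]] <- df
    }
    st <- do.call(rbind, cells)
    if (config$prefer_whole_population &&
        any(st$subgroup_level == "whole_population"))
      st <- st[st$subgroup_level == "whole_population", , drop = FALSE]
    if (config$prefer_combined_endpoint && any(st$endpoint_type == "combined"))
      st <- st[st$endpoint_type == "combined", , drop = FALSE]
    for (g in unique(st$group_key)) {
      df <- st[st$group_key == g, , drop = FALSE]
      df <- df[df$adjustment_rank == max(df$adjustment_rank), , drop = FALSE]
      if (config$break_ties && nrow(df) > 1) {
        se <- ifelse(is.na(df$se_log_rr),
                     (log(df$ci_upper) - log(df$ci_lower)) / (2 * 1.96),
                     df$se_log_rr)
        df <- df[order(se, df$obs_id)[1], , drop = FALSE]
      }
      out[[paste(s, g)]] <- df
    }
  }
  res <- do.call(rbind, out)
  res <- res[order(res$obs_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}
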