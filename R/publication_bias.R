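# Egger's regression on heterogeneity-inflated model residuals and
# funnel-plot data export.

#' Egger's regression test for funnel asymmetry
#'
#' Regresses the model residual of each untrimmed observation on its total
#' standard deviation `sqrt(se^2 + gamma)`, weighting by inverse squared
#' total SD. A significant slope indicates that smaller (noisier) studies
#' report systematically larger (or smaller) effects — the funnel-plot
#' asymmetry characteristic of publication or reporting bias. The pipeline
#' flags a significant test but never corrects for it.
#'
#' @param funnel Data frame as returned by [export_funnel()] /
#'   [predict_residuals()]: columns `residual`, `residual_sd` (or
#'   `total_sd`) and optionally `trimmed`.
#' @param alpha Two-sided significance threshold, default 0.05.
#' @return List with `slope`, `se`, `p_value`, `flagged`, `n`, and
#'   `evaluable` (`FALSE` with all-`NA` statistics when fewer than 3
#'   untrimmed observations are available).
#' @export
eggers_test <- function(funnel, alpha = 0.05) {
  sd_col <- if ("residual_sd" %in% names(funnel)) "residual_sd" else "total_sd"
  if (!is.null(funnel$trimmed))
    funnel <- funnel[!funnel$trimmed, , drop = FALSE]
  n <- nrow(funnel)
  if (n < 3)
    return(list(slope = NA_real_, se = NA_real_, p_value = NA_real_,
                flagged = FALSE, n = n, evaluable = FALSE))
  x <- funnel[[sd_col]]
  y <- funnel$residual
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(slope = 0, se = NA_real_, p_value = 1, flagged = FALSE,
                n = n, evaluable = TRUE))
  fit <- stats::lm(y ~ x, weights = 1 / x^2)
  sm <- summary(fit)$coefficients
  slope <- sm["x", "Estimate"]
  se <- sm["x", "Std. Error"]
  p <- sm["x", "Pr(>|t|)"]
  list(slope = slope, se = se, p_value = p, flagged = p < alpha, n = n,
       evaluable = TRUE)
}

#' Export funnel-plot data
#'
#' One row per observation: the residual from the fitted mean on the log
#' RR scale, the total standard deviation inflated by between-study
#' heterogeneity, and whether the observation was trimmed (funnel plots
#' mark trimmed observations separately).
#'
#' @param fit A `"meta_fit"`.
#' @param records All observations (including trimmed ones).
#' @param path Optional CSV path; when given the table is written there.
#' @param design Optional design matrix matching `records`.
#' @return Data frame with `obs_id`, `residual`, `residual_sd`, `trimmed`
#'   (invisibly when `path` is given).
#' @export
export_funnel <- function(fit, records = fit$data, path = NULL,
                          design = NULL) {
  res <- predict_residuals(fit, records, design)
  out <- data.frame(obs_id = res$obs_id,
                    residual = res$residual,
                    residual_sd = res$total_sd,
                    trimmed = res$obs_id %in% fit$trimmed_ids,
                    stringsAsFactors = FALSE)
  if (!is.null(path)) {
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
    return(invisible(out))
  }
  out
}
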