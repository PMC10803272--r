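# Evidence scoring: conservative uncertainty intervals, the Burden of
# Proof Risk Function (BPRF), risk-outcome scores and star ratings.

#' Uncertainty intervals with and without between-study heterogeneity
#'
#' The interval without gamma is the conventional meta-analytic 95%
#' interval `exp(beta +/- 1.96 * beta_se)`. The conservative interval adds
#' between-study heterogeneity at its own 95th quantile,
#' `gamma_q95 = gamma + 1.645 * gamma_sd` (normal approximation via the
#' inverse Fisher information; truncated below at `gamma`), giving
#' `exp(beta +/- 1.96 * sqrt(beta_se^2 + gamma_q95))`.
#'
#' @param fit A `"meta_fit"`.
#' @param gamma_draws Optional vector of sampled gamma values; when given,
#'   `gamma_q95` is their empirical 95th percentile instead of the normal
#'   approximation (cross-checking variant).
#' @return List with `ui_no_gamma`, `ui_with_gamma` (each `c(lower, upper)`
#'   on the RR scale) and `gamma_q95`.
#' @export
compute_intervals <- function(fit, gamma_draws = NULL) {
  b <- fit$beta_mean; s <- fit$beta_se
  gq <- if (is.null(gamma_draws))
    fit$gamma + stats::qnorm(0.95) * fit$gamma_sd
  else as.numeric(stats::quantile(gamma_draws, 0.95, names = FALSE))
  gq <- max(gq, fit$gamma)
  list(ui_no_gamma = exp(b + c(-1, 1) * 1.96 * s),
       ui_with_gamma = exp(b + c(-1, 1) * 1.96 * sqrt(s^2 + gq)),
       gamma_q95 = gq)
}

#' Burden of Proof Risk Function
#'
#' The BPRF is the quantile of the relative-risk estimate, inclusive of
#' between-study heterogeneity, closest to the null: the 5th quantile for
#' a harmful risk, the 95th for a protective one. It is the most
#' conservative effect consistent with the available evidence and is only
#' defined when the association is significant without heterogeneity
#' (zero-star rule).
#'
#' @param fit A `"meta_fit"`.
#' @param direction `"harmful"` or `"protective"`.
#' @param gamma_q95 95th-quantile heterogeneity from [compute_intervals()];
#'   computed from the fit if missing.
#' @return The BPRF on the RR scale.
#' @export
compute_bprf <- function(fit, direction = c("harmful", "protective"),
                         gamma_q95 = NULL) {
  direction <- match.arg(direction)
  iv <- compute_intervals(fit)
  if (is.null(gamma_q95)) gamma_q95 <- iv$gamma_q95
  if (iv$ui_no_gamma[1] <= 1 && iv$ui_no_gamma[2] >= 1)
    stop("zero-star rule: 95% interval without heterogeneity crosses the ",
         "null; BPRF is undefined")
  sdtot <- sqrt(fit$beta_se^2 + gamma_q95)
  shift <- stats::qnorm(0.95) * sdtot
  if (direction == "harmful") exp(fit$beta_mean - shift)
  else exp(fit$beta_mean + shift)
}

#' Risk-outcome score
#'
#' For a dichotomous risk factor the ROS is the signed value of
#' `log(BPRF) / 2`: positive when even the conservative estimate stays on
#' the harmful (or protective) side of the null, negative when it crosses.
#'
#' @param bprf BPRF on the RR scale.
#' @param direction `"harmful"` or `"protective"`.
#' @return The risk-outcome score.
#' @export
compute_ros <- function(bprf, direction = c("harmful", "protective")) {
  direction <- match.arg(direction)
  stopifnot(bprf > 0)
  if (direction == "harmful") log(bprf) / 2 else -log(bprf) / 2
}

#' Round a risk-outcome score for reporting
#'
#' Reporting convention: two decimals, three when the magnitude is below
#' 0.01 (so very small scores remain distinguishable from zero).
#'
#' @param ros Risk-outcome score.
#' @return Rounded score.
#' @export
round_ros <- function(ros) {
  ifelse(abs(ros) < 0.01, round(ros, 3), round(ros, 2))
}

#' Star rating from a risk-outcome score
#'
#' Ordinal 0-5 translation of the ROS: 0 stars when the zero-star rule is
#' triggered (no significant association before heterogeneity); otherwise
#' 1 star for ROS <= 0, 2 for (0, 0.14], 3 for (0.14, 0.41], 4 for
#' (0.41, 0.62], 5 above 0.62. Upper bounds are inclusive.
#'
#' @param ros Risk-outcome score (ignored when `zero_star`).
#' @param zero_star Logical; `TRUE` when the 95% interval without
#'   heterogeneity crosses the null.
#' @return Integer star rating 0-5.
#' @export
assign_stars <- function(ros, zero_star = FALSE) {
  if (isTRUE(zero_star)) return(0L)
  stopifnot(is.finite(ros))
  if (ros <= 0) 1L
  else if (ros <= 0.14) 2L
  else if (ros <= 0.41) 3L
  else if (ros <= 0.62) 4L
  else 5L
}

#' Minimum percent change in risk implied by the BPRF
#'
#' For a harmful risk the BPRF bounds the smallest increase in risk
#' consistent with the evidence: `(BPRF - 1) * 100`, rounded to the
#' nearest integer percent. For a protective risk, `(1 - BPRF) * 100` as a
#' minimum decrease.
#'
#' @param bprf BPRF on the RR scale.
#' @param direction `"harmful"` or `"protective"`.
#' @return Integer percentage.
#' @export
min_percent_change <- function(bprf, direction = c("harmful", "protective")) {
  direction <- match.arg(direction)
  if (direction == "harmful") round((bprf - 1) * 100)
  else round((1 - bprf) * 100)
}

#' Full evidence score for a fitted risk-outcome pair
#'
#' Bundles the published evidence summary: pooled RR, 95% intervals with
#' and without between-study heterogeneity, BPRF, ROS, star rating and the
#' minimum percent change, applying the zero-star rule when the interval
#' without heterogeneity crosses the null.
#'
#' @param fit A `"meta_fit"`.
#' @param direction `"harmful"` or `"protective"`.
#' @param gamma_draws Optional gamma draws passed to [compute_intervals()].
#' @return An object of class `"evidence_score"`.
#' @export
evidence_score <- function(fit, direction = c("harmful", "protective"),
                           gamma_draws = NULL) {
  direction <- match.arg(direction)
  iv <- compute_intervals(fit, gamma_draws)
  zero_star <- iv$ui_no_gamma[1] <= 1 && iv$ui_no_gamma[2] >= 1
  if (zero_star) {
    bprf <- NA_real_; ros <- NA_real_; mpc <- NA_real_
  } else {
    bprf <- compute_bprf(fit, direction, iv$gamma_q95)
    ros <- compute_ros(bprf, direction)
    mpc <- min_percent_change(bprf, direction)
  }
  structure(list(
    rr = exp(fit$beta_mean),
    ui_no_gamma = iv$ui_no_gamma,
    ui_with_gamma = iv$ui_with_gamma,
    gamma = fit$gamma,
    gamma_q95 = iv$gamma_q95,
    bprf = bprf,
    ros = ros,
    stars = assign_stars(ros, zero_star),
    direction = direction,
    min_percent_change = mpc,
    n_studies = fit$n_studies,
    n_obs_used = fit$n_obs_used,
    n_trimmed = length(fit$trimmed_ids)
  ), class = "evidence_score")
}

#' @export
print.evidence_score <- function(x, ...) {
  fmt_ui <- function(ui) sprintf("(%.2f-%.2f)", ui[1], ui[2])
  cat("Burden of Proof evidence score\n")
  cat(sprintf("  RR %.2f %s without gamma, %s with gamma\n",
              x$rr, fmt_ui(x$ui_no_gamma), fmt_ui(x$ui_with_gamma)))
  if (x$stars == 0L) {
    cat("  zero-star pair: no significant association before",
        "between-study heterogeneity; BPRF/ROS undefined\n")
  } else {
    cat(sprintf("  BPRF %.2f, ROS %s, %d star(s)\n",
                x$bprf, format(round_ros(x$ros)), x$stars))
    cat(sprintf("  minimum %s in risk: %d%%\n",
                if (x$direction == "harmful") "increase" else "decrease",
                x$min_percent_change))
  }
  cat(sprintf("  studies: %d, observations: %d (%d trimmed), gamma %.5f\n",
              x$n_studies, x$n_obs_used, x$n_trimmed, x$gamma))
  invisible(x)
}
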