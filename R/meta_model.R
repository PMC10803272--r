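# Trimmed mixed-effects meta-regression in log relative-risk space.
#
# Model: y_i = beta + X_i b + u_{s(i)} + eps_i, with u_s ~ N(0, gamma)
# shared by all observations of study s and eps_i ~ N(0, se_i^2) from the
# reported sampling error. beta is the pooled log RR at the gold-standard
# covariate level (all X = 0). Estimation is profile maximum likelihood:
# for fixed gamma the fixed effects have the GLS closed form, and the
# profile likelihood is optimized over gamma >= 0 in one dimension. The
# study-block covariance V_s = D_s + gamma * 11' is handled through the
# rank-one Woodbury identities, so no dense solves are needed.

## Precompute per-study structures. Z includes the intercept column.
.mm_prepare <- function(y, se, study, X = NULL) {
  n <- length(y)
  Z <- cbind(intercept = rep(1, n), X)
  study <- as.character(study)
  sidx <- match(study, unique(study))
  w <- 1 / se^2
  list(y = y, se = se, w = w, Z = Z, sidx = sidx,
       n = n, n_study = max(sidx), p = ncol(Z))
}

## Profile GLS fit at fixed gamma. Returns coefficients, their covariance,
## the residuals and the full marginal log-likelihood.
.mm_gls <- function(prep, gamma) {
  w <- prep$w; Z <- prep$Z; y <- prep$y; sidx <- prep$sidx
  t_s <- as.vector(rowsum(w, sidx))            # 1' D^-1 1 per study
  shrink <- gamma / (1 + gamma * t_s)          # Woodbury factor per study
  Zw <- Z * w
  Sz <- rowsum(Zw, sidx)                       # per-study Z' D^-1 1 sums
  Sy <- as.vector(rowsum(y * w, sidx))
  A <- crossprod(Z, Zw) - crossprod(Sz, Sz * shrink)        # Z' V^-1 Z
  b <- crossprod(Z, y * w) - crossprod(Sz, Sy * shrink)     # Z' V^-1 y
  qrA <- qr(A)
  if (qrA$rank < prep$p) {
    bad <- colnames(prep$Z)[qrA$pivot[(qrA$rank + 1):prep$p]]
    stop("rank-deficient design: collinear column(s) ",
         paste(bad, collapse = ", "))
  }
  coefs <- solve(qrA, b)
  r <- y - as.vector(Z %*% coefs)
  Sr <- as.vector(rowsum(r * w, sidx))
  quad <- sum(r^2 * w) - sum(shrink * Sr^2)                 # r' V^-1 r
  logdet <- sum(log(prep$se^2)) + sum(log1p(gamma * t_s))
  loglik <- -0.5 * (prep$n * log(2 * pi) + logdet + quad)
  list(coefs = as.vector(coefs), names = colnames(Z),
       vcov = solve(qrA, diag(prep$p)), resid = r, loglik = loglik,
       t_s = t_s)
}

## Fisher information for gamma: dV/dgamma = 11' blockwise, so
## I(gamma) = 1/2 sum_s (1' V_s^-1 1)^2 with 1'V_s^-1 1 = t_s/(1+gamma t_s).
.mm_gamma_sd <- function(t_s, gamma) {
  info <- 0.5 * sum((t_s / (1 + gamma * t_s))^2)
  if (info <= 0) return(NA_real_)
  sqrt(1 / info)
}

#' Fit the mixed-effects meta-regression (no trimming)
#'
#' Maximizes the marginal likelihood of log relative risks with a
#' study-level random effect of variance `gamma` and known observation-level
#' sampling variances. Bias covariates, if supplied, are 0/1 columns whose
#' gold-standard level is 0, so the pooled effect `beta_mean` is reported at
#' the gold standard.
#'
#' @param records Data frame with `obs_id`, `study_id`, `log_rr`,
#'   `se_log_rr` (run [to_log_scale()] first).
#' @param design Optional numeric matrix (or data frame) of 0/1 bias
#'   covariates, one row per record, or `NULL` for an intercept-only model.
#' @param gamma Either `NULL` (default: estimate by profile maximum
#'   likelihood, boundary at 0 allowed) or a fixed non-negative value.
#' @param tol Convergence tolerance on the profile objective.
#' @return An object of class `"meta_fit"`: list with `beta_mean`,
#'   `beta_se`, `bias_coefs` (named vector), `coef_se`, `gamma`, `gamma_sd`
#'   (inverse Fisher information), `trimmed_ids` (empty here), `n_obs_used`,
#'   `loglik`, plus the data actually used.
#' @export
fit_mixed_model <- function(records, design = NULL, gamma = NULL,
                            tol = 1e-10) {
  stopifnot(all(c("obs_id", "study_id", "log_rr", "se_log_rr") %in%
                  names(records)))
  X <- NULL
  if (!is.null(design) && NCOL(design) > 0) {
    X <- as.matrix(design)
    if (nrow(X) != nrow(records))
      stop("design must have one row per record")
    if (is.null(colnames(X)))
      colnames(X) <- paste0("x", seq_len(ncol(X)))
  }
  prep <- .mm_prepare(records$log_rr, records$se_log_rr,
                      records$study_id, X)

  single_study <- prep$n_study < 2
  if (single_study && is.null(gamma)) {
    warning("single study: between-study heterogeneity fixed at 0")
    gamma <- 0
  }

  if (is.null(gamma)) {
    nll <- function(g) -.mm_gls(prep, g)$loglik
    upper <- max(1, 10 * stats::var(prep$y))
    opt <- stats::optimize(nll, c(0, upper), tol = tol)
    gamma_hat <- if (nll(0) <= opt$objective + tol) 0 else opt$minimum
  } else {
    stopifnot(gamma >= 0)
    gamma_hat <- gamma
  }

  g <- .mm_gls(prep, gamma_hat)
  est_gamma <- is.null(gamma) && !single_study
  fit <- structure(list(
    beta_mean = unname(g$coefs[1]),
    beta_se = unname(sqrt(g$vcov[1, 1])),
    bias_coefs = if (prep$p > 1) stats::setNames(g$coefs[-1], g$names[-1])
                 else stats::setNames(numeric(0), character(0)),
    coef_se = if (prep$p > 1)
                stats::setNames(sqrt(diag(g$vcov))[-1], g$names[-1])
              else stats::setNames(numeric(0), character(0)),
    gamma = gamma_hat,
    gamma_sd = if (est_gamma) .mm_gamma_sd(g$t_s, gamma_hat) else 0,
    trimmed_ids = character(0),
    n_obs_used = prep$n,
    n_studies = prep$n_study,
    loglik = g$loglik,
    converged = TRUE,
    obs_id = records$obs_id,
    data = records,
    design = X
  ), class = "meta_fit")
  fit
}

## Per-observation negative marginal log-likelihood contribution under a
## fit, with the study random effect integrated out observation-wise:
## y_i ~ N(beta + X_i b, se_i^2 + gamma).
.obs_nll <- function(fit, records, design = NULL) {
  mu <- fit$beta_mean
  if (length(fit$bias_coefs) && !is.null(design))
    mu <- mu + as.vector(as.matrix(design) %*% fit$bias_coefs)
  v <- records$se_log_rr^2 + fit$gamma
  0.5 * (log(2 * pi * v) + (records$log_rr - mu)^2 / v)
}

#' Fit with likelihood-based trimming
#'
#' Robustified fit that detects and removes a fixed fraction of outlying
#' observations. With fewer than 10 observations no trimming is applied
#' (small analysis sets are left intact). Otherwise the algorithm
#' alternates: fit the model on the current inlier set; score every
#' observation by its negative marginal log-likelihood contribution under
#' that fit (study random effect integrated out); mark the
#' `floor(trim_fraction * n)` worst-scoring observations as trimmed. It
#' stops when the trimmed set is stable. Ties in the score break by
#' `obs_id` so the result is order-invariant.
#'
#' @inheritParams fit_mixed_model
#' @param trim_fraction Fraction of observations to trim, in `[0, 0.5)`.
#'   Default 0.10.
#' @param max_iter Maximum alternations before the best iterate is returned
#'   flagged non-converged.
#' @return A `"meta_fit"` on the final inlier set, with `trimmed_ids` the
#'   trimmed observation ids and `n_obs_used` the inlier count.
#' @export
fit_trimmed <- function(records, design = NULL, trim_fraction = 0.10,
                        gamma = NULL, max_iter = 100L) {
  stopifnot(trim_fraction >= 0, trim_fraction < 0.5)
  n <- nrow(records)
  h <- floor(trim_fraction * n)
  if (n < 10 || h == 0) {
    fit <- fit_mixed_model(records, design, gamma = gamma)
    return(fit)
  }
  ord0 <- order(records$obs_id)  # order-invariance
  records <- records[ord0, , drop = FALSE]
  if (!is.null(design)) design <- as.matrix(design)[ord0, , drop = FALSE]

  trimmed <- rep(FALSE, n)
  fit <- NULL
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    keep <- !trimmed
    fit <- fit_mixed_model(records[keep, , drop = FALSE],
                           if (!is.null(design)) design[keep, , drop = FALSE],
                           gamma = gamma)
    nll <- .obs_nll(fit, records, design)
    worst <- order(-nll, records$obs_id)[seq_len(h)]
    new_trim <- rep(FALSE, n)
    new_trim[worst] <- TRUE
    if (identical(new_trim, trimmed)) { converged <- TRUE; break }
    trimmed <- new_trim
  }
  keep <- !trimmed
  fit <- fit_mixed_model(records[keep, , drop = FALSE],
                         if (!is.null(design)) design[keep, , drop = FALSE],
                         gamma = gamma)
  fit$trimmed_ids <- records$obs_id[trimmed]
  fit$converged <- converged
  if (!converged)
    warning("trimming did not stabilize after ", max_iter,
            " iterations; best iterate returned")
  fit
}

#' Residuals and total standard deviations under a fit
#'
#' For each observation returns the residual of the log relative risk from
#' the fitted mean (`y_i - (beta + X_i b)`) and the total standard
#' deviation `sqrt(se_i^2 + gamma)` combining the reported sampling error
#' with between-study heterogeneity — the quantities plotted in the
#' modified funnel plots.
#'
#' @param fit A `"meta_fit"`.
#' @param records Observation records to score (defaults to the fit's own
#'   data, including any trimmed observations passed here explicitly).
#' @param design Optional design matrix matching `records`.
#' @return Data frame with `obs_id`, `residual`, `total_sd`.
#' @export
predict_residuals <- function(fit, records = fit$data, design = NULL) {
  if (is.null(design) && !is.null(fit$design) &&
      identical(records$obs_id, fit$obs_id))
    design <- fit$design
  mu <- fit$beta_mean
  if (length(fit$bias_coefs)) {
    if (is.null(design))
      stop("design matrix required to score records under a covariate model")
    mu <- mu + as.vector(as.matrix(design) %*% fit$bias_coefs)
  }
  data.frame(obs_id = records$obs_id,
             residual = records$log_rr - mu,
             total_sd = sqrt(records$se_log_rr^2 + fit$gamma),
             stringsAsFactors = FALSE)
}

#' @export
print.meta_fit <- function(x, ...) {
  cat("Mixed-effects meta-regression (log RR scale)\n")
  cat(sprintf("  studies: %d, observations used: %d, trimmed: %d\n",
              x$n_studies, x$n_obs_used, length(x$trimmed_ids)))
  cat(sprintf("  pooled log RR (gold standard): %.4f (SE %.4f)  RR %.3f\n",
              x$beta_mean, x$beta_se, exp(x$beta_mean)))
  cat(sprintf("  between-study variance gamma: %.5f (SD %.5f)\n",
              x$gamma, x$gamma_sd))
  if (length(x$bias_coefs)) {
    cat("  bias covariates:\n")
    for (nm in names(x$bias_coefs))
      cat(sprintf("    %s: %.4f (SE %.4f)\n", nm, x$bias_coefs[[nm]],
                  x$coef_se[[nm]]))
  }
  invisible(x)
}
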