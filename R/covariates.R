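# Candidate bias-covariate matrix construction and step-wise Lasso
# selection of statistically significant covariates.

#' Build the candidate bias-covariate matrix
#'
#' Collects the 0/1 bias flags (`bc_*` columns) of an observation table
#' into a candidate design matrix. A covariate is eligible for testing only
#' if at least `min_per_level` observations sit at each of its two levels;
#' among columns with identical value patterns exactly one is retained,
#' chosen by a seeded random draw so the choice is reproducible. The
#' gold-standard level of every covariate is 0.
#'
#' @param records Data frame of observation records carrying `bc_*` columns.
#' @param min_per_level Minimum observations required at each covariate
#'   level (default 2).
#' @param seed Integer seed for the duplicate-column draw.
#' @return List with `matrix` (numeric 0/1 matrix, possibly 0 columns),
#'   `obs_ids`, and `excluded` (data frame of `name`, `reason`).
#' @export
build_candidate_matrix <- function(records, min_per_level = 2L, seed = 1L) {
  bc <- grep("^bc_", names(records), value = TRUE)
  excluded <- data.frame(name = character(), reason = character(),
                         stringsAsFactors = FALSE)
  keep <- character(0)
  for (col in bc) {
    v <- records[[col]]
    if (!all(v %in% c(0, 1))) stop("bias flag ", col, " must be 0/1")
    n1 <- sum(v == 1)
    if (n1 < min_per_level || (length(v) - n1) < min_per_level) {
      excluded <- rbind(excluded, data.frame(
        name = col, reason = sprintf("fewer than %d observations at a level",
                                     min_per_level),
        stringsAsFactors = FALSE))
    } else keep <- c(keep, col)
  }
  if (length(keep) > 1) {
    pat <- vapply(keep, function(col) paste(records[[col]], collapse = ""), "")
    dup_groups <- split(keep, pat)
    set.seed(seed)
    chosen <- character(0)
    for (g in dup_groups[order(vapply(dup_groups, `[`, "", 1L))]) {
      pick <- if (length(g) == 1) g else sample(g, 1L)
      chosen <- c(chosen, pick)
      if (length(g) > 1)
        excluded <- rbind(excluded, data.frame(
          name = setdiff(g, pick),
          reason = sprintf("duplicate value pattern; %s retained", pick),
          stringsAsFactors = FALSE))
    }
    keep <- keep[keep %in% chosen]
  }
  m <- as.matrix(records[, keep, drop = FALSE])
  storage.mode(m) <- "double"
  list(matrix = m, obs_ids = records$obs_id, excluded = excluded)
}

## Order of entry of covariates along a decreasing-penalty Lasso path of
## the weighted regression of log RR on standardized candidate columns.
.lasso_entry_order <- function(y, X, w) {
  p <- ncol(X)
  if (p == 1) return(colnames(X))
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) sds[sds == 0] <- 1
  Xs <- scale(X, center = TRUE, scale = sds)
  fit <- glmnet::glmnet(Xs, y, weights = w, family = "gaussian",
                        alpha = 1, standardize = FALSE, nlambda = 200,
                        lambda.min.ratio = 1e-4)
  B <- as.matrix(fit$beta) != 0
  first <- apply(B, 1, function(z) if (any(z)) which(z)[1] else Inf)
  # all names ranked by first entry along the path; never-entering ones last
  colnames(X)[order(first, seq_len(p))]
}

#' Select statistically significant bias covariates
#'
#' Operationalizes a step-wise Lasso strategy: (1) an L1-penalized weighted
#' regression of log RR on the standardized candidate columns is traced
#' over a decreasing penalty path and covariates are ranked by their order
#' of entry; (2) in that order each covariate is added to the unpenalized
#' mixed-effects model and retained only if its coefficient is significant
#' at `alpha` by a two-sided Wald test. Coefficients are reported on the
#' original 0/1 scale from the final refit, and the pooled effect of the
#' resulting fit refers to the gold-standard level (all covariates 0).
#'
#' Two variants are provided: `"stepwise"` (classical forward selection by
#' smallest Wald p-value, no Lasso ranking) and `"lasso_refit"` (the
#' nonzero set at the BIC-optimal point of the Lasso path, refit
#' unpenalized without per-covariate testing).
#'
#' @param records Observation records with `log_rr`, `se_log_rr` populated.
#' @param candidates Result of [build_candidate_matrix()] (or a bare
#'   matrix).
#' @param alpha Two-sided significance threshold, default 0.05.
#' @param method `"stepwise_lasso"` (default), `"stepwise"` or
#'   `"lasso_refit"`.
#' @return List with `selected` (character vector), `coefficients`
#'   (data frame: name, coefficient, se, p_value), and `fit` (the final
#'   `"meta_fit"` including the selected covariates).
#' @export
select_bias_covariates <- function(records, candidates, alpha = 0.05,
                                   method = c("stepwise_lasso", "stepwise",
                                              "lasso_refit")) {
  method <- match.arg(method)
  X <- if (is.list(candidates) && !is.data.frame(candidates))
    candidates$matrix else as.matrix(candidates)
  empty <- function(fit) list(
    selected = character(0),
    coefficients = data.frame(name = character(), coefficient = numeric(),
                              se = numeric(), p_value = numeric(),
                              stringsAsFactors = FALSE),
    fit = fit)
  if (is.null(X) || ncol(X) == 0)
    return(empty(fit_mixed_model(records)))

  w <- 1 / records$se_log_rr^2
  wald_p <- function(fit, nm) {
    z <- fit$bias_coefs[[nm]] / fit$coef_se[[nm]]
    2 * stats::pnorm(-abs(z))
  }

  selected <- character(0)
  if (method == "lasso_refit") {
    sds <- apply(X, 2, stats::sd); sds[sds == 0] <- 1
    Xs <- scale(X, center = TRUE, scale = sds)
    gfit <- glmnet::glmnet(Xs, records$log_rr, weights = w, alpha = 1,
                           standardize = FALSE, nlambda = 200,
                           lambda.min.ratio = 1e-4)
    pred <- stats::predict(gfit, newx = Xs)
    rss <- colSums(w * (records$log_rr - pred)^2)
    bic <- length(w) * log(rss / length(w)) + gfit$df * log(length(w))
    sel <- which(as.matrix(gfit$beta)[, which.min(bic)] != 0)
    selected <- colnames(X)[sel]
  } else {
    ranking <- if (method == "stepwise_lasso")
      .lasso_entry_order(records$log_rr, X, w) else colnames(X)
    remaining <- ranking
    while (length(remaining)) {
      if (method == "stepwise_lasso") {
        nm <- remaining[1]
        trial <- c(selected, nm)
        fit <- fit_mixed_model(records, X[, trial, drop = FALSE])
        if (wald_p(fit, nm) < alpha) selected <- trial
        remaining <- setdiff(remaining, nm)
      } else {
        ps <- vapply(remaining, function(nm) {
          fit <- fit_mixed_model(records, X[, c(selected, nm), drop = FALSE])
          wald_p(fit, nm)
        }, numeric(1))
        best <- names(which.min(ps))
        if (ps[[best]] < alpha) {
          selected <- c(selected, best)
          remaining <- setdiff(remaining, best)
        } else break
      }
    }
  }

  fit <- fit_mixed_model(records,
                         if (length(selected)) X[, selected, drop = FALSE])
  if (!length(selected)) return(empty(fit))
  coefs <- data.frame(
    name = selected,
    coefficient = unname(fit$bias_coefs[selected]),
    se = unname(fit$coef_se[selected]),
    p_value = vapply(selected, function(nm) wald_p(fit, nm), numeric(1)),
    stringsAsFactors = FALSE)
  list(selected = selected, coefficients = coefs, fit = fit)
}
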