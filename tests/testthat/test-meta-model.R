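test_that("identical observations give their common value and zero gamma", {
  df <- make_records(3, rr = exp(0.2), se_log_rr = 0.1)
  fit <- fit_mixed_model(to_log_scale(df))
  expect_equal(fit$beta_mean, 0.2, tolerance = 1e-8)
  expect_equal(fit$gamma, 0)
})

test_that("with gamma fixed at zero the fit is the inverse-variance mean", {
  set.seed(101)
  df <- make_records(3, rr = exp(c(0.1, 0.3, 0.25)),
                     se_log_rr = c(0.05, 0.2, 0.1))
  df <- to_log_scale(df)
  fit <- fit_mixed_model(df, gamma = 0)
  w <- 1 / df$se_log_rr^2
  expect_equal(fit$beta_mean, sum(w * df$log_rr) / sum(w), tolerance = 1e-8)
  expect_equal(fit$beta_se, sqrt(1 / sum(w)), tolerance = 1e-8)
})

test_that("estimates agree with an independent mixed-effects implementation", {
  set.seed(102)
  ns <- 25
  u <- stats::rnorm(ns, 0, sqrt(0.03))
  rows <- do.call(rbind, lapply(seq_len(ns), function(s) {
    m <- sample(1:3, 1)
    se <- stats::runif(m, 0.08, 0.3)
    make_records(m, study_id = sprintf("st%02d", s),
                 rr = exp(0.25 + u[s] + stats::rnorm(m, 0, se)),
                 se_log_rr = se)
  }))
  rows$obs_id <- sprintf("obs%03d", seq_len(nrow(rows)))
  rows <- to_log_scale(rows)
  fit <- fit_mixed_model(rows)
  mv <- metafor::rma.mv(log_rr ~ 1, V = se_log_rr^2, random = ~ 1 | study_id,
                        data = rows, method = "ML")
  expect_equal(fit$beta_mean, as.numeric(coef(mv)), tolerance = 1e-5)
  expect_equal(fit$beta_se, as.numeric(mv$se), tolerance = 1e-5)
  expect_equal(fit$gamma, as.numeric(mv$sigma2), tolerance = 1e-5)
})

test_that("large synthetic set recovers beta and gamma", {
  g <- generate_synthetic(synthetic_config(
    n_studies = 200, true_beta0 = 0.25, true_gamma = 0.04,
    bias_effects = numeric(0), covariate_prevalence = numeric(0),
    repeat_prob = 0, seed = 103))
  fit <- fit_mixed_model(to_log_scale(g$data))
  expect_lt(abs(fit$beta_mean - 0.25), 3 * fit$beta_se)
  expect_lt(abs(fit$gamma - 0.04), 3 * fit$gamma_sd)
})

test_that("the optimum dominates the true parameters in likelihood", {
  g <- generate_synthetic(synthetic_config(
    n_studies = 50, true_beta0 = 0.2, true_gamma = 0.02,
    bias_effects = numeric(0), covariate_prevalence = numeric(0),
    repeat_prob = 0, seed = 104))
  d <- to_log_scale(g$data)
  fit <- fit_mixed_model(d)
  expect_gte(fit$loglik + 1e-8, dense_loglik(d, 0.2, 0.02))
  # and the returned loglik itself matches the dense computation
  expect_equal(fit$loglik, dense_loglik(d, fit$beta_mean, fit$gamma),
               tolerance = 1e-8)
})

test_that("collinear covariates raise a rank-deficiency error naming them", {
  df <- to_log_scale(make_records(6, study_id = sprintf("st%d", 1:6)))
  X <- cbind(dup1 = c(1, 1, 0, 0, 1, 0), dup2 = c(1, 1, 0, 0, 1, 0))
  expect_error(fit_mixed_model(df, X), "dup2")
})

test_that("a single study fixes gamma at zero with a warning", {
  df <- to_log_scale(make_records(4, study_id = "st01",
                                  rr = exp(c(0.1, 0.2, 0.3, 0.15))))
  expect_warning(fit <- fit_mixed_model(df), "single study")
  expect_equal(fit$gamma, 0)
})

test_that("fewer than ten observations are never trimmed", {
  df <- to_log_scale(make_records(9, rr = exp(seq(0.1, 0.5, length.out = 9)),
                                  study_id = sprintf("st%d", 1:9)))
  fit <- fit_trimmed(df, trim_fraction = 0.1)
  ref <- fit_mixed_model(df)
  expect_length(fit$trimmed_ids, 0)
  expect_equal(fit$beta_mean, ref$beta_mean)
})

test_that("gross outliers are the observations trimmed", {
  set.seed(105)
  se <- stats::runif(20, 0.08, 0.2)
  y <- stats::rnorm(20, 0.2, se)
  y[c(7, 13)] <- 3
  df <- to_log_scale(make_records(20, study_id = sprintf("st%02d", 1:20),
                                  rr = exp(y), se_log_rr = se))
  fit <- fit_trimmed(df, trim_fraction = 0.1)
  expect_setequal(fit$trimmed_ids, df$obs_id[c(7, 13)])
  untrimmed <- fit_mixed_model(df)
  expect_lt(abs(fit$beta_mean - 0.2), abs(untrimmed$beta_mean - 0.2))
})

test_that("ten identical observations trim exactly one, beta unchanged", {
  df <- to_log_scale(make_records(10, rr = exp(0.2), se_log_rr = 0.1,
                                  study_id = sprintf("st%02d", 1:10)))
  fit <- fit_trimmed(df, trim_fraction = 0.1)
  expect_length(fit$trimmed_ids, 1)
  expect_equal(fit$n_obs_used, 9)
  expect_equal(fit$beta_mean, 0.2, tolerance = 1e-8)
})

test_that("trimming is invariant to observation order", {
  set.seed(106)
  se <- stats::runif(20, 0.08, 0.2)
  y <- stats::rnorm(20, 0.2, se); y[4] <- 2.5
  df <- to_log_scale(make_records(20, study_id = sprintf("st%02d", 1:20),
                                  rr = exp(y), se_log_rr = se))
  a <- fit_trimmed(df)
  b <- fit_trimmed(df[sample(20), , drop = FALSE])
  expect_setequal(a$trimmed_ids, b$trimmed_ids)
  expect_equal(a$beta_mean, b$beta_mean, tolerance = 1e-10)
})

test_that("residuals and total sd follow the fitted model", {
  df <- to_log_scale(make_records(3, rr = exp(c(0.1, 0.2, 0.3)),
                                  se_log_rr = c(0.1, 0.15, 0.2),
                                  study_id = c("a", "b", "c")))
  fit <- fit_mixed_model(df, gamma = 0.01)
  res <- predict_residuals(fit, df)
  expect_equal(res$residual, df$log_rr - fit$beta_mean, tolerance = 1e-12)
  expect_equal(res$total_sd, sqrt(df$se_log_rr^2 + 0.01), tolerance = 1e-12)
  # observation exactly at the fitted mean has residual zero
  at_mean <- df[1, ]; at_mean$log_rr <- fit$beta_mean
  expect_equal(predict_residuals(fit, at_mean)$residual, 0)
  # with gamma = 0 the total sd is the reported se
  f0 <- fit_mixed_model(df, gamma = 0)
  expect_equal(predict_residuals(f0, df)$total_sd, df$se_log_rr)
})

test_that("residuals subtract the covariate contribution", {
  set.seed(107)
  df <- to_log_scale(make_records(8, study_id = sprintf("st%d", 1:8),
                                  rr = exp(stats::rnorm(8, 0.2, 0.1))))
  X <- cbind(bias = c(1, 1, 1, 1, 0, 0, 0, 0))
  fit <- fit_mixed_model(df, X, gamma = 0)
  res <- predict_residuals(fit, df, design = X)
  mu <- fit$beta_mean + X[, 1] * fit$bias_coefs[["bias"]]
  expect_equal(res$residual, df$log_rr - mu, tolerance = 1e-10)
})

test_that("the nominal 95% interval for beta has close-to-nominal coverage", {
  set.seed(108)
  n_rep <- 500
  covered <- logical(n_rep)
  for (i in seq_len(n_rep)) {
    se <- exp(stats::runif(60, log(0.08), log(0.3)))
    y <- stats::rnorm(60, 0.2, sqrt(se^2 + 0.02))  # one obs per study
    df <- data.frame(obs_id = sprintf("o%02d", 1:60),
                     study_id = sprintf("s%02d", 1:60),
                     log_rr = y, se_log_rr = se)
    fit <- fit_mixed_model(df)
    covered[i] <- abs(fit$beta_mean - 0.2) <= 1.96 * fit$beta_se
  }
  expect_gte(mean(covered), 0.92)
  expect_lte(mean(covered), 0.98)
})
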