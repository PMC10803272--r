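test_that("whole-population rows beat sex-specific duplicates", {
  df <- make_records(3, study_id = "st01",
                     subgroup_level = c("sex_specific", "sex_specific",
                                        "whole_population"),
                     sex_scope = c("female", "male", "both"),
                     group_key = c("f", "m", "all"))
  out <- select_observations(df)
  expect_equal(out$obs_id, "obs03")
  audit <- attr(out, "audit")
  expect_setequal(audit$obs_id, c("obs01", "obs02"))
  expect_true(all(audit$eliminated_by_rule == "subgroup_dropped_for_aggregate"))
})

test_that("a single observation selects itself", {
  df <- make_records(1)
  out <- select_observations(df)
  expect_equal(out$obs_id, df$obs_id)
  expect_equal(nrow(attr(out, "audit")), 0)
})

test_that("sex-specific groups survive when no aggregate exists", {
  df <- make_records(2, study_id = "st01",
                     subgroup_level = "sex_specific",
                     sex_scope = c("female", "male"),
                     group_key = c("f", "m"))
  out <- select_observations(df)
  expect_equal(nrow(out), 2)
})

test_that("exposure-definition cascade follows the priority lists", {
  df <- make_records(4, study_id = "st01",
                     smoking_status = c("any_unspecified", "never", "never",
                                        "never"),
                     exposure_location = c("home_or_work", "work", "home",
                                           "home"),
                     exposure_timing = c("current", "current", "ever",
                                         "current"))
  out <- select_observations(df)
  # never beats any_unspecified; home beats work; current beats ever
  expect_equal(out$obs_id, "obs04")
})

test_that("selection matches an independent rule-by-rule oracle", {
  set.seed(301)
  cfg <- selection_config()
  for (case in 1:60) {
    n <- 6
    df <- make_records(
      n,
      study_id = sample(c("stA", "stB"), n, replace = TRUE),
      smoking_status = sample(.obs_levels("smoking_status"), n, TRUE),
      exposure_location = sample(.obs_levels("exposure_location"), n, TRUE),
      exposure_source = sample(.obs_levels("exposure_source"), n, TRUE),
      exposure_timing = sample(c("current", "ever"), n, TRUE),
      subgroup_level = sample(c("whole_population", "sex_specific",
                                "age_specific"), n, TRUE),
      endpoint_type = sample(c("incidence", "mortality", "combined"), n, TRUE),
      adjustment_rank = sample(1:3, n, TRUE),
      group_key = sample(c("g1", "g2"), n, TRUE),
      se_log_rr = round(stats::runif(n, 0.05, 0.3), 3))
    got <- select_observations(df, cfg)
    want <- oracle_select(df, cfg)
    expect_equal(got$obs_id, want$obs_id, info = paste("case", case))
  }
})

test_that("selection is deterministic and order-invariant", {
  set.seed(302)
  n <- 8
  df <- make_records(n, study_id = sample(c("stA", "stB"), n, TRUE),
                     adjustment_rank = sample(1:2, n, TRUE),
                     group_key = sample(c("g1", "g2"), n, TRUE),
                     se_log_rr = round(stats::runif(n, 0.05, 0.3), 3))
  a <- select_observations(df)
  b <- select_observations(df[sample(n), , drop = FALSE])
  expect_equal(a$obs_id, b$obs_id)
})

test_that("empty input warns and returns empty output", {
  expect_warning(out <- select_observations(make_records(0)), "empty")
  expect_equal(nrow(out), 0)
})

test_that("stroke-style subtypes are dropped when the aggregate is present", {
  df <- make_records(3, study_id = c("st01", "st01", "st02"),
                     group_key = c("all", "sub", "all"))
  df$outcome_id <- c("stroke", "ischemic_stroke", "ischemic_stroke")
  cfg <- selection_config(subtype_outcomes =
                            list(stroke = c("ischemic_stroke",
                                            "hemorrhagic_stroke")))
  out <- select_observations(df, cfg)
  # st01 keeps the aggregate row; st02 has only a subtype row and keeps it
  expect_setequal(out$obs_id, c("obs01", "obs03"))
})

test_that("se inflation is a no-op when every group has one observation", {
  df <- to_log_scale(make_records(3))
  expect_equal(adjust_se_for_repeats(df), df)
})

test_that("sqrt(k) inflation makes a repeat group carry one observation", {
  df <- make_records(4, study_id = "st01", group_key = "g1",
                     mutually_exclusive = FALSE, se_log_rr = 0.1)
  out <- adjust_se_for_repeats(to_log_scale(df))
  expect_equal(out$se_log_rr, rep(0.2, 4))
  # information: sum of inverse variances equals one pre-inflation obs
  expect_equal(sum(1 / out$se_log_rr^2), 1 / 0.1^2)
  lit <- adjust_se_for_repeats(to_log_scale(df), factor = "k")
  expect_equal(lit$se_log_rr, rep(0.4, 4))
})

test_that("inflation is local to the study containing the repeats", {
  df <- make_records(4, study_id = c("st01", "st01", "st02", "st03"),
                     group_key = c("g1", "g1", "g1", "g1"),
                     mutually_exclusive = c(FALSE, FALSE, FALSE, TRUE),
                     se_log_rr = 0.1)
  out <- adjust_se_for_repeats(to_log_scale(df))
  expect_equal(out$se_log_rr, c(0.1 * sqrt(2), 0.1 * sqrt(2), 0.1, 0.1))
})

test_that("inflation never decreases a standard error", {
  g <- generate_synthetic(synthetic_config(n_studies = 30, repeat_prob = 0.5,
                                           seed = 21))
  d <- to_log_scale(g$data)
  out <- adjust_se_for_repeats(d)
  expect_true(all(out$se_log_rr >= d$se_log_rr))
  # mutually exclusive groups untouched
  expect_equal(out$se_log_rr[out$mutually_exclusive],
               d$se_log_rr[d$mutually_exclusive])
})
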