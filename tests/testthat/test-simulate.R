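test_that("a degenerate config yields one person with zero comorbidities", {
  p0 <- setNames(rep(0, 57), unique(default_registry()$condition))
  cfg <- sim_config(
    n_community = 1, n_trial = 1, condition_prevalences = p0,
    comorbidity_dispersion = 0, egfr_baseline_mean_sd = c(100, 1e-6),
    dereg_rate = 0, seed = 1
  )
  coh <- generate_community(cfg)
  expect_equal(nrow(coh$persons), 1L)
  expect_equal(coh$truth$count_true, 0L)
  # only the index-condition code is ever recorded
  expect_true(all(coh$diagnoses$code %in% t2d_codes()))
})

test_that("generation is deterministic for a fixed config and seed", {
  cfg <- sim_config(n_community = 300, n_trial = 30, seed = 77)
  a <- generate_community(cfg)
  b <- generate_community(cfg)
  expect_identical(a, b)
  # and the serialised form is byte-identical
  d1 <- tempfile()
  d2 <- tempfile()
  write_dataset(a, d1)
  write_dataset(b, d2)
  for (f in list.files(d1)) {
    expect_identical(
      readLines(file.path(d1, f)), readLines(file.path(d2, f))
    )
  }
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(n_community = 0), class = "trialrep_invalid_config")
  expect_error(sim_config(n_community = 10, n_trial = 20), class = "trialrep_invalid_config")
  expect_error(sim_config(cv_death_fraction = 1.4), class = "trialrep_invalid_config")
  expect_error(sim_config(base_event_rate = 0), class = "trialrep_invalid_config")
  expect_error(sim_config(comorbidity_dispersion = -1), class = "trialrep_invalid_config")
})

test_that("registration precedes index by a year and records stay in window", {
  cfg <- sim_config(n_community = 2000, n_trial = 100, seed = 5)
  coh <- generate_community(cfg)
  expect_true(all(coh$persons$registration_day <= -365))
  ev <- dplyr::left_join(coh$diagnoses, coh$persons, by = "person_id")
  expect_true(all(ev$day >= ev$registration_day))
  expect_true(all(ev$day < 0))
  # admissions are only observable before deregistration
  adm <- dplyr::left_join(coh$admissions, coh$persons, by = "person_id")
  expect_true(all(is.na(adm$dereg_day) | adm$day < adm$dereg_day))
})

test_that("first-event fraction matches the closed-form exponential probability", {
  # rate 0.1/yr, no covariate effects, 2y window, no deregistration:
  # P(event) = 1 - exp(-0.2) = 0.1813
  cfg <- sim_config(
    n_community = 20000, n_trial = 10, base_event_rate = 0.1,
    rate_log_hr_per_comorbidity = 0, rate_log_hr_age_per_year = 0,
    sex_log_hr = 0, followup_years = 2, dereg_rate = 0, seed = 31
  )
  coh <- generate_community(cfg)
  tar <- quiet(time_at_risk(coh, "sae", window_days = 730))
  p_true <- 1 - exp(-0.2)
  se <- sqrt(p_true * (1 - p_true) / 20000)
  expect_lt(abs(mean(tar$event) - p_true), 3 * se)
})

test_that("comorbidity-count dispersion tracks the gamma frailty", {
  p <- setNames(rep(0.02, 57), unique(default_registry()$condition))
  ratio_at <- function(d, seed) {
    cfg <- sim_config(
      n_community = 20000, n_trial = 10, condition_prevalences = p,
      comorbidity_dispersion = d, egfr_baseline_mean_sd = c(100, 1e-6),
      seed = seed
    )
    ct <- generate_community(cfg)$truth$count_true
    c(ratio = var(ct) / mean(ct), target = 1 + d * mean(ct))
  }
  # Poisson-like at d = 0; the small Bernoulli-thinning correction and the
  # Monte-Carlo error together stay within 0.1 at this n
  r0 <- ratio_at(0, 11)
  expect_lt(abs(r0[["ratio"]] - 1), 0.1)
  r6 <- ratio_at(0.6, 12)
  expect_lt(abs(r6[["ratio"]] - r6[["target"]]), 0.15)
  expect_gt(r6[["ratio"]], 1.5)
})

test_that("unbiased trial sampling reproduces the eligible-pool mean count", {
  cfg <- sim_config(
    n_community = 10000, n_trial = 500,
    selection_log_odds_per_comorbidity = 0, seed = 21
  )
  coh <- generate_community(cfg)
  crit <- bundled_criteria()[["BROAD-1"]]
  el <- quiet(classify_cohort(coh, crit))
  pool_mean <- mean(coh$truth$count_true[el$person_id[el$eligible]])
  tr <- quiet(sample_trial(coh, crit, cfg))
  se <- sd(coh$truth$count_true) / sqrt(500)
  expect_lt(abs(mean(tr$truth$count_true) - pool_mean), 3 * se)
})

test_that("biased sampling matches the weighted-enumeration oracle", {
  cfg <- sim_config(n_community = 20000, n_trial = 500, seed = 22) # -0.5/condition
  coh <- generate_community(cfg)
  crit <- bundled_criteria()[["BROAD-1"]]
  el <- quiet(classify_cohort(coh, crit))
  pool <- el$person_id[el$eligible]
  cnt <- coh$truth$count_true
  w <- exp(-0.5 * cnt[pool])
  oracle <- sum(w * cnt[pool]) / sum(w) # brute-force weighted mean over the pool
  tr <- quiet(sample_trial(coh, crit, cfg))
  se <- sd(cnt[pool]) / sqrt(500)
  expect_lt(abs(mean(tr$truth$count_true) - oracle), 3 * se)
  # and the selected mean is visibly below the unweighted pool mean
  expect_lt(mean(tr$truth$count_true), mean(cnt[pool]))
})

test_that("impossible criteria raise a sampling error naming the shortfall", {
  cfg <- sim_config(n_community = 200, n_trial = 50, seed = 3)
  coh <- generate_community(cfg)
  none <- trial_criteria_set(
    "NONE",
    list(criterion("age_range", min = 120)), 2
  )
  expect_error(
    quiet(sample_trial(coh, none, cfg)),
    class = "trialrep_sampling_error"
  )
})

test_that("trial datasets carry history in the trial dialect with ground truth", {
  cfg <- sim_config(n_community = 3000, n_trial = 200, seed = 8)
  coh <- generate_community(cfg)
  tr <- quiet(sample_trial(coh, bundled_criteria()[["BROAD-1"]], cfg))
  expect_equal(nrow(tr$baseline), 200L)
  expect_true(all(grepl("^tr", tr$history$code)))
  expect_length(tr$truth$selected_person_id, 200L)
  # adjudicated flags respect the three-point definition
  adj <- tr$adjudicated
  expect_true(all(adj$mace_day[adj$mace] <= adj$followup_days[adj$mace] + 1e-9,
    na.rm = TRUE
  ))
  expect_true(all(adj$sae[adj$death]))
})

test_that("noise-free eGFR series follow the exact piecewise line", {
  cfg <- sim_config(residual_sd = 0, acute_change = -3, chronic_slope = -2, seed = 2)
  params <- tibble::tibble(person_id = 1, egfr_baseline = 90, chronic_slope = -2)
  sched <- c(0, 21, 21 + 365.25, 731)
  ser <- generate_egfr_series(params, sched, cfg)
  expect_equal(ser$egfr[ser$day == 21], 87)
  expect_equal(ser$egfr[ser$day == 21 + 365.25], 85)
  # zero change: a constant series
  cfg0 <- sim_config(residual_sd = 0, acute_change = 0, chronic_slope = 0, seed = 2)
  params0 <- tibble::tibble(person_id = 1, egfr_baseline = 90, chronic_slope = 0)
  ser0 <- generate_egfr_series(params0, sched, cfg0)
  expect_equal(ser0$egfr, rep(90, 4))
})

test_that("visit-level noise reproduces the configured residual SD", {
  cfg <- sim_config(residual_sd = 1, acute_change = -3, chronic_slope = -2, seed = 9)
  pr <- tibble::tibble(person_id = 1:500, egfr_baseline = 90, chronic_slope = -2)
  sched <- c(0, round(seq(91, 731, by = 91)), 731)
  ser <- generate_egfr_series(pr, sched, cfg)
  mu <- 90 - 3 * pmin(ser$day, 21) / 21 - 2 * pmax(ser$day - 21, 0) / 365.25
  expect_lt(abs(sd(ser$egfr - mu) - 1), 0.1)
})

test_that("inadmissible visit schedules are refused", {
  cfg <- sim_config(seed = 1)
  pr <- tibble::tibble(person_id = 1, egfr_baseline = 90)
  expect_error(
    generate_egfr_series(pr, c(10, 100, 800), cfg),
    class = "trialrep_invalid_config"
  )
  expect_error(
    generate_egfr_series(pr, c(0, 100), cfg),
    class = "trialrep_invalid_config"
  )
  expect_error(
    generate_egfr_series(pr, c(0, 100, 400), cfg),
    class = "trialrep_invalid_config"
  )
  expect_silent(
    generate_egfr_series(pr, c(0, 100, 400), cfg, enforce_min_followup = FALSE)
  )
})

test_that("fitting the rate model to generated cohorts recovers the true log hazard ratio", {
  # 100 seeded replicates; the 95% CI for the comorbidity coefficient should
  # cover the generating value in at least 90
  hits <- vapply(1:100, function(r) {
    cfg <- sim_config(
      n_community = 5000, n_trial = 10, lab_missing_prob = 0,
      seed = 9000 + r
    )
    coh <- generate_community(cfg)
    rows <- quiet(community_rate_rows(coh, "sae", 730))
    m <- fit_rate_model(rows, rate_structure("poisson"))
    est <- m$beta[["count^1"]]
    se <- sqrt(m$sigma["count^1", "count^1"])
    abs(est - 0.25) <= qnorm(0.975) * se
  }, logical(1))
  expect_gte(sum(hits), 90)
})
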