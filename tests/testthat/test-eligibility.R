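test_that("latest_lab honours lookback, recency and strict-before", {
  labs <- tibble::tibble(
    person_id = c(1, 2, 2, 3, 4, 4),
    day = c(-800, -100, -10, 0, -50, -50),
    analyte = "hba1c",
    value = c(9, 8.0, 7.5, 8.5, 7.0, 7.2)
  )
  out <- quiet(latest_lab(labs, "hba1c"))
  expect_false(1 %in% out$person_id) # beyond the 2-year lookback
  expect_equal(out$value[out$person_id == 2], 7.5) # most recent wins
  expect_false(3 %in% out$person_id) # dated exactly at index
  expect_message( # same-day tie: highest sequence number, logged
    out2 <- latest_lab(labs, "hba1c"),
    "tie"
  )
  expect_equal(out2$value[out2$person_id == 4], 7.2)
})

test_that("criterion evaluation distinguishes violated from unevaluable", {
  coh <- manual_cohort(
    tibble::tibble(person_id = 1:3, age = c(80, 50, 45)),
    labs = tibble::tibble(
      person_id = 2, day = -30, analyte = "hba1c", value = 8.1
    ),
    procedures = tibble::tibble(
      person_id = c(1, 2), day = c(-1000, -300), code = "pbar01"
    )
  )
  st <- function(cr) evaluate_criterion(coh, cr)$status
  expect_equal(
    st(criterion("age_range", min = 40, max = 75)),
    c("violated", "satisfied", "satisfied")
  )
  # bariatric surgery at day -1000 is outside the 2-year window; -300 is not
  expect_equal(
    st(criterion("procedure_excluded", codes = "pbar01", window_days = 730)),
    c("satisfied", "violated", "satisfied")
  )
  expect_equal(
    quiet(st(criterion("lab_range", analyte = "hba1c", min = 7, max = 10))),
    c("unevaluable", "satisfied", "unevaluable")
  )
  expect_error(
    criterion("lab_rage", analyte = "hba1c"),
    class = "trialrep_config_error"
  )
})

test_that("classification agrees with hand enumeration on a ten-person fixture", {
  ages <- c(35, 42, 51, 63, 64, 70, 74, 76, 81, 90)
  coh <- manual_cohort(tibble::tibble(person_id = 1:10, age = ages))
  cs <- trial_criteria_set(
    "AGE40_75",
    list(criterion("age_range", min = 40, max = 75)), 2
  )
  res <- classify_cohort(coh, cs)
  manual <- ages >= 40 & ages <= 75 # brute force over the fixture
  expect_identical(res$eligible, manual)
  expect_equal(eligible_proportion(res), mean(manual))
  expect_equal(sum(res$eligible) + sum(!res$eligible), 10L)
  # eligible persons carry no failed criteria
  expect_true(all(lengths(res$failed_criteria[res$eligible]) == 0L))
})

test_that("policy boundaries behave as specified", {
  coh <- manual_cohort(tibble::tibble(person_id = 1:4, age = 50))
  always <- trial_criteria_set(
    "ALL", list(criterion("age_range", min = 18)), 2
  )
  expect_equal(eligible_proportion(classify_cohort(coh, always)), 1.0)
  needs_lab <- trial_criteria_set(
    "LAB", list(criterion("lab_range", analyte = "hba1c", min = 7, max = 10)), 2
  )
  expect_equal(
    eligible_proportion(quiet(classify_cohort(coh, needs_lab, policy = "strict"))),
    0.0
  )
  expect_equal(
    eligible_proportion(quiet(classify_cohort(coh, needs_lab, policy = "lenient"))),
    1.0
  )
  empty <- manual_cohort(tibble::tibble(person_id = integer(), age = numeric()))
  expect_error(classify_cohort(empty, always), class = "trialrep_eligibility_error")
})

test_that("adding criteria never increases eligibility; order never matters", {
  cfg <- sim_config(n_community = 300, n_trial = 10, seed = 14)
  coh <- generate_community(cfg)
  reg_cond <- unique(default_registry()$condition)
  withr::with_seed(99, {
    for (rep in 1:8) {
      crits <- list(
        criterion("age_range",
          min = sample(30:60, 1), max = sample(65:90, 1)
        ),
        criterion("sex", value = sample(c("male", "female"), 1)),
        criterion("diagnosis_excluded", conditions = sample(reg_cond, 3)),
        criterion("egfr_range", min = sample(c(15, 30, 45, 60), 1))
      )
      k <- sample(2:4, 1)
      cs_small <- trial_criteria_set("S", crits[seq_len(k - 1)], 2)
      cs_big <- trial_criteria_set("B", crits[seq_len(k)], 2)
      p_small <- eligible_proportion(quiet(classify_cohort(coh, cs_small)))
      p_big <- eligible_proportion(quiet(classify_cohort(coh, cs_big)))
      expect_lte(p_big, p_small)
      # permuting the criteria changes no per-person result
      cs_perm <- trial_criteria_set("P", sample(crits[seq_len(k)]), 2)
      r1 <- quiet(classify_cohort(coh, cs_big))
      r2 <- quiet(classify_cohort(coh, cs_perm))
      expect_identical(r1$eligible, r2$eligible)
    }
  })
})

test_that("criteria files round-trip through JSON and YAML", {
  cs <- bundled_criteria()[["GLYCO-1"]]
  expect_length(cs$criteria, 5L)
  for (ext in c(".json", ".yaml")) {
    path <- tempfile(fileext = ext)
    write_criteria(cs, path)
    back <- read_criteria(path)
    expect_equal(back$trial_id, cs$trial_id)
    expect_equal(back$followup_years, cs$followup_years)
    expect_equal(
      vapply(back$criteria, function(x) x$label, character(1)),
      vapply(cs$criteria, function(x) x$label, character(1))
    )
    unlink(path)
  }
})
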