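test_that("death classification keys on the circulatory-chapter prefix", {
  expect_equal(
    classify_death(c("I21.0", "C34.9", "i60", "", NA)),
    c("cv", "noncv", "cv", "unknown", "unknown")
  )
})

test_that("censoring follows first-of event, deregistration, death, window end", {
  coh <- manual_cohort(
    tibble::tibble(
      person_id = 1:5,
      dereg_day = c(NA, 400, NA, NA, -5),
      death_day = c(NA, NA, NA, 200, NA),
      death_cause = c(NA, NA, NA, "I21.0", NA)
    ),
    admissions = tibble::tibble(
      person_id = c(1, 2, 4),
      day = c(100, 500, 30),
      code = c("J18.1", "J18.1", "K52.9")
    )
  )
  tar <- quiet(time_at_risk(coh, "sae", window_days = 730))
  # event at day 100 inside the window
  expect_equal(tar$time_at_risk[tar$person_id == 1], 100)
  expect_true(tar$event[tar$person_id == 1])
  # deregistration at 400 censors the day-500 admission
  expect_equal(tar$time_at_risk[tar$person_id == 2], 400)
  expect_false(tar$event[tar$person_id == 2])
  # nothing happens: censored at the window end
  expect_equal(tar$time_at_risk[tar$person_id == 3], 730)
  expect_false(tar$event[tar$person_id == 3])
  # admission precedes death: the admission is the first serious event
  expect_equal(tar$time_at_risk[tar$person_id == 4], 30)
  # deregistered before index: excluded entirely
  expect_false(5 %in% tar$person_id)
})

test_that("first serious adverse event is the first of admission or death", {
  coh <- manual_cohort(
    tibble::tibble(
      person_id = 1:3,
      death_day = c(200, 50, NA),
      death_cause = c("C34.9", "I50.0", NA)
    ),
    admissions = tibble::tibble(person_id = 1, day = 30, code = "J18.1")
  )
  sae <- first_sae_community(coh, 730)
  expect_equal(sae$event_day[sae$person_id == 1], 30)
  expect_equal(sae$event_day[sae$person_id == 2], 50) # death alone qualifies
  expect_false(sae$event[sae$person_id == 3])
})

test_that("MACE is the three-point composite and non-CV death censors", {
  coh <- manual_cohort(
    tibble::tibble(
      person_id = 1:4,
      death_day = c(300, 10, NA, 250),
      death_cause = c("I21.9", "C34.9", NA, "I63.0")
    ),
    admissions = tibble::tibble(
      person_id = c(1, 3, 4),
      day = c(90, 120, 40),
      code = c("I63.9", "J18.1", "N39.0") # stroke, neither, neither
    )
  )
  mace <- first_mace(coh, 730)
  # stroke admission at 90 beats the CV death at 300
  expect_equal(mace$event_day[mace$person_id == 1], 90)
  # non-CV death at day 10: no MACE, censored at death
  expect_false(mace$event[mace$person_id == 2])
  expect_equal(mace$time_at_risk[mace$person_id == 2], 10)
  # a non-MACE admission is not an event
  expect_false(mace$event[mace$person_id == 3])
  # CV death with an unrelated admission: the death is the event
  expect_equal(mace$event_day[mace$person_id == 4], 250)
})

test_that("day-zero events are prevalent, not incident", {
  coh <- manual_cohort(
    tibble::tibble(person_id = 1),
    admissions = tibble::tibble(person_id = 1, day = 0, code = "J18.1")
  )
  sae <- first_sae_community(coh, 730)
  expect_false(sae$event[1])
})

test_that("trial outcomes use the adjudicated component flags", {
  cfg <- sim_config(n_community = 2000, n_trial = 150, seed = 41)
  coh <- generate_community(cfg)
  tr <- quiet(sample_trial(coh, bundled_criteria()[["BROAD-1"]], cfg))
  # hand-inject a clean MI flag to pin the convention
  tr$adjudicated$mi_day[1] <- 45
  tr$adjudicated$mi[1] <- TRUE
  tr$adjudicated$mace_day[1] <- 45
  tr$adjudicated$mace[1] <- TRUE
  mace <- trial_outcomes(tr, "mace")
  expect_equal(mace$event_day[1], 45)
  sae <- trial_outcomes(tr, "sae")
  expect_true(all(sae$time_at_risk <= 731))
  # arm restriction partitions the participants
  a <- trial_outcomes(tr, "sae", arm = "sglt2i")
  b <- trial_outcomes(tr, "sae", arm = "control")
  expect_equal(nrow(a) + nrow(b), nrow(sae))
})

test_that("outcome invariants hold on a generated cohort", {
  cfg <- sim_config(n_community = 3000, n_trial = 10, seed = 42)
  coh <- generate_community(cfg)
  outs <- c("sae", "mace", "death_all", "death_cv", "death_noncv")
  tabs <- lapply(outs, function(o) quiet(time_at_risk(coh, o, 730)))
  names(tabs) <- outs
  for (o in outs) {
    expect_true(all(tabs[[o]]$time_at_risk <= 730))
    expect_true(all(tabs[[o]]$time_at_risk > 0))
    expect_true(all(tabs[[o]]$event_day[tabs[[o]]$event] > 0))
  }
  # every CV death is a serious adverse event
  cv_ids <- tabs$death_cv$person_id[tabs$death_cv$event]
  sae_ids <- tabs$sae$person_id[tabs$sae$event]
  expect_true(all(cv_ids %in% sae_ids))
  # shrinking the window never increases any event count
  for (o in c("sae", "mace", "death_all")) {
    counts <- vapply(
      c(180, 365, 545, 730),
      function(w) sum(quiet(time_at_risk(coh, o, w))$event),
      numeric(1)
    )
    expect_true(all(diff(counts) >= 0))
  }
})
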