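reg <- default_registry()

test_that("the registry satisfies its structural contract", {
  expect_length(unique(reg$condition), 57L)
  cm <- unique(reg$condition[reg$class == "cardiometabolic"])
  expect_setequal(cm, c(
    "stroke", "coronary artery disease", "heart failure",
    "peripheral artery disease", "heart valve disorders", "arrhythmia",
    "venous thromboembolic disease", "aneurysm", "hypertension",
    "chronic kidney disease"
  ))
  expect_false(any(grepl("diabetes", reg$condition)))
  # the shipped JSON fixture round-trips to the same registry
  fixture <- read_registry(
    system.file("extdata", "condition_registry.json", package = "trialrep")
  )
  expect_equal(
    dplyr::arrange(as.data.frame(fixture), condition, vocabulary, code),
    dplyr::arrange(as.data.frame(reg), condition, vocabulary, code)
  )
  short <- dplyr::filter(reg, condition != "asthma")
  expect_error(validate_registry(short), class = "trialrep_registry_error")
  expect_silent(validate_registry(short, allow_custom = TRUE))
})

hyp_code <- reg$code[reg$condition == "hypertension" & reg$vocabulary == "community"][1]
asthma_code <- reg$code[reg$condition == "asthma" & reg$vocabulary == "community"][1]
ckd_code <- reg$code[reg$condition == "chronic kidney disease" & reg$vocabulary == "community"][1]

test_that("conditions are counted by class, once each, from codes before index", {
  hist <- tibble::tibble(
    person_id = c(1, 1, 1, 1),
    day = c(-100, -50, -10, -400),
    code = c(hyp_code, asthma_code, asthma_code, hyp_code) # duplicates
  )
  out <- comorbidity_counts(hist, reg)
  expect_equal(out$total, 2L)
  expect_equal(out$cardiometabolic, 1L)
  expect_equal(out$non_cardiometabolic, 1L)
})

test_that("CKD enters through eGFR only, never through codes", {
  # a CKD diagnosis code alone contributes nothing
  hist <- tibble::tibble(person_id = 1, day = -30, code = ckd_code)
  expect_equal(comorbidity_counts(hist, reg)$total, 0L)
  # an eGFR of 50 with an empty history contributes one cardiometabolic
  out <- comorbidity_counts(
    empty_events(), reg,
    ids = 1, egfr = tibble::tibble(person_id = 1, egfr = 50)
  )
  expect_equal(out$total, 1L)
  expect_equal(out$cardiometabolic, 1L)
  expect_true(out$ckd)
  # unknown eGFR is counted absent, flagged NA, and logged
  expect_message(
    out2 <- comorbidity_counts(
      empty_events(), reg,
      ids = 1, egfr = tibble::tibble(person_id = 1, egfr = NA_real_)
    ),
    "unknown CKD"
  )
  expect_equal(out2$total, 0L)
  expect_true(is.na(out2$ckd))
})

test_that("index-condition codes are excluded and unknown codes warn", {
  t2d_hist <- tibble::tibble(person_id = 1, day = -10, code = t2d_codes()[1])
  expect_no_warning(out <- comorbidity_counts(t2d_hist, reg))
  expect_equal(out$total, 0L)
  junk <- tibble::tibble(person_id = 1, day = c(-10, -5), code = c("zzz9", hyp_code))
  expect_warning(
    out2 <- comorbidity_counts(junk, reg),
    class = "trialrep_unknown_codes"
  )
  expect_equal(out2$total, 1L)
})

test_that("the community and trial dialects phenotype identically", {
  conditions <- c("hypertension", "asthma", "gout", "stroke")
  comm <- reg |>
    dplyr::filter(condition %in% conditions, vocabulary == "community") |>
    dplyr::distinct(condition, .keep_all = TRUE)
  tri <- reg |>
    dplyr::filter(condition %in% conditions, vocabulary == "trial")
  h_comm <- tibble::tibble(person_id = 1, day = -20, code = comm$code)
  h_tri <- tibble::tibble(person_id = 1, day = -20, code = tri$code)
  expect_equal(
    comorbidity_counts(h_comm, reg)[c("total", "cardiometabolic", "non_cardiometabolic")],
    comorbidity_counts(h_tri, reg)[c("total", "cardiometabolic", "non_cardiometabolic")]
  )
})

test_that("codes dated on/after the index date never change counts", {
  withr::with_seed(42, {
    all_codes <- unique(reg$code)
    for (i in 1:10) {
      pre <- tibble::tibble(
        person_id = 1, day = -sample(1:500, 5), code = sample(all_codes, 5)
      )
      post <- tibble::tibble(
        person_id = 1, day = sample(0:300, 4), code = sample(all_codes, 4)
      )
      expect_identical(
        comorbidity_counts(pre, reg)$total,
        comorbidity_counts(dplyr::bind_rows(pre, post), reg)$total
      )
      expect_identical(
        comorbidity_counts(pre, reg)$total,
        comorbidity_counts(pre, reg)$cardiometabolic +
          comorbidity_counts(pre, reg)$non_cardiometabolic
      )
    }
  })
})

test_that("eGFR at index uses the most recent creatinine within two years", {
  demo <- tibble::tibble(person_id = 1:3, age = 60, sex = "male")
  labs <- tibble::tibble(
    person_id = c(1, 1, 2, 3),
    day = c(-100, -10, -800, 0),
    analyte = "creatinine",
    value = c(2.0, 1.0, 1.0, 1.0)
  )
  out <- egfr_at_index(labs, demo)
  # person 1: the day -10 value (1.0) wins over day -100 (2.0)
  expect_equal(out$egfr[out$person_id == 1], egfr_ckd_epi(1.0, 60, "male"))
  # person 2: only value is beyond the 730-day lookback
  expect_true(is.na(out$egfr[out$person_id == 2]))
  # person 3: value dated exactly at index is excluded (strictly before)
  expect_true(is.na(out$egfr[out$person_id == 3]))
})
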