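# shared helpers: independent oracles and hand-built fixtures

quiet <- function(expr) suppressMessages(expr)

# independently coded CKD-EPI 2009 oracle: explicit sex-specific branches,
# written from the published constants without min/max algebra
oracle_ckdepi_2009 <- function(scr, age, female) {
  mapply(function(s, a, f) {
    if (f) {
      base <- 141 * 0.993^a * 1.018
      if (s <= 0.7) base * (s / 0.7)^(-0.329) else base * (s / 0.7)^(-1.209)
    } else {
      base <- 141 * 0.993^a
      if (s <= 0.9) base * (s / 0.9)^(-0.411) else base * (s / 0.9)^(-1.209)
    }
  }, scr, age, female)
}

# a minimal hand-constructed cohort in the community toy vocabulary
manual_cohort <- function(persons,
                          diagnoses = empty_events(),
                          labs = empty_labs(),
                          admissions = empty_events(),
                          procedures = empty_events()) {
  defaults <- tibble::tibble(
    person_id = persons$person_id,
    age = 60, sex = "male", female = FALSE,
    registration_day = -2000L, index_day = 0L,
    dereg_day = NA_real_, death_day = NA_real_, death_cause = NA_character_
  )
  for (nm in names(persons)) defaults[[nm]] <- persons[[nm]]
  defaults$female <- defaults$sex == "female"
  structure(
    list(
      persons = defaults, diagnoses = diagnoses, procedures = procedures,
      labs = labs, admissions = admissions,
      truth = list(), vocabulary_id = "community"
    ),
    class = "community_cohort"
  )
}

empty_events <- function() {
  tibble::tibble(person_id = integer(), day = numeric(), code = character())
}

empty_labs <- function() {
  tibble::tibble(
    person_id = integer(), day = numeric(),
    analyte = character(), value = numeric()
  )
}

# simulated covariate/event rows with known Poisson or negbin rates,
# for rate-model tests (py fixed; events drawn at the linear-predictor rate)
make_rate_rows <- function(n, seed, b0 = -2.2, b_age = 0.03, b_sex = -0.1,
                           b_count = 0.25, py = 2, size = Inf) {
  withr::with_seed(seed, {
    rows <- tibble::tibble(
      age = runif(n, 40, 85),
      female = rbinom(n, 1, 0.4) == 1,
      count = rpois(n, 2),
      py = py
    )
    lam <- exp(b0 + b_age * (rows$age - 60) + b_sex * rows$female +
      b_count * rows$count) * rows$py
    rows$events <- if (is.finite(size)) {
      rnbinom(n, mu = lam, size = size)
    } else {
      rpois(n, lam)
    }
    rows
  })
}
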