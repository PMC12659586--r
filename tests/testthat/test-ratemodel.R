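test_that("fractional-polynomial columns follow the standard conventions", {
  expect_equal(unname(fp_basis(5, 1)[, 1]), 5) # identity power
  expect_equal(unname(fp_basis(exp(1), 0)[, 1]), 1) # power 0 is log
  rep2 <- fp_basis(2, c(2, 2)) # repeated power adds the log-multiplied term
  expect_equal(unname(rep2[1, ]), c(4, 4 * log(2)))
  expect_equal(unname(fp_basis(4, c(-0.5, 1))[1, ]), c(0.5, 4))
  # pre-scaling: age/10 and count+1
  expect_equal(unname(fp_basis(50, 2, scale = 10)[, 1]), 25)
  expect_equal(unname(fp_basis(0, 0, shift = 1)[, 1]), 0)
  expect_error(fp_basis(-2, 0.5), class = "trialrep_fp_error")
  expect_error(fp_basis(2, c(1, 2, 3)), class = "trialrep_fp_error")
  expect_error(fp_basis(2, 1.7), class = "trialrep_fp_error")
})

test_that("an intercept-only truth is recovered and constants are rejected", {
  n <- 20000
  rows <- withr::with_seed(61, tibble::tibble(
    age = 60, female = FALSE, count = 1, py = 2,
    events = rpois(n, 0.1 * 2)
  ))
  expect_warning(
    m <- fit_rate_model(rows, rate_structure("poisson")),
    class = "trialrep_collinear"
  )
  expect_length(m$beta, 1L) # all constant covariates dropped
  se <- sqrt(m$sigma[1, 1])
  expect_lt(abs(m$beta[[1]] - log(0.1)), 3 * se)
})

test_that("doubling person-time shifts only the intercept, by exactly log 2", {
  rows <- make_rate_rows(4000, seed = 62)
  m1 <- fit_rate_model(rows, rate_structure("poisson"))
  rows2 <- dplyr::mutate(rows, py = 2 * py)
  m2 <- fit_rate_model(rows2, rate_structure("poisson"))
  expect_equal(
    m2$beta[["(Intercept)"]], m1$beta[["(Intercept)"]] - log(2),
    tolerance = 1e-6
  )
  expect_equal(
    m2$beta[names(m2$beta) != "(Intercept)"],
    m1$beta[names(m1$beta) != "(Intercept)"],
    tolerance = 1e-6
  )
})

test_that("fitting requires events and positive person-time", {
  rows <- make_rate_rows(200, seed = 63)
  rows$events <- 0L
  expect_error(
    fit_rate_model(rows, rate_structure("poisson")),
    class = "trialrep_rate_error"
  )
  rows2 <- make_rate_rows(200, seed = 64)
  rows2$py[1] <- -1
  expect_error(
    fit_rate_model(rows2, rate_structure("poisson")),
    class = "trialrep_rate_error"
  )
})

test_that("known coefficients are recovered within three standard errors", {
  rows <- make_rate_rows(20000, seed = 65)
  m <- fit_rate_model(rows, rate_structure("poisson"))
  truth <- c(
    # design is intercept + age/10 + female + (count+1); re-express the
    # generating coefficients in that basis
    `(Intercept)` = -2.2 - 0.03 * 60 - 0.25,
    `age^1` = 0.3, female = -0.1, `count^1` = 0.25
  )
  se <- sqrt(diag(m$sigma))
  expect_true(all(abs(m$beta - truth[names(m$beta)]) <= 3 * se))
})

test_that("negative-binomial fits report dispersion and match Poisson means", {
  rows <- make_rate_rows(5000, seed = 66, size = 1)
  m <- fit_rate_model(rows, rate_structure("negbin"))
  expect_gt(m$dispersion, 0.5)
  mp <- fit_rate_model(rows, rate_structure("poisson"))
  # mean structure is shared; coefficient estimates agree loosely
  expect_equal(unname(m$beta), unname(mp$beta), tolerance = 0.1)
  # and the negbin SEs are wider
  expect_true(all(diag(m$sigma) > diag(mp$sigma)))
})

test_that("the closed test keeps a linear term for log-linear data", {
  # generated log-linear in age; powers (1) should be selected in at least
  # 85% of seeded replicates (40 here keep the search affordable)
  picks <- vapply(1:40, function(r) {
    rows <- withr::with_seed(7000 + r, {
      n <- 20000
      out <- tibble::tibble(
        age = runif(n, 40, 85), female = rbinom(n, 1, 0.4) == 1, py = 2
      )
      lam <- exp(-2.5 + 0.04 * (out$age - 60)) * out$py
      out$events <- rpois(n, lam)
      out
    })
    st <- select_structure(rows, use_count = FALSE)
    identical(st$age_powers, 1)
  }, logical(1))
  expect_gte(mean(picks), 0.85)
})

test_that("curvature in the log rate favours two-term fractional polynomials", {
  n_terms <- vapply(1:40, function(r) {
    rows <- withr::with_seed(7500 + r, {
      n <- 5000
      out <- tibble::tibble(
        age = runif(n, 40, 85), female = rbinom(n, 1, 0.4) == 1, py = 2
      )
      z <- out$age / 10
      lam <- exp(-1.5 - 0.35 * (z - 6)^2) * out$py
      out$events <- rpois(n, lam)
      out
    })
    length(select_structure(rows, use_count = FALSE)$age_powers)
  }, numeric(1))
  expect_gt(sum(n_terms == 2), sum(n_terms == 1))
})

test_that("interactions are only kept when both the LRT and AIC support them", {
  # a strong age-by-sex interaction in the truth
  rows <- withr::with_seed(71, {
    n <- 20000
    out <- tibble::tibble(
      age = runif(n, 40, 85), female = rbinom(n, 1, 0.4) == 1,
      count = rpois(n, 2), py = 2
    )
    lam <- exp(-3 + 0.03 * (out$age - 60) + 0.2 * out$count +
      0.12 * (out$age / 10) * out$female) * out$py
    out$events <- rpois(n, lam)
    out
  })
  st <- select_structure(rows)
  expect_true("age:sex" %in% st$interactions)
  dec <- attr(st, "decisions")
  expect_true(all(c("family", "fp_age", "interaction") %in% dec$step))
})

test_that("model JSON export and import round-trip the transported quantities", {
  rows <- make_rate_rows(3000, seed = 72)
  m <- fit_rate_model(rows, rate_structure("poisson"))
  path <- tempfile(fileext = ".json")
  write_rate_model(m, path, outcome = "sae")
  back <- read_rate_model(path)
  expect_equal(back$beta, m$beta)
  expect_equal(back$sigma, m$sigma, tolerance = 1e-12)
  newrows <- make_rate_rows(500, seed = 73)
  expect_equal(
    quiet(expected_count(back, newrows)),
    quiet(expected_count(m, newrows))
  )
})
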