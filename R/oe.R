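#' Expected event count under a transported rate model
#'
#' Applies a community-fitted [rate_model()] to a trial covariate
#' distribution: the expected count is
#' \deqn{E = \sum_i \exp(x_i \beta) \, t_i}
#' over trial participants with their covariates \eqn{x_i} and person-time
#' at risk \eqn{t_i} in years. Participants whose covariates fall outside
#' the support the model was fitted on are flagged with a warning (they are
#' extrapolations, not errors).
#'
#' @param model A fitted `rate_model`.
#' @param trial_rows Tibble with `age`, `female`, `py` (person-years; or
#'   `time_at_risk` in days) and `count` when the model uses it.
#' @return The expected count (scalar).
#' @export
expected_count <- function(model, trial_rows) {
  py <- person_years(trial_rows)
  X <- rate_design(trial_rows, model$struct)
  X <- X[, names(model$beta), drop = FALSE]
  out_age <- trial_rows$age < model$support$age[1] |
    trial_rows$age > model$support$age[2]
  out_cnt <- if (!is.null(model$support$count)) {
    trial_rows$count < model$support$count[1] |
      trial_rows$count > model$support$count[2]
  } else {
    rep(FALSE, nrow(trial_rows))
  }
  extrap <- which(out_age | out_cnt)
  if (length(extrap) > 0L) {
    warn(
      paste0(
        length(extrap), " trial row(s) outside the fitted covariate support ",
        "(e.g. rows ", paste(head(extrap, 5L), collapse = ", "), ")"
      ),
      class = "trialrep_extrapolation"
    )
  }
  sum(exp(as.vector(X %*% model$beta)) * py)
}

#' Observed/expected event ratio with Monte-Carlo confidence interval
#'
#' The point estimate is `observed / expected` with the expected count from
#' the coefficient point estimates. Uncertainty combines two sources, each
#' with `n_samples` Monte-Carlo draws from independent substreams of one
#' seed:
#' * coefficient uncertainty — draws \eqn{\beta_s \sim MVN(\hat\beta,
#'   \Sigma)} applied to the trial covariate distribution give a sample of
#'   expected counts;
#' * observed-count uncertainty — the observed first-event proportion is
#'   given its conjugate beta posterior; by default the Jeffreys prior, so
#'   \eqn{p_s \sim Beta(o + 1/2,\; n - o + 1/2)} and \eqn{O_s = p_s n}.
#'
#' The 95% interval is the 2.5th and 97.5th centiles of
#' \eqn{O_s / E_s}. Samples with nonpositive or non-finite expected counts
#' are rejected and logged; more than 1% rejections is an error.
#'
#' @param observed Observed first-event count in the trial (0..n).
#' @param n_participants Number of trial participants.
#' @param model A fitted `rate_model`.
#' @param trial_rows Trial covariate rows, as [expected_count()].
#' @param n_samples Monte-Carlo samples (default 10,000).
#' @param seed Seed; substream 1 drives the coefficient draws, substream 2
#'   the beta draws.
#' @param beta_prior Length-2 beta prior (default Jeffreys `c(0.5, 0.5)`).
#' @return An `oe_result`: observed, expected, ratio, `ci95`, sample
#'   diagnostics.
#' @export
oe_ratio <- function(observed, n_participants, model, trial_rows,
                     n_samples = 10000, seed = 1L,
                     beta_prior = c(0.5, 0.5)) {
  if (observed < 0 || observed > n_participants) {
    abort("observed must lie in [0, n_participants] (first-event convention)",
      class = "trialrep_oe_error"
    )
  }
  e_point <- suppressWarnings(expected_count(model, trial_rows))
  if (e_point <= 0) {
    abort("expected count is nonpositive", class = "trialrep_oe_error")
  }
  py <- person_years(trial_rows)
  X <- rate_design(trial_rows, model$struct)[, names(model$beta), drop = FALSE]

  sig <- model$sigma
  degenerate_sigma <- all(abs(sig) < .Machine$double.eps)
  betas <- with_seed(derive_seed(seed, 1L), {
    if (degenerate_sigma) {
      matrix(model$beta, n_samples, length(model$beta), byrow = TRUE)
    } else {
      MASS::mvrnorm(n_samples, mu = model$beta, Sigma = sig)
    }
  })
  # expected counts per coefficient draw, chunked to bound memory
  e_s <- numeric(n_samples)
  chunk <- 2500L
  for (s0 in seq(1L, n_samples, by = chunk)) {
    idx <- s0:min(s0 + chunk - 1L, n_samples)
    eta <- X %*% t(betas[idx, , drop = FALSE])
    e_s[idx] <- colSums(exp(eta) * py)
  }
  o_s <- with_seed(derive_seed(seed, 2L), {
    rbeta(
      n_samples, observed + beta_prior[1],
      n_participants - observed + beta_prior[2]
    ) * n_participants
  })
  ok <- is.finite(e_s) & e_s > 0
  n_rej <- sum(!ok)
  if (n_rej > 0L) {
    log_note(n_rej, " Monte-Carlo sample(s) rejected (nonpositive expected count)")
    if (n_rej > 0.01 * n_samples) {
      abort(
        paste0(
          n_rej, " of ", n_samples,
          " samples rejected (> 1%); the model is unstable on this trial"
        ),
        class = "trialrep_oe_error"
      )
    }
  }
  ratio_s <- o_s[ok] / e_s[ok]
  ci <- unname(quantile(ratio_s, c(0.025, 0.975)))
  structure(
    list(
      observed = observed, expected = e_point,
      ratio = observed / e_point,
      ci95 = ci, n_samples = n_samples, n_rejected = n_rej,
      n_participants = n_participants, seed = seed,
      beta_prior = beta_prior
    ),
    class = "oe_result"
  )
}

#' @export
print.oe_result <- function(x, ...) {
  cat(
    "<oe_result> observed ", x$observed, " / expected ", signif(x$expected, 5),
    " = ", signif(x$ratio, 4),
    " (95% CI ", signif(x$ci95[1], 4), "-", signif(x$ci95[2], 4),
    ", ", x$n_samples, " MC samples)\n",
    sep = ""
  )
  invisible(x)
}

#' @method tidy oe_result
#' @export
tidy.oe_result <- function(x, ...) {
  tibble(
    observed = x$observed,
    expected = x$expected,
    ratio = x$ratio,
    conf.low = x$ci95[1],
    conf.high = x$ci95[2]
  )
}

#' @method glance oe_result
#' @export
glance.oe_result <- function(x, ...) {
  tibble(
    n_participants = x$n_participants,
    n_samples = x$n_samples,
    n_rejected = x$n_rejected,
    seed = x$seed
  )
}

#' Export / import a rate model as JSON
#'
#' The export carries the family, the basis specification (variables,
#' powers, pre-scaling), the coefficient vector, the variance-covariance
#' matrix (row-major), the dispersion, the covariate support and the sample
#' size — summaries only, never row-level data, so the file can leave a
#' secure analysis platform and be applied to trial data held elsewhere.
#'
#' @param model A `rate_model`.
#' @param path Output path.
#' @param outcome Optional outcome label stored in the file.
#' @return `path` invisibly; `read_rate_model()` returns a `rate_model`.
#' @export
write_rate_model <- function(model, path, outcome = NULL) {
  jsonlite::write_json(
    list(
      family = model$family,
      outcome = outcome,
      basis = list(
        age_powers = model$struct$age_powers,
        count_powers = model$struct$count_powers,
        use_count = model$struct$use_count,
        interactions = model$struct$interactions,
        age_scale = 10, count_shift = 1
      ),
      terms = names(model$beta),
      beta = unname(model$beta),
      sigma = as.vector(t(model$sigma)),
      dispersion = model$dispersion,
      n = model$n, events = model$events,
      support = model$support
    ),
    path,
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_rate_model
#' @export
read_rate_model <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  k <- length(raw$beta)
  struct <- rate_structure(
    family = raw$family,
    age_powers = raw$basis$age_powers,
    count_powers = raw$basis$count_powers,
    use_count = isTRUE(raw$basis$use_count),
    interactions = as.character(raw$basis$interactions %||% character())
  )
  structure(
    list(
      family = raw$family, struct = struct,
      beta = setNames(raw$beta, raw$terms),
      sigma = matrix(raw$sigma, k, k,
        byrow = TRUE,
        dimnames = list(raw$terms, raw$terms)
      ),
      dispersion = raw$dispersion,
      loglik = NA_real_, aic = NA_real_, converged = TRUE,
      n = raw$n, events = raw$events,
      support = list(
        age = as.numeric(raw$support$age),
        count = if (!is.null(raw$support$count)) as.numeric(raw$support$count)
      )
    ),
    class = "rate_model"
  )
}
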