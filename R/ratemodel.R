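#' Specify a rate-model structure
#'
#' A structure fixes everything about the covariate basis of a community
#' rate model: the family, the fractional-polynomial powers for age and
#' comorbidity count, whether comorbidity count enters at all (model 1 is
#' age + sex; model 2 adds comorbidity count), and any interaction terms.
#' Age is pre-scaled by 1/10 and count is shifted by +1 before the FP
#' transform (see [fp_basis()]).
#'
#' @param family `"poisson"` or `"negbin"`.
#' @param age_powers FP powers for age (default linear).
#' @param count_powers FP powers for comorbidity count (default linear).
#' @param use_count Include comorbidity count (model 2)?
#' @param interactions Subset of `c("age:sex", "sex:count", "age:count")`;
#'   an interaction multiplies the first basis column of each constituent.
#' @return A `rate_structure` list.
#' @export
rate_structure <- function(family = c("poisson", "negbin"),
                           age_powers = 1, count_powers = 1,
                           use_count = TRUE, interactions = character()) {
  family <- match.arg(family)
  ok <- c("age:sex", "sex:count", "age:count")
  if (!all(interactions %in% ok)) {
    abort(paste0("interactions must be among ", paste(ok, collapse = ", ")),
      class = "trialrep_config_error"
    )
  }
  structure(
    list(
      family = family, age_powers = age_powers, count_powers = count_powers,
      use_count = use_count, interactions = interactions
    ),
    class = "rate_structure"
  )
}

# internal: build the design matrix for a structure
rate_design <- function(rows, struct) {
  age_b <- fp_basis(rows$age, struct$age_powers, scale = 10, var_name = "age")
  female <- matrix(as.double(rows$female), ncol = 1L, dimnames = list(NULL, "female"))
  X <- cbind(`(Intercept)` = 1, age_b, female)
  if (isTRUE(struct$use_count)) {
    cnt_b <- fp_basis(rows$count, struct$count_powers, shift = 1, var_name = "count")
    X <- cbind(X, cnt_b)
  }
  for (ia in struct$interactions) {
    col <- switch(ia,
      "age:sex" = age_b[, 1L] * as.double(rows$female),
      "sex:count" = if (isTRUE(struct$use_count)) {
        as.double(rows$female) * fp_basis(rows$count, struct$count_powers,
          shift = 1, var_name = "count"
        )[, 1L]
      },
      "age:count" = if (isTRUE(struct$use_count)) {
        age_b[, 1L] * fp_basis(rows$count, struct$count_powers,
          shift = 1, var_name = "count"
        )[, 1L]
      }
    )
    if (!is.null(col)) {
      X <- cbind(X, matrix(col, ncol = 1L, dimnames = list(NULL, ia)))
    }
  }
  X
}

# internal: person-years column with validation
person_years <- function(rows) {
  py <- if ("py" %in% names(rows)) {
    rows$py
  } else if ("time_at_risk" %in% names(rows)) {
    rows$time_at_risk / DAYS_PER_YEAR
  } else {
    abort("rows need a 'py' (person-years) or 'time_at_risk' (days) column",
      class = "trialrep_rate_error"
    )
  }
  if (any(!is.finite(py)) || any(py < 0)) {
    abort("person-time must be finite and nonnegative", class = "trialrep_rate_error")
  }
  py
}

#' Fit a community event-rate model
#'
#' Poisson or negative-binomial regression of first-event counts with a
#' log link and an offset of log person-time at risk, on a fractional-
#' polynomial basis in age (and, for model 2, comorbidity count) plus a
#' female indicator and optional interactions. Constant covariate columns
#' are collinear with the intercept and are dropped with a warning. The
#' fitted coefficients and their variance-covariance matrix are retained so
#' they can be exported and transported to a trial covariate distribution
#' without any row-level data leaving the model.
#'
#' @param rows Tibble with `age`, `female`, `events` (0/1 first-event
#'   indicator or count), `py` person-years at risk (or `time_at_risk` in
#'   days), and `count` when the structure uses it. Rows with zero
#'   person-time are dropped.
#' @param struct A [rate_structure()].
#' @return A `rate_model`: family, structure, `beta`, `sigma`, `dispersion`
#'   (negbin 1/theta, else 0), log-likelihood, AIC, convergence flag, the
#'   covariate support seen at fit time, and sample size.
#' @export
fit_rate_model <- function(rows, struct = rate_structure()) {
  py <- person_years(rows)
  keep <- py > 0
  if (!all(keep)) {
    log_note(sum(!keep), " row(s) with zero person-time dropped")
    rows <- rows[keep, , drop = FALSE]
    py <- py[keep]
  }
  y <- rows$events
  if (sum(y) < 1) {
    abort("no events in the fitting window; widen the observation window",
      class = "trialrep_rate_error"
    )
  }
  X <- rate_design(rows, struct)
  # constant non-intercept columns are unidentifiable next to the intercept
  const <- apply(X[, -1L, drop = FALSE], 2L, function(v) {
    diff(range(v)) < sqrt(.Machine$double.eps)
  })
  if (any(const)) {
    dropped <- colnames(X)[-1L][const]
    warn(
      paste0(
        "covariate column(s) constant across rows rejected as collinear ",
        "with the intercept: ", paste(dropped, collapse = ", ")
      ),
      class = "trialrep_collinear"
    )
    X <- X[, c(TRUE, !const), drop = FALSE]
  }
  off <- log(py)

  if (struct$family == "poisson") {
    fit <- glm.fit(X, y,
      offset = off, family = poisson(),
      control = list(maxit = 100)
    )
    if (!fit$converged || any(is.na(fit$coefficients))) {
      abort(
        paste0(
          "Poisson rate model failed: ",
          if (!fit$converged) "IRLS did not converge" else "separation (NA coefficients)",
          "; deviance ", signif(fit$deviance, 6)
        ),
        class = "trialrep_rate_error"
      )
    }
    beta <- fit$coefficients
    # vcov = (X' W X)^-1 from the final IRLS weights
    w <- fit$weights
    sigma <- chol2inv(chol(crossprod(X * sqrt(w))))
    dimnames(sigma) <- list(names(beta), names(beta))
    mu <- fit$fitted.values
    ll <- sum(dpois(y, mu, log = TRUE))
    aic <- -2 * ll + 2 * length(beta)
    disp <- 0
    converged <- fit$converged
  } else {
    df <- data.frame(.y = y, .off = off)
    fit <- suppressWarnings(
      MASS::glm.nb(.y ~ 0 + X + offset(.off), data = df, control = stats::glm.control(maxit = 100))
    )
    if (any(is.na(coef(fit)))) {
      abort("negative-binomial rate model produced NA coefficients (separation?)",
        class = "trialrep_rate_error"
      )
    }
    beta <- setNames(coef(fit), colnames(X))
    sigma <- vcov(fit)
    dimnames(sigma) <- list(names(beta), names(beta))
    ll <- as.numeric(logLik(fit))
    aic <- AIC(fit)
    disp <- 1 / fit$theta
    converged <- fit$converged %||% TRUE
  }

  structure(
    list(
      family = struct$family, struct = struct,
      beta = beta, sigma = sigma, dispersion = disp,
      loglik = ll, aic = aic, converged = converged,
      n = nrow(rows), events = sum(y),
      support = list(
        age = range(rows$age),
        count = if (isTRUE(struct$use_count)) range(rows$count) else NULL
      )
    ),
    class = "rate_model"
  )
}

#' @export
print.rate_model <- function(x, ...) {
  cat(
    "<rate_model> ", x$family, ", ", length(x$beta), " terms, n = ", x$n,
    ", events = ", x$events, ", AIC = ", signif(x$aic, 6), "\n",
    sep = ""
  )
  print(signif(x$beta, 4))
  invisible(x)
}

#' @method tidy rate_model
#' @export
tidy.rate_model <- function(x, ...) {
  tibble(
    term = names(x$beta),
    estimate = unname(x$beta),
    std.error = sqrt(diag(x$sigma))
  )
}

#' @method glance rate_model
#' @export
glance.rate_model <- function(x, ...) {
  tibble(
    family = x$family, nobs = x$n, events = x$events,
    logLik = x$loglik, AIC = x$aic, dispersion = x$dispersion,
    converged = x$converged
  )
}

# internal: quick Poisson deviance fit used inside structure search
search_fit <- function(X, y, off, family, theta = NULL) {
  if (family == "poisson") {
    fit <- glm.fit(X, y, offset = off, family = poisson(), control = list(maxit = 100))
    mu <- fit$fitted.values
    ll <- sum(dpois(y, mu, log = TRUE))
  } else {
    fam <- MASS::negative.binomial(theta)
    fit <- suppressWarnings(
      glm.fit(X, y,
        offset = off, family = fam, mustart = y + 0.1,
        control = list(maxit = 100)
      )
    )
    mu <- fit$fitted.values
    ll <- sum(dnbinom(y, size = theta, mu = mu, log = TRUE))
  }
  list(loglik = ll, df = sum(!is.na(fit$coefficients)), converged = fit$converged)
}

#' Choose the count-regression family by boundary-corrected likelihood ratio
#'
#' Compares Poisson against negative binomial under the linear covariate
#' structure. The dispersion null sits on the boundary of the parameter
#' space, so the likelihood-ratio statistic is referred to a 50:50 mixture
#' of a point mass at zero and chi-squared with 1 df.
#'
#' @param rows As [fit_rate_model()].
#' @param use_count Include the comorbidity-count column in the linear
#'   structure used for the comparison.
#' @param alpha Test level (default 0.05).
#' @return List: `family`, `lr`, `p`, `theta` (the negative-binomial size
#'   estimate used, `Inf` when it degenerates to Poisson).
#' @export
select_family <- function(rows, use_count = TRUE, alpha = 0.05) {
  py <- person_years(rows)
  keep <- py > 0
  rows <- rows[keep, , drop = FALSE]
  off <- log(py[keep])
  y <- rows$events
  lin <- rate_structure("poisson", use_count = use_count)
  X <- rate_design(rows, lin)
  pois <- search_fit(X, y, off, "poisson")
  theta0 <- tryCatch(
    suppressWarnings(as.numeric(MASS::theta.ml(
      y, glm.fit(X, y, offset = off, family = poisson())$fitted.values,
      limit = 50
    ))),
    error = function(e) Inf
  )
  # theta.ml can truncate at zero when the sample is not overdispersed;
  # a nonpositive size is not a usable family, so treat it as the boundary
  if (!is.finite(theta0) || theta0 <= 0) theta0 <- Inf
  ll_nb <- if (is.finite(theta0)) {
    search_fit(X, y, off, "negbin", theta = theta0)$loglik
  } else {
    pois$loglik
  }
  lr <- max(0, 2 * (ll_nb - pois$loglik))
  p <- 0.5 * pchisq(lr, df = 1, lower.tail = FALSE) + ifelse(lr <= 0, 0.5, 0)
  list(
    family = if (p < alpha) "negbin" else "poisson",
    lr = lr, p = p, theta = theta0
  )
}

#' Select the rate-model structure from the data
#'
#' Data-driven structure choice, every comparison logged:
#' 1. **Family** — Poisson vs negative binomial by likelihood-ratio test on
#'    the dispersion under the linear structure; the null is on the boundary
#'    of the parameter space, so the statistic is referred to a 50:50
#'    mixture of a point mass at zero and chi-squared(1) (`alpha` = 0.05).
#' 2. **Fractional-polynomial powers** for age, then comorbidity count, by
#'    the closed-test procedure on deviance: best two-term FP against the
#'    null (4 df), against linear (3 df), and against the best one-term FP
#'    (2 df). Variables are never dropped from the model (the analysis
#'    models standardise by age and sex by design): when the closed test
#'    finds no evidence of non-linearity the variable stays linear.
#' 3. **Interactions** (`age:sex`, `sex:count`, `age:count`) are kept when
#'    the likelihood-ratio p-value is below `alpha` *and* AIC improves.
#'
#' During the FP and interaction searches the negative-binomial dispersion
#' is held fixed at its linear-structure estimate; the returned structure is
#' meant to be refitted with [fit_rate_model()], which frees it again.
#'
#' @param rows As [fit_rate_model()].
#' @param use_count Search a model-2 (comorbidity count) structure?
#' @param alpha Test level for family, FP and interaction decisions.
#' @return A [rate_structure()] with the decision log in
#'   `attr(, "decisions")` (a tibble).
#' @export
select_structure <- function(rows, use_count = TRUE, alpha = 0.05) {
  py <- person_years(rows)
  keep <- py > 0
  rows <- rows[keep, , drop = FALSE]
  off <- log(py[keep])
  y <- rows$events
  decisions <- list()
  note <- function(step, comparison, stat, p, chosen) {
    decisions[[length(decisions) + 1L]] <<- tibble(
      step = step, comparison = comparison,
      statistic = stat, p = p, chosen = chosen
    )
  }

  # 1. family, under the linear structure
  fam_sel <- select_family(rows, use_count = use_count, alpha = alpha)
  family <- fam_sel$family
  note(
    "family", "negbin vs poisson (boundary LRT on dispersion)",
    fam_sel$lr, fam_sel$p, family
  )
  theta_fixed <- if (family == "negbin") fam_sel$theta else NULL

  # 2. FP powers by the closed test, age first, then count
  pick_fp <- function(var, base_struct) {
    set_p <- function(st, p) {
      if (var == "age") st$age_powers <- p else st$count_powers <- p
      st
    }
    get_ll <- function(p) {
      st <- set_p(base_struct, p)
      search_fit(rate_design(rows, st), y, off, family, theta = theta_fixed)$loglik
    }
    ll_lin <- get_ll(1)
    fp1 <- purrr::map_dbl(fp_powers_pool(), get_ll)
    best1 <- fp_powers_pool()[which.max(fp1)]
    fp2 <- purrr::map_dbl(fp2_pairs(), get_ll)
    best2 <- fp2_pairs()[[which.max(fp2)]]
    ll1 <- max(fp1)
    ll2 <- max(fp2)
    # null reference: the model without the variable
    ll0 <- if (var == "age") {
      Xn <- rate_design(rows, set_p(base_struct, 1))
      Xn <- Xn[, setdiff(colnames(Xn), "age^1"), drop = FALSE]
      search_fit(Xn, y, off, family, theta = theta_fixed)$loglik
    } else {
      st_null <- base_struct
      st_null$use_count <- FALSE
      search_fit(rate_design(rows, st_null), y, off, family, theta = theta_fixed)$loglik
    }
    p_any <- pchisq(2 * (ll2 - ll0), df = 4, lower.tail = FALSE)
    note(paste0("fp_", var), "best FP2 vs null (4 df)", 2 * (ll2 - ll0), p_any, NA)
    if (p_any >= alpha) {
      note(paste0("fp_", var), "no evidence of effect; kept linear by design", NA, NA, "1")
      return(1)
    }
    p_nonlin <- pchisq(2 * (ll2 - ll_lin), df = 3, lower.tail = FALSE)
    note(paste0("fp_", var), "best FP2 vs linear (3 df)", 2 * (ll2 - ll_lin), p_nonlin, NA)
    if (p_nonlin >= alpha) {
      return(1)
    }
    p_two <- pchisq(2 * (ll2 - ll1), df = 2, lower.tail = FALSE)
    note(
      paste0("fp_", var), "best FP2 vs best FP1 (2 df)", 2 * (ll2 - ll1), p_two,
      NA
    )
    if (p_two < alpha) best2 else best1
  }

  st <- rate_structure(family, use_count = use_count)
  st$age_powers <- pick_fp("age", st)
  if (use_count) {
    st$count_powers <- pick_fp("count", st)
  }

  # 3. interactions: LRT and AIC must both favour inclusion
  cand <- c("age:sex", if (use_count) c("sex:count", "age:count"))
  base_ll <- search_fit(rate_design(rows, st), y, off, family, theta = theta_fixed)
  for (ia in cand) {
    st_try <- st
    st_try$interactions <- c(st$interactions, ia)
    with_ll <- search_fit(rate_design(rows, st_try), y, off, family, theta = theta_fixed)
    lr_ia <- 2 * (with_ll$loglik - base_ll$loglik)
    p_ia <- pchisq(max(lr_ia, 0), df = with_ll$df - base_ll$df, lower.tail = FALSE)
    aic_gain <- (-2 * base_ll$loglik + 2 * base_ll$df) -
      (-2 * with_ll$loglik + 2 * with_ll$df)
    keep_ia <- p_ia < alpha && aic_gain > 0
    note(
      "interaction", paste0(ia, " (LRT & AIC)"), lr_ia, p_ia,
      if (keep_ia) "kept" else "dropped"
    )
    if (keep_ia) {
      st <- st_try
      base_ll <- with_ll
    }
  }

  attr(st, "decisions") <- bind_rows(decisions)
  st
}
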