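#' Total eGFR slope from longitudinal trajectories
#'
#' Fits the piecewise-linear (linear-spline) trajectory model with a knot at
#' `knot_days` after treatment initiation:
#' an acute segment over days 0 to `knot_days` (coefficient expressed as the
#' change over the whole knot interval, mL/min/1.73m2) and a chronic annual
#' slope thereafter. Fixed effects are intercept + acute + chronic; random
#' effects are a per-person intercept and chronic slope (this structure
#' accommodates the irregular visit grids of routine care; an optional
#' `"mmrm"` engine with an unstructured residual covariance over a declared
#' common visit grid is available for trial-style data). The headline
#' estimate is the annualised *total* slope over the analysis window
#' \eqn{W} (years):
#' \deqn{\mathrm{total} = \big(a + s\,(W - 21/365.25)\big) / W}
#' i.e. including the acute change, with the chronic slope reported
#' alongside for diagnostics.
#'
#' Persons are retained when they have a baseline value (the most recent
#' eGFR on or before day 0) plus at least one post-baseline value, and
#' follow-up of at least `min_followup_years`; dropped persons are counted
#' in the log. Fewer than 10 retained persons is an error.
#'
#' @param series Long tibble `person_id`, `day`, `egfr`.
#' @param knot_days Acute/chronic knot (default 21 days).
#' @param min_followup_years Minimum per-person follow-up (default 2).
#' @param window_years Analysis window for annualising the total slope;
#'   defaults to the largest retained visit day.
#' @param method `"ri_rs"` (random intercept + random chronic slope,
#'   default) or `"mmrm"` (unstructured residual covariance on a common
#'   visit grid via generalised least squares).
#' @return A `slope_fit`: `acute_change_estimate`, `chronic_slope`,
#'   `total_slope_annualized`, standard errors, `n_persons`,
#'   `n_observations`, `converged`, `window_years`, `method`.
#' @export
fit_total_slope <- function(series, knot_days = 21, min_followup_years = 2,
                            window_years = NULL,
                            method = c("ri_rs", "mmrm")) {
  method <- match.arg(method)
  base <- series |>
    filter(.data$day <= 0, !is.na(.data$egfr)) |>
    arrange(dplyr::desc(.data$day)) |>
    distinct(.data$person_id, .keep_all = TRUE)
  post <- series |>
    filter(.data$day > 0, !is.na(.data$egfr)) |>
    semi_join(base, by = "person_id")
  span <- post |>
    group_by(.data$person_id) |>
    summarise(last_day = max(.data$day), n_post = n(), .groups = "drop")
  keep <- span |>
    filter(
      .data$n_post >= 1L,
      .data$last_day >= min_followup_years * DAYS_PER_YEAR
    )
  n_dropped <- dplyr::n_distinct(series$person_id) - nrow(keep)
  if (n_dropped > 0L) {
    log_note(
      n_dropped, " person(s) dropped (no baseline, no post-baseline value, ",
      "or follow-up under ", min_followup_years, " years)"
    )
  }
  if (nrow(keep) < 10L) {
    abort(
      paste0("only ", nrow(keep), " person(s) retained; at least 10 required"),
      class = "trialrep_slope_error"
    )
  }
  dat <- bind_rows(base, post) |>
    semi_join(keep, by = "person_id") |>
    arrange(.data$person_id, .data$day) |>
    mutate(
      acute = pmin(.data$day, knot_days) / knot_days,
      chronic = pmax(.data$day - knot_days, 0) / DAYS_PER_YEAR
    )
  if (is.null(window_years)) {
    window_years <- max(dat$day) / DAYS_PER_YEAR
  }

  if (method == "ri_rs") {
    fit <- tryCatch(
      suppressWarnings(suppressMessages(
        lme4::lmer(
          egfr ~ acute + chronic + (1 + chronic | person_id),
          data = dat,
          control = lme4::lmerControl(
            check.conv.singular = "ignore",
            calc.derivs = FALSE
          )
        )
      )),
      error = function(e) NULL
    )
    if (!is.null(fit)) {
      beta <- lme4::fixef(fit)
      V <- as.matrix(vcov(fit))
      converged <- length(fit@optinfo$conv$lme4$messages %||% character()) == 0L
    } else {
      # degenerate data (e.g. noise-free trajectories) can defeat the mixed
      # model; per-person fixed intercepts give the exact spline fit there
      fit <- stats::lm(egfr ~ 0 + factor(person_id) + acute + chronic, data = dat)
      cf <- coef(fit)
      beta <- c(`(Intercept)` = mean(cf[grepl("person_id", names(cf))]),
        acute = cf[["acute"]], chronic = cf[["chronic"]]
      )
      Vf <- vcov(fit)
      V <- matrix(0, 3, 3, dimnames = list(names(beta), names(beta)))
      V[2:3, 2:3] <- Vf[c("acute", "chronic"), c("acute", "chronic")]
      converged <- TRUE
    }
  } else {
    grid <- sort(unique(dat$day))
    if (length(grid) > 30L) {
      abort("mmrm engine needs a common visit grid (too many distinct days)",
        class = "trialrep_slope_error"
      )
    }
    dat$visit <- match(dat$day, grid)
    fit <- nlme::gls(
      egfr ~ acute + chronic,
      data = dat,
      correlation = nlme::corSymm(form = ~ visit | person_id),
      weights = nlme::varIdent(form = ~ 1 | visit),
      na.action = stats::na.omit
    )
    beta <- coef(fit)
    V <- as.matrix(vcov(fit))
    converged <- TRUE
  }

  a <- beta[["acute"]]
  s <- beta[["chronic"]]
  w <- window_years
  kyr <- knot_days / DAYS_PER_YEAR
  total <- (a + s * (w - kyr)) / w
  cvec <- c(0, 1 / w, (w - kyr) / w)
  se_total <- sqrt(drop(t(cvec) %*% V %*% cvec))
  structure(
    list(
      acute_change_estimate = a,
      chronic_slope = s,
      total_slope_annualized = total,
      se_acute = sqrt(V["acute", "acute"]),
      se_chronic = sqrt(V["chronic", "chronic"]),
      se_total = se_total,
      intercept = beta[[1L]],
      n_persons = nrow(keep),
      n_observations = nrow(dat),
      n_dropped = n_dropped,
      window_years = w,
      knot_days = knot_days,
      method = method,
      converged = converged
    ),
    class = "slope_fit"
  )
}

#' @export
print.slope_fit <- function(x, ...) {
  cat(
    "<slope_fit> total ", signif(x$total_slope_annualized, 4),
    " mL/min/1.73m2/yr (acute ", signif(x$acute_change_estimate, 4),
    " over ", x$knot_days, "d, chronic ", signif(x$chronic_slope, 4),
    "/yr); n = ", x$n_persons, " persons, ", x$n_observations, " values\n",
    sep = ""
  )
  invisible(x)
}

#' @method tidy slope_fit
#' @export
tidy.slope_fit <- function(x, ...) {
  tibble(
    term = c("acute_change", "chronic_slope", "total_slope_annualized"),
    estimate = c(
      x$acute_change_estimate, x$chronic_slope, x$total_slope_annualized
    ),
    std.error = c(x$se_acute, x$se_chronic, x$se_total)
  )
}

#' @method glance slope_fit
#' @export
glance.slope_fit <- function(x, ...) {
  tibble(
    n_persons = x$n_persons, n_observations = x$n_observations,
    n_dropped = x$n_dropped, window_years = x$window_years,
    method = x$method, converged = x$converged
  )
}

#' Write a slope fit as JSON
#'
#' @param fit A `slope_fit`.
#' @param population_id Label for the population fitted.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_slope_fit <- function(fit, population_id, path) {
  jsonlite::write_json(
    c(list(population_id = population_id), unclass(fit)),
    path,
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
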