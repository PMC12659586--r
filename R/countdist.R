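#' Fit a count distribution to comorbidity counts
#'
#' Maximum-likelihood fit of a Poisson or negative-binomial distribution to
#' nonnegative integer counts. The negative binomial uses the
#' mean/dispersion parameterisation, `Var = mean * (1 + dispersion * mean)`
#' (`dispersion = 1/size`); its mean MLE equals the sample mean, and the
#' dispersion is profiled numerically. A sample without any variability
#' cannot identify a dispersion: the fit is flagged degenerate and falls
#' back to Poisson with a warning.
#'
#' @param counts Nonnegative integer vector (nonempty).
#' @param family `"poisson"` or `"negbin"`.
#' @return A `fitted_count_dist`: list with `family`, `mean`, `dispersion`
#'   (`NA` for Poisson), `loglik`, `n`, `degenerate`, and (once
#'   [goodness_of_fit()] has run) `gof_statistic`, `gof_p`.
#' @examples
#' fit_count(c(0, 1, 2, 3), "poisson")$mean
#' @export
fit_count <- function(counts, family = c("poisson", "negbin")) {
  family <- match.arg(family)
  if (length(counts) == 0L) {
    abort("counts must be nonempty", class = "trialrep_countdist_error")
  }
  if (any(!is.finite(counts)) || any(counts < 0) || any(counts != floor(counts))) {
    abort("counts must be nonnegative integers", class = "trialrep_countdist_error")
  }
  m <- mean(counts)
  ll_pois <- sum(dpois(counts, pmax(m, 1e-300), log = TRUE))
  degenerate <- FALSE
  if (family == "poisson") {
    fit <- list(
      family = "poisson", mean = m, dispersion = NA_real_,
      loglik = ll_pois, n = length(counts), degenerate = FALSE
    )
  } else {
    if (var(counts) == 0 || m == 0) {
      warn("counts have no variability; negative-binomial fit is degenerate, falling back to Poisson",
        class = "trialrep_degenerate_fit"
      )
      fit <- list(
        family = "poisson", mean = m, dispersion = NA_real_,
        loglik = ll_pois, n = length(counts), degenerate = TRUE
      )
    } else {
      # profile log-likelihood in log(dispersion); mean MLE = sample mean
      nll <- function(ld) {
        -sum(dnbinom(counts, size = 1 / exp(ld), mu = m, log = TRUE))
      }
      opt <- optimize(nll, interval = c(-25, 10))
      ll_nb <- -opt$objective
      disp <- exp(opt$minimum)
      # the Poisson is the dispersion->0 boundary of this family; never
      # report a negbin likelihood below it (optimiser tolerance guard)
      if (ll_nb < ll_pois) {
        ll_nb <- ll_pois
        disp <- 0
      }
      fit <- list(
        family = "negbin", mean = m, dispersion = disp,
        loglik = ll_nb, n = length(counts), degenerate = FALSE
      )
    }
  }
  structure(fit, class = "fitted_count_dist")
}

#' @export
print.fitted_count_dist <- function(x, ...) {
  cat(
    "<fitted_count_dist> ", x$family, ": mean ", signif(x$mean, 4),
    if (x$family == "negbin") paste0(", dispersion ", signif(x$dispersion, 4)),
    ", loglik ", signif(x$loglik, 6), ", n ", x$n, "\n",
    sep = ""
  )
  invisible(x)
}

# internal: fitted CDF on 0..k
count_dist_cdf <- function(fit, k) {
  if (fit$family == "poisson" || is.na(fit$dispersion) || fit$dispersion <= 0) {
    ppois(k, fit$mean)
  } else {
    pnbinom(k, size = 1 / fit$dispersion, mu = fit$mean)
  }
}

# internal: fitted pmf on 0..k
count_dist_pmf <- function(fit, k) {
  if (fit$family == "poisson" || is.na(fit$dispersion) || fit$dispersion <= 0) {
    dpois(k, fit$mean)
  } else {
    dnbinom(k, size = 1 / fit$dispersion, mu = fit$mean)
  }
}

# internal: KS-type statistic, max |ECDF - fitted CDF| over observed support
ks_count_statistic <- function(counts, fit) {
  kmax <- max(counts)
  tab <- tabulate(counts + 1L, nbins = kmax + 1L)
  ecdf_vals <- cumsum(tab) / length(counts)
  max(abs(ecdf_vals - count_dist_cdf(fit, 0:kmax)))
}

#' Goodness of fit for a fitted count distribution
#'
#' Kolmogorov-Smirnov-type statistic (the maximum absolute difference
#' between the empirical CDF and the fitted CDF over the observed support)
#' with a parametric-bootstrap p-value: because the data are discrete and
#' the parameters are estimated, the classical KS null distribution does not
#' apply, so the null is simulated by drawing samples of the same size from
#' the fitted distribution and refitting the same family.
#'
#' @param counts The counts the distribution was fitted to.
#' @param fit A [fit_count()] result.
#' @param n_boot Bootstrap replicates (default 999).
#' @param seed Seed for the bootstrap stream.
#' @return The `fit`, augmented with `gof_statistic` and `gof_p`.
#' @export
goodness_of_fit <- function(counts, fit, n_boot = 999, seed = 1L) {
  stat <- ks_count_statistic(counts, fit)
  n <- length(counts)
  boot <- with_seed(derive_seed(seed, "countdist"), {
    vapply(seq_len(n_boot), function(b) {
      sim <- if (fit$family == "poisson" || is.na(fit$dispersion) || fit$dispersion <= 0) {
        rpois(n, fit$mean)
      } else {
        rnbinom(n, size = 1 / fit$dispersion, mu = fit$mean)
      }
      refit <- suppressWarnings(fit_count(sim, fit$family))
      ks_count_statistic(sim, refit)
    }, numeric(1))
  })
  fit$gof_statistic <- stat
  fit$gof_p <- (1 + sum(boot >= stat)) / (n_boot + 1)
  fit
}

#' Select the best-fitting count distribution
#'
#' Fits Poisson and negative binomial, then:
#' 1. tests for overdispersion with a boundary-corrected likelihood-ratio
#'    test (the dispersion null lies on the parameter-space boundary, so the
#'    LR statistic is referred to an equal mixture of a point mass at zero
#'    and chi-squared with 1 df). If the families are not distinguishable
#'    (p >= `alpha`), the more parsimonious Poisson is selected;
#' 2. otherwise both families receive a parametric-bootstrap goodness-of-fit
#'    p-value and the family with the larger p is selected (exact ties go to
#'    Poisson).
#'
#' @param counts Nonnegative integer counts (at least 2 values).
#' @param n_boot,seed Passed to [goodness_of_fit()].
#' @param alpha Level of the dispersion test (default 0.05).
#' @return A `fitted_count_dist` for the selected family, with goodness-of-
#'   fit fields filled in and the selection path in `attr(, "selection")`.
#' @export
select_best <- function(counts, n_boot = 999, seed = 1L, alpha = 0.05) {
  if (length(counts) < 2L) {
    abort("count-distribution selection needs at least 2 observations",
      class = "trialrep_countdist_error"
    )
  }
  pois <- fit_count(counts, "poisson")
  nb <- suppressWarnings(fit_count(counts, "negbin"))
  lr <- 2 * (nb$loglik - pois$loglik)
  p_disp <- 0.5 * pchisq(max(lr, 0), df = 1, lower.tail = FALSE) +
    ifelse(lr <= 0, 0.5, 0)
  if (nb$degenerate || p_disp >= alpha) {
    sel <- goodness_of_fit(counts, pois, n_boot = n_boot, seed = seed)
    path <- list(dispersion_lrt_p = p_disp, decided_by = "parsimony (no evidence of overdispersion)")
  } else {
    pois <- goodness_of_fit(counts, pois, n_boot = n_boot, seed = seed)
    nb <- goodness_of_fit(counts, nb, n_boot = n_boot, seed = derive_seed(seed, 2L))
    sel <- if (nb$gof_p > pois$gof_p) nb else pois
    path <- list(
      dispersion_lrt_p = p_disp,
      gof_p_poisson = pois$gof_p, gof_p_negbin = nb$gof_p,
      decided_by = "larger bootstrap goodness-of-fit p"
    )
  }
  attr(sel, "selection") <- path
  sel
}

#' Export fitted count-distribution parameters as JSON
#'
#' Writes distribution parameters only — never row-level counts — mirroring
#' a federated workflow where individual-level data stay inside their secure
#' platform and only summaries leave.
#'
#' @param fit A `fitted_count_dist` (ideally from [select_best()] or after
#'   [goodness_of_fit()]).
#' @param population_id Identifier of the population summarised.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
export_count_dist <- function(fit, population_id, path) {
  jsonlite::write_json(
    list(
      population_id = population_id,
      family = fit$family,
      mean = fit$mean,
      dispersion = if (is.na(fit$dispersion)) NULL else fit$dispersion,
      gof_statistic = fit$gof_statistic,
      gof_p = fit$gof_p,
      n = fit$n
    ),
    path,
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @method tidy fitted_count_dist
#' @export
tidy.fitted_count_dist <- function(x, ...) {
  tibble(
    family = x$family,
    mean = x$mean,
    dispersion = x$dispersion,
    loglik = x$loglik,
    gof_statistic = x$gof_statistic %||% NA_real_,
    gof_p = x$gof_p %||% NA_real_,
    n = x$n
  )
}
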