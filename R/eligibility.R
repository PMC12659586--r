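#' Construct a single eligibility criterion
#'
#' Criteria are declarative and conjunctive; a trial's criteria set is the
#' AND of its criteria (OR logic is expressed by expanding into several
#' criteria sets). Supported kinds:
#' * `age_range`, `egfr_range`, `lab_range` — interval checks, bounds closed,
#'   either bound may be open (`NULL`); labs/eGFR use the most recent value
#'   strictly before the index date within `lookback_days`.
#' * `sex` — required sex.
#' * `diagnosis_required` / `diagnosis_excluded` — presence of any coded
#'   record of the named registry condition(s) strictly before index.
#' * `procedure_excluded` — no procedure from `codes` within `window_days`
#'   before index.
#'
#' @param kind Criterion kind (see above).
#' @param min,max Interval bounds (may be `NULL` for open).
#' @param analyte Lab analyte name (for `lab_range`).
#' @param value Required sex (for `sex`).
#' @param conditions Registry condition names (for diagnosis kinds).
#' @param codes Procedure code set (for `procedure_excluded`).
#' @param lookback_days Lab/eGFR lookback (default 730 = 2 years).
#' @param window_days Procedure exclusion window.
#' @param label Optional human-readable label (auto-generated otherwise).
#' @return A `criterion` object.
#' @export
criterion <- function(kind, min = NULL, max = NULL, analyte = NULL,
                      value = NULL, conditions = NULL, codes = NULL,
                      lookback_days = 730, window_days = NULL, label = NULL) {
  kinds <- c(
    "age_range", "sex", "lab_range", "egfr_range",
    "diagnosis_required", "diagnosis_excluded", "procedure_excluded"
  )
  if (!kind %in% kinds) {
    abort(paste0("unknown criterion kind '", kind, "'"),
      class = "trialrep_config_error"
    )
  }
  if (!is.null(min) && !is.null(max) && min > max) {
    abort("criterion min must be <= max", class = "trialrep_config_error")
  }
  if (kind == "lab_range" && is.null(analyte)) {
    abort("lab_range criterion requires an analyte", class = "trialrep_config_error")
  }
  if (kind %in% c("lab_range", "egfr_range") && lookback_days <= 0) {
    abort("lookback_days must be > 0", class = "trialrep_config_error")
  }
  if (kind == "procedure_excluded" && (is.null(codes) || is.null(window_days))) {
    abort("procedure_excluded requires codes and window_days",
      class = "trialrep_config_error"
    )
  }
  if (kind %in% c("diagnosis_required", "diagnosis_excluded") && is.null(conditions)) {
    abort(paste0(kind, " requires condition names"), class = "trialrep_config_error")
  }
  if (is.null(label)) {
    label <- switch(kind,
      age_range = paste0("age ", min %||% "-Inf", "-", max %||% "Inf"),
      sex = paste0("sex ", value),
      lab_range = paste0(analyte, " ", min %||% "-Inf", "-", max %||% "Inf"),
      egfr_range = paste0("egfr ", min %||% "-Inf", "-", max %||% "Inf"),
      diagnosis_required = paste0("requires ", paste(conditions, collapse = "|")),
      diagnosis_excluded = paste0("excludes ", paste(conditions, collapse = "|")),
      procedure_excluded = paste0("no procedure ", paste(codes, collapse = "|"),
        " within ", window_days, "d"
      )
    )
  }
  structure(
    list(
      kind = kind, min = min, max = max, analyte = analyte, value = value,
      conditions = conditions, codes = codes, lookback_days = lookback_days,
      window_days = window_days, label = label
    ),
    class = "criterion"
  )
}

#' Construct a trial criteria set
#'
#' @param trial_id Trial identifier.
#' @param criteria List of [criterion()] objects (nonempty).
#' @param followup_years Follow-up duration of the corresponding trial (> 0).
#' @return A `trial_criteria_set`.
#' @export
trial_criteria_set <- function(trial_id, criteria, followup_years) {
  if (length(criteria) == 0L) {
    abort("criteria set must be nonempty", class = "trialrep_config_error")
  }
  if (!all(vapply(criteria, inherits, logical(1), "criterion"))) {
    abort("criteria must be a list of criterion objects",
      class = "trialrep_config_error"
    )
  }
  if (!is.numeric(followup_years) || followup_years <= 0) {
    abort("followup_years must be > 0", class = "trialrep_config_error")
  }
  structure(
    list(trial_id = trial_id, criteria = criteria, followup_years = followup_years),
    class = "trial_criteria_set"
  )
}

#' Most recent laboratory value before the index date
#'
#' Returns each person's most recent value of `analyte` strictly before
#' `index_day` and within the lookback window. Ties on the same day are
#' broken by the highest record sequence number (input row order), with a
#' log note. Missingness is a value: persons with no qualifying record are
#' absent from the result.
#'
#' @param labs Tibble `person_id`, `day`, `analyte`, `value`.
#' @param analyte Analyte to extract.
#' @param index_day Index date (day).
#' @param lookback_days Lookback window (default 730).
#' @return Tibble `person_id`, `day`, `value`.
#' @export
latest_lab <- function(labs, analyte, index_day = 0, lookback_days = 730) {
  cand <- labs |>
    mutate(.seq = row_number()) |>
    filter(
      .data$analyte == !!analyte,
      .data$day < index_day,
      .data$day >= index_day - lookback_days,
      !is.na(.data$value)
    )
  picked <- cand |>
    arrange(dplyr::desc(.data$day), dplyr::desc(.data$.seq)) |>
    distinct(.data$person_id, .keep_all = TRUE)
  n_ties <- cand |>
    count(.data$person_id, .data$day) |>
    filter(.data$n > 1L) |>
    nrow()
  if (n_ties > 0L) {
    log_note(
      n_ties, " same-day tie(s) for '", analyte,
      "' broken by highest record sequence number"
    )
  }
  select(picked, "person_id", "day", "value")
}

#' Evaluate one criterion against every person in a cohort
#'
#' A pure function of records strictly before the index date. Each person is
#' classified `"satisfied"`, `"violated"` or `"unevaluable"` (the latter
#' when the data needed to decide — e.g. a lab value within lookback — do
#' not exist).
#'
#' @param cohort A `community_cohort` (or a compatible list of tibbles).
#' @param crit A [criterion()].
#' @param registry Condition registry (for diagnosis kinds and eGFR).
#' @param index_day Index date (day 0 by default).
#' @return Tibble `person_id`, `status`.
#' @export
evaluate_criterion <- function(cohort, crit, registry = default_registry(),
                               index_day = 0) {
  if (!inherits(crit, "criterion")) {
    abort("crit must be a criterion object", class = "trialrep_config_error")
  }
  persons <- cohort$persons
  ids <- persons$person_id
  status <- rep("satisfied", length(ids))

  in_range <- function(x, lo, hi) {
    ok <- rep(TRUE, length(x))
    if (!is.null(lo)) ok <- ok & x >= lo
    if (!is.null(hi)) ok <- ok & x <= hi
    ok
  }

  if (crit$kind == "age_range") {
    ok <- in_range(persons$age, crit$min, crit$max)
    status <- if_else(is.na(ok), "unevaluable", if_else(ok, "satisfied", "violated"))
  } else if (crit$kind == "sex") {
    ok <- persons$sex == crit$value
    status <- if_else(is.na(ok), "unevaluable", if_else(ok, "satisfied", "violated"))
  } else if (crit$kind == "lab_range") {
    vals <- latest_lab(cohort$labs, crit$analyte, index_day, crit$lookback_days)
    v <- vals$value[match(ids, vals$person_id)]
    ok <- in_range(v, crit$min, crit$max)
    status <- if_else(is.na(v), "unevaluable", if_else(ok, "satisfied", "violated"))
  } else if (crit$kind == "egfr_range") {
    eg <- egfr_at_index(cohort$labs, persons, index_day, crit$lookback_days)
    v <- eg$egfr[match(ids, eg$person_id)]
    ok <- in_range(v, crit$min, crit$max)
    status <- if_else(is.na(v), "unevaluable", if_else(ok, "satisfied", "violated"))
  } else if (crit$kind %in% c("diagnosis_required", "diagnosis_excluded")) {
    codes <- registry |>
      filter(.data$condition %in% crit$conditions) |>
      pull(.data$code)
    if (length(codes) == 0L) {
      abort(
        paste0(
          "no registry codes for condition(s): ",
          paste(crit$conditions, collapse = ", ")
        ),
        class = "trialrep_config_error"
      )
    }
    hit <- cohort$diagnoses |>
      filter(.data$day < index_day, .data$code %in% codes) |>
      distinct(.data$person_id)
    present <- ids %in% hit$person_id
    ok <- if (crit$kind == "diagnosis_required") present else !present
    status <- if_else(ok, "satisfied", "violated")
  } else if (crit$kind == "procedure_excluded") {
    hit <- cohort$procedures |>
      filter(
        .data$code %in% crit$codes,
        .data$day < index_day,
        .data$day >= index_day - crit$window_days
      ) |>
      distinct(.data$person_id)
    status <- if_else(ids %in% hit$person_id, "violated", "satisfied")
  }
  tibble(person_id = ids, status = status)
}

#' Classify a cohort against a trial's eligibility criteria
#'
#' Applies every criterion at the index date and partitions the cohort into
#' eligible and ineligible. Under the default `"strict"` policy a person
#' must satisfy every criterion with no unevaluable ones (a conservative
#' reading when required data are missing); under `"lenient"`, unevaluable
#' criteria are ignored.
#'
#' @param cohort A `community_cohort`.
#' @param criteria_set A [trial_criteria_set()].
#' @param registry Condition registry.
#' @param policy `"strict"` (default) or `"lenient"`.
#' @param index_day Index date.
#' @return Tibble of class `eligibility_result`: `person_id`, `eligible`,
#'   `failed_criteria` and `unevaluable_criteria` (list-columns of labels),
#'   with the eligible proportion in `attr(, "proportion")` (also via
#'   [eligible_proportion()]).
#' @export
classify_cohort <- function(cohort, criteria_set, registry = default_registry(),
                            policy = c("strict", "lenient"), index_day = 0) {
  policy <- match.arg(policy)
  if (is.null(cohort$persons) || nrow(cohort$persons) == 0L) {
    abort("cohort is empty", class = "trialrep_eligibility_error")
  }
  if (!inherits(criteria_set, "trial_criteria_set")) {
    abort("criteria_set must be a trial_criteria_set", class = "trialrep_config_error")
  }
  ids <- cohort$persons$person_id
  labels <- vapply(criteria_set$criteria, function(cr) cr$label, character(1))
  status_mat <- vapply(
    criteria_set$criteria,
    function(cr) evaluate_criterion(cohort, cr, registry, index_day)$status,
    character(length(ids))
  )
  if (is.null(dim(status_mat))) status_mat <- matrix(status_mat, nrow = 1L)
  violated <- status_mat == "violated"
  uneval <- status_mat == "unevaluable"
  eligible <- rowSums(violated) == 0L &
    (if (policy == "strict") rowSums(uneval) == 0L else TRUE)
  out <- tibble(
    person_id = ids,
    eligible = eligible,
    failed_criteria = apply(violated, 1L, function(v) labels[v], simplify = FALSE),
    unevaluable_criteria = apply(uneval, 1L, function(v) labels[v], simplify = FALSE)
  )
  attr(out, "proportion") <- mean(eligible)
  attr(out, "trial_id") <- criteria_set$trial_id
  attr(out, "policy") <- policy
  class(out) <- c("eligibility_result", class(out))
  out
}

#' @rdname classify_cohort
#' @param x An `eligibility_result`.
#' @export
eligible_proportion <- function(x) {
  attr(x, "proportion")
}

#' Read / write trial criteria files
#'
#' One file per trial, JSON or YAML by extension, with fields `trial_id`,
#' `followup_years` and `criteria` (an array of criterion objects whose
#' fields mirror [criterion()]).
#'
#' @param path File path (`.json`, `.yaml` or `.yml`).
#' @return A [trial_criteria_set()].
#' @export
read_criteria <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = FALSE)
  }
  crits <- purrr::map(raw$criteria, function(cr) {
    criterion(
      kind = cr$kind,
      min = cr$min, max = cr$max, analyte = cr$analyte, value = cr$value,
      conditions = unlist(cr$conditions), codes = unlist(cr$codes),
      lookback_days = cr$lookback_days %||% 730,
      window_days = cr$window_days, label = cr$label
    )
  })
  trial_criteria_set(raw$trial_id, crits, raw$followup_years)
}

#' @rdname read_criteria
#' @param criteria_set A [trial_criteria_set()].
#' @export
write_criteria <- function(criteria_set, path) {
  out <- list(
    trial_id = criteria_set$trial_id,
    followup_years = criteria_set$followup_years,
    criteria = purrr::map(criteria_set$criteria, function(cr) {
      Filter(Negate(is.null), unclass(cr))
    })
  )
  if (grepl("\\.ya?ml$", path)) {
    yaml::write_yaml(out, path)
  } else {
    jsonlite::write_json(out, path, auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(path)
}

#' Criteria sets shipped with the package
#'
#' Reads the demo criteria fixtures under `inst/extdata/criteria`: a broad
#' glycaemia trial, a high-risk cardiovascular-outcome trial and a narrow
#' glycaemia trial.
#'
#' @return Named list of [trial_criteria_set()] objects.
#' @export
bundled_criteria <- function() {
  dir <- system.file("extdata", "criteria", package = "trialrep")
  files <- list.files(dir, pattern = "\\.json$", full.names = TRUE)
  sets <- purrr::map(files, read_criteria)
  setNames(sets, vapply(sets, function(s) s$trial_id, character(1)))
}
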