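#' Classify a death as cardiovascular or not from its underlying cause
#'
#' Cardiovascular iff the underlying-cause code starts with "I" (case
#' normalised), the circulatory-system chapter; every other coded death is
#' non-cardiovascular. Empty or missing codes are `"unknown"`: such deaths
#' are excluded from the cause-specific outcomes with a log entry.
#'
#' @param underlying_cause_code Character vector of cause codes.
#' @return Character vector: `"cv"`, `"noncv"` or `"unknown"`.
#' @examples
#' classify_death(c("I21.0", "C34.9", "i60", NA))
#' @export
classify_death <- function(underlying_cause_code) {
  code <- trimws(toupper(as.character(underlying_cause_code)))
  out <- if_else(startsWith(code, "I"), "cv", "noncv")
  out[is.na(code) | code == ""] <- "unknown"
  out
}

#' Time at risk and first-event ascertainment in a community cohort
#'
#' For each person, follow-up for an outcome runs from the index date (day
#' 0, exclusive — day-0 events are prevalent, not incident) to the first of:
#' the outcome event, deregistration from the practice, death, or the end of
#' the trial-matched observation window. The event flag is true only when
#' the outcome event is that minimum. Persons who deregistered on or before
#' the index date are excluded with a logged reason.
#'
#' Outcomes:
#' * `"sae"` — first all-cause hospital admission or death (either is, by
#'   definition, a serious adverse event in a trial context);
#' * `"death_all"`, `"death_cv"`, `"death_noncv"` — deaths, split by
#'   [classify_death()]; deaths of unknown cause are excluded from the
#'   cause-specific outcomes (censored at death) with a log entry;
#' * `"mace"` — first of an admission matching the myocardial-infarction or
#'   ischaemic-stroke code lists, or a cardiovascular death. A
#'   non-cardiovascular death censors.
#'
#' @param cohort A `community_cohort`.
#' @param outcome One of `"sae"`, `"mace"`, `"death_all"`, `"death_cv"`,
#'   `"death_noncv"`.
#' @param window_days Observation window length in days (> 0), matched to
#'   the corresponding trial's follow-up.
#' @param mace_codes MACE component code lists (default [mace_code_lists()]).
#' @return Tibble: `person_id`, `outcome`, `event` (logical),
#'   `time_at_risk` (days, > 0), `event_day` (`NA` when censored).
#' @export
time_at_risk <- function(cohort, outcome = c(
                           "sae", "mace", "death_all", "death_cv", "death_noncv"
                         ),
                         window_days, mace_codes = mace_code_lists()) {
  outcome <- match.arg(outcome)
  if (window_days <= 0) {
    abort("window_days must be > 0", class = "trialrep_outcome_error")
  }
  per <- cohort$persons
  excluded <- !is.na(per$dereg_day) & per$dereg_day <= 0
  if (any(excluded)) {
    log_note(
      sum(excluded),
      " person(s) deregistered on/before the index date excluded from '",
      outcome, "'"
    )
    per <- per[!excluded, , drop = FALSE]
  }
  ids <- per$person_id

  death_day <- per$death_day
  death_class <- classify_death(per$death_cause)
  n_unknown <- sum(!is.na(death_day) & death_class == "unknown")
  if (outcome %in% c("death_cv", "death_noncv") && n_unknown > 0L) {
    log_note(
      n_unknown, " death(s) with unknown cause excluded from '", outcome,
      "' (censored at death)"
    )
  }

  first_admission <- function(codes = NULL) {
    adm <- cohort$admissions |>
      filter(.data$person_id %in% ids, .data$day > 0)
    if (!is.null(codes)) {
      adm <- filter(adm, startsWith3(.data$code, codes))
    }
    adm <- adm |>
      arrange(.data$day) |>
      distinct(.data$person_id, .keep_all = TRUE)
    adm$day[match(ids, adm$person_id)]
  }

  event_day <- switch(outcome,
    sae = pmin(first_admission(), death_day, na.rm = TRUE),
    death_all = death_day,
    death_cv = if_else(death_class == "cv", death_day, NA_real_),
    death_noncv = if_else(death_class == "noncv", death_day, NA_real_),
    mace = pmin(
      first_admission(c(mace_codes$mi, mace_codes$ischaemic_stroke)),
      if_else(death_class == "cv", death_day, NA_real_),
      na.rm = TRUE
    )
  )
  event_day[!is.finite(event_day)] <- NA_real_
  event_day[!is.na(event_day) & event_day > window_days] <- NA_real_

  censor_day <- pmin(
    if_else(is.na(per$dereg_day), Inf, per$dereg_day),
    if_else(is.na(death_day), Inf, death_day),
    window_days
  )
  time <- pmin(if_else(is.na(event_day), Inf, event_day), censor_day)
  event <- !is.na(event_day) & event_day <= censor_day
  tibble(
    person_id = ids,
    outcome = outcome,
    event = event,
    time_at_risk = as.double(time),
    event_day = if_else(event, event_day, NA_real_)
  )
}

#' @rdname time_at_risk
#' @export
first_sae_community <- function(cohort, window_days) {
  time_at_risk(cohort, "sae", window_days)
}

#' @rdname time_at_risk
#' @export
first_mace <- function(cohort, window_days, mace_codes = mace_code_lists()) {
  time_at_risk(cohort, "mace", window_days, mace_codes = mace_codes)
}

#' First events and time at risk in a trial dataset
#'
#' The trial-format counterpart of [time_at_risk()]: uses the adjudicated
#' component flags (first serious adverse event, death with cardiovascular
#' adjudication, myocardial infarction, ischaemic stroke) rather than codes.
#' Death censors non-death outcomes; there is no deregistration in a trial.
#'
#' @param trial A `trial_dataset`.
#' @param outcome As [time_at_risk()].
#' @param window_days Observation window (defaults to the trial follow-up).
#' @param arm Restrict to one arm (e.g. `"sglt2i"`); `NULL` keeps all.
#' @return Tibble: `participant_id`, `outcome`, `event`, `time_at_risk`
#'   (days), `event_day`.
#' @export
trial_outcomes <- function(trial, outcome = c(
                             "sae", "mace", "death_all", "death_cv", "death_noncv"
                           ),
                           window_days = NULL, arm = NULL) {
  outcome <- match.arg(outcome)
  adj <- trial$adjudicated
  if (!is.null(arm)) {
    keep <- trial$baseline$participant_id[trial$baseline$arm == arm]
    adj <- filter(adj, .data$participant_id %in% keep)
  }
  if (is.null(window_days)) {
    window_days <- round(trial$baseline$followup_years[1] * DAYS_PER_YEAR)
  }
  death_day <- adj$death_day
  event_day <- switch(outcome,
    sae = adj$sae_day,
    death_all = death_day,
    death_cv = if_else(adj$death_cv, death_day, NA_real_),
    death_noncv = if_else(adj$death & !adj$death_cv, death_day, NA_real_),
    mace = adj$mace_day
  )
  event_day[!is.na(event_day) & event_day > window_days] <- NA_real_
  censor_day <- pmin(if_else(is.na(death_day), Inf, death_day), window_days)
  time <- pmin(if_else(is.na(event_day), Inf, event_day), censor_day)
  event <- !is.na(event_day) & event_day <= censor_day
  tibble(
    participant_id = adj$participant_id,
    outcome = outcome,
    event = event,
    time_at_risk = as.double(time),
    event_day = if_else(event, event_day, NA_real_)
  )
}
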