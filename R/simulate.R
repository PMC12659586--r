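#' Simulation configuration
#'
#' Bundles every ground-truth parameter of the synthetic linked-data
#' generator. Defaults describe a routinely treated type 2 diabetes
#' population starting a new glucose-lowering drug: overdispersed
#' comorbidity counts (gamma-frailty Bernoulli conditions), first-event
#' hazards log-linear in age, sex and comorbidity count, comorbidity-
#' dependent trial selection, censoring by practice deregistration, a
#' cardiovascular/non-cardiovascular death split, and piecewise-linear eGFR
#' trajectories with an acute change over the first 21 days followed by a
#' chronic annual slope.
#'
#' @param n_community Community cohort size (>= 1).
#' @param n_trial Trial size sampled from the eligible community.
#' @param condition_prevalences Named per-condition probability vector over
#'   the 57-condition registry. The chronic kidney disease entry is ignored:
#'   CKD prevalence is induced by the baseline eGFR distribution.
#' @param comorbidity_dispersion Gamma-frailty variance `d`; the
#'   comorbidity-count variance/mean ratio is approximately `1 + d * mean`
#'   (0 gives Poisson-like counts).
#' @param base_event_rate First-event (hospitalisation or death) rate in
#'   events per person-year for a 60-year-old male with zero comorbidities.
#' @param rate_log_hr_per_comorbidity,rate_log_hr_age_per_year,sex_log_hr
#'   Log hazard ratios per condition, per year of age (centred at 60), and
#'   for female sex.
#' @param selection_log_odds_per_comorbidity Trial-inclusion log-odds per
#'   condition among the eligible (<= 0 emulates under-representation of
#'   multimorbidity).
#' @param cv_death_fraction Probability that a death is cardiovascular.
#' @param egfr_baseline_mean_sd Length-2: mean and SD of baseline eGFR
#'   (mL/min/1.73m2).
#' @param acute_change Mean eGFR change (mL/min/1.73m2) over days 0-21.
#' @param chronic_slope Mean chronic eGFR slope (mL/min/1.73m2 per year)
#'   after day 21.
#' @param residual_sd Visit-level eGFR measurement noise SD.
#' @param followup_years Observation window after the index date.
#' @param dereg_rate Practice-deregistration rate per person-year (>= 0).
#' @param seed Integer seed; every generator call derives its own substream.
#' @param age_mean_sd,female_prop Demographics of new users.
#' @param death_given_event Probability that a first-event is a death rather
#'   than a hospitalisation.
#' @param mi_frac,stroke_frac Fraction of hospitalisations coded as
#'   myocardial infarction / ischaemic stroke.
#' @param cv_death_log_or_per_comorbidity Log odds-ratio linking comorbidity
#'   count to a death being cardiovascular (0 = independent, the default).
#' @param hba1c_mean_sd HbA1c (%) distribution at baseline.
#' @param lab_missing_prob Probability a baseline lab is absent.
#' @param chronic_slope_sd Between-person SD of the chronic eGFR slope.
#' @param bariatric_prob Probability of a historic bariatric procedure code.
#' @param registration_years_mean Mean extra registration time (years)
#'   beyond the mandatory one year before the index date.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_community = 20000,
                       n_trial = 2000,
                       condition_prevalences = default_prevalences(),
                       comorbidity_dispersion = 0.4,
                       base_event_rate = 0.12,
                       rate_log_hr_per_comorbidity = 0.25,
                       rate_log_hr_age_per_year = 0.03,
                       sex_log_hr = -0.1,
                       selection_log_odds_per_comorbidity = -0.5,
                       cv_death_fraction = 0.4,
                       egfr_baseline_mean_sd = c(80, 18),
                       acute_change = -3,
                       chronic_slope = -2,
                       residual_sd = 3,
                       followup_years = 3,
                       dereg_rate = 0.02,
                       seed = 42L,
                       age_mean_sd = c(62, 10),
                       female_prop = 0.39,
                       death_given_event = 0.2,
                       mi_frac = 0.10,
                       stroke_frac = 0.08,
                       cv_death_log_or_per_comorbidity = 0,
                       hba1c_mean_sd = c(8, 1.3),
                       lab_missing_prob = 0.05,
                       chronic_slope_sd = 1.5,
                       bariatric_prob = 0.02,
                       registration_years_mean = 4) {
  cfg <- list(
    n_community = n_community, n_trial = n_trial,
    condition_prevalences = condition_prevalences,
    comorbidity_dispersion = comorbidity_dispersion,
    base_event_rate = base_event_rate,
    rate_log_hr_per_comorbidity = rate_log_hr_per_comorbidity,
    rate_log_hr_age_per_year = rate_log_hr_age_per_year,
    sex_log_hr = sex_log_hr,
    selection_log_odds_per_comorbidity = selection_log_odds_per_comorbidity,
    cv_death_fraction = cv_death_fraction,
    egfr_baseline_mean_sd = egfr_baseline_mean_sd,
    acute_change = acute_change, chronic_slope = chronic_slope,
    residual_sd = residual_sd, followup_years = followup_years,
    dereg_rate = dereg_rate, seed = seed,
    age_mean_sd = age_mean_sd, female_prop = female_prop,
    death_given_event = death_given_event,
    mi_frac = mi_frac, stroke_frac = stroke_frac,
    cv_death_log_or_per_comorbidity = cv_death_log_or_per_comorbidity,
    hba1c_mean_sd = hba1c_mean_sd, lab_missing_prob = lab_missing_prob,
    chronic_slope_sd = chronic_slope_sd, bariatric_prob = bariatric_prob,
    registration_years_mean = registration_years_mean
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

#' Default per-condition prevalences
#'
#' Chosen so the mean comorbidity count (excluding CKD) is about 2.7, in the
#' range reported for routinely treated type 2 diabetes populations, with
#' hypertension, osteoarthritis, depression and coronary artery disease the
#' commonest conditions. All entries are kept at or below 0.3 so that the
#' gamma-frailty scaling rarely saturates a per-condition probability.
#'
#' @return Named numeric vector over the 57 registry conditions.
#' @export
default_prevalences <- function() {
  reg_conditions <- unique(default_registry()$condition)
  p <- setNames(rep(0.02, length(reg_conditions)), reg_conditions)
  p[["hypertension"]] <- 0.30
  p[["coronary artery disease"]] <- 0.14
  p[["arrhythmia"]] <- 0.09
  p[["stroke"]] <- 0.05
  p[["heart failure"]] <- 0.06
  p[["peripheral artery disease"]] <- 0.04
  p[["heart valve disorders"]] <- 0.03
  p[["venous thromboembolic disease"]] <- 0.04
  p[["aneurysm"]] <- 0.015
  p[["chronic kidney disease"]] <- 0 # induced via the eGFR distribution
  p[["osteoarthritis"]] <- 0.15
  p[["depression"]] <- 0.16
  p[["anxiety"]] <- 0.14
  p[["chronic pain"]] <- 0.12
  p[["asthma"]] <- 0.12
  p[["copd"]] <- 0.08
  p[["thyroid disorder"]] <- 0.09
  p[["cataract"]] <- 0.06
  p[["hearing loss"]] <- 0.06
  p[["gout"]] <- 0.05
  p[["osteoporosis"]] <- 0.04
  p[["solid organ cancer"]] <- 0.05
  p[["sleep apnoea"]] <- 0.04
  p[["peripheral neuropathy"]] <- 0.06
  p
}

#' @rdname sim_config
#' @param config A `sim_config`.
#' @export
validate_sim_config <- function(config) {
  if (!is.numeric(config$n_community) || config$n_community < 1) {
    abort("n_community must be a positive integer",
      class = "trialrep_invalid_config"
    )
  }
  if (config$n_trial > config$n_community) {
    abort("n_trial cannot exceed n_community",
      class = "trialrep_invalid_config"
    )
  }
  assert_prob(config$condition_prevalences, "condition_prevalences")
  assert_prob(config$cv_death_fraction, "cv_death_fraction")
  assert_prob(config$female_prop, "female_prop")
  assert_prob(config$death_given_event, "death_given_event")
  assert_prob(config$lab_missing_prob, "lab_missing_prob")
  assert_nonneg(config$comorbidity_dispersion, "comorbidity_dispersion")
  assert_nonneg(config$dereg_rate, "dereg_rate")
  assert_nonneg(config$residual_sd, "residual_sd")
  assert_nonneg(config$chronic_slope_sd, "chronic_slope_sd")
  if (config$base_event_rate <= 0) {
    abort("base_event_rate must be > 0", class = "trialrep_invalid_config")
  }
  if (config$followup_years <= 0) {
    abort("followup_years must be > 0", class = "trialrep_invalid_config")
  }
  invisible(config)
}

# toy hospital / mortality code pools (ICD-10-like strings; the
# cardiovascular-death rule keys on the leading "I")
.codes <- list(
  cv_death = c("I21.9", "I50.0", "I63.8", "I25.1"),
  noncv_death = c("C34.9", "J44.0", "A41.9", "G30.9"),
  mi = c("I21.0", "I21.4"),
  stroke = c("I63.9", "I63.5"),
  other_hosp = c("J18.1", "K52.9", "N39.0", "E11.5", "S72.0", "R07.4"),
  bariatric = c("pbar01", "pbar02")
)

#' Code lists for MACE components
#'
#' Editable fixture code lists (in the toy hospital vocabulary) for
#' myocardial infarction and ischaemic stroke; matching is by code prefix.
#'
#' @return Named list with elements `mi` and `ischaemic_stroke`.
#' @export
mace_code_lists <- function() {
  list(mi = c("I21", "I22"), ischaemic_stroke = c("I63"))
}

# internal: first-events process. Given per-person hazards (per year) and a
# window, simulates up to `max_events` hospitalisation/death events; a death
# terminates the stream. Returns tibble(idx, day, type, code).
simulate_event_stream <- function(lambda, years, config, count = NULL,
                                  max_events = 3L) {
  n <- length(lambda)
  if (is.null(count)) count <- rep(0, n)
  t_years <- rep(0, n)
  alive <- rep(TRUE, n)
  p_cv <- stats::plogis(
    stats::qlogis(min(max(config$cv_death_fraction, 1e-9), 1 - 1e-9)) +
      config$cv_death_log_or_per_comorbidity * count
  )
  out <- vector("list", max_events)
  for (k in seq_len(max_events)) {
    gap <- rep(Inf, n)
    pos <- lambda > 0
    gap[pos] <- rexp(sum(pos), rate = lambda[pos])
    t_years <- t_years + gap
    active <- alive & is.finite(t_years) & t_years < years
    if (!any(active)) break
    m <- sum(active)
    is_death <- rbinom(m, 1L, config$death_given_event) == 1L
    cv <- rbinom(m, 1L, p_cv[active]) == 1L
    u <- runif(m)
    kind <- ifelse(is_death, "death",
      ifelse(u < config$mi_frac, "mi",
        ifelse(u < config$mi_frac + config$stroke_frac, "stroke", "other")
      )
    )
    code <- character(m)
    code[kind == "death" & cv] <- sample(.codes$cv_death, sum(kind == "death" & cv), TRUE)
    code[kind == "death" & !cv] <- sample(.codes$noncv_death, sum(kind == "death" & !cv), TRUE)
    code[kind == "mi"] <- sample(.codes$mi, sum(kind == "mi"), TRUE)
    code[kind == "stroke"] <- sample(.codes$stroke, sum(kind == "stroke"), TRUE)
    code[kind == "other"] <- sample(.codes$other_hosp, sum(kind == "other"), TRUE)
    out[[k]] <- tibble(
      idx = which(active),
      day = ceiling(t_years[active] * DAYS_PER_YEAR),
      type = if_else(is_death, "death", "admission"),
      code = code
    )
    alive[active][is_death] <- FALSE
  }
  rows <- bind_rows(out)
  if (nrow(rows) == 0L) {
    return(tibble(
      idx = integer(), day = numeric(), type = character(), code = character()
    ))
  }
  # day 0 events would be prevalent, not incident; push to day 1
  rows$day <- pmax(rows$day, 1)
  arrange(rows, .data$idx, .data$day)
}

# internal: invert the CKD-EPI 2009 equation for a target eGFR
creatinine_for_egfr <- function(egfr, age, female) {
  kappa <- if_else(female, 0.7, 0.9)
  alpha <- if_else(female, -0.329, -0.411)
  base <- 141 * 0.993^age * if_else(female, 1.018, 1)
  # eGFR at creatinine == kappa equals `base`; pick the branch accordingly
  if_else(
    egfr <= base,
    kappa * (egfr / base)^(-1 / 1.209),
    kappa * (egfr / base)^(1 / alpha)
  )
}

#' Generate a synthetic community cohort
#'
#' Emulates a routinely treated community population with linked primary
#' care (coded diagnoses, prescriptions implicit in the index date, labs),
#' hospital admission, procedure and mortality records. Per-person
#' comorbidities are Bernoulli draws whose probabilities are scaled by a
#' gamma frailty (mean 1, variance `comorbidity_dispersion`), so condition
#' identities exist while total counts are overdispersed. First events after
#' the index date follow an exponential law whose log-rate is linear in age
#' (centred at 60), female sex and the true comorbidity count (coded
#' conditions plus eGFR-defined CKD). Deaths receive an underlying-cause
#' code starting with "I" with probability `cv_death_fraction`.
#'
#' Every person registers at least one year before the index date (day 0),
#' and all pre-index records fall within the registration window.
#'
#' @param config A [sim_config()].
#' @param registry Condition registry (defaults to [default_registry()]).
#' @return A `community_cohort`: list of tibbles `persons`, `diagnoses`,
#'   `procedures`, `labs`, `admissions`, plus `truth` (ground-truth
#'   per-person counts, hazards and the config) and `vocabulary_id`.
#' @export
generate_community <- function(config = sim_config(), registry = default_registry()) {
  validate_sim_config(config)
  n <- as.integer(config$n_community)
  with_seed(derive_seed(config$seed, "community"), {
    age <- stats::qnorm(
      runif(
        n,
        stats::pnorm(18, config$age_mean_sd[1], config$age_mean_sd[2]),
        stats::pnorm(92, config$age_mean_sd[1], config$age_mean_sd[2])
      ),
      config$age_mean_sd[1], config$age_mean_sd[2]
    )
    female <- rbinom(n, 1L, config$female_prop) == 1L
    d <- config$comorbidity_dispersion
    frailty <- if (d > 0) rgamma(n, shape = 1 / d, rate = 1 / d) else rep(1, n)

    conds <- unique(registry$condition)
    coded_conds <- setdiff(conds, "chronic kidney disease")
    prev <- config$condition_prevalences[coded_conds]
    if (anyNA(prev)) {
      abort("condition_prevalences must be named by registry condition",
        class = "trialrep_invalid_config"
      )
    }
    probs <- pmin(outer(frailty, unname(prev)), 1)
    cond_mat <- matrix(
      rbinom(length(probs), 1L, as.vector(probs)),
      nrow = n, dimnames = list(NULL, coded_conds)
    )

    egfr_true <- pmin(pmax(
      rnorm(n, config$egfr_baseline_mean_sd[1], config$egfr_baseline_mean_sd[2]),
      10
    ), 150)
    ckd_true <- egfr_true < 60
    count_coded <- as.integer(rowSums(cond_mat))
    count_true <- count_coded + as.integer(ckd_true)

    lambda <- config$base_event_rate * exp(
      config$rate_log_hr_per_comorbidity * count_true +
        config$rate_log_hr_age_per_year * (age - 60) +
        config$sex_log_hr * female
    )

    registration_day <- -round(
      365 + rexp(n, rate = 1 / (config$registration_years_mean * DAYS_PER_YEAR))
    )
    dereg_day <- if (config$dereg_rate > 0) {
      ceiling(rexp(n, rate = config$dereg_rate / DAYS_PER_YEAR))
    } else {
      rep(Inf, n)
    }

    # coded diagnosis history: one randomly dated code per present condition,
    # from the community dialect (two interchangeable codes per condition)
    hit <- which(cond_mat == 1L, arr.ind = TRUE)
    cond_idx <- match(coded_conds[hit[, "col"]], conds)
    diagnoses <- tibble(
      person_id = hit[, "row"],
      day = floor(runif(
        nrow(hit),
        registration_day[hit[, "row"]], 0
      )),
      code = sprintf("cm%03d%s", cond_idx, sample(c("a", "b"), nrow(hit), TRUE))
    )
    t2d_rows <- tibble(
      person_id = seq_len(n),
      day = floor(runif(n, registration_day, 0)),
      code = sample(c("cmT2Da", "cmT2Db"), n, TRUE)
    )
    diagnoses <- arrange(bind_rows(diagnoses, t2d_rows), .data$person_id, .data$day)

    has_bar <- rbinom(n, 1L, config$bariatric_prob) == 1L
    procedures <- tibble(
      person_id = which(has_bar),
      day = floor(runif(sum(has_bar), pmax(registration_day[has_bar], -1500), 0)),
      code = sample(.codes$bariatric, sum(has_bar), TRUE)
    )

    creat <- creatinine_for_egfr(egfr_true, age, female)
    cre_missing <- rbinom(n, 1L, config$lab_missing_prob) == 1L
    hba1c <- rnorm(n, config$hba1c_mean_sd[1], config$hba1c_mean_sd[2])
    hb_missing <- rbinom(n, 1L, config$lab_missing_prob) == 1L
    labs <- bind_rows(
      tibble(
        person_id = which(!cre_missing),
        day = -sample(10:300, sum(!cre_missing), TRUE),
        analyte = "creatinine",
        value = round(creat[!cre_missing], 3)
      ),
      tibble(
        person_id = which(!hb_missing),
        day = -sample(10:300, sum(!hb_missing), TRUE),
        analyte = "hba1c",
        value = round(hba1c[!hb_missing], 2)
      )
    ) |>
      arrange(.data$person_id, .data$analyte)

    events <- simulate_event_stream(
      lambda, config$followup_years, config,
      count = count_true
    )
    # deregistration ends observability: records on/after it are unseen
    events <- events |>
      filter(.data$day < dereg_day[.data$idx])
    deaths <- events |>
      filter(.data$type == "death") |>
      group_by(.data$idx) |>
      slice(1L) |>
      ungroup()
    admissions <- events |>
      filter(.data$type == "admission") |>
      select(person_id = "idx", "day", "code")

    persons <- tibble(
      person_id = seq_len(n),
      age = round(age, 1),
      sex = if_else(female, "female", "male"),
      female = female,
      registration_day = as.integer(registration_day),
      index_day = 0L,
      dereg_day = if_else(is.finite(dereg_day), dereg_day, NA_real_),
      death_day = NA_real_,
      death_cause = NA_character_
    )
    persons$death_day[deaths$idx] <- deaths$day
    persons$death_cause[deaths$idx] <- deaths$code

    structure(
      list(
        persons = persons,
        diagnoses = diagnoses,
        procedures = procedures,
        labs = labs,
        admissions = admissions,
        truth = list(
          config = config,
          count_true = count_true,
          count_coded = count_coded,
          ckd_true = ckd_true,
          egfr_true = egfr_true,
          lambda = lambda
        ),
        vocabulary_id = "community"
      ),
      class = "community_cohort"
    )
  })
}

#' @export
print.community_cohort <- function(x, ...) {
  cat(
    "<community_cohort> ", nrow(x$persons), " persons, ",
    nrow(x$diagnoses), " coded diagnoses, ",
    nrow(x$admissions), " admissions, ",
    sum(!is.na(x$persons$death_day)), " deaths\n",
    sep = ""
  )
  invisible(x)
}

#' Sample a synthetic trial from a community cohort
#'
#' Applies a trial's eligibility criteria at the index date and then samples
#' participants from the eligible pool with inclusion weights
#' `exp(selection_log_odds_per_comorbidity * comorbidity count)`, emulating
#' selection on multimorbidity beyond the explicit criteria. Selected
#' persons' records are converted to trial format: baseline medical-history
#' terms in the trial coding dialect, baseline labs, and fresh post-
#' randomisation outcome streams (serious adverse events, deaths with
#' cardiovascular adjudication, MACE components) generated from each
#' person's ground-truth hazard over the trial's follow-up.
#'
#' @param cohort A [generate_community()] cohort.
#' @param criteria A [trial_criteria_set()].
#' @param config The [sim_config()] used for the cohort.
#' @param registry Condition registry.
#' @param policy Missing-data policy forwarded to [classify_cohort()].
#' @return A `trial_dataset`: list of tibbles `baseline`, `history`, `labs`,
#'   `events`, `adjudicated`, plus `truth`.
#' @export
sample_trial <- function(cohort, criteria, config = cohort$truth$config,
                         registry = default_registry(), policy = "strict") {
  n_trial <- as.integer(config$n_trial)
  elig <- classify_cohort(cohort, criteria, registry = registry, policy = policy)
  pool <- elig$person_id[elig$eligible]
  if (length(pool) == 0L) {
    abort("no eligible persons under these criteria",
      class = "trialrep_sampling_error"
    )
  }
  if (length(pool) < n_trial) {
    abort(
      paste0(
        "too few eligible persons: need ", n_trial, ", have ", length(pool),
        " (shortfall ", n_trial - length(pool), ")"
      ),
      class = "trialrep_sampling_error"
    )
  }
  count_true <- cohort$truth$count_true
  with_seed(derive_seed(config$seed, "trial"), {
    w <- exp(config$selection_log_odds_per_comorbidity * count_true[pool])
    sel <- sample(pool, n_trial, replace = FALSE, prob = w)

    per <- cohort$persons[match(sel, cohort$persons$person_id), ]
    baseline <- tibble(
      participant_id = sprintf("T%05d", seq_len(n_trial)),
      source_person_id = sel,
      age = per$age,
      sex = per$sex,
      female = per$female,
      arm = sample(rep(c("sglt2i", "control"), length.out = n_trial)),
      followup_years = criteria$followup_years
    )

    # baseline history terms, re-expressed in the trial dialect
    conds <- unique(registry$condition)
    code_map <- registry |>
      filter(.data$vocabulary == "community") |>
      distinct(.data$code, .data$condition)
    trial_code <- setNames(sprintf("tr%03d", seq_along(conds)), conds)
    hist <- cohort$diagnoses |>
      filter(.data$person_id %in% sel, .data$day < 0) |>
      inner_join(code_map, by = "code") |>
      distinct(.data$person_id, .data$condition) |>
      mutate(
        participant_id = baseline$participant_id[match(
          .data$person_id, baseline$source_person_id
        )],
        code = unname(trial_code[.data$condition])
      ) |>
      select("participant_id", term = "condition", "code")
    hist <- bind_rows(
      hist,
      tibble(
        participant_id = baseline$participant_id,
        term = "type 2 diabetes", code = "trT2D"
      )
    ) |>
      arrange(.data$participant_id)

    # baseline labs measured at randomisation (day 0)
    comm_labs <- cohort$labs |>
      filter(.data$person_id %in% sel, .data$day < 0, .data$day >= -730) |>
      arrange(dplyr::desc(.data$day)) |>
      distinct(.data$person_id, .data$analyte, .keep_all = TRUE)
    labs <- comm_labs |>
      mutate(
        participant_id = baseline$participant_id[match(
          .data$person_id, baseline$source_person_id
        )],
        day = 0L
      ) |>
      select("participant_id", "day", "analyte", "value")

    # fresh outcome streams over the trial window (no deregistration)
    lam <- cohort$truth$lambda[sel]
    ev <- simulate_event_stream(
      lam, criteria$followup_years, config,
      count = count_true[sel]
    )
    ev$participant_id <- baseline$participant_id[ev$idx]
    events <- select(ev, "participant_id", "day", "type", "code")

    window_days <- round(criteria$followup_years * DAYS_PER_YEAR)
    adjudicated <- adjudicate_trial_events(
      baseline$participant_id, events, window_days
    )

    structure(
      list(
        baseline = baseline,
        history = hist,
        labs = labs,
        events = events,
        adjudicated = adjudicated,
        truth = list(
          config = config,
          trial_id = criteria$trial_id,
          selected_person_id = sel,
          count_true = count_true[sel],
          lambda = lam
        ),
        vocabulary_id = "trial"
      ),
      class = "trial_dataset"
    )
  })
}

# internal: derive per-participant adjudicated outcome flags from the raw
# trial event stream (mirrors how trial datasets report first events)
adjudicate_trial_events <- function(ids, events, window_days) {
  mace_codes <- mace_code_lists()
  first_of <- function(df) {
    df |>
      arrange(.data$day) |>
      distinct(.data$participant_id, .keep_all = TRUE) |>
      select("participant_id", "day")
  }
  in_window <- events |> filter(.data$day <= window_days, .data$day > 0)
  sae <- first_of(in_window)
  deaths <- in_window |>
    filter(.data$type == "death") |>
    group_by(.data$participant_id) |>
    slice(1L) |>
    ungroup()
  mi <- first_of(in_window |> filter(
    .data$type == "admission",
    startsWith3(.data$code, mace_codes$mi)
  ))
  stroke <- first_of(in_window |> filter(
    .data$type == "admission",
    startsWith3(.data$code, mace_codes$ischaemic_stroke)
  ))
  cv_death <- deaths |>
    filter(classify_death(.data$code) == "cv") |>
    select("participant_id", "day")

  out <- tibble(participant_id = ids) |>
    left_join(rename(sae, sae_day = "day"), by = "participant_id") |>
    left_join(
      deaths |> select("participant_id", death_day = "day", death_cause = "code"),
      by = "participant_id"
    ) |>
    left_join(rename(mi, mi_day = "day"), by = "participant_id") |>
    left_join(rename(stroke, stroke_day = "day"), by = "participant_id") |>
    left_join(rename(cv_death, cv_death_day = "day"), by = "participant_id")
  out |>
    mutate(
      sae = !is.na(.data$sae_day),
      death = !is.na(.data$death_day),
      death_cv = !is.na(.data$cv_death_day),
      mi = !is.na(.data$mi_day),
      stroke = !is.na(.data$stroke_day),
      mace_day = pmin(.data$mi_day, .data$stroke_day, .data$cv_death_day, na.rm = TRUE),
      mace = is.finite(.data$mace_day),
      mace_day = if_else(is.finite(.data$mace_day), .data$mace_day, NA_real_),
      followup_days = pmin(dplyr::coalesce(.data$death_day, Inf), window_days)
    )
}

# internal: prefix matching against a code list
startsWith3 <- function(code, prefixes) {
  Reduce(`|`, lapply(prefixes, function(p) startsWith(code, p)))
}

#' @export
print.trial_dataset <- function(x, ...) {
  cat(
    "<trial_dataset> '", x$truth$trial_id %||% "?", "': ",
    nrow(x$baseline), " participants, ",
    sum(x$adjudicated$sae), " first serious adverse events\n",
    sep = ""
  )
  invisible(x)
}

#' Generate longitudinal eGFR series
#'
#' Trajectories are piecewise linear with a knot at `knot_days` (21 days by
#' default): an acute change spread linearly over days 0-21 followed by a
#' chronic annual slope, plus independent visit-level noise:
#' \deqn{eGFR(t) = b + a\,\min(t,21)/21 + s\,\max(t-21,0)/365.25 + \epsilon}
#' The chronic slope varies between persons (SD `chronic_slope_sd`).
#'
#' @param params Tibble with `person_id` and `egfr_baseline` (optionally a
#'   per-person `chronic_slope` to override the population draw).
#' @param schedule Visit days; must contain day 0 and at least two
#'   post-baseline visits.
#' @param config A [sim_config()].
#' @param knot_days Acute/chronic knot (days).
#' @param enforce_min_followup Refuse schedules spanning under two years
#'   (slope estimation over shorter spans is not supported downstream).
#' @return Long tibble `person_id`, `day`, `egfr`.
#' @export
generate_egfr_series <- function(params, schedule, config = sim_config(),
                                 knot_days = 21,
                                 enforce_min_followup = TRUE) {
  schedule <- sort(unique(as.double(schedule)))
  if (!0 %in% schedule || sum(schedule > 0) < 2L) {
    abort("schedule must include day 0 and at least two post-baseline visits",
      class = "trialrep_invalid_config"
    )
  }
  if (enforce_min_followup && max(schedule) < 2 * DAYS_PER_YEAR) {
    abort("schedule must span at least 2 years (set enforce_min_followup = FALSE to override)",
      class = "trialrep_invalid_config"
    )
  }
  n <- nrow(params)
  with_seed(derive_seed(config$seed, "egfr"), {
    slope <- if ("chronic_slope" %in% names(params)) {
      params$chronic_slope
    } else {
      rnorm(n, config$chronic_slope, config$chronic_slope_sd)
    }
    grid <- tidyr::expand_grid(
      i = seq_len(n), day = schedule
    )
    mu <- params$egfr_baseline[grid$i] +
      config$acute_change * pmin(grid$day, knot_days) / knot_days +
      slope[grid$i] * pmax(grid$day - knot_days, 0) / DAYS_PER_YEAR
    tibble(
      person_id = params$person_id[grid$i],
      day = grid$day,
      egfr = mu + rnorm(nrow(grid), 0, config$residual_sd)
    )
  })
}

#' Write a cohort or trial dataset as delimited text plus ground truth
#'
#' One CSV per record stream, plus `ground_truth.json` holding the
#' generating parameters (per-run provenance for recovery tests).
#'
#' @param x A `community_cohort` or `trial_dataset`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(x, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tabs <- Filter(is.data.frame, x)
  for (nm in names(tabs)) {
    write.csv(tabs[[nm]], file.path(dir, paste0(nm, ".csv")), row.names = FALSE)
  }
  truth <- x$truth
  truth$config <- unclass(truth$config)
  jsonlite::write_json(
    truth, file.path(dir, "ground_truth.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(dir)
}
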