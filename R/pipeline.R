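#' Build community rate-model rows for one outcome
#'
#' Joins demographics, phenotyped comorbidity counts and outcome
#' ascertainment into the row format [fit_rate_model()] consumes: one row
#' per person with `age`, `female`, `count`, `events` and `py`.
#'
#' @param cohort A `community_cohort`.
#' @param counts Phenotyped counts from [comorbidity_counts()] (computed if
#'   omitted).
#' @param outcome,window_days Passed to [time_at_risk()].
#' @param registry Condition registry.
#' @param person_ids Optional restriction (e.g. the trial-eligible).
#' @return Tibble ready for [fit_rate_model()].
#' @export
community_rate_rows <- function(cohort, outcome = "sae", window_days,
                                counts = NULL, registry = default_registry(),
                                person_ids = NULL) {
  if (is.null(counts)) {
    counts <- comorbidity_counts(
      cohort$diagnoses, registry,
      ids = cohort$persons$person_id,
      egfr = egfr_at_index(cohort$labs, cohort$persons)
    )
  }
  tar <- time_at_risk(cohort, outcome, window_days)
  rows <- cohort$persons |>
    select("person_id", "age", "female") |>
    inner_join(select(counts, "person_id", count = "total"), by = "person_id") |>
    inner_join(
      select(tar, "person_id", "event", "time_at_risk"),
      by = "person_id"
    ) |>
    mutate(events = as.integer(.data$event), py = .data$time_at_risk / DAYS_PER_YEAR) |>
    select("person_id", "age", "female", "count", "events", "py")
  if (!is.null(person_ids)) {
    rows <- filter(rows, .data$person_id %in% person_ids)
  }
  rows
}

#' Comorbidity counts for trial participants
#'
#' Phenotypes trial baseline medical-history terms (in the trial coding
#' dialect) with the same registry used for the community, and adds CKD from
#' the baseline creatinine (most recent value on or before randomisation)
#' via [egfr_ckd_epi()] and [flag_ckd()].
#'
#' @param trial A `trial_dataset`.
#' @param registry Condition registry.
#' @return Tibble `person_id` (participant id), `total`, `cardiometabolic`,
#'   `non_cardiometabolic`, `ckd`.
#' @export
trial_comorbidity_counts <- function(trial, registry = default_registry()) {
  hist <- trial$history |>
    transmute(
      person_id = .data$participant_id,
      day = -1L, # baseline terms are, by construction, pre-randomisation
      code = .data$code
    )
  cre <- trial$labs |>
    filter(.data$analyte == "creatinine", .data$day <= 0) |>
    arrange(dplyr::desc(.data$day)) |>
    distinct(.data$participant_id, .keep_all = TRUE) |>
    select(person_id = "participant_id", creatinine = "value")
  demo <- trial$baseline |>
    select(person_id = "participant_id", "age", "sex")
  eg <- demo |>
    left_join(cre, by = "person_id") |>
    mutate(egfr = if_else(
      is.na(.data$creatinine), NA_real_,
      egfr_ckd_epi(pmax(.data$creatinine, 1e-6), .data$age, .data$sex)
    )) |>
    select("person_id", "egfr")
  comorbidity_counts(
    hist, registry,
    ids = trial$baseline$participant_id, egfr = eg
  )
}

#' Build trial-side rows for expected counts and observed events
#'
#' One row per participant with covariates, per-participant person-time at
#' risk for the outcome (the faithful transport choice; nominal trial
#' duration is the fallback when events are unavailable) and the first-event
#' indicator.
#'
#' @param trial A `trial_dataset`.
#' @param outcome Outcome name, as [trial_outcomes()].
#' @param registry Condition registry.
#' @param arm Restrict to one arm (`NULL` = all participants).
#' @return Tibble `participant_id`, `age`, `female`, `count`, `events`, `py`.
#' @export
trial_rate_rows <- function(trial, outcome = "sae",
                            registry = default_registry(), arm = NULL) {
  cnt <- trial_comorbidity_counts(trial, registry)
  out <- trial_outcomes(trial, outcome, arm = arm)
  trial$baseline |>
    select("participant_id", "age", "female") |>
    inner_join(
      select(cnt, participant_id = "person_id", count = "total"),
      by = "participant_id"
    ) |>
    inner_join(
      select(out, "participant_id", "event", "time_at_risk"),
      by = "participant_id"
    ) |>
    mutate(
      events = as.integer(.data$event),
      py = .data$time_at_risk / DAYS_PER_YEAR
    ) |>
    select("participant_id", "age", "female", "count", "events", "py")
}

#' Observed/expected ratio for a trial against a community model
#'
#' Convenience wrapper: builds the trial rows, counts observed first events,
#' and calls [oe_ratio()].
#'
#' @param trial A `trial_dataset`.
#' @param model A community-fitted `rate_model`.
#' @param outcome Outcome name.
#' @param registry Condition registry.
#' @param arm Arm restriction (`NULL` = all).
#' @param trial_rows Prebuilt rows (rebuilt if omitted).
#' @inheritParams oe_ratio
#' @return An `oe_result`.
#' @export
trial_oe <- function(trial, model, outcome = "sae",
                     registry = default_registry(), arm = NULL,
                     trial_rows = NULL, n_samples = 10000, seed = 1L) {
  if (is.null(trial_rows)) {
    trial_rows <- trial_rate_rows(trial, outcome, registry, arm)
  }
  oe_ratio(
    observed = sum(trial_rows$events),
    n_participants = nrow(trial_rows),
    model = model, trial_rows = trial_rows,
    n_samples = n_samples, seed = seed
  )
}

#' Ratios of mean comorbidity counts between populations
#'
#' Ratio 1 compares trial participants with the trial-eligible community
#' (trial mean / eligible mean); ratio 2 compares the eligible with the
#' ineligible community (eligible mean / ineligible mean); each for total,
#' cardiometabolic and non-cardiometabolic counts.
#'
#' @param trial_counts,eligible_counts,ineligible_counts Count tibbles as
#'   returned by [comorbidity_counts()].
#' @return Tibble `measure`, `trial_mean`, `eligible_mean`,
#'   `ineligible_mean`, `ratio_trial_vs_eligible`,
#'   `ratio_eligible_vs_ineligible`.
#' @export
comorbidity_ratio_table <- function(trial_counts, eligible_counts,
                                    ineligible_counts) {
  one <- function(df, m) mean(df[[m]])
  measures <- c("total", "cardiometabolic", "non_cardiometabolic")
  purrr::map_dfr(measures, function(m) {
    tm <- one(trial_counts, m)
    em <- one(eligible_counts, m)
    im <- one(ineligible_counts, m)
    tibble(
      measure = m,
      trial_mean = tm, eligible_mean = em, ineligible_mean = im,
      ratio_trial_vs_eligible = tm / em,
      ratio_eligible_vs_ineligible = em / im
    )
  })
}

#' Predicted rate across comorbidity counts at fixed age and sex midpoint
#'
#' Evaluates a rate model over a grid of comorbidity counts at a fixed age
#' (typically the trial mean) and at the midpoint between the estimates for
#' men and women (`female = 0.5`), with a 95% band from multivariate-normal
#' coefficient sampling.
#'
#' @param model A `rate_model` (fitted with comorbidity count).
#' @param count_grid Integer grid of comorbidity counts.
#' @param age Age at which to evaluate.
#' @param female Sex indicator value (0.5 = midpoint between sexes).
#' @param n_samples Coefficient samples for the band.
#' @param seed Seed.
#' @return Tibble `count`, `rate`, `lo`, `hi` (events per person-year).
#' @export
rate_curves <- function(model, count_grid = 0:10, age = 65, female = 0.5,
                        n_samples = 1000, seed = 1L) {
  if (!isTRUE(model$struct$use_count)) {
    abort("rate_curves needs a model fitted with comorbidity count",
      class = "trialrep_config_error"
    )
  }
  rows <- tibble(
    age = age, female = female, count = count_grid, py = 1
  )
  X <- rate_design(rows, model$struct)[, names(model$beta), drop = FALSE]
  rate <- exp(as.vector(X %*% model$beta))
  degenerate <- all(abs(model$sigma) < .Machine$double.eps)
  if (degenerate) {
    lo <- hi <- rate
  } else {
    betas <- with_seed(derive_seed(seed, "oe"), {
      MASS::mvrnorm(n_samples, model$beta, model$sigma)
    })
    draws <- exp(X %*% t(betas))
    qs <- apply(draws, 1L, quantile, probs = c(0.025, 0.975))
    lo <- qs[1L, ]
    hi <- qs[2L, ]
  }
  tibble(count = count_grid, rate = rate, lo = lo, hi = hi)
}

#' Descriptive summary of one population
#'
#' Counts/percentages and means/SDs for age, sex and comorbidity counts —
#' the per-population descriptive block of the standard reporting tables.
#'
#' @param demo Tibble with `age` and `female`.
#' @param counts Count tibble ([comorbidity_counts()]-shaped).
#' @param population Label.
#' @return One-row tibble of summaries.
#' @export
population_summary <- function(demo, counts, population = "population") {
  tibble(
    population = population,
    n = nrow(demo),
    age_mean = mean(demo$age), age_sd = sd(demo$age),
    pct_female = 100 * mean(demo$female),
    comorbidity_mean = mean(counts$total),
    comorbidity_sd = sd(counts$total),
    cardiometabolic_mean = mean(counts$cardiometabolic),
    non_cardiometabolic_mean = mean(counts$non_cardiometabolic)
  )
}

#' Run the full representativeness pipeline
#'
#' Orchestrates: synthetic community generation, phenotyping, per-trial
#' eligibility classification, trial sampling, descriptive summaries,
#' count-distribution selection per population, observed/expected serious-
#' adverse-event ratios under model 1 (age + sex) and model 2 (+ comorbidity
#' count), and eGFR slope fits where the trial follow-up reaches two years.
#' All outputs are written to `out_dir` as delimited text and JSON together
#' with a run log recording seeds and every structure-selection decision;
#' re-running with the same configuration and seed reproduces every file.
#'
#' @param config A list (or path to a YAML file) with optional entries:
#'   `sim` (arguments to [sim_config()]), `criteria_dir` (directory of
#'   criteria JSON files; default the bundled demo criteria), `policy`
#'   (eligibility missing-data policy), `select_structure` (data-driven
#'   structure search instead of linear model bases), `n_mc` (Monte-Carlo
#'   samples for O/E), `n_boot` (bootstrap replicates for count-distribution
#'   fit), `outcome` (default `"sae"`), `trial_ids` (restrict to a subset of
#'   the criteria sets), `slope_max_persons` (seeded subsample cap for the
#'   community slope stage, default 2000), `out_dir`.
#' @return Invisibly, a named list with all in-memory results (one entry per
#'   trial plus the cohort-level objects).
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  out_dir <- config$out_dir %||% tempfile("trialrep_run_")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "run_log.txt")
  log_lines <- character()
  say <- function(...) {
    line <- paste0(format(Sys.time(), "%H:%M:%S"), " ", paste0(...))
    log_lines <<- c(log_lines, line)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      writeLines(c(log_lines, paste0("FAILED at stage '", name, "'")), log_path)
      abort(paste0("pipeline stage '", name, "' failed: ", conditionMessage(e)),
        class = "trialrep_pipeline_error"
      )
    })
  }

  scfg <- do.call(sim_config, config$sim %||% list())
  registry <- default_registry()
  policy <- config$policy %||% "strict"
  n_mc <- config$n_mc %||% 10000
  n_boot <- config$n_boot %||% 199
  outcome <- config$outcome %||% "sae"
  # slope SEs are already tiny at a few thousand persons; a seeded subsample
  # keeps the mixed-model stage proportionate on large communities
  slope_max <- config$slope_max_persons %||% 2000
  say("seed ", scfg$seed, "; community n = ", scfg$n_community)

  cohort <- stage("simulate", generate_community(scfg, registry))
  counts <- stage("phenotype", suppressMessages(comorbidity_counts(
    cohort$diagnoses, registry,
    ids = cohort$persons$person_id,
    egfr = egfr_at_index(cohort$labs, cohort$persons)
  )))

  criteria_sets <- stage("criteria", {
    if (!is.null(config$criteria_dir)) {
      files <- list.files(config$criteria_dir,
        pattern = "\\.(json|ya?ml)$",
        full.names = TRUE
      )
      sets <- purrr::map(files, read_criteria)
      setNames(sets, vapply(sets, function(s) s$trial_id, character(1)))
    } else {
      bundled_criteria()
    }
  })
  if (!is.null(config$trial_ids)) {
    criteria_sets <- criteria_sets[
      intersect(names(criteria_sets), config$trial_ids)
    ]
  }

  results <- list(cohort = cohort, counts = counts, trials = list())
  prop_rows <- list()
  oe_rows <- list()
  summary_rows <- list()

  for (cs in criteria_sets) {
    tid <- cs$trial_id
    say("trial ", tid, ": classifying eligibility (policy ", policy, ")")
    elig <- stage(paste0("eligibility:", tid), suppressMessages(
      classify_cohort(cohort, cs, registry, policy = policy)
    ))
    prop_rows[[tid]] <- tibble(
      trial_id = tid, eligible_proportion = eligible_proportion(elig),
      n_eligible = sum(elig$eligible), n = nrow(elig)
    )
    trial <- stage(paste0("sample:", tid), suppressMessages(
      sample_trial(cohort, cs, scfg, registry, policy = policy)
    ))
    t_counts <- suppressMessages(trial_comorbidity_counts(trial, registry))
    el_ids <- elig$person_id[elig$eligible]
    in_ids <- elig$person_id[!elig$eligible]
    el_counts <- filter(counts, .data$person_id %in% el_ids)
    in_counts <- filter(counts, .data$person_id %in% in_ids)
    demo <- select(cohort$persons, "person_id", "age", "female")
    summary_rows[[tid]] <- bind_rows(
      population_summary(
        filter(demo, .data$person_id %in% in_ids), in_counts,
        paste0(tid, ":ineligible")
      ),
      population_summary(
        filter(demo, .data$person_id %in% el_ids), el_counts,
        paste0(tid, ":eligible")
      ),
      population_summary(
        select(trial$baseline, person_id = "participant_id", "age", "female"),
        t_counts, paste0(tid, ":trial")
      )
    )

    dist_fits <- stage(paste0("countdist:", tid), {
      pops <- list(
        ineligible = in_counts$total, eligible = el_counts$total,
        trial = t_counts$total
      )
      purrr::imap(pops, function(x, nm) {
        if (length(x) < 2L) {
          return(NULL)
        }
        fit <- suppressWarnings(select_best(x, n_boot = n_boot, seed = scfg$seed))
        say(
          "trial ", tid, ": ", nm, " counts -> ", fit$family,
          " (gof p ", signif(fit$gof_p, 3), ")"
        )
        export_count_dist(
          fit, paste0(tid, ":", nm),
          file.path(out_dir, paste0("countdist_", tid, "_", nm, ".json"))
        )
        fit
      })
    })

    window_days <- round(cs$followup_years * DAYS_PER_YEAR)
    models <- stage(paste0("fit-rates:", tid), {
      rows <- suppressMessages(community_rate_rows(
        cohort, outcome, window_days,
        counts = counts, registry = registry, person_ids = el_ids
      ))
      build <- function(use_count) {
        if (isTRUE(config$select_structure)) {
          st <- select_structure(rows, use_count = use_count)
          dec <- attr(st, "decisions")
          for (i in seq_len(nrow(dec))) {
            say(
              "trial ", tid, " structure[", if (use_count) "m2" else "m1", "] ",
              dec$step[i], ": ", dec$comparison[i], " -> ", dec$chosen[i] %||% ""
            )
          }
        } else {
          st <- rate_structure("poisson", use_count = use_count)
        }
        fit_rate_model(rows, st)
      }
      m1 <- build(FALSE)
      m2 <- build(TRUE)
      write_rate_model(m1, file.path(out_dir, paste0("model1_", tid, ".json")), outcome)
      write_rate_model(m2, file.path(out_dir, paste0("model2_", tid, ".json")), outcome)
      list(model1 = m1, model2 = m2, rows = rows)
    })

    oes <- stage(paste0("oe:", tid), {
      t_rows <- suppressMessages(trial_rate_rows(trial, outcome, registry))
      oe1 <- suppressMessages(trial_oe(trial, models$model1,
        outcome = outcome,
        trial_rows = t_rows, n_samples = n_mc, seed = derive_seed(scfg$seed, "oe")
      ))
      oe2 <- suppressMessages(trial_oe(trial, models$model2,
        outcome = outcome,
        trial_rows = t_rows, n_samples = n_mc, seed = derive_seed(scfg$seed, "oe")
      ))
      list(model1 = oe1, model2 = oe2)
    })
    oe_rows[[tid]] <- bind_rows(
      mutate(tidy(oes$model1), trial_id = tid, model_id = "model1"),
      mutate(tidy(oes$model2), trial_id = tid, model_id = "model2")
    )

    slope_fits <- if (cs$followup_years >= 2) {
      stage(paste0("slope:", tid), {
        w_days <- ceiling(cs$followup_years * DAYS_PER_YEAR)
        sched <- unique(c(0, round(seq(91, w_days, by = 91)), w_days))
        slope_ids <- if (length(el_ids) > slope_max) {
          with_seed(derive_seed(scfg$seed, "slope"), sample(el_ids, slope_max))
        } else {
          el_ids
        }
        el_base <- tibble(
          person_id = slope_ids,
          egfr_baseline = cohort$truth$egfr_true[slope_ids]
        )
        comm_series <- suppressMessages(generate_egfr_series(el_base, sched, scfg))
        sf_comm <- suppressMessages(fit_total_slope(comm_series))
        tr_base <- tibble(
          person_id = trial$baseline$participant_id,
          egfr_baseline = cohort$truth$egfr_true[trial$truth$selected_person_id]
        )
        tr_series <- suppressMessages(generate_egfr_series(tr_base, sched, scfg))
        sf_tr <- suppressMessages(fit_total_slope(tr_series))
        write_slope_fit(
          sf_comm, paste0(tid, ":eligible"),
          file.path(out_dir, paste0("slope_", tid, "_eligible.json"))
        )
        write_slope_fit(
          sf_tr, paste0(tid, ":trial"),
          file.path(out_dir, paste0("slope_", tid, "_trial.json"))
        )
        say(
          "trial ", tid, ": total slope eligible ",
          signif(sf_comm$total_slope_annualized, 4), ", trial ",
          signif(sf_tr$total_slope_annualized, 4)
        )
        list(eligible = sf_comm, trial = sf_tr)
      })
    } else {
      say("trial ", tid, ": follow-up under 2 years, slope not fitted")
      NULL
    }

    results$trials[[tid]] <- list(
      eligibility = elig, trial = trial, counts = t_counts,
      dist_fits = dist_fits, models = models[c("model1", "model2")],
      oe = oes, slopes = slope_fits,
      ratio_table = comorbidity_ratio_table(t_counts, el_counts, in_counts)
    )
    write.csv(
      results$trials[[tid]]$ratio_table,
      file.path(out_dir, paste0("comorbidity_ratios_", tid, ".csv")),
      row.names = FALSE
    )
  }

  prop_tbl <- bind_rows(prop_rows)
  prop_tbl_summary <- tibble(
    median_eligible = median(prop_tbl$eligible_proportion),
    iqr_lo = unname(quantile(prop_tbl$eligible_proportion, 0.25)),
    iqr_hi = unname(quantile(prop_tbl$eligible_proportion, 0.75))
  )
  write.csv(prop_tbl, file.path(out_dir, "eligible_proportions.csv"), row.names = FALSE)
  write.csv(bind_rows(summary_rows), file.path(out_dir, "population_summaries.csv"),
    row.names = FALSE
  )
  forest <- bind_rows(oe_rows) |>
    select("trial_id", "model_id", "ratio", lo = "conf.low", hi = "conf.high")
  write.csv(forest, file.path(out_dir, "oe_forest.csv"), row.names = FALSE)
  say("run complete")
  writeLines(log_lines, log_path)

  results$eligible_proportions <- prop_tbl
  results$eligible_proportions_summary <- prop_tbl_summary
  results$summaries <- bind_rows(summary_rows)
  results$forest <- forest
  results$out_dir <- out_dir
  invisible(results)
}
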