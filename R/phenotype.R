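#' Count long-term conditions at the index date
#'
#' A condition counts as present when any of its mapped codes appears in the
#' coded history strictly before the index date, regardless of vocabulary
#' and regardless of how many times it was recorded. Chronic kidney disease
#' is the exception: it contributes through the eGFR rule ([flag_ckd()])
#' only, never through codes. Type 2 diabetes (the index condition) is
#' recognised and never counted. Codes that map to nothing are ignored with
#' a logged warning.
#'
#' @param history Tibble of coded events with columns `person_id`, `day`
#'   (integer day on the study timeline) and `code`.
#' @param registry A [default_registry()]-style `condition_registry`.
#' @param ids Optional vector of person ids that must appear in the output
#'   (persons with empty histories get zero counts). Defaults to the ids
#'   present in `history` and `egfr`.
#' @param index_day Index date (day); events dated on/after it never count.
#' @param egfr Optional tibble `person_id`, `egfr` giving eGFR at index;
#'   eGFR < 60 adds chronic kidney disease. A missing eGFR leaves CKD
#'   "unknown": it is counted as absent and noted in the log.
#' @return Tibble with one row per person: `person_id`, `total`,
#'   `cardiometabolic`, `non_cardiometabolic`, `ckd` (logical, `NA` if
#'   unknown). `total = cardiometabolic + non_cardiometabolic` always.
#' @examples
#' reg <- default_registry()
#' hist <- tibble::tibble(person_id = 1, day = -100, code = "cm009a") # hypertension
#' comorbidity_counts(hist, reg)
#' @export
comorbidity_counts <- function(history, registry, ids = NULL, index_day = 0,
                               egfr = NULL) {
  validate_registry(registry, allow_custom = TRUE)
  if (is.null(ids)) {
    ids <- unique(c(history$person_id, if (!is.null(egfr)) egfr$person_id))
  }
  if (length(ids) == 0L) {
    abort("no persons to phenotype", class = "trialrep_phenotype_error")
  }

  code_map <- registry |>
    distinct(.data$code, .data$condition, .data$class)

  prior <- history |>
    filter(.data$day < index_day)

  unknown <- setdiff(unique(prior$code), c(code_map$code, t2d_codes()))
  if (length(unknown) > 0L) {
    warn(
      paste0(
        length(unknown), " unmapped code(s) ignored during phenotyping (e.g. ",
        paste(head(unknown, 3L), collapse = ", "), ")"
      ),
      class = "trialrep_unknown_codes"
    )
  }

  coded <- prior |>
    inner_join(code_map, by = "code") |>
    filter(.data$condition != "chronic kidney disease") |>
    distinct(.data$person_id, .data$condition, .data$class)

  counts <- coded |>
    group_by(.data$person_id) |>
    summarise(
      cardiometabolic = sum(.data$class == "cardiometabolic"),
      non_cardiometabolic = sum(.data$class == "non-cardiometabolic"),
      .groups = "drop"
    )

  out <- tibble(person_id = ids) |>
    left_join(counts, by = "person_id") |>
    mutate(
      cardiometabolic = dplyr::coalesce(.data$cardiometabolic, 0L),
      non_cardiometabolic = dplyr::coalesce(.data$non_cardiometabolic, 0L)
    )

  if (!is.null(egfr)) {
    out <- out |>
      left_join(select(egfr, "person_id", "egfr"), by = "person_id") |>
      mutate(ckd = flag_ckd(.data$egfr)) |>
      select(-"egfr")
    n_unknown <- sum(is.na(out$ckd))
    if (n_unknown > 0L) {
      log_note(
        n_unknown, " person(s) with unknown CKD status (no usable eGFR); ",
        "counted as CKD-absent"
      )
    }
    out <- out |>
      mutate(
        cardiometabolic = .data$cardiometabolic +
          as.integer(!is.na(.data$ckd) & .data$ckd)
      )
  } else {
    out$ckd <- NA
  }

  out |>
    mutate(
      total = .data$cardiometabolic + .data$non_cardiometabolic,
      across(c("total", "cardiometabolic", "non_cardiometabolic"), as.integer)
    ) |>
    select("person_id", "total", "cardiometabolic", "non_cardiometabolic", "ckd")
}

#' eGFR at the index date from the laboratory record
#'
#' Takes each person's single most recent creatinine strictly before the
#' index date within a 2-year lookback (the same convention as laboratory
#' eligibility criteria) and converts it with [egfr_ckd_epi()]. Persons with
#' no usable creatinine get `NA` ("unknown").
#'
#' @param labs Tibble `person_id`, `day`, `analyte`, `value`; creatinine in
#'   mg/dL under `analyte == "creatinine"`.
#' @param demographics Tibble `person_id`, `age`, `sex`.
#' @param index_day Index date (day).
#' @param lookback_days Lookback window (default 730 days).
#' @return Tibble `person_id`, `egfr`.
#' @export
egfr_at_index <- function(labs, demographics, index_day = 0, lookback_days = 730) {
  cre <- labs |>
    filter(
      .data$analyte == "creatinine",
      .data$day < index_day,
      .data$day >= index_day - lookback_days,
      !is.na(.data$value)
    ) |>
    arrange(dplyr::desc(.data$day)) |>
    distinct(.data$person_id, .keep_all = TRUE) |>
    select("person_id", creatinine = "value")

  demographics |>
    select("person_id", "age", "sex") |>
    left_join(cre, by = "person_id") |>
    mutate(
      egfr = if_else(
        is.na(.data$creatinine),
        NA_real_,
        egfr_ckd_epi(pmax(.data$creatinine, 1e-6), .data$age, .data$sex)
      )
    ) |>
    select("person_id", "egfr")
}
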