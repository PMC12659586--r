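#' The long-term condition registry
#'
#' The analyses in this package count long-term conditions from coded health
#' records. The registry names the 57 conditions that are counted, assigns
#' each to the cardiometabolic or non-cardiometabolic class, and carries the
#' diagnostic code lists for each supported vocabulary. Two toy vocabularies
#' ship with the package: `"community"` (emulating primary-care/hospital
#' coding) and `"trial"` (emulating baseline medical-history terms), with
#' deliberately different code strings for the same condition so that the
#' dual mapping between coding systems is exercised.
#'
#' Chronic kidney disease is a registry entry (it belongs to the
#' cardiometabolic class) but is never identified from codes: it is defined
#' from estimated GFR below 60 mL/min/1.73m2 at the index date (see
#' [flag_ckd()]). Type 2 diabetes is the index condition and is deliberately
#' not a registry entry; its codes are recognised and silently ignored when
#' counting.
#'
#' @return A tibble of class `condition_registry` with columns `condition`,
#'   `class` (`"cardiometabolic"` or `"non-cardiometabolic"`), `vocabulary`
#'   and `code`, one row per (condition, vocabulary, code).
#' @examples
#' reg <- default_registry()
#' dplyr::count(reg, class)
#' @export
default_registry <- function() {
  cardiometabolic <- c(
    "stroke", "coronary artery disease", "heart failure",
    "peripheral artery disease", "heart valve disorders", "arrhythmia",
    "venous thromboembolic disease", "aneurysm", "hypertension",
    "chronic kidney disease"
  )
  non_cardiometabolic <- c(
    "asthma", "copd", "bronchiectasis", "chronic liver disease",
    "inflammatory bowel disease", "irritable bowel syndrome",
    "peptic ulcer disease", "diverticular disease", "chronic pancreatitis",
    "coeliac disease", "depression", "anxiety", "bipolar disorder",
    "schizophrenia", "substance use disorder", "alcohol problems",
    "dementia", "parkinsons disease", "multiple sclerosis", "epilepsy",
    "migraine", "peripheral neuropathy", "chronic pain", "osteoarthritis",
    "rheumatoid arthritis", "gout", "osteoporosis",
    "connective tissue disorder", "psoriasis", "eczema", "hearing loss",
    "visual impairment", "glaucoma", "cataract", "thyroid disorder",
    "adrenal insufficiency", "polycystic ovary syndrome",
    "chronic fatigue syndrome", "sleep apnoea", "chronic anaemia",
    "haemoglobinopathy", "hiv", "chronic viral hepatitis",
    "solid organ cancer", "haematological cancer", "prostate disorders",
    "chronic sinusitis"
  )
  conditions <- c(cardiometabolic, non_cardiometabolic)
  idx <- seq_along(conditions)
  long <- tibble(
    condition = rep(conditions, times = 3L),
    class = rep(
      if_else(conditions %in% cardiometabolic,
        "cardiometabolic", "non-cardiometabolic"
      ),
      times = 3L
    ),
    vocabulary = rep(c("community", "community", "trial"), each = length(conditions)),
    code = c(
      sprintf("cm%03da", idx), sprintf("cm%03db", idx), sprintf("tr%03d", idx)
    )
  )
  new_condition_registry(long)
}

new_condition_registry <- function(x) {
  x <- as_tibble(x)
  class(x) <- c("condition_registry", class(x))
  validate_registry(x)
}

#' Validate a condition registry
#'
#' Checks the structural contract: exactly 57 conditions (unless
#' `allow_custom = TRUE`), the cardiometabolic class is exactly the ten
#' circulatory/kidney conditions, type 2 diabetes is absent, and no code is
#' mapped to two conditions within one vocabulary.
#'
#' @param registry A `condition_registry` tibble.
#' @param allow_custom Allow a registry with a different number of
#'   conditions (for sensitivity analyses with bespoke condition lists).
#' @return The registry, invisibly validated (errors on violation).
#' @export
validate_registry <- function(registry, allow_custom = FALSE) {
  needed <- c("condition", "class", "vocabulary", "code")
  if (!all(needed %in% names(registry))) {
    abort("registry must have columns condition, class, vocabulary, code",
      class = "trialrep_registry_error"
    )
  }
  conds <- unique(registry$condition)
  if (!allow_custom && length(conds) != 57L) {
    abort(
      paste0("registry must contain exactly 57 conditions, found ", length(conds)),
      class = "trialrep_registry_error"
    )
  }
  if (any(grepl("type 2 diabetes", conds, fixed = TRUE))) {
    abort("type 2 diabetes is the index condition and must not be a registry entry",
      class = "trialrep_registry_error"
    )
  }
  cm <- sort(unique(registry$condition[registry$class == "cardiometabolic"]))
  expected_cm <- sort(c(
    "stroke", "coronary artery disease", "heart failure",
    "peripheral artery disease", "heart valve disorders", "arrhythmia",
    "venous thromboembolic disease", "aneurysm", "hypertension",
    "chronic kidney disease"
  ))
  if (!allow_custom && !identical(cm, expected_cm)) {
    abort("cardiometabolic class must be exactly the ten circulatory/kidney conditions",
      class = "trialrep_registry_error"
    )
  }
  dup <- registry |>
    distinct(.data$vocabulary, .data$code, .data$condition) |>
    count(.data$vocabulary, .data$code) |>
    filter(.data$n > 1L)
  if (nrow(dup) > 0L) {
    abort(
      paste0(
        "codes mapped to more than one condition within a vocabulary: ",
        paste(head(dup$code, 5L), collapse = ", ")
      ),
      class = "trialrep_registry_error"
    )
  }
  invisible(registry)
}

#' Read / write a condition registry as JSON
#'
#' The on-disk format is an array of objects with fields `name`, `class` and
#' `codes` (an object keyed by vocabulary). This is the editable fixture
#' format; real Read/ICD-10/MedDRA code lists are intentionally not shipped.
#'
#' @param path File path.
#' @param allow_custom Passed to [validate_registry()].
#' @return `read_registry()` returns a `condition_registry`;
#'   `write_registry()` returns `path` invisibly.
#' @export
read_registry <- function(path, allow_custom = FALSE) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  rows <- purrr::map_dfr(raw, function(entry) {
    vocabs <- names(entry$codes)
    purrr::map_dfr(vocabs, function(v) {
      tibble(
        condition = entry$name,
        class = entry$class,
        vocabulary = v,
        code = unlist(entry$codes[[v]], use.names = FALSE)
      )
    })
  })
  reg <- as_tibble(rows)
  class(reg) <- c("condition_registry", class(reg))
  validate_registry(reg, allow_custom = allow_custom)
  reg
}

#' @rdname read_registry
#' @param registry A `condition_registry`.
#' @export
write_registry <- function(registry, path) {
  validate_registry(registry, allow_custom = TRUE)
  split_cond <- split(registry, factor(registry$condition, levels = unique(registry$condition)))
  out <- purrr::map(split_cond, function(df) {
    list(
      name = df$condition[[1L]],
      class = df$class[[1L]],
      codes = purrr::map(split(df$code, df$vocabulary), as.list)
    )
  })
  jsonlite::write_json(unname(out), path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Codes for the index condition (type 2 diabetes)
#'
#' These codes identify the index condition itself; they are recognised by
#' the phenotyper and excluded from every comorbidity count without a
#' warning.
#'
#' @return Character vector of codes across all toy vocabularies.
#' @export
t2d_codes <- function() {
  c("cmT2Da", "cmT2Db", "trT2D")
}
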