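#' Estimated glomerular filtration rate (CKD-EPI 2009)
#'
#' Computes eGFR from serum creatinine, age and sex using the 2009 CKD-EPI
#' creatinine equation (without the race coefficient):
#' \deqn{eGFR = 141 \times \min(Scr/\kappa, 1)^{\alpha} \times
#'       \max(Scr/\kappa, 1)^{-1.209} \times 0.993^{age}
#'       \times 1.018\,[\mathrm{female}]}
#' with \eqn{\kappa = 0.7} (female) or \eqn{0.9} (male) and
#' \eqn{\alpha = -0.329} (female) or \eqn{-0.411} (male).
#'
#' @param creatinine Serum creatinine in mg/dL (strictly positive).
#' @param age Age in years (>= 18).
#' @param sex `"male"`/`"female"` (also accepts `"m"`/`"f"`, any case).
#' @return eGFR in mL/min/1.73m2, same length as the inputs.
#' @examples
#' egfr_ckd_epi(1.0, 60, "male")
#' @export
egfr_ckd_epi <- function(creatinine, age, sex) {
  n <- max(length(creatinine), length(age), length(sex))
  creatinine <- rep_len(as.double(creatinine), n)
  age <- rep_len(as.double(age), n)
  sex <- rep_len(as.character(sex), n)
  ok <- is.na(creatinine) | creatinine > 0
  if (!all(ok)) {
    abort("creatinine must be strictly positive", class = "trialrep_domain_error")
  }
  if (any(!is.na(age) & age < 18)) {
    abort("the adult CKD-EPI equation requires age >= 18",
      class = "trialrep_domain_error"
    )
  }
  female <- parse_sex(sex)
  kappa <- if_else(female, 0.7, 0.9)
  alpha <- if_else(female, -0.329, -0.411)
  ratio <- creatinine / kappa
  out <- 141 *
    pmin(ratio, 1)^alpha *
    pmax(ratio, 1)^(-1.209) *
    0.993^age
  out <- if_else(female, out * 1.018, out)
  out
}

# internal: normalise sex coding to a logical "is female"
parse_sex <- function(sex) {
  s <- tolower(as.character(sex))
  female <- s %in% c("female", "f", "woman", "2")
  male <- s %in% c("male", "m", "man", "1")
  bad <- !female & !male & !is.na(s)
  if (any(bad)) {
    abort(paste0("unrecognised sex value(s): ", paste(unique(s[bad]), collapse = ", ")),
      class = "trialrep_domain_error"
    )
  }
  out <- female
  out[is.na(s)] <- NA
  out
}

#' Flag chronic kidney disease from eGFR
#'
#' CKD is present when eGFR is strictly below 60 mL/min/1.73m2 at the index
#' date. A missing eGFR yields `NA` ("unknown"), which is distinct from
#' `FALSE`: downstream counting treats unknown CKD as absent but logs it.
#'
#' @param egfr eGFR in mL/min/1.73m2 (may contain `NA`).
#' @return Logical vector: `TRUE` (eGFR < 60), `FALSE` (eGFR >= 60) or `NA`.
#' @examples
#' flag_ckd(c(59.9, 60, NA))
#' @export
flag_ckd <- function(egfr) {
  if (any(is.finite(egfr) & egfr < 0)) {
    abort("egfr must be nonnegative", class = "trialrep_domain_error")
  }
  egfr < 60
}
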