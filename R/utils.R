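#' @keywords internal
"_PACKAGE"

#' @importFrom rlang abort warn inform %||% .data
#' @importFrom dplyr mutate filter select arrange group_by summarise ungroup
#'   left_join inner_join anti_join semi_join bind_rows n distinct across
#'   rename count pull slice first if_else row_number transmute
#' @importFrom tibble tibble as_tibble
#' @importFrom stats rnorm rexp rbinom rgamma rpois rnbinom rbeta runif
#'   qbeta quantile sd var dpois dnbinom ppois pnbinom glm poisson coef vcov
#'   logLik AIC pchisq optimize optim setNames as.formula predict complete.cases
#'   qnorm median offset
#' @importFrom utils head tail write.csv read.csv
NULL

DAYS_PER_YEAR <- 365.25

#' Derive a reproducible child seed from a parent seed
#'
#' Splits one user-facing seed into independent substreams (one per pipeline
#' stage) so that stages can be re-run in isolation. Pure integer arithmetic
#' keeps results identical across platforms; outputs stay below 2^31.
#'
#' @param seed Integer parent seed.
#' @param stream Integer stream index (>= 1) or a known stage name.
#' @return A single integer seed.
#' @export
derive_seed <- function(seed, stream = 1L) {
  if (is.character(stream)) {
    stages <- c(
      community = 1L, trial = 2L, egfr = 3L, rates = 4L, oe = 5L,
      countdist = 6L, slope = 7L, report = 8L
    )
    if (!stream %in% names(stages)) {
      abort(paste0("unknown seed stream '", stream, "'"))
    }
    stream <- stages[[stream]]
  }
  stopifnot(is.numeric(seed), length(seed) == 1L, is.numeric(stream))
  m <- 2147483647 # 2^31 - 1, Mersenne prime modulus
  s <- (abs(as.double(seed)) %% m)
  # two rounds of a Lehmer-style mix keep nearby parent seeds decorrelated
  s <- (s * 48271 + 7 * as.double(stream)) %% m
  s <- (s * 16807 + 104729) %% m
  as.integer(max(1, s))
}

# internal: run code with a local RNG seed without disturbing the caller's RNG
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# internal: structured log message, suppressible via suppressMessages()
log_note <- function(..., class = "trialrep_log") {
  inform(paste0(...), class = class)
}

# internal: check a scalar probability
assert_prob <- function(x, what) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    abort(paste0(what, " must be a probability in [0, 1]"),
      class = "trialrep_invalid_config"
    )
  }
  invisible(x)
}

assert_nonneg <- function(x, what) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0)) {
    abort(paste0(what, " must be finite and nonnegative"),
      class = "trialrep_invalid_config"
    )
  }
  invisible(x)
}
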