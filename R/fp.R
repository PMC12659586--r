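#' Fractional-polynomial design columns
#'
#' Standard fractional-polynomial transform with powers drawn from
#' \{-2, -1, -0.5, 0, 0.5, 1, 2, 3\}: power 0 denotes the natural
#' logarithm, and a repeated power `p` denotes the pair
#' `(x^p, x^p * log(x))`. Inputs are pre-scaled as `(x + shift) / scale`
#' and must be strictly positive after pre-scaling; by package convention
#' age enters as `age / 10` and comorbidity count as `count + 1` so that
#' logarithms and negative powers are defined at count zero.
#'
#' @param x Numeric vector.
#' @param powers One or two powers from the permitted set.
#' @param scale,shift Pre-scaling constants: `z = (x + shift) / scale`.
#' @param var_name Name stem for the returned columns.
#' @return Numeric matrix with one column per basis term.
#' @examples
#' fp_basis(5, 1)
#' fp_basis(2, c(2, 2))
#' @export
fp_basis <- function(x, powers, scale = 1, shift = 0, var_name = "x") {
  allowed <- c(-2, -1, -0.5, 0, 0.5, 1, 2, 3)
  if (length(powers) < 1L || length(powers) > 2L || !all(powers %in% allowed)) {
    abort("powers must be 1-2 values from {-2, -1, -0.5, 0, 0.5, 1, 2, 3}",
      class = "trialrep_fp_error"
    )
  }
  z <- (x + shift) / scale
  bad <- which(!is.na(z) & z <= 0)
  if (length(bad) > 0L) {
    abort(
      paste0(
        "fractional polynomial input must be positive after pre-scaling; ",
        "offending row(s): ", paste(head(bad, 5L), collapse = ", ")
      ),
      class = "trialrep_fp_error"
    )
  }
  one <- function(p) if (p == 0) log(z) else z^p
  if (length(powers) == 1L) {
    out <- matrix(one(powers), ncol = 1L)
    colnames(out) <- paste0(var_name, "^", powers)
  } else if (powers[1] == powers[2]) {
    out <- cbind(one(powers[1]), one(powers[1]) * log(z))
    colnames(out) <- paste0(var_name, c(
      paste0("^", powers[1]), paste0("^", powers[1], ".log")
    ))
  } else {
    out <- cbind(one(powers[1]), one(powers[2]))
    colnames(out) <- paste0(var_name, "^", powers)
  }
  out
}

# the FP power pool
fp_powers_pool <- function() c(-2, -1, -0.5, 0, 0.5, 1, 2, 3)

# all FP2 power pairs (with repetition), 36 of them
fp2_pairs <- function() {
  p <- fp_powers_pool()
  pairs <- list()
  for (i in seq_along(p)) {
    for (j in i:length(p)) {
      pairs[[length(pairs) + 1L]] <- c(p[i], p[j])
    }
  }
  pairs
}
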