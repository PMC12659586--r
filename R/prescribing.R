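#' Community prescribing uptake percentages
#'
#' Recomputes the percentage of the type 2 diabetes population prescribed
#' the index drug class per calendar year from the numerator/denominator
#' counts shipped with the package (`inst/extdata/prescribing_counts.csv`).
#'
#' @param path Optional path to a counts CSV with columns `year`,
#'   `numerator`, `denominator`.
#' @return Tibble `year`, `numerator`, `denominator`, `percent`.
#' @examples
#' prescribing_percentages()
#' @export
prescribing_percentages <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "prescribing_counts.csv", package = "trialrep")
  }
  as_tibble(read.csv(path)) |>
    mutate(percent = 100 * .data$numerator / .data$denominator)
}
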