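# Small analytic helpers for summary quantities reported alongside
# model results.

#' Expected variance explained across technologies
#'
#' When a model is trained on one assay and evaluated against pausing
#' indices measured with a second assay, the variance it can be expected
#' to explain is bounded by the product of the between-technology
#' concordance (R-squared between the two measurements) and the model's
#' own holdout R-squared.
#'
#' @param r2_concordance R-squared between the two technologies'
#'   measurements.
#' @param r2_model the model's holdout R-squared on its own technology.
#' @return Expected cross-technology R-squared (the product).
#' @export
expected_transfer_r2 <- function(r2_concordance, r2_model) {
  stopifnot(r2_concordance >= 0, r2_concordance <= 1,
            r2_model <= 1)
  r2_concordance * r2_model
}

#' Share of a factor or feature subset, as a percentage
#'
#' @param n subset size.
#' @param total universe size.
#' @return `100 * n / total`, rounded to the nearest integer percent.
#' @export
percent_share <- function(n, total) {
  stopifnot(total > 0, n >= 0)
  round(100 * n / total)
}
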