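#' MAG quality filter
#'
#' A bin passes when `completion - 5 * contamination > 50` (strict
#' inequality).  This is the standard medium-quality gate applied before
#' dereplication: percentages on the 0--100 scale, contamination penalised
#' five-fold.
#'
#' @param completion numeric vector, checkM-style completeness in percent
#'   (0--100).
#' @param contamination numeric vector, contamination in percent (>= 0).
#' @return logical vector, `TRUE` for bins passing the filter.
#' @examples
#' quality_filter(99.3, 0)   # TRUE
#' quality_filter(60, 2)     # FALSE: 60 - 10 = 50 is not > 50
#' @seealso [quality_score()]
#' @export
quality_filter <- function(completion, contamination) {
  check_quality_args(completion, contamination)
  completion - 5 * contamination > 50
}

#' MAG quality score for representative selection
#'
#' `completion - 5 * contamination + 0.5 * log10(n50)`.  The N50 term
#' rewards contiguity: an order of magnitude in N50 is worth half a point,
#' so it only breaks near-ties between bins of similar completeness.
#'
#' @inheritParams quality_filter
#' @param n50 numeric vector, assembly N50 in bp (> 0).
#' @return numeric vector of dimensionless scores.
#' @examples
#' quality_score(100, 0, 1e6)  # 103
#' quality_score(90, 4, 1e4)   # 72
#' @export
quality_score <- function(completion, contamination, n50) {
  check_quality_args(completion, contamination)
  if (any(!is.finite(n50) | n50 <= 0))
    stop("`n50` must be positive and finite", call. = FALSE)
  completion - 5 * contamination + 0.5 * log10(n50)
}

check_quality_args <- function(completion, contamination) {
  if (any(!is.finite(completion) | completion < 0 | completion > 100))
    stop("`completion` must lie in [0, 100]", call. = FALSE)
  if (any(!is.finite(contamination) | contamination < 0))
    stop("`contamination` must be >= 0", call. = FALSE)
  invisible(TRUE)
}

#' Score and filter a bin-quality table
#'
#' Adds `score` and `pass` columns to a checkM-style quality table.
#'
#' @param quality data.frame with columns `bin_id`, `completion`,
#'   `contamination`, `n50` (and optionally `has_16s`).
#' @return the input with `score` (numeric) and `pass` (logical) appended.
#' @export
qc_table <- function(quality) {
  need <- c("bin_id", "completion", "contamination", "n50")
  miss <- setdiff(need, names(quality))
  if (length(miss))
    stop("quality table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  quality$score <- quality_score(quality$completion, quality$contamination,
                                 quality$n50)
  quality$pass <- quality_filter(quality$completion, quality$contamination)
  quality
}
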