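#' Pearson chi-square comparison of count tables
#'
#' Tests homogeneity of a contingency table of observed counts (e.g. a
#' demographic characteristic tabulated across two respondent groups)
#' with the plain Pearson chi-square statistic: no continuity correction,
#' no exact test. A warning is emitted when any expected cell count is
#' below 5, but the statistic is reported unchanged; no multiple-testing
#' adjustment is applied, so p-values across many characteristics are raw.
#'
#' @param table Numeric matrix of non-negative observed counts, at least
#'   2 x 2.
#' @return Object of class `contingency_result`: list with `statistic`,
#'   `dof` (= (rows-1)(cols-1)), `p_value`, `observed` and `expected`.
#' @examples
#' compare_counts(matrix(c(24, 167, 30, 161), 2, byrow = TRUE))
#' @export
compare_counts <- function(table) {
  table <- as.matrix(table)
  if (nrow(table) < 2 || ncol(table) < 2) {
    stop("'table' must be at least 2 x 2", call. = FALSE)
  }
  if (any(table < 0) || anyNA(table)) {
    stop("'table' must contain non-negative counts", call. = FALSE)
  }
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop("degenerate table: all-zero row or column", call. = FALSE)
  }
  ht <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  if (any(ht$expected < 5)) {
    warning("expected count below 5 in at least one cell; ",
            "chi-square approximation may be inaccurate", call. = FALSE)
  }
  structure(list(statistic = unname(ht$statistic),
                 dof = unname(ht$parameter),
                 p_value = unname(ht$p.value),
                 observed = table, expected = ht$expected),
            class = "contingency_result")
}

#' @export
print.contingency_result <- function(x, ...) {
  cat(sprintf("Pearson chi-square: X2 = %.4g, df = %d, p = %.3g\n",
              x$statistic, x$dof, x$p_value))
  invisible(x)
}

#' Euclidean distance between two Better/Worse coordinates
#'
#' Used to quantify how far the same attribute lands in two groups or
#' strata; agreement below 5% of the maximal in-square distance
#' (0.05 * sqrt(2) ~ 0.0707) is the conventional closeness yardstick for
#' replicate groups.
#'
#' @param worse_a,better_a,worse_b,better_b Coordinates of the two points
#'   in the signed convention; vectorized.
#' @return Numeric distance(s) in \[0, sqrt(2)\].
#' @examples
#' between_group_distance(-0.80, 0.25, -0.81, 0.25)
#' @export
between_group_distance <- function(worse_a, better_a, worse_b, better_b) {
  check_in_square(worse_a, better_a)
  check_in_square(worse_b, better_b)
  sqrt((worse_a - worse_b)^2 + (better_a - better_b)^2)
}
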