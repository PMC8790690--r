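#' Fit the full Kano evaluation to a survey panel
#'
#' The main entry point: tabulates per-attribute category counts from the
#' answer pairs, applies the mode and if-then assignment rules, computes
#' Timko Better/Worse indices, and weights them by the mean self-stated
#' importance. The returned object carries everything downstream: rank it
#' with [rank_attributes()], plot it, or use [simulate()] to draw
#' calibrated synthetic panels from it.
#'
#' @param data A [kano_survey] (or a data.frame in canonical long format,
#'   which is validated first).
#' @param importance_map Relevance-to-weight mapping, see
#'   [kano_importance_map()].
#' @param precedence Tie-break precedence for the assignment rules, see
#'   [assign_mode()].
#' @return Object of class `kano`: list with
#'   \describe{
#'     \item{table}{data.frame, one row per attribute: counts M, P, A, I,
#'       R, Q, `n_complete`, `n_missing`, assigned `category` (mode rule)
#'       and `category_ifthen`, `better`, `worse`, `importance`,
#'       `better_weighted`, `worse_weighted` — all indices at full
#'       precision.}
#'     \item{counts}{named list of `kano_counts` objects.}
#'     \item{n_respondents, attributes, call}{bookkeeping.}
#'   }
#' @examples
#' prof <- profile_from_counts(
#'   kano_counts("practicality", c(M = 127, P = 42, A = 10, I = 7)), 0.88)
#' fit <- kano(generate_survey(list(prof), n_respondents = 200, seed = 1))
#' summary(fit)
#' @export
kano <- function(data, importance_map = kano_importance_map(),
                 precedence = c("M", "P", "A", "I", "R", "Q")) {
  if (!inherits(data, "kano_survey")) data <- kano_survey(data)
  attrs <- survey_attributes(data)
  counts <- lapply(attrs, function(a) tabulate_attribute(data, a))
  names(counts) <- attrs
  count_tab <- data.frame(attribute = attrs,
                          do.call(rbind, lapply(counts, `[[`, "counts")),
                          n_complete = vapply(counts, `[[`, integer(1), "n_complete"),
                          n_missing = vapply(counts, `[[`, integer(1), "n_missing"),
                          row.names = NULL, stringsAsFactors = FALSE)
  count_tab$category <- vapply(counts, assign_mode, character(1),
                               precedence = precedence)
  count_tab$category_ifthen <- vapply(counts, assign_ifthen, character(1),
                                      precedence = precedence)
  imp <- vapply(attrs, function(a) importance_score(data, a, importance_map),
                numeric(1))
  tab <- cbind(count_tab, timko_indices(count_tab, importance = imp)[-1L])
  structure(list(table = tab, counts = counts, attributes = attrs,
                 n_respondents = n_respondents(data), call = match.call()),
            class = "kano")
}

#' Coordinates of a fitted Kano evaluation
#'
#' @param object A `kano` fit.
#' @param weighted Use importance-weighted coordinates (default) or the
#'   raw indices.
#' @return Data.frame with columns `attribute`, `worse`, `better` suitable
#'   for [rank_attributes()].
#' @export
kano_coordinates <- function(object, weighted = TRUE) {
  stopifnot(inherits(object, "kano"))
  t <- object$table
  data.frame(attribute = t$attribute,
             worse = if (weighted) t$worse_weighted else t$worse,
             better = if (weighted) t$better_weighted else t$better,
             stringsAsFactors = FALSE)
}

#' @export
print.kano <- function(x, ...) {
  cat(sprintf("Kano evaluation of %d attributes, %d respondents\n",
              length(x$attributes), x$n_respondents))
  t <- x$table
  shown <- data.frame(attribute = t$attribute, t[kano_categories()],
                      category = t$category,
                      better = round_half_up(t$better, 2),
                      worse = round_half_up(t$worse, 2),
                      importance = round_half_up(t$importance, 2))
  print(shown, row.names = FALSE)
  invisible(x)
}

#' @export
summary.kano <- function(object, pov = "must-be", ...) {
  structure(list(fit = object, ranking = rank_attributes(
    kano_coordinates(object), pov)), class = "summary.kano")
}

#' @export
print.summary.kano <- function(x, ...) {
  print(x$fit)
  t <- x$fit$table
  cat("\nimportance-weighted coordinates:\n")
  shown <- data.frame(attribute = t$attribute,
                      better_weighted = round_half_up(t$better_weighted, 2),
                      worse_weighted = round_half_up(t$worse_weighted, 2))
  print(shown, row.names = FALSE)
  cat("\n")
  print(x$ranking)
  invisible(x)
}

#' @export
coef.kano <- function(object, ...) {
  t <- object$table
  m <- as.matrix(t[c("better", "worse", "importance",
                     "better_weighted", "worse_weighted")])
  rownames(m) <- t$attribute
  m
}

#' Draw synthetic panels calibrated to a fitted evaluation
#'
#' Re-simulates the survey: each attribute's empirical category
#' distribution and mean importance are inverted into an
#' [attribute_profile] (see [profile_from_counts()]) and `nsim` fresh
#' panels are generated. Useful for rank-stability checks: refit and
#' re-rank each replicate to see how often the observed permutation
#' recurs under sampling noise.
#'
#' @param object A `kano` fit.
#' @param nsim Number of panels.
#' @param seed Integer seed.
#' @param n_respondents Panel size; defaults to the fitted panel's size.
#' @param ... Unused.
#' @return List of [kano_survey] objects of length `nsim`.
#' @export
simulate.kano <- function(object, nsim = 1, seed = 1,
                          n_respondents = object$n_respondents, ...) {
  profiles <- lapply(object$attributes, function(a) {
    profile_from_counts(object$counts[[a]],
                        object$table$importance[object$table$attribute == a])
  })
  lapply(seq_len(nsim), function(i) {
    generate_survey(profiles, n_respondents, seed = seed + i - 1L)
  })
}

#' Quadrant chart of a Kano evaluation
#'
#' Plots each attribute at (|Worse|, Better) with the conventional
#' quadrant boundaries at 0.5: high |Worse|, low Better = must-be; both
#' high = one-dimensional; low |Worse|, high Better = attractive; both
#' low = indifferent. With `annotate_importance_shift`, arrows run from
#' the unweighted to the importance-weighted coordinate of each
#' attribute.
#'
#' @param x A `kano` fit.
#' @param weighted Plot importance-weighted coordinates (default).
#' @param annotate_importance_shift Draw unweighted-to-weighted arrows.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.kano <- function(x, weighted = TRUE, annotate_importance_shift = FALSE, ...) {
  co <- kano_coordinates(x, weighted = weighted)
  graphics::plot(abs(co$worse), co$better, xlim = c(0, 1), ylim = c(0, 1),
                 xlab = "|Worse| (dissatisfaction index)",
                 ylab = "Better (satisfaction index)", pch = 19, ...)
  graphics::abline(h = 0.5, v = 0.5, lty = 2, col = "grey50")
  lab <- c("indifferent", "must-be", "attractive", "one-dimensional")
  graphics::text(c(0.02, 0.98, 0.02, 0.98), c(0.02, 0.02, 0.98, 0.98),
                 lab, adj = c(0.5, 0.5), cex = 0.7, col = "grey40",
                 pos = c(4, 2, 4, 2), offset = 0)
  if (annotate_importance_shift && weighted) {
    raw <- kano_coordinates(x, weighted = FALSE)
    graphics::arrows(abs(raw$worse), raw$better, abs(co$worse), co$better,
                     length = 0.06, col = "grey60")
  }
  graphics::text(abs(co$worse), co$better, co$attribute, pos = 3, cex = 0.7)
  invisible(x)
}

#' Quadrant label of a coordinate
#'
#' Assigns the Kano quadrant of a (worse, better) coordinate using the
#' midlines |worse| = 0.5 and better = 0.5 of the unit square; points on
#' a boundary are labelled `"borderline"`.
#'
#' @param worse,better Signed coordinates; vectorized.
#' @param tol Numeric tolerance for boundary detection.
#' @return Character vector of quadrant names.
#' @examples
#' quadrant_of(c(-0.8, -0.37), c(0.25, 0.31))
#' @export
quadrant_of <- function(worse, better, tol = 1e-9) {
  check_in_square(worse, better)
  w <- abs(worse)
  out <- ifelse(w > 0.5,
                ifelse(better > 0.5, "one-dimensional", "must-be"),
                ifelse(better > 0.5, "attractive", "indifferent"))
  out[abs(w - 0.5) <= tol | abs(better - 0.5) <= tol] <- "borderline"
  out
}
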