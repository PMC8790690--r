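#' Timko satisfaction and dissatisfaction indices
#'
#' The satisfaction index Better = (A+P)/(A+P+M+I) measures the relative
#' gain from meeting a requirement; the dissatisfaction index
#' Worse = -(P+M)/(A+P+M+I) the relative cost of not meeting it.
#' Reverse and questionable answers are excluded from both. By
#' construction 0 <= Better <= 1 and -1 <= Worse <= 0; Worse is kept on
#' its negative scale (plots conventionally show its absolute value).
#'
#' @param counts A `kano_counts` object, or a named numeric vector with at
#'   least A, P, M, I entries.
#' @return Single numeric index.
#' @examples
#' x <- kano_counts("practicality", c(M = 127, P = 42, A = 10, I = 7))
#' better_index(x)   # 52/186
#' worse_index(x)    # -169/186
#' @export
better_index <- function(counts) {
  ct <- as_category_vector(counts)
  denom <- sum(ct[c("A", "P", "M", "I")])
  if (denom == 0) stop("index undefined: A+P+M+I is zero", call. = FALSE)
  unname((ct[["A"]] + ct[["P"]]) / denom)
}

#' @rdname better_index
#' @export
worse_index <- function(counts) {
  ct <- as_category_vector(counts)
  denom <- sum(ct[c("A", "P", "M", "I")])
  if (denom == 0) stop("index undefined: A+P+M+I is zero", call. = FALSE)
  unname(-(ct[["P"]] + ct[["M"]]) / denom)
}

as_category_vector <- function(counts) {
  if (inherits(counts, "kano_counts")) return(counts$counts)
  full <- stats::setNames(numeric(6), kano_categories())
  full[names(counts)] <- counts
  full
}

#' Mean self-stated importance of an attribute
#'
#' Averages the relevance answers for one attribute after mapping the five
#' relevance levels onto numeric weights (default: the uniform grid of
#' [kano_importance_map()], very_important = 1 down to unimportant = 0).
#' Absent answers are excluded.
#'
#' @param data A [kano_survey].
#' @param attribute Attribute id.
#' @param importance_map Named numeric vector over the relevance tokens.
#' @return Mean importance in \[0, 1\].
#' @export
importance_score <- function(data, attribute, importance_map = kano_importance_map()) {
  stopifnot(inherits(data, "kano_survey"))
  rel <- data$relevance[data$attribute == attribute]
  if (!length(rel)) stop("no records for attribute: ", attribute, call. = FALSE)
  vals <- importance_map[as.character(rel)]
  vals <- vals[!is.na(vals)]
  if (!length(vals)) stop("no relevance answers for attribute: ", attribute,
                          call. = FALSE)
  mean(vals)
}

#' Weight Better/Worse indices by importance
#'
#' Scalar importance weighting: both indices are multiplied by the mean
#' self-stated importance, pulling unimportant attributes toward the
#' origin of the Better-Worse plane and improving discrimination between
#' attributes that sit close together unweighted.
#'
#' @param better,worse Unweighted indices (Better in \[0,1\], Worse in
#'   \[-1,0\]).
#' @param importance Importance weight in \[0, 1\].
#' @return Named numeric vector `c(better_weighted=, worse_weighted=)`.
#' @examples
#' weight_by_importance(0.28, -0.91, 0.88)
#' @export
weight_by_importance <- function(better, worse, importance) {
  stopifnot_scalar_prob(importance, "importance")
  c(better_weighted = better * importance, worse_weighted = worse * importance)
}

#' Per-attribute index table from counts and importance
#'
#' The workhorse joining the two indices with importance weighting for a
#' whole set of attributes at once, e.g. a published counts table.
#'
#' @param counts Data.frame with columns `attribute`, `M`, `P`, `A`, `I`
#'   (`R`, `Q` optional and unused by the indices), one row per attribute.
#' @param importance Optional numeric vector of importance weights in
#'   \[0, 1\] (recycled), or `NULL` for unweighted indices only.
#' @return Data.frame with columns `attribute`, `better`, `worse` and,
#'   when importance is supplied, `importance`, `better_weighted`,
#'   `worse_weighted`. Full precision; round at the reporting boundary
#'   with [round_half_up()].
#' @examples
#' tab <- data.frame(attribute = "practicality", M = 127, P = 42, A = 10, I = 7)
#' timko_indices(tab, importance = 0.88)
#' @export
timko_indices <- function(counts, importance = NULL) {
  stopifnot(is.data.frame(counts), all(c("attribute", "M", "P", "A", "I") %in% names(counts)))
  denom <- counts$A + counts$P + counts$M + counts$I
  if (any(denom == 0)) stop("index undefined: A+P+M+I is zero for ",
                            paste(counts$attribute[denom == 0], collapse = ", "),
                            call. = FALSE)
  out <- data.frame(attribute = as.character(counts$attribute),
                    better = (counts$A + counts$P) / denom,
                    worse = -(counts$P + counts$M) / denom,
                    stringsAsFactors = FALSE)
  if (!is.null(importance)) {
    if (any(importance < 0 | importance > 1)) {
      stop("'importance' must lie in [0, 1]", call. = FALSE)
    }
    out$importance <- rep_len(importance, nrow(out))
    out$better_weighted <- out$better * out$importance
    out$worse_weighted <- out$worse * out$importance
  }
  out
}
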