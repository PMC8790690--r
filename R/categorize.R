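#' Kano categories
#'
#' The six categories an answer pair can map to: attractive (A), must-be
#' (M), one-dimensional/performance (P, often written O in the
#' literature — an alias, never a seventh category), indifferent (I),
#' reverse (R) and questionable (Q).
#'
#' @return Character vector `c("A","P","M","I","R","Q")`.
#' @export
kano_categories <- function() c("A", "P", "M", "I", "R", "Q")

#' The answer-pair categorization matrix
#'
#' The classical 5x5 lookup assigning one Kano category to each complete
#' (functional, dysfunctional) answer pair. Rows are functional answers,
#' columns dysfunctional answers, both in the order of
#' `kano_levels("functional")` (delighted, expected, neutral, tolerated,
#' dislike). Over the 25 cells the category multiset is
#' Q:4, A:3, P:1, M:3, I:7, R:7.
#'
#' @return 5x5 character matrix with dimnames on the canonical levels.
#' @examples
#' kano_matrix()["delighted", "dislike"]   # "P"
#' @export
kano_matrix <- function() {
  lv <- kano_levels("functional")
  m <- matrix(c(
    # dysf: delighted expected neutral tolerated dislike
    "Q", "A", "A", "A", "P",   # functional: delighted
    "R", "Q", "I", "I", "M",   # expected
    "R", "I", "I", "I", "M",   # neutral
    "R", "I", "I", "Q", "M",   # tolerated
    "R", "R", "R", "R", "Q"),  # dislike
    nrow = 5, byrow = TRUE, dimnames = list(functional = lv, dysfunctional = lv))
  m
}

#' Categorize functional/dysfunctional answer pairs
#'
#' Vectorized lookup into [kano_matrix()]. If either half of a pair is
#' absent (`NA`) the pair is not categorizable and `NA` is returned; this
#' is the only missing-answer handling — no imputation.
#'
#' @param functional,dysfunctional Canonical tokens or factors on the
#'   canonical levels (recycled to a common length).
#' @return Factor on [kano_categories()], `NA` for incomplete pairs.
#' @examples
#' categorize_pair("delighted", "dislike")  # P
#' categorize_pair("expected", "dislike")   # M
#' categorize_pair("neutral", NA)           # <NA>
#' @export
categorize_pair <- function(functional, dysfunctional) {
  lv <- kano_levels("functional")
  f <- factor(as.character(functional), levels = lv)
  d <- factor(as.character(dysfunctional), levels = lv)
  n <- max(length(f), length(d))
  f <- rep_len(f, n); d <- rep_len(d, n)
  out <- rep(NA_character_, n)
  ok <- !is.na(f) & !is.na(d)
  out[ok] <- kano_matrix()[cbind(as.integer(f[ok]), as.integer(d[ok]))]
  factor(out, levels = kano_categories())
}

#' Tally Kano categories for one attribute
#'
#' Counts how often each category was assigned across the respondents of a
#' survey for a single attribute. Pairs with a missing half are not
#' categorized; they are reported in `n_missing` so that
#' `sum(counts) == n_complete` and `n_complete + n_missing` equals the
#' number of records for the attribute.
#'
#' @param data A [kano_survey].
#' @param attribute Attribute id present in `data`.
#' @return Object of class `kano_counts`: a list with `attribute`,
#'   `counts` (named integer vector over A, P, M, I, R, Q), `n_complete`
#'   and `n_missing`.
#' @examples
#' s <- generate_survey(list(attribute_profile("x")), n_respondents = 25, seed = 1)
#' tabulate_attribute(s, "x")
#' @export
tabulate_attribute <- function(data, attribute) {
  stopifnot(inherits(data, "kano_survey"))
  rows <- data$attribute == attribute
  if (!any(rows)) stop("no records for attribute: ", attribute, call. = FALSE)
  cat <- categorize_pair(data$functional[rows], data$dysfunctional[rows])
  counts <- table(cat)
  kano_counts(attribute, counts, n_missing = sum(is.na(cat)))
}

#' @rdname tabulate_attribute
#' @param counts Named non-negative counts over (a subset of)
#'   [kano_categories()]; omitted categories are zero.
#' @param n_missing Number of records whose pair could not be categorized.
#' @export
kano_counts <- function(attribute, counts, n_missing = 0L) {
  full <- stats::setNames(integer(6), kano_categories())
  counts <- unlist(counts)
  bad <- setdiff(names(counts), names(full))
  if (length(bad)) stop("unknown category name(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  if (any(counts < 0)) stop("category counts must be non-negative", call. = FALSE)
  full[names(counts)] <- as.integer(counts)
  structure(list(attribute = as.character(attribute), counts = full,
                 n_complete = sum(full), n_missing = as.integer(n_missing)),
            class = "kano_counts")
}

#' @export
print.kano_counts <- function(x, ...) {
  cat(sprintf("Kano counts for %s (n_complete = %d, n_missing = %d)\n",
              sQuote(x$attribute), x$n_complete, x$n_missing))
  print(x$counts)
  invisible(x)
}

# shared argmax with the documented tie precedence M > P > A > I > R > Q
argmax_category <- function(counts, within = kano_categories(),
                            precedence = c("M", "P", "A", "I", "R", "Q")) {
  within <- within[order(match(within, precedence))]
  within[which.max(counts[within])]
}

#' Category assignment rules
#'
#' The two classical rules condensing a count vector into a single
#' category per attribute.
#'
#' `assign_mode()` picks the category with the greatest frequency.
#'
#' `assign_ifthen()` first compares the "functional" mass P+A+M with the
#' "non-functional" mass I+R+Q: if P+A+M > I+R+Q the argmax over
#' \{P, A, M\} is returned, if smaller the argmax over \{I, R, Q\}; on
#' equality it falls back to the global argmax.
#'
#' Ties inside any argmax are broken by the fixed precedence
#' M > P > A > I > R > Q (configurable), a conservative essentials-first
#' ordering; the classical sources never specify a tie rule.
#'
#' @param counts A `kano_counts` (see [tabulate_attribute()]) with
#'   `n_complete > 0`.
#' @param precedence Permutation of [kano_categories()] used to break ties.
#' @return Single category string.
#' @examples
#' x <- kano_counts("legal_conformity", c(M = 148, P = 27, A = 2, I = 13, Q = 1))
#' assign_mode(x)    # "M"
#' assign_ifthen(x)  # "M"
#' @export
assign_mode <- function(counts, precedence = c("M", "P", "A", "I", "R", "Q")) {
  stopifnot(inherits(counts, "kano_counts"))
  if (counts$n_complete == 0L) stop("no categorizable pairs", call. = FALSE)
  argmax_category(counts$counts, precedence = precedence)
}

#' @rdname assign_mode
#' @export
assign_ifthen <- function(counts, precedence = c("M", "P", "A", "I", "R", "Q")) {
  stopifnot(inherits(counts, "kano_counts"))
  if (counts$n_complete == 0L) stop("no categorizable pairs", call. = FALSE)
  ct <- counts$counts
  functional <- sum(ct[c("P", "A", "M")])
  other <- sum(ct[c("I", "R", "Q")])
  if (functional > other) {
    argmax_category(ct, within = c("P", "A", "M"), precedence = precedence)
  } else if (functional < other) {
    argmax_category(ct, within = c("I", "R", "Q"), precedence = precedence)
  } else {
    argmax_category(ct, precedence = precedence)
  }
}
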