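#' Canonical answer scales
#'
#' A Kano item pairs a functional question ("what if the feature is
#' present?") with a dysfunctional question ("what if it is absent?").
#' Both are answered on the same 5-level scale; a third question asks for
#' the attribute's perceived relevance on a 5-level importance scale.
#' Internally every answer is stored as a short stable token so that the
#' arithmetic is decoupled from the (locale-dependent) survey wording; the
#' default English labels accepted by [read_survey()] are listed below.
#'
#' Functional/dysfunctional tokens, most to least favourable reaction to
#' the feature being present:
#' \describe{
#'   \item{delighted}{"I would be very pleased"}
#'   \item{expected}{"I'd expect this"}
#'   \item{neutral}{"I don't care"}
#'   \item{tolerated}{"I could accept that"}
#'   \item{dislike}{"That would really bother me"}
#' }
#'
#' Relevance tokens: `very_important`, `important`, `neutral`,
#' `less_important`, `unimportant`.
#'
#' A missing answer is stored as `NA` ("absent"); no imputation is ever
#' performed, because an answer pair with a missing half cannot be
#' categorized.
#'
#' @param scale `"functional"`, `"dysfunctional"` or `"relevance"`.
#' @return Character vector of the five canonical tokens, in scale order.
#' @examples
#' kano_levels("functional")
#' kano_levels("relevance")
#' @export
kano_levels <- function(scale = c("functional", "dysfunctional", "relevance")) {
  scale <- match.arg(scale)
  if (scale == "relevance") {
    c("very_important", "important", "neutral", "less_important", "unimportant")
  } else {
    c("delighted", "expected", "neutral", "tolerated", "dislike")
  }
}

#' Default wording-to-token lookup tables
#'
#' Maps accepted answer strings (canonical tokens plus the default English
#' survey wording) to canonical tokens. Users running surveys in another
#' language pass their own mapping to [read_survey()].
#'
#' @param scale `"functional"`, `"dysfunctional"` or `"relevance"`.
#' @return Named character vector: names are accepted strings (lower case),
#'   values are canonical tokens.
#' @export
kano_labels <- function(scale = c("functional", "dysfunctional", "relevance")) {
  scale <- match.arg(scale)
  lv <- kano_levels(scale)
  wording <- if (scale == "relevance") {
    c("very important", "important", "neutral", "less important", "unimportant")
  } else {
    c("i would be very pleased", "i'd expect this", "i don't care",
      "i could accept that", "that would really bother me")
  }
  stats::setNames(c(lv, lv), c(lv, wording))
}

#' Relevance-to-importance mapping
#'
#' The mean self-stated relevance of an attribute is expressed as an
#' importance weight in \[0, 1\] by mapping the five relevance levels onto a
#' uniform linear grid. The grid is the package default and can be replaced
#' wherever an `importance_map` argument is accepted.
#'
#' @return Named numeric vector mapping relevance tokens to weights.
#' @examples
#' kano_importance_map()
#' @export
kano_importance_map <- function() {
  stats::setNames(c(1, 0.75, 0.5, 0.25, 0), kano_levels("relevance"))
}

# map raw answer strings to canonical tokens; empty / NA sentinels -> NA.
# Errors name the offending 1-based data row.
canonicalize_answers <- function(x, scale, na_strings = c("", "NA"), labels = NULL) {
  if (is.null(labels)) labels <- kano_labels(scale)
  x <- trimws(as.character(x))
  out <- rep(NA_character_, length(x))
  miss <- is.na(x) | x %in% na_strings
  key <- tolower(x[!miss])
  mapped <- unname(labels[key])
  if (anyNA(mapped)) {
    bad <- which(!miss)[which(is.na(mapped))[1L]]
    stop(sprintf("unrecognized %s answer %s at row %d",
                 scale, dQuote(x[bad]), bad), call. = FALSE)
  }
  out[!miss] <- mapped
  factor(out, levels = kano_levels(scale))
}
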