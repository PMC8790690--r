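#' Randomly split respondents into two groups
#'
#' Partitions the respondents of a survey into a test and a validation
#' group, reproducibly for a given seed. Group A receives
#' `ceiling(fraction * n)` respondents, group B the remainder, so a 50%
#' split of an even panel gives two equal halves (e.g. 382 -> 191 + 191).
#'
#' @param data A [kano_survey].
#' @param fraction Proportion of respondents assigned to group A, strictly
#'   between 0 and 1. Default 0.5.
#' @param seed Integer seed; identical seeds give identical partitions.
#'   The caller's RNG state is left untouched.
#' @return Named list with `kano_survey` elements `A` and `B`; their
#'   respondent sets are disjoint and their union is the input panel.
#' @examples
#' s <- generate_survey(list(attribute_profile("x")), n_respondents = 10, seed = 1)
#' g <- split_groups(s, 0.5, seed = 42)
#' sapply(g, n_respondents)
#' @export
split_groups <- function(data, fraction = 0.5, seed) {
  stopifnot(inherits(data, "kano_survey"))
  stopifnot_scalar_prob(fraction, "fraction", open = TRUE)
  ids <- unique(data$respondent)
  n_a <- ceiling(fraction * length(ids))
  picked <- with_seed(seed, sample(ids, n_a))
  subset_survey <- function(keep) {
    kano_survey(as.data.frame(data)[data$respondent %in% keep, , drop = FALSE],
                attributes = survey_attributes(data))
  }
  list(A = subset_survey(picked), B = subset_survey(setdiff(ids, picked)))
}

#' Stratify a survey by a respondent-level label
#'
#' Splits the panel into sub-surveys according to one stratification
#' column, optionally after aggregating raw values into coarser strata
#' (e.g. collapsing a 5-level interest scale into "interested" vs
#' "uninterested"). Respondents whose value is missing or not covered by
#' the aggregation map are collected in an explicit `"unmapped"` stratum.
#'
#' @param data A [kano_survey].
#' @param label Name of a strata column present in `data`.
#' @param aggregation Optional named character vector mapping raw values to
#'   stratum names; `NULL` (default) keeps each raw value as its own
#'   stratum.
#' @return Named list of `kano_survey` objects, one per stratum; the
#'   respondent sets partition the input panel.
#' @examples
#' prof <- attribute_profile("x")
#' s <- generate_survey(list(prof), n_respondents = 20, seed = 1,
#'                      strata_spec = list(gender = c(female = 0.5, male = 0.5)))
#' names(stratify(s, "gender"))
#' @export
stratify <- function(data, label, aggregation = NULL) {
  stopifnot(inherits(data, "kano_survey"))
  if (!label %in% attr(data, "strata")) {
    stop("unknown strata label: ", label, call. = FALSE)
  }
  raw <- as.character(data[[label]])
  if (is.null(aggregation)) {
    stratum <- raw
    stratum[is.na(stratum)] <- "unmapped"
  } else {
    stratum <- unname(aggregation[raw])
    stratum[is.na(stratum)] <- "unmapped"
  }
  # a respondent's stratum comes from their first record; ingestion keeps
  # strata constant within respondent so any record serves
  out <- lapply(split(seq_len(nrow(data)), stratum), function(i) {
    kano_survey(as.data.frame(data)[i, , drop = FALSE],
                attributes = survey_attributes(data))
  })
  out[order(names(out) == "unmapped")]
}
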