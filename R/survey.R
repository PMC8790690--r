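#' Construct a Kano survey dataset
#'
#' The canonical container for raw responses: one row per respondent x
#' attribute, with the functional, dysfunctional and relevance answers as
#' factors on the canonical scales (see [kano_levels()]) and any number of
#' additional stratification columns (e.g. gender, interest). Most users
#' will build one via [read_survey()] or [generate_survey()] rather than
#' directly.
#'
#' @param data A data.frame with columns `respondent`, `attribute`,
#'   `functional`, `dysfunctional`, `relevance`; further columns are kept
#'   as strata. Answer columns may be character (canonical tokens) or
#'   factors on the canonical levels; `NA` means no answer given.
#' @param attributes Optional character vector fixing the attribute order;
#'   defaults to order of first appearance.
#' @return An object of class `kano_survey`: the validated data.frame with
#'   attributes `attributes` (ordered attribute ids) and `strata`
#'   (names of the stratification columns).
#' @examples
#' df <- data.frame(respondent = c("r1", "r1"), attribute = c("a", "b"),
#'                  functional = "expected", dysfunctional = "dislike",
#'                  relevance = "very_important")
#' kano_survey(df)
#' @export
kano_survey <- function(data, attributes = NULL) {
  req <- c("respondent", "attribute", "functional", "dysfunctional", "relevance")
  missing_cols <- setdiff(req, names(data))
  if (length(missing_cols)) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  data <- as.data.frame(data, stringsAsFactors = FALSE)
  data$respondent <- as.character(data$respondent)
  data$attribute <- as.character(data$attribute)
  for (col in c("functional", "dysfunctional", "relevance")) {
    scale <- if (col == "relevance") "relevance" else col
    lv <- kano_levels(scale)
    x <- data[[col]]
    if (is.factor(x)) x <- as.character(x)
    bad <- !is.na(x) & !(x %in% lv)
    if (any(bad)) {
      stop(sprintf("non-canonical %s level(s): %s (use read_survey() to map wording)",
                   col, paste(unique(x[bad]), collapse = ", ")), call. = FALSE)
    }
    data[[col]] <- factor(x, levels = lv)
  }
  key <- paste(data$respondent, data$attribute, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate (respondent, attribute) pair(s), e.g. ",
         sub("\r", " x ", key[duplicated(key)][1L]), call. = FALSE)
  }
  if (is.null(attributes)) attributes <- unique(data$attribute)
  if (!all(data$attribute %in% attributes)) {
    stop("records reference attribute(s) outside the attribute list", call. = FALSE)
  }
  strata <- setdiff(names(data), req)
  data <- data[c(req, strata)]
  structure(data, class = c("kano_survey", "data.frame"),
            attributes_ = attributes, strata = strata)
}

#' @export
print.kano_survey <- function(x, ...) {
  cat(sprintf("Kano survey: %d respondents x %d attributes (%d records)\n",
              n_respondents(x), length(survey_attributes(x)), nrow(x)))
  cat("attributes:", paste(survey_attributes(x), collapse = ", "), "\n")
  if (length(attr(x, "strata"))) {
    cat("strata columns:", paste(attr(x, "strata"), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Attribute ids and respondent count of a survey
#'
#' @param x A `kano_survey`.
#' @return `survey_attributes()`: character vector of attribute ids in
#'   canonical order; `n_respondents()`: number of distinct respondents.
#' @export
survey_attributes <- function(x) attr(x, "attributes_")

#' @rdname survey_attributes
#' @export
n_respondents <- function(x) length(unique(x$respondent))

#' Read a survey response table from CSV
#'
#' Reads a delimited response file and maps every answer string onto the
#' canonical scales. Two layouts are supported: *long* (one row per
#' respondent x attribute; the default) and *wide* (one row per
#' respondent, three columns per attribute). Empty cells and the
#' configured `na_strings` become "absent" (`NA`); any other unrecognized
#' answer string is an error naming the row.
#'
#' @param path Path to a CSV file (RFC-4180, UTF-8).
#' @param schema Named list mapping roles to column names. For the long
#'   layout: `respondent`, `attribute`, `functional`, `dysfunctional`,
#'   `relevance`, optional `strata` (character vector of extra columns).
#'   For the wide layout: `respondent`, `attributes` (attribute ids),
#'   `suffixes` (length-3 named c(functional=, dysfunctional=, relevance=)
#'   appended to each attribute id to form column names), optional
#'   `strata`. Defaults to the long layout with canonical column names.
#' @param layout `"long"` or `"wide"`.
#' @param delim Field delimiter, default `","`.
#' @param na_strings Strings treated as "no answer given".
#' @param labels Optional list with elements `functional`, `dysfunctional`,
#'   `relevance`: custom wording-to-token maps (see [kano_labels()]).
#' @return A [kano_survey].
#' @seealso [write_survey()] for the canonical long-format writer.
#' @export
read_survey <- function(path, schema = list(), layout = c("long", "wide"),
                        delim = ",", na_strings = c("", "NA"), labels = list()) {
  layout <- match.arg(layout)
  if (!file.exists(path)) stop("input file not found: ", path, call. = FALSE)
  raw <- utils::read.table(path, header = TRUE, sep = delim, quote = "\"",
                           colClasses = "character", check.names = FALSE,
                           stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  if (layout == "wide") {
    raw <- wide_to_long(raw, schema)
    schema <- list(strata = schema$strata)
  }
  defaults <- list(respondent = "respondent", attribute = "attribute",
                   functional = "functional", dysfunctional = "dysfunctional",
                   relevance = "relevance", strata = character())
  schema <- utils::modifyList(defaults, schema[intersect(names(schema), names(defaults))])
  need <- unlist(schema[c("respondent", "attribute", "functional",
                          "dysfunctional", "relevance")], use.names = FALSE)
  need <- c(need, schema$strata)
  absent <- setdiff(need, names(raw))
  if (length(absent)) {
    stop("schema column(s) not present in file: ", paste(absent, collapse = ", "),
         call. = FALSE)
  }
  out <- data.frame(respondent = raw[[schema$respondent]],
                    attribute = raw[[schema$attribute]],
                    stringsAsFactors = FALSE)
  out$functional <- canonicalize_answers(raw[[schema$functional]], "functional",
                                         na_strings, labels$functional)
  out$dysfunctional <- canonicalize_answers(raw[[schema$dysfunctional]], "dysfunctional",
                                            na_strings, labels$dysfunctional)
  out$relevance <- canonicalize_answers(raw[[schema$relevance]], "relevance",
                                        na_strings, labels$relevance)
  for (s in schema$strata) out[[s]] <- raw[[s]]
  kano_survey(out)
}

# wide layout -> canonical long layout. schema$attributes lists attribute
# ids; schema$suffixes gives the three per-attribute column suffixes.
wide_to_long <- function(raw, schema) {
  if (is.null(schema$attributes)) {
    stop("wide layout requires schema$attributes", call. = FALSE)
  }
  suff <- schema$suffixes
  if (is.null(suff)) {
    suff <- c(functional = "_functional", dysfunctional = "_dysfunctional",
              relevance = "_relevance")
  }
  id_col <- if (is.null(schema$respondent)) "respondent" else schema$respondent
  if (!id_col %in% names(raw)) {
    stop("schema column(s) not present in file: ", id_col, call. = FALSE)
  }
  pieces <- lapply(schema$attributes, function(a) {
    cols <- paste0(a, suff[c("functional", "dysfunctional", "relevance")])
    absent <- setdiff(cols, names(raw))
    if (length(absent)) {
      stop("schema column(s) not present in file: ", paste(absent, collapse = ", "),
           call. = FALSE)
    }
    d <- data.frame(respondent = raw[[id_col]], attribute = a,
                    functional = raw[[cols[1L]]], dysfunctional = raw[[cols[2L]]],
                    relevance = raw[[cols[3L]]], stringsAsFactors = FALSE)
    for (s in schema$strata) d[[s]] <- raw[[s]]
    d
  })
  do.call(rbind, pieces)
}

#' Write a survey in canonical long format
#'
#' Writes the canonical long-format CSV (one row per respondent x
#' attribute, canonical tokens, empty cells for absent answers). Reading
#' the file back with [read_survey()] reproduces the dataset level for
#' level.
#'
#' @param x A [kano_survey].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_survey <- function(x, path) {
  stopifnot(inherits(x, "kano_survey"))
  df <- as.data.frame(x)
  for (col in c("functional", "dysfunctional", "relevance")) {
    df[[col]] <- as.character(df[[col]])
  }
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}
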