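#' Reference category counts: nine health-app quality principles
#'
#' Category counts and mean self-stated importance from a Kano survey in
#' which physicians rated nine quality principles for mobile health apps
#' (practicality, risk adequacy, ethical soundness, legal conformity,
#' content validity, technical adequacy, usability, resource efficiency,
#' transparency). The panel of 382 respondents was randomly split into a
#' test group (`"A"`) and a validation group (`"B"`) of 191 respondents
#' each; counts are per attribute and group over the six categories, with
#' the group's mean importance on the default \[0, 1\] scale.
#'
#' This table is the package's worked reference: running
#' [timko_indices()] and [rank_attributes()] on it reproduces the
#' published index table and the identical rank permutation of the two
#' groups (legal conformity first, resource efficiency last).
#'
#' @param group `"A"`, `"B"` or `"both"` (default).
#' @return Data.frame with columns `attribute`, `group`, `M`, `P`, `A`,
#'   `I`, `R`, `Q`, `importance`.
#' @examples
#' head(app_quality_counts("A"))
#' @export
app_quality_counts <- function(group = c("both", "A", "B")) {
  group <- match.arg(group)
  path <- system.file("extdata", "app_quality_counts.csv", package = "kanosight",
                      mustWork = TRUE)
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (group != "both") x <- x[x$group == group, , drop = FALSE]
  rownames(x) <- NULL
  x
}
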