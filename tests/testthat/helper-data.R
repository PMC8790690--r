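# Shared fixtures: the bundled reference counts plus the published index
# and ranking tables they must reproduce, and small independent oracles.

ref_counts <- function(group = "both") app_quality_counts(group)

# published per-group index table (2-decimal cells): better/worse raw,
# importance, and importance-weighted values
published_indices <- function() {
  x <- rbind(
    c("practicality",        "A", 0.28, -0.91, 0.88, 0.25, -0.80),
    c("risk_adequacy",       "A", 0.27, -0.94, 0.87, 0.23, -0.82),
    c("ethical_soundness",   "A", 0.26, -0.86, 0.85, 0.22, -0.72),
    c("legal_conformity",    "A", 0.15, -0.92, 0.89, 0.14, -0.82),
    c("content_validity",    "A", 0.23, -0.96, 0.91, 0.21, -0.88),
    c("technical_adequacy",  "A", 0.47, -0.80, 0.82, 0.38, -0.66),
    c("usability",           "A", 0.37, -0.80, 0.84, 0.31, -0.67),
    c("resource_efficiency", "A", 0.45, -0.55, 0.68, 0.31, -0.37),
    c("transparency",        "A", 0.33, -0.78, 0.79, 0.26, -0.62),
    c("practicality",        "B", 0.28, -0.91, 0.88, 0.25, -0.81),
    c("risk_adequacy",       "B", 0.26, -0.96, 0.88, 0.23, -0.85),
    c("ethical_soundness",   "B", 0.22, -0.84, 0.83, 0.18, -0.69),
    c("legal_conformity",    "B", 0.13, -0.89, 0.86, 0.12, -0.77),
    c("content_validity",    "B", 0.23, -0.94, 0.94, 0.21, -0.88),
    c("technical_adequacy",  "B", 0.44, -0.79, 0.83, 0.37, -0.65),
    c("usability",           "B", 0.35, -0.83, 0.84, 0.30, -0.70),
    c("resource_efficiency", "B", 0.39, -0.59, 0.71, 0.28, -0.42),
    c("transparency",        "B", 0.37, -0.73, 0.79, 0.29, -0.58))
  out <- data.frame(attribute = x[, 1], group = x[, 2], stringsAsFactors = FALSE)
  out[c("better", "worse", "importance", "better_weighted", "worse_weighted")] <-
    lapply(3:7, function(j) as.numeric(x[, j]))
  out
}

# published per-group ranking table: d, alpha (integer degrees), f, rank
published_ranking <- function() {
  x <- rbind(
    c("practicality",        "A", 0.32, 51, 0.36, 4),
    c("risk_adequacy",       "A", 0.29, 53, 0.34, 3),
    c("ethical_soundness",   "A", 0.35, 38, 0.38, 5),
    c("legal_conformity",    "A", 0.23, 37, 0.26, 1),
    c("content_validity",    "A", 0.24, 59, 0.29, 2),
    c("technical_adequacy",  "A", 0.51, 48, 0.55, 8),
    c("usability",           "A", 0.45, 43, 0.48, 6),
    c("resource_efficiency", "A", 0.70, 26, 0.72, 9),
    c("transparency",        "A", 0.46, 34, 0.49, 7),
    c("practicality",        "B", 0.31, 52, 0.35, 4),
    c("risk_adequacy",       "B", 0.27, 56, 0.32, 3),
    c("ethical_soundness",   "B", 0.35, 30, 0.38, 5),
    c("legal_conformity",    "B", 0.26, 27, 0.28, 1),
    c("content_validity",    "B", 0.24, 61, 0.29, 2),
    c("technical_adequacy",  "B", 0.50, 47, 0.54, 8),
    c("usability",           "B", 0.42, 45, 0.46, 6),
    c("resource_efficiency", "B", 0.64, 26, 0.66, 9),
    c("transparency",        "B", 0.51, 34, 0.54, 7))
  out <- data.frame(attribute = x[, 1], group = x[, 2], stringsAsFactors = FALSE)
  out[c("distance", "angle", "coefficient", "rank")] <-
    lapply(3:6, function(j) as.numeric(x[, j]))
  out
}

# ranking of a group's counts+importance through the package pipeline
rank_reference_group <- function(group) {
  ref <- ref_counts(group)
  ind <- timko_indices(ref, importance = ref$importance)
  rank_attributes(data.frame(attribute = ind$attribute,
                             worse = ind$worse_weighted,
                             better = ind$better_weighted))
}

# independent Pearson chi-square oracle: explicit (O - E)^2 / E summation
chisq_oracle <- function(m) {
  e <- outer(rowSums(m), colSums(m)) / sum(m)
  stat <- sum((m - e)^2 / e)
  dof <- (nrow(m) - 1) * (ncol(m) - 1)
  list(statistic = stat, dof = dof,
       p_value = stats::pchisq(stat, dof, lower.tail = FALSE))
}

# tiny long-format survey data.frame, one attribute, constant answers
constant_survey_df <- function(n, functional = "expected",
                               dysfunctional = "dislike",
                               relevance = "very_important",
                               attribute = "x") {
  data.frame(respondent = sprintf("r%03d", seq_len(n)), attribute = attribute,
             functional = functional, dysfunctional = dysfunctional,
             relevance = relevance, stringsAsFactors = FALSE)
}

# random valid category count vector (possibly with ties)
random_counts <- function(max_n = 30) {
  repeat {
    ct <- stats::setNames(sample(0:max_n, 6, replace = TRUE), kano_categories())
    if (sum(ct) > 0) return(ct)
  }
}
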