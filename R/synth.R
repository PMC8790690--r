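#' Attribute response profile for the synthetic generator
#'
#' A profile gives, for one attribute, the probability of every complete
#' (functional, dysfunctional) answer pair on the 5 x 5 grid (plus an
#' optional mass on "pair incomplete"), and the distribution of the
#' 5-level relevance answer (plus optional missing mass). [generate_survey()]
#' draws each respondent's answers independently from these tables.
#'
#' @param attribute Attribute id.
#' @param pair_probs 5 x 5 numeric matrix of pair probabilities (rows =
#'   functional, columns = dysfunctional, in canonical level order); the
#'   grid plus `missing_pair` must sum to 1. Default: uniform over the
#'   25 cells.
#' @param relevance_probs Length-5 probability vector over the relevance
#'   levels; with `missing_relevance` it must sum to 1. Default: uniform.
#' @param missing_pair Probability that the pair is incomplete (one half,
#'   chosen at random, is absent). Default 0.
#' @param missing_relevance Probability the relevance answer is absent.
#'   Default 0.
#' @return Object of class `attribute_profile`.
#' @export
attribute_profile <- function(attribute,
                              pair_probs = matrix((1 - missing_pair) / 25, 5, 5),
                              relevance_probs = rep((1 - missing_relevance) / 5, 5),
                              missing_pair = 0, missing_relevance = 0) {
  pair_probs <- as.matrix(pair_probs)
  stopifnot(all(dim(pair_probs) == c(5L, 5L)), length(relevance_probs) == 5L)
  stopifnot_scalar_prob(missing_pair, "missing_pair")
  stopifnot_scalar_prob(missing_relevance, "missing_relevance")
  if (any(pair_probs < 0) || any(relevance_probs < 0)) {
    stop("probabilities must be non-negative", call. = FALSE)
  }
  if (abs(sum(pair_probs) + missing_pair - 1) > 1e-9) {
    stop("pair_probs plus missing_pair must sum to 1", call. = FALSE)
  }
  if (abs(sum(relevance_probs) + missing_relevance - 1) > 1e-9) {
    stop("relevance_probs plus missing_relevance must sum to 1", call. = FALSE)
  }
  lv <- kano_levels("functional")
  dimnames(pair_probs) <- list(functional = lv, dysfunctional = lv)
  structure(list(attribute = as.character(attribute), pair_probs = pair_probs,
                 relevance_probs = stats::setNames(as.numeric(relevance_probs),
                                                   kano_levels("relevance")),
                 missing_pair = missing_pair,
                 missing_relevance = missing_relevance),
            class = "attribute_profile")
}

#' @export
print.attribute_profile <- function(x, ...) {
  cat(sprintf("Response profile for %s (missing pair %.3g, missing relevance %.3g)\n",
              sQuote(x$attribute), x$missing_pair, x$missing_relevance))
  cat("expected category distribution:\n")
  cats <- categorize_pair(rep(rownames(x$pair_probs), each = 5),
                          rep(colnames(x$pair_probs), times = 5))
  print(round(tapply(as.vector(t(x$pair_probs)), cats, sum), 4))
  invisible(x)
}

#' Generate a synthetic survey panel
#'
#' Draws a complete panel of respondents: for each attribute, every
#' respondent independently draws one functional/dysfunctional answer
#' pair and one relevance answer from the attribute's profile.
#' Respondent-level strata labels (e.g. gender) are drawn from optional
#' categorical distributions. Identical seeds give identical datasets.
#'
#' The generator models answers as independent across respondents and
#' across attributes; an optional `consistency` parameter makes a
#' fraction of respondents answer all attributes from a single latent
#' profile draw per respondent (a stress hook for correlated panels,
#' default off).
#'
#' @param profiles List of [attribute_profile] objects.
#' @param n_respondents Number of respondents, >= 1.
#' @param seed Integer seed (the caller's RNG state is preserved).
#' @param strata_spec Optional named list: each element a named
#'   probability vector over the values of one respondent-level stratum.
#' @param consistency Probability in \[0, 1\] that a respondent reuses one
#'   latent pair-cell rank across all attributes (inverse-CDF coupling);
#'   0 (default) draws every attribute independently.
#' @return A [kano_survey] with respondents `r001`, `r002`, ...
#' @examples
#' prof <- attribute_profile("x")
#' s <- generate_survey(list(prof), n_respondents = 5, seed = 1)
#' n_respondents(s)
#' @export
generate_survey <- function(profiles, n_respondents, seed, strata_spec = NULL,
                            consistency = 0) {
  if (inherits(profiles, "attribute_profile")) profiles <- list(profiles)
  stopifnot(length(profiles) >= 1L,
            all(vapply(profiles, inherits, logical(1), "attribute_profile")))
  if (!is.numeric(n_respondents) || n_respondents < 1) {
    stop("'n_respondents' must be >= 1", call. = FALSE)
  }
  stopifnot_scalar_prob(consistency, "consistency")
  n <- as.integer(n_respondents)
  ids <- sprintf("r%0*d", max(3L, nchar(n)), seq_len(n))
  lv <- kano_levels("functional")
  with_seed(seed, {
    # latent uniform per respondent drives the consistency coupling
    u_latent <- stats::runif(n)
    consistent <- stats::runif(n) < consistency
    blocks <- lapply(profiles, function(prof) {
      p <- as.vector(prof$pair_probs)      # column-major: dysf varies slowest
      cdf <- cumsum(p / sum(p))
      u <- stats::runif(n)
      u[consistent] <- u_latent[consistent]
      cell <- findInterval(u, cdf, rightmost.closed = TRUE) + 1L
      f <- lv[(cell - 1L) %% 5L + 1L]
      d <- lv[(cell - 1L) %/% 5L + 1L]
      if (prof$missing_pair > 0) {
        drop <- stats::runif(n) < prof$missing_pair
        half <- stats::runif(n) < 0.5
        f[drop & half] <- NA
        d[drop & !half] <- NA
      }
      r <- sample(c(kano_levels("relevance"), NA), n, replace = TRUE,
                  prob = c(prof$relevance_probs, prof$missing_relevance))
      data.frame(respondent = ids, attribute = prof$attribute,
                 functional = f, dysfunctional = d, relevance = r,
                 stringsAsFactors = FALSE)
    })
    long <- do.call(rbind, blocks)
    if (!is.null(strata_spec)) {
      for (label in names(strata_spec)) {
        p <- strata_spec[[label]]
        vals <- sample(names(p), n, replace = TRUE, prob = p)
        long[[label]] <- vals[match(long$respondent, ids)]
      }
    }
    kano_survey(long, attributes = vapply(profiles, `[[`, character(1), "attribute"))
  })
}

#' Calibrate a profile from category counts and importance
#'
#' Inverse calibration for simulation studies: builds a profile whose
#' induced category distribution equals `counts / n_complete` exactly, by
#' placing each category's probability mass on one canonical
#' representative pair (A -> (delighted, expected), P -> (delighted,
#' dislike), M -> (expected, dislike), I -> (neutral, neutral),
#' R -> (dislike, expected), Q -> (delighted, delighted)), and whose
#' expected mean importance equals the given value, by splitting the
#' relevance mass between the two grid levels bracketing it.
#'
#' @param counts A `kano_counts` with `n_complete > 0`.
#' @param importance Target mean importance in \[0, 1\].
#' @param importance_map Relevance-level grid (see [kano_importance_map()]);
#'   must be the default uniform grid for the two-point bracket to be exact.
#' @return An [attribute_profile].
#' @examples
#' x <- kano_counts("legal_conformity", c(M = 148, P = 27, A = 2, I = 13, Q = 1))
#' prof <- profile_from_counts(x, importance = 0.89)
#' @export
profile_from_counts <- function(counts, importance,
                                importance_map = kano_importance_map()) {
  stopifnot(inherits(counts, "kano_counts"))
  if (counts$n_complete == 0L) stop("no categorizable pairs", call. = FALSE)
  stopifnot_scalar_prob(importance, "importance")
  rep_pairs <- list(A = c("delighted", "expected"), P = c("delighted", "dislike"),
                    M = c("expected", "dislike"), I = c("neutral", "neutral"),
                    R = c("dislike", "expected"), Q = c("delighted", "delighted"))
  lv <- kano_levels("functional")
  pp <- matrix(0, 5, 5, dimnames = list(lv, lv))
  prop <- counts$counts / counts$n_complete
  for (cat in names(rep_pairs)) {
    pr <- rep_pairs[[cat]]
    pp[pr[1L], pr[2L]] <- pp[pr[1L], pr[2L]] + prop[[cat]]
  }
  # two adjacent grid levels bracketing the target mean, mass split linearly
  grid <- sort(importance_map, decreasing = TRUE)
  hi <- max(which(grid >= importance - 1e-12))
  lo <- min(hi + 1L, length(grid))
  rp <- stats::setNames(numeric(5), kano_levels("relevance"))
  if (abs(grid[hi] - importance) < 1e-12 || lo == hi) {
    rp[names(grid)[hi]] <- 1
  } else {
    w <- (importance - grid[lo]) / (grid[hi] - grid[lo])
    rp[names(grid)[hi]] <- w
    rp[names(grid)[lo]] <- 1 - w
  }
  attribute_profile(counts$attribute, pair_probs = pp, relevance_probs = rp)
}

#' Read or write profiles as plain-text tables
#'
#' Profiles serialize to two CSV tables: pair-probability rows
#' (`attribute, functional, dysfunctional, prob`, omitting zero cells) and
#' relevance rows (`attribute, level, prob`). `write_profiles()` writes
#' both into one file separated by a `# relevance` marker line;
#' `read_profiles()` reads it back.
#'
#' @param profiles List of [attribute_profile] objects.
#' @param path File path.
#' @return `read_profiles()`: list of profiles; `write_profiles()`:
#'   `path`, invisibly.
#' @export
write_profiles <- function(profiles, path) {
  if (inherits(profiles, "attribute_profile")) profiles <- list(profiles)
  pair_rows <- do.call(rbind, lapply(profiles, function(p) {
    idx <- which(p$pair_probs > 0, arr.ind = TRUE)
    data.frame(attribute = p$attribute,
               functional = rownames(p$pair_probs)[idx[, 1L]],
               dysfunctional = colnames(p$pair_probs)[idx[, 2L]],
               prob = p$pair_probs[idx], stringsAsFactors = FALSE)
  }))
  rel_rows <- do.call(rbind, lapply(profiles, function(p) {
    data.frame(attribute = p$attribute, level = names(p$relevance_probs),
               prob = unname(p$relevance_probs), stringsAsFactors = FALSE)
  }))
  con <- file(path, "w")
  on.exit(close(con))
  utils::write.csv(pair_rows, con, row.names = FALSE)
  writeLines("# relevance", con)
  utils::write.csv(rel_rows, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_profiles
#' @export
read_profiles <- function(path) {
  lines <- readLines(path)
  sep <- which(lines == "# relevance")
  if (!length(sep)) stop("malformed profile file: no '# relevance' marker",
                         call. = FALSE)
  pair_rows <- utils::read.csv(textConnection(lines[seq_len(sep - 1L)]),
                               stringsAsFactors = FALSE)
  rel_rows <- utils::read.csv(textConnection(lines[-seq_len(sep)]),
                              stringsAsFactors = FALSE)
  lv <- kano_levels("functional")
  lapply(unique(pair_rows$attribute), function(a) {
    pp <- matrix(0, 5, 5, dimnames = list(lv, lv))
    sub <- pair_rows[pair_rows$attribute == a, ]
    pp[cbind(sub$functional, sub$dysfunctional)] <- sub$prob
    rsub <- rel_rows[rel_rows$attribute == a, ]
    rp <- stats::setNames(rsub$prob[match(kano_levels("relevance"), rsub$level)],
                          kano_levels("relevance"))
    attribute_profile(a, pair_probs = pp, relevance_probs = rp,
                      missing_pair = max(0, 1 - sum(pp)),
                      missing_relevance = max(0, 1 - sum(rp)))
  })
}
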