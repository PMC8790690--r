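# the calibrated multinomial panel generator

test_that("degenerate profiles generate constant panels", {
  pp <- matrix(0, 5, 5); pp[2, 5] <- 1  # (expected, dislike) -> M
  prof <- attribute_profile("x", pair_probs = pp,
                            relevance_probs = c(1, 0, 0, 0, 0))
  s <- generate_survey(list(prof), 50, seed = 1)
  ct <- tabulate_attribute(s, "x")
  expect_equal(unname(ct$counts["M"]), 50L)
  expect_equal(importance_score(s, "x"), 1)
})

test_that("identical seeds give byte-identical canonical CSVs, other seeds differ", {
  prof <- attribute_profile("x", missing_pair = 0.1)
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  f3 <- withr::local_tempfile(fileext = ".csv")
  write_survey(generate_survey(list(prof), 30, seed = 9), f1)
  write_survey(generate_survey(list(prof), 30, seed = 9), f2)
  write_survey(generate_survey(list(prof), 30, seed = 10), f3)
  expect_identical(readLines(f1), readLines(f2))
  expect_false(identical(readLines(f1), readLines(f3)))
})

test_that("generation does not disturb the caller's RNG stream", {
  set.seed(123); before <- stats::runif(1)
  set.seed(123); invisible(generate_survey(list(attribute_profile("x")), 5, seed = 1))
  expect_identical(stats::runif(1), before)
})

test_that("profile probabilities are validated", {
  expect_error(attribute_profile("x", pair_probs = matrix(1 / 20, 5, 5)),
               "sum to 1")
  expect_error(attribute_profile("x", relevance_probs = c(2, 0, 0, 0, -1)),
               "non-negative")
  expect_error(generate_survey(list(attribute_profile("x")), 0, seed = 1), ">= 1")
})

test_that("inverse calibration reproduces category proportions exactly in expectation", {
  ct <- kano_counts("legal_conformity",
                    c(M = 148, P = 27, A = 2, I = 13, R = 0, Q = 1))
  prof <- profile_from_counts(ct, importance = 0.89)
  # analytic expectation: category mass of the pair table equals counts/n
  lv <- kano_levels("functional")
  cats <- categorize_pair(rep(lv, times = 5), rep(lv, each = 5))
  mass <- tapply(as.vector(prof$pair_probs), cats, sum)
  expect_equal(as.numeric(mass[c("M", "P", "A", "I", "R", "Q")]),
               as.numeric(ct$counts[c("M", "P", "A", "I", "R", "Q")] / ct$n_complete))
  # relevance mean hits the target
  expect_equal(sum(prof$relevance_probs * kano_importance_map()), 0.89)

  # concentrated count with full importance -> degenerate profile
  prof_m <- profile_from_counts(kano_counts("m", c(M = 10)), 1)
  expect_equal(unname(prof_m$pair_probs["expected", "dislike"]), 1)
  expect_equal(unname(prof_m$relevance_probs["very_important"]), 1)

  # mean 0.875 splits mass over the top two relevance levels
  prof_875 <- profile_from_counts(kano_counts("m", c(M = 10)), 0.875)
  expect_equal(unname(prof_875$relevance_probs[c("very_important", "important")]),
               c(0.5, 0.5))
  expect_equal(sum(prof_875$relevance_probs), 1)

  expect_error(profile_from_counts(ct, importance = 1.2), "importance")
})

test_that("profiles round-trip through the plain-text config format", {
  ct <- kano_counts("a", c(M = 5, P = 3, I = 2))
  profs <- list(profile_from_counts(ct, 0.8),
                attribute_profile("b", missing_pair = 0.2,
                                  pair_probs = matrix(0.8 / 25, 5, 5)))
  path <- withr::local_tempfile(fileext = ".csv")
  write_profiles(profs, path)
  back <- read_profiles(path)
  for (i in 1:2) {
    expect_equal(back[[i]]$attribute, profs[[i]]$attribute)
    expect_equal(back[[i]]$pair_probs, profs[[i]]$pair_probs)
    expect_equal(back[[i]]$relevance_probs, profs[[i]]$relevance_probs)
    expect_equal(back[[i]]$missing_pair, profs[[i]]$missing_pair)
  }
})

test_that("generated panels match calibrated counts within multinomial envelopes", {
  ref <- ref_counts("A")
  profiles <- lapply(seq_len(nrow(ref)), function(i) {
    profile_from_counts(kano_counts(ref$attribute[i],
                                    ref[i, c("M", "P", "A", "I", "R", "Q")]),
                        ref$importance[i])
  })
  s <- generate_survey(profiles, 191, seed = 20)
  for (i in seq_len(nrow(ref))) {
    ct <- tabulate_attribute(s, ref$attribute[i])
    n <- ct$n_complete
    for (cat in c("M", "P", "A", "I", "R", "Q")) {
      p <- ref[i, cat] / sum(ref[i, c("M", "P", "A", "I", "R", "Q")])
      # 99% binomial envelope around the calibrated expectation
      lim <- stats::qbinom(c(0.005, 0.995), n, p)
      expect_gte(ct$counts[[cat]], lim[1])
      expect_lte(ct$counts[[cat]], lim[2])
    }
  }
})

test_that("indices on generated panels converge to the profile's analytic values", {
  ct <- kano_counts("x", c(M = 120, P = 40, A = 20, I = 15, R = 3, Q = 2))
  prof <- profile_from_counts(ct, importance = 0.85)
  b_true <- better_index(ct); w_true <- worse_index(ct)
  errs <- sapply(c(100, 1000, 10000), function(n) {
    s <- generate_survey(list(prof), n, seed = 31)
    tab <- tabulate_attribute(s, "x")
    c(abs(better_index(tab) - b_true), abs(worse_index(tab) - w_true))
  })
  # errors shrink within ~4 binomial standard errors of each n
  bound <- 4 * sqrt(0.25 / c(100, 1000, 10000))
  expect_true(all(errs[1, ] <= bound))
  expect_true(all(errs[2, ] <= bound))
  # and the largest n is the most accurate overall
  expect_lt(max(errs[, 3]), max(errs[, 1]))
})

test_that("the consistency hook couples answers across attributes", {
  pp <- matrix(0, 5, 5); pp[2, 5] <- 0.5; pp[1, 2] <- 0.5  # M or A, same CDF rank
  profs <- list(attribute_profile("u", pair_probs = pp),
                attribute_profile("v", pair_probs = pp))
  s <- generate_survey(profs, 200, seed = 8, consistency = 1)
  cu <- categorize_pair(s$functional[s$attribute == "u"],
                        s$dysfunctional[s$attribute == "u"])
  cv <- categorize_pair(s$functional[s$attribute == "v"],
                        s$dysfunctional[s$attribute == "v"])
  expect_equal(as.character(cu), as.character(cv))  # fully coupled
  s0 <- generate_survey(profs, 200, seed = 8, consistency = 0)
  c0u <- categorize_pair(s0$functional[s0$attribute == "u"],
                         s0$dysfunctional[s0$attribute == "u"])
  c0v <- categorize_pair(s0$functional[s0$attribute == "v"],
                         s0$dysfunctional[s0$attribute == "v"])
  expect_false(all(as.character(c0u) == as.character(c0v)))
})
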