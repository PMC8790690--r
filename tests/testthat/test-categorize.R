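# the answer-pair matrix and the two category-assignment rules

test_that("enumerating all 25 complete pairs reproduces the categorization matrix", {
  lv <- kano_levels("functional")
  grid <- expand.grid(functional = lv, dysfunctional = lv,
                      stringsAsFactors = FALSE)
  cats <- categorize_pair(grid$functional, grid$dysfunctional)
  # category multiset over the whole grid
  expect_equal(as.vector(table(cats)[c("Q", "A", "P", "M", "I", "R")]),
               c(4L, 3L, 1L, 3L, 7L, 7L))
  # spot cells, including each distinct category
  expect_equal(as.character(categorize_pair("delighted", "dislike")), "P")
  expect_equal(as.character(categorize_pair("expected", "dislike")), "M")
  expect_equal(as.character(categorize_pair("delighted", "delighted")), "Q")
  expect_equal(as.character(categorize_pair("delighted", "expected")), "A")
  expect_equal(as.character(categorize_pair("neutral", "neutral")), "I")
  expect_equal(as.character(categorize_pair("dislike", "expected")), "R")
  # diagonal symmetry of contradictions: mirrored extreme pairs are R vs P
  expect_equal(as.character(categorize_pair("dislike", "delighted")), "R")
})

test_that("pairs with an absent half are never categorized", {
  expect_true(is.na(categorize_pair("neutral", NA)))
  expect_true(is.na(categorize_pair(NA, "dislike")))
  expect_true(is.na(categorize_pair(NA, NA)))
})

test_that("tabulate_attribute counts complete pairs and books missing ones", {
  s <- kano_survey(constant_survey_df(3))
  ct <- tabulate_attribute(s, "x")
  expect_equal(unname(ct$counts["M"]), 3L)
  expect_equal(sum(ct$counts), ct$n_complete)
  expect_equal(ct$n_missing, 0L)

  df <- constant_survey_df(10)
  df$functional[4] <- NA
  ct2 <- tabulate_attribute(kano_survey(df), "x")
  expect_equal(ct2$n_complete, 9L)
  expect_equal(ct2$n_missing, 1L)

  expect_error(tabulate_attribute(s, "zzz"), "no records")

  # conservation holds on arbitrary generated panels with missingness
  for (seed in 1:4) {
    prof <- attribute_profile("g", missing_pair = 0.2)
    sg <- generate_survey(list(prof), 60, seed = seed)
    ctg <- tabulate_attribute(sg, "g")
    expect_equal(sum(ctg$counts), ctg$n_complete)
    expect_equal(ctg$n_complete + ctg$n_missing, 60L)
  }
})

test_that("tabulating the reference count profiles reproduces the published tallies", {
  ref <- ref_counts("A")
  legal <- ref[ref$attribute == "legal_conformity", ]
  # rebuild a panel carrying exactly that category profile and re-tally it
  cats <- rep(c("M", "P", "A", "I", "R", "Q"),
              times = unlist(legal[c("M", "P", "A", "I", "R", "Q")]))
  rep_pairs <- list(A = c("delighted", "expected"), P = c("delighted", "dislike"),
                    M = c("expected", "dislike"), I = c("neutral", "neutral"),
                    R = c("dislike", "expected"), Q = c("delighted", "delighted"))
  df <- data.frame(respondent = sprintf("r%03d", seq_along(cats)),
                   attribute = "legal_conformity",
                   functional = vapply(rep_pairs[cats], `[`, "", 1),
                   dysfunctional = vapply(rep_pairs[cats], `[`, "", 2),
                   relevance = "very_important", stringsAsFactors = FALSE)
  ct <- tabulate_attribute(kano_survey(df), "legal_conformity")
  expect_equal(unname(ct$counts[c("M", "P", "A", "I", "R", "Q")]),
               c(148L, 27L, 2L, 13L, 0L, 1L))
  expect_equal(assign_mode(ct), "M")
})

test_that("assignment rules pick the documented categories, with precedence on ties", {
  res_eff <- kano_counts("resource_efficiency",
                         c(M = 63, P = 40, A = 45, I = 40, R = 1, Q = 2))
  expect_equal(assign_mode(res_eff), "M")
  expect_equal(assign_ifthen(res_eff), "M")

  tie <- kano_counts("t", c(A = 5, P = 5))
  expect_equal(assign_mode(tie), "P")  # M > P > A precedence
  expect_equal(assign_ifthen(tie), "P")

  # if-then can disagree with the mode rule when the global argmax is
  # on the losing side of the inequality
  split <- kano_counts("s", c(P = 30, A = 25, M = 10, I = 40, R = 5, Q = 2))
  expect_equal(assign_mode(split), "I")
  expect_equal(assign_ifthen(split), "P")  # 65 > 47

  only_i <- kano_counts("i", c(I = 10))
  expect_equal(assign_ifthen(only_i), "I")

  empty <- kano_counts("e", c(A = 0))
  expect_error(assign_mode(empty), "no categorizable")
  expect_error(assign_ifthen(empty), "no categorizable")
})

test_that("if-then equals the mode rule whenever the global argmax lies on the winning side", {
  precedence <- c("M", "P", "A", "I", "R", "Q")
  oracle_ifthen <- function(ct) {
    # brute-force restatement of the rule, independent of the implementation
    ord <- ct[precedence]
    win <- if (sum(ct[c("P", "A", "M")]) > sum(ct[c("I", "R", "Q")])) {
      c("P", "A", "M")
    } else if (sum(ct[c("P", "A", "M")]) < sum(ct[c("I", "R", "Q")])) {
      c("I", "R", "Q")
    } else {
      precedence
    }
    cand <- names(ord)[names(ord) %in% win]
    cand[which.max(ord[cand])]
  }
  set.seed(42)
  for (i in 1:200) {
    ct <- random_counts()
    kc <- kano_counts("r", ct)
    expect_equal(assign_ifthen(kc), oracle_ifthen(ct))
    mode_cat <- assign_mode(kc)
    winning <- if (sum(ct[c("P", "A", "M")]) >= sum(ct[c("I", "R", "Q")])) {
      c("P", "A", "M")
    } else {
      c("I", "R", "Q")
    }
    if (mode_cat %in% winning) expect_equal(assign_ifthen(kc), mode_cat)
  }
})
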