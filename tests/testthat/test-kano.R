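# the kano() fit object, its methods, and the reporting pipeline

make_fit <- function(n = 120, seed = 13) {
  ref <- ref_counts("A")[1:3, ]
  profiles <- lapply(seq_len(nrow(ref)), function(i) {
    profile_from_counts(kano_counts(ref$attribute[i],
                                    ref[i, c("M", "P", "A", "I", "R", "Q")]),
                        ref$importance[i])
  })
  kano(generate_survey(profiles, n, seed = seed))
}

test_that("kano() assembles counts, rules and indices into one coherent table", {
  fit <- make_fit()
  expect_s3_class(fit, "kano")
  t <- fit$table
  expect_equal(t$attribute, ref_counts("A")$attribute[1:3])
  expect_equal(rowSums(t[kano_categories()]), t$n_complete,
               ignore_attr = TRUE)
  expect_true(all(t$better >= 0 & t$better <= 1))
  expect_true(all(t$worse >= -1 & t$worse <= 0))
  expect_equal(t$better_weighted, t$better * t$importance)
  # counts list is consistent with the table
  expect_equal(unname(fit$counts[[2]]$counts[["M"]]), t$M[2])
  cm <- coef(fit)
  expect_equal(dim(cm), c(3L, 5L))
  expect_equal(rownames(cm), t$attribute)
  expect_output(print(fit), "Kano evaluation")
  expect_output(print(summary(fit)), "ranking from the must-be corner")
})

test_that("simulate() redraws panels calibrated to the fit, reproducibly", {
  fit <- make_fit()
  sims <- simulate(fit, nsim = 2, seed = 5, n_respondents = 40)
  expect_length(sims, 2L)
  expect_equal(n_respondents(sims[[1]]), 40L)
  expect_equal(survey_attributes(sims[[1]]), fit$attributes)
  sims2 <- simulate(fit, nsim = 2, seed = 5, n_respondents = 40)
  expect_identical(as.data.frame(sims[[1]]), as.data.frame(sims2[[1]]))
})

test_that("quadrant assignment uses the 0.5 midlines with borderline labels", {
  expect_equal(quadrant_of(c(-0.8, -0.8, -0.2, -0.2), c(0.2, 0.8, 0.8, 0.2)),
               c("must-be", "one-dimensional", "attractive", "indifferent"))
  expect_equal(quadrant_of(-0.5, 0.2), "borderline")
  expect_equal(quadrant_of(-0.8, 0.5), "borderline")
})

test_that("after weighting, only resource efficiency leaves the must-be quadrant", {
  ref <- ref_counts("A")
  ind <- timko_indices(ref, importance = ref$importance)
  q_raw <- quadrant_of(ind$worse, ind$better)
  expect_true(all(q_raw == "must-be"))
  q_wt <- quadrant_of(ind$worse_weighted, ind$better_weighted)
  expect_equal(q_wt[ind$attribute == "resource_efficiency"], "indifferent")
  expect_true(all(q_wt[ind$attribute != "resource_efficiency"] == "must-be"))
})

test_that("run_pipeline produces per-group tables, comparisons and files", {
  ref <- ref_counts("A")
  profiles <- lapply(seq_len(nrow(ref)), function(i) {
    profile_from_counts(kano_counts(ref$attribute[i],
                                    ref[i, c("M", "P", "A", "I", "R", "Q")]),
                        ref$importance[i])
  })
  s <- generate_survey(profiles, 140, seed = 17)
  out <- withr::local_tempdir()
  res <- run_pipeline(s, output_dir = out, split = list(fraction = 0.5, seed = 3))
  expect_named(res$fits, c("A", "B"))
  expect_equal(sum(sapply(res$fits, `[[`, "n_respondents")), 140)
  expect_s3_class(res$rankings$A, "kano_ranking")
  expect_true(all(res$comparison$coordinate_distance$distance >= 0))
  for (f in c("counts_A.csv", "indices_B.csv", "ranking_A.csv",
              "ranking_A_full.csv", "quadrant_B.csv",
              "coordinate_distance.csv", "run_log.txt")) {
    expect_true(file.exists(file.path(out, f)), label = f)
  }
  # full-precision export round-trips into the identical ranking
  full <- read.csv(file.path(out, "ranking_A_full.csv"))
  rk2 <- rank_attributes(full[c("attribute", "worse", "better")])
  expect_equal(rk2$coefficient, res$rankings$A$coefficient)
  expect_equal(rk2$rank, res$rankings$A$rank)

  # explicit group column instead of a random split
  s2 <- generate_survey(profiles[1], 30, seed = 18,
                        strata_spec = list(grp = c(g1 = 0.5, g2 = 0.5)))
  res2 <- run_pipeline(s2, output_dir = NULL, split = "grp")
  expect_setequal(names(res2$fits), c("g1", "g2"))

  expect_error(run_pipeline(file.path(tempdir(), "missing.csv")), "not found")
})

test_that("the quadrant plot's data twin carries the exact plotted coordinates", {
  fit <- make_fit()
  img <- withr::local_tempfile(fileext = ".png")
  twin <- export_quadrant_plot(fit, img, annotate_importance_shift = TRUE)
  expect_true(file.exists(img))
  csv <- sub("\\.png$", ".csv", img)
  expect_true(file.exists(csv))
  back <- read.csv(csv)
  co <- kano_coordinates(fit)
  expect_equal(back$worse, co$worse)
  expect_equal(back$better, co$better)
  expect_true(all(c("worse_unweighted", "better_unweighted") %in% names(back)))
  # re-ranking the twin reproduces the fit's ranking at full precision
  expect_identical(rank_attributes(back[c("attribute", "worse", "better")])$rank,
                   rank_attributes(kano_coordinates(fit))$rank)

  twin2 <- export_quadrant_plot(fit, withr::local_tempfile(fileext = ".svg"))
  expect_false("worse_unweighted" %in% names(twin2))  # arrows off: no shift columns
})

test_that("plain-text key-value configs parse into pipeline settings", {
  cfg <- withr::local_tempfile(fileext = ".cfg")
  writeLines(c("input = survey.csv", "pov = must-be  # corner",
               "fraction = 0.5", "seed = 7",
               "schema.respondent = id", "schema.strata = gender, interest"),
             cfg)
  conf <- read_config(cfg)
  expect_equal(conf$input, "survey.csv")
  expect_equal(conf$pov, "must-be")
  expect_equal(conf$fraction, 0.5)
  expect_equal(conf$seed, 7)
  expect_equal(conf$schema$respondent, "id")
  expect_equal(conf$schema$strata, c("gender", "interest"))
  writeLines("oops", cfg)
  expect_error(read_config(cfg), "malformed")
})
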