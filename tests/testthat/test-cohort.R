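test_that("compareGroups is label-symmetric and reports panel-ordered rows", {
  mc <- syntheticFeatureCohort(n = 40, p = 8, shift = 1.5, seed = 61)
  cmp <- compareGroups(mc)
  expect_equal(cmp$marker, rownames(markerMatrix(mc)))
  swapped <- MarkerCohort(markerMatrix(mc),
                          group = ifelse(groupLabels(mc) == "case", "control", "case"))
  cmp2 <- compareGroups(swapped)
  expect_equal(cmp2$p_t, cmp$p_t, tolerance = 1e-12)
  expect_equal(cmp2$p_w, cmp$p_w, tolerance = 1e-12)
  expect_equal(cmp2$case_mean - cmp2$control_mean,
               -(cmp$case_mean - cmp$control_mean), tolerance = 1e-12)
})

test_that("compareGroups has power for large shifts and drops sparse markers", {
  mc <- syntheticFeatureCohort(n = 60, p = 5, shift = 3, seed = 62)
  cmp <- compareGroups(mc)
  expect_lt(cmp$p_t[cmp$marker == "f01"], 1e-3)
  expect_lt(cmp$p_w[cmp$marker == "f01"], 1e-3)
  # a marker with < 2 valid values in one group gets NA p-values
  M <- markerMatrix(mc)
  M["f02", groupLabels(mc) == "case"] <- NA
  M["f02", which(groupLabels(mc) == "case")[1]] <- 1
  cmp3 <- compareGroups(MarkerCohort(M, groupLabels(mc)))
  expect_true(is.na(cmp3$p_t[cmp3$marker == "f02"]))
  expect_equal(cmp3$case_n[cmp3$marker == "f02"], 1)
})

test_that("null p-values are approximately uniform", {
  set.seed(63)
  p <- replicate(400, {
    x <- rnorm(15); y <- rnorm(15)
    t.test(x, y)$p.value
  })
  # sanity for the harness route on a null cohort
  mc <- syntheticFeatureCohort(n = 30, p = 30, shift = 0, seed = 63)
  cmp <- compareGroups(mc)
  expect_gt(stats::ks.test(cmp$p_t, "punif")$p.value, 0.01)
  expect_gt(stats::ks.test(p, "punif")$p.value, 0.01)
})

test_that("every available backend ranks a single informative feature first", {
  mc <- syntheticFeatureCohort(n = 80, p = 10, shift = 2.5, seed = 64)
  for (b in setdiff(importanceBackends(), "attention_tabular")) {
    rep <- rankImportance(mc, backend = b, seed = 5)
    expect_equal(rep$ranking[1], "f01")
    expect_true(all(rep$scores >= 0))
    expect_setequal(rep$ranking, rownames(markerMatrix(mc)))
  }
})

test_that("an unavailable backend errors explicitly, never silently falls back", {
  mc <- syntheticFeatureCohort(n = 20, p = 4, seed = 65)
  expect_error(rankImportance(mc, backend = "attention_tabular"), "backend missing")
  expect_error(rankImportance(mc, backend = "bogus"), "'arg' should be one of")
})

test_that("importance is reproducible and robust to feature order", {
  mc <- syntheticFeatureCohort(n = 60, p = 10, shift = 2, seed = 66)
  M <- markerMatrix(mc)
  M["f02", ] <- M["f02", ] + 1.2 * (groupLabels(mc) == "case")  # second signal
  mc <- MarkerCohort(M, groupLabels(mc))
  r1 <- rankImportance(mc, "tree_shap", seed = 9)
  r2 <- rankImportance(mc, "tree_shap", seed = 9)
  expect_identical(r1$scores, r2$scores)
  shuf <- MarkerCohort(M[sample(nrow(M)), ], groupLabels(mc))
  r3 <- rankImportance(shuf, "tree_shap", seed = 9)
  expect_equal(utils::head(r3$ranking, 2), utils::head(r1$ranking, 2))
})

test_that("duplicated features split importance but the pair stays on top", {
  mc <- syntheticFeatureCohort(n = 80, p = 8, shift = 2.5, seed = 67)
  M <- markerMatrix(mc)
  M2 <- rbind(M, f01_copy = M["f01", ])
  rep2 <- rankImportance(MarkerCohort(M2, groupLabels(mc)), "tree_shap", seed = 4)
  # the duplicated pair carries the top of the ranking (documented tolerance:
  # the better-ranked copy is first, the union dominates everything else)
  pairScore <- sum(rep2$scores[c("f01", "f01_copy")])
  expect_gt(pairScore, max(rep2$scores[setdiff(names(rep2$scores),
                                               c("f01", "f01_copy"))]))
  expect_true(rep2$ranking[1] %in% c("f01", "f01_copy"))
})

test_that("undersampling stability counts top-k membership deterministically", {
  mc <- syntheticFeatureCohort(n = 90, p = 10, shift = 2.5, seed = 68)
  # make it imbalanced: 30 case / 60 control
  keep <- c(which(groupLabels(mc) == "case")[1:30],
            which(groupLabels(mc) == "control"))
  mc <- mc[, keep]
  rep1 <- undersampleStability(mc, "tree_shap", k = 3, repeats = 4, seed = 2)
  rep2 <- undersampleStability(mc, "tree_shap", k = 3, repeats = 4, seed = 2)
  expect_identical(rep1$repeats, rep2$repeats)
  expect_identical(rep1$topkFrequency, rep2$topkFrequency)
  expect_equal(unname(rep1$topkFrequency["f01"]), 4)
  expect_true(all(rep1$topkFrequency <= 4))
  # balanced input warns that repeats differ only by seed
  bal <- syntheticFeatureCohort(n = 40, p = 5, seed = 69)
  expect_warning(undersampleStability(bal, "tree_shap", repeats = 2, seed = 1),
                 "balanced")
})

test_that("covariates can be included as features", {
  mc <- syntheticFeatureCohort(n = 60, p = 6, shift = 0, seed = 70)
  cd <- data.frame(age = rnorm(60, 45, 6) + 5 * (groupLabels(mc) == "case"),
                   sex = sample(c("M", "F"), 60, TRUE),
                   bmi = rnorm(60, 24, 3))
  mc2 <- MarkerCohort(markerMatrix(mc), groupLabels(mc), covariates = cd)
  rep <- rankImportance(mc2, "tree_shap", includeCovariates = TRUE, seed = 3)
  expect_true(all(c("age", "sex", "bmi") %in% names(rep$scores)))
  expect_equal(rep$ranking[1], "age")
})
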