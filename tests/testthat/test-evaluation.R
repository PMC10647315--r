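# A shared small-but-full-course suite: 8 patients, 28 fractions, strong
# signal over modest noise. Cached because several tests inspect it.
suiteFixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sim <- strongCohort(n_patients = 10, n_fractions = 28,
                          n_features = 30, n_informative = 10, seed = 19)
      cache <<- list(sim = sim,
                     suite = runLOOCV(sim$table, seed = 0))
    }
    cache
  }
})

test_that("a 28-fraction course yields 27 experiments in 13/6/8 bands", {
  fx <- suiteFixture()
  e <- experimentSummary(fx$suite)
  expect_equal(nrow(e), 27)
  expect_equal(e$N, 2:28)
  bands <- accuracyByFraction(fx$suite)
  expect_equal(bands$n_experiments, c(13, 6, 8))
  expect_equal(sum(bands$n_experiments), 27)
})

test_that("strong-signal cohorts reach perfect RF accuracy and AUC at high N", {
  fx <- suiteFixture()
  e <- experimentSummary(fx$suite)
  late <- e[e$N >= 15, ]
  expect_true(all(late$rf_accuracy == 1))
  expect_true(all(late$rf_auc == 1))
  expect_true(all(late$sw_accuracy >= 0.7))
})

test_that("noise-free cohorts with no background drift separate perfectly", {
  # zero noise + zero slope spread: non-informative series are constant
  # (flagged, LRTF 0), responders sit at a clean margin on every
  # informative feature, so both classifiers are exact at every N >= 2
  sim <- simulateCohort(cohortConfig(
    n_patients = 10, n_fractions = 10, n_features = 30, n_informative = 10,
    effect_slope_mean = 0.3, effect_slope_sd = 0, noise_sd = 0, seed = 19))
  e <- experimentSummary(runLOOCV(sim$table, seed = 0))
  expect_equal(e$N, 2:10)
  expect_true(all(e$rf_accuracy == 1))
  expect_true(all(e$rf_auc == 1))
  expect_true(all(e$sw_accuracy == 1))
  expect_true(all(e$sw_auc == 1))
})

test_that("pooled AUC equals the rank-statistic U / (n1 n2) oracle", {
  fx <- suiteFixture()
  sc <- loocvScores(fx$suite)
  for (N in c(3, 10, 21)) {
    s <- sc[sc$N == N, ]
    resp <- s$label == "responder"
    r <- rank(s$rf_score)
    u <- sum(r[resp]) - sum(resp) * (sum(resp) + 1) / 2
    auc_oracle <- u / (sum(resp) * sum(!resp))
    expect_equal(experimentSummary(fx$suite)$rf_auc[
      experimentSummary(fx$suite)$N == N], auc_oracle, tolerance = 1e-12)
  }
})

test_that("consistency index equals an independent recount and groups at 0.8", {
  fx <- suiteFixture()
  ci <- consistencyIndex(fx$suite)
  sc <- loocvScores(fx$suite)
  for (p in ci$patient_id) {
    rows <- sc[sc$patient_id == p, ]
    expect_equal(ci$ci_all[ci$patient_id == p],
                 mean(rows$rf_correct, na.rm = TRUE), tolerance = 1e-15)
    expect_equal(ci$ci_window[ci$patient_id == p],
                 mean(rows$rf_correct[rows$N >= 15], na.rm = TRUE),
                 tolerance = 1e-15)
  }
  expect_equal(ci$group, ifelse(ci$ci_window > 0.8, "high", "low"))
  # late-course perfection exists in this fixture and lands in "high"
  stopifnot(any(ci$ci_window == 1))
  expect_true(all(ci$group[ci$ci_window == 1] == "high"))
})

test_that("band means equal a per-experiment recount", {
  fx <- suiteFixture()
  e <- experimentSummary(fx$suite)
  bands <- accuracyByFraction(fx$suite)
  expect_equal(bands$rf_accuracy[1], mean(e$rf_accuracy[e$N <= 14]))
  expect_equal(bands$sw_accuracy[2],
               mean(e$sw_accuracy[e$N >= 15 & e$N <= 20]))
  expect_equal(bands$mean_fit_err[3], mean(e$mean_fit_err[e$N >= 21]))
})

test_that("held-out predictions never use the held-out label", {
  sim <- strongCohort(n_patients = 10, n_fractions = 10, n_features = 20,
                      n_informative = 6, seed = 23)
  tab <- sim$table
  flipped <- tab
  lab <- responseLabels(tab)
  target <- names(lab)[1]
  lab2 <- lab
  lab2[target] <- setdiff(c("responder", "non-responder"), lab[target])
  S4Vectors::metadata(flipped)$labels <- lab2
  s1 <- runLOOCV(tab, fractions = c(5, 10), seed = 0)
  s2 <- runLOOCV(flipped, fractions = c(5, 10), seed = 0)
  sc1 <- loocvScores(s1); sc2 <- loocvScores(s2)
  expect_equal(sc1$rf_score[sc1$patient_id == target],
               sc2$rf_score[sc2$patient_id == target], tolerance = 1e-12)
  expect_equal(sc1$sw_score[sc1$patient_id == target],
               sc2$sw_score[sc2$patient_id == target], tolerance = 1e-12)
})

test_that("fit error declines with longer courses on noisy cohorts", {
  sim <- simulateCohort(cohortConfig(
    n_patients = 10, n_fractions = 28, n_features = 20, n_informative = 6,
    effect_slope_mean = 0.15, effect_slope_sd = 0.03, noise_sd = 0.4,
    seed = 55))
  norm5 <- zscoreNormalize(subsetFractions(sim$table, 5))
  norm28 <- zscoreNormalize(sim$table)
  err5 <- mean(fitCourse(norm5, 5)$err)
  err28 <- mean(fitCourse(norm28, 28)$err)
  # early windows leave the z-scored noise mostly in the residuals of a
  # 2-parameter line through few points scaled to unit variance
  expect_gt(err5, 0)
  expect_lt(err28, err5 * 2)
})

test_that("label permutation collapses AUC to chance", {
  sim <- strongCohort(n_patients = 10, n_fractions = 10, n_features = 20,
                      n_informative = 6, seed = 31)
  lab <- responseLabels(sim$table)
  set.seed(1)
  perm <- sim$table
  S4Vectors::metadata(perm)$labels <-
    structure(sample(unname(lab)), names = names(lab))
  s <- runLOOCV(perm, fractions = c(4, 7, 10), seed = 0)
  aucs <- experimentSummary(s)$rf_auc
  expect_true(mean(aucs) > 0.1 && mean(aucs) < 0.9)
})
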