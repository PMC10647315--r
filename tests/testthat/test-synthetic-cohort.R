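test_that("cohort dimensions and record counts follow the configuration", {
  sim <- simulateCohort(cohortConfig(n_patients = 6, n_fractions = 10,
                                     n_features = 25, n_informative = 8,
                                     seed = 3))
  expect_s4_class(sim$table, "LongitudinalFeatureTable")
  expect_equal(ncol(sim$table), 6 * 10)
  expect_equal(nrow(sim$table), 25)
  expect_equal(length(patientIds(sim$table)), 6)
  lab <- responseLabels(sim$table)
  expect_equal(sum(lab == "responder"), ceiling(6 * 14 / 30))
  expect_length(informativeFeatures(sim$truth), 8)
  expect_true(all(informativeFeatures(sim$truth) <= 25))
})

test_that("zero-noise series lie exactly on their ground-truth lines", {
  sim <- simulateCohort(cohortConfig(n_patients = 4, n_fractions = 8,
                                     n_features = 15, n_informative = 5, noise_sd = 0,
                                     outlier_rate = 0.1, seed = 11))
  v <- SummarizedExperiment::assay(sim$table)
  cd <- SummarizedExperiment::colData(sim$table)
  for (p in patientIds(sim$table)) {
    idx <- which(cd$patient_id == p)
    expected <- sim$truth@intercepts[, p] %o% rep(1, length(idx)) +
      sim$truth@slopes[, p] %o% cd$fraction[idx]
    expect_equal(unname(v[, idx]), unname(expected), tolerance = 1e-12)
  }
})

test_that("identical seeds give identical cohorts; different seeds differ", {
  cfg <- cohortConfig(n_patients = 5, n_fractions = 6, n_features = 10, n_informative = 4,
                      missing_rate = 0.1, outlier_rate = 0.05, seed = 42)
  a <- simulateCohort(cfg)
  b <- simulateCohort(cfg)
  expect_identical(SummarizedExperiment::assay(a$table),
                   SummarizedExperiment::assay(b$table))
  expect_identical(a$truth@slopes, b$truth@slopes)
  cfg2 <- cohortConfig(n_patients = 5, n_fractions = 6, n_features = 10, n_informative = 4,
                       missing_rate = 0.1, outlier_rate = 0.05, seed = 43)
  expect_false(identical(SummarizedExperiment::assay(a$table),
                         SummarizedExperiment::assay(simulateCohort(cfg2)$table)))
})

test_that("group slope difference of informative features matches the effect", {
  cfg <- cohortConfig(n_patients = 40, n_fractions = 10, n_features = 50,
                      n_informative = 20, effect_slope_mean = 0.12,
                      effect_slope_sd = 0.02, noise_sd = 0, seed = 9)
  sim <- simulateCohort(cfg)
  resp <- sim$truth@labels == "responder"
  inf <- informativeFeatures(sim$truth)
  d <- mean(trueSlopes(sim$truth)[inf, resp]) -
    mean(trueSlopes(sim$truth)[inf, !resp])
  expect_lt(abs(d - 0.12), 0.01)
  noninf <- setdiff(seq_len(50), inf)
  expect_lt(abs(mean(trueSlopes(sim$truth)[noninf, ])), 0.01)
})

test_that("missing scans thin the table but never below two per patient", {
  sim <- simulateCohort(cohortConfig(n_patients = 12, n_fractions = 20,
                                     n_features = 5, n_informative = 2, missing_rate = 0.3,
                                     seed = 5))
  n <- ncol(sim$table)
  expect_lt(n, 12 * 20)
  expect_gt(n, 12 * 20 * 0.5)
  expect_true(all(table(SummarizedExperiment::colData(sim$table)$patient_id) >= 2))
  # extreme missingness still leaves a valid table
  sim2 <- simulateCohort(cohortConfig(n_patients = 4, n_fractions = 5,
                                      n_features = 3, n_informative = 1, missing_rate = 0.95,
                                      seed = 5))
  expect_true(all(table(SummarizedExperiment::colData(sim2$table)$patient_id) >= 2))
})

test_that("outliers land at the line value +/- 10 * noise_sd", {
  cfg <- cohortConfig(n_patients = 3, n_fractions = 30, n_features = 40,
                      noise_sd = 0.5, outlier_rate = 0.1, seed = 21)
  sim <- simulateCohort(cfg)
  v <- SummarizedExperiment::assay(sim$table)
  cd <- SummarizedExperiment::colData(sim$table)
  hits <- 0
  for (p in patientIds(sim$table)) {
    idx <- which(cd$patient_id == p)
    line <- sim$truth@intercepts[, p] %o% rep(1, length(idx)) +
      sim$truth@slopes[, p] %o% cd$fraction[idx]
    dev <- abs(v[, idx] - line)
    hits <- hits + sum(abs(dev - 5) < 1e-9)  # 10 * 0.5
  }
  expect_gt(hits, 0.05 * length(v))
  expect_lt(hits, 0.15 * length(v))
})

test_that("invalid configurations name the offending field", {
  expect_error(cohortConfig(n_fractions = 1), "n_fractions")
  expect_error(cohortConfig(fraction_responders = 1.4),
               "fraction_responders")
  expect_error(cohortConfig(n_features = 10, n_informative = 11),
               "n_informative")
  expect_error(cohortConfig(missing_rate = 1), "missing_rate")
  expect_error(cohortConfig(noise_sd = -1), "noise_sd")
})
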