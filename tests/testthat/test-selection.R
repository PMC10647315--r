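test_that("U-test p-values match exhaustive enumeration for small groups", {
  # the canonical fully-separated 3 vs 3 case: U = 0, exact p = 2/20
  m <- matrix(c(1, 2, 3, 4, 5, 6), ncol = 1,
              dimnames = list(NULL, "f"))
  lab <- c(rep("responder", 3), rep("non-responder", 3))
  sel <- utestScreen(m, lab)
  expect_equal(unname(uTestPvalues(sel)), 0.1, tolerance = 1e-12)
  expect_length(sel@uRetained, 0)  # 0.1 is not < 0.05

  set.seed(15)
  for (i in 1:40) {
    n1 <- sample(2:5, 1); n2 <- sample(2:5, 1)
    x1 <- rnorm(n1); x2 <- rnorm(n2, 1)
    p_enum <- enumMannWhitneyP(x1, x2)
    p_pkg <- unname(uTestPvalues(utestScreen(
      matrix(c(x1, x2), dimnames = list(NULL, "f")),
      c(rep("responder", n1), rep("non-responder", n2)))))
    expect_equal(p_pkg, p_enum, tolerance = 1e-12)
    # and both agree with the standard exact test
    expect_equal(p_pkg, wilcox.test(x1, x2)$p.value, tolerance = 1e-12)
  }
})

test_that("identical groups give p = 1 and are never retained", {
  m <- matrix(rep(c(1, 2, 3, 4), 2), ncol = 1,
              dimnames = list(NULL, "f"))
  lab <- rep(c("responder", "non-responder"), each = 4)
  sel <- utestScreen(m, lab)
  expect_equal(unname(uTestPvalues(sel)), 1, tolerance = 1e-9)
  expect_length(sel@uRetained, 0)
})

test_that("single-class labels are a screening error", {
  m <- matrix(rnorm(8), 4, 2, dimnames = list(NULL, c("a", "b")))
  expect_error(utestScreen(m, rep("responder", 4)), "screening error")
})

test_that("the screen recovers informative features beyond chance", {
  hyper_p <- sapply(1:20, function(s) {
    sim <- simulateCohort(cohortConfig(
      n_patients = 30, n_fractions = 15, n_features = 120,
      n_informative = 40, effect_slope_mean = 0.15,
      effect_slope_sd = 0.03, noise_sd = 0.15, seed = 400 + s))
    norm <- zscoreNormalize(sim$table)
    fits <- fitCourse(norm, 15)
    M <- lrtfMatrix(fits, features = featureIds(featureSchema(sim$table)))
    sel <- utestScreen(M, responseLabels(sim$table))
    inf <- featureIds(featureSchema(sim$table))[
      informativeFeatures(sim$truth)]
    hits <- length(intersect(sel@uRetained, inf))
    # P(>= hits informative among the retained draw), hypergeometric
    phyper(hits - 1, length(inf), 120 - length(inf),
           length(sel@uRetained), lower.tail = FALSE)
  })
  expect_true(all(hyper_p < 0.01))
})

test_that("logistic LOOCV accuracy matches a glm oracle", {
  set.seed(44)
  for (i in 1:10) {
    n <- 16
    y <- rep(c(1, 0), each = n / 2)
    X <- cbind(sep = y * 3 + rnorm(n, 0, 0.2),     # strong feature
               weak = y * 0.4 + rnorm(n),          # weak feature
               null = rnorm(n))                    # label-independent
    oracle <- sapply(colnames(X), function(k) {
      mean(sapply(seq_len(n), function(j) {
        fit <- suppressWarnings(
          glm(y[-j] ~ X[-j, k], family = binomial))
        ph <- plogis(sum(coef(fit) * c(1, X[j, k])))
        (ph > 0.5) == (y[j] == 1)
      }))
    })
    got <- lrtrend:::.logisticLoocvAccuracy(X, y)
    expect_equal(unname(got), unname(oracle), tolerance = 1e-8)
  }
})

test_that("perfect separation is retained at any accuracy cut, no crash", {
  n <- 12
  lab <- rep(c("responder", "non-responder"), each = n / 2)
  M <- cbind(sep = c(rnorm(n / 2, 5, 0.1), rnorm(n / 2, -5, 0.1)),
             noise = rnorm(n))
  sel <- utestScreen(M, lab)
  expect_true("sep" %in% sel@uRetained)
  sel <- logisticScreen(M, lab, sel, minAccuracy = 1.0)
  expect_equal(sel@logitRetained, "sep")
  expect_equal(unname(sel@logitAccuracy["sep"]), 1.0)
})

test_that("label-independent features rarely pass the 0.7 accuracy cut", {
  set.seed(91)
  n <- 20
  lab01 <- rep(c(1, 0), each = n / 2)
  kept <- replicate(200, {
    x <- matrix(rnorm(n), dimnames = list(NULL, "f"))
    acc <- lrtrend:::.logisticLoocvAccuracy(x, lab01)
    acc >= 0.7
  })
  expect_lt(mean(kept), 0.15)
})

test_that("empty logistic survivor set warns and falls back to U set", {
  n <- 14
  lab <- rep(c("responder", "non-responder"), each = n / 2)
  set.seed(3)
  # modest feature: significant U-test but imperfect LOOCV
  M <- cbind(f1 = rep(c(1.5, 0), each = n / 2) + rnorm(n, 0, 1))
  sel <- utestScreen(M, lab, alpha = 0.5)
  expect_true(length(sel@uRetained) > 0)
  expect_warning(sel <- logisticScreen(M, lab, sel, minAccuracy = 1.0),
                 "fall back")
  expect_length(sel@logitRetained, 0)
  expect_equal(retainedFeatures(sel), sel@uRetained)
})

test_that("SW weight formula hits its endpoints and midpoint", {
  expect_equal(swWeight(0.05), 0)
  expect_equal(swWeight(0), 1)
  expect_equal(swWeight(0.025), 0.5)
})

test_that("a single retained feature reduces the SW score to oriented LRTF", {
  n <- 10
  lab <- rep(c("responder", "non-responder"), each = n / 2)
  M <- cbind(f = c(rnorm(n / 2, 3, 0.1), rnorm(n / 2, -3, 0.1)))
  sel <- utestScreen(M, lab)
  sw <- buildSWModel(M, lab, sel)
  expect_equal(unname(sw@signs["f"]), 1)  # responders trend higher
  expect_equal(swScore(sw, c(f = 2)), 2)
  expect_equal(swClassify(sw, c(f = 2)), "responder")
  expect_equal(swClassify(sw, c(f = -0.5)), "non-responder")
})

test_that("increasing an oriented LRTF never decreases the SW score", {
  set.seed(10)
  n <- 12
  lab <- rep(c("responder", "non-responder"), each = n / 2)
  M <- cbind(up = rep(c(2, -2), each = n / 2) + rnorm(n, 0, 0.3),
             down = rep(c(-2, 2), each = n / 2) + rnorm(n, 0, 0.3),
             mid = rep(c(1, -1), each = n / 2) + rnorm(n, 0, 0.5))
  sel <- utestScreen(M, lab)
  sw <- buildSWModel(M, lab, sel)
  x <- M[1, sel@uRetained]
  base <- swScore(sw, x)
  for (f in sw@features) {
    bump <- x
    bump[f] <- bump[f] + sw@signs[f] * 0.7  # move along the orientation
    expect_gte(swScore(sw, bump), base)
  }
})

test_that("duplicating a feature with identical p and values is score-neutral", {
  n <- 10
  lab <- rep(c("responder", "non-responder"), each = n / 2)
  set.seed(5)
  f <- rep(c(2, -2), each = n / 2) + rnorm(n, 0, 0.2)
  M1 <- cbind(a = f)
  M2 <- cbind(a = f, b = f)
  s1 <- buildSWModel(M1, lab, utestScreen(M1, lab))
  s2 <- buildSWModel(M2, lab, utestScreen(M2, lab))
  x1 <- c(a = 1.3); x2 <- c(a = 1.3, b = 1.3)
  expect_equal(swScore(s2, x2), swScore(s1, x1), tolerance = 1e-12)
})
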