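# Small cohorts reused across tests. Effect/noise chosen so informative
# features separate the groups cleanly (signal over the course is many times
# the per-fraction noise).

strongCohort <- function(n_patients = 10, n_fractions = 28, n_features = 40,
                         n_informative = 12, seed = 7, noise_sd = 0.1,
                         ...) {
  simulateCohort(cohortConfig(
    n_patients = n_patients, n_fractions = n_fractions,
    n_features = n_features, n_informative = n_informative,
    effect_slope_mean = 0.3, effect_slope_sd = 0.01, noise_sd = noise_sd,
    seed = seed, ...))
}

# Exhaustive two-sided Mann-Whitney p by enumerating all group assignments
# of the pooled sample (valid without ties): P(|U - n1 n2 / 2| >= |u_obs -
# n1 n2 / 2|) under the permutation null.
enumMannWhitneyP <- function(x1, x2) {
  pooled <- c(x1, x2)
  n1 <- length(x1)
  r <- rank(pooled)
  uOf <- function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2
  uobs <- uOf(seq_len(n1))
  combs <- utils::combn(length(pooled), n1)
  us <- apply(combs, 2, uOf)
  mu <- n1 * length(x2) / 2
  mean(abs(us - mu) >= abs(uobs - mu) - 1e-9)
}

# Independent normal-equations OLS solve.
olsOracle <- function(x, y) {
  X <- cbind(1, x)
  as.vector(solve(t(X) %*% X, t(X) %*% y))  # (intercept, slope)
}
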