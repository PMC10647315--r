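#' CohortConfig: parameters of the synthetic longitudinal cohort
#'
#' The simulator emulates a fractionated-radiotherapy cohort in which each
#' radiomic feature of each patient follows a linear trend over daily
#' fractions plus i.i.d. Gaussian noise. A subset of "informative" features
#' carries the group signal: in responders their slopes centre on
#' `effect_slope_mean`, in non-responders (and for all non-informative
#' features) on zero, both with spread `effect_slope_sd`, so the group
#' *difference* in trend, not the absolute slope, is what downstream analysis
#' must recover.
#'
#' Defaults mirror a 30-patient course of 28 daily fractions with 1688
#' features per scan and 14/30 responders.
#'
#' @slot n_patients,n_fractions,n_features cohort dimensions.
#' @slot fraction_responders proportion of responders in (0,1); the first
#'   `ceiling(n_patients * fraction_responders)` patients are labelled
#'   responders (deterministic, so label counts do not jitter across seeds).
#' @slot effect_slope_mean,effect_slope_sd responder-group trend (feature
#'   units per fraction) for informative features and its spread.
#' @slot n_informative number of features carrying group signal.
#' @slot noise_sd per-(patient, fraction, feature) additive Gaussian noise.
#' @slot missing_rate probability a fraction's scan is absent (at least two
#'   scans per patient are always kept).
#' @slot outlier_rate probability a value is replaced by a gross outlier at
#'   the ground-truth line value +/- 10 * noise_sd.
#' @slot seed integer RNG seed; identical seeds give identical cohorts.
#' @seealso [cohortConfig()], [simulateCohort()]
#' @exportClass CohortConfig
setClass("CohortConfig",
  representation(
    n_patients = "integer", n_fractions = "integer", n_features = "integer",
    fraction_responders = "numeric", effect_slope_mean = "numeric",
    effect_slope_sd = "numeric", n_informative = "integer",
    noise_sd = "numeric", missing_rate = "numeric", outlier_rate = "numeric",
    seed = "integer"
  )
)

setValidity("CohortConfig", function(object) {
  chk <- function(cond, field, what) if (cond) NULL else
    sprintf("invalid configuration: %s %s", field, what)
  msg <- c(
    chk(object@n_patients >= 2, "n_patients", "must be >= 2"),
    chk(object@n_fractions >= 2, "n_fractions", "must be >= 2"),
    chk(object@n_features >= 1, "n_features", "must be >= 1"),
    chk(object@fraction_responders >= 0 && object@fraction_responders <= 1,
        "fraction_responders", "must be in [0, 1]"),
    chk(object@n_informative >= 0 &&
          object@n_informative <= object@n_features,
        "n_informative", "must be in [0, n_features]"),
    chk(object@effect_slope_sd >= 0, "effect_slope_sd", "must be >= 0"),
    chk(object@noise_sd >= 0, "noise_sd", "must be >= 0"),
    chk(object@missing_rate >= 0 && object@missing_rate < 1, "missing_rate",
        "must be in [0, 1)"),
    chk(object@outlier_rate >= 0 && object@outlier_rate <= 1, "outlier_rate",
        "must be in [0, 1]")
  )
  if (length(msg)) msg else TRUE
})

#' Create a cohort configuration
#'
#' @param n_patients,n_fractions,n_features cohort dimensions.
#' @param fraction_responders proportion of responders.
#' @param effect_slope_mean,effect_slope_sd responder trend for informative
#'   features (feature units/fraction) and its spread.
#' @param n_informative number of informative features.
#' @param noise_sd additive Gaussian noise sd.
#' @param missing_rate,outlier_rate corruption rates in `[0, 1]`.
#' @param seed RNG seed.
#' @return A validated [CohortConfig-class].
#' @examples
#' cfg <- cohortConfig(n_patients = 6, n_features = 20, seed = 1)
#' @export
cohortConfig <- function(n_patients = 30, n_fractions = 28, n_features = 1688,
                         fraction_responders = 14 / 30,
                         effect_slope_mean = 0.05, effect_slope_sd = 0.02,
                         n_informative = 40, noise_sd = 0.2,
                         missing_rate = 0, outlier_rate = 0, seed = 1) {
  new("CohortConfig",
      n_patients = as.integer(n_patients),
      n_fractions = as.integer(n_fractions),
      n_features = as.integer(n_features),
      fraction_responders = as.numeric(fraction_responders),
      effect_slope_mean = as.numeric(effect_slope_mean),
      effect_slope_sd = as.numeric(effect_slope_sd),
      n_informative = as.integer(n_informative),
      noise_sd = as.numeric(noise_sd),
      missing_rate = as.numeric(missing_rate),
      outlier_rate = as.numeric(outlier_rate), seed = as.integer(seed))
}

setMethod("show", "CohortConfig", function(object) {
  cat("CohortConfig: ", object@n_patients, " patients x ",
      object@n_fractions, " fractions x ", object@n_features, " features\n",
      "  responders ", round(object@fraction_responders, 3),
      ", informative ", object@n_informative,
      ", effect ", object@effect_slope_mean, " +/- ", object@effect_slope_sd,
      ", noise ", object@noise_sd, ", seed ", object@seed, "\n", sep = "")
})

#' GroundTruth: the generating parameters of a simulated cohort
#'
#' @slot labels named character vector, patient -> responder status.
#' @slot slopes,intercepts numeric matrices (features x patients) of the true
#'   per-series line parameters.
#' @slot informative integer indices of the features carrying group signal.
#' @exportClass GroundTruth
setClass("GroundTruth",
  representation(labels = "character", slopes = "matrix",
                 intercepts = "matrix", informative = "integer"))

setMethod("show", "GroundTruth", function(object) {
  cat("GroundTruth: ", ncol(object@slopes), " patients, ",
      nrow(object@slopes), " features, ", length(object@informative),
      " informative\n", sep = "")
})

#' @describeIn GroundTruth-class Indices of informative features.
#' @param truth a `GroundTruth`.
#' @export
informativeFeatures <- function(truth) truth@informative

#' @describeIn GroundTruth-class True per-(feature, patient) slopes.
#' @export
trueSlopes <- function(truth) truth@slopes

#' Simulate a longitudinal radiomic cohort with known ground truth
#'
#' Generates `value = intercept + slope * fraction + noise` for every
#' (patient, fraction, feature), with group-dependent slopes for the
#' informative features (see [CohortConfig-class]), then optionally drops
#' scans at `missing_rate` and injects gross outliers at `outlier_rate`.
#' Fully reproducible given the seed.
#'
#' @param config a [CohortConfig-class].
#' @return A list with elements `table` (a
#'   [LongitudinalFeatureTable-class]) and `truth` (a [GroundTruth-class]).
#' @examples
#' sim <- simulateCohort(cohortConfig(n_patients = 6, n_features = 20))
#' sim$table
#' @export
simulateCohort <- function(config) {
  validObject(config)
  set.seed(config@seed)
  np <- config@n_patients; nf <- config@n_fractions; nk <- config@n_features
  patients <- sprintf("P%02d", seq_len(np))
  n_resp <- ceiling(np * config@fraction_responders)
  labels <- structure(
    c(rep("responder", n_resp), rep("non-responder", np - n_resp)),
    names = patients)

  informative <- sort(sample.int(nk, config@n_informative))
  is_resp <- labels == "responder"

  # slopes: background drift N(0, sd) everywhere; responders' informative
  # features get the group effect added on top
  slopes <- matrix(rnorm(nk * np, 0, config@effect_slope_sd), nk, np)
  slopes[informative, is_resp] <- slopes[informative, is_resp] +
    config@effect_slope_mean
  intercepts <- matrix(rnorm(nk * np, 0, 1), nk, np)

  schema <- if (nk == 1688L) buildDefaultSchema("PTV") else
    syntheticSchema(nk)

  vals <- vector("list", np)
  pid <- frac <- vector("list", np)
  for (p in seq_len(np)) {
    x <- seq_len(nf)
    line <- intercepts[, p] %o% rep(1, nf) + slopes[, p] %o% x
    y <- line + matrix(rnorm(nk * nf, 0, config@noise_sd), nk, nf)
    if (config@outlier_rate > 0) {
      hit <- matrix(runif(nk * nf) < config@outlier_rate, nk, nf)
      sgn <- matrix(sample(c(-1, 1), nk * nf, replace = TRUE), nk, nf)
      y[hit] <- line[hit] + 10 * config@noise_sd * sgn[hit]
    }
    keep <- rep(TRUE, nf)
    if (config@missing_rate > 0) {
      keep <- runif(nf) >= config@missing_rate
      if (sum(keep) < 2) keep[1:2] <- TRUE
    }
    vals[[p]] <- y[, keep, drop = FALSE]
    pid[[p]] <- rep(patients[p], sum(keep))
    frac[[p]] <- x[keep]
  }
  values <- do.call(cbind, vals)
  tab <- longitudinalFeatureTable(values, unlist(pid), unlist(frac), schema,
                                  labels = labels)
  truth <- new("GroundTruth", labels = labels, slopes = slopes,
               intercepts = intercepts, informative = informative)
  dimnames(truth@slopes) <- dimnames(truth@intercepts) <-
    list(featureIds(schema), patients)
  list(table = tab, truth = truth)
}

#' Write ground truth as a JSON sidecar
#' @param truth a [GroundTruth-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeGroundTruth <- function(truth, path) {
  jsonlite::write_json(list(
    labels = as.list(truth@labels),
    informative = truth@informative,
    slopes = truth@slopes, intercepts = truth@intercepts
  ), path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}
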