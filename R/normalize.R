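#' NormalizedFeatureTable: per-patient z-scored features with outlier bounding
#'
#' Same container as [LongitudinalFeatureTable-class]; the assay holds, for
#' each (patient, feature) series, `z = (value - mean) / sd` clipped to
#' `[-bound, bound]`. Metadata gains `norm_mean` and `norm_sd` (features x
#' patients matrices of the statistics used), `norm_constant` (logical
#' features x patients flags for zero-variance series, which map to all-zero)
#' and `norm_bound`.
#'
#' @seealso [zscoreNormalize()]
#' @exportClass NormalizedFeatureTable
setClass("NormalizedFeatureTable", contains = "LongitudinalFeatureTable")

setValidity("NormalizedFeatureTable", function(object) {
  b <- metadata(object)$norm_bound
  if (is.null(b)) return("missing norm_bound metadata")
  v <- assay(object, "values")
  if (any(abs(v) > b + 1e-12, na.rm = TRUE))
    return(sprintf("normalized values exceed the +/-%g bound", b))
  TRUE
})

#' Per-patient z-score normalization with outlier bounding
#'
#' Each (patient, feature) series is standardized with its own mean and
#' sample (n-1) standard deviation, then clipped to `[-bound, +bound]`:
#' trend analysis cares about the shape of each patient's series, not its
#' magnitude, and the bound caps gross acquisition outliers without breaking
#' the fraction grid (clipped, not discarded). Constant series (sd = 0) map
#' to all zeros and are flagged; downstream fitting omits them for that
#' patient.
#'
#' @param table a [LongitudinalFeatureTable-class]; every patient must have
#'   at least 2 scans.
#' @param bound clip boundary on the absolute z-score (default 3).
#' @return A [NormalizedFeatureTable-class].
#' @examples
#' sim <- simulateCohort(cohortConfig(n_patients = 4, n_features = 10))
#' norm <- zscoreNormalize(sim$table)
#' range(SummarizedExperiment::assay(norm))  # within [-3, 3]
#' @export
zscoreNormalize <- function(table, bound = 3) {
  stopifnot(bound > 0)
  v <- assay(table, "values")
  cd <- colData(table)
  pats <- patientIds(table)
  nfrac <- table(cd$patient_id)
  if (any(nfrac < 2))
    stop("validation error: series with < 2 observations for patient(s) ",
         paste(names(nfrac)[nfrac < 2], collapse = ", "))
  mu <- sg <- matrix(NA_real_, nrow(v), length(pats),
                     dimnames = list(rownames(v), pats))
  z <- v
  for (p in pats) {
    idx <- which(cd$patient_id == p)
    y <- v[, idx, drop = FALSE]
    m <- rowMeans(y)
    s <- sqrt(rowSums((y - m)^2) / (length(idx) - 1))
    mu[, p] <- m; sg[, p] <- s
    zz <- (y - m) / s
    zz[s == 0, ] <- 0
    z[, idx] <- pmin(pmax(zz, -bound), bound)
  }
  out <- table
  assay(out, "values") <- z
  metadata(out)$norm_mean <- mu
  metadata(out)$norm_sd <- sg
  metadata(out)$norm_constant <- sg == 0
  metadata(out)$norm_bound <- bound
  new("NormalizedFeatureTable", out)
}

#' @describeIn NormalizedFeatureTable-class The per-(feature, patient) means
#'   and standard deviations used, as a list of two matrices.
#' @param x a `NormalizedFeatureTable`.
#' @export
normalizationStats <- function(x) {
  list(mean = metadata(x)$norm_mean, sd = metadata(x)$norm_sd,
       bound = metadata(x)$norm_bound)
}

#' @describeIn NormalizedFeatureTable-class Logical features x patients
#'   matrix flagging constant (zero-variance) series.
#' @export
constantFlags <- function(x) metadata(x)$norm_constant
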