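#' Fit the linear trend of one feature series over fractions
#'
#' Ordinary least squares of `value ~ fraction`: the slope is the
#' longitudinal radiomic trend (LRT) of the feature, the intercept is beta,
#' and the trend statistic LRTF = slope + intercept (equivalently, the fitted
#' value at fraction 1) summarizes the series for selection and modelling.
#' The fit error ERR is the mean absolute residual by default (signed
#' residuals of an OLS fit sum to zero, so their mean carries no
#' information); the root-mean-square alternative is available via
#' `errorType`.
#'
#' @param x fraction indices (length >= 2, not all equal).
#' @param y feature values, same length as `x`.
#' @param errorType `"absolute"` (mean absolute residual, default) or
#'   `"rmse"`.
#' @return A one-row data.frame with `n`, `slope`, `intercept`, `err`,
#'   `lrtf`.
#' @examples
#' fitFeatureTrend(1:5, 2 * (1:5) + 1)  # slope 2, intercept 1, lrtf 3
#' @export
fitFeatureTrend <- function(x, y, errorType = c("absolute", "rmse")) {
  errorType <- match.arg(errorType)
  if (length(x) != length(y) || length(x) < 2)
    stop("validation error: need two series of equal length >= 2")
  if (all(x == x[1]))
    stop("degenerate design: all fraction indices equal")
  xb <- mean(x); yb <- mean(y)
  sxx <- sum(x * x) - length(x) * xb^2
  slope <- (sum(x * y) - length(x) * xb * yb) / sxx
  intercept <- yb - slope * xb
  r <- y - (slope * x + intercept)
  err <- if (errorType == "absolute") mean(abs(r)) else sqrt(mean(r^2))
  data.frame(n = length(x), slope = slope, intercept = intercept,
             err = err, lrtf = slope + intercept)
}

#' Fit per-(patient, feature) trends over the first N fractions
#'
#' For each patient, fits the OLS line of every non-constant feature series
#' against the fraction indices 1..`uptoFraction` present for that patient.
#' Features flagged constant during normalization are omitted for that
#' patient; patients with fewer than two scans in the window are skipped
#' with a warning.
#'
#' @param norm a [NormalizedFeatureTable-class].
#' @param uptoFraction highest fraction index to use (>= 2).
#' @param errorType see [fitFeatureTrend()].
#' @return A data.frame with one row per (patient, feature):
#'   `patient_id, feature_id, n, slope, intercept, err, lrtf`.
#' @export
fitCourse <- function(norm, uptoFraction, errorType = c("absolute", "rmse")) {
  errorType <- match.arg(errorType)
  stopifnot(uptoFraction >= 2)
  v <- assay(norm, "values")
  cd <- colData(norm)
  flags <- constantFlags(norm)
  pats <- patientIds(norm)
  acc <- list(pid = list(), fid = list(), n = list(), slope = list(),
              intercept = list(), err = list())
  for (p in pats) {
    idx <- which(cd$patient_id == p & cd$fraction <= uptoFraction)
    if (length(idx) < 2) {
      warning("patient ", p, " has < 2 fractions <= ", uptoFraction,
              "; skipped")
      next
    }
    x <- cd$fraction[idx]
    keep <- which(!flags[, p])
    y <- v[keep, idx, drop = FALSE]
    xb <- mean(x)
    xc <- x - xb
    sxx <- sum(xc^2)
    ybar <- rowMeans(y)
    slope <- as.vector((y %*% xc) / sxx)
    intercept <- ybar - slope * xb
    r <- y - outer(slope, x) - intercept
    err <- if (errorType == "absolute") rowMeans(abs(r)) else
      sqrt(rowMeans(r^2))
    acc$pid[[p]] <- rep(p, length(keep))
    acc$fid[[p]] <- rownames(v)[keep]
    acc$n[[p]] <- rep(length(x), length(keep))
    acc$slope[[p]] <- slope
    acc$intercept[[p]] <- unname(intercept)
    acc$err[[p]] <- unname(err)
  }
  slope <- unlist(acc$slope, use.names = FALSE)
  intercept <- unlist(acc$intercept, use.names = FALSE)
  data.frame(
    patient_id = unlist(acc$pid, use.names = FALSE),
    feature_id = unlist(acc$fid, use.names = FALSE),
    n = unlist(acc$n, use.names = FALSE),
    slope = slope, intercept = intercept,
    err = unlist(acc$err, use.names = FALSE),
    lrtf = slope + intercept, row.names = NULL)
}

#' Patients x features matrix of LRTF statistics
#'
#' Reshapes the output of [fitCourse()]. Features omitted for a patient
#' (constant series) enter as 0, their normalized value.
#'
#' @param fits data.frame from [fitCourse()].
#' @param patients,features row/column universes; default those present.
#' @param what which statistic to spread (`"lrtf"`, `"slope"`,
#'   `"intercept"`, `"err"`).
#' @return numeric matrix patients x features.
#' @export
lrtfMatrix <- function(fits, patients = unique(fits$patient_id),
                       features = unique(fits$feature_id), what = "lrtf") {
  m <- matrix(0, length(patients), length(features),
              dimnames = list(patients, features))
  keep <- fits$patient_id %in% patients & fits$feature_id %in% features
  f <- fits[keep, ]
  m[cbind(match(f$patient_id, patients), match(f$feature_id, features))] <-
    f[[what]]
  m
}
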