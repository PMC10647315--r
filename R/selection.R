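#' SelectionResult: outcome of the two-stage feature screen
#'
#' @slot pvalues named numeric vector of two-sided Mann-Whitney p-values per
#'   feature (responders vs non-responders).
#' @slot alpha significance cut used (default 0.05).
#' @slot uRetained feature ids with `p < alpha`.
#' @slot logitAccuracy named numeric vector of per-feature leave-one-out
#'   logistic-regression accuracies (for U-retained features).
#' @slot minAccuracy accuracy cut of the logistic screen.
#' @slot logitRetained U-retained features whose LOOCV accuracy reached
#'   `minAccuracy`; always a subset of `uRetained`.
#' @seealso [utestScreen()], [logisticScreen()]
#' @exportClass SelectionResult
setClass("SelectionResult",
  representation(pvalues = "numeric", alpha = "numeric",
                 uRetained = "character", logitAccuracy = "numeric",
                 minAccuracy = "numeric", logitRetained = "character"),
  prototype(alpha = 0.05, minAccuracy = NA_real_,
            logitAccuracy = structure(numeric(), names = character()),
            logitRetained = character()))

setValidity("SelectionResult", function(object) {
  msg <- character()
  if (any(object@pvalues < 0 | object@pvalues > 1, na.rm = TRUE))
    msg <- c(msg, "p-values must be in [0, 1]")
  if (!all(object@uRetained %in% names(object@pvalues)))
    msg <- c(msg, "uRetained must be a subset of the tested features")
  if (!all(object@logitRetained %in% object@uRetained))
    msg <- c(msg, "logitRetained must be a subset of uRetained")
  if (length(msg)) msg else TRUE
})

setMethod("show", "SelectionResult", function(object) {
  cat("SelectionResult: ", length(object@pvalues), " features tested, ",
      length(object@uRetained), " retained at p < ", object@alpha, sep = "")
  if (!is.na(object@minAccuracy))
    cat(", ", length(object@logitRetained),
        " after logistic screen (accuracy >= ", object@minAccuracy, ")",
        sep = "")
  cat("\n")
})

#' @describeIn SelectionResult-class Per-feature U-test p-values.
#' @param x a `SelectionResult`.
#' @export
uTestPvalues <- function(x) x@pvalues

#' @describeIn SelectionResult-class The finally retained feature set: the
#'   logistic-screen survivors when that screen ran and kept anything,
#'   otherwise the U-test survivors.
#' @export
retainedFeatures <- function(x) {
  if (length(x@logitRetained)) x@logitRetained else x@uRetained
}

# Two-sided Mann-Whitney p-values, one per column of `m` (compiled; see
# src/mann_whitney.cpp). Exact via a precomputed pwilcox CDF table when a
# column has no ties, else normal approximation with tie correction and
# continuity correction, mirroring stats::wilcox.test (the test oracle for
# this routine, alongside exhaustive permutation enumeration). Compiled
# because the LOOCV evaluation calls this for every (experiment, fold)
# pair. The pwilcox table per (n1, n2) is cached across calls.
.mwCache <- new.env(parent = emptyenv())
.mannWhitneyP <- function(m, grp1) {
  n1 <- sum(grp1); n2 <- nrow(m) - n1
  key <- paste0(n1, "_", n2)
  pw <- .mwCache[[key]]
  if (is.null(pw)) {
    pw <- pwilcox(0:(n1 * n2), n1, n2)  # pw[k + 1] = P(U <= k)
    .mwCache[[key]] <- pw
  }
  .mannWhitneyPCpp(m, grp1, pw)
}

#' Mann-Whitney U-test screen of LRTF features
#'
#' For every feature, tests whether the trend statistic (LRTF) differs in
#' distribution between responders and non-responders with a two-sided
#' Mann-Whitney U test (exact for untied small samples, tie- and
#' continuity-corrected normal approximation otherwise). Features with
#' `p < alpha` are retained. Raw p-values are used by design — the
#' downstream statistical-weight model is built on them — but
#' Benjamini-Hochberg adjustment is available via `adjust`.
#'
#' @param lrtf numeric matrix, patients x features (see [lrtfMatrix()]).
#' @param labels character vector or named vector of
#'   `"responder"`/`"non-responder"`, aligned with (or named by) the rows of
#'   `lrtf`.
#' @param alpha retention cut on the p-value (default 0.05).
#' @param adjust `"none"` (default) or `"BH"`.
#' @return A [SelectionResult-class].
#' @export
utestScreen <- function(lrtf, labels, alpha = 0.05, adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  labels <- .alignLabels(labels, rownames(lrtf), nrow(lrtf))
  grp1 <- labels == "responder"
  if (!any(grp1) || all(grp1))
    stop("screening error: both response groups must be non-empty")
  p <- .mannWhitneyP(lrtf, grp1)
  names(p) <- colnames(lrtf)
  if (adjust == "BH") p <- stats::p.adjust(p, "BH")
  new("SelectionResult", pvalues = p, alpha = alpha,
      uRetained = colnames(lrtf)[p < alpha])
}

.alignLabels <- function(labels, ids, n) {
  if (!is.null(names(labels)) && !is.null(ids)) labels <- labels[ids]
  if (length(labels) != n)
    stop("labels do not align with the rows of the matrix")
  as.character(labels)
}

# Single-covariate logistic LOOCV accuracy for every column of X, by a
# Newton iteration with a closed-form 2x2 solve, compiled (see
# src/logistic_loocv.cpp). Coefficients are clamped, which doubles as the
# bounded-coefficient fallback under perfect separation (predictions
# saturate instead of diverging). stats::glm is the test oracle for this
# routine.
.logisticLoocvAccuracy <- function(X, y01, cap = 30, maxit = 50,
                                   tol = 1e-10) {
  acc <- .logisticLoocvAccuracyCpp(X, as.integer(y01), cap, maxit, tol)
  structure(acc, names = colnames(X))
}

#' Univariate logistic LOOCV screen
#'
#' For each U-test survivor, fits a single-covariate logistic regression in
#' leave-one-out cross-validation and keeps the feature if its held-out
#' classification accuracy reaches `minAccuracy`. Perfect separation is
#' handled by bounding the coefficients (predictions saturate; no failure).
#' If no feature survives, the result keeps an empty `logitRetained` set
#' with a warning and downstream models fall back to the U-retained set
#' (see [retainedFeatures()]).
#'
#' @param lrtf patients x features matrix.
#' @param labels response labels as in [utestScreen()].
#' @param selection a [SelectionResult-class] from [utestScreen()].
#' @param minAccuracy held-out accuracy required to keep a feature
#'   (default 0.7; `1` demands every fold correct).
#' @return The updated [SelectionResult-class].
#' @export
logisticScreen <- function(lrtf, labels, selection, minAccuracy = 0.7) {
  stopifnot(minAccuracy >= 0, minAccuracy <= 1)
  if (!length(selection@uRetained))
    stop("screening error: U-retained set is empty")
  labels <- .alignLabels(labels, rownames(lrtf), nrow(lrtf))
  X <- lrtf[, selection@uRetained, drop = FALSE]
  acc <- .logisticLoocvAccuracy(X, as.integer(labels == "responder"))
  kept <- names(acc)[acc >= minAccuracy]
  if (!length(kept))
    warning("logistic screen retained no features; ",
            "downstream models fall back to the U-retained set")
  selection@logitAccuracy <- acc
  selection@minAccuracy <- minAccuracy
  selection@logitRetained <- kept
  selection
}
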