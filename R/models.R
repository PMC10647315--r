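#' SWModel: the interpretable statistical-weight classifier
#'
#' Each retained feature's trend statistic (LRTF = slope + intercept) is
#' weighted by how strongly it separates the groups in the Mann-Whitney
#' screen, `w = (0.05 - p) / 0.05`, so `p = 0.05` gives weight 0 and `p = 0`
#' weight 1. An orientation sign per feature (+1 if responders' mean LRTF
#' exceeds non-responders' in the training data, else -1) stops
#' oppositely-trending informative features from cancelling; it can be
#' disabled (`orient = FALSE`) for a literal unsigned average. A patient's
#' score is the weight-normalized mean of oriented LRTFs; scores above 0
#' suggest a responder.
#'
#' @slot features retained feature ids.
#' @slot weights,signs,pvalues named per-feature vectors.
#' @slot orient logical: were orientation signs applied?
#' @slot threshold decision threshold (0).
#' @seealso [buildSWModel()], [swScore()]
#' @exportClass SWModel
setClass("SWModel",
  representation(features = "character", weights = "numeric",
                 signs = "numeric", pvalues = "numeric", orient = "logical",
                 threshold = "numeric"),
  prototype(orient = TRUE, threshold = 0))

setValidity("SWModel", function(object) {
  msg <- character()
  if (any(object@weights <= 0 | object@weights > 1))
    msg <- c(msg, "weights must lie in (0, 1] (features need p < 0.05)")
  if (!all(object@signs %in% c(-1, 1)))
    msg <- c(msg, "signs must be +/- 1")
  if (length(msg)) msg else TRUE
})

setMethod("show", "SWModel", function(object) {
  cat("SWModel: ", length(object@features), " features, orientation ",
      if (object@orient) "on" else "off", ", threshold ",
      object@threshold, "\n", sep = "")
})

#' P-value weight of the statistical-weight model
#'
#' `w = (alpha - p) / alpha` with `alpha = 0.05`: 0 at the significance
#' boundary, 1 for a vanishing p-value.
#'
#' @param p p-value(s).
#' @param alpha significance level (default 0.05).
#' @return numeric weight(s).
#' @export
swWeight <- function(p, alpha = 0.05) (alpha - p) / alpha

#' Build a statistical-weight model from screened trend features
#'
#' @param lrtf patients x features training matrix of LRTF values.
#' @param labels response labels (`"responder"`/`"non-responder"`), aligned
#'   with or named by the rows of `lrtf`.
#' @param selection a [SelectionResult-class]; the U-retained features and
#'   their p-values define the model.
#' @param orient apply orientation signs (default TRUE).
#' @param alpha the significance level of the weight formula.
#' @return An [SWModel-class].
#' @export
buildSWModel <- function(lrtf, labels, selection, orient = TRUE,
                         alpha = 0.05) {
  feats <- selection@uRetained
  if (!length(feats))
    stop("model-degenerate error: no retained features to weight")
  labels <- .alignLabels(labels, rownames(lrtf), nrow(lrtf))
  p <- selection@pvalues[feats]
  w <- swWeight(p, alpha)
  if (all(w <= 0))
    stop("model-degenerate error: all weights are zero")
  keep <- w > 0
  feats <- feats[keep]; w <- w[keep]; p <- p[keep]
  resp <- labels == "responder"
  X <- lrtf[, feats, drop = FALSE]
  s <- if (orient) {
    d <- colMeans(X[resp, , drop = FALSE]) -
      colMeans(X[!resp, , drop = FALSE])
    ifelse(d >= 0, 1, -1)
  } else rep(1, length(feats))
  new("SWModel", features = feats, weights = structure(w, names = feats),
      signs = structure(s, names = feats),
      pvalues = structure(p, names = feats), orient = orient, threshold = 0)
}

#' Score patients with a statistical-weight model
#'
#' @param model an [SWModel-class].
#' @param lrtf a named numeric vector of one patient's LRTF values, or a
#'   patients x features matrix.
#' @return numeric score(s); `> 0` suggests a responder.
#' @export
swScore <- function(model, lrtf) {
  if (is.null(dim(lrtf))) lrtf <- matrix(lrtf, 1,
                                         dimnames = list(NULL, names(lrtf)))
  X <- lrtf[, model@features, drop = FALSE]
  as.vector(X %*% (model@weights * model@signs)) / sum(model@weights)
}

#' @describeIn swScore Classify from the score against the 0 threshold.
#' @export
swClassify <- function(model, lrtf) {
  ifelse(swScore(model, lrtf) > model@threshold, "responder",
         "non-responder")
}

#' RFModel: seeded random-forest responder classifier
#'
#' A thin wrapper around a probability forest; the RF score of a patient is
#' the forest's predicted probability of the responder class.
#'
#' @slot forest the fitted ranger forest.
#' @slot features feature ids the forest was trained on.
#' @slot numTrees,seed hyperparameters (defaults 500 trees, seed 0).
#' @seealso [trainRF()], [rfScore()]
#' @exportClass RFModel
setClass("RFModel",
  representation(forest = "ANY", features = "character",
                 numTrees = "integer", seed = "integer"))

setMethod("show", "RFModel", function(object) {
  cat("RFModel: ", object@numTrees, " trees on ", length(object@features),
      " features (seed ", object@seed, ")\n", sep = "")
})

#' Train the random-forest responder model
#'
#' @param lrtf patients x features training matrix.
#' @param labels response labels, aligned with or named by the rows.
#' @param numTrees number of trees (default 500).
#' @param seed RNG seed of the forest (default 0); fixed seed + fixed data
#'   give identical scores.
#' @return An [RFModel-class].
#' @export
trainRF <- function(lrtf, labels, numTrees = 500, seed = 0) {
  labels <- .alignLabels(labels, rownames(lrtf), nrow(lrtf))
  if (length(unique(labels)) < 2)
    stop("training error: both classes must be present")
  if (min(table(labels)) < 2)
    stop("training error: need >= 2 patients per class")
  df <- as.data.frame(lrtf)
  colnames(df) <- make.names(colnames(lrtf))
  fit <- ranger::ranger(
    x = df, y = factor(labels, levels = c("non-responder", "responder")),
    probability = TRUE, num.trees = numTrees,
    # grow to pure leaves: probability forests otherwise default to
    # min.node.size 10, which cannot split leave-one-out cohorts this small
    min.node.size = 1,
    # ranger treats seed 0 as "draw a seed", so offset by one to keep
    # seed = 0 (the documented default) deterministic
    seed = as.integer(seed) + 1L,
    num.threads = 1)
  new("RFModel", forest = fit, features = colnames(lrtf),
      numTrees = as.integer(numTrees), seed = as.integer(seed))
}

#' RF score: predicted responder probability
#'
#' @param model an [RFModel-class].
#' @param lrtf a named numeric vector (one patient) or patients x features
#'   matrix with the model's features.
#' @return numeric in `[0, 1]`.
#' @export
rfScore <- function(model, lrtf) {
  if (is.null(dim(lrtf))) lrtf <- matrix(lrtf, 1,
                                         dimnames = list(NULL, names(lrtf)))
  df <- as.data.frame(lrtf[, model@features, drop = FALSE])
  colnames(df) <- make.names(model@features)
  unname(predict(model@forest, data = df,
                 num.threads = 1)$predictions[, "responder"])
}
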