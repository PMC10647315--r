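#' LRTExperimentSuite: results of the per-fraction LOOCV experiments
#'
#' One "experiment" fixes a treatment-length cutoff N and asks how well the
#' cohort's responders can be separated using only fractions 1..N: the
#' feature table is normalized and trend-fitted on that window, features are
#' screened and models trained inside each leave-one-out training fold, and
#' the held-out patient is scored by both the random forest and the
#' statistical-weight model. A full 28-fraction course yields 27 experiments
#' (N = 2..28).
#'
#' @slot scores data.frame with one row per (N, patient): held-out
#'   `rf_score`, `sw_score`, the true `label`, correctness indicators and a
#'   `fallback` flag (TRUE when no feature survived screening in that fold
#'   and neutral scores were emitted).
#' @slot experiments data.frame with one row per N: `rf_accuracy`,
#'   `sw_accuracy`, pooled `rf_auc`, `sw_auc`, `mean_fit_err`,
#'   `n_u_retained` (mean over folds).
#' @slot patientErr data.frame (N, patient_id, mean_err): per-patient mean
#'   least-squares fit error at each N.
#' @slot config the evaluation configuration used.
#' @seealso [runLOOCV()], [consistencyIndex()], [accuracyByFraction()]
#' @exportClass LRTExperimentSuite
setClass("LRTExperimentSuite",
  representation(scores = "data.frame", experiments = "data.frame",
                 patientErr = "data.frame", config = "list"))

setMethod("show", "LRTExperimentSuite", function(object) {
  e <- object@experiments
  cat("LRTExperimentSuite: ", nrow(e), " experiments (N = ",
      min(e$N), "..", max(e$N), "), ",
      length(unique(object@scores$patient_id)), " patients\n",
      "  mean RF AUC ", round(mean(e$rf_auc), 3),
      ", mean RF accuracy ", round(mean(e$rf_accuracy), 3),
      ", mean SW accuracy ", round(mean(e$sw_accuracy), 3), "\n", sep = "")
})

#' @describeIn LRTExperimentSuite-class Per-experiment summary table.
#' @param suite an `LRTExperimentSuite`.
#' @export
experimentSummary <- function(suite) suite@experiments

#' @describeIn LRTExperimentSuite-class Per-(N, patient) held-out scores.
#' @export
loocvScores <- function(suite) suite@scores

# Pooled AUC of held-out scores for one experiment; pROC implementation,
# cross-checked in tests against the rank-statistic U/(n1*n2) identity.
.pooledAUC <- function(scores, labels) {
  if (length(unique(scores)) < 2) return(0.5)
  as.numeric(pROC::auc(
    response = factor(labels, levels = c("non-responder", "responder")),
    predictor = scores, quiet = TRUE, direction = "<"))
}

#' Run the per-fraction-cutoff LOOCV experiment suite
#'
#' For each cutoff N in `fractions`: restrict the table to fractions 1..N,
#' z-score normalize (per patient, so leakage-free), fit per-feature trends,
#' and run leave-one-out cross-validation over patients. Inside each fold,
#' the Mann-Whitney screen, the logistic screen, the random forest and the
#' statistical-weight model are built from the training patients only; the
#' held-out patient is then scored. Folds whose training set loses a class
#' are skipped with a warning; folds whose screening retains nothing emit
#' neutral scores (RF 0.5, SW 0) and are flagged.
#'
#' @param table a labelled [LongitudinalFeatureTable-class] with at least
#'   two patients per class.
#' @param fractions integer vector of cutoffs N (default `2:maxFraction`).
#' @param alpha U-test retention cut (default 0.05).
#' @param minAccuracy logistic-screen accuracy cut (default 0.7); `NULL`
#'   disables the logistic screen.
#' @param orient apply orientation signs in the SW model (default TRUE).
#' @param numTrees,seed random-forest hyperparameters.
#' @param bound normalization clip boundary (default 3).
#' @param errorType trend fit-error type, see [fitFeatureTrend()].
#' @param adjust p-value adjustment of the U screen (`"none"`/`"BH"`).
#' @return An [LRTExperimentSuite-class].
#' @export
runLOOCV <- function(table, fractions = NULL, alpha = 0.05,
                     minAccuracy = 0.7, orient = TRUE, numTrees = 500,
                     seed = 0, bound = 3,
                     errorType = c("absolute", "rmse"),
                     adjust = c("none", "BH")) {
  errorType <- match.arg(errorType)
  adjust <- match.arg(adjust)
  labels <- responseLabels(table)
  if (is.null(labels)) stop("table has no response labels")
  if (is.null(fractions)) fractions <- 2:max(fractions(table))
  stopifnot(all(fractions >= 2))
  pats <- patientIds(table)
  labels <- labels[pats]
  if (min(table(labels)) < 2)
    stop("need >= 2 patients per class for LOOCV")

  score_rows <- vector("list", length(fractions))
  exp_rows <- vector("list", length(fractions))
  err_rows <- vector("list", length(fractions))

  for (i in seq_along(fractions)) {
    N <- fractions[i]
    sub <- subsetFractions(table, N)
    norm <- zscoreNormalize(sub, bound = bound)
    fits <- fitCourse(norm, N, errorType = errorType)
    M <- lrtfMatrix(fits, patients = patientIds(sub))
    pe <- stats::aggregate(err ~ patient_id, data = fits, FUN = mean)
    err_rows[[i]] <- data.frame(N = N, patient_id = pe$patient_id,
                                mean_err = pe$err)
    fold_pats <- rownames(M)
    rf_s <- sw_s <- rep(NA_real_, length(fold_pats))
    fallback <- rep(FALSE, length(fold_pats))
    n_u <- rep(NA_real_, length(fold_pats))
    for (h in seq_along(fold_pats)) {
      tr_lab <- labels[fold_pats[-h]]
      if (length(unique(tr_lab)) < 2) {
        warning("fold ", fold_pats[h], " at N=", N,
                " skipped: training set lost a class")
        next
      }
      Mtr <- M[-h, , drop = FALSE]
      sel <- utestScreen(Mtr, tr_lab, alpha = alpha, adjust = adjust)
      n_u[h] <- length(sel@uRetained)
      if (!length(sel@uRetained)) {
        fallback[h] <- TRUE
        rf_s[h] <- 0.5; sw_s[h] <- 0
        next
      }
      if (!is.null(minAccuracy))
        sel <- suppressWarnings(
          logisticScreen(Mtr, tr_lab, sel, minAccuracy = minAccuracy))
      feats <- retainedFeatures(sel)
      rf <- trainRF(Mtr[, feats, drop = FALSE], tr_lab,
                    numTrees = numTrees, seed = seed)
      rf_s[h] <- rfScore(rf, M[h, feats, drop = FALSE])
      sw <- buildSWModel(Mtr, tr_lab, sel, orient = orient, alpha = alpha)
      sw_s[h] <- swScore(sw, M[h, , drop = FALSE])
    }
    lab_f <- labels[fold_pats]
    ok <- !is.na(rf_s)
    rf_correct <- (rf_s > 0.5) == (lab_f == "responder")
    sw_correct <- (sw_s > 0) == (lab_f == "responder")
    score_rows[[i]] <- data.frame(
      N = N, patient_id = fold_pats, label = unname(lab_f),
      rf_score = rf_s, sw_score = sw_s, rf_correct = rf_correct,
      sw_correct = sw_correct, fallback = fallback, row.names = NULL)
    exp_rows[[i]] <- data.frame(
      N = N,
      rf_accuracy = mean(rf_correct[ok]),
      sw_accuracy = mean(sw_correct[ok]),
      rf_auc = .pooledAUC(rf_s[ok], lab_f[ok]),
      sw_auc = .pooledAUC(sw_s[ok], lab_f[ok]),
      mean_fit_err = mean(fits$err),
      n_u_retained = mean(n_u, na.rm = TRUE),
      n_folds = sum(ok))
  }
  new("LRTExperimentSuite",
      scores = do.call(rbind, score_rows),
      experiments = do.call(rbind, exp_rows),
      patientErr = do.call(rbind, err_rows),
      config = list(fractions = fractions, alpha = alpha,
                    minAccuracy = minAccuracy, orient = orient,
                    numTrees = numTrees, seed = seed, bound = bound,
                    errorType = errorType, adjust = adjust))
}

#' Per-patient consistency index and high/low-consistency grouping
#'
#' The consistency index (CI) of a patient is the fraction of experiments in
#' which the patient was correctly classified, regardless of the
#' experiment's N. The grouping applies a cut (default 0.8) to the mean CI
#' over the late-course experiments (N >= 15 by default), where
#' classification has stabilized: patients at or above the cut form the
#' high-consistency group.
#'
#' @param suite an [LRTExperimentSuite-class].
#' @param model `"rf"` or `"sw"`: whose classifications to audit.
#' @param windowStart first N of the late-course window (default 15).
#' @param cut consistency cut defining the high-consistency group
#'   (default 0.8).
#' @return data.frame with one row per patient: `ci_all` (over all
#'   experiments), `ci_window` (over `N >= windowStart`), and `group`
#'   (`"high"`/`"low"`).
#' @export
consistencyIndex <- function(suite, model = c("rf", "sw"), windowStart = 15,
                             cut = 0.8) {
  model <- match.arg(model)
  sc <- suite@scores
  col <- paste0(model, "_correct")
  ci_all <- tapply(sc[[col]], sc$patient_id, mean, na.rm = TRUE)
  inw <- sc$N >= windowStart
  ci_w <- tapply(sc[[col]][inw], sc$patient_id[inw], mean, na.rm = TRUE)
  pats <- names(ci_all)
  data.frame(patient_id = pats, ci_all = as.numeric(ci_all),
             ci_window = as.numeric(ci_w[pats]),
             group = ifelse(ci_w[pats] > cut, "high", "low"),
             row.names = NULL)
}

#' Accuracy summarized over fraction bands
#'
#' Groups the per-experiment accuracies into treatment-length bands
#' (defaults: early N 2-14, mid 15-20, late 21-28, which partition a
#' 28-fraction course's 27 experiments as 13 + 6 + 8) and reports the mean
#' accuracy of both models per band.
#'
#' @param suite an [LRTExperimentSuite-class].
#' @param bands named list of `c(lo, hi)` fraction ranges.
#' @return data.frame: band, N range, number of experiments, mean RF and SW
#'   accuracy, mean RF AUC, mean fit error.
#' @export
accuracyByFraction <- function(suite,
                               bands = list(early = c(2, 14),
                                            mid = c(15, 20),
                                            late = c(21, 28))) {
  e <- suite@experiments
  do.call(rbind, lapply(names(bands), function(b) {
    rg <- bands[[b]]
    sel <- e$N >= rg[1] & e$N <= rg[2]
    data.frame(band = b, from = rg[1], to = rg[2],
               n_experiments = sum(sel),
               rf_accuracy = mean(e$rf_accuracy[sel]),
               sw_accuracy = mean(e$sw_accuracy[sel]),
               rf_auc = mean(e$rf_auc[sel]),
               mean_fit_err = mean(e$mean_fit_err[sel]),
               row.names = NULL)
  }))
}
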