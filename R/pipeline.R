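#' Create and validate a pipeline configuration
#'
#' Collects every tunable of the end-to-end analysis: paths (or a simulation
#' config), the contoured region, the normalization bound, the screening
#' thresholds, the SW orientation switch, random-forest hyperparameters and
#' the master seed. Serializes losslessly to YAML via [saveConfig()] /
#' [loadConfig()].
#'
#' @param features_csv,labels_csv input paths; `NULL` to simulate instead.
#' @param simulate a [CohortConfig-class] (or arguments for
#'   [cohortConfig()] as a list) used when no input paths are given.
#' @param transforms_csv optional rigid-transform CSV for registration QC.
#' @param region `"GTV"` or `"PTV"`.
#' @param bound normalization clip boundary.
#' @param alpha U-test cut.
#' @param min_accuracy logistic-screen accuracy cut (`NULL` disables).
#' @param orient SW orientation signs on/off.
#' @param num_trees,seed random-forest trees and master seed.
#' @param qc_threshold registration-QC relative-deviation threshold.
#' @param bands fraction bands for the accuracy report.
#' @param plots emit ggplot figures (default FALSE).
#' @return A validated list of class `lrt_config`.
#' @export
pipelineConfig <- function(features_csv = NULL, labels_csv = NULL,
                           simulate = list(), transforms_csv = NULL,
                           region = "PTV", bound = 3, alpha = 0.05,
                           min_accuracy = 0.7, orient = TRUE,
                           num_trees = 500, seed = 1, qc_threshold = 0.05,
                           bands = list(early = c(2, 14), mid = c(15, 20),
                                        late = c(21, 28)),
                           plots = FALSE) {
  sim <- if (is(simulate, "CohortConfig")) .configToList(simulate)
         else if (length(simulate)) {
           if (!"seed" %in% names(simulate)) simulate$seed <- seed
           .configToList(do.call(cohortConfig, simulate))
         } else list()
  cfg <- list(features_csv = features_csv, labels_csv = labels_csv,
              simulate = sim,
              transforms_csv = transforms_csv, region = region,
              bound = as.numeric(bound), alpha = as.numeric(alpha),
              min_accuracy = if (is.null(min_accuracy)) NULL else
                as.numeric(min_accuracy),
              orient = as.logical(orient),
              num_trees = as.integer(num_trees), seed = as.integer(seed),
              qc_threshold = as.numeric(qc_threshold),
              bands = lapply(bands, as.numeric), plots = as.logical(plots))
  stopifnot(cfg$bound > 0, cfg$alpha >= 0, cfg$alpha <= 1,
            is.null(cfg$min_accuracy) ||
              (cfg$min_accuracy >= 0 && cfg$min_accuracy <= 1),
            cfg$num_trees >= 1, cfg$qc_threshold >= 0)
  class(cfg) <- c("lrt_config", "list")
  cfg
}

.configToList <- function(cc) {
  nm <- slotNames("CohortConfig")
  structure(lapply(nm, function(s) slot(cc, s)), names = nm)
}

#' Save / load a pipeline configuration as YAML
#' @param config an `lrt_config` list from [pipelineConfig()].
#' @param path YAML file path.
#' @return `loadConfig` returns the `lrt_config`; `saveConfig` returns
#'   `path` invisibly.
#' @export
saveConfig <- function(config, path) {
  yaml::write_yaml(unclass(config), path, precision = 15)
  invisible(path)
}

#' @rdname saveConfig
#' @export
loadConfig <- function(path) {
  x <- yaml::read_yaml(path)
  x$bands <- lapply(x$bands, as.numeric)
  do.call(pipelineConfig, x)
}

#' Run the full longitudinal-trend pipeline
#'
#' Simulate (or read and validate) the cohort, optionally audit
#' registration transforms, run the per-fraction LOOCV experiment suite,
#' and write every report artifact to `out_dir`:
#' `metrics.json` (per-experiment and band summaries, consistency, the full
#' configuration and seed), `experiments.csv`, `scores.csv`,
#' `consistency.csv`, `qc_report.csv` (if transforms given) and, with
#' `plots = TRUE`, figure PDFs.
#'
#' @param config an `lrt_config` from [pipelineConfig()].
#' @param out_dir output directory (created if needed).
#' @return The [LRTExperimentSuite-class], invisibly.
#' @export
runPipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "lrt_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(config$features_csv)) {
    tab <- readFeatureTable(config$features_csv, config$labels_csv,
                            region = config$region)
  } else {
    sim_args <- config$simulate
    if (!length(sim_args)) sim_args <- list(seed = config$seed)
    sim <- simulateCohort(do.call(cohortConfig, sim_args))
    tab <- sim$table
    writeGroundTruth(sim$truth, file.path(out_dir, "ground_truth.json"))
  }
  if (!is.null(config$transforms_csv)) {
    qc <- registrationQC(readTransforms(config$transforms_csv),
                         threshold = config$qc_threshold)
    data.table::fwrite(qc, file.path(out_dir, "qc_report.csv"))
    nwarn <- sum(qc$status == "warn")
    if (nwarn) message(nwarn,
      " fraction(s) flagged for manual registration review")
  }
  suite <- runLOOCV(tab, alpha = config$alpha,
                    minAccuracy = config$min_accuracy,
                    orient = config$orient, numTrees = config$num_trees,
                    seed = config$seed, bound = config$bound)
  bands <- lapply(config$bands, as.numeric)
  bandrep <- accuracyByFraction(suite, bands = bands)
  ci <- consistencyIndex(suite)
  data.table::fwrite(experimentSummary(suite),
                     file.path(out_dir, "experiments.csv"))
  data.table::fwrite(loocvScores(suite), file.path(out_dir, "scores.csv"))
  data.table::fwrite(ci, file.path(out_dir, "consistency.csv"))
  e <- experimentSummary(suite)
  metrics <- list(
    config = unclass(config),
    seed = config$seed,
    n_experiments = nrow(e),
    mean_rf_auc = mean(e$rf_auc),
    mean_rf_accuracy = mean(e$rf_accuracy),
    mean_sw_accuracy = mean(e$sw_accuracy),
    bands = bandrep,
    mean_consistency = mean(ci$ci_all),
    n_high_consistency = sum(ci$group == "high"))
  jsonlite::write_json(metrics, file.path(out_dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows",
                       null = "null")
  if (isTRUE(config$plots)) {
    ggplot2::ggsave(file.path(out_dir, "score_boxplots.pdf"),
                    plotScoreDistributions(suite), width = 8, height = 4)
    ggplot2::ggsave(file.path(out_dir, "accuracy_bands.pdf"),
                    plotAccuracyByFraction(suite), width = 6, height = 4)
    ggplot2::ggsave(file.path(out_dir, "consistency.pdf"),
                    plotConsistency(suite), width = 6, height = 4)
  }
  invisible(suite)
}

#' Plot held-out score distributions per experiment
#'
#' Box plots of held-out RF scores by treatment-length cutoff N, coloured by
#' response group.
#'
#' @param suite an [LRTExperimentSuite-class].
#' @param model `"rf"` or `"sw"`.
#' @return a ggplot object.
#' @export
plotScoreDistributions <- function(suite, model = c("rf", "sw")) {
  model <- match.arg(model)
  sc <- loocvScores(suite)
  sc$score <- sc[[paste0(model, "_score")]]
  ggplot2::ggplot(sc, ggplot2::aes(x = factor(.data$N), y = .data$score,
                                   fill = .data$label)) +
    ggplot2::geom_boxplot(outlier.size = 0.5) +
    ggplot2::scale_fill_manual(values = c(responder = "#d62728",
                                          `non-responder` = "#1f77b4")) +
    ggplot2::labs(x = "fractions used (N)",
                  y = paste(toupper(model), "score"), fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot accuracy against the treatment-length cutoff
#' @inheritParams plotScoreDistributions
#' @return a ggplot object.
#' @export
plotAccuracyByFraction <- function(suite) {
  e <- experimentSummary(suite)
  df <- rbind(data.frame(N = e$N, accuracy = e$rf_accuracy, model = "RF"),
              data.frame(N = e$N, accuracy = e$sw_accuracy, model = "SW"))
  ggplot2::ggplot(df, ggplot2::aes(.data$N, .data$accuracy,
                                   colour = .data$model)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 1) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "fractions used (N)", y = "LOOCV accuracy") +
    ggplot2::theme_minimal()
}

#' Plot per-patient consistency curves
#' @inheritParams plotScoreDistributions
#' @return a ggplot object.
#' @export
plotConsistency <- function(suite, model = c("rf", "sw")) {
  model <- match.arg(model)
  sc <- loocvScores(suite)
  col <- paste0(model, "_correct")
  sc$running <- stats::ave(as.numeric(sc[[col]]), sc$patient_id,
                           FUN = function(v) cumsum(v) / seq_along(v))
  ggplot2::ggplot(sc, ggplot2::aes(.data$N, .data$running,
                                   group = .data$patient_id,
                                   colour = .data$label)) +
    ggplot2::geom_line(alpha = 0.6) +
    ggplot2::scale_colour_manual(values = c(responder = "#d62728",
                                            `non-responder` = "#1f77b4")) +
    ggplot2::labs(x = "fractions used (N)", y = "running consistency",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
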