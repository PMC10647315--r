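#' @import SummarizedExperiment
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

#' LongitudinalFeatureTable: per-fraction radiomic feature values for a cohort
#'
#' A [SummarizedExperiment::SummarizedExperiment] whose rows are radiomic
#' features (named by the attached [FeatureSchema-class]) and whose columns
#' are scans, i.e. (patient, fraction) pairs. `colData` carries `patient_id`
#' and `fraction` (1-based index of delivered fractions); metadata carries
#' the schema, the per-patient response labels ("responder"/"non-responder")
#' and optional 0-3 response scores. Missing scans are simply absent columns;
#' trend fitting requires at least two fractions per patient.
#'
#' @seealso [longitudinalFeatureTable()], [readFeatureTable()],
#'   [zscoreNormalize()]
#' @exportClass LongitudinalFeatureTable
setClass("LongitudinalFeatureTable", contains = "SummarizedExperiment")

setValidity("LongitudinalFeatureTable", function(object) {
  msg <- character()
  cd <- colData(object)
  if (!all(c("patient_id", "fraction") %in% colnames(cd)))
    return("colData must contain 'patient_id' and 'fraction'")
  fr <- cd$fraction
  if (!is.numeric(fr) || any(fr < 1) || any(fr != round(fr)))
    msg <- c(msg, "fraction indices must be integers >= 1")
  key <- paste(cd$patient_id, fr)
  if (anyDuplicated(key))
    msg <- c(msg, "duplicate (patient, fraction) scans")
  nfrac <- table(cd$patient_id)
  bad <- names(nfrac)[nfrac < 2]
  if (length(bad))
    msg <- c(msg, paste0("patients with < 2 fractions: ",
                         paste(bad, collapse = ", ")))
  sch <- metadata(object)$schema
  if (!is.null(sch) && !identical(rownames(object), featureIds(sch)))
    msg <- c(msg, "rownames do not match the attached schema's featureIds")
  lab <- metadata(object)$labels
  if (!is.null(lab)) {
    if (!all(lab %in% c("responder", "non-responder")))
      msg <- c(msg, "labels must be 'responder' or 'non-responder'")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a LongitudinalFeatureTable
#'
#' @param values numeric matrix, features x scans. Rownames must match the
#'   schema's feature ids; they are set from the schema if absent.
#' @param patient_id character vector, one entry per scan (column).
#' @param fraction integer vector of 1-based fraction indices per scan.
#' @param schema a [FeatureSchema-class].
#' @param labels named character vector (`patient_id -> "responder" /
#'   "non-responder"`), optional.
#' @param scores named numeric vector of 0-3 response scores, optional.
#' @return A [LongitudinalFeatureTable-class].
#' @export
longitudinalFeatureTable <- function(values, patient_id, fraction, schema,
                                     labels = NULL, scores = NULL) {
  stopifnot(is.matrix(values),
            length(patient_id) == ncol(values),
            length(fraction) == ncol(values))
  rownames(values) <- featureIds(schema)
  fraction <- as.integer(fraction)
  colnames(values) <- paste0(patient_id, ".f", fraction)
  se <- SummarizedExperiment(
    assays = list(values = values),
    colData = DataFrame(patient_id = as.character(patient_id),
                        fraction = fraction,
                        row.names = colnames(values)))
  metadata(se)$schema <- schema
  if (!is.null(labels)) metadata(se)$labels <- labels
  if (!is.null(scores)) metadata(se)$scores <- scores
  new("LongitudinalFeatureTable", se)
}

#' @describeIn LongitudinalFeatureTable-class Patient identifiers (unique, in
#'   order of first appearance).
#' @param table a `LongitudinalFeatureTable`.
#' @export
patientIds <- function(table) unique(colData(table)$patient_id)

#' @describeIn LongitudinalFeatureTable-class Per-scan fraction indices.
#' @export
fractions <- function(table) colData(table)$fraction

#' @describeIn LongitudinalFeatureTable-class The attached
#'   [FeatureSchema-class].
#' @export
featureSchema <- function(table) metadata(table)$schema

#' @describeIn LongitudinalFeatureTable-class Named per-patient response
#'   labels, or `NULL`.
#' @export
responseLabels <- function(table) metadata(table)$labels

#' @describeIn LongitudinalFeatureTable-class Restrict to fractions
#'   `1..upto`; patients left with fewer than two scans are dropped with a
#'   warning.
#' @param upto highest fraction index to keep.
#' @export
subsetFractions <- function(table, upto) {
  keep <- colData(table)$fraction <= upto
  out <- table[, keep]
  nfrac <- table(colData(out)$patient_id)
  bad <- names(nfrac)[nfrac < 2]
  if (length(bad)) {
    warning("dropping patients with < 2 fractions <= ", upto, ": ",
            paste(bad, collapse = ", "))
    out <- out[, !colData(out)$patient_id %in% bad]
  }
  out
}

setMethod("show", "LongitudinalFeatureTable", function(object) {
  cd <- colData(object)
  cat(class(object), ": ", nrow(object), " features x ", ncol(object),
      " scans (", length(unique(cd$patient_id)), " patients, fractions ",
      min(cd$fraction), "-", max(cd$fraction), ")\n", sep = "")
  lab <- metadata(object)$labels
  if (!is.null(lab)) {
    tb <- table(lab)
    cat("  labels: ", paste(names(tb), tb, sep = "=", collapse = ", "),
        "\n", sep = "")
  }
})

#' Read a longitudinal feature table from long-format CSV
#'
#' The canonical on-disk form is a tidy CSV with columns
#' `patient_id,fraction,feature_id,value` plus a labels CSV with columns
#' `patient_id,label[,score]`. Long format is robust to missing scans.
#'
#' @param features_csv path to the long-format feature CSV.
#' @param labels_csv optional path to the labels CSV. Labels must be
#'   `responder` / `non-responder`.
#' @param schema optional [FeatureSchema-class]. When supplied, feature ids
#'   not in the schema raise a schema error and rows are ordered by the
#'   schema; otherwise a free-form schema is built from the ids found.
#' @param region region recorded when no schema is supplied.
#' @return A [LongitudinalFeatureTable-class].
#' @export
readFeatureTable <- function(features_csv, labels_csv = NULL, schema = NULL,
                             region = "PTV") {
  dt <- data.table::fread(features_csv, colClasses = list(
    character = "patient_id", integer = "fraction",
    character = "feature_id", numeric = "value"))
  need <- c("patient_id", "fraction", "feature_id", "value")
  if (!all(need %in% names(dt)))
    stop("feature CSV must have columns ", paste(need, collapse = ","))
  if (anyDuplicated(dt[, c("patient_id", "fraction", "feature_id")]))
    stop("integrity error: duplicated (patient, fraction, feature) records")
  if (is.null(schema)) {
    ids <- unique(dt$feature_id)
    schema <- new("FeatureSchema", region = region, featureIds = ids)
  } else {
    unknown <- setdiff(unique(dt$feature_id), featureIds(schema))
    if (length(unknown))
      stop("schema error: unknown feature_id(s): ",
           paste(head(unknown, 5), collapse = ", "))
  }
  scan <- unique(dt[, c("patient_id", "fraction")])
  data.table::setorder(scan, patient_id, fraction)
  nfrac <- table(scan$patient_id)
  bad <- names(nfrac)[nfrac < 2]
  if (length(bad))
    stop("validation error: patients with < 2 fractions: ",
         paste(bad, collapse = ", "))
  fid <- factor(dt$feature_id, levels = featureIds(schema))
  cid <- match(paste(dt$patient_id, dt$fraction),
               paste(scan$patient_id, scan$fraction))
  values <- matrix(NA_real_, nFeatures(schema), nrow(scan))
  values[cbind(as.integer(fid), cid)] <- dt$value
  labels <- scores <- NULL
  if (!is.null(labels_csv)) {
    lb <- data.table::fread(labels_csv,
                            colClasses = list(character = "patient_id"))
    labels <- structure(as.character(lb$label), names = lb$patient_id)
    if ("score" %in% names(lb))
      scores <- structure(as.numeric(lb$score), names = lb$patient_id)
  }
  longitudinalFeatureTable(values, scan$patient_id, scan$fraction, schema,
                           labels = labels, scores = scores)
}

#' Write a longitudinal feature table as long-format CSV
#'
#' @param table a [LongitudinalFeatureTable-class].
#' @param features_csv output path for the feature CSV.
#' @param labels_csv optional output path for the labels CSV.
#' @return the feature CSV path, invisibly.
#' @export
writeFeatureTable <- function(table, features_csv, labels_csv = NULL) {
  v <- assay(table, "values")
  cd <- colData(table)
  dt <- data.table::data.table(
    patient_id = rep(cd$patient_id, each = nrow(v)),
    fraction = rep(cd$fraction, each = nrow(v)),
    feature_id = rep(rownames(v), times = ncol(v)),
    # %.17g guarantees the double round-trips bit-exactly through text
    value = sprintf("%.17g", as.vector(v)))
  data.table::fwrite(dt, features_csv, quote = FALSE)
  if (!is.null(labels_csv)) {
    lab <- responseLabels(table)
    if (is.null(lab)) stop("table has no labels to write")
    lb <- data.table::data.table(patient_id = names(lab), label = unname(lab))
    sc <- metadata(table)$scores
    if (!is.null(sc)) lb$score <- unname(sc[lb$patient_id])
    data.table::fwrite(lb, labels_csv)
  }
  invisible(features_csv)
}
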