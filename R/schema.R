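#' @import methods
#' @importFrom stats rnorm runif sd pnorm plogis pwilcox predict
#' @importFrom utils head
#' @importFrom Rcpp sourceCpp
#' @useDynLib lrtrend, .registration = TRUE
NULL

#' FeatureSchema: the layout of a radiomic feature set
#'
#' Describes which image transformations and feature families make up a
#' feature vector, and fixes the stable feature identifiers used throughout
#' the package. The canonical layout (see [buildDefaultSchema()]) has 18
#' image types (the original image, 4 Laplacian-of-Gaussian scales, 8 wavelet
#' band combinations, and 5 further intensity transforms), 93 features per
#' transformed image (18 first-order, 24 GLCM, 16 GLRLM, 16 GLSZM, 14 GLDM,
#' 5 NGTDM) and 14 shape features computed on the original image only, for a
#' total of 18 * 93 + 14 = 1688 features per region.
#'
#' @slot region character, contoured region the features are computed from
#'   ("GTV" or "PTV").
#' @slot imageTypes character vector of image transformation names. May be
#'   empty for free-form (e.g. synthetic) schemas.
#' @slot familyCounts named integer vector: feature count per texture/intensity
#'   family within each transformed image.
#' @slot shapeCount integer, number of shape features (original image only).
#' @slot featureIds character vector of unique feature identifiers.
#'
#' @seealso [buildDefaultSchema()], [syntheticSchema()]
#' @exportClass FeatureSchema
setClass("FeatureSchema",
  representation(
    region = "character",
    imageTypes = "character",
    familyCounts = "integer",
    shapeCount = "integer",
    featureIds = "character"
  ),
  prototype(
    region = "PTV",
    imageTypes = character(),
    familyCounts = integer(),
    shapeCount = 0L,
    featureIds = character()
  )
)

setValidity("FeatureSchema", function(object) {
  msg <- character()
  if (length(object@region) != 1L || !object@region %in% c("GTV", "PTV"))
    msg <- c(msg, "region must be one of 'GTV', 'PTV'")
  if (anyDuplicated(object@featureIds))
    msg <- c(msg, "featureIds must be unique")
  if (length(object@imageTypes) > 0L) {
    expected <- length(object@imageTypes) * sum(object@familyCounts) +
      object@shapeCount
    if (length(object@featureIds) != expected)
      msg <- c(msg, sprintf(
        "featureIds length (%d) != imageTypes x familyCounts + shape (%d)",
        length(object@featureIds), expected))
  }
  if (length(msg)) msg else TRUE
})

.imageTypes18 <- function() {
  c("original",
    paste0("log-sigma-", c("0.6", "1.0", "3.0", "5.0")),
    paste0("wavelet-", c("LLL", "LLH", "LHL", "LHH", "HLL", "HLH", "HHL", "HHH")),
    "gradient", "squareroot", "logarithm", "exponential", "square")
}

.familyCounts93 <- function() {
  c(firstorder = 18L, glcm = 24L, glrlm = 16L, glszm = 16L,
    gldm = 14L, ngtdm = 5L)
}

#' Build the canonical 1688-feature radiomic schema
#'
#' The default layout mirrors a standard radiomics extraction on a contoured
#' target region: shape features from the original image, plus six
#' intensity/texture families from the original image and 17 filtered images
#' (Laplacian of Gaussian at sigma 0.6/1.0/3.0/5.0 mm, the 8 wavelet high/low
#' band combinations, gradient, square-root, logarithm, exponential and
#' square transforms).
#'
#' @param region `"GTV"` or `"PTV"`: the contoured region the features come
#'   from. The layout is identical for both; the region is carried as
#'   metadata.
#' @return A [FeatureSchema-class] with 18 image types, 93 features per
#'   transformed image, 14 shape features and 1688 feature ids of the form
#'   `"<imagetype>_<family>_<index>"` and `"shape_<index>"`.
#' @examples
#' sch <- buildDefaultSchema("PTV")
#' nFeatures(sch)  # 1688
#' @export
buildDefaultSchema <- function(region = c("PTV", "GTV")) {
  region <- match.arg(region)
  types <- .imageTypes18()
  fams <- .familyCounts93()
  ids <- unlist(lapply(types, function(ty) {
    unlist(lapply(names(fams), function(fm) {
      sprintf("%s_%s_%02d", ty, fm, seq_len(fams[[fm]]))
    }), use.names = FALSE)
  }), use.names = FALSE)
  ids <- c(ids, sprintf("shape_%02d", seq_len(14L)))
  new("FeatureSchema", region = region, imageTypes = types,
      familyCounts = fams, shapeCount = 14L, featureIds = ids)
}

#' Build a free-form schema with generic feature ids
#'
#' Used by the cohort simulator when the number of features differs from the
#' canonical 1688-feature layout.
#'
#' @param n number of features.
#' @param region `"GTV"` or `"PTV"`.
#' @return A [FeatureSchema-class] with ids `feat_00001`, `feat_00002`, ...
#' @export
syntheticSchema <- function(n, region = c("PTV", "GTV")) {
  region <- match.arg(region)
  new("FeatureSchema", region = region,
      featureIds = sprintf("feat_%05d", seq_len(n)))
}

#' @describeIn FeatureSchema-class Feature identifiers, in schema order.
#' @param schema a `FeatureSchema`.
#' @export
featureIds <- function(schema) schema@featureIds

#' @describeIn FeatureSchema-class Total number of features.
#' @export
nFeatures <- function(schema) length(schema@featureIds)

#' @describeIn FeatureSchema-class Image transformation names (may be empty
#'   for free-form schemas).
#' @export
imageTypes <- function(schema) schema@imageTypes

setMethod("show", "FeatureSchema", function(object) {
  cat("FeatureSchema (", object@region, " region)\n", sep = "")
  cat("  features: ", length(object@featureIds), "\n", sep = "")
  if (length(object@imageTypes)) {
    cat("  image types: ", length(object@imageTypes),
        " x ", sum(object@familyCounts), " features + ",
        object@shapeCount, " shape\n", sep = "")
  }
})

#' Write / read a schema as JSON
#' @param schema a [FeatureSchema-class].
#' @param path file path.
#' @return `readSchema` returns a `FeatureSchema`; `writeSchema` returns
#'   `path` invisibly.
#' @export
writeSchema <- function(schema, path) {
  jsonlite::write_json(list(
    region = schema@region, imageTypes = schema@imageTypes,
    familyCounts = as.list(schema@familyCounts),
    shapeCount = schema@shapeCount, featureIds = schema@featureIds
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeSchema
#' @export
readSchema <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  new("FeatureSchema", region = x$region,
      imageTypes = as.character(x$imageTypes),
      familyCounts = vapply(x$familyCounts, as.integer, integer(1)),
      shapeCount = as.integer(x$shapeCount),
      featureIds = as.character(x$featureIds))
}
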