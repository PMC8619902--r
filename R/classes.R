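# S4 containers for the scanning pipeline.

#' DomainTable: one analysis domain of typed features
#'
#' A `DomainTable` holds one domain of the dataset -- features in columns,
#' patients in rows -- together with the per-feature type (`"numeric"` or
#' `"nominal"`) and a domain label (`"clinical"`, `"expression"` or
#' `"image"`). Missing values are `NA`, the package's unknown marker.
#'
#' @slot patientIds Character vector of unique patient identifiers, one
#'   per row of `data`.
#' @slot data A `data.frame` of feature columns (no identifier columns).
#' @slot kinds Named character vector, one entry per column of `data`,
#'   each `"numeric"` or `"nominal"`.
#' @slot domain Single domain label.
#'
#' @seealso [makeDomainTable()], [filterFeatures()], [imputeMissing()]
#' @export
setClass("DomainTable", representation(
  patientIds = "character",
  data = "data.frame",
  kinds = "character",
  domain = "character"
))

setValidity("DomainTable", function(object) {
  msgs <- character()
  if (anyDuplicated(object@patientIds))
    msgs <- c(msgs, "patient IDs must be unique")
  if (nrow(object@data) != length(object@patientIds))
    msgs <- c(msgs, "one row per patient required")
  if (ncol(object@data) != length(object@kinds) ||
      !identical(names(object@kinds), colnames(object@data)))
    msgs <- c(msgs, "'kinds' must name every feature column exactly")
  if (length(object@kinds) && !all(object@kinds %in% c("numeric", "nominal")))
    msgs <- c(msgs, "feature kinds must be 'numeric' or 'nominal'")
  if (length(object@domain) != 1L)
    msgs <- c(msgs, "'domain' must be a single label")
  if (length(msgs)) msgs else TRUE
})

#' Construct a DomainTable
#'
#' @param data A `data.frame` of feature columns (unknowns as `NA`).
#' @param patientIds Character vector of unique patient IDs, parallel to
#'   the rows of `data`.
#' @param kinds Named character vector of feature kinds; inferred with
#'   [inferFeatureKind()] when omitted (columns inferred as `"drop"` are
#'   removed).
#' @param domain Domain label, one of `"clinical"`, `"expression"`,
#'   `"image"`.
#' @return A [DomainTable-class] object.
#' @export
#' @examples
#' df <- data.frame(AGE = rnorm(30) * 5 + 70,
#'                  APOE = sample(c("E3", "E4"), 30, TRUE))
#' dt <- makeDomainTable(df, sprintf("P%02d", 1:30), domain = "clinical")
#' featureKinds(dt)
makeDomainTable <- function(data, patientIds, kinds = NULL,
                            domain = c("clinical", "expression", "image")) {
  domain <- match.arg(domain)
  patientIds <- as.character(patientIds)
  if (is.null(kinds)) {
    kinds <- vapply(data, inferFeatureKind, character(1))
    data <- data[, kinds != "drop", drop = FALSE]
    kinds <- kinds[kinds != "drop"]
  }
  new("DomainTable", patientIds = patientIds,
      data = as.data.frame(data, optional = TRUE), kinds = kinds,
      domain = domain)
}

#' @describeIn DomainTable-class Patient identifiers.
#' @param object,x A `DomainTable`.
#' @export
setGeneric("patientIds", function(object) standardGeneric("patientIds"))
#' @rdname DomainTable-class
#' @export
setMethod("patientIds", "DomainTable", function(object) object@patientIds)

#' @describeIn DomainTable-class Named vector of feature kinds.
#' @export
setGeneric("featureKinds", function(object) standardGeneric("featureKinds"))
#' @rdname DomainTable-class
#' @export
setMethod("featureKinds", "DomainTable", function(object) object@kinds)

#' @describeIn DomainTable-class Feature data as a `data.frame`.
#' @export
setGeneric("featureData", function(object) standardGeneric("featureData"))
#' @rdname DomainTable-class
#' @export
setMethod("featureData", "DomainTable", function(object) object@data)

#' @describeIn DomainTable-class Domain label.
#' @export
setGeneric("domainLabel", function(object) standardGeneric("domainLabel"))
#' @rdname DomainTable-class
#' @export
setMethod("domainLabel", "DomainTable", function(object) object@domain)

#' @describeIn DomainTable-class Number of features.
#' @export
setGeneric("nFeatures", function(object) standardGeneric("nFeatures"))
#' @rdname DomainTable-class
#' @export
setMethod("nFeatures", "DomainTable", function(object) ncol(object@data))

setMethod("show", "DomainTable", function(object) {
  cat(sprintf("DomainTable [%s]: %d patients x %d features (%d numeric, %d nominal)\n",
              object@domain, length(object@patientIds), ncol(object@data),
              sum(object@kinds == "numeric"), sum(object@kinds == "nominal")))
})

#' MergedDataset: typed features from all domains, one row per patient
#'
#' The analysis-ready dataset: the column-wise union of the clinical,
#' expression and image domains restricted to the patients present in
#' every included domain. Each feature carries both its kind and the
#' domain it came from.
#'
#' @slot patientIds Unique patient identifiers.
#' @slot data Feature `data.frame`.
#' @slot kinds Named character vector (`"numeric"`/`"nominal"`).
#' @slot domains Named character vector mapping each feature to its
#'   domain label.
#' @slot untestable Character vector of features flagged untestable
#'   (fewer than two distinct observed values); populated by
#'   [makeSubsets()].
#'
#' @seealso [assembleDataset()], [scanAll()]
#' @export
setClass("MergedDataset", representation(
  patientIds = "character",
  data = "data.frame",
  kinds = "character",
  domains = "character",
  untestable = "character"
))

setValidity("MergedDataset", function(object) {
  msgs <- character()
  if (anyDuplicated(object@patientIds))
    msgs <- c(msgs, "patient IDs must be unique")
  if (nrow(object@data) != length(object@patientIds))
    msgs <- c(msgs, "one row per patient required")
  if (!identical(names(object@kinds), colnames(object@data)) ||
      !identical(names(object@domains), colnames(object@data)))
    msgs <- c(msgs, "'kinds' and 'domains' must name every feature column")
  if (length(msgs)) msgs else TRUE
})

#' @rdname MergedDataset-class
#' @param object A `MergedDataset`.
#' @export
setMethod("patientIds", "MergedDataset", function(object) object@patientIds)
#' @rdname MergedDataset-class
#' @export
setMethod("featureKinds", "MergedDataset", function(object) object@kinds)
#' @rdname MergedDataset-class
#' @export
setMethod("featureData", "MergedDataset", function(object) object@data)
#' @rdname MergedDataset-class
#' @export
setMethod("nFeatures", "MergedDataset", function(object) ncol(object@data))

#' @describeIn MergedDataset-class Named feature-to-domain map.
#' @export
setGeneric("featureDomains", function(object) standardGeneric("featureDomains"))
#' @rdname MergedDataset-class
#' @export
setMethod("featureDomains", "MergedDataset", function(object) object@domains)

#' @describeIn MergedDataset-class Per-domain and total feature counts.
#' @export
setGeneric("featureCounts", function(object) standardGeneric("featureCounts"))
#' @rdname MergedDataset-class
#' @export
setMethod("featureCounts", "MergedDataset", function(object) {
  counts <- c(clinical = sum(object@domains == "clinical"),
              expression = sum(object@domains == "expression"),
              image = sum(object@domains == "image"))
  c(counts, total = sum(counts))
})

setMethod("show", "MergedDataset", function(object) {
  fc <- featureCounts(object)
  cat(sprintf(paste0("MergedDataset: %d patients x %d features ",
                     "(clinical %d + expression %d + image %d)\n"),
              length(object@patientIds), fc[["total"]], fc[["clinical"]],
              fc[["expression"]], fc[["image"]]))
  if (length(object@untestable))
    cat(sprintf("  %d features flagged untestable\n", length(object@untestable)))
})

#' LatentMatrix: concatenated per-slice autoencoder features
#'
#' Tabular image domain: one row per patient, and for each slice index
#' the `latentDim` latent features of that slice's autoencoder,
#' concatenated in slice order. Columns are named `SLICE{i}_L{j}`.
#'
#' @slot patientIds Patient identifiers (row order).
#' @slot values Numeric matrix, patients x (nSlices * latentDim).
#' @slot sliceIndex Integer vector giving the slice of origin of every
#'   column.
#' @slot latentDim Latent dimension per slice.
#'
#' @seealso [encodeDomain()], [trainImageDomain()]
#' @export
setClass("LatentMatrix", representation(
  patientIds = "character",
  values = "matrix",
  sliceIndex = "integer",
  latentDim = "integer"
))

setValidity("LatentMatrix", function(object) {
  msgs <- character()
  nSlices <- length(unique(object@sliceIndex))
  if (ncol(object@values) != nSlices * object@latentDim)
    msgs <- c(msgs, "column count must equal nSlices * latentDim")
  if (length(object@sliceIndex) != ncol(object@values))
    msgs <- c(msgs, "one slice index per column required")
  if (nrow(object@values) != length(object@patientIds))
    msgs <- c(msgs, "one row per patient required")
  if (length(object@values) && !all(is.finite(object@values)))
    msgs <- c(msgs, "all latent values must be finite")
  if (length(msgs)) msgs else TRUE
})

#' @rdname LatentMatrix-class
#' @param object A `LatentMatrix`.
#' @export
setMethod("patientIds", "LatentMatrix", function(object) object@patientIds)

#' @describeIn LatentMatrix-class The numeric feature matrix.
#' @export
setGeneric("latentValues", function(object) standardGeneric("latentValues"))
#' @rdname LatentMatrix-class
#' @export
setMethod("latentValues", "LatentMatrix", function(object) object@values)

setMethod("show", "LatentMatrix", function(object) {
  cat(sprintf("LatentMatrix: %d patients x %d features (%d slices x latent %d)\n",
              nrow(object@values), ncol(object@values),
              length(unique(object@sliceIndex)), object@latentDim))
})

#' Number of tabular features an encoded image domain declares
#'
#' The shape contract of slice-wise encoding: concatenating one
#' `latentDim`-long latent vector per slice yields
#' `nSlices * latentDim` columns per patient.
#'
#' @param nSlices Number of slices per patient.
#' @param latentDim Latent dimension of each slice autoencoder.
#' @return Integer-valued count (as a double, exact for all practical
#'   sizes).
#' @export
#' @examples
#' latentFeatureCount(124, 6400)  # 793600
latentFeatureCount <- function(nSlices, latentDim) {
  stopifnot(nSlices >= 1, latentDim >= 1)
  as.numeric(nSlices) * as.numeric(latentDim)
}

#' SignificantPairStore: retained significant feature pairs
#'
#' The set of feature pairs whose association p-value fell at or below
#' the Bonferroni-corrected threshold, stored in canonical order
#' (`featureA < featureB` lexicographically) and queryable from either
#' endpoint.
#'
#' @slot alpha The corrected significance threshold used.
#' @slot pairs A `data.frame` with columns `featureA`, `featureB`,
#'   `test`, `statistic`, `pValue`, `underflow` (logical: p-value fell
#'   below the smallest representable positive double, recorded as 0 and
#'   interpreted as p <= 5e-324).
#'
#' @seealso [scanAll()], [pairsFor()], [countFrequencies()]
#' @export
setClass("SignificantPairStore", representation(
  alpha = "numeric",
  pairs = "data.frame"
))

setValidity("SignificantPairStore", function(object) {
  msgs <- character()
  req <- c("featureA", "featureB", "test", "statistic", "pValue", "underflow")
  if (!all(req %in% colnames(object@pairs)))
    msgs <- c(msgs, "pairs must have columns featureA/featureB/test/statistic/pValue/underflow")
  else {
    if (any(object@pairs$featureA >= object@pairs$featureB))
      msgs <- c(msgs, "pairs must be in canonical order featureA < featureB")
    bad <- !object@pairs$underflow & object@pairs$pValue > object@alpha
    if (any(bad))
      msgs <- c(msgs, "every stored p-value must be <= alpha")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a SignificantPairStore
#'
#' @param pairs `data.frame` of pair results (see
#'   [SignificantPairStore-class]).
#' @param alpha Significance threshold the pairs were retained at.
#' @return A [SignificantPairStore-class].
#' @export
makePairStore <- function(pairs, alpha) {
  pairs <- pairs[order(pairs$featureA, pairs$featureB), , drop = FALSE]
  rownames(pairs) <- NULL
  new("SignificantPairStore", alpha = alpha, pairs = pairs)
}

#' @describeIn SignificantPairStore-class The retained pairs,
#'   canonically sorted.
#' @param object A `SignificantPairStore`.
#' @export
setGeneric("storedPairs", function(object) standardGeneric("storedPairs"))
#' @rdname SignificantPairStore-class
#' @export
setMethod("storedPairs", "SignificantPairStore", function(object) object@pairs)

#' @describeIn SignificantPairStore-class The threshold used.
#' @export
setGeneric("storeAlpha", function(object) standardGeneric("storeAlpha"))
#' @rdname SignificantPairStore-class
#' @export
setMethod("storeAlpha", "SignificantPairStore", function(object) object@alpha)

#' @describeIn SignificantPairStore-class All pairs involving a feature
#'   (symmetric lookup).
#' @param feature Feature identifier.
#' @export
setGeneric("pairsFor", function(object, feature) standardGeneric("pairsFor"))
#' @rdname SignificantPairStore-class
#' @export
setMethod("pairsFor", "SignificantPairStore", function(object, feature) {
  p <- object@pairs
  p[p$featureA == feature | p$featureB == feature, , drop = FALSE]
})

setMethod("show", "SignificantPairStore", function(object) {
  cat(sprintf("SignificantPairStore: %d pairs at alpha = %.6g (%d underflowed)\n",
              nrow(object@pairs), object@alpha, sum(object@pairs$underflow)))
})

#' GroundTruth: planted structure of a synthetic dataset
#'
#' Records what the synthetic-data generator planted, so downstream
#' stages can be checked against known answers.
#'
#' @slot blockMembership Named character vector: feature ID -> block ID
#'   for features belonging to a planted correlated block.
#' @slot plantedAssociations `data.frame` with columns `a`, `b`: feature
#'   pairs expected to reach significance.
#' @slot duplicatePairs `data.frame` with columns `a`, `b`: bit-identical
#'   columns planted under different names.
#'
#' @export
setClass("GroundTruth", representation(
  blockMembership = "character",
  plantedAssociations = "data.frame",
  duplicatePairs = "data.frame"
))

setMethod("show", "GroundTruth", function(object) {
  cat(sprintf("GroundTruth: %d block features, %d planted pairs, %d duplicate pairs\n",
              length(object@blockMembership), nrow(object@plantedAssociations),
              nrow(object@duplicatePairs)))
})
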