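# Stratified revalidation: form sex and dementia-rating subsets, re-run
# the maximally significant comparisons within each, and account for
# comparisons lost to reduced significance versus lost to untestability.

#' Specify a patient subset
#'
#' @param name Subset name (e.g. `"female"`, `"cdr_0"`).
#' @param column Stratification column in the merged dataset.
#' @param predicate Function mapping the column's values to a logical
#'   keep-mask.
#' @return A `subsetSpec` list.
#' @export
#' @examples
#' subsetSpec("female", "PTGENDER", function(v) v == "Female")
subsetSpec <- function(name, column, predicate) {
  stopifnot(is.character(name), is.character(column), is.function(predicate))
  structure(list(name = name, column = column, predicate = predicate),
            class = "subsetSpec")
}

#' The five standard stratification subsets
#'
#' Female and male patients by the sex column, and the three
#' dementia-rating strata: rating equal to 0 (cognitively normal), equal
#' to 0.5 (mild cognitive impairment), and at least 1.0 (dementia). The
#' two axes each partition the patients.
#'
#' @param sexColumn,cdrColumn Column names in the merged dataset.
#' @return List of five [subsetSpec()]s.
#' @export
standardSubsets <- function(sexColumn = "PTGENDER", cdrColumn = "CDR") {
  num <- function(v) suppressWarnings(as.numeric(as.character(v)))
  list(
    subsetSpec("female", sexColumn, function(v) v == "Female"),
    subsetSpec("male", sexColumn, function(v) v == "Male"),
    subsetSpec("cdr_0", cdrColumn, function(v) num(v) == 0),
    subsetSpec("cdr_0.5", cdrColumn, function(v) num(v) == 0.5),
    subsetSpec("cdr_ge_1", cdrColumn, function(v) num(v) >= 1.0)
  )
}

#' Form row-filtered subset datasets
#'
#' Applies each spec's predicate to its stratification column and
#' re-checks every feature's testability within the subset: features
#' with fewer than two distinct observed values are flagged untestable
#' (not dropped, so loss accounting can name them).
#'
#' @param dataset A [MergedDataset-class].
#' @param specs List of [subsetSpec()]s.
#' @return Named list of `MergedDataset`s, each with its `untestable`
#'   slot populated.
#' @export
makeSubsets <- function(dataset, specs) {
  out <- list()
  for (sp in specs) {
    if (!sp$column %in% colnames(dataset@data))
      stop(sprintf("subset '%s': column '%s' not in dataset",
                   sp$name, sp$column), call. = FALSE)
    keep <- sp$predicate(dataset@data[[sp$column]])
    keep[is.na(keep)] <- FALSE
    if (!any(keep))
      stop(sprintf("subset '%s' selects no patients", sp$name),
           call. = FALSE)
    sub <- dataset@data[keep, , drop = FALSE]
    rownames(sub) <- NULL
    untestable <- colnames(sub)[vapply(sub, nDistinctKnown,
                                       integer(1)) < 2L]
    out[[sp$name]] <- new("MergedDataset",
                          patientIds = dataset@patientIds[keep],
                          data = sub, kinds = dataset@kinds,
                          domains = dataset@domains,
                          untestable = untestable)
  }
  out
}

#' Extract the maximally significant pairs from a store
#'
#' Pairs whose p-value underflowed double precision (recorded p of 0,
#' interpreted as p <= 5e-324, the smallest representable positive
#' value).
#'
#' @param store A [SignificantPairStore-class].
#' @return The subset of [storedPairs()] at maximal significance.
#' @export
extractMaxSignificant <- function(store) {
  p <- storedPairs(store)
  p[p$underflow | p$pValue <= UNDERFLOW_P, , drop = FALSE]
}

#' Re-test pairs within a subset and account for the losses
#'
#' Each pair is re-dispatched and re-tested on the subset's rows --
#' normality is reassessed, since sample properties change under
#' sub-setting -- and classified as: `retained` (p at or below `alpha`),
#' `lost_untestable` (a feature is constant in the subset, or the chosen
#' test's preconditions fail there), or `lost_significance` (testable
#' but p above `alpha`). Per-feature counts satisfy
#' `full = retained + lost_untestable + lost_significance` exactly; the
#' aggregate mean and population SD of losses are computed over features
#' carrying at least one qualifying pair in the full data.
#'
#' @param pairs Pair `data.frame` (e.g. from [extractMaxSignificant()]).
#' @param subset A [MergedDataset-class] from [makeSubsets()] (or the
#'   full dataset, which must lose nothing).
#' @param alpha Retention threshold; default the maximal-significance
#'   level 5e-324.
#' @param normalityAlpha Level of the normality pre-test.
#' @return `data.frame` (`feature`, `full`, `retained`,
#'   `lost_untestable`, `lost_significance`) with an `"aggregate"`
#'   attribute (list: `meanLost`, `sdLost`, per-class totals).
#' @export
revalidate <- function(pairs, subset, alpha = UNDERFLOW_P,
                       normalityAlpha = 0.05) {
  df <- subset@data
  kinds <- subset@kinds
  flagged <- subset@untestable
  cols <- lapply(df, function(v) if (is.numeric(v)) v else as.character(v))

  classify <- function(a, b) {
    if (a %in% flagged || b %in% flagged) return("lost_untestable")
    res <- comparePair(cols[[a]], cols[[b]], a, b,
                       kindA = kinds[[a]], kindB = kinds[[b]],
                       normalityAlpha = normalityAlpha)
    if (res$test == "skipped") return("lost_untestable")
    if (res$underflow || res$pValue <= alpha) "retained"
    else "lost_significance"
  }
  outcome <- character(nrow(pairs))
  for (k in seq_len(nrow(pairs)))
    outcome[k] <- classify(pairs$featureA[k], pairs$featureB[k])

  feats <- sort(unique(c(pairs$featureA, pairs$featureB)))
  tallies <- function(cls) {
    hit <- outcome == cls
    table(factor(c(pairs$featureA[hit], pairs$featureB[hit]),
                 levels = feats))
  }
  full <- table(factor(c(pairs$featureA, pairs$featureB), levels = feats))
  report <- data.frame(feature = feats,
                    full = as.integer(full),
                    retained = as.integer(tallies("retained")),
                    lost_untestable = as.integer(tallies("lost_untestable")),
                    lost_significance = as.integer(tallies("lost_significance")),
                    stringsAsFactors = FALSE)
  lost <- report$lost_untestable + report$lost_significance
  attr(report, "aggregate") <- list(
    meanLost = if (nrow(report)) mean(lost) else NA_real_,
    sdLost = if (nrow(report)) popSD(lost) else NA_real_,
    nPairs = nrow(pairs),
    retained = sum(outcome == "retained"),
    lostUntestable = sum(outcome == "lost_untestable"),
    lostSignificance = sum(outcome == "lost_significance"))
  report
}
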