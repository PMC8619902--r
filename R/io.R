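# Plain-text serialisation of the pipeline's objects: CSV for tables
# and pair stores, JSON for ground truth and mappings, a
# directory-per-patient CSV layout for slice stacks.

UNDERFLOW_TOKEN <- "0.0E0_UNDERFLOW"

#' Read and write domain tables as CSV
#'
#' Unknown values are written as the `unknown` string (default: empty
#' field) and read back as `NA`. The patient-ID column is written
#' first; feature kinds travel in a sidecar `<path>.kinds.csv` so the
#' round trip preserves typing.
#'
#' @param dt A [DomainTable-class].
#' @param path CSV file path.
#' @param unknown Unknown-marker string.
#' @param idCol Patient-ID column name used in the file.
#' @return `readDomainTable()`: a [DomainTable-class].
#' @export
writeDomainTable <- function(dt, path, unknown = "", idCol = "RID") {
  df <- cbind(setNames(data.frame(dt@patientIds, stringsAsFactors = FALSE),
                       idCol), dt@data)
  write.csv(df, path, row.names = FALSE, na = unknown)
  kinds <- data.frame(feature = names(dt@kinds), kind = unname(dt@kinds),
                      domain = dt@domain, stringsAsFactors = FALSE)
  write.csv(kinds, paste0(path, ".kinds.csv"), row.names = FALSE)
  invisible(path)
}

#' @rdname writeDomainTable
#' @export
readDomainTable <- function(path, unknown = "", idCol = "RID") {
  df <- read.csv(path, stringsAsFactors = FALSE, na.strings = unknown,
                 check.names = FALSE)
  kinds <- read.csv(paste0(path, ".kinds.csv"), stringsAsFactors = FALSE)
  km <- setNames(kinds$kind, kinds$feature)
  new("DomainTable", patientIds = as.character(df[[idCol]]),
      data = df[, setdiff(colnames(df), idCol), drop = FALSE],
      kinds = km[setdiff(colnames(df), idCol)],
      domain = kinds$domain[1])
}

#' Read and write a significant-pair store as CSV
#'
#' Columns `feature_a,feature_b,test,statistic,p_value`; underflowed
#' p-values are written as the token `0.0E0_UNDERFLOW`. The threshold
#' is kept in a header comment line.
#'
#' @param store A [SignificantPairStore-class].
#' @param path CSV file path.
#' @return `readPairStore()`: a [SignificantPairStore-class].
#' @export
writePairStore <- function(store, path) {
  p <- storedPairs(store)
  out <- data.frame(feature_a = p$featureA, feature_b = p$featureB,
                    test = p$test,
                    statistic = formatC(p$statistic, format = "g",
                                        digits = 17),
                    p_value = ifelse(p$underflow, UNDERFLOW_TOKEN,
                                     formatC(p$pValue, format = "g",
                                             digits = 17)),
                    stringsAsFactors = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# alpha=%s", formatC(storeAlpha(store), format = "g",
                                           digits = 17)), con)
  write.csv(out, con, row.names = FALSE)
  invisible(path)
}

#' @rdname writePairStore
#' @export
readPairStore <- function(path) {
  first <- readLines(path, n = 1L)
  alpha <- as.numeric(sub("# alpha=", "", first, fixed = TRUE))
  df <- read.csv(path, skip = 1L, stringsAsFactors = FALSE)
  under <- df$p_value == UNDERFLOW_TOKEN
  pairs <- data.frame(featureA = df$feature_a, featureB = df$feature_b,
                      test = df$test, statistic = as.numeric(df$statistic),
                      pValue = ifelse(under, 0,
                                      suppressWarnings(as.numeric(df$p_value))),
                      underflow = under, stringsAsFactors = FALSE)
  makePairStore(pairs, alpha)
}

#' Write a latent matrix as CSV
#'
#' One row per patient, columns `SLICE{i}_L{j}`, patient IDs in the
#' first column.
#'
#' @param lm A [LatentMatrix-class].
#' @param path CSV file path.
#' @export
writeLatentMatrix <- function(lm, path) {
  df <- data.frame(PATIENT = lm@patientIds, stringsAsFactors = FALSE)
  df <- cbind(df, as.data.frame(lm@values))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write ground truth as JSON
#'
#' @param truth A [GroundTruth-class].
#' @param path JSON file path.
#' @export
writeGroundTruth <- function(truth, path) {
  jsonlite::write_json(list(
    blockMembership = as.list(truth@blockMembership),
    plantedAssociations = truth@plantedAssociations,
    duplicatePairs = truth@duplicatePairs
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a redundancy mapping as JSON
#'
#' Feature -> sorted list of correlated feature IDs.
#'
#' @param mapping Output of [buildMapping()].
#' @param path JSON file path.
#' @export
writeMapping <- function(mapping, path) {
  jsonlite::write_json(mapping, path, digits = NA)
  invisible(path)
}

#' Write frequency records and domain summaries as CSV
#'
#' Summaries are printed at table precision: averages and standard
#' deviations rounded half away from zero to 2 decimals.
#'
#' @param records Output of [countFrequencies()].
#' @param summary Output of [summarizeFrequencies()].
#' @param path CSV file path.
#' @export
writeFrequencyTable <- function(records, path) {
  write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeFrequencyTable
#' @export
writeDomainSummary <- function(summary, path) {
  summary$average <- roundHalfUp(summary$average, 2L)
  summary$sd <- roundHalfUp(summary$sd, 2L)
  write.csv(summary, path, row.names = FALSE)
  invisible(path)
}

#' Write a revalidation report as CSV plus a JSON aggregate
#'
#' @param report Output of [revalidate()].
#' @param path CSV file path; the aggregate goes to
#'   `<path>.aggregate.json`.
#' @export
writeRevalidationReport <- function(report, path) {
  write.csv(report, path, row.names = FALSE)
  jsonlite::write_json(attr(report, "aggregate"),
                       paste0(path, ".aggregate.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read and write image stacks in a directory-per-patient layout
#'
#' Each patient gets a directory of `slice_###.csv` files holding the
#' pixel matrices as headerless CSV -- a portable plain-text array
#' layout.
#'
#' @param stacks Named list of per-patient slice lists.
#' @param dir Root directory.
#' @return `readImageStacks()`: the stacks list.
#' @export
writeImageStacks <- function(stacks, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (pid in names(stacks)) {
    pdir <- file.path(dir, pid)
    dir.create(pdir, showWarnings = FALSE)
    for (s in seq_along(stacks[[pid]])) {
      utils::write.table(stacks[[pid]][[s]],
                         file.path(pdir, sprintf("slice_%03d.csv", s)),
                         sep = ",", row.names = FALSE, col.names = FALSE)
    }
  }
  invisible(dir)
}

#' @rdname writeImageStacks
#' @export
readImageStacks <- function(dir) {
  pids <- sort(list.dirs(dir, recursive = FALSE, full.names = FALSE))
  stacks <- lapply(pids, function(pid) {
    files <- sort(list.files(file.path(dir, pid), pattern = "^slice_.*\\.csv$",
                             full.names = TRUE))
    lapply(files, function(f)
      as.matrix(read.csv(f, header = FALSE)))
  })
  names(stacks) <- pids
  stacks
}
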