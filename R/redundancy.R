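# Redundancy summaries: per-feature correlate frequencies split by
# domain, domain-level summary statistics, percent-of-domain figures,
# the feature-to-correlates mapping, and a representative-feature
# reducer.

#' Per-feature significant-correlate frequencies by domain
#'
#' One record per dataset feature: how many of its stored significant
#' partners fall in each domain, plus the total. Every stored pair
#' increments both endpoints' counters, in the column of the partner's
#' domain, so the total equals the number of stored pairs involving the
#' feature and column sums obey handshake conservation.
#'
#' @param store A [SignificantPairStore-class].
#' @param domainOf Named character vector mapping every dataset feature
#'   to its domain (`"clinical"`, `"expression"`, `"image"`), e.g.
#'   `featureDomains(dataset)`. Features absent from the store get
#'   all-zero records.
#' @return `data.frame` with columns `feature`, `clinical_freq`,
#'   `expression_freq`, `image_freq`, `total_freq`.
#' @export
countFrequencies <- function(store, domainOf) {
  p <- storedPairs(store)
  inStore <- unique(c(p$featureA, p$featureB))
  missing <- setdiff(inStore, names(domainOf))
  if (length(missing))
    stop("stored features without a domain label: ",
         paste(head(missing, 3), collapse = ", "), call. = FALSE)
  feats <- names(domainOf)
  doms <- c("clinical", "expression", "image")
  counts <- matrix(0L, length(feats), 3L,
                   dimnames = list(feats, doms))
  if (nrow(p)) {
    # endpoint A gains a count in B's domain and vice versa
    inc <- data.frame(feature = c(p$featureA, p$featureB),
                      partnerDomain = c(domainOf[p$featureB],
                                        domainOf[p$featureA]),
                      stringsAsFactors = FALSE)
    tab <- table(factor(inc$feature, levels = feats),
                 factor(inc$partnerDomain, levels = doms))
    counts <- counts + unclass(tab)
  }
  data.frame(feature = feats,
             clinical_freq = as.integer(counts[, "clinical"]),
             expression_freq = as.integer(counts[, "expression"]),
             image_freq = as.integer(counts[, "image"]),
             total_freq = as.integer(rowSums(counts)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Percentage of a domain, at printed precision
#'
#' `100 * count / domainSize`, rounded half away from zero to three
#' decimals -- the precision at which replacement percentages are
#' reported.
#'
#' @param count Number of features (0 <= count <= domainSize).
#' @param domainSize Domain size (>= 1).
#' @return The percentage, rounded to 3 decimals.
#' @export
#' @examples
#' percentOfDomain(24588, 48157)  # 51.058
percentOfDomain <- function(count, domainSize) {
  if (domainSize < 1) stop("domainSize must be >= 1", call. = FALSE)
  stopifnot(count >= 0, count <= domainSize)
  roundHalfUp(100 * count / domainSize, 3L)
}

#' Domain-level summary of correlate frequencies
#'
#' For every combination of feature domain (rows) and correlate domain
#' (columns `clinical`, `expression`, `image`, `total`), the mean,
#' population standard deviation, minimum and maximum of the per-feature
#' counts from [countFrequencies()].
#'
#' @param records Output of [countFrequencies()].
#' @param domainOf Named feature-to-domain map.
#' @return `data.frame` with columns `featureDomain`, `correlateDomain`,
#'   `average`, `sd`, `minimum`, `maximum` (unrounded; see
#'   [writeDomainSummary()] for printed precision).
#' @export
summarizeFrequencies <- function(records, domainOf) {
  stopifnot(nrow(records) > 0)
  fd <- domainOf[records$feature]
  cols <- c(clinical = "clinical_freq", expression = "expression_freq",
            image = "image_freq", total = "total_freq")
  rows <- list()
  for (d in unique(fd)) {
    sub <- records[fd == d, , drop = FALSE]
    for (cd in names(cols)) {
      x <- sub[[cols[[cd]]]]
      rows[[length(rows) + 1L]] <- data.frame(
        featureDomain = d, correlateDomain = cd,
        average = mean(x), sd = popSD(x),
        minimum = min(x), maximum = max(x),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Feature-to-correlates redundancy mapping
#'
#' Maps each feature in the included domains to the sorted list of its
#' significantly correlated partners, restricted to features also in the
#' included domains (image features are conventionally excluded: latent
#' pixels carry no direct biological reading). Only features with at
#' least one included correlate appear; the mapping is symmetric by
#' construction.
#'
#' @param store A [SignificantPairStore-class].
#' @param domainOf Named feature-to-domain map.
#' @param includeDomains Domains to keep (default clinical +
#'   expression).
#' @return Named list: feature -> sorted character vector of correlates.
#' @export
buildMapping <- function(store, domainOf,
                         includeDomains = c("clinical", "expression")) {
  p <- storedPairs(store)
  keep <- domainOf[p$featureA] %in% includeDomains &
    domainOf[p$featureB] %in% includeDomains
  p <- p[keep, , drop = FALSE]
  if (!nrow(p)) return(structure(list(), names = character(0)))
  edges <- data.frame(from = c(p$featureA, p$featureB),
                      to = c(p$featureB, p$featureA),
                      stringsAsFactors = FALSE)
  sp <- split(edges$to, edges$from)
  lapply(sp, function(v) sort(unique(v)))
}

#' Greedy representative-feature selection
#'
#' Reduces a redundancy mapping to a smaller representative set by
#' greedy cover: repeatedly keep the feature with the most not-yet-
#' covered correlates (ties broken lexicographically), marking it and
#' its correlates covered, until every mapped feature is covered. A
#' heuristic, not a minimum-cover solver.
#'
#' @param mapping A mapping from [buildMapping()] (possibly augmented
#'   with isolated features holding empty correlate vectors).
#' @return List with `kept` (sorted representative IDs) and `replaced`
#'   (named list: representative -> features it covered).
#' @export
#' @examples
#' m <- list(a = "b", b = c("a", "c"), c = "b")
#' selectRepresentatives(m)  # keeps "b"
selectRepresentatives <- function(mapping) {
  universe <- sort(unique(c(names(mapping), unlist(mapping))))
  covered <- setNames(rep(FALSE, length(universe)), universe)
  kept <- character(0)
  replaced <- list()
  candidates <- sort(names(mapping))
  while (!all(covered)) {
    gains <- vapply(candidates, function(f)
      sum(!covered[mapping[[f]]]), integer(1))
    pick <- candidates[which.max(gains)]  # ties: first in sorted order
    newly <- mapping[[pick]][!covered[mapping[[pick]]]]
    covered[pick] <- TRUE
    covered[newly] <- TRUE
    kept <- c(kept, pick)
    replaced[[pick]] <- sort(newly)
    candidates <- setdiff(candidates, pick)
    if (!length(candidates) && !all(covered)) {
      # uncovered features that only appear as correlates keep themselves
      rest <- names(covered)[!covered]
      kept <- c(kept, rest)
      covered[rest] <- TRUE
      for (f in rest) replaced[[f]] <- character(0)
    }
  }
  list(kept = sort(kept), replaced = replaced)
}
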