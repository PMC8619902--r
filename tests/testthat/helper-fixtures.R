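# Shared fixtures and independent statistical oracles.
#
# The oracles deliberately take a different computational route from the
# package: tests implemented in the package from closed-form statistics
# are checked against base R's own test functions, and tests the package
# delegates to base R are checked against first-principles formulas.

# -- first-principles p-values ------------------------------------------

oracleChisq <- function(a, b) {
  tab <- table(a, b)
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  X2 <- sum((tab - E)^2 / E)
  df <- (nrow(tab) - 1) * (ncol(tab) - 1)
  list(statistic = X2, p = pchisq(X2, df, lower.tail = FALSE))
}

oracleKruskal <- function(x, g) {
  g <- factor(g)
  N <- length(x)
  r <- rank(x)
  Rj <- tapply(r, g, sum)
  nj <- tapply(r, g, length)
  H <- 12 / (N * (N + 1)) * sum(Rj^2 / nj) - 3 * (N + 1)
  ties <- table(x)
  H <- H / (1 - sum(ties^3 - ties) / (N^3 - N))
  list(statistic = H, p = pchisq(H, nlevels(g) - 1, lower.tail = FALSE))
}

# Monte-Carlo permutation p-value for any statistic function.
permutationP <- function(x, y, statFn, nPerm = 20000, seed = 1) {
  obs <- statFn(x, y)
  perms <- pairscan:::withSeed(seed, {
    replicate(nPerm, statFn(x, sample(y)))
  })
  (1 + sum(perms >= obs - 1e-12)) / (nPerm + 1)
}

absPearson <- function(x, y) abs(cor(x, y))
absSpearman <- function(x, y) abs(cor(rank(x), rank(y)))
chisqStat <- function(x, y) {
  tab <- table(x, y)
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - E)^2 / E)
}
fStat <- function(x, g) {
  g <- factor(g)
  means <- tapply(x, g, mean); sizes <- tapply(x, g, length)
  k <- nlevels(g); n <- length(x)
  ssb <- sum(sizes * (means - mean(x))^2)
  ssw <- sum((x - means[g])^2)
  (ssb / (k - 1)) / (ssw / (n - k))
}
kwStat <- function(x, g) oracleKruskal(x, g)$statistic

# -- dataset builders ----------------------------------------------------

# A numeric-only MergedDataset from a matrix (all features one domain).
numericDataset <- function(m, domain = "clinical",
                           ids = sprintf("P%04d", seq_len(nrow(m)))) {
  colnames(m) <- if (is.null(colnames(m)))
    sprintf("F%03d", seq_len(ncol(m))) else colnames(m)
  df <- as.data.frame(m)
  new("MergedDataset", patientIds = ids, data = df,
      kinds = setNames(rep("numeric", ncol(df)), colnames(df)),
      domains = setNames(rep(domain, ncol(df)), colnames(df)),
      untestable = character(0))
}

# A small mixed clinical dataset with planted structure, strata and a
# duplicate pair; used by the scan/stratification tests.
plantedDataset <- function(n = 200, seed = 42) {
  gen <- generateTabularDomain(syntheticSpec(
    n, numericBlocks = list(c(4, 0.95)), nNoiseNumeric = 4,
    nDuplicatePairs = 1, stratSex = TRUE, stratCDR = TRUE, seed = seed))
  collapsed <- gen$table
  dt <- makeDomainTable(collapsed[setdiff(colnames(collapsed), "RID")],
                        collapsed$RID, domain = "clinical")
  ds <- assembleDataset(dt)
  list(dataset = ds, truth = gen$truth)
}

# Build a SignificantPairStore directly from a pair list (all underflow,
# so any alpha is honoured).
storeFromEdges <- function(a, b, test = "pearson") {
  k <- length(a)
  pairs <- data.frame(featureA = pmin(a, b), featureB = pmax(a, b),
                      test = rep(test, k), statistic = rep(1, k),
                      pValue = rep(0, k), underflow = rep(TRUE, k),
                      stringsAsFactors = FALSE)
  makePairStore(pairs, 1e-13)
}
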