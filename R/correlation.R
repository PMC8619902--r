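# The all-vs-all association scan: comparison-count arithmetic,
# Bonferroni control, normality-driven test dispatch, pair testing, and
# the scan itself.

# p-values at or below the smallest representable positive double are
# "maximally significant": the test statistic was so extreme the p-value
# underflowed. 5e-324 is the smallest positive denormal.
UNDERFLOW_P <- 5e-324

#' Number of unordered pairwise comparisons
#'
#' All feature-vs-feature comparisons excluding self-comparisons:
#' `m * (m - 1) / 2`. Exact in double precision for any realistic `m`
#' (the product stays far below 2^53).
#'
#' @param m Feature count (>= 0).
#' @return The comparison count.
#' @export
#' @examples
#' nPairwise(842888)  # 355229668828
nPairwise <- function(m) {
  stopifnot(m >= 0)
  m <- as.numeric(m)
  m * (m - 1) / 2
}

#' Bonferroni-corrected significance threshold
#'
#' Divides the family-wise level by the number of planned comparisons.
#' The divisor is the full planned family -- every unordered pair --
#' whether or not some pairs later turn out untestable.
#'
#' @param baseAlpha Family-wise significance level (default 0.05).
#' @param nComparisons Number of planned comparisons (>= 1).
#' @return The per-comparison threshold.
#' @export
#' @examples
#' bonferroniAlpha(0.05, 355229668828)  # 1.40754e-13
bonferroniAlpha <- function(baseAlpha, nComparisons) {
  if (nComparisons < 1) stop("nComparisons must be >= 1", call. = FALSE)
  stopifnot(baseAlpha > 0, baseAlpha <= 1)
  baseAlpha / nComparisons
}

#' Omnibus skew/kurtosis normality test
#'
#' The D'Agostino-Pearson K-squared test: transformed sample skewness
#' and kurtosis are each brought to approximate standard normality, and
#' `K2 = Zs^2 + Zk^2` referred to a chi-squared distribution with 2
#' degrees of freedom. Samples smaller than 8 (where the kurtosis
#' transformation is undefined) and degenerate (constant) samples are
#' deemed non-normal, routing them to the non-parametric branch.
#'
#' @param x Numeric sample (no unknowns).
#' @param alpha Test level (default 0.05).
#' @return `isNormal()`: `TRUE` iff the test fails to reject normality.
#'   `normalityTest()`: list with `statistic` (K2) and `p.value`.
#' @export
#' @examples
#' isNormal(rnorm(500))
#' isNormal(rexp(500))
isNormal <- function(x, alpha = 0.05) {
  if (length(x) < 8L) return(FALSE)
  res <- normalityTest(x)
  if (!is.finite(res$p.value)) return(FALSE)
  res$p.value > alpha
}

#' @rdname isNormal
#' @export
normalityTest <- function(x) {
  n <- length(x)
  if (n < 8L) stop("normality test requires n >= 8", call. = FALSE)
  x <- as.numeric(x)
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 == 0) return(list(statistic = NaN, p.value = NaN))
  m3 <- mean((x - m)^3)
  m4 <- mean((x - m)^4)

  # skewness: D'Agostino (1970) transformation
  b1 <- m3 / m2^1.5
  y <- b1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  W2 <- -1 + sqrt(2 * (beta2 - 1))
  delta <- 1 / sqrt(0.5 * log(W2))
  alpha_ <- sqrt(2 / (W2 - 1))
  Zs <- delta * log(y / alpha_ + sqrt((y / alpha_)^2 + 1))

  # kurtosis: Anscombe & Glynn (1983) transformation
  b2 <- m4 / m2^2
  E <- 3 * (n - 1) / (n + 1)
  varb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xx <- (b2 - E) / sqrt(varb2)
  sqrtbeta1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  A <- 6 + 8 / sqrtbeta1 * (2 / sqrtbeta1 + sqrt(1 + 4 / sqrtbeta1^2))
  Zk <- ((1 - 2 / (9 * A)) -
           ((1 - 2 / A) / (1 + xx * sqrt(2 / (A - 4))))^(1 / 3)) /
    sqrt(2 / (9 * A))

  K2 <- Zs^2 + Zk^2
  list(statistic = K2, p.value = pchisq(K2, df = 2, lower.tail = FALSE))
}

#' Choose the statistical test for a feature pair
#'
#' The dispatch table: two numeric features take Pearson correlation if
#' both are normal, Spearman otherwise; two nominal features take the
#' chi-squared test of independence unless any contingency cell holds
#' fewer than five observations, in which case the pair is skipped; a
#' numeric/nominal pair takes one-way ANOVA if the numeric values are
#' normal within every category, Kruskal-Wallis otherwise.
#'
#' @param kindA,kindB Feature kinds (`"numeric"` or `"nominal"`).
#' @param normalA,normalB For numeric features, whether each is normal.
#' @param perCategoryNormal For a numeric/nominal pair, logical vector of
#'   within-category normality.
#' @param contingencyMinCell For a nominal/nominal pair, the smallest
#'   observed contingency cell count.
#' @return A list with `test` (one of `"pearson"`, `"spearman"`,
#'   `"chi_squared"`, `"anova"`, `"kruskal_wallis"`, `"skipped"`) and
#'   `reason` (non-empty only when skipped).
#' @export
#' @examples
#' selectTest("numeric", "numeric", normalA = TRUE, normalB = TRUE)
#' selectTest("nominal", "nominal", contingencyMinCell = 4)
selectTest <- function(kindA, kindB, normalA = NA, normalB = NA,
                       perCategoryNormal = NULL, contingencyMinCell = NA) {
  stopifnot(kindA %in% c("numeric", "nominal"),
            kindB %in% c("numeric", "nominal"))
  sel <- function(test, reason = "") list(test = test, reason = reason)
  if (kindA == "numeric" && kindB == "numeric") {
    if (isTRUE(normalA) && isTRUE(normalB)) sel("pearson") else sel("spearman")
  } else if (kindA == "nominal" && kindB == "nominal") {
    if (is.na(contingencyMinCell))
      stop("contingencyMinCell required for nominal/nominal", call. = FALSE)
    if (contingencyMinCell < 5)
      sel("skipped", "contingency cell < 5")
    else sel("chi_squared")
  } else {
    if (is.null(perCategoryNormal))
      stop("perCategoryNormal required for numeric/nominal", call. = FALSE)
    if (all(perCategoryNormal)) sel("anova") else sel("kruskal_wallis")
  }
}

# Internal: run the chosen test, returning statistic and p-value.
# Statistics reported: r (Pearson), rho (Spearman), X^2, F, H.
runChosenTest <- function(test, a, b, kindA) {
  switch(test,
    pearson = {
      r <- suppressWarnings(cor(a, b))
      n <- length(a)
      if (abs(r) >= 1) return(list(statistic = r, p = 0))
      tstat <- r * sqrt((n - 2) / (1 - r^2))
      list(statistic = r, p = 2 * pt(-abs(tstat), df = n - 2))
    },
    spearman = {
      ra <- rank(a); rb <- rank(b)  # average ranks for ties
      rho <- suppressWarnings(cor(ra, rb))
      n <- length(a)
      if (is.na(rho)) return(list(statistic = NA_real_, p = NA_real_))
      if (abs(rho) >= 1) return(list(statistic = rho, p = 0))
      tstat <- rho * sqrt((n - 2) / (1 - rho^2))  # large-sample t approx
      list(statistic = rho, p = 2 * pt(-abs(tstat), df = n - 2))
    },
    chi_squared = {
      res <- suppressWarnings(chisq.test(table(a, b), correct = FALSE))
      list(statistic = unname(res$statistic), p = res$p.value)
    },
    anova = {
      g <- factor(b)
      num <- if (kindA == "numeric") a else stop("internal dispatch error")
      means <- tapply(num, g, mean)
      sizes <- tapply(num, g, length)
      k <- nlevels(g); n <- length(num)
      ssb <- sum(sizes * (means - mean(num))^2)
      ssw <- sum((num - means[g])^2)
      if (ssw == 0) {
        p <- if (ssb > 0) 0 else 1
        return(list(statistic = if (ssb > 0) Inf else 0, p = p))
      }
      f <- (ssb / (k - 1)) / (ssw / (n - k))
      list(statistic = f, p = pf(f, k - 1, n - k, lower.tail = FALSE))
    },
    kruskal_wallis = {
      res <- kruskal.test(a, factor(b))
      list(statistic = unname(res$statistic), p = res$p.value)
    },
    stop("unknown test: ", test, call. = FALSE)
  )
}

#' Compare one pair of aligned feature columns
#'
#' Dispatches via [selectTest()] -- assessing normality with
#' [isNormal()] where the dispatch needs it -- runs the chosen test, and
#' reports the canonicalised pair. A p-value that underflows the
#' smallest representable positive double is recorded as 0 with
#' `underflow = TRUE` (interpreted as p <= 5e-324). Nominal features
#' with fewer than two observed categories, or constant numeric
#' features, make the pair untestable and it is skipped with a reason.
#'
#' @param a,b Aligned value vectors (no unknowns).
#' @param nameA,nameB Feature identifiers.
#' @param kindA,kindB Feature kinds.
#' @param normalityAlpha Level of the normality pre-test (default 0.05).
#' @param normalCache Optional environment caching per-feature normality
#'   by name (used by [scanAll()]).
#' @return One-row `data.frame`: `featureA`, `featureB`, `test`,
#'   `reason`, `statistic`, `pValue`, `underflow`.
#' @export
comparePair <- function(a, b, nameA = "A", nameB = "B",
                        kindA = c("numeric", "nominal"),
                        kindB = c("numeric", "nominal"),
                        normalityAlpha = 0.05, normalCache = NULL) {
  kindA <- match.arg(kindA); kindB <- match.arg(kindB)
  stopifnot(length(a) == length(b), nameA != nameB)

  # orient so numeric comes first for mixed pairs
  if (kindA == "nominal" && kindB == "numeric") {
    tmp <- a; a <- b; b <- tmp
    tmpk <- kindA; kindA <- kindB; kindB <- tmpk
    tmpn <- nameA; nameA <- nameB; nameB <- tmpn
  }

  featNormal <- function(v, nm) {
    if (!is.null(normalCache) && !is.null(normalCache[[nm]]))
      return(normalCache[[nm]])
    res <- isNormal(as.numeric(v), normalityAlpha)
    if (!is.null(normalCache)) normalCache[[nm]] <- res
    res
  }

  untestable <- function(reason) sel <<- list(test = "skipped", reason = reason)
  sel <- NULL
  if (kindA == "numeric" && nDistinctKnown(a) < 2L)
    untestable(sprintf("constant numeric feature %s", nameA))
  else if (kindB == "numeric" && nDistinctKnown(b) < 2L)
    untestable(sprintf("constant numeric feature %s", nameB))
  else if (kindA == "nominal" && nDistinctKnown(a) < 2L)
    untestable(sprintf("fewer than 2 categories in %s", nameA))
  else if (kindB == "nominal" && nDistinctKnown(b) < 2L)
    untestable(sprintf("fewer than 2 categories in %s", nameB))

  if (is.null(sel)) {
    if (kindA == "numeric" && kindB == "numeric") {
      sel <- selectTest(kindA, kindB,
                        normalA = featNormal(a, nameA),
                        normalB = featNormal(b, nameB))
    } else if (kindA == "nominal" && kindB == "nominal") {
      sel <- selectTest(kindA, kindB,
                        contingencyMinCell = min(table(a, b)))
    } else {
      perCat <- vapply(split(as.numeric(a), b), isNormal, logical(1),
                       alpha = normalityAlpha)
      sel <- selectTest(kindA, kindB, perCategoryNormal = perCat)
    }
  }

  if (sel$test == "skipped") {
    stat <- NA_real_; p <- NA_real_; under <- FALSE
  } else {
    res <- runChosenTest(sel$test, a, b, kindA)
    stat <- res$statistic
    p <- res$p
    under <- is.finite(p) && p <= UNDERFLOW_P
    if (under) p <- 0
  }

  cp <- canonicalPair(nameA, nameB)
  data.frame(featureA = cp$a, featureB = cp$b, test = sel$test,
             reason = sel$reason, statistic = stat, pValue = p,
             underflow = under, stringsAsFactors = FALSE)
}

#' Scan all feature pairs and retain the significant ones
#'
#' Evaluates every unordered feature pair once, in canonical
#' (lexicographic) order, dispatching each through [comparePair()], and
#' keeps the pairs with `p <= alpha` where
#' `alpha = bonferroniAlpha(baseAlpha, nPairwise(m))` and `m` counts
#' every feature -- including those whose pairs end up skipped, since
#' the planned family is all pairs. Per-feature normality is assessed
#' once and cached. The result is independent of worker count and of
#' pair evaluation order.
#'
#' @param dataset A [MergedDataset-class] (imputed: no unknowns).
#' @param baseAlpha Family-wise level (default 0.05).
#' @param workers Number of parallel workers (forked; default 1).
#' @param normalityAlpha Level for the normality pre-test.
#' @return A [SignificantPairStore-class].
#' @export
scanAll <- function(dataset, baseAlpha = 0.05, workers = 1L,
                    normalityAlpha = 0.05) {
  df <- dataset@data
  kinds <- dataset@kinds
  m <- ncol(df)
  if (m < 2L) stop("need at least 2 features to scan", call. = FALSE)
  alpha <- bonferroniAlpha(baseAlpha, nPairwise(m))

  feats <- sort(colnames(df))  # canonical order
  cols <- lapply(df, function(v) if (is.numeric(v)) v else as.character(v))

  # cache per-feature normality up front (numeric features only)
  normalCache <- new.env(parent = emptyenv())
  for (nm in feats) {
    if (kinds[[nm]] == "numeric")
      normalCache[[nm]] <- isNormal(as.numeric(cols[[nm]]), normalityAlpha)
  }

  pairIdx <- utils::combn(length(feats), 2)
  evalPair <- function(k) {
    i <- pairIdx[1, k]; j <- pairIdx[2, k]
    nmA <- feats[i]; nmB <- feats[j]
    comparePair(cols[[nmA]], cols[[nmB]], nmA, nmB,
                kindA = kinds[[nmA]], kindB = kinds[[nmB]],
                normalityAlpha = normalityAlpha, normalCache = normalCache)
  }
  ks <- seq_len(ncol(pairIdx))
  results <- if (workers > 1L) {
    parallel::mclapply(ks, evalPair, mc.cores = workers)
  } else {
    lapply(ks, evalPair)
  }
  res <- do.call(rbind, results)
  sig <- res[!is.na(res$pValue) & (res$underflow | res$pValue <= alpha), ,
             drop = FALSE]
  sig$reason <- NULL
  makePairStore(sig, alpha)
}
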