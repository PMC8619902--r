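test_that("pairwise comparison counts follow m(m-1)/2", {
  expect_equal(nPairwise(2), 1)
  expect_equal(nPairwise(0), 0)
  expect_equal(nPairwise(1), 0)
  for (m in c(3, 10, 101)) expect_equal(nPairwise(m), choose(m, 2))
})

test_that("Bonferroni correction divides by the planned family size", {
  expect_equal(bonferroniAlpha(0.05, 1), 0.05)
  # oracle: long division carried to 10+ significant figures
  expect_equal(bonferroniAlpha(0.05, 1214628828), 4.116483888e-11,
               tolerance = 1e-10)
  expect_error(bonferroniAlpha(0.05, 0), "nComparisons")
})

test_that("the omnibus normality test matches its reference implementation", {
  # frozen reference values (scipy.stats.normaltest) on deterministic
  # fixtures reproducible here
  ref <- list(
    list(x = sin(1:50), k2 = 43.26765816707633, p = 4.022975674741114e-10),
    list(x = (1:30)^2, k2 = 3.8582005415682414, p = 0.14527885132570745),
    list(x = cos(1:12), k2 = 3.4157105010984194, p = 0.18125412071087982))
  for (r in ref) {
    res <- normalityTest(r$x)
    expect_equal(res$statistic, r$k2, tolerance = 1e-12)
    expect_equal(res$p.value, r$p, tolerance = 1e-12)
  }
})

test_that("isNormal behaves as a size-0.05 test on normal and skewed data", {
  hits <- vapply(1:100, function(s) {
    pairscan:::withSeed(s, isNormal(rnorm(500)))
  }, logical(1))
  expect_gte(mean(hits), 0.95)  # accepts normal draws at the test size
  skewHits <- vapply(1:20, function(s) {
    pairscan:::withSeed(s, isNormal(rexp(500)))
  }, logical(1))
  expect_false(any(skewHits))   # heavy skew is always rejected
  expect_false(isNormal(rnorm(5)))  # small samples take the
                                    # non-parametric branch
  expect_false(isNormal(rep(1, 50)))
})

test_that("test dispatch reproduces the full condition table", {
  # numeric/numeric: Pearson iff both normal
  for (na in c(TRUE, FALSE)) for (nb in c(TRUE, FALSE)) {
    sel <- selectTest("numeric", "numeric", normalA = na, normalB = nb)
    expect_identical(sel$test, if (na && nb) "pearson" else "spearman")
    expect_identical(sel$reason, "")
  }
  # nominal/nominal: chi-squared unless any contingency cell < 5
  for (cell in c(0, 1, 4, 5, 6, 100)) {
    sel <- selectTest("nominal", "nominal", contingencyMinCell = cell)
    if (cell < 5) {
      expect_identical(sel$test, "skipped")
      expect_match(sel$reason, "contingency")
    } else {
      expect_identical(sel$test, "chi_squared")
    }
  }
  # numeric/nominal: ANOVA iff every category is normal
  cases <- list(c(TRUE, TRUE), c(TRUE, FALSE), c(FALSE, FALSE),
                c(TRUE, TRUE, TRUE), c(TRUE, TRUE, FALSE))
  for (pcn in cases) {
    for (ordering in list(c("numeric", "nominal"), c("nominal", "numeric"))) {
      sel <- selectTest(ordering[1], ordering[2], perCategoryNormal = pcn)
      expect_identical(sel$test, if (all(pcn)) "anova" else "kruskal_wallis")
    }
  }
})

test_that("each test's p-value matches an independent reference", {
  # routes are independent: closed-form statistics in the package are
  # checked against base R's test functions, and base-R-backed tests
  # against first-principles formulas
  for (s in 1:25) {
    pairscan:::withSeed(s, {
      n <- sample(30:80, 1)
      x <- rnorm(n); y <- 0.3 * x + rnorm(n)
      g2 <- sample(c("a", "b"), n, replace = TRUE)
      g3 <- sample(c("a", "b", "c"), n, replace = TRUE)
      h <- sample(c("u", "v"), n, replace = TRUE)

      p <- pairscan:::runChosenTest("pearson", x, y, "numeric")
      expect_equal(p$p, cor.test(x, y)$p.value, tolerance = 1e-10)

      sp <- pairscan:::runChosenTest("spearman", x, exp(y), "numeric")
      expect_equal(sp$p,
                   suppressWarnings(cor.test(x, exp(y), method = "spearman",
                                             exact = FALSE))$p.value,
                   tolerance = 1e-10)

      cs <- pairscan:::runChosenTest("chi_squared", g2, h, "nominal")
      expect_equal(cs$p, oracleChisq(g2, h)$p, tolerance = 1e-10)

      av <- pairscan:::runChosenTest("anova", x, g3, "numeric")
      expect_equal(av$p,
                   oneway.test(x ~ factor(g3), var.equal = TRUE)$p.value,
                   tolerance = 1e-10)

      kw <- pairscan:::runChosenTest("kruskal_wallis", round(x, 1), g3,
                                     "numeric")
      expect_equal(kw$p, oracleKruskal(round(x, 1), g3)$p,
                   tolerance = 1e-10)
    })
  }
})

test_that("a chi-squared example reproduces the hand-computed value", {
  a <- rep(c("x", "x", "y", "y"), c(30, 10, 10, 30))
  b <- rep(c("p", "q", "p", "q"), c(30, 10, 10, 30))
  res <- comparePair(a, b, "A", "B", "nominal", "nominal")
  # [[30,10],[10,30]]: expected cells all 20, X2 = 4 * 100/20 = 20
  expect_equal(res$statistic, 20)
  expect_equal(res$pValue, pchisq(20, 1, lower.tail = FALSE),
               tolerance = 1e-12)
})

test_that("duplicate columns underflow; independent columns stay insignificant", {
  v <- pairscan:::withSeed(1, rnorm(200))
  dup <- comparePair(v, v + 0, "A", "B", "numeric", "numeric")
  expect_true(dup$underflow || dup$pValue < 1e-30)

  u1 <- pairscan:::withSeed(2, runif(200))
  u2 <- pairscan:::withSeed(3, runif(200))
  ind <- comparePair(u1, u2, "A", "B", "numeric", "numeric")
  expect_gt(ind$pValue, 1.40754e-13)
})

test_that("comparison is symmetric in its arguments", {
  pairscan:::withSeed(7, {
    x <- rnorm(60); y <- rnorm(60)
    g <- sample(c("a", "b", "c"), 60, replace = TRUE)
    h <- sample(c("p", "q"), 60, replace = TRUE)
    for (cols in list(list(x, y, "numeric", "numeric"),
                      list(x, g, "numeric", "nominal"),
                      list(g, h, "nominal", "nominal"))) {
      ab <- comparePair(cols[[1]], cols[[2]], "A", "B", cols[[3]], cols[[4]])
      ba <- comparePair(cols[[2]], cols[[1]], "B", "A", cols[[4]], cols[[3]])
      expect_identical(ab$pValue, ba$pValue)
      expect_identical(ab$test, ba$test)
      expect_identical(ab$featureA, ba$featureA)  # canonical order
    }
  })
})

test_that("degenerate columns are skipped with a reason", {
  res <- comparePair(rep("a", 50), rnorm(50), "G", "X", "nominal", "numeric")
  expect_identical(res$test, "skipped")
  expect_match(res$reason, "categories")
  res2 <- comparePair(rep(1, 50), rnorm(50), "C", "X", "numeric", "numeric")
  expect_identical(res2$test, "skipped")
  expect_true(is.na(res2$pValue))
})

test_that("a two-duplicate dataset scans to exactly one stored pair", {
  v <- pairscan:::withSeed(4, rnorm(100))
  ds <- numericDataset(cbind(A = v, B = v))
  store <- scanAll(ds)
  expect_equal(nrow(storedPairs(store)), 1)
  expect_true(storedPairs(store)$underflow)
})

test_that("independent features scan to an empty store", {
  m <- pairscan:::withSeed(8, matrix(rnorm(100 * 8), 100))
  store <- scanAll(numericDataset(m))
  expect_equal(nrow(storedPairs(store)), 0)
})

test_that("a planted block is recovered exactly among independent features", {
  gen <- generateTabularDomain(syntheticSpec(
    500, numericBlocks = list(c(4, 0.95)), nNoiseNumeric = 4, seed = 13))
  m <- as.matrix(gen$table[setdiff(colnames(gen$table), "RID")])
  store <- scanAll(numericDataset(m))
  got <- storedPairs(store)[, c("featureA", "featureB")]
  want <- plantedAssociations(gen$truth)
  want <- data.frame(featureA = pmin(want$a, want$b),
                     featureB = pmax(want$a, want$b))
  want <- want[order(want$featureA, want$featureB), ]
  rownames(want) <- NULL
  expect_identical(got, want)
  # oracle: every retained pair agrees with a direct per-pair test
  for (k in seq_len(nrow(got))) {
    direct <- comparePair(m[, got$featureA[k]], m[, got$featureB[k]],
                          got$featureA[k], got$featureB[k],
                          "numeric", "numeric")
    expect_lte(ifelse(direct$underflow, 0, direct$pValue), storeAlpha(store))
  }
})

test_that("the scan is deterministic across worker counts", {
  pd <- plantedDataset(n = 120, seed = 17)
  s1 <- scanAll(pd$dataset, workers = 1)
  s2 <- scanAll(pd$dataset, workers = 2)
  s4 <- scanAll(pd$dataset, workers = 4)
  expect_identical(storedPairs(s1), storedPairs(s2))
  expect_identical(storedPairs(s1), storedPairs(s4))
})

test_that("the alpha divisor counts all pairs, including skipped ones", {
  pairscan:::withSeed(5, {
    df <- data.frame(X = rnorm(60), Y = rnorm(60),
                     G = sample(c("a", "b"), 60, TRUE),
                     H = c(rep("p", 57), rep("q", 3)))  # tiny cell: skipped
  })
  ds <- new("MergedDataset", patientIds = sprintf("P%02d", 1:60), data = df,
            kinds = c(X = "numeric", Y = "numeric",
                      G = "nominal", H = "nominal"),
            domains = setNames(rep("clinical", 4), colnames(df)),
            untestable = character(0))
  store <- scanAll(ds, baseAlpha = 0.05)
  expect_equal(storeAlpha(store), 0.05 / nPairwise(4))
  expect_error(scanAll(numericDataset(matrix(rnorm(10), 10, 1))), "2 features")
})

test_that("the pair store index is symmetric and thresholded", {
  store <- storeFromEdges(c("A", "B"), c("B", "C"))
  expect_equal(nrow(pairsFor(store, "B")), 2)
  expect_equal(nrow(pairsFor(store, "A")), 1)
  expect_identical(pairsFor(store, "A")$featureB, "B")
  expect_true(all(storedPairs(store)$featureA < storedPairs(store)$featureB))
})
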