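test_that("feature-kind inference applies the cardinality rules", {
  expect_identical(inferFeatureKind(rep(1:9, 5)), "nominal")   # 9 distinct
  expect_identical(inferFeatureKind(rep(1:10, 5)), "numeric")  # 10 distinct
  expect_identical(inferFeatureKind(rep(letters[1:20], 3)), "nominal")
  expect_identical(inferFeatureKind(rep(letters[1:21], 3)), "drop")
  # unknown markers never count towards the distinct tally
  expect_identical(inferFeatureKind(c(rep(1:9, 5), NA)), "nominal")
  expect_identical(inferFeatureKind(c(rep(letters[1:20], 2), NA)), "nominal")
  # mixed text/number columns follow the text rules
  expect_identical(inferFeatureKind(c(as.character(1:15), "high")), "nominal")
  expect_identical(inferFeatureKind(c(as.character(1:25), "high")), "drop")
  # number-valued text parses as numeric
  expect_identical(inferFeatureKind(as.character(1:30)), "numeric")
  expect_identical(inferFeatureKind(rep(NA_character_, 5)), "drop")
})

test_that("longitudinal collapse keeps the latest known value per feature", {
  v <- data.frame(RID = c("A", "A", "B"), EXAMDATE = c(10, 20, 5),
                  X = c(1, 2, 7), Y = c("p", NA, "q"),
                  stringsAsFactors = FALSE)
  out <- collapseLongitudinal(v)
  expect_equal(nrow(out), 2)
  expect_equal(out$X[out$RID == "A"], 2)        # most recent wins
  expect_equal(out$Y[out$RID == "A"], "p")      # day-10 value retained over
                                                # the later unknown
  expect_equal(out$X[out$RID == "B"], 7)        # single visit: identity

  # tie dates and undated rows resolve to first occurrence in input order
  tie <- data.frame(RID = "A", EXAMDATE = c(10, 10), X = c(1, 2))
  expect_equal(collapseLongitudinal(tie)$X, 1)
  undated <- data.frame(RID = "A", X = c(3, 4))
  expect_equal(collapseLongitudinal(undated)$X, 3)
  # a dated known value beats an undated one regardless of order
  mixed <- data.frame(RID = "A", EXAMDATE = c(NA, 5), X = c(9, 1))
  expect_equal(collapseLongitudinal(mixed)$X, 1)
})

test_that("longitudinal collapse agrees with a per-feature brute-force scan", {
  gen <- generateTabularDomain(syntheticSpec(
    30, nNoiseNumeric = 3, longitudinal = TRUE, maxVisits = 4,
    missingFraction = 0.3, seed = 21))
  tb <- gen$table
  out <- collapseLongitudinal(tb)
  # oracle: scan every (patient, feature) for the latest non-missing entry
  for (cn in c("NOISE1", "NOISE2", "NOISE3")) {
    for (pid in unique(tb$RID)) {
      rows <- tb[tb$RID == pid, ]
      known <- rows[!is.na(rows[[cn]]), ]
      expected <- if (nrow(known)) known[[cn]][which.max(known$EXAMDATE)]
                  else NA_real_
      expect_identical(out[[cn]][out$RID == pid], expected)
    }
  }
})

test_that("merge capitalises headers, joins on patient ID and skips keyless tables", {
  t1 <- data.frame(RID = c("A", "B"), icv = c(1500, 1600))
  t2 <- data.frame(rid = c("A", "B"), age = c(70, 80))
  merged <- mergeTables(list(t1, t2))
  expect_setequal(colnames(merged), c("RID", "ICV", "AGE"))
  expect_equal(merged$ICV[merged$RID == "A"], 1500)

  dictionary <- data.frame(FLDNAME = c("ICV", "AGE"),
                           NOTES = c("volume", "years"))
  expect_warning(m2 <- mergeTables(list(t1, dictionary)), "no patient-ID")
  expect_setequal(colnames(m2), c("RID", "ICV"))
})

test_that("colliding columns resolve by recency, then input order", {
  t1 <- data.frame(RID = c("A", "B"), EXAMDATE = c(100, 100), X = c(1, 1))
  t2 <- data.frame(RID = c("A", "B"), EXAMDATE = c(200, 50), X = c(2, 2))
  m <- mergeTables(list(t1, t2))
  expect_equal(m$X[m$RID == "A"], 2)  # t2's record is newer for A
  expect_equal(m$X[m$RID == "B"], 1)  # t1's record is newer for B

  u1 <- data.frame(RID = "A", X = 1)
  u2 <- data.frame(RID = "A", X = 2)
  expect_equal(mergeTables(list(u1, u2))$X, 1)  # undated: first table wins
})

test_that("merge is order-insensitive for disjoint columns", {
  t1 <- data.frame(RID = c("A", "B", "C"), X = 1:3)
  t2 <- data.frame(RID = c("B", "C", "D"), Y = 4:6)
  t3 <- data.frame(RID = c("A", "D"), Z = 7:8)
  m1 <- mergeTables(list(t1, t2, t3))
  m2 <- mergeTables(list(t3, t1, t2))
  m2 <- m2[match(m1$RID, m2$RID), colnames(m1)]
  rownames(m2) <- NULL
  expect_identical(m1, m2)
  expect_equal(ncol(m1), 1 + 3)  # ID + disjoint union of features
})

test_that("feature filtering drops in order with one logged reason each", {
  n <- 100
  df <- data.frame(
    CONST = rep(1, n),
    LOWKNOWN = c(rnorm(79), rep(NA, 21)),          # 79% known
    ATBOUND = c(seq_len(80) / 7, rep(NA, 20)),     # exactly 80% known
    SMALLCAT = rep(c("a", "b"), c(81, 19)),        # category of 19
    OKCAT = rep(c("a", "b"), c(75, 25)),
    OKNUM = rnorm(n))
  dt <- makeDomainTable(df, sprintf("P%03d", 1:n), domain = "clinical")
  flt <- filterFeatures(dt)
  log <- attr(flt, "dropLog")
  expect_setequal(colnames(featureData(flt)), c("ATBOUND", "OKCAT", "OKNUM"))
  expect_identical(log$reason[log$feature == "CONST"], "single_value")
  expect_identical(log$reason[log$feature == "LOWKNOWN"], "low_known_fraction")
  expect_identical(log$reason[log$feature == "SMALLCAT"], "small_category")
  # count conservation: in = out + dropped, one reason per drop
  expect_equal(nFeatures(dt), nFeatures(flt) + nrow(log))
  expect_false(anyDuplicated(log$feature) > 0)
  # idempotence: filtering the filtered table changes nothing
  again <- filterFeatures(flt)
  expect_identical(featureData(again), featureData(flt))
  expect_equal(nrow(attr(again, "dropLog")), 0)
})

test_that("imputation fills every unknown and touches nothing known", {
  gen <- generateTabularDomain(syntheticSpec(
    120, numericBlocks = list(c(3, 0.9)), nNoiseNumeric = 2,
    nominalSpecs = list(list(nCategories = 2)),
    missingFraction = 0.15, seed = 31))
  dt <- makeDomainTable(gen$table[setdiff(colnames(gen$table), "RID")],
                        gen$table$RID, domain = "clinical")
  flt <- filterFeatures(dt, minCategory = 10)
  imp <- imputeMissing(flt, seed = 5)
  expect_equal(sum(is.na(featureData(imp))), 0)
  for (cn in colnames(featureData(flt))) {
    known <- !is.na(featureData(flt)[[cn]])
    expect_identical(featureData(imp)[[cn]][known],
                     featureData(flt)[[cn]][known])
  }
  # deterministic per seed
  expect_identical(featureData(imputeMissing(flt, seed = 5)),
                   featureData(imp))
  # a table with no unknowns passes through unchanged
  expect_identical(featureData(imputeMissing(imp, seed = 1)),
                   featureData(imp))
})

test_that("nominal imputation uses the modal category, ties lexicographic", {
  df <- data.frame(G = c(rep("A", 30), rep("B", 10), rep(NA, 5)),
                   T = c(rep(c("z", "y"), 20), rep(NA, 5)),
                   N = rnorm(45))
  dt <- makeDomainTable(df, sprintf("P%02d", 1:45),
                        kinds = c(G = "nominal", T = "nominal", N = "numeric"),
                        domain = "clinical")
  imp <- imputeMissing(dt, seed = 1)
  expect_true(all(featureData(imp)$G[41:45] == "A"))   # modal category
  expect_true(all(featureData(imp)$T[41:45] == "y"))   # 20-20 tie: lexicographic
})

test_that("expression shaping transposes and preserves values", {
  ex <- generateExpressionDomain(10, 5, seed = 8)
  shaped <- shapeExpression(ex$raw)
  expect_equal(dim(featureData(shaped)), c(5L, 10L))
  # oracle: direct index lookup in the raw features-as-rows matrix
  expect_equal(featureData(shaped)[["PROBE3_AT"]][2],
               as.numeric(ex$raw[ex$raw$ProbeSet == "PROBE3_AT", ][[3]]))
  expect_true(all(featureKinds(shaped) == "numeric"))

  noHeader <- ex$raw
  colnames(noHeader) <- sprintf("V%d", seq_len(ncol(noHeader)))
  expect_error(shapeExpression(noHeader), "patient-ID")
})

test_that("assembly intersects patients and adds feature counts", {
  mkdt <- function(ids, cols, domain) {
    df <- as.data.frame(matrix(rnorm(length(ids) * cols), length(ids)))
    colnames(df) <- sprintf("%s_F%d", toupper(domain), seq_len(cols))
    new("DomainTable", patientIds = ids, data = df,
        kinds = setNames(rep("numeric", cols), colnames(df)),
        domain = domain)
  }
  cl <- mkdt(c("A", "B", "C"), 3, "clinical")
  ex <- mkdt(c("B", "C"), 2, "expression")
  lat <- new("LatentMatrix", patientIds = "C",
             values = matrix(rnorm(4), 1, 4,
                             dimnames = list(NULL, sprintf("SLICE1_L%d", 1:4))),
             sliceIndex = rep(1L, 4L), latentDim = 4L)
  ds <- assembleDataset(cl, ex, lat)
  expect_identical(patientIds(ds), "C")
  fc <- featureCounts(ds)
  expect_equal(unname(fc["total"]),
               unname(fc["clinical"] + fc["expression"] + fc["image"]))
  expect_equal(unname(fc["total"]), 9)

  # any domain absent: the total is the sum of the others
  ds2 <- assembleDataset(cl, ex)
  expect_equal(unname(featureCounts(ds2)["total"]), 5)

  ex2 <- mkdt(c("X", "Y"), 2, "expression")
  expect_error(assembleDataset(cl, ex2), "no patients")
})
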