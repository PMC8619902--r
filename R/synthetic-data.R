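# Synthetic multi-domain data with known correlation structure.
#
# The generator emulates the data regime of a large observational
# neuro-imaging cohort at desk scale: a longitudinal clinical table with
# mixed numeric/nominal columns, identifier-like metadata, duplicated
# columns under different names and per-feature missingness; a wide
# expression matrix that needs transposing and stripping; and per-patient
# ordered grayscale slice stacks with smooth learnable content.

#' Specification of a synthetic tabular domain
#'
#' @param nPatients Number of patients (positive integer).
#' @param numericBlocks List of `c(size, rho)` pairs: each block is
#'   `size >= 2` numeric features drawn from a compound-symmetric
#'   multivariate normal with pairwise correlation `rho` in \[0, 1\].
#' @param nNoiseNumeric Number of mutually independent numeric features.
#' @param nominalSpecs List of `list(nCategories =, partner =, effect =)`
#'   entries. When `partner` is `TRUE`, a companion numeric feature is
#'   generated whose mean shifts by `effect` standard deviations per
#'   category, so the pair is detectable by ANOVA/Kruskal-Wallis.
#' @param missingFraction Either a single fraction in \[0, 1\] applied to
#'   every feature column, or a named vector of per-feature fractions.
#' @param nMetadata Number of identifier-like text columns (unique per
#'   patient, so they exceed the nominal cardinality cap and are dropped
#'   by type inference).
#' @param nDuplicatePairs Number of planted pairs of bit-identical numeric
#'   columns under distinct names.
#' @param longitudinal `TRUE` to emit 1..`maxVisits` dated rows per
#'   patient instead of one row each.
#' @param maxVisits Maximum visits per patient when `longitudinal`.
#' @param stratSex,stratCDR Include a two-level sex column / a three-level
#'   dementia-rating column (values 0, 0.5, 1) for stratified reanalysis.
#' @param seed Integer seed; generation is deterministic per seed.
#' @return A validated `syntheticSpec` list.
#' @export
#' @examples
#' sp <- syntheticSpec(nPatients = 100,
#'                     numericBlocks = list(c(4, 0.95)),
#'                     nNoiseNumeric = 5, seed = 1)
syntheticSpec <- function(nPatients,
                          numericBlocks = list(),
                          nNoiseNumeric = 0L,
                          nominalSpecs = list(),
                          missingFraction = 0,
                          nMetadata = 0L,
                          nDuplicatePairs = 0L,
                          longitudinal = FALSE,
                          maxVisits = 3L,
                          stratSex = FALSE,
                          stratCDR = FALSE,
                          seed = 1L) {
  if (!is.numeric(nPatients) || length(nPatients) != 1L || nPatients < 1)
    specStop("nPatients", "must be a positive integer")
  for (blk in numericBlocks) {
    if (length(blk) != 2L)
      specStop("numericBlocks", "each block must be c(size, rho)")
    if (blk[1] < 2) specStop("numericBlocks", "block size must be >= 2")
    if (blk[2] < 0 || blk[2] > 1)
      specStop("numericBlocks", "within-block correlation must be in [0, 1]")
  }
  if (nNoiseNumeric < 0) specStop("nNoiseNumeric", "must be >= 0")
  for (nom in nominalSpecs) {
    if (is.null(nom$nCategories) || nom$nCategories < 2)
      specStop("nominalSpecs", "nCategories must be >= 2")
  }
  mf <- unlist(missingFraction)
  if (any(mf < 0 | mf > 1))
    specStop("missingFraction", "fractions must be in [0, 1]")
  if (nMetadata < 0) specStop("nMetadata", "must be >= 0")
  if (nDuplicatePairs < 0) specStop("nDuplicatePairs", "must be >= 0")
  if (longitudinal && maxVisits < 1)
    specStop("maxVisits", "must be >= 1 when longitudinal")
  structure(list(nPatients = as.integer(nPatients),
                 numericBlocks = numericBlocks,
                 nNoiseNumeric = as.integer(nNoiseNumeric),
                 nominalSpecs = nominalSpecs,
                 missingFraction = missingFraction,
                 nMetadata = as.integer(nMetadata),
                 nDuplicatePairs = as.integer(nDuplicatePairs),
                 longitudinal = isTRUE(longitudinal),
                 maxVisits = as.integer(maxVisits),
                 stratSex = isTRUE(stratSex),
                 stratCDR = isTRUE(stratCDR),
                 seed = as.integer(seed)),
            class = "syntheticSpec")
}

# Compound-symmetric multivariate normal via a shared latent factor:
# x_j = sqrt(rho) z + sqrt(1 - rho) e_j gives cor(x_i, x_j) = rho.
rCompoundSymmetric <- function(n, size, rho) {
  z <- rnorm(n)
  sapply(seq_len(size), function(j) sqrt(rho) * z + sqrt(1 - rho) * rnorm(n))
}

#' Generate a synthetic clinical-style tabular domain
#'
#' Produces a visit-level (or patient-level) table with the structural
#' quirks the preprocessing stage must handle -- longitudinal duplication
#' with dates, identifier metadata, bit-identical duplicate columns,
#' per-feature missingness, stratification columns -- plus the ground
#' truth of every planted association.
#'
#' @param spec A [syntheticSpec()].
#' @return A list with elements `table` (a `data.frame` with `RID` and,
#'   if longitudinal, `EXAMDATE` integer day offsets) and `truth` (a
#'   [GroundTruth-class]).
#' @export
#' @examples
#' out <- generateTabularDomain(syntheticSpec(50, list(c(3, 0.9)), seed = 2))
#' head(out$table)
#' out$truth
generateTabularDomain <- function(spec) {
  stopifnot(inherits(spec, "syntheticSpec"))
  withSeed(spec$seed, {
    n <- spec$nPatients
    ids <- sprintf("P%04d", seq_len(n))
    df <- data.frame(RID = ids, stringsAsFactors = FALSE)

    blockMembership <- character(0)
    planted <- list()
    dupPairs <- list()

    # planted correlated numeric blocks
    for (b in seq_along(spec$numericBlocks)) {
      blk <- spec$numericBlocks[[b]]
      size <- as.integer(blk[1]); rho <- blk[2]
      m <- rCompoundSymmetric(n, size, rho)
      nms <- sprintf("BLK%d_F%d", b, seq_len(size))
      colnames(m) <- nms
      df <- cbind(df, as.data.frame(m))
      blockMembership[nms] <- sprintf("block%d", b)
      cmb <- utils::combn(nms, 2)
      planted[[length(planted) + 1L]] <-
        data.frame(a = cmb[1, ], b = cmb[2, ], stringsAsFactors = FALSE)
    }

    # independent numeric noise
    if (spec$nNoiseNumeric > 0) {
      m <- matrix(rnorm(n * spec$nNoiseNumeric), n)
      colnames(m) <- sprintf("NOISE%d", seq_len(spec$nNoiseNumeric))
      df <- cbind(df, as.data.frame(m))
    }

    # nominal features, optionally with an associated numeric partner
    for (k in seq_along(spec$nominalSpecs)) {
      nom <- spec$nominalSpecs[[k]]
      nc <- as.integer(nom$nCategories)
      cats <- sprintf("C%d", seq_len(nc))
      # balanced assignment so categories survive the size-20 filter
      lv <- sample(rep_len(cats, n))
      nm <- sprintf("NOM%d", k)
      df[[nm]] <- lv
      if (isTRUE(nom$partner)) {
        effect <- if (is.null(nom$effect)) 1 else nom$effect
        pnm <- sprintf("NOM%d_PARTNER", k)
        df[[pnm]] <- rnorm(n) + effect * (match(lv, cats) - 1)
        planted[[length(planted) + 1L]] <-
          data.frame(a = nm, b = pnm, stringsAsFactors = FALSE)
      }
    }

    # bit-identical duplicate columns under distinct names
    for (k in seq_len(spec$nDuplicatePairs)) {
      v <- rnorm(n)
      a <- sprintf("DUP%d_A", k); b <- sprintf("DUP%d_B", k)
      df[[a]] <- v
      df[[b]] <- v
      dupPairs[[k]] <- data.frame(a = a, b = b, stringsAsFactors = FALSE)
      planted[[length(planted) + 1L]] <- dupPairs[[k]]
    }

    # identifier-like metadata (unique text -> dropped by type inference)
    for (k in seq_len(spec$nMetadata)) {
      df[[sprintf("META%d", k)]] <- sprintf("ID%d_%06d", k, sample.int(1e6, n))
    }

    # stratification columns
    if (spec$stratSex)
      df$PTGENDER <- sample(c("Female", "Male"), n, replace = TRUE)
    if (spec$stratCDR)
      df$CDR <- sample(c(0, 0.5, 1), n, replace = TRUE)

    featCols <- setdiff(colnames(df), "RID")

    # longitudinal duplication: earlier visits perturb numeric values;
    # the most recent visit carries the generated (final) value
    if (spec$longitudinal) {
      visits <- sample.int(spec$maxVisits, n, replace = TRUE)
      rows <- list()
      for (i in seq_len(n)) {
        v <- visits[i]
        dates <- sort(sample.int(3650, v))
        for (j in seq_len(v)) {
          r <- df[i, , drop = FALSE]
          if (j < v) {
            for (cn in featCols) {
              if (is.numeric(r[[cn]]) && !cn %in% c("CDR"))
                r[[cn]] <- r[[cn]] + rnorm(1, sd = 0.1)
            }
          }
          r$EXAMDATE <- dates[j]
          rows[[length(rows) + 1L]] <- r
        }
      }
      df <- do.call(rbind, rows)
      rownames(df) <- NULL
    }

    # per-feature missingness (never on RID/EXAMDATE)
    mf <- spec$missingFraction
    for (cn in featCols) {
      frac <- if (length(mf) == 1L && is.null(names(mf))) mf[[1]]
              else if (cn %in% names(mf)) mf[[cn]] else 0
      if (frac > 0) {
        nr <- nrow(df)
        hit <- sample.int(nr, round(frac * nr))
        df[hit, cn] <- NA
      }
    }

    planted <- if (length(planted)) do.call(rbind, planted)
               else data.frame(a = character(0), b = character(0))
    dupPairs <- if (length(dupPairs)) do.call(rbind, dupPairs)
                else data.frame(a = character(0), b = character(0))
    truth <- new("GroundTruth", blockMembership = blockMembership,
                 plantedAssociations = planted, duplicatePairs = dupPairs)
    list(table = df, truth = truth)
  })
}

#' Generate a synthetic expression-style matrix
#'
#' Emits the matrix in features-as-rows orientation, as microarray
#' exports arrive: a `ProbeSet` name column followed by one column per
#' patient. A metadata row (text values) and a row with an empty feature
#' name are injected so [shapeExpression()] has something to strip.
#' Planted probe pairs share a latent factor (correlation 0.95).
#'
#' @param nProbes Number of probe features (>= 1).
#' @param nPatients Number of patients.
#' @param nCorrelatedPairs Number of planted highly correlated probe
#'   pairs (consumes `2 * nCorrelatedPairs` of the probes).
#' @param seed Integer seed.
#' @return A list with `raw` (the features-as-rows `data.frame`) and
#'   `truth` (a [GroundTruth-class] with the planted pairs).
#' @export
#' @examples
#' ex <- generateExpressionDomain(10, 25, nCorrelatedPairs = 2, seed = 3)
#' dim(ex$raw)
generateExpressionDomain <- function(nProbes, nPatients,
                                     nCorrelatedPairs = 0L, seed = 1L) {
  if (nProbes < 1) specStop("nProbes", "must be >= 1")
  if (2 * nCorrelatedPairs > nProbes)
    specStop("nCorrelatedPairs", "needs 2 probes per pair")
  withSeed(seed, {
    ids <- sprintf("P%04d", seq_len(nPatients))
    probes <- sprintf("PROBE%d_AT", seq_len(nProbes))
    vals <- matrix(rnorm(nProbes * nPatients), nrow = nProbes)
    planted <- list()
    for (k in seq_len(nCorrelatedPairs)) {
      i <- 2L * k - 1L; j <- 2L * k
      m <- rCompoundSymmetric(nPatients, 2L, 0.95)
      vals[i, ] <- m[, 1]; vals[j, ] <- m[, 2]
      planted[[k]] <- data.frame(a = probes[i], b = probes[j],
                                 stringsAsFactors = FALSE)
    }
    raw <- data.frame(ProbeSet = probes, stringsAsFactors = FALSE)
    raw[ids] <- as.data.frame(vals)
    # metadata row: text values, not expression
    metaRow <- c("SAMPLE_BARCODE", sprintf("BC%06d", sample.int(1e6, nPatients)))
    # headerless row: empty feature name
    blankRow <- c("", as.character(round(rnorm(nPatients), 6)))
    raw[] <- lapply(raw, as.character)
    raw <- rbind(raw, setNames(as.list(metaRow), colnames(raw)),
                 setNames(as.list(blankRow), colnames(raw)))
    rownames(raw) <- NULL
    planted <- if (length(planted)) do.call(rbind, planted)
               else data.frame(a = character(0), b = character(0))
    truth <- new("GroundTruth", blockMembership = character(0),
                 plantedAssociations = planted,
                 duplicatePairs = data.frame(a = character(0), b = character(0)))
    list(raw = raw, truth = truth)
  })
}

#' Generate per-patient ordered image-slice stacks
#'
#' Each slice is a grayscale array containing a smooth elliptical blob
#' whose size and position vary per patient and drift across slice
#' indices, over a low level of noise -- structured content an
#' autoencoder can actually compress, unlike pure noise.
#'
#' @param nPatients,nSlices Number of patients and slices per patient.
#' @param height,width Slice dimensions in pixels (>= 1).
#' @param seed Integer seed.
#' @return Named list (by patient ID) of lists of `height x width`
#'   matrices with values in \[0, 1\), each slice guaranteed
#'   non-constant.
#' @export
#' @examples
#' st <- generateImageStacks(3, 4, 16, 16, seed = 1)
#' dim(st[["P0001"]][[2]])
generateImageStacks <- function(nPatients, nSlices, height, width, seed = 1L) {
  stopifnot(nPatients >= 1, nSlices >= 1, height >= 1, width >= 1)
  withSeed(seed, {
    ids <- sprintf("P%04d", seq_len(nPatients))
    ys <- seq_len(height); xs <- seq_len(width)
    stacks <- lapply(seq_len(nPatients), function(i) {
      cy <- runif(1, 0.35, 0.65) * height
      cx <- runif(1, 0.35, 0.65) * width
      ry0 <- runif(1, 0.15, 0.3) * height
      rx0 <- runif(1, 0.15, 0.3) * width
      amp <- runif(1, 0.6, 0.95)
      lapply(seq_len(nSlices), function(s) {
        # radius drifts smoothly across the stack, vanishing at the ends
        g <- sin(pi * s / (nSlices + 1))
        ry <- ry0 * (0.5 + 0.5 * g); rx <- rx0 * (0.5 + 0.5 * g)
        d2 <- outer((ys - cy)^2 / ry^2, (xs - cx)^2 / rx^2, "+")
        img <- amp * exp(-d2) + matrix(runif(height * width, 0, 0.02),
                                       height, width)
        img / 1.02  # keep within [0, 1)
      })
    })
    names(stacks) <- ids
    stacks
  })
}

#' Ground-truth accessors
#'
#' @param truth A [GroundTruth-class].
#' @return `blockMembership()`: named character vector feature -> block;
#'   `plantedAssociations()` / `duplicatePairs()`: `data.frame`s with
#'   columns `a`, `b`.
#' @export
blockMembership <- function(truth) truth@blockMembership

#' @rdname blockMembership
#' @export
plantedAssociations <- function(truth) truth@plantedAssociations

#' @rdname blockMembership
#' @export
duplicatePairs <- function(truth) truth@duplicatePairs
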