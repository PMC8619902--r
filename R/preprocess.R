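# Cleaning, typing, collapsing, merging, filtering and imputing the
# tabular domains into one analysis-ready dataset.

#' Infer a feature's kind from its raw values
#'
#' Number-valued columns are numeric unless they show fewer than ten
#' distinct observed values, in which case they are treated as nominal
#' (low-cardinality codes behave like categories). Text-valued columns
#' are nominal unless they show more than 20 distinct values, in which
#' case they are dropped as identifier-like (near-unique IDs or
#' free-text notes). Unknown markers (`NA`) never count towards the
#' distinct tally. Columns mixing text and numbers are treated as text.
#'
#' @param values Raw column values (any atomic vector).
#' @return One of `"numeric"`, `"nominal"`, `"drop"`.
#' @export
#' @examples
#' inferFeatureKind(rnorm(50))            # "numeric"
#' inferFeatureKind(rep(1:5, 10))         # "nominal" (9 or fewer levels)
#' inferFeatureKind(sprintf("id%03d", 1:50)) # "drop"
inferFeatureKind <- function(values) {
  known <- values[!is.na(values)]
  if (!length(known)) return("drop")
  if (is.numeric(known)) {
    num <- known
  } else {
    num <- suppressWarnings(as.numeric(as.character(known)))
    if (anyNA(num)) num <- NULL  # mixed or text column
  }
  if (!is.null(num)) {
    if (length(unique(num)) >= 10L) "numeric" else "nominal"
  } else {
    if (length(unique(as.character(known))) <= 20L) "nominal" else "drop"
  }
}

#' Collapse a longitudinal visit-level table to one row per patient
#'
#' For every feature independently, keeps the value from the latest
#' dated visit at which the feature is known; an earlier known value is
#' preferred over a later unknown one. Rows with no usable date are
#' considered only when no dated value exists, and ties (equal dates, or
#' several undated rows) resolve to the first occurrence in stable input
#' order, making the "arbitrary" choice reproducible. Patients with no
#' known value for a feature get the unknown marker.
#'
#' @param df Visit-level `data.frame`.
#' @param idCol Patient-ID column name.
#' @param dateCol Date column name (numeric day offsets or anything
#'   coercible to numeric order); may be absent.
#' @return A `data.frame` with one row per patient, `idCol` first and
#'   `dateCol` removed. Patient order is first appearance.
#' @export
#' @examples
#' v <- data.frame(RID = c("A", "A"), EXAMDATE = c(10, 20), X = c(1, 2))
#' collapseLongitudinal(v)  # keeps X = 2
collapseLongitudinal <- function(df, idCol = "RID", dateCol = "EXAMDATE") {
  if (!idCol %in% colnames(df))
    stop(sprintf("patient-ID column '%s' not found", idCol), call. = FALSE)
  ids <- unique(as.character(df[[idCol]]))
  feats <- setdiff(colnames(df), c(idCol, dateCol))
  dates <- if (dateCol %in% colnames(df))
    suppressWarnings(as.numeric(df[[dateCol]])) else rep(NA_real_, nrow(df))
  dates[is.na(dates)] <- -Inf
  rowsOf <- split(seq_len(nrow(df)),
                  factor(as.character(df[[idCol]]), levels = ids))
  out <- setNames(data.frame(ids, stringsAsFactors = FALSE), idCol)
  for (cn in feats) {
    v <- df[[cn]]
    pick <- vapply(rowsOf, function(ii) {
      known <- ii[!is.na(v[ii])]
      if (!length(known)) return(NA_integer_)
      d <- dates[known]
      known[d == max(d)][1L]  # ties/undated: first in input order
    }, integer(1))
    out[[cn]] <- v[pick]
  }
  out
}

#' Merge several raw tables into one patient-level table
#'
#' Headers are capitalised before anything else, so that the same
#' feature spelled in different cases in different tables collides and
#' is merged. Each table is collapsed to one row per patient, then
#' joined on patient ID (outer join over the union of patients). When
#' two tables carry an identically named column, each patient takes the
#' value from the table whose record for that patient is most recent;
#' with no dates to compare, the earlier table in input order wins.
#' Tables without a recognisable patient-ID column are skipped with a
#' warning (a data dictionary, say, carries no patient rows).
#'
#' @param tables List of visit- or patient-level `data.frame`s.
#' @param idCols Candidate patient-ID column names, checked in order
#'   after capitalisation.
#' @param dateCol Date column name used for recency.
#' @return A patient-level `data.frame` keyed by `idCols[1]`.
#' @export
mergeTables <- function(tables, idCols = c("RID", "PTID", "PATIENT_ID"),
                        dateCol = "EXAMDATE") {
  prepared <- list()
  for (k in seq_along(tables)) {
    tb <- tables[[k]]
    colnames(tb) <- toupper(colnames(tb))
    idc <- idCols[idCols %in% colnames(tb)][1]
    if (is.na(idc)) {
      warning(sprintf("table %d has no patient-ID column; skipped", k),
              call. = FALSE)
      next
    }
    pid <- as.character(tb[[idc]])
    d <- if (dateCol %in% colnames(tb))
      suppressWarnings(as.numeric(tb[[dateCol]])) else rep(NA_real_, nrow(tb))
    d[is.na(d)] <- -Inf
    lastDate <- tapply(d, factor(pid, levels = unique(pid)), max)
    colnames(tb)[colnames(tb) == idc] <- idCols[1]
    prepared[[length(prepared) + 1L]] <-
      list(tab = collapseLongitudinal(tb, idCols[1], dateCol),
           lastDate = lastDate)
  }
  if (!length(prepared)) stop("no mergeable tables", call. = FALSE)

  allIds <- unique(unlist(lapply(prepared, function(p) p$tab[[idCols[1]]])))
  out <- setNames(data.frame(allIds, stringsAsFactors = FALSE), idCols[1])
  recency <- list()  # per merged column, the source recency per patient
  for (p in prepared) {
    loc <- match(allIds, p$tab[[idCols[1]]])
    present <- !is.na(loc)
    srcDate <- rep(-Inf, length(allIds))
    srcDate[present] <- as.numeric(p$lastDate[p$tab[[idCols[1]]][loc[present]]])
    for (cn in setdiff(colnames(p$tab), idCols[1])) {
      vals <- p$tab[[cn]][loc]
      if (!cn %in% colnames(out)) {
        out[[cn]] <- vals
        recency[[cn]] <- ifelse(present, srcDate, -Inf)
      } else {
        newer <- present & srcDate > recency[[cn]]
        if (any(newer)) {
          out[[cn]][newer] <- vals[newer]
          recency[[cn]][newer] <- srcDate[newer]
        }
      }
    }
  }
  out
}

#' Filter uninformative and under-observed features
#'
#' Applies, in order: (1) drop columns with fewer than two distinct
#' observed values; (2) drop columns known for less than `knownMin` of
#' patients; (3) drop nominal columns any of whose observed categories
#' holds fewer than `minCategory` patients (too small for the
#' contingency and group tests downstream). Each dropped feature is
#' logged with exactly one reason, the first that applied.
#'
#' @param dt A [DomainTable-class].
#' @param knownMin Minimum known fraction (default 0.80).
#' @param minCategory Minimum patients per nominal category (default 20).
#' @return The filtered `DomainTable`, with a `data.frame` attribute
#'   `"dropLog"` (columns `feature`, `reason`).
#' @export
filterFeatures <- function(dt, knownMin = 0.8, minCategory = 20L) {
  df <- dt@data
  kinds <- dt@kinds
  n <- nrow(df)
  reasons <- character(0)
  for (cn in colnames(df)) {
    v <- df[[cn]]
    if (nDistinctKnown(v) < 2L) {
      reasons[cn] <- "single_value"
    } else if (sum(!is.na(v)) / n < knownMin) {
      reasons[cn] <- "low_known_fraction"
    } else if (kinds[[cn]] == "nominal") {
      sizes <- table(v[!is.na(v)])
      if (any(sizes < minCategory)) reasons[cn] <- "small_category"
    }
  }
  keep <- setdiff(colnames(df), names(reasons))
  out <- new("DomainTable", patientIds = dt@patientIds,
             data = df[, keep, drop = FALSE], kinds = kinds[keep],
             domain = dt@domain)
  attr(out, "dropLog") <- data.frame(feature = names(reasons),
                                     reason = unname(reasons),
                                     stringsAsFactors = FALSE)
  out
}

# Modal category with lexicographic tie-break.
modalCategory <- function(v) {
  tab <- table(as.character(v[!is.na(v)]))
  sort(names(tab)[tab == max(tab)])[1L]
}

#' Impute remaining unknown values
#'
#' Nominal unknowns become the most frequent known category (ties broken
#' lexicographically). Numeric unknowns are filled by an iterative
#' regression imputer: starting from column means, each numeric feature
#' with missing entries is regressed on all other numeric features with
#' a ridge-regularised linear model and its missing entries replaced by
#' the fit, cycling in a seeded random order for a fixed number of
#' rounds. Known values are never modified, and the result is
#' deterministic per seed.
#'
#' @param dt A filtered [DomainTable-class].
#' @param seed Integer seed for the visit order of the iterative pass.
#' @param maxIter Number of imputation rounds (default 10).
#' @param ridge Ridge penalty on the standardised regression (default
#'   1e-3).
#' @return A `DomainTable` with no unknown markers.
#' @export
imputeMissing <- function(dt, seed = 1L, maxIter = 10L, ridge = 1e-3) {
  df <- dt@data
  kinds <- dt@kinds
  numCols <- names(kinds)[kinds == "numeric"]
  nomCols <- names(kinds)[kinds == "nominal"]

  for (cn in nomCols) {
    v <- df[[cn]]
    if (anyNA(v)) df[[cn]][is.na(v)] <- modalCategory(v)
  }

  if (length(numCols)) {
    X <- as.matrix(as.data.frame(lapply(df[numCols], as.numeric)))
    colnames(X) <- numCols
    miss <- is.na(X)
    if (any(colSums(!miss) == 0))
      stop("numeric feature with no known values; filter first", call. = FALSE)
    if (any(miss)) {
      mu <- colMeans(X, na.rm = TRUE)
      for (j in seq_along(numCols)) X[miss[, j], j] <- mu[j]
      needs <- which(colSums(miss) > 0)
      if (length(numCols) >= 2L) {
        withSeed(seed, {
          for (iter in seq_len(maxIter)) {
            for (j in sample(needs)) {
              others <- X[, -j, drop = FALSE]
              A <- scale(others)
              A[, attr(A, "scaled:scale") == 0] <- 0
              y <- X[!miss[, j], j]
              Ak <- A[!miss[, j], , drop = FALSE]
              p <- ncol(Ak)
              beta <- solve(crossprod(Ak) + ridge * diag(p), crossprod(Ak, y - mean(y)))
              pred <- mean(y) + A[miss[, j], , drop = FALSE] %*% beta
              X[miss[, j], j] <- pred
            }
          }
        })
      }  # a lone numeric column keeps its mean fill
      df[numCols] <- as.data.frame(X)
    }
  }

  new("DomainTable", patientIds = dt@patientIds, data = df,
      kinds = kinds, domain = dt@domain)
}

#' Shape a features-as-rows expression matrix into a DomainTable
#'
#' Expression exports arrive transposed: one row per probe, one column
#' per patient, the first column holding probe names. This transposes to
#' patients x probes and strips what cannot be an expression feature --
#' rows with an empty name (headerless after transposition) and rows
#' whose values are not numeric (injected metadata).
#'
#' @param raw `data.frame`; column 1 = feature names, remaining columns
#'   named by patient IDs.
#' @return An expression-domain [DomainTable-class], all columns
#'   numeric.
#' @export
shapeExpression <- function(raw) {
  if (ncol(raw) < 2L) stop("no patient columns in expression matrix",
                           call. = FALSE)
  ids <- colnames(raw)[-1]
  if (any(ids == "" | is.na(ids)) || anyDuplicated(ids) ||
      all(grepl("^V[0-9]+$", ids)))
    stop("expression matrix has no patient-ID header", call. = FALSE)
  nms <- as.character(raw[[1]])
  keepRows <- which(!is.na(nms) & nms != "")
  cols <- list()
  for (i in keepRows) {
    v <- suppressWarnings(as.numeric(unlist(raw[i, -1])))
    if (anyNA(v)) next  # metadata row -> metadata column post-transpose
    cols[[toupper(nms[i])]] <- v
  }
  if (!length(cols)) stop("no numeric probe rows found", call. = FALSE)
  df <- as.data.frame(cols, optional = TRUE)
  new("DomainTable", patientIds = ids, data = df,
      kinds = setNames(rep("numeric", ncol(df)), colnames(df)),
      domain = "expression")
}

#' Assemble the merged multi-domain dataset
#'
#' Restricts all domains to the patients present in every one of them
#' and concatenates their feature columns, recording each feature's
#' domain of origin. The total feature count is by construction the sum
#' of the per-domain counts.
#'
#' @param clinical Clinical [DomainTable-class].
#' @param expression Expression [DomainTable-class], or `NULL`.
#' @param image A [LatentMatrix-class] (image domain), or `NULL`.
#' @return A [MergedDataset-class].
#' @export
assembleDataset <- function(clinical, expression = NULL, image = NULL) {
  ids <- patientIds(clinical)
  if (!is.null(expression)) ids <- ids[ids %in% patientIds(expression)]
  if (!is.null(image)) ids <- ids[ids %in% patientIds(image)]
  if (!length(ids)) stop("no patients shared by all domains", call. = FALSE)

  pieces <- list()
  kinds <- character(0)
  domains <- character(0)

  addDomain <- function(df, kd, label) {
    pieces[[length(pieces) + 1L]] <<- df
    kinds <<- c(kinds, kd)
    domains <<- c(domains, setNames(rep(label, length(kd)), names(kd)))
  }
  cl <- clinical@data[match(ids, clinical@patientIds), , drop = FALSE]
  addDomain(cl, clinical@kinds, "clinical")
  if (!is.null(expression)) {
    ex <- expression@data[match(ids, expression@patientIds), , drop = FALSE]
    addDomain(ex, expression@kinds, "expression")
  }
  if (!is.null(image)) {
    im <- as.data.frame(image@values[match(ids, image@patientIds), ,
                                     drop = FALSE])
    addDomain(im, setNames(rep("numeric", ncol(im)), colnames(im)), "image")
  }
  data <- do.call(cbind, pieces)
  rownames(data) <- NULL
  new("MergedDataset", patientIds = ids, data = data, kinds = kinds,
      domains = domains, untestable = character(0))
}
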