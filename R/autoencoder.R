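# Tabularising image stacks: min-max normalisation, per-slice
# convolutional autoencoders, and concatenation of latent vectors.
#
# The autoencoder is a compact symmetric design implemented directly in
# R: stride-2 3x3 convolutions (ReLU) halving the spatial dimensions
# until they are at most 8x8, a dense linear map to the latent space,
# and a mirrored decoder (dense, then nearest-neighbour upsampling
# followed by 3x3 convolutions, sigmoid output), trained by Adam on
# mean-squared reconstruction error. Convolutions use im2col matrix
# multiplication; everything is deterministic per seed.

#' Min-max normalise a slice to \[0, 1\]
#'
#' `(x - min) / (max - min)` element-wise, so the output attains 0 and 1
#' exactly. A constant slice has no defined normalisation and is an
#' error.
#'
#' @param x Numeric matrix (or array).
#' @return The rescaled object, same shape.
#' @export
#' @examples
#' minmaxNormalize(matrix(c(0, 5, 10, 2), 2))
minmaxNormalize <- function(x) {
  lo <- min(x); hi <- max(x)
  if (lo == hi)
    stop("constant slice: min-max normalisation undefined", call. = FALSE)
  (x - lo) / (hi - lo)
}

#' Autoencoder hyper-parameters
#'
#' @param inputHeight,inputWidth Slice dimensions in pixels. Each must
#'   halve cleanly (stay even) down to the 8-pixel bottleneck.
#' @param latentDim Latent dimension per slice; must be smaller than
#'   `inputHeight * inputWidth` (it is a compression). Desk default 64;
#'   full-scale runs use larger values (e.g. 6400 at 128x128).
#' @param epochs,learningRate,batchSize Adam training parameters.
#' @param seed Integer seed controlling weight initialisation and batch
#'   shuffling.
#' @return A validated `autoencoderSpec` list.
#' @export
#' @examples
#' autoencoderSpec(16, 16, latentDim = 16, epochs = 3, seed = 1)
autoencoderSpec <- function(inputHeight, inputWidth, latentDim = 64L,
                            epochs = 5L, learningRate = 1e-3,
                            batchSize = 16L, seed = 1L) {
  if (latentDim >= inputHeight * inputWidth)
    specStop("latentDim", "must be smaller than the input pixel count")
  if (latentDim < 1) specStop("latentDim", "must be positive")
  h <- inputHeight; w <- inputWidth
  nLayers <- 0L
  while (max(h, w) > 8L) {
    if (h %% 2L || w %% 2L)
      specStop("inputHeight/inputWidth",
               "must halve cleanly to the 8-pixel bottleneck")
    h <- h %/% 2L; w <- w %/% 2L
    nLayers <- nLayers + 1L
  }
  structure(list(inputHeight = as.integer(inputHeight),
                 inputWidth = as.integer(inputWidth),
                 latentDim = as.integer(latentDim),
                 epochs = as.integer(epochs),
                 learningRate = learningRate,
                 batchSize = as.integer(batchSize),
                 nLayers = nLayers,
                 bottleneckH = h, bottleneckW = w,
                 seed = as.integer(seed)),
            class = "autoencoderSpec")
}

## ---- low-level layers (arrays are N x H x W x C) ----------------------

padSpatial <- function(X) {
  d <- dim(X)
  Xp <- array(0, c(d[1], d[2] + 2L, d[3] + 2L, d[4]))
  Xp[, 2:(d[2] + 1L), 2:(d[3] + 1L), ] <- X
  Xp
}

# 3x3 convolution, padding 1, stride s, via im2col.
convForward <- function(X, W, b, s) {
  d <- dim(X); N <- d[1]; H <- d[2]; Wd <- d[3]; Cin <- d[4]
  Hout <- (H + 2L - 3L) %/% s + 1L
  Wout <- (Wd + 2L - 3L) %/% s + 1L
  Xp <- padSpatial(X)
  ys <- seq(1L, by = s, length.out = Hout)
  xs <- seq(1L, by = s, length.out = Wout)
  cols <- matrix(0, N * Hout * Wout, 9L * Cin)
  k <- 0L
  for (dx in 0:2) for (dy in 0:2) {
    sl <- Xp[, ys + dy, xs + dx, , drop = FALSE]
    cols[, k * Cin + seq_len(Cin)] <- matrix(sl, N * Hout * Wout, Cin)
    k <- k + 1L
  }
  Cout <- length(b)
  out <- cols %*% W + matrix(b, nrow(cols), Cout, byrow = TRUE)
  list(out = array(out, c(N, Hout, Wout, Cout)), cols = cols,
       inDim = d, s = s)
}

convBackward <- function(cache, W, dOut) {
  d <- cache$inDim; N <- d[1]; H <- d[2]; Wd <- d[3]; Cin <- d[4]
  s <- cache$s
  dod <- dim(dOut); Hout <- dod[2]; Wout <- dod[3]; Cout <- dod[4]
  dOutMat <- matrix(dOut, N * Hout * Wout, Cout)
  dW <- crossprod(cache$cols, dOutMat)
  db <- colSums(dOutMat)
  dCols <- tcrossprod(dOutMat, W)
  dXp <- array(0, c(N, H + 2L, Wd + 2L, Cin))
  ys <- seq(1L, by = s, length.out = Hout)
  xs <- seq(1L, by = s, length.out = Wout)
  k <- 0L
  for (dx in 0:2) for (dy in 0:2) {
    sl <- array(dCols[, k * Cin + seq_len(Cin)], c(N, Hout, Wout, Cin))
    dXp[, ys + dy, xs + dx, ] <- dXp[, ys + dy, xs + dx, , drop = FALSE] + sl
    k <- k + 1L
  }
  list(dX = dXp[, 2:(H + 1L), 2:(Wd + 1L), , drop = FALSE], dW = dW, db = db)
}

upsample2 <- function(X) {
  d <- dim(X)
  idxH <- rep(seq_len(d[2]), each = 2L)
  idxW <- rep(seq_len(d[3]), each = 2L)
  X[, idxH, idxW, , drop = FALSE]
}

downsampleGrad2 <- function(dY) {
  d <- dim(dY)
  H <- d[2] %/% 2L; W <- d[3] %/% 2L
  dY4 <- array(dY, c(d[1], 2L, H, 2L, W, d[4]))
  # sum the 2x2 blocks that each source pixel fed
  out <- apply(dY4, c(1, 3, 5, 6), sum)
  array(out, c(d[1], H, W, d[4]))
}

relu <- function(x) pmax(x, 0)
sigmoid <- function(x) 1 / (1 + exp(-x))

## ---- model ------------------------------------------------------------

initAutoencoder <- function(spec) {
  withSeed(spec$seed, {
    chans <- c(1L, pmin(8L * 2L^(seq_len(spec$nLayers) - 1L), 64L))
    flat <- spec$bottleneckH * spec$bottleneckW * chans[length(chans)]
    heW <- function(nr, nc, fanIn)
      matrix(rnorm(nr * nc, sd = sqrt(2 / fanIn)), nr, nc)
    params <- list(chans = chans, flat = flat)
    for (l in seq_len(spec$nLayers)) {
      params[[sprintf("encW%d", l)]] <- heW(9L * chans[l], chans[l + 1L],
                                            9L * chans[l])
      params[[sprintf("encB%d", l)]] <- rep(0, chans[l + 1L])
    }
    params$latW <- heW(flat, spec$latentDim, flat)
    params$latB <- rep(0, spec$latentDim)
    params$delatW <- heW(spec$latentDim, flat, spec$latentDim)
    params$delatB <- rep(0, flat)
    for (l in seq_len(spec$nLayers)) {
      # decoder layer l maps chans[nLayers+1-l+1] -> chans[nLayers+1-l]
      cin <- chans[spec$nLayers + 2L - l]
      cout <- chans[spec$nLayers + 1L - l]
      params[[sprintf("decW%d", l)]] <- heW(9L * cin, cout, 9L * cin)
      params[[sprintf("decB%d", l)]] <- rep(0, cout)
    }
    params
  })
}

# Forward through the full autoencoder; returns activations for backprop.
aeForward <- function(X, params, spec) {
  act <- list(enc = list(), dec = list())
  cur <- X
  for (l in seq_len(spec$nLayers)) {
    cv <- convForward(cur, params[[sprintf("encW%d", l)]],
                      params[[sprintf("encB%d", l)]], s = 2L)
    act$enc[[l]] <- list(cache = cv, pre = cv$out)
    cur <- relu(cv$out)
    act$enc[[l]]$post <- cur
  }
  N <- dim(cur)[1]
  flatX <- matrix(cur, N, params$flat)
  act$flatX <- flatX
  z <- flatX %*% params$latW + matrix(params$latB, N, spec$latentDim,
                                      byrow = TRUE)
  act$z <- z
  h <- z %*% params$delatW + matrix(params$delatB, N, params$flat,
                                    byrow = TRUE)
  act$hPre <- h
  h <- relu(h)
  act$hPost <- h
  cur <- array(h, c(N, spec$bottleneckH, spec$bottleneckW,
                    params$chans[length(params$chans)]))
  for (l in seq_len(spec$nLayers)) {
    up <- upsample2(cur)
    cv <- convForward(up, params[[sprintf("decW%d", l)]],
                      params[[sprintf("decB%d", l)]], s = 1L)
    act$dec[[l]] <- list(cache = cv, pre = cv$out)
    cur <- if (l < spec$nLayers) relu(cv$out) else sigmoid(cv$out)
    act$dec[[l]]$post <- cur
  }
  act$recon <- cur
  act
}

aeBackward <- function(X, act, params, spec) {
  N <- dim(X)[1]
  grads <- list()
  dCur <- 2 * (act$recon - X) / length(X)  # d MSE / d recon
  for (l in rev(seq_len(spec$nLayers))) {
    pre <- act$dec[[l]]$pre
    dPre <- if (l < spec$nLayers) dCur * (pre > 0)
            else dCur * act$dec[[l]]$post * (1 - act$dec[[l]]$post)
    bk <- convBackward(act$dec[[l]]$cache, params[[sprintf("decW%d", l)]],
                       dPre)
    grads[[sprintf("decW%d", l)]] <- bk$dW
    grads[[sprintf("decB%d", l)]] <- bk$db
    dCur <- downsampleGrad2(bk$dX)
  }
  dH <- matrix(dCur, N, params$flat)
  dHPre <- dH * (act$hPre > 0)
  grads$delatW <- crossprod(act$z, dHPre)
  grads$delatB <- colSums(dHPre)
  dZ <- tcrossprod(dHPre, params$delatW)
  grads$latW <- crossprod(act$flatX, dZ)
  grads$latB <- colSums(dZ)
  dFlat <- tcrossprod(dZ, params$latW)
  chans <- params$chans
  dCur <- array(dFlat, c(N, spec$bottleneckH, spec$bottleneckW,
                         chans[length(chans)]))
  for (l in rev(seq_len(spec$nLayers))) {
    dPre <- dCur * (act$enc[[l]]$pre > 0)
    bk <- convBackward(act$enc[[l]]$cache, params[[sprintf("encW%d", l)]],
                       dPre)
    grads[[sprintf("encW%d", l)]] <- bk$dW
    grads[[sprintf("encB%d", l)]] <- bk$db
    dCur <- bk$dX
  }
  grads
}

#' Train one slice-index autoencoder
#'
#' Trains the autoencoder on all patients' images at a single slice
#' index, minimising mean-squared reconstruction error with Adam.
#' Weight initialisation and batch order are seeded, so the same data
#' and spec give bit-identical weights, losses and encodings. The loss
#' before any update (epoch 0) is recorded alongside the per-epoch
#' trajectory.
#'
#' @param images List of normalised (\[0, 1\]) matrices, one per
#'   patient, all `inputHeight x inputWidth`; at least 2.
#' @param spec An [autoencoderSpec()].
#' @return A `sliceEncoder` object (weights, spec, `lossHistory` with
#'   the epoch-0 entry first, `finalLoss`).
#' @export
trainSliceAutoencoder <- function(images, spec) {
  stopifnot(inherits(spec, "autoencoderSpec"))
  if (length(images) < 2L)
    stop("need at least 2 training images", call. = FALSE)
  dims <- vapply(images, dim, integer(2))
  if (any(dims[1, ] != spec$inputHeight) || any(dims[2, ] != spec$inputWidth))
    stop("image dimensions do not match the spec", call. = FALSE)
  rng <- range(unlist(lapply(images, range)))
  if (rng[1] < -1e-8 || rng[2] > 1 + 1e-8)
    stop("images must be min-max normalised to [0, 1]", call. = FALSE)

  N <- length(images)
  X <- array(0, c(N, spec$inputHeight, spec$inputWidth, 1L))
  for (i in seq_len(N)) X[i, , , 1L] <- images[[i]]

  params <- initAutoencoder(spec)
  pnames <- setdiff(names(params), c("chans", "flat"))
  adamM <- lapply(params[pnames], function(p) p * 0)
  adamV <- adamM
  t <- 0L
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8

  mseLoss <- function(P) {
    act <- aeForward(X, P, spec)
    mean((act$recon - X)^2)
  }
  losses <- c(epoch0 = mseLoss(params))

  withSeed(spec$seed + 1L, {
    for (ep in seq_len(spec$epochs)) {
      ord <- sample.int(N)
      for (start in seq(1L, N, by = spec$batchSize)) {
        bidx <- ord[start:min(start + spec$batchSize - 1L, N)]
        Xb <- X[bidx, , , , drop = FALSE]
        act <- aeForward(Xb, params, spec)
        grads <- aeBackward(Xb, act, params, spec)
        t <- t + 1L
        for (nm in pnames) {
          g <- grads[[nm]]
          adamM[[nm]] <- b1 * adamM[[nm]] + (1 - b1) * g
          adamV[[nm]] <- b2 * adamV[[nm]] + (1 - b2) * g^2
          mhat <- adamM[[nm]] / (1 - b1^t)
          vhat <- adamV[[nm]] / (1 - b2^t)
          params[[nm]] <- params[[nm]] -
            spec$learningRate * mhat / (sqrt(vhat) + eps)
        }
      }
      losses[sprintf("epoch%d", ep)] <- mseLoss(params)
    }
  })

  structure(list(params = params, spec = spec, lossHistory = losses,
                 finalLoss = unname(losses[length(losses)])),
            class = "sliceEncoder")
}

#' Encode images with a trained slice autoencoder
#'
#' @param encoder A `sliceEncoder` from [trainSliceAutoencoder()].
#' @param images A single matrix or a list of matrices.
#' @return A numeric matrix, one row per image, `latentDim` columns.
#' @export
encodeSlices <- function(encoder, images) {
  if (is.matrix(images)) images <- list(images)
  spec <- encoder$spec
  N <- length(images)
  X <- array(0, c(N, spec$inputHeight, spec$inputWidth, 1L))
  for (i in seq_len(N)) X[i, , , 1L] <- images[[i]]
  params <- encoder$params
  cur <- X
  for (l in seq_len(spec$nLayers)) {
    cv <- convForward(cur, params[[sprintf("encW%d", l)]],
                      params[[sprintf("encB%d", l)]], s = 2L)
    cur <- relu(cv$out)
  }
  flatX <- matrix(cur, N, params$flat)
  flatX %*% params$latW + matrix(params$latB, N, spec$latentDim,
                                 byrow = TRUE)
}

#' Concatenate per-slice encodings into the tabular image domain
#'
#' Encodes slice `i` of every patient with encoder `i` and concatenates
#' the latent vectors in slice order (slice-major), producing one row
#' per patient with columns `SLICE{i}_L{j}`.
#'
#' @param stacks Named list (patient ID -> list of slice matrices).
#' @param encoders List of `sliceEncoder`s, one per slice index.
#' @param normalize Min-max normalise each slice before encoding
#'   (default `TRUE`; set `FALSE` if the stacks are already normalised).
#' @return A [LatentMatrix-class].
#' @export
encodeDomain <- function(stacks, encoders, normalize = TRUE) {
  nSlices <- length(encoders)
  ids <- names(stacks)
  for (pid in ids) {
    have <- length(stacks[[pid]])
    for (s in seq_len(nSlices)) {
      if (s > have || is.null(stacks[[pid]][[s]]))
        stop(sprintf("patient %s is missing slice %d", pid, s),
             call. = FALSE)
    }
  }
  latentDim <- encoders[[1]]$spec$latentDim
  blocks <- lapply(seq_len(nSlices), function(s) {
    imgs <- lapply(stacks, function(st)
      if (normalize) minmaxNormalize(st[[s]]) else st[[s]])
    encodeSlices(encoders[[s]], imgs)
  })
  values <- do.call(cbind, blocks)
  colnames(values) <- unlist(lapply(seq_len(nSlices), function(s)
    sprintf("SLICE%d_L%d", s, seq_len(latentDim))))
  rownames(values) <- NULL
  new("LatentMatrix", patientIds = ids, values = values,
      sliceIndex = rep(seq_len(nSlices), each = latentDim),
      latentDim = as.integer(latentDim))
}

#' Train and encode the whole image domain
#'
#' Convenience wrapper: min-max normalises every slice, trains one
#' autoencoder per slice index on the normalised images across
#' patients, then encodes and concatenates (the slice-`i` encoder seeded
#' at `spec$seed + i` so the per-slice models differ but the whole run
#' is reproducible).
#'
#' @param stacks Named list of per-patient slice lists (as produced by
#'   [generateImageStacks()]).
#' @param spec An [autoencoderSpec()].
#' @return A list with `latent` (a [LatentMatrix-class]) and `encoders`.
#' @export
trainImageDomain <- function(stacks, spec) {
  nSlices <- length(stacks[[1]])
  norm <- lapply(stacks, function(st) lapply(st, minmaxNormalize))
  encoders <- lapply(seq_len(nSlices), function(s) {
    sspec <- spec
    sspec$seed <- spec$seed + s
    trainSliceAutoencoder(lapply(norm, `[[`, s), sspec)
  })
  list(latent = encodeDomain(norm, encoders, normalize = FALSE),
       encoders = encoders)
}
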