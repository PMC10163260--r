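# Model families and training. Three architectures share one trunk design:
#  - CLA: conv trunk -> Weibull activation pooling (activation, GAP, power
#    normalisation) -> classifier head; per-cell multi-label predictions.
#  - CLH: conv trunk with hybrid fusion blocks injecting wavelet-scattering
#    coefficients of the input crop into the trunk -> GAP -> head.
#  - DSA: shared trunk + Weibull pooling producing per-cell descriptors;
#    a cell stream classifies each descriptor, an image stream classifies
#    the elementwise max over the bag of descriptors from one image, and
#    the two stream losses are combined as L_f = W1*L1 + W2*L2.

# ---- specs ------------------------------------------------------------

#' Backbone specification
#'
#' @param family backbone family; "small-conv" is a stack of 3x3
#'   convolution + ReLU + 2x2 average-pooling blocks.
#' @param inputSize input side in pixels; must be divisible by
#'   \code{2^length(channels)}.
#' @param channels output channels of the successive blocks; the last
#'   entry is the descriptor dimension D (must be >= 8).
#' @param inputChannels number of image channels (4).
#' @return A list of class \code{BackboneSpec}.
#' @export
backboneSpec <- function(family = "small-conv", inputSize = 24L,
                         channels = c(8L, 16L), inputChannels = 4L) {
  family <- match.arg(family, "small-conv")
  channels <- as.integer(channels)
  if (utils::tail(channels, 1L) < 8L) .stopf("feature dimension D must be >= 8")
  if (inputSize %% 2^length(channels) != 0)
    .stopf("inputSize must be divisible by 2^%d", length(channels))
  structure(list(family = family, inputSize = as.integer(inputSize),
                 channels = channels, inputChannels = as.integer(inputChannels),
                 featureDim = utils::tail(channels, 1L)),
            class = "BackboneSpec")
}

#' Loss weights for the two-stream loss
#'
#' Round 1 (weak cell labels, trusted image labels) uses (1, 0.2); round 2
#' (refined cell labels) uses (1, 1).
#'
#' @param round training round, 1 or 2.
#' @param wImage,wCell optional explicit overrides.
#' @return Named numeric vector (wImage, wCell).
#' @export
lossWeights <- function(round = 1L, wImage = NULL, wCell = NULL) {
  if (!round %in% c(1L, 2L)) .stopf("round must be 1 or 2")
  w <- if (round == 1L) c(wImage = 1, wCell = 0.2) else c(wImage = 1, wCell = 1)
  if (!is.null(wImage)) w["wImage"] <- wImage
  if (!is.null(wCell)) w["wCell"] <- wCell
  if (any(w < 0)) .stopf("loss weights must be nonnegative")
  w
}

# ---- losses -----------------------------------------------------------

#' Inverse-frequency class weights
#'
#' Weights proportional to 1/frequency, capped at 100 times the median
#' weight (rare/zero-frequency control) and normalised to mean 1.
#'
#' @param freq per-class frequency vector (need not sum to 1).
#' @return Numeric weight vector with mean 1.
#' @export
classWeightsFromFrequencies <- function(freq) {
  w <- 1 / pmax(freq, .Machine$double.eps)
  cap <- 100 * stats::median(w[is.finite(w)])
  w <- pmin(w, cap)
  w / mean(w)
}

#' Weighted binary cross-entropy
#'
#' Mean over cells of \eqn{\sum_c w_c(-t\log p - (1-t)\log(1-p))};
#' continuous targets in [0, 1] are allowed (refined labels).
#'
#' @param probs matrix (cells x C) of probabilities in (0, 1).
#' @param targets matrix of targets in [0, 1], same shape.
#' @param classWeights per-class weights (default: all 1).
#' @return Scalar loss.
#' @export
weightedBCE <- function(probs, targets, classWeights = NULL) {
  probs <- as.matrix(probs); targets <- as.matrix(targets)
  stopifnot(identical(dim(probs), dim(targets)))
  if (any(targets < 0 | targets > 1)) .stopf("targets must lie in [0, 1]")
  if (is.null(classWeights)) classWeights <- rep(1, ncol(probs))
  p <- pmin(pmax(probs, 1e-12), 1 - 1e-12)
  el <- -(targets * log(p) + (1 - targets) * log(1 - p))
  sum(sweep(el, 2, classWeights, "*")) / nrow(probs)
}

#' Focal loss
#'
#' Standard focal modulation \eqn{(1-p_t)^{\gamma_f}} of binary
#' cross-entropy, reducing to (unweighted) BCE at \eqn{\gamma_f = 0}.
#'
#' @inheritParams weightedBCE
#' @param gammaF focusing exponent (>= 0, default 2).
#' @return Scalar loss.
#' @export
focalLoss <- function(probs, targets, gammaF = 2, classWeights = NULL) {
  if (gammaF < 0) .stopf("gammaF must be >= 0")
  probs <- as.matrix(probs); targets <- as.matrix(targets)
  stopifnot(identical(dim(probs), dim(targets)))
  if (is.null(classWeights)) classWeights <- rep(1, ncol(probs))
  p <- pmin(pmax(probs, 1e-12), 1 - 1e-12)
  el <- targets * (1 - p)^gammaF * (-log(p)) +
    (1 - targets) * p^gammaF * (-log(1 - p))
  sum(sweep(el, 2, classWeights, "*")) / nrow(probs)
}

#' Combined two-stream loss
#'
#' \eqn{L_f = W_{image} L_1 + W_{cell} L_2}.
#'
#' @param L1 image-stream loss.
#' @param L2 cell-stream loss.
#' @param w weights from \code{\link{lossWeights}}.
#' @return Scalar.
#' @export
combinedLoss <- function(L1, L2, w = lossWeights(1L)) {
  if (!is.finite(L1) || !is.finite(L2)) .stopf("losses must be finite")
  unname(w[["wImage"]] * L1 + w[["wCell"]] * L2)
}

# gradient of [BCE + focalWeight * focal] w.r.t. probabilities
.bceFocalGradP <- function(p, t, classWeights, gammaF, focalWeight, nRows) {
  p <- pmin(pmax(p, 1e-7), 1 - 1e-7)
  g <- (p - t) / (p * (1 - p)) # d(BCE)/dp
  if (focalWeight > 0) {
    gf <- t * (gammaF * (1 - p)^(gammaF - 1) * log(p) - (1 - p)^gammaF / p) +
      (1 - t) * (gammaF * p^(gammaF - 1) * (-log(1 - p)) + p^gammaF / (1 - p))
    g <- g + focalWeight * gf
  }
  sweep(g, 2, classWeights, "*") / nRows
}

# ---- model construction ----------------------------------------------

.initActPar <- function() {
  c(logLambda = 0, logZeta = log(2), logGamma = 0, logEta = 0,
    logAlpha = 0, logBeta = log(0.5))
}

#' Build an untrained model
#'
#' @param type "cla", "clh" or "dsa".
#' @param spec a \code{\link{backboneSpec}}.
#' @param nClasses number of classes C.
#' @param headType "sigmoid" (independent per-class probabilities,
#'   matching the binary cross-entropy multi-label losses) or "softmax"
#'   (competing-class normalised head, available for single-label use).
#' @param seed RNG seed for weight initialisation.
#' @param fusion for "clh": list with elements J, L and insertAfter
#'   (block indices after which hybrid fusion blocks are inserted).
#' @return A list of class \code{SCLModel}.
#' @export
buildModel <- function(type = c("cla", "clh", "dsa", "capture"),
                       spec = backboneSpec(),
                       nClasses = 6L, headType = c("sigmoid", "softmax"),
                       seed = 1L, fusion = list(J = 2L, L = 4L,
                                                insertAfter = c(1L, 2L))) {
  type <- match.arg(type)
  headType <- if (type == "capture") "softmax" else match.arg(headType)
  .withSeed(seed, {
    ch <- spec$channels
    nb <- length(ch)
    cin <- c(spec$inputChannels, ch[-nb])
    params <- list()
    for (i in seq_len(nb)) {
      fanIn <- 9L * cin[i]
      params[[sprintf("conv%d_W", i)]] <-
        matrix(rnorm(fanIn * ch[i], 0, sqrt(2 / fanIn)), fanIn, ch[i])
      params[[sprintf("conv%d_b", i)]] <- rep(0, ch[i])
    }
    D <- spec$featureDim
    if (type %in% c("cla", "dsa")) params$actPar <- .initActPar()
    params$head_W <- matrix(rnorm(D * nClasses, 0, 1 / sqrt(D)), D, nClasses)
    params$head_b <- rep(0, nClasses)
    if (type == "dsa") {
      params$headImg_W <- matrix(rnorm(D * nClasses, 0, 1 / sqrt(D)),
                                 D, nClasses)
      params$headImg_b <- rep(0, nClasses)
    }
    scat <- NULL
    if (type == "clh") {
      scat <- fusion
      scat$insertAfter <- as.integer(scat$insertAfter)
      nPaths <- 1L + scat$J * scat$L +
        scat$L^2 * ((scat$J * (scat$J - 1L)) %/% 2L)
      scat$K <- as.integer(nPaths * spec$inputChannels)
      for (i in scat$insertAfter) {
        params[[sprintf("proj%d_W", i)]] <-
          matrix(rnorm(scat$K * ch[i], 0, 0.1 / sqrt(scat$K)), scat$K, ch[i])
        params[[sprintf("proj%d_b", i)]] <- rep(0, ch[i])
        params[[sprintf("red%d_W", i)]] <-
          matrix(rnorm(2L * ch[i] * ch[i], 0, 0.1 / sqrt(2 * ch[i])),
                 2L * ch[i], ch[i])
        params[[sprintf("red%d_b", i)]] <- rep(0, ch[i])
      }
    }
    structure(list(type = type, spec = spec, nClasses = as.integer(nClasses),
                   headType = headType, params = params, scat = scat,
                   fusionEnabled = type == "clh", seed = as.integer(seed)),
              class = "SCLModel")
  })
}

#' @export
print.SCLModel <- function(x, ...) {
  cat(sprintf("SCLModel <%s>: %s backbone, input %d px, channels (%s), C = %d, head %s\n",
              toupper(x$type), x$spec$family, x$spec$inputSize,
              paste(x$spec$channels, collapse = ", "), x$nClasses, x$headType))
  invisible(x)
}

# ---- hybrid fusion ----------------------------------------------------

#' Hybrid fusion block
#'
#' Projects a stack of scattering coefficients to the trunk's channel
#' width by a learnable 1x1 mixing, resamples it to the trunk's spatial
#' size (nearest neighbour), concatenates it with the deep feature map and
#' reduces back to the trunk width with a second learnable 1x1 mixing,
#' added residually: \code{out = deep + reduce(cat(deep, project(scat)))}.
#' The output shape equals the trunk shape, so the block is
#' insertion-transparent; with zeroed projection weights the output is a
#' function of the deep features alone.
#'
#' @param deep trunk feature map, H x W x Ct x B.
#' @param scat scattering stack, Hs x Ws x K x B.
#' @param projW,projb 1x1 projection (K x Ct) and bias.
#' @param redW,redb 1x1 reduction (2Ct x Ct) and bias.
#' @return List with \code{out} (H x W x Ct x B) and a cache for the
#'   backward pass.
#' @export
hybridFusionBlock <- function(deep, scat, projW, projb, redW, redb) {
  dd <- dim(deep); ds <- dim(scat)
  Ct <- dd[3]
  if (ncol(projW) != Ct) .stopf("projection output channels must match trunk width")
  S <- matrix(aperm(scat, c(1, 2, 4, 3)), ds[1] * ds[2] * ds[4], ds[3])
  Pj <- sweep(S %*% projW, 2, projb, "+") # (Hs*Ws*B) x Ct
  Pj <- array(aperm(array(Pj, c(ds[1], ds[2], ds[4], Ct)), c(1, 2, 4, 3)),
              c(ds[1], ds[2], Ct, ds[4]))
  ri <- pmin(pmax(round(seq(1, ds[1], length.out = dd[1])), 1L), ds[1])
  ci <- pmin(pmax(round(seq(1, ds[2], length.out = dd[2])), 1L), ds[2])
  Up <- Pj[ri, ci, , , drop = FALSE]
  catm <- rbind(matrix(aperm(deep, c(3, 1, 2, 4)), Ct),
                matrix(aperm(Up, c(3, 1, 2, 4)), Ct)) # 2Ct x (HWB)
  Red <- sweep(crossprod(catm, redW), 2, redb, "+") # (HWB) x Ct
  out <- deep + .chwbToArray(Red, dd)
  list(out = out, cache = list(S = S, catm = catm, ri = ri, ci = ci,
                               dd = dd, ds = ds))
}

# (HWB) x Ct matrix whose rows iterate channel-major flattening from
# aperm(x, c(3,1,2,4)) back to H x W x Ct x B
.chwbToArray <- function(M, dd) {
  a <- array(t(M), c(dd[3], dd[1], dd[2], dd[4]))
  aperm(a, c(2, 3, 1, 4))
}
.arrayToChwb <- function(A) {
  d <- dim(A)
  t(matrix(aperm(A, c(3, 1, 2, 4)), d[3]))
}

.fusionBackward <- function(dOut, cache, projW, redW) {
  dd <- cache$dd; ds <- cache$ds
  Ct <- dd[3]
  dRed <- .arrayToChwb(dOut) # (HWB) x Ct
  dRedW <- cache$catm %*% dRed
  dRedb <- colSums(dRed)
  dCat <- redW %*% t(dRed) # 2Ct x (HWB)
  dDeepPart <- .chwbToArray(t(dCat[seq_len(Ct), , drop = FALSE]), dd)
  dUp <- .chwbToArray(t(dCat[Ct + seq_len(Ct), , drop = FALSE]), dd)
  dDeep <- dOut + dDeepPart
  # reverse the nearest-neighbour resampling: accumulate into source cells
  dPj <- array(0, c(ds[1], ds[2], Ct, ds[4]))
  for (r in seq_along(cache$ri))
    for (cc in seq_along(cache$ci))
      dPj[cache$ri[r], cache$ci[cc], , ] <-
        dPj[cache$ri[r], cache$ci[cc], , , drop = FALSE] +
        dUp[r, cc, , , drop = FALSE]
  dPjM <- matrix(aperm(dPj, c(1, 2, 4, 3)), ds[1] * ds[2] * ds[4], Ct)
  dProjW <- crossprod(cache$S, dPjM)
  dProjb <- colSums(dPjM)
  list(dDeep = dDeep, dProjW = dProjW, dProjb = dProjb,
       dRedW = dRedW, dRedb = dRedb)
}

# ---- forward / backward -----------------------------------------------

# trunk forward over all blocks; X: H x W x Cin x B
.trunkForward <- function(model, X, scatStacks = NULL) {
  p <- model$params
  nb <- length(model$spec$channels)
  caches <- vector("list", nb)
  cur <- X
  for (i in seq_len(nb)) {
    cv <- .convForward(cur, p[[sprintf("conv%d_W", i)]],
                       p[[sprintf("conv%d_b", i)]])
    rl <- .reluForward(cv$out)
    pooled <- .pool2Forward(rl$out)
    fus <- NULL
    if (!is.null(model$scat) && model$fusionEnabled &&
        i %in% model$scat$insertAfter && !is.null(scatStacks)) {
      fus <- hybridFusionBlock(pooled, scatStacks,
                               p[[sprintf("proj%d_W", i)]],
                               p[[sprintf("proj%d_b", i)]],
                               p[[sprintf("red%d_W", i)]],
                               p[[sprintf("red%d_b", i)]])
      nxt <- fus$out
    } else nxt <- pooled
    caches[[i]] <- list(conv = cv, keep = rl$keep,
                        poolIn = dim(rl$out), fusion = fus)
    cur <- nxt
  }
  # final rectification guarantees nonnegative features for pooling
  fr <- .reluForward(cur)
  list(out = fr$out, finalKeep = fr$keep, caches = caches)
}

.trunkBackward <- function(model, dF, fw, grads) {
  p <- model$params
  nb <- length(model$spec$channels)
  cur <- dF * fw$finalKeep
  for (i in rev(seq_len(nb))) {
    ch <- fw$caches[[i]]
    if (!is.null(ch$fusion)) {
      fb <- .fusionBackward(cur, ch$fusion$cache,
                            p[[sprintf("proj%d_W", i)]],
                            p[[sprintf("red%d_W", i)]])
      grads[[sprintf("proj%d_W", i)]] <-
        (grads[[sprintf("proj%d_W", i)]] %||% 0) + fb$dProjW
      grads[[sprintf("proj%d_b", i)]] <-
        (grads[[sprintf("proj%d_b", i)]] %||% 0) + fb$dProjb
      grads[[sprintf("red%d_W", i)]] <-
        (grads[[sprintf("red%d_W", i)]] %||% 0) + fb$dRedW
      grads[[sprintf("red%d_b", i)]] <-
        (grads[[sprintf("red%d_b", i)]] %||% 0) + fb$dRedb
      cur <- fb$dDeep
    }
    cur <- .pool2Backward(cur, ch$poolIn)
    cur <- cur * ch$keep
    cb <- .convBackward(cur, ch$conv, p[[sprintf("conv%d_W", i)]])
    grads[[sprintf("conv%d_W", i)]] <-
      (grads[[sprintf("conv%d_W", i)]] %||% 0) + cb$dW
    grads[[sprintf("conv%d_b", i)]] <-
      (grads[[sprintf("conv%d_b", i)]] %||% 0) + cb$db
    cur <- cb$dX
  }
  grads
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# descriptors for a batch of crops: D x B plus caches
.descriptorForward <- function(model, X, scatStacks = NULL) {
  fw <- .trunkForward(model, X, scatStacks)
  if (!is.null(model$params$actPar)) {
    wp <- .weibullPoolForward(fw$out, model$params$actPar)
    P <- wp$out
  } else {
    d <- dim(fw$out)
    P <- matrix(colMeans(matrix(fw$out, d[1] * d[2], d[3] * d[4])),
                d[3], d[4])
    wp <- list(dims = d)
  }
  list(P = P, trunk = fw, pool = wp)
}

.descriptorBackward <- function(model, dP, fwd, grads) {
  if (!is.null(model$params$actPar)) {
    wb <- .weibullPoolBackward(dP, fwd$pool)
    grads$actPar <- (grads$actPar %||% 0) + wb$dLogPar
    dF <- wb$dF
  } else {
    d <- fwd$pool$dims
    dF <- array(rep(as.vector(dP), each = d[1] * d[2]) / (d[1] * d[2]), d)
  }
  .trunkBackward(model, dF, fwd$trunk, grads)
}

.headForward <- function(P, W, b, headType) {
  logits <- sweep(t(P) %*% W, 2, b, "+")
  probs <- if (headType == "softmax") .softmaxRows(logits)
  else .sigmoid(logits)
  list(probs = probs, logits = logits)
}

# ---- public forward ops ----------------------------------------------

# coerce crops (CellInstance list / matrix stack / array) to H x W x 4 x B
# at the model's input size
.cropBatch <- function(cells, inputSize) {
  if (is(cells, "CellInstance")) cells <- list(cells)
  if (is.list(cells)) {
    arr <- array(0, c(inputSize, inputSize, 4L, length(cells)))
    for (i in seq_along(cells)) {
      cr <- cropData(cells[[i]])
      arr[, , , i] <- if (all(dim(cr)[1:2] == inputSize)) cr
      else .resizeArray(cr, inputSize, inputSize)
    }
    return(arr)
  }
  d <- dim(cells)
  if (length(d) == 3L) cells <- array(cells, c(d, 1L))
  if (dim(cells)[3] != 4L) .stopf("expected 4-channel crops")
  if (dim(cells)[1] != inputSize)
    .stopf("crops are %d px but the model expects %d px",
           dim(cells)[1], inputSize)
  cells
}

.scatForBatch <- function(model, X) {
  if (is.null(model$scat) || !model$fusionEnabled) return(NULL)
  d <- dim(X)
  one <- scatteringTransform(X[, , , 1], J = model$scat$J, L = model$scat$L)
  out <- array(0, c(dim(one)[1:2], dim(one)[3], d[4]))
  out[, , , 1] <- one
  if (d[4] > 1)
    for (b in 2:d[4])
      out[, , , b] <- scatteringTransform(X[, , , b], J = model$scat$J,
                                          L = model$scat$L)
  out
}

#' Cell-level forward pass
#'
#' Runs a cell crop (or a batch of crops) through a cell-level model:
#' backbone, Weibull activation pooling (CLA) or scattering hybrid trunk
#' and GAP (CLH), then the classifier head.
#'
#' @param cells a \linkS4class{CellInstance}, a list of them, or an
#'   H x W x 4 (x B) crop array at the model's input size.
#' @param model an \code{SCLModel} of type "cla" or "clh".
#' @return Matrix B x C of probabilities (a single crop gives one row).
#' @export
claForward <- function(cells, model) {
  stopifnot(inherits(model, "SCLModel"), model$type %in% c("cla", "clh"))
  X <- .cropBatch(cells, model$spec$inputSize)
  fwd <- .descriptorForward(model, X, .scatForBatch(model, X))
  .headForward(fwd$P, model$params$head_W, model$params$head_b,
               model$headType)$probs
}

#' Dual-stream forward pass on a bag of cells
#'
#' Computes per-cell descriptors (trunk + Weibull pooling), forms the
#' image representation as the elementwise maximum over the bag, and
#' applies the image-stream and cell-stream heads.
#'
#' @param bag cells of one image (list of \linkS4class{CellInstance} or
#'   crop array).
#' @param model an \code{SCLModel} of type "dsa".
#' @return List with \code{imageProbs} (length C) and \code{cellProbs}
#'   (N x C).
#' @export
dsaForward <- function(bag, model) {
  stopifnot(inherits(model, "SCLModel"), model$type == "dsa")
  X <- .cropBatch(bag, model$spec$inputSize)
  if (dim(X)[4] < 1) .stopf("bag must contain at least one cell")
  fwd <- .descriptorForward(model, X)
  V <- apply(fwd$P, 1, max)
  img <- .headForward(matrix(V, ncol = 1), model$params$headImg_W,
                      model$params$headImg_b, model$headType)
  cell <- .headForward(fwd$P, model$params$head_W, model$params$head_b,
                       model$headType)
  list(imageProbs = as.numeric(img$probs), cellProbs = cell$probs)
}

# ---- data preparation -------------------------------------------------

#' Resize all cells of a dataset to model input crops
#'
#' @param ds a \linkS4class{LocDataset}.
#' @param inputSize crop side in pixels.
#' @param pad bounding-box padding at extraction.
#' @return List with \code{crops} (H x W x 4 x nCells), \code{imageIndex},
#'   \code{info} (the dataset's cellInfo), \code{labels} (ground-truth
#'   cell labels) and \code{imageLabels}.
#' @export
prepareCells <- function(ds, inputSize = 24L, pad = 1L) {
  stopifnot(is(ds, "LocDataset"))
  info <- cellInfo(ds)
  n <- nCells(ds)
  crops <- array(0, c(inputSize, inputSize, 4L, n))
  k <- 0L
  for (i in seq_len(nImages(ds))) {
    cr <- extractCells(getImage(ds, i), instanceMasks(ds)[[i]], pad = pad,
                       imageId = sprintf("img%04d", i))
    for (cl in cr) {
      k <- k + 1L
      crops[, , , k] <- .resizeArray(cropData(cl), inputSize, inputSize)
    }
  }
  stopifnot(k == n)
  list(crops = crops, imageIndex = info$image, info = info,
       labels = cellLabels(ds), imageLabels = imageLabels(ds),
       inputSize = as.integer(inputSize))
}

#' Weak cell labels from image labels
#'
#' The naive weak-labelling scheme: every cell inherits the full label
#' vector of its parent image (the union of all its cells' labels).
#'
#' @param ds a \linkS4class{LocDataset}.
#' @return Binary matrix nCells x C.
#' @export
weakCellLabels <- function(ds) {
  imageLabels(ds)[cellInfo(ds)$image, , drop = FALSE]
}

# ---- training ---------------------------------------------------------

#' Training configuration
#'
#' @param epochs number of epochs.
#' @param batchSize cells per batch (cell-level models) or images per
#'   batch (DSA).
#' @param lr initial learning rate of the cosine-annealed Adam schedule
#'   (default 2e-4).
#' @param lrFloor terminal learning rate.
#' @param seed RNG seed controlling shuffling and augmentation.
#' @param augment FALSE, TRUE (default probabilities) or a list of
#'   augmentation probabilities (pFlip, pRotate, pShift, maxShift, pScale,
#'   pCutout).
#' @param round training round for the DSA two-stream loss weights.
#' @param bagSize N, the number of cells drawn per image for DSA bags
#'   (cells are subsampled without replacement when an image has more,
#'   resampled with replacement when it has fewer).
#' @param gammaF focal exponent for cell-level training.
#' @param focalWeight weight of the focal term added to weighted BCE.
#' @return A list of class \code{TrainConfig}.
#' @export
trainConfig <- function(epochs = 8L, batchSize = 64L, lr = 2e-4,
                        lrFloor = lr / 100, seed = 1L, augment = FALSE,
                        round = 1L, bagSize = 20L, gammaF = 2,
                        focalWeight = 1) {
  aug <- if (isTRUE(augment)) .defaultAugment()
  else if (is.list(augment)) utils::modifyList(.defaultAugment(), augment)
  else NULL
  structure(list(epochs = as.integer(epochs), batchSize = as.integer(batchSize),
                 lr = lr, lrFloor = lrFloor, seed = as.integer(seed),
                 augment = aug, round = as.integer(round),
                 bagSize = as.integer(bagSize), gammaF = gammaF,
                 focalWeight = focalWeight),
            class = "TrainConfig")
}

#' Train a model on a (weakly or refinement-) labelled dataset
#'
#' Cell-level models (CLA, CLH) minimise inverse-frequency-weighted binary
#' cross-entropy plus a focal term over per-cell targets. The dual-stream
#' model (DSA) minimises \eqn{L_f = W_1 L_1 + W_2 L_2} where \eqn{L_1} is
#' the image-stream loss against image labels and \eqn{L_2} the
#' cell-stream loss against (weak or refined) cell labels; round-1 weights
#' are (1, 0.2), round-2 weights (1, 1). Optimisation is Adam under a
#' cosine-annealed learning rate. Training is deterministic for a fixed
#' seed.
#'
#' @param data a \linkS4class{LocDataset} or the output of
#'   \code{\link{prepareCells}}.
#' @param model an \code{SCLModel} from \code{\link{buildModel}}.
#' @param cellTargets nCells x C target matrix in [0, 1]; defaults to the
#'   weak labels (image labels mapped to every cell).
#' @param config a \code{\link{trainConfig}}.
#' @return The trained model, with a \code{history} data frame of
#'   per-epoch losses attached.
#' @export
trainModel <- function(data, model, cellTargets = NULL,
                       config = trainConfig()) {
  if (is(data, "LocDataset")) data <- prepareCells(data, model$spec$inputSize)
  if (data$inputSize != model$spec$inputSize)
    .stopf("prepared crops are %d px but the model expects %d px",
           data$inputSize, model$spec$inputSize)
  if (model$headType != "sigmoid")
    .stopf("training is implemented for the sigmoid (multi-label) head")
  if (is.null(cellTargets))
    cellTargets <- data$imageLabels[data$imageIndex, , drop = FALSE]
  if (any(cellTargets < 0 | cellTargets > 1))
    .stopf("cell targets must lie in [0, 1]")
  freq <- pmax(colMeans(cellTargets > 0.5), 1e-6)
  cw <- classWeightsFromFrequencies(freq)
  .withSeed(config$seed, {
    if (model$type == "dsa")
      .trainDSA(data, model, cellTargets, cw, config)
    else .trainCellLevel(data, model, cellTargets, cw, config)
  })
}

.trainCellLevel <- function(data, model, targets, cw, config) {
  n <- dim(data$crops)[4]
  state <- .adamInit(model$params)
  hist <- data.frame(epoch = integer(0), loss = numeric(0))
  scatAll <- NULL
  if (model$type == "clh") # scattering of clean crops, computed once
    scatAll <- .scatForBatch(model, data$crops)
  for (e in seq_len(config$epochs) - 1L) {
    lr <- cosineLR(e, config$epochs, config$lr, config$lrFloor)
    ord <- sample.int(n)
    tot <- 0
    nb <- 0L
    for (s in seq(1L, n, config$batchSize)) {
      idx <- ord[s:min(s + config$batchSize - 1L, n)]
      X <- data$crops[, , , idx, drop = FALSE]
      if (!is.null(config$augment)) X <- .augmentBatch(X, config$augment)
      # scattering must see the same pixels as the trunk: recompute under
      # augmentation, reuse the precomputed stacks otherwise
      scat <- if (is.null(scatAll)) NULL
      else if (!is.null(config$augment)) .scatForBatch(model, X)
      else scatAll[, , , idx, drop = FALSE]
      t <- targets[idx, , drop = FALSE]
      fwd <- .descriptorForward(model, X, scat)
      hd <- .headForward(fwd$P, model$params$head_W, model$params$head_b,
                         "sigmoid")
      loss <- weightedBCE(hd$probs, t, cw) +
        config$focalWeight * focalLoss(hd$probs, t, config$gammaF, cw)
      if (!is.finite(loss))
        .stopf("training diverged (non-finite loss) at epoch %d", e)
      dP <- .bceFocalGradP(hd$probs, t, cw, config$gammaF,
                           config$focalWeight, length(idx))
      dLogits <- dP * hd$probs * (1 - hd$probs)
      grads <- list()
      grads$head_W <- fwd$P %*% dLogits
      grads$head_b <- colSums(dLogits)
      dDesc <- model$params$head_W %*% t(dLogits)
      grads <- .descriptorBackward(model, dDesc, fwd, grads)
      upd <- .adamStep(model$params, grads, state, lr)
      model$params <- upd$params
      state <- upd$state
      tot <- tot + loss
      nb <- nb + 1L
    }
    hist <- rbind(hist, data.frame(epoch = e, loss = tot / nb))
  }
  model$history <- hist
  model
}

.trainDSA <- function(data, model, targets, cw, config) {
  imgs <- sort(unique(data$imageIndex))
  N <- config$bagSize
  state <- .adamInit(model$params)
  w <- lossWeights(config$round)
  hist <- data.frame(epoch = integer(0), loss = numeric(0),
                     lossImage = numeric(0), lossCell = numeric(0))
  cellsOf <- split(seq_along(data$imageIndex), data$imageIndex)
  for (e in seq_len(config$epochs) - 1L) {
    lr <- cosineLR(e, config$epochs, config$lr, config$lrFloor)
    ord <- sample(imgs)
    tot <- c(0, 0, 0)
    nb <- 0L
    for (s in seq(1L, length(ord), config$batchSize)) {
      bi <- ord[s:min(s + config$batchSize - 1L, length(ord))]
      pick <- unlist(lapply(bi, function(i) {
        ci <- cellsOf[[as.character(i)]]
        if (length(ci) >= N) .resample(ci, N)
        else .resample(ci, N, replace = TRUE)
      }))
      bagOf <- rep(seq_along(bi), each = N)
      X <- data$crops[, , , pick, drop = FALSE]
      if (!is.null(config$augment)) X <- .augmentBatch(X, config$augment)
      t2 <- targets[pick, , drop = FALSE]
      t1 <- data$imageLabels[bi, , drop = FALSE]
      fwd <- .descriptorForward(model, X)
      P <- fwd$P # D x (N*B)
      B <- length(bi)
      D <- nrow(P)
      V <- matrix(0, D, B)
      amax <- matrix(0L, D, B)
      for (b in seq_len(B)) {
        cols <- which(bagOf == b)
        sub <- P[, cols, drop = FALSE]
        am <- max.col(sub, ties.method = "first")
        V[, b] <- sub[cbind(seq_len(D), am)]
        amax[, b] <- cols[am]
      }
      img <- .headForward(V, model$params$headImg_W, model$params$headImg_b,
                          "sigmoid")
      cell <- .headForward(P, model$params$head_W, model$params$head_b,
                           "sigmoid")
      L1 <- weightedBCE(img$probs, t1, cw)
      L2 <- weightedBCE(cell$probs, t2, cw)
      Lf <- combinedLoss(L1, L2, w)
      if (!is.finite(Lf))
        .stopf("training diverged (non-finite loss) at epoch %d", e)
      dP1 <- .bceFocalGradP(img$probs, t1, cw, 0, 0, B) * w[["wImage"]]
      dL1 <- dP1 * img$probs * (1 - img$probs)
      dP2 <- .bceFocalGradP(cell$probs, t2, cw, 0, 0, nrow(t2)) * w[["wCell"]]
      dL2 <- dP2 * cell$probs * (1 - cell$probs)
      grads <- list()
      grads$headImg_W <- V %*% dL1
      grads$headImg_b <- colSums(dL1)
      grads$head_W <- P %*% dL2
      grads$head_b <- colSums(dL2)
      dV <- model$params$headImg_W %*% t(dL1) # D x B
      dP <- model$params$head_W %*% t(dL2) # D x (N*B)
      for (b in seq_len(B)) # route image-stream gradient to argmax cells
        dP[cbind(seq_len(D), amax[, b])] <-
          dP[cbind(seq_len(D), amax[, b])] + dV[, b]
      grads <- .descriptorBackward(model, dP, fwd, grads)
      upd <- .adamStep(model$params, grads, state, lr)
      model$params <- upd$params
      state <- upd$state
      tot <- tot + c(Lf, L1, L2)
      nb <- nb + 1L
    }
    hist <- rbind(hist, data.frame(epoch = e, loss = tot[1] / nb,
                                   lossImage = tot[2] / nb,
                                   lossCell = tot[3] / nb))
  }
  model$history <- hist
  model
}

# ---- batched prediction ----------------------------------------------

#' Predict per-cell probabilities for prepared crops
#'
#' @param model trained \code{SCLModel}.
#' @param data output of \code{\link{prepareCells}} (or a crop array).
#' @param chunk cells per forward chunk.
#' @return For cell-level models, an nCells x C probability matrix. For a
#'   DSA, a list with \code{cellProbs} (nCells x C) and \code{imageProbs}
#'   (nImages x C, rows indexed by image), where the image stream runs on
#'   the full bag of each image's cells.
#' @export
predictCells <- function(model, data, chunk = 256L) {
  crops <- if (is.list(data) && !is.null(data$crops)) data$crops else data
  n <- dim(crops)[4]
  probs <- matrix(0, n, model$nClasses)
  desc <- matrix(0, model$spec$featureDim, n)
  for (s in seq(1L, n, chunk)) {
    idx <- s:min(s + chunk - 1L, n)
    X <- crops[, , , idx, drop = FALSE]
    fwd <- .descriptorForward(model, X, .scatForBatch(model, X))
    desc[, idx] <- fwd$P
    probs[idx, ] <- .headForward(fwd$P, model$params$head_W,
                                 model$params$head_b, model$headType)$probs
  }
  if (model$type != "dsa") return(probs)
  imageIndex <- data$imageIndex
  imgs <- sort(unique(imageIndex))
  imgProbs <- matrix(0, max(imgs), model$nClasses)
  for (i in imgs) {
    V <- apply(desc[, imageIndex == i, drop = FALSE], 1, max)
    imgProbs[i, ] <- .headForward(matrix(V, ncol = 1),
                                  model$params$headImg_W,
                                  model$params$headImg_b,
                                  model$headType)$probs
  }
  list(cellProbs = probs, imageProbs = imgProbs)
}
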