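# Minimal dense/convolutional network engine in base R matrix algebra.
# Layout conventions: feature maps are H x W x C x B arrays; descriptors
# are D x B matrices; batches of flat inputs are B x D matrices.
# Each layer has an explicit forward (returning a cache) and backward.

# ---- 3x3 same convolution via im2col ---------------------------------

# weights: (9 * Cin) x Cout, rows ordered offset-major then channel
.convForward <- function(X, W, b) {
  d <- dim(X)
  H <- d[1]; Wd <- d[2]; Cin <- d[3]; B <- d[4]
  Xp <- array(0, c(H + 2L, Wd + 2L, Cin, B))
  Xp[2:(H + 1L), 2:(Wd + 1L), , ] <- X
  blocks <- vector("list", 9L)
  t <- 1L
  for (dj in 0:2) for (di in 0:2) {
    blk <- Xp[di + seq_len(H), dj + seq_len(Wd), , , drop = FALSE]
    blk <- aperm(array(blk, c(H * Wd, Cin, B)), c(1, 3, 2))
    blocks[[t]] <- matrix(blk, H * Wd * B, Cin)
    t <- t + 1L
  }
  M <- do.call(cbind, blocks)
  Y <- M %*% W
  Y <- sweep(Y, 2, b, "+")
  out <- aperm(array(Y, c(H * Wd, B, ncol(W))), c(1, 3, 2))
  dim(out) <- c(H, Wd, ncol(W), B)
  list(out = out, M = M, dims = d)
}

.convBackward <- function(dOut, cache, W) {
  d <- cache$dims
  H <- d[1]; Wd <- d[2]; Cin <- d[3]; B <- d[4]
  Cout <- ncol(W)
  dY <- matrix(aperm(array(dOut, c(H * Wd, Cout, B)), c(1, 3, 2)),
               H * Wd * B, Cout)
  dW <- crossprod(cache$M, dY)
  db <- colSums(dY)
  dM <- tcrossprod(dY, W)
  dXp <- array(0, c(H + 2L, Wd + 2L, Cin, B))
  t <- 1L
  for (dj in 0:2) for (di in 0:2) {
    blk <- dM[, ((t - 1L) * Cin + 1L):(t * Cin), drop = FALSE]
    blk <- aperm(array(blk, c(H * Wd, B, Cin)), c(1, 3, 2))
    dim(blk) <- c(H, Wd, Cin, B)
    dXp[di + seq_len(H), dj + seq_len(Wd), , ] <-
      dXp[di + seq_len(H), dj + seq_len(Wd), , , drop = FALSE] + blk
    t <- t + 1L
  }
  list(dX = dXp[2:(H + 1L), 2:(Wd + 1L), , , drop = FALSE],
       dW = dW, db = db)
}

# ---- 2x2 average pooling ---------------------------------------------

.pool2Forward <- function(X) {
  d <- dim(X)
  stopifnot(d[1] %% 2L == 0L, d[2] %% 2L == 0L)
  X1 <- array(X, c(2L, d[1] %/% 2L, d[2], d[3], d[4]))
  s <- colMeans(X1) # (H/2, W, C, B)
  s <- aperm(array(s, c(d[1] %/% 2L, 2L, d[2] %/% 2L, d[3], d[4])),
             c(2, 1, 3, 4, 5))
  out <- colMeans(s) # (H/2, W/2, C, B)
  array(out, c(d[1] %/% 2L, d[2] %/% 2L, d[3], d[4]))
}

.pool2Backward <- function(dOut, inDims) {
  ri <- rep(seq_len(inDims[1] %/% 2L), each = 2L)
  ci <- rep(seq_len(inDims[2] %/% 2L), each = 2L)
  (dOut / 4)[ri, ci, , , drop = FALSE]
}

# ---- misc layers ------------------------------------------------------

.reluForward <- function(X) {
  keep <- X > 0
  list(out = X * keep, keep = keep)
}

.sigmoid <- function(z) 1 / (1 + exp(-z))

.softmaxRows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# Weibull activation + GAP + power normalisation on a feature map.
# logPar: named numeric (logLambda, logZeta, logGamma, logEta,
# logAlpha, logBeta). Returns descriptor D x B.
.weibullPoolForward <- function(F, logPar, eps = 1e-8) {
  p <- exp(logPar)
  Fc <- pmax(F, eps)
  g <- weibullGradients(Fc, p[["logLambda"]], p[["logZeta"]],
                        p[["logGamma"]], p[["logEta"]], eps = eps)
  Tv <- g$value
  d <- dim(F)
  S <- colMeans(matrix(Tv, d[1] * d[2], d[3] * d[4])) # GAP
  S <- matrix(S, d[3], d[4])
  Sc <- pmax(S, eps)
  P <- p[["logAlpha"]] * Sc^p[["logBeta"]]
  list(out = P, S = Sc, grads = g, par = p, dims = d, clampKeep = F > eps)
}

.weibullPoolBackward <- function(dP, cache) {
  p <- cache$par
  S <- cache$S
  d <- cache$dims
  alpha <- p[["logAlpha"]]; beta <- p[["logBeta"]]
  dAlpha <- sum(dP * S^beta)
  dBeta <- sum(dP * alpha * S^beta * log(S))
  dS <- dP * alpha * beta * S^(beta - 1)
  dT <- array(rep(as.vector(dS), each = d[1] * d[2]) / (d[1] * d[2]), d)
  g <- cache$grads
  dF <- dT * g$dR * cache$clampKeep
  dLog <- c(
    logLambda = sum(dT * g$dLambda) * p[["logLambda"]],
    logZeta = sum(dT * g$dZeta) * p[["logZeta"]],
    logGamma = sum(dT * g$dGamma) * p[["logGamma"]],
    logEta = sum(dT * g$dEta) * p[["logEta"]],
    logAlpha = dAlpha * alpha,
    logBeta = dBeta * beta)
  list(dF = dF, dLogPar = dLog)
}

# ---- optimiser and schedule ------------------------------------------

#' Cosine-annealed learning rate
#'
#' \eqn{lr(e) = floor + (lr_0 - floor)(1 + \cos(\pi e/(E-1)))/2}:
#' equal to \code{lr0} at epoch 0 and to \code{floor} at the final epoch.
#'
#' @param epoch 0-based epoch index.
#' @param epochs total number of epochs E.
#' @param lr0 initial learning rate (default 2e-4).
#' @param floor terminal learning rate (default \code{lr0/100}).
#' @return The learning rate for \code{epoch}.
#' @export
cosineLR <- function(epoch, epochs, lr0 = 2e-4, floor = lr0 / 100) {
  if (epochs <= 1) return(lr0)
  floor + 0.5 * (lr0 - floor) * (1 + cos(pi * epoch / (epochs - 1)))
}

.adamInit <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

.adamStep <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

# ---- augmentations ----------------------------------------------------

# crops: H x W x C x B; each sample augmented independently
.augmentBatch <- function(crops, config) {
  d <- dim(crops)
  for (b in seq_len(d[4])) {
    x <- crops[, , , b, drop = FALSE]
    dim(x) <- d[1:3]
    if (runif(1) < config$pFlip) x <- x[rev(seq_len(d[1])), , , drop = FALSE]
    if (runif(1) < config$pFlip) x <- x[, rev(seq_len(d[2])), , drop = FALSE]
    if (runif(1) < config$pRotate) {
      k <- sample(1:3, 1L)
      for (kk in seq_len(k)) x <- aperm(x, c(2, 1, 3))[rev(seq_len(d[2])), , , drop = FALSE]
    }
    if (runif(1) < config$pShift) {
      sh <- sample(-config$maxShift:config$maxShift, 2L, replace = TRUE)
      y <- array(0, d[1:3])
      rs <- intersect(seq_len(d[1]), seq_len(d[1]) + sh[1])
      cs <- intersect(seq_len(d[2]), seq_len(d[2]) + sh[2])
      y[rs, cs, ] <- x[rs - sh[1], cs - sh[2], , drop = FALSE]
      x <- y
    }
    if (runif(1) < config$pScale) {
      # random zoom by nearest-neighbour index resampling (85-115%)
      f <- runif(1, 0.85, 1.15)
      ri <- pmin(pmax(round((seq_len(d[1]) - d[1] / 2) / f + d[1] / 2), 1L), d[1])
      ci <- pmin(pmax(round((seq_len(d[2]) - d[2] / 2) / f + d[2] / 2), 1L), d[2])
      x <- x[ri, ci, , drop = FALSE]
    }
    if (runif(1) < config$pCutout) {
      s <- max(2L, round(d[1] / 4))
      r0 <- sample(seq_len(d[1] - s + 1L), 1L)
      c0 <- sample(seq_len(d[2] - s + 1L), 1L)
      x[r0:(r0 + s - 1L), c0:(c0 + s - 1L), ] <- 0
    }
    crops[, , , b] <- x
  }
  crops
}

.defaultAugment <- function() {
  list(pFlip = 0.5, pRotate = 0.25, pShift = 0.25, maxShift = 2L,
       pScale = 0.15, pCutout = 0.25)
}
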