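test_that("loss weights and the combined loss follow the round scheme", {
  expect_equal(combinedLoss(1, 1, lossWeights(1L)), 1.2)
  expect_equal(combinedLoss(1, 1, lossWeights(2L)), 2.0)
  expect_equal(combinedLoss(0, 0, lossWeights(1L)), 0)
  expect_error(lossWeights(3L), "round")
  expect_error(combinedLoss(Inf, 0), "finite")
})

test_that("weighted BCE matches hand computation and inverse-frequency rule", {
  t <- matrix(c(1, 0), 1, 2)
  expect_equal(weightedBCE(t, t), 0, tolerance = 1e-9)
  w <- classWeightsFromFrequencies(c(0.5, 0.25))
  expect_equal(w[2] / w[1], 2)
  expect_equal(mean(w), 1)
  # scalar oracle on a random case
  withr::with_seed(83L, {
    p <- matrix(runif(12, 0.05, 0.95), 3, 4)
    tt <- matrix(rbinom(12, 1, 0.5), 3, 4)
    cw <- runif(4, 0.5, 2)
    man <- 0
    for (i in 1:3) for (j in 1:4)
      man <- man + cw[j] * (-tt[i, j] * log(p[i, j]) -
                              (1 - tt[i, j]) * log(1 - p[i, j]))
    expect_lt(abs(weightedBCE(p, tt, cw) - man / 3), 1e-10)
  })
})

test_that("zero-frequency classes get capped weights", {
  w <- classWeightsFromFrequencies(c(0.5, 0.5, 0))
  expect_true(is.finite(w[3]))
  expect_lte(w[3] / stats::median(w), 100 * 3) # capped before normalisation
})

test_that("focal loss reduces to BCE at gamma 0 and vanishes at p_t -> 1", {
  withr::with_seed(89L, {
    p <- matrix(runif(20, 0.05, 0.95), 4, 5)
    t <- matrix(rbinom(20, 1, 0.5), 4, 5)
    expect_lt(abs(focalLoss(p, t, gammaF = 0) - weightedBCE(p, t)), 1e-12)
  })
  expect_lt(focalLoss(matrix(1 - 1e-9), matrix(1), 2), 1e-8)
  expect_lt(focalLoss(matrix(1e-9), matrix(0), 2), 1e-8)
  expect_error(focalLoss(matrix(0.5), matrix(1), gammaF = -1), "gammaF")
  # direct formula oracle
  p <- matrix(c(0.3, 0.8), 1, 2); t <- matrix(c(1, 0), 1, 2)
  man <- (1 - 0.3)^2 * (-log(0.3)) + 0.8^2 * (-log(1 - 0.8))
  expect_lt(abs(focalLoss(p, t, 2) - man), 1e-12)
})

test_that("cosine schedule starts at 2e-4 and ends at the floor", {
  expect_equal(cosineLR(0, 10), 2e-4)
  expect_equal(cosineLR(9, 10), 2e-6, tolerance = 1e-12)
  lrs <- vapply(0:9, cosineLR, numeric(1), epochs = 10)
  expect_true(all(diff(lrs) < 0))
})

test_that("scattering of a constant image has vanishing higher orders", {
  s <- scatteringTransform(matrix(0.7, 32, 32), J = 2L, order = 2L)
  order0 <- s[, , 1]
  expect_gt(mean(order0), 0)
  expect_lt(max(abs(s[, , -1])), 1e-6 * mean(abs(order0)))
})

test_that("scattering is equivariant to shifts by 2^J", {
  withr::with_seed(97L, {
    x <- matrix(runif(32 * 32), 32, 32)
  })
  a <- scatteringTransform(x, J = 2L)
  xs <- x[c(5:32, 1:4), ] # circular shift by 4 = 2^J rows
  b <- scatteringTransform(xs, J = 2L)
  expect_lt(max(abs(b - a[c(2:8, 1), , , drop = FALSE])), 1e-6)
})

test_that("scattering does not increase energy", {
  withr::with_seed(101L, {
    for (rep in 1:5) {
      x <- matrix(runif(16 * 16, 0, 2), 16, 16)
      s <- scatteringTransform(x, J = 1L)
      expect_lte(sum(s^2), sum(x^2))
    }
  })
})

test_that("scattering rejects indivisible sizes", {
  expect_error(scatteringTransform(matrix(0, 30, 30), J = 2L),
               "divisible")
})

test_that("hybrid fusion is shape-preserving and ablates to deep-only", {
  withr::with_seed(103L, {
    deep <- array(runif(12 * 12 * 8 * 2), c(12, 12, 8, 2))
    scat <- array(runif(6 * 6 * 10 * 2), c(6, 6, 10, 2))
    projW <- matrix(rnorm(80), 10, 8); projb <- rep(0, 8)
    redW <- matrix(rnorm(16 * 8, 0, 0.1), 16, 8); redb <- rep(0, 8)
  })
  out <- hybridFusionBlock(deep, scat, projW, projb, redW, redb)
  expect_identical(dim(out$out), dim(deep))
  # zeroed projection: output depends on deep features only
  z <- hybridFusionBlock(deep, scat, projW * 0, projb, redW, redb)
  z2 <- hybridFusionBlock(deep, scat * 2 + 1, projW * 0, projb, redW, redb)
  expect_equal(z$out, z2$out)
})

test_that("gradients reach the scattering projection weights", {
  spec <- backboneSpec(inputSize = 16L, channels = c(8L, 8L))
  m <- buildModel("clh", spec, nClasses = 2L, seed = 7L,
                  fusion = list(J = 2L, L = 2L, insertAfter = c(1L, 2L)))
  withr::with_seed(5L, {
    X <- array(runif(16 * 16 * 4 * 3), c(16, 16, 4, 3))
    t <- matrix(rbinom(6, 1, 0.5), 3, 2)
  })
  ns <- asNamespace("SubCellLoc")
  scat <- ns$.scatForBatch(m, X)
  fwd <- ns$.descriptorForward(m, X, scat)
  hd <- ns$.headForward(fwd$P, m$params$head_W, m$params$head_b, "sigmoid")
  dP <- ns$.bceFocalGradP(hd$probs, t, rep(1, 2), 2, 1, 3)
  dLogits <- dP * hd$probs * (1 - hd$probs)
  grads <- list(head_W = fwd$P %*% dLogits, head_b = colSums(dLogits))
  dDesc <- m$params$head_W %*% t(dLogits)
  grads <- ns$.descriptorBackward(m, dDesc, fwd, grads)
  expect_gt(max(abs(grads$proj1_W)), 0)
  expect_gt(max(abs(grads$proj2_W)), 0)
  expect_gt(max(abs(grads$red1_W)), 0)
})

test_that("full backpropagation matches finite differences", {
  ns <- asNamespace("SubCellLoc")
  m <- buildModel("cla", backboneSpec(inputSize = 8L, channels = c(8L, 8L)),
                  nClasses = 3L, seed = 2L)
  withr::with_seed(1L, {
    X <- array(runif(8 * 8 * 4 * 4, 0.1, 1), c(8, 8, 4, 4))
    t <- matrix(rbinom(12, 1, 0.5), 4, 3)
  })
  cw <- rep(1, 3)
  lossOf <- function(params) {
    m2 <- m; m2$params <- params
    fwd <- ns$.descriptorForward(m2, X)
    hd <- ns$.headForward(fwd$P, params$head_W, params$head_b, "sigmoid")
    weightedBCE(hd$probs, t, cw) + focalLoss(hd$probs, t, 2, cw)
  }
  fwd <- ns$.descriptorForward(m, X)
  hd <- ns$.headForward(fwd$P, m$params$head_W, m$params$head_b, "sigmoid")
  dP <- ns$.bceFocalGradP(hd$probs, t, cw, 2, 1, 4)
  dLogits <- dP * hd$probs * (1 - hd$probs)
  grads <- list(head_W = fwd$P %*% dLogits, head_b = colSums(dLogits))
  dDesc <- m$params$head_W %*% t(dLogits)
  grads <- ns$.descriptorBackward(m, dDesc, fwd, grads)
  withr::with_seed(9L, {
    for (nm in names(m$params)) {
      for (i in sample(seq_along(m$params[[nm]]),
                       min(3L, length(m$params[[nm]])))) {
        eps <- 1e-5
        pp <- m$params; pp[[nm]][i] <- pp[[nm]][i] + eps
        pm <- m$params; pm[[nm]][i] <- pm[[nm]][i] - eps
        fd <- (lossOf(pp) - lossOf(pm)) / (2 * eps)
        expect_lt(abs(grads[[nm]][i] - fd), 1e-4 * max(1, abs(fd)))
      }
    }
  })
})

test_that("dual-stream outputs are bag-order invariant", {
  m <- buildModel("dsa", tinySpec(), nClasses = 4L, seed = 11L)
  withr::with_seed(13L, {
    X <- array(runif(24 * 24 * 4 * 6), c(24, 24, 4, 6))
  })
  out <- dsaForward(X, m)
  perm <- c(4, 2, 6, 1, 5, 3)
  out2 <- dsaForward(X[, , , perm, drop = FALSE], m)
  expect_equal(out2$imageProbs, out$imageProbs, tolerance = 1e-12)
  expect_equal(out2$cellProbs, out$cellProbs[perm, ], tolerance = 1e-12)
})

test_that("a bag of identical cells collapses to a single descriptor", {
  m <- buildModel("dsa", tinySpec(), nClasses = 3L, seed = 17L)
  withr::with_seed(19L, {
    one <- array(runif(24 * 24 * 4), c(24, 24, 4, 1))
  })
  X <- one[, , , rep(1, 5), drop = FALSE]
  out <- dsaForward(X, m)
  expect_equal(apply(out$cellProbs, 2, stats::sd), rep(0, 3))
  single <- dsaForward(one, m)
  expect_equal(out$imageProbs, single$imageProbs, tolerance = 1e-12)
})

test_that("zeroed heads produce 0.5 sigmoid probabilities", {
  m <- buildModel("cla", tinySpec(), nClasses = 5L, seed = 23L)
  m$params$head_W[] <- 0
  m$params$head_b[] <- 0
  withr::with_seed(29L, {
    X <- array(runif(24 * 24 * 4 * 2), c(24, 24, 4, 2))
  })
  expect_equal(claForward(X, m), matrix(0.5, 2, 5), tolerance = 1e-12)
  md <- buildModel("dsa", tinySpec(), nClasses = 5L, seed = 23L)
  md$params$head_W[] <- 0; md$params$head_b[] <- 0
  md$params$headImg_W[] <- 0; md$params$headImg_b[] <- 0
  out <- dsaForward(X, md)
  expect_equal(out$imageProbs, rep(0.5, 5), tolerance = 1e-12)
})

test_that("model outputs stay in [0, 1] over random inputs", {
  m <- buildModel("cla", tinySpec(), nClasses = 6L, seed = 31L)
  withr::with_seed(37L, {
    X <- array(runif(24 * 24 * 4 * 50, 0, 2), c(24, 24, 4, 50))
  })
  p <- claForward(X, m)
  expect_true(all(p >= 0 & p <= 1))
  ph <- claForward(X, buildModel("clh", tinySpec(), nClasses = 6L,
                                 seed = 31L))
  expect_true(all(ph >= 0 & ph <= 1))
})

test_that("clh with fusion disabled equals its plain backbone", {
  m <- buildModel("clh", tinySpec(), nClasses = 4L, seed = 41L)
  m$fusionEnabled <- FALSE
  withr::with_seed(43L, {
    X <- array(runif(24 * 24 * 4 * 3), c(24, 24, 4, 3))
  })
  # weight-compatible ablation path: same trunk weights, no fusion blocks
  ns <- asNamespace("SubCellLoc")
  plain <- buildModel("capture", tinySpec(), nClasses = 4L, seed = 1L)
  for (nm in c("conv1_W", "conv1_b", "conv2_W", "conv2_b"))
    plain$params[[nm]] <- m$params[[nm]]
  fa <- ns$.descriptorForward(m, X, NULL)
  fb <- ns$.descriptorForward(plain, X, NULL)
  expect_equal(fa$P, fb$P, tolerance = 1e-12)
})

test_that("training is reproducible and records its history", {
  ds <- generateDataset(synthConfig(nImages = 8L, cellsPerImage = c(3L, 3L),
                                    imageSize = 96L, rngSeed = 47L))
  prep <- prepareCells(ds, 16L)
  spec <- backboneSpec(inputSize = 16L)
  run <- function() {
    m <- buildModel("cla", spec, nClasses = 6L, seed = 5L)
    trainModel(prep, m, config = trainConfig(epochs = 2L, batchSize = 12L,
                                             lr = 1e-3, seed = 7L))
  }
  t1 <- run(); t2 <- run()
  expect_equal(t1$history$loss[1], t2$history$loss[1], tolerance = 1e-6)
  expect_identical(t1$params, t2$params)
  expect_identical(nrow(t1$history), 2L)
  # dsa: history carries both stream losses
  md <- buildModel("dsa", spec, nClasses = 6L, seed = 5L)
  td <- trainModel(prep, md, config = trainConfig(epochs = 1L, batchSize = 4L,
                                                  bagSize = 3L, seed = 7L))
  expect_true(all(c("lossImage", "lossCell") %in% names(td$history)))
  expect_equal(td$history$loss,
               1 * td$history$lossImage + 0.2 * td$history$lossCell,
               tolerance = 1e-9)
})
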