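test_that("mask IoU handles identity, disjoint and partial overlap", {
  m <- randomMask(6, 6)
  m[1, 1] <- 1
  expect_equal(maskIoU(m, m), 1)
  a <- matrix(0, 4, 4); a[1:2, 1:2] <- 1
  b <- matrix(0, 4, 4); b[3:4, 3:4] <- 1
  expect_equal(maskIoU(a, b), 0)
  # two 2x4 rectangles overlapping in a 2x2 region: 4 / 12
  a <- matrix(0, 6, 8); a[1:2, 1:4] <- 1
  b <- matrix(0, 6, 8); b[1:2, 3:6] <- 1
  expect_equal(maskIoU(a, b), 1 / 3)
  expect_equal(maskIoU(matrix(0, 3, 3), matrix(0, 3, 3)), 0)
  expect_error(maskIoU(matrix(0, 2, 2), matrix(0, 3, 3)), "shape")
})

test_that("greedy matcher pairs identical masks and flags disjoint ones", {
  gt <- list(randomMask(8, 8, 0.3), randomMask(8, 8, 0.3))
  gt[[1]][1, 1] <- 1; gt[[2]][8, 8] <- 1
  mm <- matchCells(gt, c(0.9, 0.8), gt)
  expect_identical(nrow(mm$pairs), 2L)
  expect_length(mm$unmatchedPred, 0L)
  expect_length(mm$unmatchedGt, 0L)
  a <- matrix(0, 6, 6); a[1:2, 1:2] <- 1
  g1 <- matrix(0, 6, 6); g1[5:6, 1:2] <- 1
  g2 <- matrix(0, 6, 6); g2[5:6, 5:6] <- 1
  mm2 <- matchCells(list(a), 0.7, list(g1, g2))
  expect_identical(nrow(mm2$pairs), 0L)
  expect_identical(mm2$unmatchedPred, 1L)
  expect_identical(sort(mm2$unmatchedGt), c(1L, 2L))
})

test_that("greedy matcher agrees with an independent implementation", {
  withr::with_seed(17L, {
    for (rep in seq_len(25L)) {
      nP <- sample(1:6, 1); nG <- sample(1:6, 1)
      mk <- function() {
        m <- matrix(0, 10, 10)
        r <- sample(1:7, 1); c <- sample(1:7, 1)
        m[r:(r + 3), c:(c + 3)] <- 1
        m
      }
      pred <- replicate(nP, mk(), simplify = FALSE)
      gt <- replicate(nG, mk(), simplify = FALSE)
      conf <- runif(nP)
      mine <- matchCells(pred, conf, gt)
      orac <- oracleMatch(pred, conf, gt)
      if (is.null(orac)) {
        expect_identical(nrow(mine$pairs), 0L)
      } else {
        expect_identical(nrow(mine$pairs), nrow(orac))
        o <- orac[order(orac[, 1]), , drop = FALSE]
        m <- mine$pairs[order(mine$pairs$pred), ]
        expect_identical(as.integer(m$pred), as.integer(o[, 1]))
        expect_identical(as.integer(m$gt), as.integer(o[, 2]))
      }
    }
  })
})

test_that("average precision reproduces hand-enumerated PR curves", {
  expect_equal(averagePrecision(0.9, TRUE, 1), 1)
  # (TP, FP) over 1 positive: AP = 1; (FP, TP): AP = 0.5
  expect_equal(averagePrecision(c(0.9, 0.8), c(TRUE, FALSE), 1), 1)
  expect_equal(averagePrecision(c(0.9, 0.8), c(FALSE, TRUE), 1), 0.5)
  expect_equal(averagePrecision(numeric(0), logical(0), 0), 0)
  expect_error(averagePrecision(0.5, TRUE, -1), "nonnegative")
})

test_that("average precision matches the threshold-sweep oracle", {
  withr::with_seed(19L, {
    for (rep in seq_len(100L)) {
      n <- sample(1:50, 1)
      conf <- round(runif(n), sample(c(1, 2, 6), 1)) # induce ties sometimes
      isTp <- runif(n) < 0.4
      nPos <- sum(isTp) + sample(0:5, 1)
      expect_lt(abs(averagePrecision(conf, isTp, nPos) -
                      oracleAP(conf, isTp, nPos)), 1e-9)
    }
  })
})

test_that("removing a false positive never decreases AP", {
  withr::with_seed(23L, {
    for (rep in seq_len(30L)) {
      n <- sample(5:30, 1)
      conf <- runif(n)
      isTp <- runif(n) < 0.5
      if (!any(!isTp)) isTp[1] <- FALSE
      nPos <- sum(isTp)
      if (nPos == 0) next
      ap0 <- averagePrecision(conf, isTp, nPos)
      drop <- sample(which(!isTp), 1)
      ap1 <- averagePrecision(conf[-drop], isTp[-drop], nPos)
      expect_gte(ap1 + 1e-12, ap0)
    }
  })
})

test_that("mean AP is the unweighted mean and rejects empty input", {
  expect_equal(meanAp(rep(0.7, 5)), 0.7)
  expect_equal(meanAp(c(1, 0)), 0.5)
  withr::with_seed(29L, {
    v <- runif(19)
    expect_lt(abs(meanAp(v) - sum(v) / 19), 1e-12)
  })
  expect_error(meanAp(numeric(0)), "nonempty")
})

test_that("perfect predictions with perfect masks give mAP 1", {
  ds <- smallDataset(seed = 31L)
  info <- cellInfo(ds)
  preds <- list(); gts <- list()
  for (i in seq_len(nImages(ds))) {
    lab <- instanceMasks(ds)[[i]]
    ids <- sort(unique(lab[lab > 0]))
    masks <- lapply(ids, function(id) (lab == id) * 1)
    labs <- cellLabels(ds)[info$image == i, , drop = FALSE]
    preds[[i]] <- list(masks = masks, probs = labs)
    gts[[i]] <- list(masks = masks, labels = labs)
  }
  res <- evaluatePredictions(preds, gts)
  expect_equal(res$map, 1)
  expect_true(all(res$perClassAp[!is.na(res$perClassAp)] == 1))
})

test_that("classification scoring agrees with the full mask-matched path", {
  ds <- smallDataset(seed = 37L)
  info <- cellInfo(ds)
  withr::with_seed(1L, {
    probs <- matrix(runif(nCells(ds) * 6), nCells(ds), 6)
  })
  direct <- scoreCellPredictions(probs, cellLabels(ds))
  preds <- list(); gts <- list()
  for (i in seq_len(nImages(ds))) {
    lab <- instanceMasks(ds)[[i]]
    ids <- sort(unique(lab[lab > 0]))
    masks <- lapply(ids, function(id) (lab == id) * 1)
    sel <- info$image == i
    preds[[i]] <- list(masks = masks, probs = probs[sel, , drop = FALSE])
    gts[[i]] <- list(masks = masks,
                     labels = cellLabels(ds)[sel, , drop = FALSE])
  }
  full <- evaluatePredictions(preds, gts)
  expect_equal(full$map, direct$map, tolerance = 1e-12)
  expect_equal(full$perClassAp, direct$perClassAp, tolerance = 1e-12)
})
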