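test_that("image labels are the elementwise union of cell labels", {
  ds <- smallDataset(seed = 7L, defectRate = 0.3)
  info <- cellInfo(ds)
  for (i in seq_len(nImages(ds))) {
    rows <- cellLabels(ds)[info$image == i, , drop = FALSE]
    # brute-force OR oracle
    orv <- as.numeric(apply(rows == 1, 2, any))
    expect_identical(unname(imageLabels(ds)[i, ]), orv)
  }
})

test_that("a one-cell image's label equals that cell's label vector", {
  ds <- generateDataset(synthConfig(nImages = 1L, cellsPerImage = c(1L, 1L),
                                    imageSize = 64L, rngSeed = 3L))
  expect_equal(unname(imageLabels(ds)[1, ]), unname(cellLabels(ds)[1, ]))
})

test_that("identical configs and seeds give identical manifests", {
  cfg <- synthConfig(nImages = 3L, cellsPerImage = c(3L, 5L),
                     imageSize = 80L, rngSeed = 19L, defectRate = 0.2)
  expect_identical(generateDataset(cfg), generateDataset(cfg))
})

test_that("per-cell instance masks are disjoint and ids map to one region", {
  ds <- smallDataset(seed = 11L)
  for (i in seq_len(nImages(ds))) {
    m <- instanceMasks(ds)[[i]]
    ids <- sort(unique(m[m > 0]))
    expect_identical(ids, seq_along(ids)) # labels are 1..n, one region each
    expect_true(all(table(m[m > 0]) > 0))
  }
})

test_that("placement failure on impossible configurations is explicit", {
  cfg <- synthConfig(nImages = 1L, cellsPerImage = c(60L, 60L),
                     imageSize = 64L, cellRadius = c(14L, 14L), rngSeed = 1L)
  expect_error(generateDataset(cfg), "placement failure")
})

test_that("sampled class frequencies follow the configured distribution", {
  # one single-label cell per image, so cell labels are iid multinomial
  cfg <- synthConfig(labelsPerCell = c(1L, 1L), rngSeed = 5L)
  counts <- withr::with_seed(5L, {
    draws <- replicate(12000L, which(SubCellLoc:::.sampleCellLabels(1L, cfg)[1, ] == 1))
    tabulate(draws, nbins = cfg@nClasses)
  })
  gof <- chisq.test(counts, p = cfg@classFrequencies)
  expect_gt(gof$p.value, 0.01)
})

test_that("cells of one image share the image's label set", {
  ds <- referenceDataset(seed = 5L)
  info <- cellInfo(ds)
  lab <- cellLabels(ds)
  for (i in sample(seq_len(nImages(ds)), 10)) {
    rows <- lab[info$image == i, , drop = FALSE]
    expect_true(all(rowSums(rows) >= 1)) # every cell expresses something
    # no cell carries a class outside the image's union
    expect_true(all(rows <= rep(imageLabels(ds)[i, ], each = nrow(rows))))
  }
})

test_that("config invariants are enforced", {
  expect_error(synthConfig(nClasses = 2L, labelsPerCell = c(1L, 2L),
                           classFrequencies = c(0.5, 0.4)), "sum to 1")
  expect_error(synthConfig(nClasses = 3L,
                           classFrequencies = c(0.5, 0.3, 0.2),
                           labelsPerCell = c(1L, 4L)), "labelsPerCell")
})

test_that("corruptCell retains the requested mask fraction", {
  ds <- smallDataset(seed = 13L)
  cells <- extractCells(getImage(ds, 1), instanceMasks(ds)[[1]])
  cell <- cells[[1]]
  a0 <- sum(maskData(cell))
  for (kf in c(0.4, 0.6, 0.8)) {
    out <- corruptCell(cell, kf, rngSeed = 21L)
    a1 <- sum(maskData(out$cell)) # pixel-count oracle
    expect_lt(abs(a1 - kf * a0) / (kf * a0), 0.05)
  }
  # crop pixels outside the retained mask are zeroed
  out <- corruptCell(cell, 0.5, rngSeed = 2L)
  gone <- maskData(cell) == 1 & maskData(out$cell) == 0
  for (k in 1:4) expect_true(all(cropData(out$cell)[, , k][gone] == 0))
})

test_that("corruptCell capture classes follow the retained-fraction bins", {
  ds <- smallDataset(seed = 13L)
  cell <- extractCells(getImage(ds, 1), instanceMasks(ds)[[1]])[[1]]
  expect_identical(corruptCell(cell, 1)$captureClass, 4L)
  expect_identical(corruptCell(cell, 0.4, 3L)$captureClass, 2L)
  expect_error(corruptCell(cell, 0), "keepFraction")
  expect_error(corruptCell(cell, -0.2), "keepFraction")
})

test_that("corruption removes one contiguous boundary-adjacent region", {
  ds <- smallDataset(seed = 17L)
  cell <- extractCells(getImage(ds, 1), instanceMasks(ds)[[1]])[[1]]
  out <- corruptCell(cell, 0.5, rngSeed = 8L)
  removed <- (maskData(cell) == 1 & maskData(out$cell) == 0) * 1
  expect_gt(sum(removed), 0)
  # a single connected component (the cap beyond a chord of a convex mask)
  comp <- EBImage::bwlabel(EBImage::Image(t(removed)))
  expect_equal(max(comp), 1)
  # boundary-adjacent: some removed pixel lies on the original mask border
  ns <- asNamespace("SubCellLoc")
  f <- geometricFeatures(cell)
  m <- maskData(cell)
  pad <- matrix(0, nrow(m) + 2, ncol(m) + 2)
  pad[2:(nrow(m) + 1), 2:(ncol(m) + 1)] <- m
  edge <- m == 1 & (pad[1:nrow(m), 2:(ncol(m) + 1)] == 0 |
                    pad[3:(nrow(m) + 2), 2:(ncol(m) + 1)] == 0 |
                    pad[2:(nrow(m) + 1), 1:ncol(m)] == 0 |
                    pad[2:(nrow(m) + 1), 3:(ncol(m) + 2)] == 0)
  expect_true(any(removed == 1 & edge))
})
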