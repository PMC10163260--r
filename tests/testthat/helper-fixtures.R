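# Shared fixtures: small synthetic datasets and brute-force oracles.
# Everything is generated in code under fixed seeds; heavyweight objects
# are memoised for the duration of the test run.

.fixtureEnv <- new.env(parent = emptyenv())

memoFixture <- function(name, builder) {
  if (is.null(.fixtureEnv[[name]])) .fixtureEnv[[name]] <- builder()
  .fixtureEnv[[name]]
}

smallDataset <- function(seed = 7L, defectRate = 0) {
  generateDataset(synthConfig(nImages = 4L, cellsPerImage = c(4L, 4L),
                              imageSize = 96L, rngSeed = seed,
                              defectRate = defectRate))
}

# the reference benchmark manifest: 200 images x 12 cells, C = 6,
# imbalanced frequencies, weak labels by union
referenceDataset <- function(seed = 42L, defectRate = 0) {
  cfg <- synthConfig(rngSeed = seed, defectRate = defectRate)
  generateDataset(cfg)
}

tinySpec <- function() backboneSpec(inputSize = 24L, channels = c(8L, 16L))

# independent naive-mean oracle for GAP
oracleGAP <- function(T) {
  d <- dim(T)
  out <- numeric(d[3])
  for (k in seq_len(d[3])) {
    s <- 0
    for (i in seq_len(d[1])) for (j in seq_len(d[2])) s <- s + T[i, j, k]
    out[k] <- s / (d[1] * d[2])
  }
  out
}

# independent threshold-sweep oracle for average precision
oracleAP <- function(conf, isTp, nPos) {
  if (nPos == 0 || !length(conf)) return(0)
  ths <- sort(unique(conf), decreasing = TRUE)
  prec <- rec <- numeric(length(ths))
  for (i in seq_along(ths)) {
    keep <- conf >= ths[i]
    tp <- sum(isTp[keep])
    prec[i] <- tp / sum(keep)
    rec[i] <- tp / nPos
  }
  sum(diff(c(0, rec)) * prec)
}

# independent greedy matcher written against the rule directly
oracleMatch <- function(predMasks, conf, gtMasks, thresh = 0.6) {
  free <- rep(TRUE, length(gtMasks))
  pairs <- NULL
  for (p in order(conf, decreasing = TRUE)) {
    best <- 0; bestG <- 0
    for (g in seq_along(gtMasks)) {
      if (!free[g]) next
      i <- sum(predMasks[[p]] & gtMasks[[g]])
      u <- sum(predMasks[[p]] | gtMasks[[g]])
      iou <- if (u == 0) 0 else i / u
      if (iou > best) { best <- iou; bestG <- g }
    }
    if (bestG > 0 && best > thresh) {
      pairs <- rbind(pairs, c(p, bestG))
      free[bestG] <- FALSE
    }
  }
  pairs
}

randomMask <- function(h, w, p = 0.4) matrix(rbinom(h * w, 1, p), h, w)

# intact vs heavily-cropped cells for the structural-integrity benchmark
structBenchFixture <- function() {
  memoFixture("structBench", function() {
    ds <- generateDataset(synthConfig(nImages = 40L,
                                      cellsPerImage = c(5L, 5L),
                                      imageSize = 96L, rngSeed = 89L))
    cells <- unlist(lapply(seq_len(nImages(ds)), function(i)
      extractCells(getImage(ds, i), instanceMasks(ds)[[i]],
                   imageId = sprintf("img%04d", i))), recursive = FALSE)
    n <- length(cells)
    bad <- rep(c(0, 1), length.out = n)
    set.seed(89L)
    for (k in which(bad == 1))
      cells[[k]] <- corruptCell(cells[[k]],
                                keepFraction = runif(1, 0.15, 0.3),
                                rngSeed = 1000L + k)$cell
    list(cells = cells, bad = bad)
  })
}
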