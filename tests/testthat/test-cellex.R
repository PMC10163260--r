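mkImage <- function(size, fill = 0.5) {
  m <- matrix(fill, size, size)
  ChannelImage(m, m, m, m)
}

test_that("bounding boxes match brute-force mask extents", {
  img <- mkImage(12)
  lab <- matrix(0L, 12, 12)
  lab[3:6, 4:10] <- 1L # rows 2-5, cols 3-9 in 0-based coordinates
  cells <- extractCells(img, lab)
  expect_identical(bbox(cells[[1]]), c(2L, 6L, 3L, 10L))
  # brute-force min/max oracle
  idx <- which(lab == 1L, arr.ind = TRUE)
  expect_identical(bbox(cells[[1]]),
                   c(min(idx[, 1]) - 1L, max(idx[, 1]),
                     min(idx[, 2]) - 1L, max(idx[, 2])))
})

test_that("a whole-image mask with no padding returns the image unchanged", {
  img <- mkImage(8, fill = 0.3)
  lab <- matrix(1L, 8, 8)
  cells <- extractCells(img, lab, pad = 0L)
  expect_length(cells, 1L)
  expect_equal(cropData(cells[[1]]), imageData(img), tolerance = 0)
})

test_that("extraction conserves foreground and zeroes neighbours", {
  ds <- smallDataset(seed = 41L)
  lab <- instanceMasks(ds)[[1]]
  cells <- extractCells(getImage(ds, 1), lab, pad = 2L)
  # union of instance masks equals input foreground exactly
  rebuilt <- matrix(0, nrow(lab), ncol(lab))
  for (cl in cells) {
    bb <- bbox(cl)
    rows <- (bb[1] + 1L):bb[2]
    cols <- (bb[3] + 1L):bb[4]
    rebuilt[rows, cols] <- rebuilt[rows, cols] + maskData(cl)
  }
  expect_identical(rebuilt > 0, lab > 0)
  expect_true(all(rebuilt <= 1)) # disjoint
  # pixels outside the mask are zeroed in the crop
  cl <- cells[[1]]
  outside <- maskData(cl) == 0
  for (k in 1:4) expect_true(all(cropData(cl)[, , k][outside] == 0))
})

test_that("an empty label raster yields an empty list", {
  img <- mkImage(8)
  expect_identical(extractCells(img, matrix(0L, 8, 8)), list())
  expect_error(extractCells(img, matrix(0L, 4, 4)), "match")
})

test_that("geometric features of a filled square are exact", {
  img <- mkImage(16, fill = 0.4)
  lab <- matrix(0L, 16, 16)
  lab[4:13, 5:14] <- 1L
  f <- geometricFeatures(extractCells(img, lab)[[1]])
  expect_equal(unname(f["bbox_height"]), 10)
  expect_equal(unname(f["bbox_width"]), 10)
  expect_equal(unname(f["aspect_ratio"]), 1)
  expect_equal(unname(f["bbox_area"]), 100)
  expect_equal(unname(f["mask_area"]), 100)
  expect_equal(unname(f["largest_dimension"]), 10)
  # 4-neighbour boundary pixels of a 10x10 square: 100 - 8^2 = 36
  expect_equal(unname(f["mask_perimeter"]), 36)
  expect_equal(unname(f["stain_flag"]), 0)
})

test_that("mask perimeter matches a brute-force 4-neighbour scan", {
  ds <- smallDataset(seed = 43L)
  cells <- extractCells(getImage(ds, 2), instanceMasks(ds)[[2]])
  for (cl in cells) {
    m <- maskData(cl)
    per <- 0L
    for (i in seq_len(nrow(m))) for (j in seq_len(ncol(m))) {
      if (m[i, j] != 1) next
      nb <- c(if (i > 1) m[i - 1, j] else 0,
              if (i < nrow(m)) m[i + 1, j] else 0,
              if (j > 1) m[i, j - 1] else 0,
              if (j < ncol(m)) m[i, j + 1] else 0)
      if (any(nb == 0)) per <- per + 1L
    }
    expect_equal(unname(geometricFeatures(cl)["mask_perimeter"]), per)
  }
})

test_that("a cell with dark nucleus and protein staining raises the flag", {
  crop <- array(0, c(6, 6, 4), dimnames = list(NULL, NULL,
                                               SubCellLoc:::CHANNELS))
  crop[, , "microtubules"] <- 0.5
  cell <- SubCellLoc:::CellInstance(crop, matrix(1, 6, 6), c(0L, 6L, 0L, 6L),
                                    "im", 1L)
  expect_equal(unname(geometricFeatures(cell)["stain_flag"]), 1)
})

test_that("geometric features are invariant to crop position", {
  size <- 40L
  img <- mkImage(size, fill = 0.6)
  mkAt <- function(r0, c0) {
    lab <- matrix(0L, size, size)
    lab[r0:(r0 + 7L), c0:(c0 + 11L)] <- 1L
    lab[r0 + 2L, c0 + 3L] <- 0L # a hole, to make the shape non-trivial
    geometricFeatures(extractCells(img, lab)[[1]])
  }
  f1 <- mkAt(3L, 5L)
  f2 <- mkAt(20L, 17L)
  expect_equal(f1, f2)
})

test_that("mask post-processing labels well-separated blobs", {
  size <- 64L
  g <- function(cx, cy) {
    r <- matrix(seq_len(size), size, size)
    c <- t(r)
    exp(-((r - cx)^2 + (c - cy)^2) / (2 * 6^2))
  }
  nuclei <- pmin(g(20, 20) + g(44, 44), 1)
  cells <- pmin(1.6 * g(20, 20) + 1.6 * g(44, 44), 1)
  lab <- postprocessMasks(nuclei, cells, scale = 0.5)
  # connected-component oracle at full resolution: two distinct blobs
  expect_identical(max(lab), 2L)
  expect_identical(sort(unique(lab[lab > 0])), c(1L, 2L))
  # scale 1.0 agrees on label count for easy inputs
  lab1 <- postprocessMasks(nuclei, cells, scale = 1)
  expect_identical(max(lab1), max(lab))
})

test_that("mask post-processing edge cases", {
  z <- matrix(0, 32, 32)
  expect_identical(max(postprocessMasks(z, z)), 0L)
  expect_error(postprocessMasks(z, z, scale = 0), "scale")
  expect_error(postprocessMasks(z, z, scale = 1.5), "scale")
  expect_error(postprocessMasks(z, matrix(0, 16, 16)), "dimensions")
})
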