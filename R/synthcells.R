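# Synthetic multi-cell fluorescence images with known per-cell ground truth.
#
# Each localisation class renders a distinct spatial pattern of the protein
# channel relative to the cell geometry (nuclear fill, nuclear rim,
# cytoplasmic fill, plasma-membrane rim, punctate cytosolic spots,
# nucleolar dots, ...), so that classes are learnable by small models while
# the weak-labelling structure (image label = union of cell labels, severe
# class imbalance, capture defects) matches the real data regime.

# ---- label sampling ---------------------------------------------------

# n x C binary matrix of cell labels for ONE image. All cells of an image
# stain the same protein, so their labels are correlated: the image draws
# a label set (size uniform on the labelsPerCell range, classes by
# classFrequencies without replacement), and each cell expresses each of
# those classes with probability expressRate (at least one per cell).
# This reproduces the weak-labelling regime: the image label (union) is
# a false positive for the cells that do not express a given class.
.sampleCellLabels <- function(n, config) {
  C <- config@nClasses
  freq <- config@classFrequencies
  k <- .resample(seq(config@labelsPerCell[1], config@labelsPerCell[2]))
  imgClasses <- .resample(seq_len(C), k, prob = freq)
  lab <- matrix(0, n, C)
  for (i in seq_len(n)) {
    on <- runif(length(imgClasses)) < config@expressRate
    if (!any(on)) on[.resample(seq_along(imgClasses))] <- TRUE
    lab[i, imgClasses[on]] <- 1
  }
  lab
}

# ---- pattern registry -------------------------------------------------

# each generator returns a protein-channel contribution for one cell given
# its geometry; `geom` carries pixel coordinate grids and cell shape
.patternRegistry <- function() {
  list(
    nuclear_fill = function(geom) 0.85 * geom$nucleus,
    nuclear_rim = function(geom) {
      0.95 * (abs(geom$distNuc - geom$rNuc) <= 1.5 & geom$cell)
    },
    cytoplasm_fill = function(geom) 0.60 * geom$cyto,
    membrane_rim = function(geom) 0.95 * (geom$rho >= 0.85 & geom$cell),
    punctate_spots = function(geom) {
      out <- matrix(0, nrow(geom$cell), ncol(geom$cell))
      idx <- which(geom$cyto > 0)
      if (!length(idx)) return(out)
      ns <- sample(5:8, 1L)
      pick <- idx[sample.int(length(idx), min(ns, length(idx)))]
      rr <- (pick - 1L) %% nrow(out) + 1L
      cc <- (pick - 1L) %/% nrow(out) + 1L
      for (s in seq_along(pick)) {
        d2 <- (geom$rows - rr[s])^2 + (geom$cols - cc[s])^2
        out <- out + exp(-d2 / (2 * 1.3^2))
      }
      pmin(out, 1) * geom$cell
    },
    nucleolar_dots = function(geom) {
      out <- matrix(0, nrow(geom$cell), ncol(geom$cell))
      idx <- which(geom$nucleus > 0)
      if (!length(idx)) return(out)
      ns <- sample(1:2, 1L)
      pick <- idx[sample.int(length(idx), min(ns, length(idx)))]
      rr <- (pick - 1L) %% nrow(out) + 1L
      cc <- (pick - 1L) %/% nrow(out) + 1L
      for (s in seq_along(pick)) {
        d2 <- (geom$rows - rr[s])^2 + (geom$cols - cc[s])^2
        out <- out + exp(-d2 / (2 * 1.1^2))
      }
      pmin(out, 1) * geom$nucleus
    },
    aggresome_dot = function(geom) {
      # one bright focus at the nuclear periphery
      band <- which(abs(geom$distNuc - geom$rNuc) <= 1.5 & geom$cyto > 0)
      out <- matrix(0, nrow(geom$cell), ncol(geom$cell))
      if (!length(band)) return(out)
      pick <- band[sample.int(length(band), 1L)]
      rr <- (pick - 1L) %% nrow(out) + 1L
      cc <- (pick - 1L) %/% nrow(out) + 1L
      d2 <- (geom$rows - rr)^2 + (geom$cols - cc)^2
      pmin(exp(-d2 / (2 * 2.0^2)), 1) * geom$cell
    },
    radial_filaments = function(geom) {
      0.7 * geom$cyto * (0.5 + 0.5 * cos(6 * geom$phi))
    }
  )
}

# assign one pattern generator per class (recycled if C exceeds registry)
.classPatterns <- function(C) {
  reg <- .patternRegistry()
  reg[((seq_len(C) - 1L) %% length(reg)) + 1L]
}

# ---- cell geometry ----------------------------------------------------

# geometry of one elliptical cell on the full image grid
.cellGeometry <- function(size, cx, cy, rad, ax, ay, theta) {
  rows <- matrix(seq_len(size), size, size)
  cols <- matrix(seq_len(size), size, size, byrow = TRUE)
  dx <- rows - cx
  dy <- cols - cy
  u <- cos(theta) * dx + sin(theta) * dy
  v <- -sin(theta) * dx + cos(theta) * dy
  rho <- sqrt((u / (rad * ax))^2 + (v / (rad * ay))^2)
  cell <- rho <= 1
  rNuc <- 0.45 * rad
  distNuc <- sqrt(dx^2 + dy^2)
  nucleus <- (distNuc <= rNuc) & cell
  list(rows = rows, cols = cols, rho = rho, phi = atan2(dy, dx),
       cell = cell, nucleus = nucleus, cyto = cell & !nucleus,
       distNuc = distNuc, rNuc = rNuc)
}

# number of pixels the unclipped ellipse would cover (for capture ratios
# of border-clipped cells); evaluated on a local grid around the centre
.fullEllipseArea <- function(rad, ax, ay) {
  g <- seq(-ceiling(rad * 1.2) - 2, ceiling(rad * 1.2) + 2)
  dx <- matrix(g, length(g), length(g))
  dy <- t(dx)
  sum((dx / (rad * ax))^2 + (dy / (rad * ay))^2 <= 1)
}

# remove a contiguous boundary-adjacent cap containing `nRemove` pixels
# of `maskIdx` (linear indices): everything beyond a chord perpendicular
# to a random direction, as when a cell is truncated at the image border
# or occluded from one side. The removed region may well contain the
# nucleus, which is what makes predictions on such cells unreliable.
.sectorRemovalIdx <- function(maskIdx, nrows, cx, cy, nRemove) {
  if (nRemove <= 0) return(integer(0))
  rr <- (maskIdx - 1L) %% nrows + 1L
  cc <- (maskIdx - 1L) %/% nrows + 1L
  a0 <- runif(1, -pi, pi)
  proj <- cos(a0) * (rr - cx) + sin(a0) * (cc - cy)
  ord <- order(proj, decreasing = TRUE)
  nRemove <- min(nRemove, length(maskIdx) - 1L)
  maskIdx[ord[seq_len(nRemove)]]
}

# ---- generator --------------------------------------------------------

#' Generate a synthetic weakly-labelled dataset
#'
#' Renders multi-cell, four-channel images with per-cell ground-truth
#' multi-labels, instance masks, and image-level labels defined as the
#' elementwise union (OR) of the labels of the cells in each image.
#' A configurable fraction of cells receives a capture defect: a
#' contiguous boundary-adjacent angular sector of the cell is removed from
#' both the mask and all channels, mimicking occluded or partially
#' captured cells. Deterministic for a fixed \code{rngSeed}.
#'
#' @param config a \linkS4class{SynthConfig}.
#' @return A \linkS4class{LocDataset}.
#' @examples
#' ds <- generateDataset(synthConfig(nImages = 2L, cellsPerImage = c(3L, 3L),
#'                                   imageSize = 64L, rngSeed = 7L))
#' nCells(ds)
#' @export
generateDataset <- function(config) {
  validObject(config)
  .withSeed(config@rngSeed, .generateDatasetImpl(config))
}

.generateDatasetImpl <- function(config) {
  size <- config@imageSize
  C <- config@nClasses
  patterns <- .classPatterns(C)
  if (size < 4 * config@cellRadius[2])
    .stopf("image_size %d too small for cell radius up to %d",
           size, config@cellRadius[2])
  images <- vector("list", config@nImages)
  masks <- vector("list", config@nImages)
  allLabels <- list()
  imageLabels <- matrix(0, config@nImages, C)
  info <- list()
  for (i in seq_len(config@nImages)) {
    nc <- .resample(seq(config@cellsPerImage[1], config@cellsPerImage[2]))
    labs <- .sampleCellLabels(nc, config)
    chan <- lapply(1:4, function(k) matrix(0, size, size))
    maskR <- matrix(0L, size, size)
    placed <- matrix(numeric(0), 0, 3) # cx, cy, rad
    capRatio <- numeric(nc)
    for (j in seq_len(nc)) {
      rad <- .resample(seq(config@cellRadius[1], config@cellRadius[2]))
      ok <- FALSE
      for (att in seq_len(600L)) {
        cx <- runif(1, 0.8 * rad, size - 0.8 * rad)
        cy <- runif(1, 0.8 * rad, size - 0.8 * rad)
        # centres may come close enough for mild contact (confluent
        # monolayer); instance masks stay disjoint because a cell only
        # claims pixels not already claimed by earlier cells. The
        # separation requirement is relaxed progressively when the field
        # is crowded, as in dense cultures.
        sep <- if (att <= 200L) 0.95 else if (att <= 400L) 0.85 else 0.70
        if (nrow(placed) == 0 ||
            all(sqrt((placed[, 1] - cx)^2 + (placed[, 2] - cy)^2) >
                sep * (placed[, 3] + rad) + 1)) {
          ok <- TRUE
          break
        }
      }
      if (!ok)
        .stopf("placement failure: could not fit %d cells of radius %d in a %d-px image",
               nc, rad, size)
      placed <- rbind(placed, c(cx, cy, rad))
      ax <- runif(1, 0.85, 1.15)
      ay <- runif(1, 0.85, 1.15)
      theta <- runif(1, 0, pi)
      geom <- .cellGeometry(size, cx, cy, rad, ax, ay, theta)
      cellIdx <- which(geom$cell & maskR == 0L)
      fullArea <- .fullEllipseArea(rad, ax, ay)
      # channel contributions
      nucI <- 0.80 * geom$nucleus
      mtI <- 0.55 * geom$cyto * (0.6 + 0.4 * cos(8 * geom$phi)^2)
      erI <- 0.65 * geom$cell *
        exp(-((geom$distNuc - 1.3 * geom$rNuc) / (0.35 * geom$rNuc))^2)
      protI <- matrix(0, size, size)
      for (k in which(labs[j, ] == 1))
        protI <- protI + patterns[[k]](geom)
      protI <- pmin(protI, 1)
      keepIdx <- cellIdx
      # capture defect: drop an angular sector at the border
      if (config@defectRate > 0 && runif(1) < config@defectRate) {
        kf <- runif(1, 0.2, 0.8)
        drop <- .sectorRemovalIdx(cellIdx, size, cx, cy,
                                  round((1 - kf) * length(cellIdx)))
        keepIdx <- setdiff(cellIdx, drop)
      }
      sel <- matrix(FALSE, size, size)
      sel[keepIdx] <- TRUE
      chan[[1]][sel] <- nucI[sel]
      chan[[2]][sel] <- protI[sel]
      chan[[3]][sel] <- mtI[sel]
      chan[[4]][sel] <- erI[sel]
      maskR[keepIdx] <- j
      capRatio[j] <- length(keepIdx) / fullArea
    }
    if (config@intensityNoiseSd > 0)
      chan <- lapply(chan, function(m)
        .clamp01(m + matrix(rnorm(size * size, 0, config@intensityNoiseSd),
                            size, size)))
    else chan <- lapply(chan, .clamp01)
    images[[i]] <- ChannelImage(chan[[1]], chan[[2]], chan[[3]], chan[[4]])
    masks[[i]] <- maskR
    allLabels[[i]] <- labs
    imageLabels[i, ] <- as.numeric(apply(labs == 1, 2, any))
    info[[i]] <- data.frame(
      image = i, imageId = sprintf("img%04d", i), cellId = seq_len(nc),
      captureRatio = pmin(capRatio, 1),
      captureClass = vapply(pmin(capRatio, 1), captureClass, integer(1)),
      stringsAsFactors = FALSE)
  }
  new("LocDataset",
      images = images, masks = masks,
      cellLabels = do.call(rbind, allLabels),
      imageLabels = imageLabels,
      cellInfo = do.call(rbind, info),
      config = config, seed = config@rngSeed)
}

#' Corrupt a cell by removing a boundary-adjacent sector
#'
#' Removes a contiguous angular sector of the cell's mask (and zeroes the
#' corresponding crop pixels) so that approximately
#' \code{keepFraction} of the original mask area is retained; the achieved
#' retained area is exact to one pixel. Used to manufacture training data
#' for the capture-ratio classifier of the visual-integrity detector.
#'
#' @param cell a \linkS4class{CellInstance}.
#' @param keepFraction fraction of the mask area to retain, in (0, 1].
#' @param rngSeed integer seed for the sector placement.
#' @return A list with elements \code{cell} (the corrupted
#'   \linkS4class{CellInstance}) and \code{captureClass} (the capture
#'   class 1-4 of the retained fraction).
#' @examples
#' ds <- generateDataset(synthConfig(nImages = 1L, cellsPerImage = c(2L, 2L),
#'                                   imageSize = 64L, rngSeed = 3L))
#' cells <- extractCells(getImage(ds, 1), instanceMasks(ds)[[1]])
#' out <- corruptCell(cells[[1]], keepFraction = 0.4, rngSeed = 11L)
#' out$captureClass
#' @export
corruptCell <- function(cell, keepFraction, rngSeed = 1L) {
  if (!is.numeric(keepFraction) || length(keepFraction) != 1L ||
      keepFraction <= 0 || keepFraction > 1)
    .stopf("keepFraction must lie in (0, 1]")
  if (keepFraction == 1)
    return(list(cell = cell, captureClass = captureClass(1)))
  .withSeed(rngSeed, {
    mask <- maskData(cell)
    idx <- which(mask == 1)
    rr <- (idx - 1L) %% nrow(mask) + 1L
    cc <- (idx - 1L) %/% nrow(mask) + 1L
    drop <- .sectorRemovalIdx(idx, nrow(mask), mean(rr), mean(cc),
                              round((1 - keepFraction) * length(idx)))
    mask[drop] <- 0
    crop <- cropData(cell)
    zero <- matrix(FALSE, nrow(mask), ncol(mask))
    zero[drop] <- TRUE
    for (k in 1:4) {
      pl <- crop[, , k]
      pl[zero] <- 0
      crop[, , k] <- pl
    }
    newRatio <- cell@captureRatio * sum(mask) / length(idx)
    out <- CellInstance(crop, mask, bbox(cell), cell@imageId, cell@cellId,
                        captureRatio = newRatio)
    list(cell = out, captureClass = captureClass(keepFraction))
  })
}
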