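#' Four-channel fluorescence image
#'
#' Container for one field of view with the fixed channel order
#' (nucleus, protein, microtubules, er). Intensities are stored as
#' doubles on the [0, 1] scale; file I/O converts losslessly from and to
#' 8- or 16-bit rasters.
#'
#' @slot data numeric array of dimension height x width x 4, with the
#'   third dimension named after the channels.
#' @export
setClass("ChannelImage", representation(data = "array"))

setValidity("ChannelImage", function(object) {
  d <- dim(object@data)
  if (length(d) != 3L || d[3] != 4L)
    return("data must be a height x width x 4 array")
  nm <- dimnames(object@data)[[3]]
  if (is.null(nm) || !identical(nm, CHANNELS))
    return(sprintf("third dimension must be named %s",
                   paste(CHANNELS, collapse = ", ")))
  if (!all(is.finite(object@data))) return("intensities must be finite")
  TRUE
})

#' Construct a ChannelImage
#'
#' @param nucleus,protein,microtubules,er numeric matrices of identical
#'   dimension, one per channel.
#' @return A \linkS4class{ChannelImage}.
#' @examples
#' m <- matrix(0, 8, 8)
#' img <- ChannelImage(m, m, m, m)
#' dim(imageData(img))
#' @export
ChannelImage <- function(nucleus, protein, microtubules, er) {
  chans <- list(nucleus, protein, microtubules, er)
  dims <- unique(lapply(chans, dim))
  if (length(dims) != 1L)
    .stopf("all four channels must share dimensions")
  a <- array(0, dim = c(dim(nucleus), 4L),
             dimnames = list(NULL, NULL, CHANNELS))
  for (k in seq_along(chans)) a[, , k] <- chans[[k]]
  new("ChannelImage", data = a)
}

#' One segmented cell
#'
#' A cell cut out of its parent image: the padded bounding-box crop of all
#' four channels (pixels outside the cell's own mask zeroed, so that
#' neighbouring cells do not leak into cell-level models), the binary mask
#' over the same crop, and bookkeeping identifiers. Bounding boxes are
#' half-open 0-based \code{[r0, r1) x [c0, c1)} in parent-image coordinates.
#'
#' @slot crop numeric array h x w x 4.
#' @slot mask binary matrix h x w.
#' @slot bbox integer vector (r0, r1, c0, c1), half-open, 0-based.
#' @slot imageId character scalar.
#' @slot cellId integer scalar.
#' @slot captureRatio numeric; fraction of the original cell body retained
#'   (1 for intact cells).
#' @export
setClass("CellInstance", representation(
  crop = "array", mask = "matrix", bbox = "integer",
  imageId = "character", cellId = "integer", captureRatio = "numeric"))

setValidity("CellInstance", function(object) {
  d <- dim(object@crop)
  if (length(d) != 3L || d[3] != 4L) return("crop must be h x w x 4")
  if (!identical(dim(object@mask), d[1:2]))
    return("mask dimensions must match crop")
  if (!all(object@mask %in% c(0, 1))) return("mask must be binary")
  if (sum(object@mask) < 1) return("mask must be nonempty")
  if (length(object@bbox) != 4L) return("bbox must have length 4")
  if (object@bbox[2] <= object@bbox[1] || object@bbox[4] <= object@bbox[3])
    return("bbox must be nonempty half-open intervals")
  if (length(object@captureRatio) != 1L || object@captureRatio <= 0 ||
      object@captureRatio > 1)
    return("captureRatio must lie in (0, 1]")
  TRUE
})

CellInstance <- function(crop, mask, bbox, imageId, cellId,
                         captureRatio = 1) {
  new("CellInstance", crop = crop, mask = mask,
      bbox = as.integer(bbox), imageId = as.character(imageId),
      cellId = as.integer(cellId), captureRatio = as.numeric(captureRatio))
}

#' Synthetic dataset configuration
#'
#' Parameters of the synthetic multi-cell image generator. Defaults follow
#' the reference benchmark conditions used throughout the package: 200
#' images of 12 cells each over C = 6 imbalanced classes, with weak image
#' labels formed as the union of per-cell labels.
#'
#' @slot nImages number of images.
#' @slot cellsPerImage integer range (min, max) of cells per image.
#' @slot nClasses number of localisation classes C.
#' @slot classFrequencies probability vector of length C (sums to 1).
#' @slot labelsPerCell integer range (min, max) of labels per image label
#'   set; cell labels are subsets of the image set.
#' @slot expressRate probability that a cell expresses each class of its
#'   image's label set (cells always express at least one).
#' @slot imageSize image side in pixels (square images).
#' @slot cellRadius pixel range (min, max) of cell radii.
#' @slot intensityNoiseSd additive Gaussian intensity noise, [0, 1] scale.
#' @slot defectRate probability that a cell is rendered with a capture
#'   defect (boundary sector removed).
#' @slot rngSeed integer seed.
#' @export
setClass("SynthConfig", representation(
  nImages = "integer", cellsPerImage = "integer", nClasses = "integer",
  classFrequencies = "numeric", labelsPerCell = "integer",
  expressRate = "numeric",
  imageSize = "integer", cellRadius = "integer",
  intensityNoiseSd = "numeric", defectRate = "numeric",
  rngSeed = "integer"))

setValidity("SynthConfig", function(object) {
  if (!.isCount(object@nImages)) return("nImages must be a positive count")
  if (!.isCount(object@nClasses)) return("nClasses must be a positive count")
  if (length(object@classFrequencies) != object@nClasses)
    return("classFrequencies must have length nClasses")
  if (any(object@classFrequencies < 0))
    return("classFrequencies must be nonnegative")
  if (abs(sum(object@classFrequencies) - 1) > 1e-9)
    return("classFrequencies must sum to 1 (tolerance 1e-9)")
  for (nm in c("cellsPerImage", "labelsPerCell", "cellRadius")) {
    r <- slot(object, nm)
    if (length(r) != 2L || r[1] < 1 || r[2] < r[1])
      return(sprintf("%s must be an increasing positive range", nm))
  }
  if (object@labelsPerCell[2] > object@nClasses)
    return("labelsPerCell max must not exceed nClasses")
  if (object@expressRate <= 0 || object@expressRate > 1)
    return("expressRate must lie in (0, 1]")
  if (!.isCount(object@imageSize)) return("imageSize must be positive")
  if (object@intensityNoiseSd < 0) return("intensityNoiseSd must be >= 0")
  if (object@defectRate < 0 || object@defectRate > 1)
    return("defectRate must lie in [0, 1]")
  TRUE
})

#' @param nImages,cellsPerImage,nClasses,classFrequencies,labelsPerCell
#'   see slots.
#' @param expressRate,imageSize,cellRadius see slots.
#' @param intensityNoiseSd,defectRate,rngSeed see slots.
#' @rdname SynthConfig-class
#' @export
synthConfig <- function(nImages = 200L,
                        cellsPerImage = c(12L, 12L),
                        nClasses = 6L,
                        classFrequencies = c(0.30, 0.25, 0.18, 0.12,
                                             0.10, 0.05),
                        labelsPerCell = c(1L, 2L),
                        expressRate = 0.65,
                        imageSize = 128L,
                        cellRadius = c(10L, 14L),
                        intensityNoiseSd = 0.02,
                        defectRate = 0,
                        rngSeed = 1L) {
  if (length(cellsPerImage) == 1L) cellsPerImage <- rep(cellsPerImage, 2L)
  if (length(labelsPerCell) == 1L) labelsPerCell <- rep(labelsPerCell, 2L)
  if (length(cellRadius) == 1L) cellRadius <- rep(cellRadius, 2L)
  new("SynthConfig",
      nImages = as.integer(nImages),
      cellsPerImage = as.integer(cellsPerImage),
      nClasses = as.integer(nClasses),
      classFrequencies = as.numeric(classFrequencies),
      labelsPerCell = as.integer(labelsPerCell),
      expressRate = as.numeric(expressRate),
      imageSize = as.integer(imageSize),
      cellRadius = as.integer(cellRadius),
      intensityNoiseSd = as.numeric(intensityNoiseSd),
      defectRate = as.numeric(defectRate),
      rngSeed = as.integer(rngSeed))
}

#' Synthetic dataset manifest
#'
#' The generator's output: images, per-image instance masks, ground-truth
#' per-cell labels (withheld from training), union-derived image labels,
#' per-cell bookkeeping and full provenance (config + seed).
#'
#' @slot images list of \linkS4class{ChannelImage}.
#' @slot masks list of integer label matrices (0 = background).
#' @slot cellLabels numeric matrix nCells x C; ground truth in {0,1} as
#'   generated, values in [0,1] after label refinement.
#' @slot imageLabels binary matrix nImages x C; row i is the elementwise OR
#'   of the cell labels of image i.
#' @slot cellInfo data.frame with columns image (index), imageId, cellId,
#'   captureRatio, captureClass.
#' @slot config the \linkS4class{SynthConfig} used.
#' @slot seed integer seed actually used.
#' @export
setClass("LocDataset", representation(
  images = "list", masks = "list", cellLabels = "matrix",
  imageLabels = "matrix", cellInfo = "data.frame",
  config = "SynthConfig", seed = "integer"))

setValidity("LocDataset", function(object) {
  nI <- length(object@images)
  if (length(object@masks) != nI) return("one mask raster per image required")
  if (nrow(object@imageLabels) != nI)
    return("imageLabels must have one row per image")
  if (nrow(object@cellLabels) != nrow(object@cellInfo))
    return("cellLabels rows must match cellInfo rows")
  if (ncol(object@cellLabels) != ncol(object@imageLabels))
    return("cellLabels and imageLabels must agree on C")
  if (any(object@cellLabels < 0 | object@cellLabels > 1))
    return("cellLabels must lie in [0, 1]")
  TRUE
})

#' Per-class stream fusion policy
#'
#' For every class, image-stream and cell-stream probabilities are combined
#' by their per-class product when the two streams correlate (r above the
#' threshold, default 0.32); otherwise the cell-stream probability is kept.
#'
#' @slot r numeric vector of per-class Pearson correlations.
#' @slot rhoTh correlation threshold.
#' @slot mode character vector, "product" or "cell_only" per class.
#' @export
setClass("FusionPolicy", representation(
  r = "numeric", rhoTh = "numeric", mode = "character"))

setValidity("FusionPolicy", function(object) {
  if (length(object@mode) != length(object@r))
    return("mode and r must have the same length")
  if (!all(object@mode %in% c("product", "cell_only")))
    return("mode must be 'product' or 'cell_only'")
  want <- ifelse(object@r > object@rhoTh, "product", "cell_only")
  if (!identical(want, object@mode))
    return("mode must equal product iff r > rhoTh")
  TRUE
})

#' @param r per-class correlation vector.
#' @param rhoTh threshold; classes with \code{r > rhoTh} use the product
#'   rule, others keep the cell-stream probability.
#' @rdname FusionPolicy-class
#' @export
fusionPolicy <- function(r, rhoTh = 0.32) {
  r <- as.numeric(r)
  new("FusionPolicy", r = r, rhoTh = as.numeric(rhoTh),
      mode = ifelse(r > rhoTh, "product", "cell_only"))
}
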