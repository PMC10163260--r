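#' @rdname accessors
#' @aliases imageData,ChannelImage-method
setMethod("imageData", "ChannelImage", function(x) x@data)

#' @rdname accessors
#' @param channel one of "nucleus", "protein", "microtubules", "er".
setMethod("getChannel", "ChannelImage", function(x, channel) {
  channel <- match.arg(channel, CHANNELS)
  x@data[, , channel]
})

#' @rdname accessors
setMethod("nImages", "LocDataset", function(x) length(x@images))

#' @rdname accessors
setMethod("nCells", "LocDataset", function(x) nrow(x@cellInfo))

#' @rdname accessors
setMethod("cellLabels", "LocDataset", function(x) x@cellLabels)

#' @rdname accessors
#' @param value replacement label matrix (same shape, values in [0, 1]).
setMethod("cellLabels<-", "LocDataset", function(x, value) {
  x@cellLabels <- value
  validObject(x)
  x
})

#' @rdname accessors
setMethod("imageLabels", "LocDataset", function(x) x@imageLabels)

#' @rdname accessors
setMethod("instanceMasks", "LocDataset", function(x) x@masks)

#' @rdname accessors
setMethod("cellInfo", "LocDataset", function(x) x@cellInfo)

#' @rdname accessors
#' @param i image index.
setMethod("getImage", "LocDataset", function(x, i) x@images[[i]])

#' @rdname accessors
setMethod("cropData", "CellInstance", function(x) x@crop)

#' @rdname accessors
setMethod("maskData", "CellInstance", function(x) x@mask)

#' @rdname accessors
setMethod("bbox", "CellInstance", function(x) x@bbox)

#' @rdname accessors
setMethod("captureRatio", "CellInstance", function(x) x@captureRatio)

setMethod("show", "ChannelImage", function(object) {
  d <- dim(object@data)
  cat(sprintf("ChannelImage %d x %d px, channels: %s\n", d[1], d[2],
              paste(CHANNELS, collapse = ", ")))
  cat(sprintf("  intensity range [%.4g, %.4g]\n",
              min(object@data), max(object@data)))
})

setMethod("show", "CellInstance", function(object) {
  d <- dim(object@crop)
  cat(sprintf("CellInstance %s/cell %d: crop %d x %d px, mask area %d px\n",
              object@imageId, object@cellId, d[1], d[2],
              as.integer(sum(object@mask))))
  if (object@captureRatio < 1)
    cat(sprintf("  capture ratio %.2f\n", object@captureRatio))
})

setMethod("show", "SynthConfig", function(object) {
  cat(sprintf(paste0(
    "SynthConfig: %d images, %d-%d cells/image, C = %d classes\n",
    "  image %d px, cell radius %d-%d px, labels/cell %d-%d\n",
    "  noise sd %.3g, defect rate %.3g, seed %d\n"),
    object@nImages, object@cellsPerImage[1], object@cellsPerImage[2],
    object@nClasses, object@imageSize, object@cellRadius[1],
    object@cellRadius[2], object@labelsPerCell[1], object@labelsPerCell[2],
    object@intensityNoiseSd, object@defectRate, object@rngSeed))
})

setMethod("show", "LocDataset", function(object) {
  cat(sprintf(paste0(
    "LocDataset: %d images, %d cells, C = %d classes (seed %d)\n",
    "  cell label mass %.1f; %d cells captured below 80%%\n"),
    nImages(object), nCells(object), ncol(object@cellLabels),
    object@seed, sum(object@cellLabels),
    sum(object@cellInfo$captureRatio < 0.8)))
})

setMethod("show", "FusionPolicy", function(object) {
  cat(sprintf("FusionPolicy: rho_th = %.2f; %d/%d classes use the product rule\n",
              object@rhoTh, sum(object@mode == "product"), length(object@r)))
  cat("  r:", paste(sprintf("%.3f", object@r), collapse = " "), "\n")
})
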