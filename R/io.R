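# File formats: single-channel rasters (PNG 8-bit, TIFF 8/16-bit), label
# masks, run-length encodings, CSV manifests and prediction tables.

.readRaster <- function(path) {
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    m <- png::readPNG(path)
  } else if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    m <- tiff::readTIFF(path)
  } else .stopf("unsupported raster format: %s", path)
  if (length(dim(m)) == 3L) m <- m[, , 1] # tolerate grey written as RGB
  m
}

.writeRaster <- function(m, path, bits = 16L) {
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    png::writePNG(m, path)
  } else if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    tiff::writeTIFF(m, path, bits.per.sample = as.integer(bits),
                    compression = "none")
  } else .stopf("unsupported raster format: %s", path)
  invisible(path)
}

#' Read a four-channel image from per-channel raster files
#'
#' @param paths character vector of 4 file paths in the fixed channel
#'   order (nucleus, protein, microtubules, er), or named with those
#'   channel names in any order.
#' @return A \linkS4class{ChannelImage}; intensities are on [0, 1] exactly
#'   as stored in the files (value / (2^bits - 1)).
#' @export
readChannelImage <- function(paths) {
  if (!is.null(names(paths)) && all(names(paths) != "")) {
    missing <- setdiff(CHANNELS, names(paths))
    if (length(missing))
      .stopf("missing channel file(s): %s", paste(missing, collapse = ", "))
    paths <- paths[CHANNELS]
  }
  if (length(paths) != 4L) {
    absent <- if (length(paths) < 4L)
      paste(CHANNELS[seq(length(paths) + 1L, 4L)], collapse = ", ")
    else "none"
    .stopf("expected 4 channel files (%s), got %d; missing: %s",
           paste(CHANNELS, collapse = ", "), length(paths), absent)
  }
  for (k in seq_len(4L))
    if (!file.exists(paths[[k]]))
      .stopf("channel '%s' file not found: %s", CHANNELS[k], paths[[k]])
  chans <- lapply(paths, .readRaster)
  dims <- unique(lapply(chans, dim))
  if (length(dims) != 1L) {
    bad <- which(!vapply(chans, function(m)
      identical(dim(m), dim(chans[[1]])), logical(1)))
    .stopf("channel '%s' dimensions differ from channel 'nucleus'",
           CHANNELS[bad[1]])
  }
  ChannelImage(chans[[1]], chans[[2]], chans[[3]], chans[[4]])
}

#' Write a four-channel image as per-channel raster files
#'
#' @param img a \linkS4class{ChannelImage}.
#' @param paths character vector of 4 output paths in channel order.
#' @param bits bit depth for TIFF output (8 or 16); PNG is 8-bit. Writing
#'   quantises to the \code{2^bits - 1} grid; values already on that grid
#'   round-trip exactly.
#' @return The paths, invisibly.
#' @export
writeChannelImage <- function(img, paths, bits = 16L) {
  stopifnot(is(img, "ChannelImage"), length(paths) == 4L)
  for (k in seq_len(4L))
    .writeRaster(.clamp01(imageData(img)[, , k]), paths[[k]], bits = bits)
  invisible(paths)
}

#' Quantise intensities to a raster bit-depth grid
#'
#' @param x numeric array or matrix in [0, 1].
#' @param bits bit depth.
#' @return \code{round(x * (2^bits - 1)) / (2^bits - 1)}.
#' @export
quantiseIntensities <- function(x, bits = 16L) {
  mx <- 2^as.integer(bits) - 1
  round(.clamp01(x) * mx) / mx
}

# ---- run-length encoding ---------------------------------------------

#' Run-length encode a binary mask
#'
#' Dialect: 1-based, column-major, space-separated (start, length) pairs —
#' the classic segmentation-submission convention. The empty mask encodes
#' to the empty string.
#'
#' @param mask binary matrix.
#' @return A character scalar.
#' @examples
#' m <- matrix(0, 2, 2); m[, 1] <- 1
#' rleEncode(m) # "1 2"
#' @export
rleEncode <- function(mask) {
  .checkBinaryMask(mask)
  idx <- which(as.vector(mask) == 1)
  if (!length(idx)) return("")
  newRun <- c(TRUE, diff(idx) != 1L)
  starts <- idx[newRun]
  lens <- tabulate(cumsum(newRun))
  paste(rbind(starts, lens), collapse = " ")
}

#' Decode a run-length encoded mask
#'
#' Inverse of \code{\link{rleEncode}} on its dialect.
#'
#' @param rle character scalar of space-separated (start, length) pairs.
#' @param height,width output dimensions.
#' @return A binary matrix of dimension \code{height x width}.
#' @export
rleDecode <- function(rle, height, width) {
  out <- matrix(0, height, width)
  if (is.na(rle) || !nzchar(trimws(rle))) return(out)
  v <- suppressWarnings(as.numeric(strsplit(trimws(rle), "\\s+")[[1]]))
  if (any(is.na(v)) || length(v) %% 2L != 0L)
    .stopf("malformed RLE string")
  starts <- v[seq(1, length(v), 2)]
  lens <- v[seq(2, length(v), 2)]
  n <- height * width
  prevEnd <- 0
  for (i in seq_along(starts)) {
    if (starts[i] < 1 || lens[i] < 1 || starts[i] + lens[i] - 1 > n)
      .stopf("RLE run %d out of bounds for a %d x %d mask", i, height, width)
    if (starts[i] <= prevEnd)
      .stopf("RLE run %d overlaps the previous run", i)
    out[seq(starts[i], starts[i] + lens[i] - 1)] <- 1
    prevEnd <- starts[i] + lens[i] - 1
  }
  out
}

# ---- prediction records ----------------------------------------------

#' Construct a per-cell prediction record
#'
#' @param imageId character id of the parent image.
#' @param cellId integer cell id within the image.
#' @param rleMask run-length encoding of the cell's mask.
#' @param classProbs numeric vector of per-class probabilities in [0, 1].
#' @param wV visual-integrity weight in [0, 1].
#' @return A validated list of class \code{PredictionRecord}.
#' @export
predictionRecord <- function(imageId, cellId, rleMask, classProbs, wV = 1) {
  if (any(classProbs < 0 | classProbs > 1))
    .stopf("class probabilities must lie in [0, 1]")
  if (wV < 0 || wV > 1) .stopf("W_v must lie in [0, 1]")
  if (!is.character(rleMask) || length(rleMask) != 1L)
    .stopf("rleMask must be a character scalar")
  structure(list(imageId = as.character(imageId), cellId = as.integer(cellId),
                 rleMask = rleMask, classProbs = as.numeric(classProbs),
                 wV = as.numeric(wV)),
            class = "PredictionRecord")
}

#' Write per-cell prediction records to CSV
#'
#' Columns, in stable order: image_id, cell_id, rle_mask, w_v,
#' prob_1 ... prob_C. Probabilities are serialised at 8 significant
#' digits, so a read-back reproduces them within 1e-6.
#'
#' @param records list of \code{\link{predictionRecord}} objects.
#' @param path output CSV path.
#' @return The path, invisibly.
#' @export
writePredictions <- function(records, path) {
  if (length(records)) {
    C <- length(records[[1]]$classProbs)
    for (i in seq_along(records)) {
      r <- records[[i]]
      if (!inherits(r, "PredictionRecord") || length(r$classProbs) != C)
        .stopf("invalid prediction record at row %d", i)
    }
    df <- data.frame(
      image_id = vapply(records, `[[`, character(1), "imageId"),
      cell_id = vapply(records, `[[`, integer(1), "cellId"),
      rle_mask = vapply(records, `[[`, character(1), "rleMask"),
      w_v = sprintf("%.8g", vapply(records, `[[`, numeric(1), "wV")),
      stringsAsFactors = FALSE)
    probs <- t(vapply(records, `[[`, numeric(C), "classProbs"))
    for (c in seq_len(C))
      df[[sprintf("prob_%d", c)]] <- sprintf("%.8g", probs[, c])
  } else {
    df <- data.frame(image_id = character(0), cell_id = integer(0),
                     rle_mask = character(0), w_v = character(0))
  }
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read a prediction CSV written by \code{\link{writePredictions}}
#'
#' @param path CSV path.
#' @return A list of \code{\link{predictionRecord}} objects.
#' @export
readPredictions <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(rle_mask = "character"))
  probCols <- grep("^prob_", names(df), value = TRUE)
  probCols <- probCols[order(as.integer(sub("^prob_", "", probCols)))]
  lapply(seq_len(nrow(df)), function(i)
    predictionRecord(df$image_id[i], df$cell_id[i], df$rle_mask[i],
                     as.numeric(df[i, probCols]), as.numeric(df$w_v[i])))
}

# ---- dataset on-disk layout ------------------------------------------

#' Write a dataset in the pipeline's on-disk layout
#'
#' One 16-bit single-channel TIFF per channel
#' (\code{<image_id>_<channel>.tif}), instance masks as 16-bit label
#' TIFFs, and a CSV manifest with columns image_id, cell_id and
#' pipe-separated class indices.
#'
#' @param ds a \linkS4class{LocDataset}.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
writeDataset <- function(ds, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  info <- cellInfo(ds)
  for (i in seq_len(nImages(ds))) {
    id <- sprintf("img%04d", i)
    img <- getImage(ds, i)
    for (k in seq_len(4L))
      .writeRaster(quantiseIntensities(imageData(img)[, , k]),
                   file.path(dir, sprintf("%s_%s.tif", id, CHANNELS[k])))
    .writeRaster(instanceMasks(ds)[[i]] / 65535,
                 file.path(dir, sprintf("%s_mask.tif", id)))
  }
  lab <- cellLabels(ds)
  labStr <- apply(lab, 1, function(r)
    paste(which(r > 0), collapse = "|"))
  man <- data.frame(image_id = info$imageId, cell_id = info$cellId,
                    labels = labStr, stringsAsFactors = FALSE)
  utils::write.csv(man, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(dir)
}

#' Read images and masks written by \code{\link{writeDataset}}
#'
#' @param dir dataset directory.
#' @return A list with elements \code{images} (list of
#'   \linkS4class{ChannelImage}), \code{masks} (list of integer label
#'   matrices) and \code{manifest} (the cell-label data frame).
#' @export
readDataset <- function(dir) {
  man <- utils::read.csv(file.path(dir, "manifest.csv"),
                         stringsAsFactors = FALSE)
  ids <- unique(man$image_id)
  images <- lapply(ids, function(id)
    readChannelImage(setNames(
      file.path(dir, sprintf("%s_%s.tif", id, CHANNELS)), CHANNELS)))
  masks <- lapply(ids, function(id) {
    m <- .readRaster(file.path(dir, sprintf("%s_mask.tif", id)))
    matrix(as.integer(round(m * 65535)), nrow(m), ncol(m))
  })
  list(images = setNames(images, ids), masks = setNames(masks, ids),
       manifest = man)
}
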