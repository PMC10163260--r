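#' Accessors for pipeline containers
#'
#' @param x an object.
#' @param ... further arguments for methods.
#' @return \code{imageData}: the raw intensity array; \code{getChannel}:
#'   one channel matrix; \code{nCells}/\code{nImages}: counts;
#'   \code{cellLabels}/\code{imageLabels}: label matrices;
#'   \code{instanceMasks}: list of label rasters; \code{cellInfo}:
#'   per-cell bookkeeping; \code{cropData}/\code{maskData}/\code{bbox}:
#'   components of a \linkS4class{CellInstance}.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("imageData", function(x) standardGeneric("imageData"))

#' @rdname accessors
#' @export
setGeneric("getChannel", function(x, channel) standardGeneric("getChannel"))

#' @rdname accessors
#' @export
setGeneric("nCells", function(x) standardGeneric("nCells"))

#' @rdname accessors
#' @export
setGeneric("nImages", function(x) standardGeneric("nImages"))

#' @rdname accessors
#' @export
setGeneric("cellLabels", function(x) standardGeneric("cellLabels"))

#' @rdname accessors
#' @export
setGeneric("cellLabels<-", function(x, value) standardGeneric("cellLabels<-"))

#' @rdname accessors
#' @export
setGeneric("imageLabels", function(x) standardGeneric("imageLabels"))

#' @rdname accessors
#' @export
setGeneric("instanceMasks", function(x) standardGeneric("instanceMasks"))

#' @rdname accessors
#' @export
setGeneric("cellInfo", function(x) standardGeneric("cellInfo"))

#' @rdname accessors
#' @export
setGeneric("getImage", function(x, i) standardGeneric("getImage"))

#' @rdname accessors
#' @export
setGeneric("cropData", function(x) standardGeneric("cropData"))

#' @rdname accessors
#' @export
setGeneric("maskData", function(x) standardGeneric("maskData"))

#' @rdname accessors
#' @export
setGeneric("bbox", function(x) standardGeneric("bbox"))

#' @rdname accessors
#' @export
setGeneric("captureRatio", function(x) standardGeneric("captureRatio"))
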