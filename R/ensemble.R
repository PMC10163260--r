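# Correlation-thresholded fusion of image- and cell-stream predictions,
# diversity-based member selection, hierarchical aggregation, and
# application of visual-integrity weights.

#' Per-class correlation between image- and cell-stream predictions
#'
#' For class c, the Pearson correlation between the two streams'
#' probabilities over the cells whose parent image carries label c.
#' Undefined correlations (fewer than two eligible cells, or constant
#' input) are set to 0, which routes the class to the conservative
#' cell-only fusion mode.
#'
#' @param imageProbs cells x C matrix of image-stream probabilities
#'   (each cell carrying its parent image's prediction).
#' @param cellProbs cells x C matrix of cell-stream probabilities.
#' @param labels cells x C eligibility matrix: nonzero where the cell's
#'   parent image is labelled with the class.
#' @return Numeric vector r of length C.
#' @export
classwiseCorrelation <- function(imageProbs, cellProbs, labels) {
  stopifnot(identical(dim(imageProbs), dim(cellProbs)),
            identical(dim(imageProbs), dim(labels)))
  C <- ncol(labels)
  r <- numeric(C)
  for (c in seq_len(C)) {
    idx <- labels[, c] > 0
    if (sum(idx) < 2L) {
      .warnf("class %d has fewer than 2 eligible cells; r set to 0", c)
      r[c] <- 0
      next
    }
    rc <- suppressWarnings(cor(imageProbs[idx, c], cellProbs[idx, c]))
    r[c] <- if (is.na(rc)) 0 else rc
  }
  r
}

#' Fuse image- and cell-stream probabilities
#'
#' Class c receives the product of image- and cell-stream probabilities
#' when the streams correlate (\code{r_c > rho_th}), and the cell-stream
#' probability alone otherwise.
#'
#' @param imageProb length-C vector or cells x C matrix.
#' @param cellProb same shape as \code{imageProb}.
#' @param policy a \linkS4class{FusionPolicy}.
#' @return Fused probabilities, same shape as the inputs.
#' @export
fuseStreams <- function(imageProb, cellProb, policy) {
  stopifnot(is(policy, "FusionPolicy"))
  vec <- is.null(dim(imageProb))
  ip <- if (vec) matrix(imageProb, nrow = 1) else as.matrix(imageProb)
  cp <- if (vec) matrix(cellProb, nrow = 1) else as.matrix(cellProb)
  stopifnot(identical(dim(ip), dim(cp)), ncol(ip) == length(policy@r))
  if (min(ip, cp) < 0 || max(ip, cp) > 1)
    .stopf("probabilities must lie in [0, 1]")
  out <- cp
  prod <- policy@mode == "product"
  out[, prod] <- ip[, prod, drop = FALSE] * cp[, prod, drop = FALSE]
  if (vec) as.numeric(out) else out
}

#' Select the best member of each architecture family
#'
#' Picks the highest-scoring candidate per family (ties broken by
#' lexicographic model id) and reports the inter-model correlation matrix
#' of flattened probabilities — diverse families show a block-diagonal
#' structure.
#'
#' @param candidates data frame with columns \code{id}, \code{family} and
#'   \code{score}.
#' @param probMatrices named list (by id) of probability matrices used
#'   for the correlation diagnostic.
#' @return A list of class \code{EnsembleSpec} with \code{members}
#'   (selected ids), \code{families}, and \code{corMatrix}.
#' @export
selectDiverse <- function(candidates, probMatrices = NULL) {
  stopifnot(all(c("id", "family", "score") %in% names(candidates)))
  sel <- do.call(rbind, lapply(split(candidates, candidates$family),
                               function(df) {
    df <- df[order(-df$score, df$id), , drop = FALSE]
    df[1, , drop = FALSE]
  }))
  corM <- NULL
  if (!is.null(probMatrices)) {
    flat <- vapply(candidates$id, function(id)
      as.numeric(probMatrices[[id]]), numeric(length(probMatrices[[1]])))
    corM <- stats::cor(flat)
    dimnames(corM) <- list(candidates$id, candidates$id)
  }
  structure(list(members = sel$id, families = sel$family,
                 corMatrix = corM),
            class = "EnsembleSpec")
}

#' Aggregate ensemble members, fuse streams, and weight by integrity
#'
#' Member cell-stream outputs are aggregated hierarchically — mean within
#' each architecture family, then mean across families (a flat mean over
#' members is available) — and likewise for the image-stream outputs; the
#' aggregated streams are fused per class under the policy, and each
#' cell's fused vector is scaled by its visual-integrity weight.
#'
#' @param memberCellProbs list of cells x C matrices, one per member.
#' @param memberImageProbs list of cells x C matrices (image-stream
#'   probabilities broadcast to cells), or NULL to skip fusion.
#' @param families character vector assigning each member to a family.
#' @param policy a \linkS4class{FusionPolicy}.
#' @param wV per-cell visual-integrity weights in [0, 1] (default 1).
#' @param aggregation "hierarchical" or "flat".
#' @return Final cells x C probability matrix.
#' @export
aggregateApply <- function(memberCellProbs, memberImageProbs = NULL,
                           families = NULL, policy = NULL, wV = NULL,
                           aggregation = c("hierarchical", "flat")) {
  aggregation <- match.arg(aggregation)
  nM <- length(memberCellProbs)
  stopifnot(nM >= 1L)
  dims <- unique(lapply(memberCellProbs, dim))
  if (length(dims) != 1L) .stopf("member matrices must share shape")
  if (is.null(families)) families <- rep("all", nM)
  agg <- function(lst) {
    if (aggregation == "flat") return(Reduce(`+`, lst) / length(lst))
    fams <- split(seq_along(lst), families)
    famMeans <- lapply(fams, function(ix)
      Reduce(`+`, lst[ix]) / length(ix))
    Reduce(`+`, famMeans) / length(famMeans)
  }
  cellAgg <- agg(memberCellProbs)
  out <- if (!is.null(memberImageProbs)) {
    stopifnot(length(memberImageProbs) == nM || length(memberImageProbs) == 1L)
    imgAgg <- if (length(memberImageProbs) == 1L) memberImageProbs[[1]]
    else agg(memberImageProbs)
    fuseStreams(imgAgg, cellAgg, policy)
  } else cellAgg
  if (!is.null(wV)) out <- applyVID(out, wV)
  out
}
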