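# Competition-style evaluation: predicted cells are matched to ground
# truth at mask IoU > 0.6, per-class detection average precision is
# computed over matched/unmatched predictions, and the mean over classes
# gives the mAP.

#' Intersection over union of two binary masks
#'
#' @param a,b binary matrices of the same shape.
#' @return \eqn{|a \cap b| / |a \cup b|}; 0 if the union is empty.
#' @export
maskIoU <- function(a, b) {
  if (!identical(dim(a), dim(b))) .stopf("mask shapes differ")
  inter <- sum(a == 1 & b == 1)
  uni <- sum(a == 1 | b == 1)
  if (uni == 0) return(0)
  inter / uni
}

#' Greedy confidence-ordered mask matching
#'
#' Predictions are visited in order of descending confidence; each claims
#' the still-unmatched ground-truth mask of highest IoU, provided that
#' IoU exceeds the threshold. Every ground-truth cell is matched at most
#' once.
#'
#' @param predMasks list of binary prediction masks.
#' @param confidences numeric vector of per-prediction confidences.
#' @param gtMasks list of binary ground-truth masks.
#' @param iouThresh matching threshold (default 0.6, strict inequality).
#' @return List with \code{pairs} (data frame pred, gt, iou),
#'   \code{unmatchedPred} and \code{unmatchedGt} (index vectors).
#' @export
matchCells <- function(predMasks, confidences, gtMasks, iouThresh = 0.6) {
  stopifnot(length(predMasks) == length(confidences))
  nP <- length(predMasks); nG <- length(gtMasks)
  gtFree <- rep(TRUE, nG)
  pairs <- data.frame(pred = integer(0), gt = integer(0), iou = numeric(0))
  for (p in order(confidences, decreasing = TRUE)) {
    if (!nG) break
    ious <- vapply(seq_len(nG), function(g)
      if (gtFree[g]) maskIoU(predMasks[[p]], gtMasks[[g]]) else -1,
      numeric(1))
    g <- which.max(ious)
    if (length(g) && ious[g] > iouThresh) {
      pairs <- rbind(pairs, data.frame(pred = p, gt = g, iou = ious[g]))
      gtFree[g] <- FALSE
    }
  }
  list(pairs = pairs,
       unmatchedPred = setdiff(seq_len(nP), pairs$pred),
       unmatchedGt = which(gtFree))
}

#' Detection average precision
#'
#' All-point (non-interpolated) area under the precision-recall curve of
#' a detection list sorted by descending confidence; tied confidences are
#' grouped as one operating point. Returns 0 when there are no positives.
#'
#' @param confidences per-detection confidence scores.
#' @param isTp logical/binary vector; TRUE where the detection is a true
#'   positive.
#' @param nPositives number of ground-truth positives (>= 0).
#' @return AP in [0, 1].
#' @export
averagePrecision <- function(confidences, isTp, nPositives) {
  if (length(nPositives) != 1L || is.na(nPositives) || nPositives < 0)
    .stopf("nPositives must be a nonnegative count")
  stopifnot(length(confidences) == length(isTp))
  if (nPositives == 0 || !length(confidences)) return(0)
  ord <- order(confidences, decreasing = TRUE)
  conf <- confidences[ord]
  tp <- as.numeric(isTp[ord])
  cumTp <- cumsum(tp)
  cumN <- seq_along(tp)
  # group tied confidences: keep the last index of each tie group
  last <- c(conf[-1] != conf[-length(conf)], TRUE)
  prec <- (cumTp / cumN)[last]
  rec <- (cumTp / nPositives)[last]
  sum(diff(c(0, rec)) * prec)
}

#' Mean average precision over classes
#'
#' @param perClassAp numeric vector of per-class AP values.
#' @return Their unweighted arithmetic mean.
#' @export
meanAp <- function(perClassAp) {
  if (!length(perClassAp)) .stopf("per-class AP vector must be nonempty")
  mean(perClassAp)
}

#' Classification mAP over cells with known identity
#'
#' The common case in this pipeline: predicted cells carry the ground
#' truth masks (IoU 1), so matching is the identity and the metric
#' reduces to per-class detection AP over the cells' probability scores.
#'
#' @param cellProbs cells x C probability (score) matrix.
#' @param gtLabels cells x C binary ground-truth matrix.
#' @return List with \code{perClassAp} (NA for classes with no
#'   ground-truth positives, which are excluded from the mean) and
#'   \code{map}.
#' @export
scoreCellPredictions <- function(cellProbs, gtLabels) {
  stopifnot(identical(dim(cellProbs), dim(gtLabels)))
  C <- ncol(gtLabels)
  nPos <- colSums(gtLabels > 0)
  ap <- vapply(seq_len(C), function(c)
    averagePrecision(cellProbs[, c], gtLabels[, c] > 0, nPos[c]),
    numeric(1))
  ap[nPos == 0] <- NA_real_ # classes absent from the ground truth
  list(perClassAp = ap, map = meanAp(ap[!is.na(ap)]))
}

#' Mask-matched evaluation of per-image predictions
#'
#' Full two-stage evaluation: per image, predicted masks are greedily
#' matched to ground-truth masks at IoU > \code{iouThresh}; per class,
#' each prediction contributes a detection with its class score, counted
#' as a true positive only if its matched ground-truth cell carries the
#' class. The per-class APs are averaged into the mAP.
#'
#' @param predictions list per image: list(masks = list of binary masks,
#'   probs = nPred x C matrix).
#' @param groundTruth list per image: list(masks = list of binary masks,
#'   labels = nGt x C binary matrix).
#' @param iouThresh matching threshold.
#' @return List with \code{perClassAp} and \code{map}.
#' @export
evaluatePredictions <- function(predictions, groundTruth, iouThresh = 0.6) {
  stopifnot(length(predictions) == length(groundTruth))
  C <- ncol(groundTruth[[1]]$labels)
  det <- vector("list", C)
  nPos <- numeric(C)
  for (i in seq_along(predictions)) {
    pr <- predictions[[i]]; gt <- groundTruth[[i]]
    nPos <- nPos + colSums(gt$labels > 0)
    conf <- apply(pr$probs, 1, max)
    mm <- matchCells(pr$masks, conf, gt$masks, iouThresh)
    gtOf <- rep(NA_integer_, length(pr$masks))
    gtOf[mm$pairs$pred] <- mm$pairs$gt
    for (c in seq_len(C)) {
      tp <- !is.na(gtOf) & gt$labels[ifelse(is.na(gtOf), 1L, gtOf), c] > 0
      det[[c]] <- rbind(det[[c]],
                        cbind(conf = pr$probs[, c], tp = as.numeric(tp)))
    }
  }
  ap <- vapply(seq_len(C), function(c) {
    if (is.null(det[[c]])) return(0)
    averagePrecision(det[[c]][, "conf"], det[[c]][, "tp"] == 1, nPos[c])
  }, numeric(1))
  ap[nPos == 0] <- NA_real_
  list(perClassAp = ap, map = meanAp(ap[!is.na(ap)]))
}
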