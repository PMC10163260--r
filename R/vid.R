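# Visual-integrity detection: a structural-integrity weight W_1 from a
# gradient-boosted tree classifier over eight geometric features, and a
# capture-ratio weight W_2 from a 4-class image classifier trained on
# synthetically corrupted cells. The final weight W_v = W_1 * W_2
# multiplies every class probability of the cell.

#' Capture class from the captured fraction of the cell body
#'
#' Bins on the fraction of the cell body captured: [0, 0.3) is class 1,
#' [0.3, 0.5) class 2, [0.5, 0.8) class 3, [0.8, 1] class 4.
#'
#' @param ratio captured fraction in [0, 1].
#' @return Integer class in 1..4.
#' @export
captureClass <- function(ratio) {
  if (!is.numeric(ratio) || length(ratio) != 1L || is.na(ratio) ||
      ratio < 0 || ratio > 1)
    .stopf("capture ratio must lie in [0, 1]")
  if (ratio < 0.3) 1L else if (ratio < 0.5) 2L else if (ratio < 0.8) 3L
  else 4L
}

#' Capture weight W_2 for a capture class
#'
#' W_2 = 0.1 for class 1, 0.5 for class 2, and 1 for classes 3 and 4.
#'
#' @param class integer capture class in 1..4.
#' @return Numeric weight.
#' @export
captureWeight <- function(class) {
  if (!length(class) == 1L || !class %in% 1:4)
    .stopf("capture class must be one of 1, 2, 3, 4")
  c(0.1, 0.5, 1, 1)[class]
}

#' Train the structural-integrity classifier
#'
#' Gradient-boosted trees (xgboost) over the eight geometric features,
#' predicting the probability that a cell is 'bad' (severely occluded or
#' substantially not visible). The number of boosting rounds is chosen by
#' fivefold cross-validation.
#'
#' @param features matrix (cells x 8) of \code{\link{geometricFeatures}}
#'   rows.
#' @param bad binary vector; 1 = bad cell.
#' @param nrounds maximum boosting rounds.
#' @param seed RNG seed.
#' @return An object of class \code{StructuralClassifier}.
#' @export
trainStructuralClassifier <- function(features, bad, nrounds = 50L,
                                      seed = 1L) {
  features <- as.matrix(features)
  stopifnot(nrow(features) == length(bad), all(bad %in% c(0, 1)))
  .withSeed(seed, {
    dtrain <- xgboost::xgb.DMatrix(features, label = as.numeric(bad))
    pars <- list(objective = "binary:logistic", max_depth = 3,
                 eta = 0.3, nthread = 1)
    cv <- xgboost::xgb.cv(params = pars, data = dtrain, nrounds = nrounds,
                          nfold = 5, verbose = 0, early_stopping_rounds = 10)
    best <- cv$best_iteration %||% nrounds
    fit <- xgboost::xgb.train(params = pars, data = dtrain,
                              nrounds = max(best, 5L), verbose = 0)
    structure(list(booster = fit, featureNames = colnames(features)),
              class = "StructuralClassifier")
  })
}

#' Structural-integrity weight W_1
#'
#' \eqn{W_1 = 1 - P_b}, where \eqn{P_b} is the classifier's predicted
#' probability that the cell is bad.
#'
#' @param features one feature vector (length 8) or a matrix of rows.
#' @param classifier a trained \code{StructuralClassifier}.
#' @return Numeric vector of weights in [0, 1].
#' @export
structuralWeight <- function(features, classifier) {
  if (!inherits(classifier, "StructuralClassifier"))
    .stopf("classifier must be a trained StructuralClassifier")
  m <- if (is.matrix(features)) features else matrix(features, nrow = 1)
  pb <- stats::predict(classifier$booster, xgboost::xgb.DMatrix(m))
  1 - pb
}

#' Train the capture-ratio classifier
#'
#' A small convolutional network with a softmax head over the four
#' capture classes, trained with cross-entropy on cell crops whose
#' capture class is known (manufactured with \code{\link{corruptCell}}).
#'
#' @param crops H x W x 4 x n crop array at \code{spec$inputSize}.
#' @param classes integer vector of capture classes 1..4.
#' @param spec a \code{\link{backboneSpec}}.
#' @param config a \code{\link{trainConfig}} (the focal/bag settings are
#'   ignored; the loss is plain softmax cross-entropy).
#' @return A trained \code{SCLModel} of type "capture".
#' @export
trainCaptureModel <- function(crops, classes, spec = backboneSpec(),
                              config = trainConfig()) {
  stopifnot(all(classes %in% 1:4), dim(crops)[4] == length(classes))
  model <- buildModel("capture", spec, nClasses = 4L, seed = config$seed)
  onehot <- diag(4)[classes, , drop = FALSE]
  n <- length(classes)
  .withSeed(config$seed, {
    state <- .adamInit(model$params)
    hist <- data.frame(epoch = integer(0), loss = numeric(0))
    for (e in seq_len(config$epochs) - 1L) {
      lr <- cosineLR(e, config$epochs, config$lr, config$lrFloor)
      ord <- sample.int(n)
      tot <- 0; nb <- 0L
      for (s in seq(1L, n, config$batchSize)) {
        idx <- ord[s:min(s + config$batchSize - 1L, n)]
        X <- crops[, , , idx, drop = FALSE]
        if (!is.null(config$augment)) X <- .augmentBatch(X, config$augment)
        t <- onehot[idx, , drop = FALSE]
        fwd <- .descriptorForward(model, X)
        hd <- .headForward(fwd$P, model$params$head_W, model$params$head_b,
                           "softmax")
        p <- pmin(pmax(hd$probs, 1e-12), 1)
        loss <- -sum(t * log(p)) / length(idx)
        if (!is.finite(loss))
          .stopf("training diverged (non-finite loss) at epoch %d", e)
        dLogits <- (hd$probs - t) / length(idx)
        grads <- list(head_W = fwd$P %*% dLogits, head_b = colSums(dLogits))
        dDesc <- model$params$head_W %*% t(dLogits)
        grads <- .descriptorBackward(model, dDesc, fwd, grads)
        upd <- .adamStep(model$params, grads, state, lr)
        model$params <- upd$params
        state <- upd$state
        tot <- tot + loss; nb <- nb + 1L
      }
      hist <- rbind(hist, data.frame(epoch = e, loss = tot / nb))
    }
    model$history <- hist
    model
  })
}

#' Predict capture classes for crops
#'
#' @param model a trained capture \code{SCLModel}.
#' @param crops crop array H x W x 4 x n.
#' @return Integer vector of predicted capture classes.
#' @export
predictCaptureClass <- function(model, crops) {
  stopifnot(model$type == "capture")
  n <- dim(crops)[4]
  out <- integer(n)
  for (s in seq(1L, n, 256L)) {
    idx <- s:min(s + 255L, n)
    fwd <- .descriptorForward(model, crops[, , , idx, drop = FALSE])
    p <- .headForward(fwd$P, model$params$head_W, model$params$head_b,
                      "softmax")$probs
    out[idx] <- max.col(p, ties.method = "first")
  }
  out
}

#' Visual-integrity weights for one cell
#'
#' Combines the structural-integrity weight \eqn{W_1 = 1 - P_b} with the
#' capture weight \eqn{W_2} of the predicted capture class into
#' \eqn{W_v = W_1 W_2}.
#'
#' @param cell a \linkS4class{CellInstance}.
#' @param structuralClassifier trained \code{StructuralClassifier}.
#' @param captureModel trained capture \code{SCLModel}.
#' @return Named numeric vector (W1, W2, Wv) with \code{Wv = W1 * W2}.
#' @export
visualIntegrity <- function(cell, structuralClassifier, captureModel) {
  f <- geometricFeatures(cell)
  w1 <- structuralWeight(matrix(f, nrow = 1,
                                dimnames = list(NULL, names(f))),
                         structuralClassifier)
  crop <- .cropBatch(cell, captureModel$spec$inputSize)
  cls <- predictCaptureClass(captureModel, crop)
  w2 <- captureWeight(cls)
  c(W1 = unname(w1), W2 = w2, Wv = unname(w1) * w2)
}

#' Apply visual-integrity weights to probabilities
#'
#' Scales each cell's probability vector by its weight; since weights lie
#' in [0, 1], no probability ever increases.
#'
#' @param probs cells x C probability matrix.
#' @param wV numeric vector of per-cell weights in [0, 1].
#' @return Weighted probability matrix.
#' @export
applyVID <- function(probs, wV) {
  stopifnot(nrow(probs) == length(wV), all(wV >= 0 & wV <= 1))
  probs * wV
}
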