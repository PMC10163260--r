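# Cells re-labelling: ensemble-averaged per-cell confidences are
# power-normalised (c -> c^beta) and replace the positive entries of the
# weak label matrix, yielding continuous-valued cell labels for the next
# training round. Negatives are never promoted.

#' Relabelling configuration
#'
#' @param beta positive exponent of the relabelling transform
#'   \eqn{c \mapsto c^\beta}; the default 0.5 inflates low-to-mid
#'   confidences, shifting mass of originally-positive labels away from 0.
#' @param nRounds number of refinement rounds (default 2).
#' @param sourceModels list of source-model descriptors, each a list with
#'   elements \code{type} ("cla", "clh" or "dsa"), \code{spec} (a
#'   \code{\link{backboneSpec}}) and \code{seed}. Diversity across
#'   members, not any specific trunk, is what matters.
#' @return A list of class \code{CRAConfig}.
#' @export
craConfig <- function(beta = 0.5, nRounds = 2L, sourceModels = NULL) {
  if (!is.numeric(beta) || length(beta) != 1L || beta <= 0)
    .stopf("beta must be a positive scalar")
  if (!.isCount(nRounds)) .stopf("nRounds must be >= 1")
  if (is.null(sourceModels))
    sourceModels <- lapply(1:3, function(k)
      list(type = "cla", spec = backboneSpec(), seed = 100L + k))
  if (!length(sourceModels)) .stopf("at least one source model is required")
  structure(list(beta = beta, nRounds = as.integer(nRounds),
                 sourceModels = sourceModels),
            class = "CRAConfig")
}

#' Combine per-model confidence matrices
#'
#' Elementwise arithmetic mean across models of the per-cell, per-class
#' probabilities.
#'
#' @param perModelProbs list of cells x C probability matrices of equal
#'   shape.
#' @return A cells x C matrix.
#' @export
combineConfidences <- function(perModelProbs) {
  stopifnot(length(perModelProbs) >= 1L)
  dims <- unique(lapply(perModelProbs, dim))
  if (length(dims) != 1L) .stopf("probability matrices must share shape")
  for (m in perModelProbs)
    if (any(m < 0 | m > 1)) .stopf("probabilities must lie in [0, 1]")
  Reduce(`+`, perModelProbs) / length(perModelProbs)
}

#' Replace positive weak labels by power-normalised confidences
#'
#' Entries with a positive (weak) label become \eqn{c^\beta} of the
#' combined confidence \eqn{c}; entries with label zero remain exactly
#' zero — only true-positive labels are re-evaluated, negatives are never
#' promoted.
#'
#' @param confidences cells x C combined confidences in [0, 1].
#' @param weakLabels cells x C label matrix (binary on round 1, possibly
#'   continuous afterwards).
#' @param beta positive exponent (or a \code{\link{craConfig}}).
#' @return A cells x C continuous label matrix in [0, 1].
#' @export
relabelCells <- function(confidences, weakLabels, beta = 0.5) {
  if (inherits(beta, "CRAConfig")) beta <- beta$beta
  if (!is.numeric(beta) || beta <= 0) .stopf("beta must be positive")
  stopifnot(identical(dim(confidences), dim(weakLabels)))
  if (any(confidences < 0 | confidences > 1))
    .stopf("confidences must lie in [0, 1]")
  out <- ifelse(weakLabels > 0, confidences^beta, 0)
  matrix(out, nrow(weakLabels), ncol(weakLabels))
}

#' Iterative label refinement
#'
#' Round r trains the source models on the labels of round r-1 (round 0
#' being the weak labels), averages their per-cell confidences, and
#' relabels. The refined labels of the final round are returned together
#' with the last round's trained models and full provenance.
#'
#' @param data a \linkS4class{LocDataset} or \code{\link{prepareCells}}
#'   output.
#' @param config a \code{\link{craConfig}}.
#' @param train a \code{\link{trainConfig}} used for every source model
#'   (each model's own seed overrides \code{train$seed}).
#' @param weakLabels optional starting labels; defaults to the weak
#'   (union-derived) cell labels.
#' @return List with \code{labels} (refined matrix), \code{models} (last
#'   round), \code{provenance} (per-round seeds and beta), and
#'   \code{labelHistory} (list of label matrices per round).
#' @export
runCraRounds <- function(data, config = craConfig(), train = trainConfig(),
                         weakLabels = NULL) {
  if (is(data, "LocDataset"))
    data <- prepareCells(data, config$sourceModels[[1]]$spec$inputSize)
  if (is.null(weakLabels))
    weakLabels <- data$imageLabels[data$imageIndex, , drop = FALSE]
  labels <- weakLabels
  hist <- list()
  models <- NULL
  prov <- list(beta = config$beta, rounds = list())
  for (r in seq_len(config$nRounds)) {
    models <- lapply(config$sourceModels, function(sm) {
      m <- buildModel(sm$type, sm$spec, nClasses = ncol(labels),
                      seed = sm$seed)
      tc <- train
      tc$seed <- .childSeed(sm$seed, r)
      trainModel(data, m, cellTargets = labels, config = tc)
    })
    probs <- lapply(models, function(m) {
      p <- predictCells(m, data)
      if (is.list(p)) p$cellProbs else p
    })
    conf <- combineConfidences(probs)
    labels <- relabelCells(conf, weakLabels, config$beta)
    hist[[r]] <- labels
    prov$rounds[[r]] <- list(round = r,
                             seeds = vapply(config$sourceModels,
                                            function(sm) sm$seed, integer(1)))
  }
  list(labels = labels, models = models, provenance = prov,
       labelHistory = hist)
}
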