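#' @import methods
#' @importFrom stats cor rnorm runif setNames
NULL

# channel order is fixed throughout the package
CHANNELS <- c("nucleus", "protein", "microtubules", "er")

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

.isCount <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) &&
  x >= 1 && x == round(x)

.clamp01 <- function(x) pmin(pmax(x, 0), 1)

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state.
.withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  force(expr)
}

# derive a child seed deterministically; kept below 2^31
.childSeed <- function(seed, k) {
  as.integer((as.double(seed) * 48271 + 7919 * as.double(k)) %% 2147483647)
}

.checkBinaryMask <- function(mask, what = "mask") {
  if (!is.matrix(mask) && !(is.array(mask) && length(dim(mask)) == 2L))
    .stopf("%s must be a 2-d matrix", what)
  v <- unique(as.vector(mask))
  if (!all(v %in% c(0, 1)))
    .stopf("%s must be binary (0/1); found other values", what)
  invisible(TRUE)
}

# bilinear resize of an H x W matrix (wraps EBImage; transposed layout:
# EBImage images are x-by-y, ours are row-by-column)
.resizeMatrix <- function(m, h, w, nearest = FALSE) {
  img <- EBImage::Image(t(m))
  out <- EBImage::resize(img, w = w, h = h,
                         filter = if (nearest) "none" else "bilinear")
  t(EBImage::imageData(out))
}

# resize an H x W x C array channel-wise
.resizeArray <- function(a, h, w) {
  nc <- dim(a)[3]
  out <- array(0, dim = c(h, w, nc), dimnames = dimnames(a))
  for (k in seq_len(nc)) out[, , k] <- .resizeMatrix(a[, , k], h, w)
  out
}

# sample from the elements of x (safe for length-1 vectors)
.resample <- function(x, size = 1L, replace = FALSE, prob = NULL) {
  x[sample.int(length(x), size, replace = replace, prob = prob)]
}
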