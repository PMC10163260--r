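# 2-d wavelet scattering transform: cascaded Morlet-wavelet convolutions
# with modulus nonlinearities and a terminal Gaussian low-pass, spatially
# downsampled by 2^J. Translation equivariant by construction (circular
# convolutions; strided subsampling), energy non-increasing because the
# filter bank is normalised to a frame bound of at most one.

.scatCache <- new.env(parent = emptyenv())

# centred frequency grid for side n: values in [-pi, pi)
.freqGrid <- function(n) {
  k <- seq_len(n) - 1L
  w <- 2 * pi * k / n
  w[w >= pi] <- w[w >= pi] - 2 * pi
  w
}

# Morlet-like band-pass and Gaussian low-pass filter bank in Fourier
# domain, normalised so |phi|^2 + sum |psi|^2 <= 1 everywhere
.scatFilters <- function(n, J, L) {
  key <- paste(n, J, L, sep = "_")
  if (!is.null(.scatCache[[key]])) return(.scatCache[[key]])
  wx <- matrix(.freqGrid(n), n, n)
  wy <- t(wx)
  psi <- vector("list", J * L)
  t <- 1L
  for (j in seq_len(J)) {
    xi <- 3 * pi / 4 / 2^(j - 1)
    sg <- 0.8 * xi
    for (l in seq_len(L)) {
      th <- pi * (l - 1) / L
      cx <- xi * cos(th)
      cy <- xi * sin(th)
      g <- exp(-((wx - cx)^2 + (wy - cy)^2) / (2 * sg^2))
      corr <- exp(-(wx^2 + wy^2) / (2 * sg^2)) * exp(-xi^2 / (2 * sg^2))
      psi[[t]] <- g - corr # zero mean: psi_hat(0) = 0
      t <- t + 1L
    }
  }
  sgp <- 0.8 * pi / 2^J
  phi <- exp(-(wx^2 + wy^2) / (2 * sgp^2))
  lp <- phi^2
  for (p in psi) lp <- lp + Mod(p)^2
  nrm <- sqrt(max(lp))
  filters <- list(phi = phi / nrm, psi = lapply(psi, function(p) p / nrm),
                  scale = vapply(seq_len(J * L),
                                 function(t) (t - 1L) %/% L + 1L, integer(1)))
  .scatCache[[key]] <- filters
  filters
}

.fftConv <- function(xhat, fhat) stats::fft(xhat * fhat, inverse = TRUE) /
  length(xhat)

.subsample <- function(m, step) m[seq(1, nrow(m), step), seq(1, ncol(m), step),
                                  drop = FALSE]

#' Wavelet scattering transform of an image patch
#'
#' Computes translation-stable scattering coefficients up to the given
#' order: the order-0 low-pass, order-1 coefficients
#' \eqn{|x \star \psi_{j_1,\theta_1}| \star \phi_J}, and order-2
#' coefficients over increasing scale pairs \eqn{j_2 > j_1}, all
#' subsampled by \eqn{2^J}. Convolutions are circular, so circularly
#' shifting the input by \eqn{2^J} pixels shifts the coefficient maps by
#' exactly one sample.
#'
#' @param x numeric matrix (one channel) or H x W x C array (channels are
#'   transformed independently and stacked).
#' @param J number of dyadic scales; the side length must be divisible by
#'   \code{2^J}.
#' @param order maximum scattering order (0, 1 or 2).
#' @param L number of wavelet orientations.
#' @return Array of dimension \code{H/2^J x W/2^J x K} of coefficient
#'   maps, order-0 first, then order-1, then order-2.
#' @export
scatteringTransform <- function(x, J = 2L, order = 2L, L = 4L) {
  J <- as.integer(J); order <- as.integer(order); L <- as.integer(L)
  if (length(dim(x)) == 3L) {
    outs <- lapply(seq_len(dim(x)[3]),
                   function(k) scatteringTransform(x[, , k], J, order, L))
    return(array(unlist(outs),
                 c(dim(outs[[1]])[1:2], dim(outs[[1]])[3] * length(outs))))
  }
  stopifnot(is.matrix(x))
  n <- nrow(x)
  if (ncol(x) != n) .stopf("scattering expects square input")
  if (n %% 2^J != 0) .stopf("side %d not divisible by 2^%d", n, J)
  if (!order %in% 0:2) .stopf("order must be 0, 1 or 2")
  filt <- .scatFilters(n, J, L)
  step <- 2^J
  xhat <- stats::fft(x)
  coef <- list(Re(.subsample(Re(.fftConv(xhat, filt$phi)), step)))
  if (order >= 1) {
    u1 <- lapply(seq_along(filt$psi), function(t)
      Mod(.fftConv(xhat, filt$psi[[t]])))
    for (t in seq_along(u1))
      coef[[length(coef) + 1L]] <-
        .subsample(Re(.fftConv(stats::fft(u1[[t]]), filt$phi)), step)
    if (order >= 2) {
      for (t1 in seq_along(u1)) {
        u1hat <- stats::fft(u1[[t1]])
        for (t2 in seq_along(filt$psi)) {
          if (filt$scale[t2] <= filt$scale[t1]) next
          u2 <- Mod(.fftConv(u1hat, filt$psi[[t2]]))
          coef[[length(coef) + 1L]] <-
            .subsample(Re(.fftConv(stats::fft(u2), filt$phi)), step)
        }
      }
    }
  }
  array(unlist(coef), c(n %/% step, n %/% step, length(coef)))
}
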