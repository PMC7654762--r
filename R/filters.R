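# Band-pass filtering, analytic signal and Morlet machinery. Time always runs
# along the second dimension (columns) of an epochs x time matrix.

#' Least-squares linear-phase FIR band-pass design
#'
#' Designs the symmetric (type I) band-pass used before the Hilbert transform.
#' The filter order is frequency dependent: `round(cycles * sf / f_start)`,
#' incremented to the next even number so the two-sided kernel has a central
#' tap. The amplitude response is fitted by least squares on a dense frequency
#' grid with a pass band `[f_start, f_end]`, stop bands down to DC and up to
#' Nyquist, and don't-care transition regions spanning 25% of each band edge.
#'
#' @param band `(f_start, f_end)` pass band in Hz.
#' @param sf sampling frequency in Hz.
#' @param cycles number of cycles of `f_start` covered by the filter; the
#'   package defaults are 3 for phase bands and 6 for amplitude bands.
#' @return An object of class `fir_filter`: list with `h` (impulse response,
#'   odd length), `order`, `band`, `sf`, `cycles`.
#' @examples
#' f <- design_fir_ls(c(5, 7), sf = 512, cycles = 3)
#' f$order   # round(3 * 512 / 5) = 307, forced even -> 308
#' @export
design_fir_ls <- function(band, sf, cycles = 3) {
  band <- as_band_matrix(band, sf, "band")[1L, ]
  stopifnot_scalar_number(cycles, "cycles", lower = 1)
  f1 <- band[[1L]]; f2 <- band[[2L]]
  order <- round(cycles * sf / f1)
  if (order %% 2 == 1) order <- order + 1
  if (f2 - f1 < sf / (16 * order))
    stop(sprintf(
      "band [%g, %g] Hz is too narrow for the achievable order %d (width must be >= %g Hz)",
      f1, f2, order, sf / (16 * order)))
  nyq <- sf / 2
  stop2 <- min(1.25 * f2, (f2 + nyq) / 2)
  M <- order %/% 2L
  # amplitude response A(w) = sum_{k=0}^{M} b_k cos(k w); fit on stop + pass
  ngrid <- max(2048L, 16L * (M + 1L))
  w <- seq(0, pi, length.out = ngrid)
  f <- w * sf / (2 * pi)
  keep <- (f <= 0.75 * f1) | (f >= f1 & f <= f2) | (f >= stop2)
  d <- as.numeric(f[keep] >= f1 & f[keep] <= f2)
  C <- outer(w[keep], 0:M, function(wg, k) cos(k * wg))
  b <- qr.coef(qr(C), d)
  b[1L] <- b[1L] - sum(b)              # exact null at DC
  # unit gain at the band centre (the least-squares fit ripples when the band
  # width approaches the filter's frequency resolution sf/order)
  wc <- pi * (f1 + f2) / sf
  b <- b / sum(b * cos(0:M * wc))
  h <- c(rev(b[-1L] / 2), b[1L], b[-1L] / 2)
  structure(list(h = h, order = order, band = c(f1, f2), sf = sf,
                 cycles = cycles),
            class = "fir_filter")
}

#' @export
print.fir_filter <- function(x, ...) {
  cat(sprintf("<fir_filter> least-squares band-pass [%g, %g] Hz @ %g Hz, order %d (%g cycles)\n",
              x$band[1L], x$band[2L], x$sf, x$order, x$cycles))
  invisible(x)
}

#' Two-way (zero-phase) FIR filtering
#'
#' Applies the filter forward and then backward along time, which cancels the
#' phase response and squares the magnitude response. Implemented as a single
#' convolution with the autocorrelation kernel of the (symmetric) impulse
#' response, using FFTs and zero padding at the edges; the result is aligned
#' so that the net group delay is zero.
#'
#' @param x numeric vector or epochs-by-time matrix.
#' @param filt a `fir_filter` from [design_fir_ls()], or a numeric impulse
#'   response of odd length.
#' @return Filtered data with the shape of `x`.
#' @export
filt_twoway <- function(x, filt) {
  h <- if (inherits(filt, "fir_filter")) filt$h else as.numeric(filt)
  # forward + backward with symmetric h == convolution with conv(h, rev(h))
  g <- stats::convolve(h, rev(h), type = "open")   # length 2L-1, symmetric
  conv_same(x, g)
}

# Centered ('same') convolution of each row of x with an odd-length symmetric
# kernel g, zero-padded edges, via FFT.
conv_same <- function(x, g) {
  vec <- is.null(dim(x))
  if (vec) x <- matrix(x, nrow = 1L)
  n <- ncol(x)
  lg <- length(g)
  delay <- (lg - 1L) %/% 2L
  nfft <- next_pow2(n + lg - 1L)
  G <- stats::fft(c(g, rep(0, nfft - lg)))
  X <- stats::mvfft(rbind(t(x), matrix(0, nfft - n, nrow(x))))
  Y <- Re(stats::mvfft(X * G, inverse = TRUE)) / nfft
  out <- t(Y[(delay + 1L):(delay + n), , drop = FALSE])
  if (vec) out[1L, ] else out
}

# Complex 'same' convolution (for Morlet wavelets).
conv_same_complex <- function(x, g) {
  vec <- is.null(dim(x))
  if (vec) x <- matrix(x, nrow = 1L)
  n <- ncol(x)
  lg <- length(g)
  delay <- (lg - 1L) %/% 2L
  nfft <- next_pow2(n + lg - 1L)
  G <- stats::fft(c(g, rep(0, nfft - lg)))
  X <- stats::mvfft(rbind(t(x), matrix(0, nfft - n, nrow(x))))
  Y <- stats::mvfft(X * G, inverse = TRUE) / nfft
  out <- t(Y[(delay + 1L):(delay + n), , drop = FALSE])
  if (vec) out[1L, ] else out
}

# Analytic signal along rows (time = columns) via the frequency-domain
# one-sided multiplier.
analytic_signal <- function(x) {
  vec <- is.null(dim(x))
  if (vec) x <- matrix(x, nrow = 1L)
  n <- ncol(x)
  X <- stats::mvfft(t(x))
  mult <- numeric(n)
  if (n %% 2 == 0) {
    mult[1L] <- 1; mult[n / 2 + 1L] <- 1; mult[2:(n / 2)] <- 2
  } else {
    mult[1L] <- 1; mult[2:((n + 1L) / 2)] <- 2
  }
  out <- t(stats::mvfft(X * mult, inverse = TRUE) / n)
  if (vec) out[1L, ] else out
}

# Complex Morlet kernel at frequency f: carrier exp(2i pi f t) under a
# Gaussian envelope with sigma_t = width / (2 pi f). The envelope is scaled to
# sum to 2 so that a sinusoid A*cos(2 pi f t) at the centre frequency is
# recovered with modulus A (unit amplitude gain).
morlet_kernel <- function(f, sf, width = 7) {
  stopifnot_scalar_number(f, "f", lower = .Machine$double.eps)
  stopifnot_scalar_number(width, "width", lower = 1)
  if (f >= sf / 2)
    stop(sprintf("Morlet centre frequency %g Hz is not below Nyquist (%g Hz)",
                 f, sf / 2))
  sigma <- width / (2 * pi * f)
  half <- ceiling(4 * sigma * sf)
  t <- (-half:half) / sf
  env <- exp(-t^2 / (2 * sigma^2))
  env <- env * (2 / sum(env))
  env * exp(2i * pi * f * t)
}

# Convolve each row of x with the Morlet kernel at frequency f.
morlet_convolve <- function(x, f, sf, width = 7) {
  conv_same_complex(x, morlet_kernel(f, sf, width))
}
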