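#' Instantaneous phase and amplitude tensors
#'
#' Extracts the instantaneous phase (radians, in `(-pi, pi]`) or the amplitude
#' envelope of every frequency band, for every epoch. With
#' `method = "hilbert"` each band is isolated with a two-way zero-phase
#' least-squares FIR filter ([design_fir_ls()]) and the angle/modulus of the
#' analytic signal is taken; with `method = "wavelet"` the angle/modulus of
#' the complex Morlet convolution at the band centre is used.
#'
#' @param x an [epoched_signal()] (or epochs-by-time matrix plus `sf`).
#' @param bands band matrix as returned by [make_bands()], or a single
#'   `(f_start, f_end)` pair.
#' @param method `"hilbert"` (filter + analytic signal, the default) or
#'   `"wavelet"` (complex Morlet at the band centre).
#' @param cycles FIR filter length in cycles of the band start; defaults: 3
#'   for phase, 6 for amplitude.
#' @param width Morlet width in cycles (default 7).
#' @param sf sampling frequency, only needed when `x` is a bare matrix.
#' @return numeric array `(n_bands, n_epochs, n_times)` with attributes
#'   `bands` and `sf`. Phases lie in `(-pi, pi]`, amplitudes are `>= 0`.
#' @examples
#' x <- sim_pac_tort(3, 1024, 256, 6, 70, coupling = 1, noise = 0, seed = 2)
#' ph <- extract_phase(x, c(5, 7))
#' range(ph)
#' @export
extract_phase <- function(x, bands, method = c("hilbert", "wavelet"),
                          cycles = 3, width = 7, sf = NULL) {
  extract_tensor(x, bands, match.arg(method), cycles, width, sf,
                 part = "phase")
}

#' @rdname extract_phase
#' @export
extract_amplitude <- function(x, bands, method = c("hilbert", "wavelet"),
                              cycles = 6, width = 7, sf = NULL) {
  extract_tensor(x, bands, match.arg(method), cycles, width, sf,
                 part = "amplitude")
}

extract_tensor <- function(x, bands, method, cycles, width, sf, part) {
  if (!inherits(x, "epoched_signal")) x <- epoched_signal(x, sf %||% attr(x, "sf"))
  sf <- attr(x, "sf")
  bands <- as_band_matrix(bands, sf)
  out <- array(0, c(nrow(bands), nrow(x), ncol(x)))
  for (b in seq_len(nrow(bands))) {
    a <- band_analytic(unclass(x), bands[b, ], sf, method, cycles, width)
    if (part == "phase") {
      if (max(Mod(a)) < 1e-12)
        warning(sprintf(
          "band [%g, %g] Hz: analytic amplitude is ~0, phase is ill-defined",
          bands[b, 1L], bands[b, 2L]))
      out[b, , ] <- wrap_phase(Arg(a))
    } else {
      out[b, , ] <- Mod(a)
    }
  }
  structure(out, bands = bands, sf = sf)
}

# Complex analytic representation of one band (epochs x time matrix in/out).
band_analytic <- function(xm, band, sf, method, cycles, width) {
  if (method == "hilbert") {
    filt <- design_fir_ls(band, sf, cycles)
    analytic_signal(filt_twoway(xm, filt))
  } else {
    morlet_convolve(xm, mean(band), sf, width)
  }
}

#' Morlet time-frequency transform
#'
#' Convolves every epoch with complex Morlet wavelets at the requested
#' frequencies (amplitude-calibrated: a sinusoid at a centre frequency is
#' recovered with unit gain).
#'
#' @inheritParams extract_phase
#' @param freqs frequencies in Hz, all below Nyquist.
#' @return complex array `(n_freqs, n_epochs, n_times)` with attributes
#'   `freqs` and `sf`.
#' @export
morlet_transform <- function(x, freqs, width = 7, sf = NULL) {
  if (!inherits(x, "epoched_signal")) x <- epoched_signal(x, sf %||% attr(x, "sf"))
  sf <- attr(x, "sf")
  if (!is.numeric(freqs) || !length(freqs) || any(!is.finite(freqs)) ||
      any(freqs <= 0))
    stop("`freqs` must be positive finite frequencies in Hz")
  if (any(freqs >= sf / 2))
    stop(sprintf("frequency %g Hz is not below Nyquist (%g Hz)",
                 max(freqs), sf / 2))
  out <- array(0i, c(length(freqs), nrow(x), ncol(x)))
  for (i in seq_along(freqs))
    out[i, , ] <- morlet_convolve(unclass(x), freqs[i], sf, width)
  structure(out, freqs = freqs, sf = sf)
}
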