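#' Simulate signals with a planted phase-amplitude coupling
#'
#' Two generators of multi-epoch signals carrying a controllable coupling
#' between the phase of a slow oscillation at `f_pha` and the amplitude of a
#' fast oscillation at `f_amp`, used throughout to validate the estimators.
#'
#' `sim_pac_tort()` builds each epoch from pure sines: the fast carrier
#' `sin(2 pi f_amp t)` is multiplied by the envelope
#' `coupling * (cos(phi - pp) + 1)/2 + (1 - coupling)` where
#' `phi = 2 pi f_pha t - pi/2` is the instantaneous phase of the slow
#' component `sin(2 pi f_pha t)` (so with `pp = 0` the envelope equals
#' `coupling * (sin(2 pi f_pha t)+1)/2 + (1-coupling)`), the slow component is
#' added, and Gaussian noise of standard deviation `noise` is superimposed.
#' At `coupling = 0` the fast envelope is constant: no modulation.
#'
#' `sim_pac_wavelet()` draws the slow phase from band-limited noise: white
#' noise is convolved with a complex Morlet wavelet centred on `f_pha` and the
#' angle of the result is the (non-sinusoidal) driver phase. The fast carrier
#' is then modulated by `1 + coupling * cos(phase - pp)` and the real part of
#' the slow analytic signal is added.
#'
#' @param n_epochs number of epochs (rows).
#' @param n_times number of time points per epoch; must cover at least two
#'   slow cycles (`n_times >= 2 * sf / f_pha`).
#' @param sf sampling frequency in Hz.
#' @param f_pha slow (phase) frequency in Hz.
#' @param f_amp fast (amplitude) frequency in Hz; requires
#'   `f_pha < f_amp < sf/2`.
#' @param coupling coupling strength in `[0, 1]`; 0 means no modulation.
#' @param noise standard deviation of additive Gaussian noise.
#' @param pp phase angle (radians) of the slow driver at which the fast
#'   amplitude is maximal; default 0.
#' @param seed integer seed making the draw reproducible; `NULL` for a
#'   nondeterministic draw.
#' @return An [epoched_signal()] with the generator parameters stored in the
#'   `spec` attribute.
#' @examples
#' x <- sim_pac_tort(5, 2048, sf = 512, f_pha = 10, f_amp = 100,
#'                   coupling = 0.8, seed = 1)
#' x
#' @export
sim_pac_tort <- function(n_epochs, n_times, sf, f_pha, f_amp,
                         coupling = 0.5, noise = 1, pp = 0, seed = NULL) {
  check_sim_args(n_epochs, n_times, sf, f_pha, f_amp, coupling, noise)
  t <- (seq_len(n_times) - 1L) / sf
  phi <- 2 * pi * f_pha * t - pi / 2          # Hilbert phase of sin(2 pi f t)
  env <- coupling * (cos(phi - pp) + 1) / 2 + (1 - coupling)
  base <- env * sin(2 * pi * f_amp * t) + sin(2 * pi * f_pha * t)
  dat <- with_seed(seed, {
    eps <- if (noise > 0)
      matrix(stats::rnorm(n_epochs * n_times, sd = noise), n_epochs)
    else matrix(0, n_epochs, n_times)
    sweep(eps, 2L, base, `+`)
  })
  out <- epoched_signal(dat, sf)
  attr(out, "spec") <- list(generator = "tort", f_pha = f_pha, f_amp = f_amp,
                            sf = sf, n_epochs = n_epochs, n_times = n_times,
                            coupling = coupling, noise = noise, pp = pp,
                            seed = seed)
  out
}

#' @rdname sim_pac_tort
#' @export
sim_pac_wavelet <- function(n_epochs, n_times, sf, f_pha, f_amp,
                            coupling = 0.5, noise = 1, pp = 0, seed = NULL) {
  check_sim_args(n_epochs, n_times, sf, f_pha, f_amp, coupling, noise)
  dat <- with_seed(seed, {
    wn <- matrix(stats::rnorm(n_epochs * n_times), n_epochs)
    slow <- morlet_convolve(wn, f_pha, sf, width = 7)
    # rescale the analytic driver to unit typical magnitude per epoch
    scale <- sqrt(rowMeans(Mod(slow)^2))
    slow <- slow / scale
    phase <- Arg(slow)
    t <- (seq_len(n_times) - 1L) / sf
    carrier <- matrix(sin(2 * pi * f_amp * t), n_epochs, n_times, byrow = TRUE)
    env <- 1 + coupling * cos(phase - pp)
    x <- env * carrier + Re(slow)
    if (noise > 0)
      x <- x + matrix(stats::rnorm(n_epochs * n_times, sd = noise), n_epochs)
    x
  })
  out <- epoched_signal(dat, sf)
  attr(out, "spec") <- list(generator = "wavelet", f_pha = f_pha,
                            f_amp = f_amp, sf = sf, n_epochs = n_epochs,
                            n_times = n_times, coupling = coupling,
                            noise = noise, pp = pp, seed = seed)
  out
}

check_sim_args <- function(n_epochs, n_times, sf, f_pha, f_amp, coupling,
                           noise) {
  stopifnot_scalar_number(n_epochs, "n_epochs", lower = 1)
  stopifnot_scalar_number(n_times, "n_times", lower = 2)
  stopifnot_scalar_number(sf, "sf", lower = .Machine$double.eps)
  stopifnot_scalar_number(f_pha, "f_pha", lower = .Machine$double.eps)
  stopifnot_scalar_number(f_amp, "f_amp")
  stopifnot_scalar_number(coupling, "coupling", lower = 0, upper = 1)
  stopifnot_scalar_number(noise, "noise", lower = 0)
  if (f_pha >= f_amp)
    stop(sprintf("f_pha (%g Hz) must be below f_amp (%g Hz)", f_pha, f_amp))
  if (f_amp >= sf / 2)
    stop(sprintf("f_amp (%g Hz) must be below the Nyquist frequency sf/2 = %g Hz",
                 f_amp, sf / 2))
  if (n_times < 2 * sf / f_pha)
    stop(sprintf("n_times (%d) must cover at least 2 slow cycles (>= %g samples)",
                 n_times, 2 * sf / f_pha))
  invisible(TRUE)
}
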