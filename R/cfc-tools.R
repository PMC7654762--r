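# Companions to the coupling estimators: preferred phase, binned amplitude,
# Welch spectra, inter-trial coherence, triangular frequency-bound search and
# peak-locked time-frequency realignment.

#' Preferred phase of the coupling
#'
#' Bins the amplitude envelope of every amplitude band by the slow phase
#' (epochs concatenated) and reports, per band, the centre of the bin where
#' the mean amplitude is maximal, in degrees on `[0, 360)` measured
#' counterclockwise from phase 0. Exact multi-modal ties return the
#' lowest-angle bin and raise the `tie` flag.
#'
#' @inheritParams compute_pac
#' @param pha_band single `(f_start, f_end)` phase band.
#' @param amp_bands amplitude band matrix.
#' @param n_bins number of 360/n degree phase slices (default 18).
#' @param tie_tol relative tolerance for declaring bins tied at the maximum
#'   (default `1e-12`, i.e. exact ties only).
#' @return An object of class `preferred_phase`: list with `binned_amp`
#'   (`n_bins x n_amp` mean amplitude per slice), `pp` (degrees per band),
#'   `tie` (logical per band), `centers_deg`, `n_bins`, `amp_bands`,
#'   `pha_band`.
#' @export
preferred_phase <- function(x, pha_band, amp_bands, n_bins = 18,
                            spectral = c("hilbert", "wavelet"),
                            cycles = c(3, 6), width = 7,
                            edge_discard = 0, tie_tol = 1e-12, sf = NULL) {
  spectral <- match.arg(spectral)
  if (!inherits(x, "epoched_signal")) x <- epoched_signal(x, sf %||% attr(x, "sf"))
  sf <- attr(x, "sf")
  pha_band <- as_band_matrix(pha_band, sf, "pha_band")[1L, , drop = FALSE]
  amp_bands <- as_band_matrix(amp_bands, sf, "amp_bands")
  if (length(cycles) == 1L) cycles <- rep(cycles, 2L)
  phase <- extract_phase(x, pha_band, spectral, cycles = cycles[1L],
                         width = width)
  ampT <- extract_amplitude(x, amp_bands, spectral, cycles = cycles[2L],
                            width = width)
  if (edge_discard > 0) {
    keep <- (edge_discard + 1L):(ncol(x) - edge_discard)
    phase <- phase[, , keep, drop = FALSE]
    ampT <- ampT[, , keep, drop = FALSE]
  }
  ph <- as.vector(phase[1L, , ])
  na <- nrow(amp_bands)
  binned <- matrix(0, n_bins, na,
                   dimnames = list(NULL, band_labels(amp_bands)))
  pp <- numeric(na)
  tie <- logical(na)
  for (a in seq_len(na)) {
    d <- suppressWarnings(
      bin_amplitude_by_phase(ph, as.vector(ampT[a, , ]), n_bins))
    binned[, a] <- d$mean_amp
    mx <- max(d$mean_amp)
    hits <- which(d$mean_amp >= mx * (1 - tie_tol))
    tie[a] <- length(hits) > 1L
    pp[a] <- (d$centers[hits[1L]] * 180 / pi) %% 360
  }
  centers <- (((seq_len(n_bins) - 0.5) * 360 / n_bins) - 180) %% 360
  structure(list(binned_amp = binned, pp = pp, tie = tie,
                 centers_deg = centers, n_bins = n_bins,
                 amp_bands = amp_bands, pha_band = pha_band),
            class = "preferred_phase")
}

#' @export
print.preferred_phase <- function(x, ...) {
  cat(sprintf("<preferred_phase> %d phase bins x %d amplitude band(s)\n",
              x$n_bins, ncol(x$binned_amp)))
  for (a in seq_along(x$pp))
    cat(sprintf("  %s Hz: preferred phase %g deg%s\n",
                colnames(x$binned_amp)[a], x$pp[a],
                if (x$tie[a]) " (tie)" else ""))
  invisible(x)
}

#' Polar display of the binned amplitude distribution
#' @param x a `preferred_phase` object.
#' @param band index of the amplitude band to draw (default 1).
#' @param ... unused.
#' @export
plot.preferred_phase <- function(x, band = 1, ...) {
  v <- x$binned_amp[, band]
  th <- x$centers_deg * pi / 180
  r <- v / max(v)
  graphics::plot(NA, xlim = c(-1, 1), ylim = c(-1, 1), asp = 1,
                 axes = FALSE, xlab = "", ylab = "",
                 main = sprintf("binned amplitude, %s Hz (PP = %g deg)",
                                colnames(x$binned_amp)[band], x$pp[band]))
  graphics::segments(0, 0, r * cos(th), r * sin(th), lwd = 4, col = "steelblue")
  graphics::symbols(0, 0, circles = 1, add = TRUE, inches = FALSE)
  invisible(x)
}

#' Phase-binned amplitude with a uniformity check
#'
#' Bins the amplitude envelope of `amp_band` by the phase of `pha_band`
#' (epochs concatenated) and tests whether the binned distribution is
#' uniform with a Friedman rank test: every epoch contributes its own
#' per-bin mean amplitude, computed on samples decimated to roughly one per
#' envelope correlation length (`stride`, default `ceiling(sf / bandwidth)`),
#' so that genuine coupling - a bin preference consistent across epochs -
#' is detected while the envelope autocorrelation does not inflate the
#' test's size. A single epoch is split into 8 time segments serving as
#' blocks. A constant amplitude is exactly uniform (statistic 0, p = 1).
#'
#' @inheritParams preferred_phase
#' @param amp_band single `(f_start, f_end)` amplitude band.
#' @param stride decimation step (samples) between amplitude samples used in
#'   the uniformity test; `NULL` picks one envelope correlation length.
#' @return list with `binned_amp` (mean amplitude per bin, all samples),
#'   `centers` (radians), `statistic` (chi-squared-distributed), `p_value`,
#'   `df`, `n_blocks`, `n_bins`, `uniform` (p >= 0.01).
#' @export
bin_amplitude <- function(x, pha_band, amp_band, n_bins = 18,
                          spectral = c("hilbert", "wavelet"),
                          cycles = c(3, 6), width = 7, edge_discard = 0,
                          stride = NULL, sf = NULL) {
  spectral <- match.arg(spectral)
  if (!inherits(x, "epoched_signal")) x <- epoched_signal(x, sf %||% attr(x, "sf"))
  sf <- attr(x, "sf")
  pha_band <- as_band_matrix(pha_band, sf, "pha_band")[1L, , drop = FALSE]
  amp_band <- as_band_matrix(amp_band, sf, "amp_band")[1L, , drop = FALSE]
  if (length(cycles) == 1L) cycles <- rep(cycles, 2L)
  stride <- as.integer(stride %||% ceiling(sf / diff(amp_band[1L, ])))
  phase <- extract_phase(x, pha_band, spectral, cycles = cycles[1L],
                         width = width)[1L, , ]
  amp <- extract_amplitude(x, amp_band, spectral, cycles = cycles[2L],
                           width = width)[1L, , ]
  phase <- matrix(phase, nrow(x)); amp <- matrix(amp, nrow(x))
  if (edge_discard > 0) {
    keep <- (edge_discard + 1L):(ncol(x) - edge_discard)
    phase <- phase[, keep, drop = FALSE]
    amp <- amp[, keep, drop = FALSE]
  }
  d <- suppressWarnings(
    bin_amplitude_by_phase(as.vector(phase), as.vector(amp), n_bins))
  # a band holding essentially none of the signal's energy carries no
  # modulation evidence: report exact uniformity
  if (mean(amp^2) < 1e-6 * mean(x[, seq_len(ncol(phase)) +
                                     (ncol(x) - ncol(phase)) %/% 2]^2))
    return(list(binned_amp = d$mean_amp, centers = d$centers, statistic = 0,
                p_value = 1, df = n_bins - 1L, n_blocks = nrow(x),
                n_bins = n_bins, uniform = TRUE))
  # independent blocks of decimated samples
  if (nrow(x) >= 2L) {
    blocks <- lapply(seq_len(nrow(x)), function(e) {
      idx <- seq(1L + (e - 1L) %% stride, ncol(phase), by = stride)
      cbind(phase[e, idx], amp[e, idx])
    })
  } else {
    cutidx <- cut(seq_len(ncol(phase)), 8L, labels = FALSE)
    blocks <- lapply(1:8, function(s) {
      idx <- which(cutidx == s)
      idx <- idx[seq(1L, length(idx), by = stride)]
      cbind(phase[1L, idx], amp[1L, idx])
    })
  }
  bm <- t(vapply(blocks, function(b) {
    suppressWarnings(bin_amplitude_by_phase(b[, 1L], b[, 2L], n_bins))$mean_amp
  }, numeric(n_bins)))
  if (max(bm) - min(bm) < 1e-12 * max(abs(bm), 1)) {
    stat <- 0; pval <- 1
  } else {
    ft <- stats::friedman.test(bm)
    stat <- unname(ft$statistic); pval <- ft$p.value
  }
  list(binned_amp = d$mean_amp, centers = d$centers, statistic = stat,
       p_value = pval, df = n_bins - 1L, n_blocks = length(blocks),
       n_bins = n_bins, uniform = pval >= 0.01)
}

#' Epoch-averaged Welch power spectral density
#'
#' Hann-windowed Welch estimate with 50% segment overlap; segments of
#' `min(n_times, 4 * sf)` samples are demeaned, transformed and averaged over
#' segments and epochs. One-sided density in units of power per Hz.
#'
#' @inheritParams compute_pac
#' @param nperseg segment length in samples.
#' @return An object of class `psd_estimate`: list with `freqs` (Hz),
#'   `power`, `df` (frequency resolution), `n_segments`.
#' @export
psd <- function(x, nperseg = NULL, sf = NULL) {
  if (!inherits(x, "epoched_signal")) x <- epoched_signal(x, sf %||% attr(x, "sf"))
  sf <- attr(x, "sf")
  n <- ncol(x)
  nperseg <- as.integer(nperseg %||% min(n, round(4 * sf)))
  if (nperseg < 8L || nperseg > n) stop("invalid `nperseg`")
  step <- max(1L, nperseg %/% 2L)
  starts <- seq(1L, n - nperseg + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(nperseg) / (nperseg + 1))  # Hann
  scale <- 1 / (sf * sum(w^2))
  nfreq <- nperseg %/% 2L + 1L
  acc <- numeric(nfreq)
  for (e in seq_len(nrow(x))) for (s in starts) {
    seg <- x[e, s:(s + nperseg - 1L)]
    seg <- (seg - mean(seg)) * w
    sp <- Mod(stats::fft(seg)[seq_len(nfreq)])^2 * scale
    sp[2:(nfreq - 1L)] <- 2 * sp[2:(nfreq - 1L)]
    acc <- acc + sp
  }
  nseg <- length(starts) * nrow(x)
  structure(list(freqs = (seq_len(nfreq) - 1L) * sf / nperseg,
                 power = acc / nseg, df = sf / nperseg,
                 n_segments = nseg, sf = sf),
            class = "psd_estimate")
}

#' @rdname psd
#' @param p a `psd_estimate`.
#' @param fmin,fmax frequency range searched for the spectral peak, in Hz.
#' @return `psd_peak()`: the frequency (Hz) of the maximal power inside
#'   `[fmin, fmax]`.
#' @export
psd_peak <- function(p, fmin, fmax) {
  if (!inherits(p, "psd_estimate")) stop("`p` must be a psd_estimate")
  sel <- which(p$freqs >= fmin & p$freqs <= fmax)
  if (!length(sel)) stop("no frequency bin inside the requested range")
  p$freqs[sel[which.max(p$power[sel])]]
}

#' @export
print.psd_estimate <- function(x, ...) {
  cat(sprintf("<psd_estimate> %d frequencies (0-%g Hz, df = %g Hz), %d segments\n",
              length(x$freqs), max(x$freqs), x$df, x$n_segments))
  invisible(x)
}

#' @export
plot.psd_estimate <- function(x, flim = NULL, ...) {
  sel <- if (is.null(flim)) seq_along(x$freqs)
         else which(x$freqs >= flim[1L] & x$freqs <= flim[2L])
  graphics::plot(x$freqs[sel], x$power[sel], type = "l", log = "y",
                 xlab = "frequency (Hz)", ylab = "power density",
                 main = "Welch PSD", ...)
  invisible(x)
}

#' Inter-trial coherence
#'
#' Modulus of the trial-averaged unit phase vector at every time point for a
#' frequency band: 1 when all epochs share the band phase, about
#' `1/sqrt(n_epochs)` for random phases. Amplitude information is discarded,
#' so the ITC is invariant to epoch-wise amplitude scaling.
#'
#' @inheritParams compute_pac
#' @param band `(f_start, f_end)` band in Hz.
#' @return list of class `itc_result` with `values` (length `n_times`, in
#'   `[0, 1]`), `times` and `band`.
#' @export
itc <- function(x, band, spectral = c("hilbert", "wavelet"), cycles = 3,
                width = 7, sf = NULL) {
  spectral <- match.arg(spectral)
  if (!inherits(x, "epoched_signal")) x <- epoched_signal(x, sf %||% attr(x, "sf"))
  phase <- extract_phase(x, band, spectral, cycles = cycles,
                         width = width)[1L, , ]
  phase <- matrix(phase, nrow(x))
  vals <- Mod(colMeans(exp(1i * phase)))
  structure(list(values = vals, times = signal_times(x),
                 band = as_band_matrix(band)[1L, ], n_epochs = nrow(x)),
            class = "itc_result")
}

#' @export
print.itc_result <- function(x, ...) {
  cat(sprintf("<itc_result> band [%g, %g] Hz, %d trials: mean ITC %.3f\n",
              x$band[1L], x$band[2L], x$n_epochs, mean(x$values)))
  invisible(x)
}

#' Triangular search for optimal frequency bounds
#'
#' Evaluates PAC for every `(f_min, f_max)` interval on a step grid with
#' `f_min < f_max`, keeping the other side's band fixed: either the amplitude
#' interval is searched for a fixed phase band (`side = "amplitude"`) or the
#' phase interval for a fixed amplitude band. The argmax pair indicates the
#' band bounds that best capture the coupling.
#'
#' @inheritParams compute_pac
#' @param fixed_band the non-searched band, `(f_start, f_end)` in Hz.
#' @param side `"amplitude"` (default) or `"phase"`: which side is searched.
#' @param f_range `(low, high)` limits of the searched bounds, in Hz.
#' @param step grid step in Hz; defaults to 2 for the amplitude side and 0.5
#'   for the phase side.
#' @param ... forwarded to [compute_pac()] (method, spectral, cycles, ...).
#' @return An object of class `triangular_grid`: list with `pairs`
#'   (`(f_min, f_max)` matrix), `values`, `best` (argmax pair), `side`,
#'   `fixed_band`, `step`.
#' @export
triangular_search <- function(x, fixed_band, side = c("amplitude", "phase"),
                              f_range, step = NULL, sf = NULL, ...) {
  side <- match.arg(side)
  if (!inherits(x, "epoched_signal")) x <- epoched_signal(x, sf %||% attr(x, "sf"))
  step <- step %||% if (side == "amplitude") 2 else 0.5
  if (length(f_range) != 2L || f_range[2L] <= f_range[1L])
    stop("`f_range` must be (low, high) with low < high")
  if (step > diff(f_range)) stop("`step` is larger than the searched range")
  fr <- seq(f_range[1L], f_range[2L], by = step)
  pairs <- do.call(rbind, lapply(seq_along(fr)[-length(fr)], function(i)
    cbind(f_min = fr[i], f_max = fr[(i + 1L):length(fr)])))
  if (side == "amplitude") {
    fit <- compute_pac(x, pha_bands = fixed_band, amp_bands = pairs, ...)
    values <- as.vector(fit$pac[, 1L])
  } else {
    fit <- compute_pac(x, pha_bands = pairs, amp_bands = fixed_band, ...)
    values <- as.vector(fit$pac[1L, ])
  }
  best <- pairs[which.max(values), ]
  structure(list(pairs = pairs, values = values, best = best, side = side,
                 fixed_band = as_band_matrix(fixed_band)[1L, ], step = step,
                 method = fit$method),
            class = "triangular_grid")
}

#' @export
print.triangular_grid <- function(x, ...) {
  cat(sprintf("<triangular_grid> %s search, %d (f_min, f_max) pairs, step %g Hz\n",
              x$side, nrow(x$pairs), x$step))
  cat(sprintf("  best interval: [%g, %g] Hz (%s = %.4g)\n",
              x$best[1L], x$best[2L], toupper(x$method), max(x$values)))
  invisible(x)
}

#' @export
plot.triangular_grid <- function(x, ...) {
  cols <- grDevices::hcl.colors(64, "viridis")
  v <- x$values
  ci <- pmin(63L, floor((v - min(v)) / max(diff(range(v)), 1e-12) * 64)) + 1L
  graphics::plot(x$pairs[, 1L], x$pairs[, 2L], col = cols[ci], pch = 15,
                 xlab = "f_min (Hz)", ylab = "f_max (Hz)",
                 main = sprintf("triangular %s search", x$side), ...)
  graphics::points(x$best[1L], x$best[2L], pch = 4, cex = 2, lwd = 2)
  invisible(x)
}

#' Peak-locked time-frequency realignment
#'
#' For every epoch the slow oscillation is isolated in `pha_band`, the local
#' maximum of the filtered signal nearest the cue sample is located, and the
#' epoch is circularly shifted so all peaks align on the cue. Averaging the
#' Morlet power maps of the realigned epochs reveals, if coupling exists, a
#' rhythmic pattern of fast-amplitude bursts at the driver period. Epochs
#' without a peak within half a driver period of the cue are dropped with a
#' warning; shifts are therefore bounded by half a driver period.
#'
#' @inheritParams compute_pac
#' @param pha_band slow `(f_start, f_end)` band in Hz.
#' @param cue sample index (1-based) the phase peaks are aligned to.
#' @param freqs frequencies (Hz) of the Morlet maps.
#' @return list of class `peak_locked_tf` with `tf` (`n_freqs x n_times`
#'   mean power), `realigned` (epochs x time), `shifts` (samples), `kept`
#'   (epoch indices), `cue`, `freqs`.
#' @export
peak_locked_tf <- function(x, pha_band, cue, freqs,
                           spectral = c("hilbert", "wavelet"),
                           cycles = 3, width = 7, sf = NULL) {
  spectral <- match.arg(spectral)
  if (!inherits(x, "epoched_signal")) x <- epoched_signal(x, sf %||% attr(x, "sf"))
  sf <- attr(x, "sf")
  pha_band <- as_band_matrix(pha_band, sf, "pha_band")[1L, , drop = FALSE]
  stopifnot_scalar_number(cue, "cue", lower = 1, upper = ncol(x))
  filt <- design_fir_ls(pha_band[1L, ], sf, cycles)
  slow <- filt_twoway(unclass(x), filt)
  half_period <- ceiling(sf / mean(pha_band) / 2)
  shifts <- integer(nrow(x))
  kept <- logical(nrow(x))
  for (e in seq_len(nrow(x))) {
    s <- slow[e, ]
    pk <- which(diff(sign(diff(s))) < 0) + 1L      # local maxima
    pk <- pk[abs(pk - cue) <= half_period]
    if (!length(pk)) next
    kept[e] <- TRUE
    shifts[e] <- pk[which.min(abs(pk - cue))] - as.integer(cue)
  }
  if (!all(kept))
    warning(sum(!kept), " epoch(s) without a phase peak near the cue were dropped")
  if (!any(kept)) stop("no epoch has a phase peak within the search window")
  realigned <- t(vapply(which(kept), function(e) {
    k <- shifts[e] %% ncol(x)
    if (k == 0L) x[e, ] else c(x[e, (k + 1L):ncol(x)], x[e, 1:k])
  }, numeric(ncol(x))))
  tfm <- morlet_transform(epoched_signal(realigned, sf), freqs, width)
  tf <- matrix(0, length(freqs), ncol(x))
  for (i in seq_along(freqs))
    tf[i, ] <- colMeans(matrix(Mod(tfm[i, , ])^2, nrow(realigned)))
  structure(list(tf = tf, realigned = realigned, shifts = shifts[kept],
                 kept = which(kept), cue = as.integer(cue), freqs = freqs,
                 half_period = half_period, sf = sf),
            class = "peak_locked_tf")
}

#' @export
print.peak_locked_tf <- function(x, ...) {
  cat(sprintf("<peak_locked_tf> %d epoch(s) realigned on sample %d (max |shift| %d)\n",
              length(x$kept), x$cue, max(abs(x$shifts))))
  invisible(x)
}
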