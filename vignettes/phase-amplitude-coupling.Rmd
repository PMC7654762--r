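---
title: "Measuring phase-amplitude coupling with pacr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring phase-amplitude coupling with pacr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pacr)
```

## The model

Phase-amplitude coupling (PAC) is a statistical dependence between the
instantaneous phase $\phi(t)$ of a slow oscillation and the amplitude
envelope $a(t)$ of a faster one, both extracted from the same recording.
`pacr` treats a recording as an epochs-by-time matrix with a sampling
frequency (`epoched_signal`) and estimates PAC over a grid of
(phase band, amplitude band) pairs — a comodulogram — with any of six
measures: mean vector length (MVL), Kullback–Leibler modulation index (MI),
heights ratio (HR), normalized direct PAC (ndPac), phase-locking value (PLV)
and Gaussian-copula mutual information (gcPAC). The measures answer the same
question under different trade-offs:

* **MVL** $= \frac{1}{N}\lvert\sum_k a(k) e^{i\phi(k)}\rvert$ is simple and
  sensitive but scales linearly with the amplitude, so power changes mimic
  coupling changes.
* **MI** and **HR** first bin the amplitude into $n = 18$ phase slices of
  20° (half-open bins starting at $-\pi$), normalise the bin means into a
  distribution $P$, and quantify its distance from uniformity:
  $\mathrm{MI} = \left(1 + \sum_j P_j \log P_j / \log n\right)$ and
  $\mathrm{HR} = (h_{\max} - h_{\min})/h_{\max}$. Both live in $[0, 1]$ and
  ignore the amplitude scale. Empty bins contribute $0$ to the entropy sum
  (the $p\log p \to 0$ limit) and emit a warning, since they signal data too
  short for the bin count.
* **ndPac** z-scores the amplitude (population standard deviation) and
  compares $\lvert\sum_k z(k)e^{i\phi(k)}\rvert^2$ to the closed-form
  threshold $x_{th} = 2N(\mathrm{erf}^{-1}(1-p))^2$, valid when the
  amplitude is normal and the phase uniform. Sub-threshold cells are set to
  zero; supra-threshold cells report the z-scored MVL (the raw sum divided
  by $N$), a scale comparable to MVL. The threshold comparison is made at
  the scale of the squared raw sum — the scale at which the bound is derived;
  at any other normalisation the threshold would grow with $N$ while the
  statistic stayed bounded and every cell would be zeroed.
* **PLV** filters the envelope itself inside the phase band, takes its
  Hilbert phase $\phi_a(t)$, and computes
  $\frac{1}{N}\lvert\sum_k e^{i(\phi(k)-\phi_a(k))}\rvert$: amplitude-blind,
  sensitive to the *timing* of envelope fluctuations.
* **gcPAC** represents the phase on the unit circle,
  $[\sin\phi, \cos\phi]$, maps every variable through its empirical CDF and
  the standard normal quantile (`copnorm`, average ranks for ties), and
  estimates mutual information with a parametric Gaussian estimator whose
  log-determinants carry a digamma small-sample bias correction. The result
  is a lower bound on the true MI in bits, invariant to any strictly
  monotone transform of the amplitude. Bias correction can produce small
  negative estimates; these are clamped to zero with the raw value kept in
  an attribute. An exactly deterministic amplitude–phase relation makes the
  joint covariance singular and the true MI infinite; the estimator warns
  and returns `Inf` rather than hiding the degeneracy.

## Extracting phase and amplitude

With `method = "hilbert"` each band is isolated by a linear-phase FIR
band-pass designed by least squares on a dense frequency grid: pass band
$[f_1, f_2]$, stop bands from DC and up to Nyquist, and don't-care
transition regions spanning 25% of each band edge. The filter order is
frequency dependent, `round(cycles * sf / f1)` forced even — 3 cycles for
phase bands, 6 for amplitude bands by default — so slow bands get
proportionally longer filters. Because the least-squares fit ripples when
the band width approaches the filter's frequency resolution `sf/order`, the
kernel is normalised to unit gain at the band centre, and its DC response is
nulled exactly. Bands narrower than a sixteenth of the resolution are
rejected as undesignable. The filter is applied forward and backward
(implemented as one convolution with the kernel's autocorrelation), which
cancels the phase response exactly and squares the magnitude response; edges
are zero-padded, with no implicit trimming — an explicit `edge_discard`
argument lets every estimator drop filter transients instead, and the
calibration tests below use it.

With `method = "wavelet"` the analytic representation is the convolution
with a complex Morlet wavelet at the band centre, width 7 cycles
($\sigma_t = \mathrm{width}/2\pi f$). The wavelet's Gaussian envelope is
scaled so a sinusoid at the centre frequency is recovered with unit gain;
this amplitude calibration (rather than unit-energy normalisation) is what
makes envelope values directly comparable with the Hilbert path and lets a
pure tone of amplitude $A$ return an envelope of $A$, which the test suite
asserts to 5%.

Epoch handling is explicit: the default `mode = "concat"` concatenates
epochs along time before the single-series measures, while
`mode = "average"` estimates per epoch and averages the grids; both usages
exist in practice and they differ for short epochs.

## Synthetic signals: what they emulate and what they do not

Two generators provide ground truth for every test.

`sim_pac_tort()` builds each epoch from pure sines: the fast carrier is
multiplied by the envelope
$c\,(\cos(\phi - pp) + 1)/2 + (1 - c)$, where $\phi$ is the phase of the
slow sine, $c$ the coupling in $[0, 1]$ and `pp` the phase angle of maximal
amplitude; the slow sine is added and Gaussian noise superimposed. At
$c = 0$ the envelope is exactly flat. Defaults used across the tests mirror
the canonical demonstration conditions: 20 epochs of 3000 samples at 512 Hz,
coupling 0.9, unit noise, 10 Hz driver, 100 Hz carrier.

`sim_pac_wavelet()` draws the slow phase from Morlet-filtered white noise,
so the driver is non-sinusoidal, drifts, and — crucially — differs across
epochs; the envelope is $1 + c\cos(\phi - pp)$.

The distinction matters for inference. The tort driver is strictly periodic
and identical in every epoch, so a block swap or time lag (both circular
shifts) merely rotates the preferred phase without destroying the coupling,
and a trial swap pairs identical drivers: surrogate nulls barely move. This
is a property of the signal, not a defect of the surrogates, and the
surrogate-based protocols (corrected comodulograms, ERPAC) therefore use the
wavelet-style generator, whose epoch-specific stochastic phase is destroyed
by any of the three transforms. Event-related PAC *requires* across-trial
phase variability and is likewise exercised with the wavelet generator.
Neither generator emulates 1/f spectra, non-stationarity, sharp non-sinusoidal
waveforms or multi-coupling mixtures — so passing tests demonstrate correct
estimator behaviour on clean planted couplings, not robustness to the
artifact zoo of real recordings.

## Surrogates and inference

The null is built by transforming the amplitude stream only (the phase is
never touched): `block_swap` cuts the time axis at a uniform random point in
$[1, n-1]$ and swaps the two blocks (the most conservative choice, and the
default), `time_lag` applies a circular shift, `trial_swap` permutes epochs
with identity permutations resampled away. All three preserve the amplitude
sample multiset exactly. P-values use the exact permutation bound
$(k+1)/(n_{perm}+1)$, so they are never zero; the corrected estimate is
either the z-score or the null-mean subtraction; and family-wise control
over the grid uses the distribution of per-permutation grid maxima. Under
the global null the suite verifies that single-cell p-values are uniform
(Kolmogorov–Smirnov) and that the maximum-statistics family-wise error rate
over a 10×10 grid sits in $[0.03, 0.07]$ at $\alpha = 0.05$ across 500
simulated exchangeable grids (grids drawn directly from the null rather than
through the filtering pipeline, which is what makes 500 replicates
tractable; the pipeline's own calibration is covered by the single-cell KS
check, 500 full pipeline runs at 100 permutations each).

Determinism is structural: the full randomisation plan (cut points, lags,
permutations) is drawn up front under the master seed, after which each
permutation is a pure function of the plan. Parallel execution
(`n_jobs > 1`) therefore returns bit-identical results to serial execution
regardless of scheduling.

## Event-related PAC

Across trials, at every time sample, the circular-linear correlation
$\rho_{cl}$ couples $[\sin\phi, \cos\phi]$ to the amplitude via the three
Pearson correlations $r_{sx}, r_{cx}, r_{sc}$. Degenerate phase sampling
($1 - r_{sc}^2 < 10^{-12}$) raises an error rather than returning a clipped
value, since it indicates pathological trial phases. The Gaussian-copula
variant applies the gcPAC machinery across the trial axis per time point
(near-singular joint covariances, possible under almost-deterministic
dependence, are floored to keep the estimate finite). Both have vectorised
paths equal to per-time-point loops to 1e-10. ERPAC p-values, when
requested, come from trial-swap permutations — the natural null for an
across-trial statistic.

## Diagnostics

**Preferred phase** is the centre of the phase bin with maximal mean
amplitude, reported in degrees on $[0°, 360°)$ counterclockwise from phase
zero. Ties (within a configurable relative tolerance, exact by default) are
broken toward the lowest angle and flagged.

**Binned-amplitude uniformity.** Naive $\chi^2$ tests on envelope samples
are badly anticonservative because envelopes are strongly autocorrelated.
The check instead decimates each epoch to roughly one sample per envelope
correlation length (`sf / bandwidth`), computes per-epoch binned means, and
applies a Friedman rank test with epochs as independent blocks (a single
epoch is split into eight segments). Size and power are verified on
simulated data. A band carrying less than $10^{-6}$ of the signal's energy
is reported as exactly uniform — there is no modulation evidence to assess.

**PSD** is the Hann-windowed Welch estimate with 50% overlap and segments of
`min(n_times, 4 * sf)` samples, averaged over segments and epochs; its
integral matches the signal variance to a few percent (Parseval check) and a
peak helper returns the argmax in a frequency range. **ITC** is the modulus
of the trial-averaged unit phase vector. **Triangular search** evaluates PAC
for every $(f_{min}, f_{max})$ interval on a step grid (default 2 Hz on the
amplitude side, 0.5 Hz on the phase side) with the other side fixed, and
returns the argmax interval. **Peak-locked realignment** finds, per epoch,
the local maximum of the band-filtered slow wave nearest a cue sample,
circularly shifts epochs so the peaks align (shifts are bounded by half a
driver period by construction; epochs without a peak in that window are
dropped with a warning), and averages Morlet power maps — rhythmic fast
bursts at the driver period are the signature of genuine coupling.

**Stationarity.** The augmented Dickey–Fuller regression (constant term,
`trunc((n-1)^(1/3))` lagged differences by default) is fit per epoch with
ordinary least squares; the unit-root null corresponds to a non-stationary
epoch. Critical values use the MacKinnon (2010) finite-sample response
surface and p-values are interpolated from the asymptotic quantiles of the
constant-case distribution, clamped to $[0.01, 0.99]$.

## Numerical choices and conventions

* Phases live in $(-\pi, \pi]$; bins are half-open `[edge, edge + 2pi/n)`
  from $-\pi$, so $+\pi$ wraps into the last bin.
* `copnorm` uses average ranks for ties and `qnorm(r/(n+1))`, keeping output
  finite for any input.
* The tensor and loop engines share the binning and copula code, so their
  1e-10 agreement checks the algebraic reorganisation, not a common bug.
* Grid cells are named by band, `[f1,f2]`, and results carry the full
  configuration (bands, mode, surrogate, seed) for reproducibility; a
  `pac_config` serialises to JSON and back identically, so a config file
  fully determines the computation.
* Problem sizes in the test suite (e.g. 10 epochs × 2000 samples for the
  engine-equivalence grids, 500 replicates at 100 permutations for
  calibration, 300 trials for event-related protocols) were chosen as the
  smallest sizes at which the checked properties are stable, keeping the
  default suite runtime around a minute.

## Known limitations

Estimates near epoch edges are contaminated by filter transients unless
`edge_discard` is used; the package deliberately never trims silently.
Block-swap and time-lag nulls are weak against strictly periodic,
trial-identical couplings (see the generator discussion above) — for such
designs use `trial_swap`. The gcPAC is a lower bound, not an unbiased MI
estimate, and the binned uniformity check trades power for calibrated size
on short recordings. Reading vendor EEG formats is out of scope: bring an
epochs-by-time matrix (CSV/NPY-exported) and a sampling rate.
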