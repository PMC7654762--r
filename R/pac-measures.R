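# Scalar PAC measures on a single (phase, amplitude) pair. These are the
# reference implementations; compute_pac() vectorises the same arithmetic
# over whole band grids.

#' Phase-binned amplitude distribution
#'
#' Bins the phase into `n_bins` equal slices of `(-pi, pi]` (edges starting at
#' `-pi`, half-open on the right), averages the amplitude inside each slice
#' and normalises the bin means to sum to one. This distribution underlies
#' the modulation index, the heights ratio and the preferred phase.
#'
#' @param phase numeric vector of phases in radians.
#' @param amp numeric vector of amplitudes, same length.
#' @param n_bins number of phase slices (default 18, i.e. 20 degrees each).
#' @return An object of class `amplitude_distribution`: list with `p`
#'   (probability vector), `mean_amp` (raw bin means), `edges`, `centers`
#'   (radians), `n_bins`, `counts`, and `degenerate` (TRUE when a single bin
#'   holds all samples). Empty bins get probability 0 with a warning.
#' @examples
#' d <- bin_amplitude_by_phase(c(-2, 0, 2, -2, 0, 2), c(1, 2, 3, 1, 2, 3),
#'                             n_bins = 3)
#' d$p   # (1, 2, 3) / 6
#' @export
bin_amplitude_by_phase <- function(phase, amp, n_bins = 18) {
  if (length(phase) != length(amp)) stop("`phase` and `amp` lengths differ")
  if (!length(phase)) stop("empty input")
  stopifnot_scalar_number(n_bins, "n_bins", lower = 2)
  n_bins <- as.integer(n_bins)
  idx <- phase_bin_index(phase, n_bins)
  counts <- tabulate(idx, nbins = n_bins)
  sums <- numeric(n_bins)
  sums[sort(unique(idx))] <- rowsum(amp, idx)[, 1L]
  mean_amp <- ifelse(counts > 0, sums / pmax(counts, 1L), 0)
  if (any(counts == 0L))
    warning("empty phase bins (data too short for ", n_bins, " bins); ",
            "their probability is set to 0")
  tot <- sum(mean_amp)
  p <- if (tot > 0) mean_amp / tot else rep(1 / n_bins, n_bins)
  edges <- seq(-pi, pi, length.out = n_bins + 1L)
  structure(list(p = p, mean_amp = mean_amp, edges = edges,
                 centers = edges[-(n_bins + 1L)] + pi / n_bins,
                 n_bins = n_bins, counts = counts,
                 degenerate = sum(counts > 0L) == 1L),
            class = "amplitude_distribution")
}

# Half-open bins [edge, edge + 2pi/n) starting at -pi; pi falls in the last bin.
phase_bin_index <- function(phase, n_bins) {
  idx <- floor((wrap_phase(phase) + pi) / (2 * pi / n_bins)) + 1L
  pmin(as.integer(idx), n_bins)
}

#' @export
print.amplitude_distribution <- function(x, ...) {
  cat(sprintf("<amplitude_distribution> %d phase bins%s\n", x$n_bins,
              if (x$degenerate) " (degenerate: single occupied bin)" else ""))
  print(round(x$p, 4))
  invisible(x)
}

#' Kullback-Leibler modulation index
#'
#' `MI = D_KL(P, uniform) / log(n) = 1 + sum(P log P) / log(n)`, in `[0, 1]`:
#' 0 for a uniform phase-binned amplitude distribution, 1 for a delta.
#' Empty bins (`P = 0`) contribute 0 by the `p log p -> 0` limit convention.
#'
#' @param dist an [bin_amplitude_by_phase()] result, or a bare probability
#'   vector.
#' @return scalar in `[0, 1]`.
#' @export
mi_kl <- function(dist) {
  p <- dist_probs(dist)
  n <- length(p)
  plogp <- ifelse(p > 0, p * log(p), 0)
  max(0, 1 + sum(plogp) / log(n))
}

#' Heights ratio
#'
#' `(h_max - h_min) / h_max` of the phase-binned amplitude distribution:
#' 0 when uniform, 1 when some bin is empty.
#'
#' @inheritParams mi_kl
#' @return scalar in `[0, 1]`.
#' @export
heights_ratio <- function(dist) {
  p <- dist_probs(dist)
  (max(p) - min(p)) / max(p)
}

dist_probs <- function(dist) {
  p <- if (inherits(dist, "amplitude_distribution")) dist$p else as.numeric(dist)
  if (length(p) < 2L || any(!is.finite(p)) || any(p < 0) ||
      abs(sum(p) - 1) > 1e-8)
    stop("`dist` must be a probability vector (>= 2 non-negative entries summing to 1)")
  p
}

#' Mean vector length
#'
#' Modulus of the amplitude-weighted mean phase vector,
#' `(1/N) |sum a(k) exp(i phi(k))|`. Scales linearly with the amplitude.
#'
#' @param phase phases in radians.
#' @param amp amplitudes, same length.
#' @return scalar `>= 0`.
#' @examples
#' pac_mvl(c(0, pi), c(1, 2))   # |1 - 2| / 2 = 0.5
#' @export
pac_mvl <- function(phase, amp) {
  if (!length(phase)) stop("empty input")
  if (length(phase) != length(amp)) stop("`phase` and `amp` lengths differ")
  Mod(sum(amp * exp(1i * phase))) / length(phase)
}

#' Normalized direct PAC with closed-form threshold
#'
#' The amplitude is z-scored over time and the squared modulus of the raw
#' coupling sum, `|sum z(k) exp(i phi(k))|^2`, is compared to the closed-form
#' threshold `x_th = 2 N (erfinv(1 - p))^2` valid under the null of a normal
#' amplitude and a uniform phase. Sub-threshold couplings are set to 0;
#' supra-threshold values are returned normalized by `N` (the MVL of the
#' z-scored amplitude, a scale comparable to the other measures).
#'
#' @inheritParams pac_mvl
#' @param p confidence level of the threshold (default 0.05).
#' @return scalar `>= 0` (0 when not significant at level `p`).
#' @export
pac_ndpac <- function(phase, amp, p = 0.05) {
  if (length(phase) != length(amp)) stop("`phase` and `amp` lengths differ")
  n <- length(phase)
  if (n < 2L) stop("need at least 2 samples")
  stopifnot_scalar_number(p, "p", lower = 1e-12, upper = 1 - 1e-12)
  s <- stats::sd(amp) * sqrt((n - 1) / n)   # population sd
  if (s == 0) stop("zero-variance amplitude: z-score undefined")
  z <- (amp - mean(amp)) / s
  raw <- Mod(sum(z * exp(1i * phase)))       # = n * MVL(phase, z)
  if (raw^2 <= ndpac_threshold(n, p)) 0 else raw / n
}

#' @rdname pac_ndpac
#' @param n number of samples.
#' @export
ndpac_threshold <- function(n, p = 0.05) 2 * n * erfinv(1 - p)^2

#' Phase-locking value between phase and amplitude-phase
#'
#' `(1/N) |sum exp(i (phi - phi_a))|` where `phi_a` is the phase of the
#' amplitude envelope (the envelope filtered in the phase band, then the
#' Hilbert angle). In `[0, 1]`; insensitive to the amplitude magnitude.
#'
#' @param phase slow-oscillation phases in radians.
#' @param amp_phase phases of the amplitude envelope, same length.
#' @return scalar in `[0, 1]`.
#' @export
pac_plv <- function(phase, amp_phase) {
  if (!length(phase)) stop("empty input")
  if (length(phase) != length(amp_phase))
    stop("`phase` and `amp_phase` lengths differ")
  Mod(sum(exp(1i * (phase - amp_phase)))) / length(phase)
}

#' Copula normalisation
#'
#' Maps each sample through its empirical CDF and then the inverse standard
#' normal CDF: `qnorm(rank / (n + 1))`. Rank-based, hence invariant to any
#' strictly monotone transform of the input; ties get average ranks.
#'
#' @param x numeric vector.
#' @return numeric vector with standard normal empirical margins.
#' @export
copnorm <- function(x) {
  if (!is.numeric(x) || !length(x)) stop("`x` must be a non-empty numeric vector")
  stats::qnorm(rank(x, ties.method = "average") / (length(x) + 1))
}

#' Gaussian-copula PAC
#'
#' Mutual information, in bits, between the copula-normalised amplitude and
#' the 2-d circular representation of the phase `[sin(phi), cos(phi)]` (each
#' dimension copula-normalised), estimated with a bias-corrected parametric
#' Gaussian estimator. Rank-based: invariant to strictly monotone transforms
#' of the amplitude. Negative bias-corrected estimates are clamped to 0; the
#' raw value is kept in the `"raw"` attribute.
#'
#' @inheritParams pac_mvl
#' @return scalar `>= 0` (bits), with attribute `raw`.
#' @export
pac_gc <- function(phase, amp) {
  if (length(phase) != length(amp)) stop("`phase` and `amp` lengths differ")
  if (length(phase) < 10L) stop("need at least 10 samples")
  if (stats::sd(amp) == 0 || stats::sd(phase) == 0)
    stop("degenerate (constant) input")
  y <- cbind(copnorm(sin(phase)), copnorm(cos(phase)))
  x <- copnorm(amp)
  raw <- mi_gauss_bits(matrix(x, ncol = 1L), y)
  structure(max(0, raw), raw = raw)
}

# Bias-corrected Gaussian mutual information in bits between the columns of
# x (d_x dims) and y (d_y dims). Entropies use the small-sample digamma
# correction for the log-determinant of an estimated covariance.
mi_gauss_bits <- function(x, y) {
  n <- nrow(x)
  hx <- gauss_entropy_biased(x)
  hy <- gauss_entropy_biased(y)
  hxy <- gauss_entropy_biased(cbind(x, y))
  (hx + hy - hxy) / log(2)
}

# 0.5*log(det(cov)) + const, minus the expected bias of the sample
# log-determinant: sum_i psi((n - i)/2)/2 + d/2 * log(2/(n-1)) terms.
gauss_entropy_biased <- function(z) {
  n <- nrow(z); d <- ncol(z)
  C <- stats::cov(z)
  ch <- tryCatch(chol(C), error = function(e) NULL)
  if (is.null(ch)) {
    # exactly deterministic dependence: differential entropy diverges
    warning("singular covariance (deterministic dependence); MI is infinite")
    return(-Inf)
  }
  h <- sum(log(diag(ch))) + 0.5 * d * log(2 * pi * exp(1))
  bias <- 0.5 * (d * log(2 / (n - 1)) + sum(digamma((n - seq_len(d)) / 2)))
  h - bias
}
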