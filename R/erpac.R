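#' Circular-linear correlation
#'
#' Correlation between a circular variable (phase) and a linear one
#' (amplitude): `rho = sqrt((r_sx^2 + r_cx^2 - 2 r_sx r_cx r_sc) /
#' (1 - r_sc^2))` with `r_sx = cor(sin phi, a)`, `r_cx = cor(cos phi, a)`,
#' `r_sc = cor(sin phi, cos phi)`. Lies in `[0, 1]`; invariant to adding a
#' constant to `a` and to rotating the phase by a constant offset.
#'
#' @param phase phases in radians (length >= 3).
#' @param amp amplitudes, same length, non-constant.
#' @return scalar in `[0, 1]`.
#' @examples
#' phi <- seq(0, 2 * pi, length.out = 50)
#' circ_corr(phi, sin(phi))   # 1
#' @export
circ_corr <- function(phase, amp) {
  if (length(phase) != length(amp)) stop("`phase` and `amp` lengths differ")
  if (length(phase) < 3L) stop("need at least 3 samples")
  if (stats::sd(amp) == 0) stop("constant amplitude: correlation undefined")
  s <- sin(phase); cph <- cos(phase)
  if (stats::sd(s) == 0 || stats::sd(cph) == 0)
    stop("degenerate phase sampling")
  rsx <- stats::cor(s, amp)
  rcx <- stats::cor(cph, amp)
  rsc <- stats::cor(s, cph)
  den <- 1 - rsc^2
  if (den < 1e-12) stop("degenerate phase sampling: |cor(sin, cos)| ~ 1")
  rho2 <- (rsx^2 + rcx^2 - 2 * rsx * rcx * rsc) / den
  sqrt(min(max(rho2, 0), 1))
}

#' Event-related (time-resolved) phase-amplitude coupling
#'
#' Estimates PAC across trials at every time sample: for each amplitude band
#' and time point, the dependence between the phases and amplitudes observed
#' over trials is measured with the circular-linear correlation
#' (`method = "circular"`, [circ_corr()]) or with Gaussian-copula mutual
#' information in bits (`method = "gc"`). Unlike time-averaged PAC this is
#' robust to non-stationarities that are consistent across trials, and it
#' resolves when in the epoch the coupling occurs.
#'
#' @inheritParams compute_pac
#' @param pha_band single `(f_start, f_end)` phase band.
#' @param amp_bands amplitude band matrix.
#' @param method `"circular"` (default) or `"gc"`.
#' @param n_perm optional number of trial-swap permutations for p-values.
#' @param engine `"tensor"` (vectorised over time) or `"loop"` (per time
#'   point reference).
#' @return An object of class `erpac_result`: list with `values`
#'   (`n_amp x n_times`), `times` (seconds), `method`, `pha_band`,
#'   `amp_bands`, and `pvalues` when `n_perm > 0`.
#' @export
compute_erpac <- function(x, pha_band, amp_bands,
                          method = c("circular", "gc"),
                          spectral = c("hilbert", "wavelet"),
                          cycles = c(3, 6), width = 7,
                          n_perm = 0, seed = NULL,
                          engine = c("tensor", "loop"), sf = NULL) {
  method <- match.arg(method)
  spectral <- match.arg(spectral)
  engine <- match.arg(engine)
  if (!inherits(x, "epoched_signal")) x <- epoched_signal(x, sf %||% attr(x, "sf"))
  sf <- attr(x, "sf")
  if (nrow(x) < 3L) stop("need at least 3 epochs for across-trial estimates")
  if (nrow(x) < 10L)
    warning("fewer than 10 epochs: across-trial estimates will be unstable")
  pha_band <- as_band_matrix(pha_band, sf, "pha_band")[1L, , drop = FALSE]
  amp_bands <- as_band_matrix(amp_bands, sf, "amp_bands")
  if (length(cycles) == 1L) cycles <- rep(cycles, 2L)

  phase <- extract_phase(x, pha_band, spectral, cycles = cycles[1L],
                         width = width)[1L, , ]      # ne x nt
  ampT <- extract_amplitude(x, amp_bands, spectral, cycles = cycles[2L],
                            width = width)           # na x ne x nt
  vals <- erpac_values(phase, ampT, method, engine)
  rownames(vals) <- band_labels(amp_bands)
  out <- list(values = vals, times = signal_times(x), method = method,
              pha_band = pha_band, amp_bands = amp_bands, sf = sf,
              n_epochs = nrow(x), call = match.call())
  class(out) <- "erpac_result"
  if (n_perm > 0) {
    plan <- surrogate_plan("trial_swap", n_perm, ncol(x), nrow(x), seed)
    exceed <- array(0L, dim(vals))
    for (i in seq_len(n_perm)) {
      vp <- erpac_values(phase, ampT[, plan[[i]], , drop = FALSE], method,
                         engine)
      exceed <- exceed + (vp >= vals)
    }
    out$pvalues <- (exceed + 1) / (n_perm + 1)
    out$n_perm <- n_perm
    out$seed <- seed
  }
  out
}

erpac_values <- function(phase, ampT, method, engine) {
  na <- dim(ampT)[1L]; ne <- dim(ampT)[2L]; nt <- dim(ampT)[3L]
  if (engine == "loop") {
    vals <- matrix(0, na, nt)
    for (a in seq_len(na)) for (t in seq_len(nt)) {
      vals[a, t] <- if (method == "circular")
        circ_corr(phase[, t], ampT[a, , t])
      else as.numeric(pac_gc(phase[, t], ampT[a, , t]))
    }
    return(vals)
  }
  if (method == "circular") erpac_circ_tensor(phase, ampT)
  else erpac_gc_tensor(phase, ampT)
}

# Vectorised Eq-10 across the trial axis: phase (ne x nt), ampT (na x ne x nt).
erpac_circ_tensor <- function(phase, ampT) {
  na <- dim(ampT)[1L]; ne <- dim(ampT)[2L]; nt <- dim(ampT)[3L]
  S <- sin(phase); C <- cos(phase)
  cS <- sweep(S, 2L, colMeans(S)); cC <- sweep(C, 2L, colMeans(C))
  sdS <- sqrt(colSums(cS^2)); sdC <- sqrt(colSums(cC^2))
  rsc <- colSums(cS * cC) / (sdS * sdC)
  den <- 1 - rsc^2
  if (any(den < 1e-12))
    stop("degenerate phase sampling: |cor(sin, cos)| ~ 1 at time index ",
         which(den < 1e-12)[1L])
  vals <- matrix(0, na, nt)
  for (a in seq_len(na)) {
    A <- matrix(ampT[a, , ], ne, nt)
    cA <- sweep(A, 2L, colMeans(A))
    sdA <- sqrt(colSums(cA^2))
    if (any(sdA == 0))
      stop("constant amplitude across trials at time index ",
           which(sdA == 0)[1L])
    rsx <- colSums(cS * cA) / (sdS * sdA)
    rcx <- colSums(cC * cA) / (sdC * sdA)
    rho2 <- (rsx^2 + rcx^2 - 2 * rsx * rcx * rsc) / den
    vals[a, ] <- sqrt(pmin(pmax(rho2, 0), 1))
  }
  vals
}

# Gaussian-copula MI across trials at each time point.
erpac_gc_tensor <- function(phase, ampT) {
  na <- dim(ampT)[1L]; ne <- dim(ampT)[2L]; nt <- dim(ampT)[3L]
  q <- stats::qnorm(seq_len(ne) / (ne + 1))
  cop <- function(M)  # column-wise copnorm of an ne x nt matrix
    matrix(q[rank_cols(M)], ne, nt)
  Sc <- cop(sin(phase)); Cc <- cop(cos(phase))
  Sc <- sweep(Sc, 2L, colMeans(Sc)); Cc <- sweep(Cc, 2L, colMeans(Cc))
  vss <- colSums(Sc^2) / (ne - 1); vcc <- colSums(Cc^2) / (ne - 1)
  vsc <- colSums(Sc * Cc) / (ne - 1)
  detS <- vss * vcc - vsc^2
  const <- 0.5 * log(2 * pi * exp(1))
  bias <- function(d) 0.5 * (d * log(2 / (ne - 1)) +
                               sum(digamma((ne - seq_len(d)) / 2)))
  hy <- 0.5 * log(detS) + 2 * const - bias(2L)
  vals <- matrix(0, na, nt)
  for (a in seq_len(na)) {
    Ac <- cop(matrix(ampT[a, , ], ne, nt))
    Ac <- sweep(Ac, 2L, colMeans(Ac))
    va <- colSums(Ac^2) / (ne - 1)
    cas <- colSums(Ac * Sc) / (ne - 1)
    cac <- colSums(Ac * Cc) / (ne - 1)
    det3 <- va * detS - (cas^2 * vcc - 2 * cas * cac * vsc + cac^2 * vss)
    det3 <- pmax(det3, .Machine$double.xmin)   # near-deterministic dependence
    hx <- 0.5 * log(va) + const - bias(1L)
    hxy <- 0.5 * log(det3) + 3 * const - bias(3L)
    vals[a, ] <- pmax(0, (hx + hy - hxy) / log(2))
  }
  vals
}

# column-wise average ranks of a matrix (linear index into q by rank)
rank_cols <- function(M) {
  apply(M, 2L, rank, ties.method = "average")
}

#' @export
print.erpac_result <- function(x, ...) {
  cat(sprintf("<erpac_result> %s ERPAC, %d amplitude band(s) x %d time points (%d trials)\n",
              x$method, nrow(x$values), ncol(x$values), x$n_epochs))
  i <- which(x$values == max(x$values), arr.ind = TRUE)[1L, ]
  cat(sprintf("  max = %.4g at amplitude %s Hz, t = %.3f s\n",
              max(x$values), rownames(x$values)[i[1L]], x$times[i[2L]]))
  invisible(x)
}

#' Time-resolved ERPAC image
#' @param x an `erpac_result`.
#' @param ... forwarded to [graphics::image()].
#' @export
plot.erpac_result <- function(x, ...) {
  graphics::image(x$times, band_centers(x$amp_bands), t(x$values),
                  xlab = "time (s)", ylab = "amplitude frequency (Hz)",
                  main = sprintf("%s ERPAC", x$method),
                  col = grDevices::hcl.colors(64, "viridis"), ...)
  invisible(x)
}
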