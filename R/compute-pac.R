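#' Phase-amplitude coupling over a comodulogram grid
#'
#' The central estimator of the package. For every (phase band, amplitude
#' band) pair the instantaneous phase and amplitude envelope are extracted
#' ([extract_phase()], [extract_amplitude()]) and one of six coupling
#' measures is evaluated: mean vector length (`"mvl"`), Kullback-Leibler
#' modulation index (`"mi"`), heights ratio (`"hr"`), normalized direct PAC
#' (`"ndpac"`), phase-locking value (`"plv"`) or Gaussian-copula mutual
#' information (`"gc"`). With `n_perm > 0` a surrogate null is built by
#' transforming the amplitude stream (`block_swap`, `time_lag` or
#' `trial_swap`), the grid is corrected (`zscore` or `mean_sub`) and
#' non-parametric p-values are attached, optionally with maximum-statistics
#' family-wise correction.
#'
#' Two evaluation engines produce identical grids (to numerical round-off):
#' the default `"tensor"` engine vectorises each measure over whole band
#' grids with matrix algebra, and the `"loop"` engine calls the scalar
#' reference implementations ([pac_mvl()], [mi_kl()], ...) per band pair.
#'
#' @param x an [epoched_signal()] (or epochs-by-time matrix; then give `sf`).
#' @param pha_bands,amp_bands band matrices from [make_bands()] (or single
#'   `(f_start, f_end)` pairs) for the slow phase and the fast amplitude.
#' @param method one of `"mvl"`, `"mi"`, `"hr"`, `"ndpac"`, `"plv"`, `"gc"`.
#' @param mode `"concat"` (default) concatenates epochs along time before the
#'   single-series measures; `"average"` evaluates per epoch and averages the
#'   grids.
#' @param spectral phase/amplitude extraction method, `"hilbert"` or
#'   `"wavelet"`.
#' @param n_bins phase bins for `"mi"`/`"hr"` (default 18).
#' @param cycles length-2 vector: filter cycles for phase and amplitude bands
#'   (default `c(3, 6)`).
#' @param width Morlet width (default 7).
#' @param p confidence level of the `"ndpac"` threshold.
#' @param edge_discard samples dropped from each epoch edge before the
#'   coupling estimation (filter edge artifacts); default 0.
#' @param n_perm number of surrogate permutations (0 = no inference).
#' @param surrogate `"block_swap"` (default), `"time_lag"` or `"trial_swap"`.
#' @param norm surrogate correction, `"zscore"` (default) or `"mean_sub"`.
#' @param correction `"maxstat"` adds family-wise corrected p-values.
#' @param seed integer driving all surrogate randomness; `NULL` for a
#'   nondeterministic null.
#' @param n_jobs number of worker processes for the surrogate loop (the
#'   randomization plan is drawn up front, so results are identical for any
#'   `n_jobs`).
#' @param engine `"tensor"` (vectorised, default) or `"loop"` (per-pair
#'   reference path).
#' @param sf sampling frequency when `x` is a bare matrix.
#' @return An object of class `pac_result`: list with `pac`
#'   (`n_amp x n_pha` matrix, amplitude bands in rows), `method`,
#'   `pha_bands`, `amp_bands`, and when `n_perm > 0` also `surrogates`
#'   (`n_perm x n_amp x n_pha`), `pac_corrected`, `pvalues`, and
#'   `pvalues_fwer` if `correction = "maxstat"`.
#' @examples
#' x <- sim_pac_tort(5, 2048, 256, 6, 70, coupling = 0.9, seed = 3)
#' fit <- compute_pac(x, c(5, 7), make_bands(40, 100, 20), method = "mi")
#' summary(fit)
#' @export
compute_pac <- function(x, pha_bands, amp_bands,
                        method = c("mvl", "mi", "hr", "ndpac", "plv", "gc"),
                        mode = c("concat", "average"),
                        spectral = c("hilbert", "wavelet"),
                        n_bins = 18, cycles = c(3, 6), width = 7, p = 0.05,
                        edge_discard = 0,
                        n_perm = 0, surrogate = "block_swap",
                        norm = c("zscore", "mean_sub"),
                        correction = c("none", "maxstat"),
                        seed = NULL, n_jobs = 1,
                        engine = c("tensor", "loop"), sf = NULL) {
  method <- match.arg(method)
  mode <- match.arg(mode)
  spectral <- match.arg(spectral)
  norm <- match.arg(norm)
  correction <- match.arg(correction)
  engine <- match.arg(engine)
  if (!inherits(x, "epoched_signal")) x <- epoched_signal(x, sf %||% attr(x, "sf"))
  sf <- attr(x, "sf")
  # validate everything before any filtering
  pha_bands <- as_band_matrix(pha_bands, sf, "pha_bands")
  amp_bands <- as_band_matrix(amp_bands, sf, "amp_bands")
  if (length(cycles) == 1L) cycles <- rep(cycles, 2L)
  stopifnot_scalar_number(edge_discard, "edge_discard", lower = 0,
                          upper = ncol(x) %/% 2 - 1)
  stopifnot_scalar_number(n_perm, "n_perm", lower = 0)

  tens <- pac_tensors(x, pha_bands, amp_bands, method, spectral, cycles,
                      width, edge_discard)
  est <- function(ampT, ampPhT)
    pac_grid_engine(tens$phaT, ampT, ampPhT, method, mode, engine, n_bins, p)
  pac <- est(tens$ampT, tens$ampPhT)
  dimnames(pac) <- list(band_labels(amp_bands), band_labels(pha_bands))

  out <- list(pac = pac, method = method, mode = mode, spectral = spectral,
              pha_bands = pha_bands, amp_bands = amp_bands, n_bins = n_bins,
              cycles = cycles, width = width, edge_discard = edge_discard,
              sf = sf, n_epochs = nrow(x), n_times = ncol(x),
              n_perm = n_perm, surrogate = surrogate, norm = norm,
              seed = seed, call = match.call())
  class(out) <- "pac_result"
  if (n_perm > 0) {
    nt <- dim(tens$phaT)[3L]
    plan <- surrogate_plan(surrogate, n_perm, nt, nrow(x), seed)
    one_perm <- function(i) {
      ampT <- apply_surrogate(tens$ampT, surrogate, plan[[i]])
      ampPhT <- if (is.null(tens$ampPhT)) NULL
        else surrogate_4d(tens$ampPhT, surrogate, plan[[i]])
      est(ampT, ampPhT)
    }
    grids <- if (n_jobs > 1L)
      parallel::mclapply(seq_len(n_perm), one_perm, mc.cores = n_jobs)
    else lapply(seq_len(n_perm), one_perm)
    null <- array(0, c(n_perm, nrow(amp_bands), nrow(pha_bands)))
    for (i in seq_len(n_perm)) null[i, , ] <- grids[[i]]
    out$surrogates <- null
    out$pac_corrected <- normalize_pac(pac, null, norm)
    out$pvalues <- pvalues_from_null(pac, null)
    if (correction == "maxstat")
      out$pvalues_fwer <- maxstat_correction(pac, null)
  }
  out
}

# Extract the tensors a method needs: phase (n_pha, ne, nt), amplitude
# (n_amp, ne, nt) and, for PLV, the phase of the amplitude envelope filtered
# in every phase band: (n_amp, n_pha, ne, nt).
pac_tensors <- function(x, pha_bands, amp_bands, method, spectral, cycles,
                        width, edge_discard) {
  phaT <- extract_phase(x, pha_bands, spectral, cycles = cycles[1L],
                        width = width)
  ampT <- extract_amplitude(x, amp_bands, spectral, cycles = cycles[2L],
                            width = width)
  sf <- attr(x, "sf")
  ampPhT <- NULL
  if (method == "plv") {
    na <- nrow(amp_bands); np <- nrow(pha_bands)
    # stack all amplitude envelopes so each phase band filters them in one
    # batched convolution
    stacked <- matrix(ampT, na * nrow(x), ncol(x))
    ampPhT <- array(0, c(na, np, nrow(x), ncol(x)))
    for (j in seq_len(np)) {
      an <- band_analytic(stacked, pha_bands[j, ], sf, spectral, cycles[1L],
                          width)
      ampPhT[, j, , ] <- array(wrap_phase(Arg(an)), c(na, nrow(x), ncol(x)))
    }
  }
  if (edge_discard > 0) {
    keep <- (edge_discard + 1L):(ncol(x) - edge_discard)
    phaT <- phaT[, , keep, drop = FALSE]
    ampT <- ampT[, , keep, drop = FALSE]
    if (!is.null(ampPhT)) ampPhT <- ampPhT[, , , keep, drop = FALSE]
  }
  list(phaT = phaT, ampT = ampT, ampPhT = ampPhT)
}

surrogate_4d <- function(a, method, draw) {
  d <- dim(a)
  m <- array(a, c(d[1L] * d[2L], d[3L], d[4L]))
  array(apply_surrogate(m, method, draw), d)
}

# Dispatch over epoch handling and engine. Tensors are (n_bands, ne, nt).
pac_grid_engine <- function(phaT, ampT, ampPhT, method, mode, engine, n_bins,
                            p) {
  ne <- dim(phaT)[2L]
  if (mode == "concat" || ne == 1L) {
    pac_grid_flat(flatten_bt(phaT), flatten_bt(ampT),
                  if (is.null(ampPhT)) NULL else flatten_bpt(ampPhT),
                  method, engine, n_bins, p)
  } else {
    dp <- dim(phaT); da <- dim(ampT)
    g <- 0
    for (e in seq_len(ne)) {
      pe <- matrix(phaT[, e, ], dp[1L], dp[3L])
      ae <- matrix(ampT[, e, ], da[1L], da[3L])
      ge <- if (is.null(ampPhT)) NULL else {
        d4 <- dim(ampPhT)
        array(ampPhT[, , e, ], c(d4[1L], d4[2L], d4[4L]))
      }
      g <- g + pac_grid_flat(pe, ae, ge, method, engine, n_bins, p)
    }
    g / ne
  }
}

flatten_bt <- function(a) {           # (b, ne, nt) -> (b, ne*nt)
  d <- dim(a)
  matrix(a, d[1L], d[2L] * d[3L])
}
flatten_bpt <- function(a) {          # (a, p, ne, nt) -> (a, p, ne*nt)
  d <- dim(a)
  array(a, c(d[1L], d[2L], d[3L] * d[4L]))
}

drop1 <- function(m) if (is.null(dim(m))) matrix(m, nrow = 1L) else m

# Grid evaluation on flattened series: phase (n_pha, T), amp (n_amp, T),
# ampPh (n_amp, n_pha, T) for PLV.
pac_grid_flat <- function(pha, amp, ampPh, method, engine, n_bins, p) {
  pha <- drop1(pha); amp <- drop1(amp)
  np <- nrow(pha); na <- nrow(amp); n <- ncol(pha)
  if (engine == "loop") {
    g <- matrix(0, na, np)
    for (j in seq_len(np)) for (a in seq_len(na)) {
      g[a, j] <- switch(method,
        mvl   = pac_mvl(pha[j, ], amp[a, ]),
        mi    = mi_kl(suppressWarnings(
                  bin_amplitude_by_phase(pha[j, ], amp[a, ], n_bins))),
        hr    = heights_ratio(suppressWarnings(
                  bin_amplitude_by_phase(pha[j, ], amp[a, ], n_bins))),
        ndpac = pac_ndpac(pha[j, ], amp[a, ], p),
        plv   = pac_plv(pha[j, ], ampPh[a, j, ]),
        gc    = as.numeric(pac_gc(pha[j, ], amp[a, ])))
    }
    return(g)
  }
  switch(method,
    mvl = {
      E <- exp(1i * pha)
      Mod(amp %*% t(E)) / n
    },
    ndpac = {
      mu <- rowMeans(amp)
      s <- sqrt(rowMeans(amp^2) - mu^2)
      if (any(s == 0)) stop("zero-variance amplitude: z-score undefined")
      Z <- (amp - mu) / s
      E <- exp(1i * pha)
      raw <- Mod(Z %*% t(E))                   # = n * MVL(z)
      ifelse(raw^2 <= ndpac_threshold(n, p), 0, raw / n)
    },
    mi = , hr = {
      g <- matrix(0, na, np)
      for (j in seq_len(np)) {
        P <- binned_probs(pha[j, ], amp, n_bins)   # (n_bins, n_amp)
        g[, j] <- if (method == "mi") {
          plogp <- ifelse(P > 0, P * log(P), 0)
          pmax(0, 1 + colSums(plogp) / log(n_bins))
        } else {
          h <- apply(P, 2L, range)
          (h[2L, ] - h[1L, ]) / h[2L, ]
        }
      }
      g
    },
    plv = {
      g <- matrix(0, na, np)
      for (j in seq_len(np)) {
        D <- exp(1i * (matrix(pha[j, ], na, n, byrow = TRUE) -
                         matrix(ampPh[, j, ], na, n)))
        g[, j] <- Mod(rowSums(D)) / n
      }
      g
    },
    gc = {
      Ac <- apply(amp, 1L, copnorm)              # T x n_amp
      g <- matrix(0, na, np)
      for (j in seq_len(np))
        g[, j] <- gc_grid_column(pha[j, ], Ac)
      g
    })
}

# Column-mean amplitude probabilities per phase bin; amp is (n_amp, T).
binned_probs <- function(phase, amp, n_bins) {
  idx <- phase_bin_index(phase, n_bins)
  counts <- tabulate(idx, nbins = n_bins)
  sums <- matrix(0, n_bins, nrow(amp))
  rs <- rowsum(t(amp), idx)                      # occupied bins x n_amp
  sums[as.integer(rownames(rs)), ] <- rs
  means <- sums / pmax(counts, 1L)
  sweep(means, 2L, colSums(means), `/`)
}

# Vectorised bias-corrected Gaussian MI (bits) between each copula-normalised
# amplitude (columns of Ac) and the 2-d circular phase representation.
gc_grid_column <- function(phase, Ac) {
  n <- nrow(Ac)
  S <- cbind(copnorm(sin(phase)), copnorm(cos(phase)))
  S <- sweep(S, 2L, colMeans(S))
  A <- sweep(Ac, 2L, colMeans(Ac))
  va <- colSums(A^2) / (n - 1)
  Cs <- crossprod(S) / (n - 1)
  cr <- crossprod(A, S) / (n - 1)                # n_amp x 2
  detS <- Cs[1L, 1L] * Cs[2L, 2L] - Cs[1L, 2L]^2
  det3 <- va * detS -
    (cr[, 1L]^2 * Cs[2L, 2L] - 2 * cr[, 1L] * cr[, 2L] * Cs[1L, 2L] +
       cr[, 2L]^2 * Cs[1L, 1L])
  const <- 0.5 * log(2 * pi * exp(1))
  bias <- function(d) 0.5 * (d * log(2 / (n - 1)) +
                               sum(digamma((n - seq_len(d)) / 2)))
  hx <- 0.5 * log(va) + const - bias(1L)
  hy <- 0.5 * log(detS) + 2 * const - bias(2L)
  hxy <- 0.5 * log(det3) + 3 * const - bias(3L)
  pmax(0, (hx + hy - hxy) / log(2))
}

#' Surrogate null stack for a PAC configuration
#'
#' Convenience wrapper around [compute_pac()] that returns only the
#' `(n_perm, n_amp, n_pha)` stack of surrogate grids.
#'
#' @inheritParams compute_pac
#' @param ... forwarded to [compute_pac()].
#' @return numeric array `(n_perm, n_amp, n_pha)`.
#' @export
build_null <- function(x, pha_bands, amp_bands, n_perm = 200,
                       surrogate = "block_swap", seed = NULL, ...) {
  compute_pac(x, pha_bands, amp_bands, n_perm = n_perm, surrogate = surrogate,
              seed = seed, ...)$surrogates
}

#' @export
print.pac_result <- function(x, ...) {
  cat(sprintf("<pac_result> %s coupling, %d amplitude x %d phase bands (%s epochs)\n",
              toupper(x$method), nrow(x$amp_bands), nrow(x$pha_bands), x$mode))
  if (x$n_perm > 0)
    cat(sprintf("  %d %s surrogates, %s-corrected\n", x$n_perm, x$surrogate,
                x$norm))
  i <- which(x$pac == max(x$pac), arr.ind = TRUE)[1L, ]
  cat(sprintf("  max %s = %.4g at amplitude %s, phase %s Hz\n",
              toupper(x$method), max(x$pac),
              rownames(x$pac)[i[1L]], colnames(x$pac)[i[2L]]))
  invisible(x)
}

#' @export
summary.pac_result <- function(object, alpha = 0.05, ...) {
  print(object)
  if (!is.null(object$pvalues)) {
    cat(sprintf("  cells with p < %g: %d / %d (uncorrected)\n", alpha,
                sum(object$pvalues < alpha), length(object$pvalues)))
    if (!is.null(object$pvalues_fwer))
      cat(sprintf("  cells with p < %g: %d / %d (max-stat FWER)\n", alpha,
                  sum(object$pvalues_fwer < alpha), length(object$pvalues_fwer)))
  }
  invisible(object)
}

#' Coupling grid of a fitted PAC object
#'
#' @param object a `pac_result`.
#' @param corrected return the surrogate-corrected grid when available.
#' @param ... unused.
#' @return numeric matrix (amplitude bands x phase bands).
#' @export
coef.pac_result <- function(object, corrected = FALSE, ...) {
  if (corrected) {
    if (is.null(object$pac_corrected))
      stop("no surrogate-corrected grid: refit with n_perm > 0")
    object$pac_corrected
  } else object$pac
}

#' Comodulogram image of a PAC fit
#'
#' @param x a `pac_result`.
#' @param corrected plot the corrected grid when available.
#' @param ... forwarded to [graphics::image()].
#' @export
plot.pac_result <- function(x, corrected = FALSE, ...) {
  g <- coef(x, corrected = corrected)
  xs <- band_centers(x$pha_bands)
  ys <- band_centers(x$amp_bands)
  graphics::image(xs, ys, t(g), xlab = "phase frequency (Hz)",
                  ylab = "amplitude frequency (Hz)",
                  main = sprintf("%s comodulogram%s", toupper(x$method),
                                 if (corrected) " (corrected)" else ""),
                  col = grDevices::hcl.colors(64, "viridis"), ...)
  invisible(x)
}
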