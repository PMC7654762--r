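# Surrogate generation and null-based correction / inference. All surrogate
# transforms act on the amplitude stream only and preserve its sample
# multiset; the phase stream is never touched.

#' Amplitude surrogate transforms
#'
#' `surrogate_block_swap()` splits the time axis into two blocks at `cut` and
#' swaps their order (equivalently: a circular rotation), the default and
#' most conservative null. `surrogate_time_lag()` circularly shifts the time
#' axis by `lag` samples. `surrogate_trial_swap()` permutes the epoch axis.
#' Vectors, matrices (last dim = time; rows = epochs for `trial_swap`) and
#' 3-d arrays `(band, epoch, time)` are supported.
#'
#' @param amp numeric vector/matrix/array of amplitudes.
#' @param cut split point, `0 < cut < n_times`; the output is
#'   `c(amp[(cut+1):n], amp[1:cut])` along time.
#' @return Same shape as `amp`.
#' @examples
#' surrogate_block_swap(1:4, 2)    # 3 4 1 2
#' surrogate_time_lag(1:3, 1)      # 3 1 2
#' @export
surrogate_block_swap <- function(amp, cut) {
  n <- time_dim(amp)
  stopifnot_scalar_number(cut, "cut", lower = 1, upper = n - 1)
  index_time(amp, c((cut + 1):n, 1:cut))
}

#' @rdname surrogate_block_swap
#' @param lag circular shift in samples (any integer; `lag %% n_times == 0`
#'   is the identity).
#' @export
surrogate_time_lag <- function(amp, lag) {
  n <- time_dim(amp)
  stopifnot_scalar_number(lag, "lag")
  k <- ((as.integer(lag) %% n) + n) %% n
  if (k == 0L) return(amp)
  index_time(amp, c((n - k + 1L):n, 1:(n - k)))
}

#' @rdname surrogate_block_swap
#' @param perm permutation of the epoch axis; the identity is rejected when
#'   more than one epoch exists (it would yield a degenerate null member).
#' @export
surrogate_trial_swap <- function(amp, perm) {
  d <- dim(amp)
  if (is.null(d)) stop("`amp` must have an epoch dimension")
  ne <- if (length(d) == 2L) d[1L] else d[2L]
  perm <- as.integer(perm)
  if (!identical(sort(perm), seq_len(ne)))
    stop("`perm` must be a permutation of 1:", ne)
  if (ne > 1L && all(perm == seq_len(ne)))
    stop("identity permutation is not a valid trial swap")
  if (length(d) == 2L) amp[perm, , drop = FALSE]
  else amp[, perm, , drop = FALSE]
}

time_dim <- function(a) {
  d <- dim(a)
  if (is.null(d)) length(a) else d[length(d)]
}

index_time <- function(a, idx) {
  d <- dim(a)
  if (is.null(d)) a[idx]
  else if (length(d) == 2L) a[, idx, drop = FALSE]
  else if (length(d) == 3L) a[, , idx, drop = FALSE]
  else stop("arrays with more than 3 dimensions are not supported")
}

# Draw the per-permutation randomization plan up front (serially, under the
# master seed); the permutations themselves are then deterministic, so
# parallel and serial execution agree bitwise.
surrogate_plan <- function(method, n_perm, n_times, n_epochs, seed = NULL) {
  method <- match.arg(method, c("block_swap", "time_lag", "trial_swap"))
  with_seed(seed, switch(method,
    block_swap = {
      if (n_perm > n_times - 1L)
        warning("n_perm exceeds the number of distinct cut points; ",
                "sampling cuts with replacement")
      lapply(sample.int(n_times - 1L, n_perm, replace = TRUE), identity)
    },
    time_lag = lapply(sample.int(n_times - 1L, n_perm, replace = TRUE),
                      identity),
    trial_swap = {
      if (n_epochs < 2L)
        stop("trial_swap needs at least 2 epochs")
      lapply(seq_len(n_perm), function(i) {
        repeat {
          p <- sample.int(n_epochs)
          if (any(p != seq_len(n_epochs))) return(p)
        }
      })
    }))
}

apply_surrogate <- function(amp, method, draw) {
  switch(method,
    block_swap = surrogate_block_swap(amp, draw),
    time_lag   = surrogate_time_lag(amp, draw),
    trial_swap = surrogate_trial_swap(amp, draw))
}

#' Normalize a PAC grid by its surrogate null
#'
#' `zscore`: `(pac - mean(null)) / sd(null)` per cell; `mean_sub`:
#' `pac - mean(null)`.
#'
#' @param pac numeric matrix (amplitude bands x phase bands) of true values.
#' @param null numeric array `(n_perm, n_amp, n_pha)` of surrogate values
#'   (a matrix is accepted for a single-permutation-axis grid).
#' @param mode `"zscore"` (default) or `"mean_sub"`.
#' @return corrected grid, same shape as `pac`.
#' @export
normalize_pac <- function(pac, null, mode = c("zscore", "mean_sub")) {
  mode <- match.arg(mode)
  null <- as_null_stack(null, pac)
  mu <- apply(null, c(2L, 3L), mean)
  if (mode == "mean_sub") return(pac - mu)
  sdv <- apply(null, c(2L, 3L), stats::sd)
  if (any(sdv == 0)) {
    bad <- which(sdv == 0, arr.ind = TRUE)[1L, ]
    stop(sprintf("zero surrogate standard deviation in cell (amp %d, pha %d)",
                 bad[1L], bad[2L]))
  }
  (pac - mu) / sdv
}

#' Non-parametric p-values from a surrogate null
#'
#' Per cell, `p = (#(null >= pac) + 1) / (n_perm + 1)` (the exact permutation
#' bound; p is never 0).
#'
#' @inheritParams normalize_pac
#' @return matrix of p-values in `(0, 1]`, same shape as `pac`.
#' @export
pvalues_from_null <- function(pac, null) {
  null <- as_null_stack(null, pac)
  n_perm <- dim(null)[1L]
  exceed <- apply(sweep(null, c(2L, 3L), pac, `>=`), c(2L, 3L), sum)
  (exceed + 1) / (n_perm + 1)
}

#' Maximum-statistics family-wise correction
#'
#' Every cell is compared to the distribution of per-permutation grid maxima,
#' which controls the family-wise error rate over the comodulogram.
#'
#' @inheritParams normalize_pac
#' @return matrix of corrected p-values, cellwise `>=` the uncorrected ones.
#' @export
maxstat_correction <- function(pac, null) {
  null <- as_null_stack(null, pac)
  n_perm <- dim(null)[1L]
  maxima <- apply(null, 1L, max)
  matrix((vapply(pac, function(v) sum(maxima >= v), 0) + 1) / (n_perm + 1),
         nrow(pac), ncol(pac), dimnames = dimnames(pac))
}

as_null_stack <- function(null, pac) {
  if (!is.matrix(pac)) stop("`pac` must be a matrix (amp bands x pha bands)")
  if (is.matrix(null) && all(dim(pac) == 1L))
    null <- array(null, c(length(null), 1L, 1L))
  if (length(dim(null)) != 3L ||
      !all(dim(null)[2:3] == dim(pac)))
    stop("`null` must be an (n_perm x n_amp x n_pha) array matching `pac`")
  null
}
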