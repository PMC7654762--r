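#' Augmented Dickey-Fuller stationarity check per epoch
#'
#' Unit-root test with a constant term: the first difference of each epoch is
#' regressed on its lagged level and `lags` lagged differences, and the
#' t-statistic of the lagged level is compared to the Dickey-Fuller
#' distribution. The null hypothesis is a unit root, i.e. a non-stationary
#' epoch; small p-values reject non-stationarity. P-values are interpolated
#' from the asymptotic distribution of the constant-case statistic and
#' critical values use the MacKinnon (2010) response surface.
#'
#' @param x an [epoched_signal()] (or numeric matrix / vector).
#' @param lags number of lagged differences; default
#'   `trunc((n_times - 1)^(1/3))`.
#' @param sf sampling frequency when `x` is a bare matrix (unused by the
#'   test; kept for interface symmetry).
#' @return data.frame with one row per epoch: `epoch`, `statistic`,
#'   `p_value`, `lags`, `stationary_0.05`, `stationary_0.01` (H0 rejected at
#'   that level) and the critical values `crit_0.05`, `crit_0.01`.
#' @examples
#' x <- epoched_signal(matrix(rnorm(2 * 500), 2), sf = 100)
#' test_stationarity(x)
#' @export
test_stationarity <- function(x, lags = NULL, sf = NULL) {
  if (!inherits(x, "epoched_signal"))
    x <- epoched_signal(if (is.null(dim(x))) matrix(x, 1L) else x,
                        sf %||% attr(x, "sf") %||% 1)
  n <- ncol(x)
  lags <- as.integer(lags %||% trunc((n - 1)^(1 / 3)))
  if (lags < 0L || n - lags - 1L < 10L)
    stop("epoch too short for the requested number of lags")
  rows <- lapply(seq_len(nrow(x)), function(e) {
    st <- adf_stat(x[e, ], lags)
    data.frame(epoch = e, statistic = st$stat, p_value = st$p, lags = lags,
               stationary_0.05 = st$stat < st$crit[1L],
               stationary_0.01 = st$stat < st$crit[2L],
               crit_0.05 = st$crit[1L], crit_0.01 = st$crit[2L])
  })
  do.call(rbind, rows)
}

adf_stat <- function(y, lags) {
  dy <- diff(y)
  n <- length(dy)
  idx <- (lags + 1L):n
  X <- cbind(1, y[idx])                      # intercept + lagged level
  if (lags > 0L)
    X <- cbind(X, vapply(seq_len(lags), function(k) dy[idx - k], dy[idx]))
  yy <- dy[idx]
  fit <- stats::lm.fit(X, yy)
  res <- fit$residuals
  dof <- length(yy) - ncol(X)
  sigma2 <- sum(res^2) / dof
  XtXinv <- chol2inv(chol(crossprod(X)))
  tstat <- fit$coefficients[2L] / sqrt(sigma2 * XtXinv[2L, 2L])
  teff <- length(yy)
  # MacKinnon (2010) response surface, constant / no trend
  crit05 <- -2.86154 - 2.8903 / teff - 4.234 / teff^2 - 40.040 / teff^3
  crit01 <- -3.43035 - 6.5393 / teff - 16.786 / teff^2 - 79.433 / teff^3
  list(stat = unname(tstat), p = adf_pvalue(tstat), crit = c(crit05, crit01))
}

# Interpolated p-value from asymptotic quantiles of the constant-case
# Dickey-Fuller t distribution; clamped to [0.01, 0.99].
adf_pvalue <- function(stat) {
  q <- c(-3.43, -3.12, -2.86, -2.57, -0.44, -0.07, 0.23, 0.60)
  p <- c(0.01, 0.025, 0.05, 0.10, 0.90, 0.95, 0.975, 0.99)
  unname(stats::approx(q, p, xout = stat, yleft = 0.01, yright = 0.99)$y)
}
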