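#' Multi-epoch signal container
#'
#' Bundles an epochs-by-time numeric matrix with its sampling frequency. This
#' is the universal input of the package: every estimator consumes an
#' `epoched_signal`.
#'
#' @param data numeric matrix (or vector, treated as a single epoch), rows are
#'   epochs and columns time points. All values must be finite.
#' @param sf sampling frequency in Hz (> 0).
#' @return An object of class `epoched_signal`: the data matrix with
#'   attributes `sf` (Hz) and, when produced by a simulator, `spec`.
#' @examples
#' x <- epoched_signal(matrix(rnorm(2 * 100), 2), sf = 100)
#' dim(x)
#' @export
epoched_signal <- function(data, sf) {
  if (is.vector(data) && is.numeric(data)) data <- matrix(data, nrow = 1L)
  if (!is.matrix(data) || !is.numeric(data))
    stop("`data` must be a numeric matrix (epochs x time)")
  if (ncol(data) < 2L) stop("`data` needs at least 2 time points")
  bad <- which(!apply(data, 1L, function(r) all(is.finite(r))))
  if (length(bad))
    stop(sprintf("non-finite values in epoch %d", bad[1L]))
  stopifnot_scalar_number(sf, "sf", lower = .Machine$double.eps)
  structure(data, sf = sf, class = c("epoched_signal", "matrix", "array"))
}

#' @export
print.epoched_signal <- function(x, ...) {
  sf <- attr(x, "sf")
  cat(sprintf("<epoched_signal> %d epoch(s) x %d samples @ %g Hz (%.3g s)\n",
              nrow(x), ncol(x), sf, ncol(x) / sf))
  sp <- attr(x, "spec")
  if (!is.null(sp))
    cat("  simulated:", paste(names(sp), unlist(sp), sep = "=", collapse = ", "),
        "\n")
  invisible(x)
}

#' Time vector of an epoched signal
#' @param x an [epoched_signal()].
#' @return numeric vector of sample times in seconds, starting at 0.
#' @export
signal_times <- function(x) {
  (seq_len(ncol(x)) - 1L) / attr(x, "sf")
}

#' Build a grid of frequency bands
#'
#' Utility for comodulogram axes: consecutive `[f, f + width]` Hz intervals
#' covering `from` to `to` with a given step between band starts.
#'
#' @param from,to range covered by the band starts/ends, in Hz.
#' @param width band width in Hz.
#' @param step distance between consecutive band starts (defaults to `width`,
#'   i.e. contiguous non-overlapping bands).
#' @return numeric matrix with columns `f_start`, `f_end`, one row per band.
#' @examples
#' make_bands(2, 20, width = 2)   # (2,4), (4,6), ..., (18,20)
#' @export
make_bands <- function(from, to, width, step = width) {
  stopifnot_scalar_number(from, "from", lower = 0)
  stopifnot_scalar_number(to, "to", lower = from + width)
  stopifnot_scalar_number(width, "width", lower = .Machine$double.eps)
  stopifnot_scalar_number(step, "step", lower = .Machine$double.eps)
  starts <- seq(from, to - width, by = step)
  cbind(f_start = starts, f_end = starts + width)
}

# Coerce a band specification to a 2-column matrix and validate against sf.
as_band_matrix <- function(bands, sf = NULL, what = "bands") {
  if (is.null(dim(bands))) {
    if (length(bands) != 2L)
      stop(sprintf("`%s` must be a (f_start, f_end) pair or a 2-column matrix",
                   what))
    bands <- matrix(as.numeric(bands), nrow = 1L)
  }
  bands <- as.matrix(bands)
  storage.mode(bands) <- "double"
  if (ncol(bands) != 2L) stop(sprintf("`%s` must have 2 columns", what))
  if (nrow(bands) == 0L) stop(sprintf("`%s` is empty", what))
  if (any(!is.finite(bands)) || any(bands[, 1L] <= 0) ||
      any(bands[, 2L] <= bands[, 1L]))
    stop(sprintf("`%s` must satisfy 0 < f_start < f_end", what))
  if (!is.null(sf) && any(bands[, 2L] >= sf / 2))
    stop(sprintf("`%s`: band end %g Hz is not below the Nyquist frequency %g Hz",
                 what, max(bands[, 2L]), sf / 2))
  colnames(bands) <- c("f_start", "f_end")
  bands
}

band_centers <- function(bands) rowMeans(as_band_matrix(bands))

band_labels <- function(bands) {
  b <- as_band_matrix(bands)
  sprintf("[%g,%g]", b[, 1L], b[, 2L])
}

#' Write / read epoched signals as CSV with a JSON sidecar
#'
#' Arrays are stored as plain CSV (rows = epochs, no header) and the sampling
#' frequency plus any simulation parameters go to `<path>.json`.
#'
#' @param x an [epoched_signal()].
#' @param path output CSV path; the sidecar is written at `paste0(path, ".json")`.
#' @return `write_epochs()` returns `path` invisibly; `read_epochs()` returns
#'   an [epoched_signal()].
#' @export
write_epochs <- function(x, path) {
  if (!inherits(x, "epoched_signal")) stop("`x` must be an epoched_signal")
  utils::write.table(unclass(x), path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  meta <- list(sf = attr(x, "sf"), n_epochs = nrow(x), n_times = ncol(x))
  sp <- attr(x, "spec")
  if (!is.null(sp)) meta$spec <- sp
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_epochs
#' @param sf sampling frequency in Hz; required if no JSON sidecar exists.
#' @export
read_epochs <- function(path, sf = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  dat <- tryCatch(
    as.matrix(utils::read.table(path, sep = ",", header = FALSE)),
    error = function(e) stop("malformed CSV: ", conditionMessage(e),
                             call. = FALSE))
  storage.mode(dat) <- "double"
  dimnames(dat) <- NULL
  side <- paste0(path, ".json")
  spec <- NULL
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    sf <- sf %||% meta$sf
    spec <- meta$spec
  }
  if (is.null(sf)) stop("`sf` must be given when no JSON sidecar is present")
  out <- epoched_signal(dat, sf)
  if (!is.null(spec)) attr(out, "spec") <- spec
  out
}
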