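#' Configuration of a corrected-PAC run
#'
#' Bundles every tunable of the 4-step workflow (extract, measure, surrogate
#' null, normalize + p-values) into a serializable object: a config written
#' to JSON and read back reproduces the computation exactly (no hidden
#' state).
#'
#' @inheritParams compute_pac
#' @return list of class `pac_config`.
#' @examples
#' cfg <- pac_config(method = "mi", n_perm = 50, seed = 1)
#' tmp <- tempfile(fileext = ".json")
#' write_pac_config(cfg, tmp)
#' identical(read_pac_config(tmp), cfg)
#' @export
pac_config <- function(method = "mi",
                       pha_bands = make_bands(2, 20, 2),
                       amp_bands = make_bands(60, 160, 10),
                       spectral = "hilbert", mode = "concat",
                       n_bins = 18, cycles = c(3, 6), width = 7, p = 0.05,
                       edge_discard = 0, n_perm = 200,
                       surrogate = "block_swap", norm = "zscore",
                       correction = "maxstat", seed = NULL, n_jobs = 1) {
  method <- match.arg(method, c("mvl", "mi", "hr", "ndpac", "plv", "gc"))
  spectral <- match.arg(spectral, c("hilbert", "wavelet"))
  mode <- match.arg(mode, c("concat", "average"))
  surrogate <- match.arg(surrogate, c("block_swap", "time_lag", "trial_swap"))
  norm <- match.arg(norm, c("zscore", "mean_sub"))
  correction <- match.arg(correction, c("none", "maxstat"))
  structure(list(method = method,
                 pha_bands = as_band_matrix(pha_bands, what = "pha_bands"),
                 amp_bands = as_band_matrix(amp_bands, what = "amp_bands"),
                 spectral = spectral, mode = mode,
                 n_bins = as.numeric(n_bins), cycles = as.numeric(cycles),
                 width = as.numeric(width), p = as.numeric(p),
                 edge_discard = as.numeric(edge_discard),
                 n_perm = as.numeric(n_perm), surrogate = surrogate,
                 norm = norm, correction = correction,
                 seed = if (is.null(seed)) NULL else as.numeric(seed),
                 n_jobs = as.numeric(n_jobs)),
            class = "pac_config")
}

#' @rdname pac_config
#' @param config a `pac_config`.
#' @param path JSON file path.
#' @export
write_pac_config <- function(config, path) {
  if (!inherits(config, "pac_config")) stop("`config` must be a pac_config")
  l <- unclass(config)
  l <- l[!vapply(l, is.null, TRUE)]    # a NULL seed is simply absent on disk
  jsonlite::write_json(l, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname pac_config
#' @export
read_pac_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pac_config, raw)
}

#' @export
print.pac_config <- function(x, ...) {
  cat(sprintf("<pac_config> %s, %d pha x %d amp bands, %d %s surrogates, %s norm\n",
              toupper(x$method), nrow(x$pha_bands), nrow(x$amp_bands),
              x$n_perm, x$surrogate, x$norm))
  invisible(x)
}

#' Corrected PAC: the full 4-step workflow
#'
#' Runs extraction, coupling estimation, surrogate null and correction /
#' inference as configured: the canonical filter-measure-permute-normalize
#' pipeline. Identical seeds (and any `n_jobs`) give identical results.
#'
#' @param x an [epoched_signal()].
#' @param config a [pac_config()].
#' @param verbose emit one structured message per pipeline stage.
#' @return a `pac_result` (see [compute_pac()]) with surrogates, corrected
#'   grid and p-values populated.
#' @export
run_corrected_pac <- function(x, config = pac_config(), verbose = FALSE) {
  if (!inherits(config, "pac_config")) stop("`config` must be a pac_config")
  if (!inherits(x, "epoched_signal")) stop("`x` must be an epoched_signal")
  # fail on inconsistent band / sampling-rate combinations before any work
  as_band_matrix(config$pha_bands, attr(x, "sf"), "pha_bands")
  as_band_matrix(config$amp_bands, attr(x, "sf"), "amp_bands")
  say <- function(stage, t0) if (verbose)
    message(sprintf("[%s] %s done in %.2fs", format(Sys.time(), "%H:%M:%S"),
                    stage, as.numeric(Sys.time()) - t0))
  t0 <- as.numeric(Sys.time())
  out <- compute_pac(x, config$pha_bands, config$amp_bands,
                     method = config$method, mode = config$mode,
                     spectral = config$spectral, n_bins = config$n_bins,
                     cycles = config$cycles, width = config$width,
                     p = config$p, edge_discard = config$edge_discard,
                     n_perm = config$n_perm, surrogate = config$surrogate,
                     norm = config$norm, correction = config$correction,
                     seed = config$seed, n_jobs = config$n_jobs)
  say(sprintf("corrected %s PAC (%dx%d grid, %d perms)", config$method,
              nrow(config$amp_bands), nrow(config$pha_bands), config$n_perm),
      t0)
  out$config <- config
  out
}

#' Figure-ready arrays from fitted objects
#'
#' Extracts the plain arrays and axis vectors (Hz / seconds / degrees) needed
#' to draw a comodulogram, a triangular search map, a polar preferred-phase
#' histogram or an ERPAC image with any plotting front end.
#'
#' @param result a `pac_result`, `triangular_grid`, `preferred_phase` or
#'   `erpac_result`.
#' @return list with `kind`, `values` and named axis vectors.
#' @export
export_plot_data <- function(result) UseMethod("export_plot_data")

#' @export
export_plot_data.pac_result <- function(result) {
  list(kind = "comodulogram",
       values = unname(result$pac),
       corrected = if (is.null(result$pac_corrected)) NULL
                   else unname(result$pac_corrected),
       pha_hz = unname(band_centers(result$pha_bands)),
       amp_hz = unname(band_centers(result$amp_bands)),
       method = result$method)
}

#' @export
export_plot_data.triangular_grid <- function(result) {
  list(kind = "triangular", values = unname(result$values),
       f_min_hz = unname(result$pairs[, 1L]),
       f_max_hz = unname(result$pairs[, 2L]),
       best_hz = unname(result$best), side = result$side)
}

#' @export
export_plot_data.preferred_phase <- function(result) {
  list(kind = "polar", values = unname(result$binned_amp),
       phase_deg = unname(result$centers_deg),
       amp_hz = unname(band_centers(result$amp_bands)),
       pp_deg = unname(result$pp))
}

#' @export
export_plot_data.erpac_result <- function(result) {
  list(kind = "erpac", values = unname(result$values),
       time_s = unname(result$times),
       amp_hz = unname(band_centers(result$amp_bands)),
       method = result$method)
}
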