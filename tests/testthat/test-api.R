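test_that("configurations round-trip exactly through their JSON form", {
  cfg <- pac_config(method = "plv", pha_bands = make_bands(2, 10, 2),
                    amp_bands = c(60, 90), n_perm = 40, seed = 3,
                    surrogate = "time_lag", norm = "mean_sub",
                    correction = "none", n_jobs = 2)
  path <- file.path(tempdir(), "cfg.json")
  write_pac_config(cfg, path)
  expect_identical(read_pac_config(path), cfg)
  # absent seed stays absent
  cfg2 <- pac_config(seed = NULL)
  write_pac_config(cfg2, path)
  expect_identical(read_pac_config(path), cfg2)
  unlink(path)
})

test_that("the corrected-PAC workflow is deterministic across seeds and workers", {
  x <- sim_pac_wavelet(6, 1024, 256, 10, 60, coupling = 0.8, noise = 1,
                       seed = 2)
  cfg <- pac_config(method = "mi", pha_bands = c(8, 12),
                    amp_bands = make_bands(40, 80, 20), n_perm = 40, seed = 5)
  a <- run_corrected_pac(x, cfg)
  b <- run_corrected_pac(x, cfg)
  expect_identical(a$surrogates, b$surrogates)
  expect_identical(a$pac_corrected, b$pac_corrected)
  cfg4 <- cfg; cfg4$n_jobs <- 4
  d <- run_corrected_pac(x, cfg4)
  expect_identical(a$surrogates, d$surrogates)
  expect_identical(a$pvalues, d$pvalues)
  expect_true(all(!is.null(a$pvalues_fwer)))
})

test_that("inconsistent bands fail before any computation and empty grids are rejected", {
  x <- white_epochs(2, 512, 128)
  cfg <- pac_config(amp_bands = c(60, 100))    # above Nyquist for sf = 128
  expect_error(run_corrected_pac(x, cfg), "Nyquist")
  expect_error(pac_config(pha_bands = matrix(numeric(0), 0, 2)), "empty")
})

test_that("surrogate correction suppresses the slow-phase artifact ridge", {
  x <- sim_pac_wavelet(20, 1024, 512, 10, 100, coupling = 0.9, noise = 1,
                       seed = 52)
  fit <- compute_pac(x, make_bands(1, 13, 2), make_bands(55, 165, 10),
                     method = "mvl", n_perm = 100, norm = "zscore",
                     surrogate = "trial_swap", seed = 152)
  unc <- fit$pac
  ms <- normalize_pac(unc, fit$surrogates, "mean_sub")
  art <- which.max(unc[, 1])                  # ridge cell, slowest phase band
  expect_gte(1 - ms[art, 1] / unc[art, 1], 0.5)
  # the z-scored peak stays within one band of the planted (10, 100) cell
  iz <- which(fit$pac_corrected == max(fit$pac_corrected), arr.ind = TRUE)[1, ]
  expect_lte(abs(rowMeans(fit$amp_bands)[iz[1]] - 100), 15)
  expect_lte(abs(rowMeans(fit$pha_bands)[iz[2]] - 10), 3)
})

test_that("plot-data exports carry matching axes and round-trip through JSON", {
  x <- sim_pac_tort(4, 1024, 256, 10, 60, coupling = 0.8, seed = 3)
  fit <- compute_pac(x, make_bands(6, 14, 4), make_bands(40, 80, 10),
                     method = "mi")
  ex <- export_plot_data(fit)
  expect_equal(dim(ex$values), c(4L, 2L))
  expect_length(ex$pha_hz, ncol(fit$pac))
  expect_length(ex$amp_hz, nrow(fit$pac))
  pp <- preferred_phase(x, c(8, 12), make_bands(40, 80, 20))
  ep <- export_plot_data(pp)
  expect_equal(nrow(ep$values), 18L)          # polar rows = n_bins
  path <- file.path(tempdir(), "plotdata.json")
  jsonlite::write_json(ex, path, auto_unbox = TRUE, digits = NA)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$values, unname(fit$pac), tolerance = 1e-12)
  expect_equal(back$pha_hz, ex$pha_hz)
  unlink(path)
})

test_that("summary/coef/plot methods expose the fitted grids", {
  x <- sim_pac_tort(4, 1024, 256, 10, 60, coupling = 0.8, seed = 3)
  fit <- compute_pac(x, c(8, 12), c(50, 70), method = "mi", n_perm = 20,
                     seed = 1)
  expect_identical(coef(fit), fit$pac)
  expect_identical(coef(fit, corrected = TRUE), fit$pac_corrected)
  expect_output(summary(fit), "cells with p")
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit))
  fit0 <- compute_pac(x, c(8, 12), c(50, 70), method = "mi")
  expect_error(coef(fit0, corrected = TRUE), "n_perm")
})

test_that("the CLI wires simulate and pac together and fails loudly on bad input", {
  d <- file.path(tempdir(), "cli-test")
  dir.create(d, showWarnings = FALSE)
  expect_equal(pac_cli("--help"), 0L)
  expect_equal(pac_cli("no-such-command"), 2L)
  sim <- file.path(d, "sim.csv")
  expect_equal(suppressMessages(pac_cli(c(
    "simulate", "--out", sim, "--sf", "512", "--f-pha", "10",
    "--f-amp", "100", "--coupling", "0.9", "--n-epochs", "5",
    "--n-times", "2048", "--seed", "1"))), 0L)
  expect_true(file.exists(sim) && file.exists(paste0(sim, ".json")))
  out <- file.path(d, "fit")
  expect_equal(pac_cli(c("pac", "--in", sim, "--out", out, "--method", "mi",
                         "--f-pha", "5,15,2", "--f-amp", "80,120,10")), 0L)
  g <- as.matrix(utils::read.csv(paste0(out, "_pac.csv"), header = FALSE))
  i <- which(g == max(g), arr.ind = TRUE)[1, ]
  pha_centers <- rowMeans(make_bands(5, 15, 2))
  amp_centers <- rowMeans(make_bands(80, 120, 10))
  expect_lte(abs(pha_centers[i[2]] - 10), 2)   # planted cell recovered
  expect_lte(abs(amp_centers[i[1]] - 100), 10)
  bad <- file.path(d, "bad.csv")
  writeLines(c("a,b,1", "2,3"), bad)
  expect_gt(suppressMessages(pac_cli(c("pac", "--in", bad, "--sf", "100"))), 0L)
  unlink(d, recursive = TRUE)
})

test_that("reading a CSV without a sampling rate is an explicit error", {
  p <- file.path(tempdir(), "nosf.csv")
  utils::write.table(matrix(rnorm(20), 2), p, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  expect_error(read_epochs(p), "sf")
  expect_equal(attr(read_epochs(p, sf = 100), "sf"), 100)
  unlink(p)
})
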