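test_that("preferred phase lands on the bin of the locked angle", {
  x <- sim_pac_tort(20, 2048, 512, 6, 100, coupling = 1, noise = 0.5,
                    pp = pi / 4, seed = 6)
  pp <- preferred_phase(x, c(5, 7), c(90, 110))
  expect_lt(min(abs(pp$pp[1] - 45), abs(pp$pp[1] - 45 - 360)), 20)
  expect_false(pp$tie[1])
  # argmax consistency with the returned binned matrix
  i <- which.max(pp$binned_amp[, 1])
  expect_equal(pp$pp[1], pp$centers_deg[i])
})

test_that("a flat amplitude distribution raises the tie flag", {
  x <- sim_pac_tort(5, 2048, 512, 6, 100, coupling = 0, noise = 0, seed = 1)
  pp <- preferred_phase(x, c(5, 7), c(90, 110), tie_tol = 1e-3)
  expect_true(pp$tie[1])
})

test_that("binned-amplitude uniformity check is calibrated and powerful", {
  p0 <- vapply(1:50, function(i) {
    x <- sim_pac_tort(20, 2048, 256, 10, 70, coupling = 0, noise = 1.5,
                      seed = 300 + i)
    bin_amplitude(x, c(8, 12), c(60, 80), edge_discard = 128)$p_value
  }, 0)
  expect_lte(sum(p0 < 0.01), 2)                        # size at alpha = 0.01
  p1 <- vapply(1:5, function(i) {
    x <- sim_pac_tort(20, 2048, 256, 10, 70, coupling = 1, noise = 1.5,
                      seed = 600 + i)
    bin_amplitude(x, c(8, 12), c(60, 80), edge_discard = 128)$p_value
  }, 0)
  expect_true(all(p1 < 0.01))                          # power
  # constant signal: no band energy, exactly uniform
  xc <- epoched_signal(matrix(5, 3, 1024), 256)
  b <- suppressWarnings(bin_amplitude(xc, c(8, 12), c(60, 80), edge_discard = 128))
  expect_equal(b$statistic, 0)
  expect_equal(b$p_value, 1)
})

test_that("Welch PSD finds spectral peaks and conserves energy", {
  sf <- 256; t <- (0:8191) / sf
  x <- epoched_signal(matrix(sin(2 * pi * 6 * t), 1), sf)
  p <- psd(x)
  expect_equal(psd_peak(p, 2, 20), 6, tolerance = p$df)
  xn <- white_epochs(4, 4096, 256, seed = 5)
  pn <- psd(xn)
  expect_lt(abs(sum(pn$power) * pn$df / mean(apply(unclass(xn), 1, stats::var))
                - 1), 0.05)
  expect_error(psd_peak(pn, 300, 400), "range")
})

test_that("inter-trial coherence is 1 for identical epochs and ~Rayleigh for noise", {
  x <- sim_pac_tort(30, 1024, 256, 6, 70, coupling = 0, noise = 0, seed = 1)
  expect_true(all(itc(x, c(5, 7))$values > 1 - 1e-6))
  xr <- white_epochs(1000, 256, 256, seed = 3)
  v <- itc(xr, c(5, 7))$values[interior(256)]
  expect_lt(mean(v), 3 / sqrt(1000))
  expect_gt(mean(v), 0.3 / sqrt(1000))
  # scaling whole epochs leaves the phase, hence the ITC, unchanged
  xs <- epoched_signal(unclass(xr) * seq_len(1000), 256)
  expect_equal(itc(xs, c(5, 7))$values, itc(xr, c(5, 7))$values,
               tolerance = 1e-9)
})

test_that("triangular search covers only f_min < f_max and matches direct fits", {
  x <- sim_pac_tort(10, 1536, 256, 6, 70, coupling = 0.8, noise = 1, seed = 7)
  tg <- triangular_search(x, c(5, 7), side = "amplitude", f_range = c(55, 85),
                          step = 5, method = "mi")
  expect_true(all(tg$pairs[, 1] < tg$pairs[, 2]))
  expect_equal(nrow(tg$pairs), choose(7, 2))
  # loop oracle: each value equals an individually computed fit
  for (k in c(1, 5, nrow(tg$pairs))) {
    direct <- compute_pac(x, c(5, 7), tg$pairs[k, ], method = "mi")$pac[1, 1]
    expect_equal(tg$values[k], direct, tolerance = 1e-12)
  }
  expect_equal(tg$best, tg$pairs[which.max(tg$values), ])
  # two-point range gives a single pair; oversized step errors
  t2 <- triangular_search(x, c(5, 7), side = "amplitude", f_range = c(60, 80),
                          step = 20, method = "mi")
  expect_equal(nrow(t2$pairs), 1L)
  expect_error(triangular_search(x, c(5, 7), side = "amplitude",
                                 f_range = c(60, 80), step = 30), "step")
})

test_that("peak-locked realignment aligns driver peaks and reveals burst rhythmicity", {
  x <- sim_pac_tort(30, 2048, 512, 10, 100, coupling = 1, noise = 0.5,
                    seed = 21)
  pl <- peak_locked_tf(x, c(9, 11), cue = 1024, freqs = seq(80, 120, 10))
  expect_lte(max(abs(pl$shifts)), pl$half_period)
  tc <- pl$tf[3, 200:1848]
  ac <- stats::acf(tc, lag.max = 60, plot = FALSE)$acf
  expect_gt(ac[52], 0.3)            # driver period = 51.2 samples at 512 Hz
  # identical epochs realign with identical shifts; cue on a peak -> zero
  xi <- sim_pac_tort(5, 2048, 512, 10, 100, coupling = 1, noise = 0, seed = 1)
  p1 <- peak_locked_tf(xi, c(9, 11), cue = 1024, freqs = 100)
  expect_equal(length(unique(p1$shifts)), 1L)
  cue0 <- 1024 + p1$shifts[1]
  p0 <- peak_locked_tf(xi, c(9, 11), cue = cue0, freqs = 100)
  expect_true(all(p0$shifts == 0))
})

test_that("epochs without a peak near the cue are dropped with a warning", {
  good <- sim_pac_tort(2, 1024, 256, 10, 70, coupling = 1, noise = 0, seed = 2)
  x <- epoched_signal(rbind(unclass(good), 0), 256)
  expect_warning(pl <- peak_locked_tf(x, c(8, 12), cue = 512, freqs = 70),
                 "dropped")
  expect_equal(pl$kept, 1:2)
})
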