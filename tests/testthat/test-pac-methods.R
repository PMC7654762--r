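test_that("phase binning reproduces hand-computable distributions", {
  # uniform: constant amplitude over evenly spread phases
  ph <- rep(seq(-pi + pi / 18, pi - pi / 18, length.out = 18), 10)
  d <- bin_amplitude_by_phase(ph, rep(2, length(ph)), 18)
  expect_equal(d$p, rep(1 / 18, 18))
  expect_false(d$degenerate)
  # delta: amplitude 1 only inside bin j
  ph2 <- seq(-pi + 0.01, pi - 0.01, length.out = 180)
  amp2 <- as.numeric(pacr:::phase_bin_index(ph2, 18) == 7)
  expect_equal(bin_amplitude_by_phase(ph2, amp2, 18)$p,
               as.numeric(1:18 == 7))
  # six samples, three bins, worked by hand
  d3 <- bin_amplitude_by_phase(c(-2, 0, 2, -2, 0, 2), c(1, 2, 3, 1, 2, 3), 3)
  expect_equal(d3$p, c(1, 2, 3) / 6)
  # constant phase occupies a single bin and is flagged
  expect_warning(dd <- bin_amplitude_by_phase(rep(0.3, 5), 1:5, 18), "empty")
  expect_true(dd$degenerate)
  expect_error(bin_amplitude_by_phase(1:3, 1:2), "lengths differ")
})

test_that("modulation index spans [0, 1] with exact endpoints and arithmetic", {
  expect_equal(mi_kl(rep(1 / 18, 18)), 0)
  expect_equal(mi_kl(as.numeric(1:18 == 4)), 1)
  # direct-arithmetic oracle for a 3-bin distribution
  oracle <- 1 + (0.5 * log(0.5) + 2 * 0.25 * log(0.25)) / log(3)
  expect_equal(mi_kl(c(0.5, 0.25, 0.25)), oracle, tolerance = 1e-12)
  expect_equal(round(oracle, 5), 0.05361)
  expect_error(mi_kl(c(0.5, 0.6)), "probability")
})

test_that("heights ratio matches its closed form", {
  expect_equal(heights_ratio(rep(1 / 18, 18)), 0)
  expect_equal(heights_ratio(c(0.7, 0.3, 0)), 1)   # a zero bin
  expect_equal(heights_ratio(c(0.5, 0.3, 0.2)), 0.6)
})

test_that("mean vector length reproduces closed-form cases", {
  expect_equal(pac_mvl(rep(0.7, 10), rep(3, 10)), 3)          # constant vector
  ph <- 2 * pi * (0:7) / 8
  expect_lt(pac_mvl(ph, rep(1, 8)), 1e-12)                     # roots of unity
  expect_equal(pac_mvl(c(0, pi), c(1, 2)), 0.5)
  expect_error(pac_mvl(numeric(0), numeric(0)), "empty")
})

test_that("ndPac threshold follows the closed form and gates the null", {
  expect_equal(ndpac_threshold(1000, 0.05), 3841.459, tolerance = 1e-3)
  expect_gt(ndpac_threshold(1000, 0.01), ndpac_threshold(1000, 0.05))
  set.seed(10)
  zeros <- vapply(1:100, function(i)
    pac_ndpac(stats::runif(1000, -pi, pi), stats::rnorm(1000)) == 0, TRUE)
  expect_gte(mean(zeros), 0.9)
  expect_error(pac_ndpac(c(0, 1, 2), c(5, 5, 5)), "zero-variance")
})

test_that("phase-locking value reproduces closed-form cases", {
  ph <- stats::runif(50, -pi, pi)
  expect_equal(pac_plv(ph, ph), 1)
  d <- 2 * pi * (0:9) / 10
  expect_lt(pac_plv(d, rep(0, 10)), 1e-12)
  expect_equal(pac_plv(c(0, pi / 2), c(0, 0)), sqrt(2) / 2)
})

test_that("copula normalisation is the rank-to-normal map", {
  x <- c(0.3, 1.2, 5.9)                           # strictly increasing ranks
  expect_equal(copnorm(sort(x)), stats::qnorm(1:3 / 4))
  expect_equal(copnorm(c(5, 1, 3)), stats::qnorm(c(3, 1, 2) / 4))
  y <- stats::rnorm(100)
  expect_equal(copnorm(exp(y)), copnorm(y))        # monotone invariance
})

test_that("gcPAC is near zero under independence and calibrated against binned MI", {
  set.seed(7)
  n <- 10000
  phi <- stats::runif(n, -pi, pi)
  expect_lt(abs(as.numeric(pac_gc(phi, stats::rnorm(n)))), 0.01)
  # noisy cosine coupling vs a Miller-Madow corrected histogram MI oracle
  a <- 2 + cos(phi) + stats::rnorm(n, sd = 0.1)
  nb <- 8                                          # 8 x 8 = 64 joint bins
  tab <- table(cut(phi, nb, labels = FALSE), cut(a, nb, labels = FALSE)) / n
  pi_ <- rowSums(tab); pj <- colSums(tab)
  mm <- sum(ifelse(tab > 0, tab * log2(tab / outer(pi_, pj)), 0)) +
    (sum(tab > 0) - 2 * nb + 1) / (2 * n * log(2))
  gc <- as.numeric(pac_gc(phi, a))
  expect_lt(abs(gc - mm) / mm, 0.1)
  # exact rank invariance under strictly monotone amplitude transforms
  expect_equal(as.numeric(pac_gc(phi, a)),
               as.numeric(pac_gc(phi, a^3 + 7)))
  expect_error(pac_gc(phi[1:5], a[1:5]), "at least 10")
  expect_error(pac_gc(rep(0.2, 100), rep(1, 100)), "degenerate")
})

test_that("a 1x1 grid equals the direct single-pair measures", {
  x <- sim_pac_tort(4, 1024, 256, 10, 60, coupling = 0.8, noise = 1, seed = 6)
  ph <- as.vector(extract_phase(x, c(8, 12))[1, , ])
  am <- as.vector(extract_amplitude(x, c(50, 70))[1, , ])
  fit <- compute_pac(x, c(8, 12), c(50, 70), method = "mvl")
  expect_equal(fit$pac[1, 1], pac_mvl(ph, am), tolerance = 1e-12)
  fit2 <- compute_pac(x, c(8, 12), c(50, 70), method = "mi")
  expect_equal(fit2$pac[1, 1], mi_kl(bin_amplitude_by_phase(ph, am, 18)),
               tolerance = 1e-12)
  fit3 <- compute_pac(x, c(8, 12), c(50, 70), method = "gc")
  expect_equal(fit3$pac[1, 1], as.numeric(pac_gc(ph, am)), tolerance = 1e-10)
})

test_that("amplitude scaling leaves MI/HR/PLV/gcPAC unchanged and scales MVL linearly", {
  set.seed(11)
  ph <- stats::runif(3000, -pi, pi)
  am <- abs(1 + 0.5 * cos(ph) + stats::rnorm(3000, sd = 0.2))
  d1 <- bin_amplitude_by_phase(ph, am); d3 <- bin_amplitude_by_phase(ph, 3 * am)
  expect_equal(mi_kl(d3), mi_kl(d1), tolerance = 1e-12)
  expect_equal(heights_ratio(d3), heights_ratio(d1), tolerance = 1e-12)
  expect_equal(as.numeric(pac_gc(ph, 3 * am)), as.numeric(pac_gc(ph, am)))
  expect_equal(pac_mvl(ph, 3 * am), 3 * pac_mvl(ph, am), tolerance = 1e-12)
  # PLV ignores the amplitude magnitude by construction (phase of envelope)
  expect_equal(pac_plv(ph, ph / 2), pac_plv(ph, ph / 2))
})

test_that("band grids above Nyquist are rejected before any filtering", {
  x <- white_epochs(2, 512, 128)
  expect_error(compute_pac(x, c(8, 12), c(60, 70), method = "mi"), "Nyquist")
  expect_error(compute_pac(x, matrix(numeric(0), 0, 2), c(20, 40),
                           method = "mi"), "empty")
})
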