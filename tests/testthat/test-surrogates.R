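test_that("block swap concatenates the two time blocks in swapped order", {
  expect_equal(surrogate_block_swap(1:4, 2), c(3, 4, 1, 2))
  v <- stats::rnorm(10)
  expect_equal(surrogate_block_swap(surrogate_block_swap(v, 3), 7), v)
  expect_error(surrogate_block_swap(1:4, 4), "cut")
  m <- matrix(1:12, 2)                    # 2 epochs x 6 time points
  expect_equal(surrogate_block_swap(m, 2), m[, c(3:6, 1:2)])
})

test_that("time lag is a circular shift with identity at 0 and n", {
  expect_equal(surrogate_time_lag(1:3, 0), 1:3)
  expect_equal(surrogate_time_lag(1:3, 3), 1:3)
  expect_equal(surrogate_time_lag(1:3, 1), c(3, 1, 2))
})

test_that("trial swap permutes whole epochs and rejects the identity", {
  m <- matrix(1:12, 2, byrow = TRUE)
  expect_equal(surrogate_trial_swap(m, c(2, 1)), m[c(2, 1), ])
  expect_error(surrogate_trial_swap(m, c(1, 2)), "identity")
  a <- array(stats::rnorm(3 * 4 * 5), c(3, 4, 5))
  s <- surrogate_trial_swap(a, c(2, 3, 4, 1))
  expect_equal(sort(as.vector(s)), sort(as.vector(a)))
  for (e in 1:4) expect_equal(s[, e, ], a[, c(2, 3, 4, 1)[e], ])
})

test_that("every surrogate preserves the amplitude sample multiset", {
  set.seed(20)
  for (rep in 1:10) {
    a <- array(stats::rnorm(2 * 3 * 50), c(2, 3, 50))
    expect_equal(sort(surrogate_block_swap(a, sample(49, 1))), sort(a))
    expect_equal(sort(surrogate_time_lag(a, sample(100, 1))), sort(a))
    expect_equal(sort(surrogate_trial_swap(a, c(2, 3, 1))), sort(a))
  }
})

test_that("seeded null stacks are reproducible and leave the true grid untouched", {
  x <- sim_pac_wavelet(4, 1024, 256, 10, 60, coupling = 0.8, noise = 1,
                       seed = 2)
  f1 <- compute_pac(x, c(8, 12), c(50, 70), method = "mvl", n_perm = 30,
                    seed = 7)
  f2 <- compute_pac(x, c(8, 12), c(50, 70), method = "mvl", n_perm = 30,
                    seed = 7)
  expect_identical(f1$surrogates, f2$surrogates)
  f0 <- compute_pac(x, c(8, 12), c(50, 70), method = "mvl")
  expect_identical(f0$pac, f1$pac)      # phase stream / true value unchanged
})

test_that("strong coupling exceeds its trial-swap null at the true cell", {
  x <- sim_pac_wavelet(10, 2048, 512, 10, 100, coupling = 0.9, noise = 1,
                       seed = 8)
  f <- compute_pac(x, c(9, 11), c(90, 110), method = "mvl", n_perm = 100,
                   surrogate = "trial_swap", seed = 9)
  expect_gt(f$pac[1, 1], max(f$surrogates))
  expect_equal(f$pvalues[1, 1], 1 / 101)
})

test_that("without coupling the true value sits inside its null distribution", {
  inside <- vapply(1:20, function(s) {
    x <- sim_pac_tort(1, 768, 256, 10, 60, coupling = 0, noise = 2,
                      seed = 100 + s)
    f <- compute_pac(x, c(8, 12), c(50, 70), method = "mvl", n_perm = 100,
                     seed = 200 + s)
    q <- stats::quantile(f$surrogates, c(0.01, 0.99))
    f$pac[1, 1] >= q[1] && f$pac[1, 1] <= q[2]
  }, TRUE)
  expect_gte(mean(inside), 0.95)
})

test_that("normalization corrects by the null moments with explicit degeneracies", {
  pac <- matrix(c(2, 3), 1)
  null <- array(stats::rnorm(200 * 2, mean = 1, sd = 0.5), c(200, 1, 2))
  z <- normalize_pac(pac, null, "zscore")
  mu <- apply(null, c(2, 3), mean); sdv <- apply(null, c(2, 3), stats::sd)
  expect_equal(z, (pac - mu) / sdv)
  expect_equal(normalize_pac(pac, null, "mean_sub"), pac - mu)
  # null members z-scored against their own stack have mean 0, sd 1 per cell
  zs <- vapply(1:200, function(i)
    normalize_pac(matrix(null[i, , ], 1), null, "zscore")[1, 1], 0)
  expect_equal(mean(zs), 0, tolerance = 1e-10)
  expect_equal(stats::sd(zs), 1, tolerance = 1e-2)
  degen <- array(1, c(50, 1, 2))
  expect_error(normalize_pac(pac, degen, "zscore"), "cell")
  # mean_sub with a zero-mean null is the identity
  null0 <- array(rep(c(-1, 1), each = 50), c(100, 1, 1))
  expect_equal(normalize_pac(matrix(5, 1, 1), null0, "mean_sub"),
               matrix(5, 1, 1))
})

test_that("p-values follow the plus-one permutation convention", {
  null <- array(seq(0.1, 20, length.out = 200), c(200, 1, 1))
  expect_equal(pvalues_from_null(matrix(100), null)[1, 1], 1 / 201)
  expect_equal(pvalues_from_null(matrix(0), null)[1, 1], 1)
  set.seed(30)
  ps <- vapply(1:300, function(i) {
    pvalues_from_null(matrix(stats::rnorm(1)),
                      array(stats::rnorm(100), c(100, 1, 1)))[1, 1]
  }, 0)
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("maximum-statistics correction dominates the cellwise p-values", {
  set.seed(31)
  pac <- matrix(stats::rnorm(12), 3)
  null <- array(stats::rnorm(100 * 12), c(100, 3, 4))
  pc <- maxstat_correction(pac, null)
  expect_true(all(pc >= pvalues_from_null(pac, null)))
  one <- matrix(stats::rnorm(1))
  n1 <- array(stats::rnorm(100), c(100, 1, 1))
  expect_equal(maxstat_correction(one, n1), pvalues_from_null(one, n1))
})

test_that("oversized permutation counts fall back to sampling with replacement", {
  expect_warning(pacr:::surrogate_plan("block_swap", 50, 10, 1, seed = 1),
                 "replacement")
})
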