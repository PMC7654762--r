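# Shared fixtures, all generated in code.

white_epochs <- function(n_epochs, n_times, sf, seed = 1, sd = 1) {
  set.seed(seed)
  epoched_signal(matrix(rnorm(n_epochs * n_times, sd = sd), n_epochs), sf)
}

# circular-circular correlation (Fisher-Lee), used to compare phase streams
circ_circ_cor <- function(a, b) {
  ma <- atan2(mean(sin(a)), mean(cos(a)))
  mb <- atan2(mean(sin(b)), mean(cos(b)))
  sa <- sin(a - ma); sb <- sin(b - mb)
  sum(sa * sb) / sqrt(sum(sa^2) * sum(sb^2))
}

# interior sample index (drop a fraction at each edge)
interior <- function(n, frac = 0.1) {
  k <- ceiling(n * frac)
  (k + 1L):(n - k)
}
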