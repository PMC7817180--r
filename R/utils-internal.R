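# Internal helpers shared across modules.

# Run `expr` under a local RNG state seeded with `seed`; the caller's RNG
# stream is untouched. All stochastic stages funnel through this so that
# identical (config, seed) pairs give identical output.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Onset / amplitude wide-column helpers for the trains table.
onset_cols <- function(n) sprintf("onset_%d", seq_len(n) - 1L)
amp_cols <- function(n) sprintf("amp_%d", seq_len(n) - 1L)

train_onsets <- function(trains, i) {
  n <- trains$n_deflections[i]
  as.numeric(trains[i, onset_cols(n)])
}

train_amps <- function(trains, i) {
  n <- trains$n_deflections[i]
  as.numeric(trains[i, amp_cols(n)])
}

# Shannon entropy (bits) of a histogram given by counts; empty bins drop out.
entropy_bits <- function(counts) {
  p <- counts / sum(counts)
  p <- p[p > 0]
  -sum(p * log2(p))
}

# IQR as the paper defines it: 75th - 25th percentile.
iqr75_25 <- function(x) unname(diff(stats::quantile(x, c(0.25, 0.75), names = FALSE)))

# Half-cosine deflection response kernel: duration `dur_s` starting at
# `latency_s` after deflection onset, normalized to integrate to 1.
halfcos_kernel <- function(t, latency_s = 0.010, dur_s = 0.025) {
  u <- (t - latency_s) / dur_s
  out <- numeric(length(t))
  inside <- u >= 0 & u <= 1
  out[inside] <- sin(pi * u[inside]) * pi / (2 * dur_s)
  out
}

# Inverse CDF sampling of spike times under the half-cosine kernel, relative
# to deflection onset. CDF of sin(pi u)*pi/2 on [0,1] is (1 - cos(pi u))/2.
sample_kernel_times <- function(n, latency_s = 0.010, dur_s = 0.025) {
  u <- acos(1 - 2 * stats::runif(n)) / pi
  latency_s + u * dur_s
}

# stopifnot-style check with a readable message.
assert_that <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a
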