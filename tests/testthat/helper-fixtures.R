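## shared fixtures and independent oracles used across test files

tb256 <- time_base(256L, 12.5)
w256 <- tb256$channel_width_ns

## brute-force circular convolution with an IRF offset kernel (offset =
## sampled channel - peak channel), written with explicit modular indexing
## so it is independent of the package's FFT path
brute_conv <- function(h, pdf, peak) {
  n <- length(h)
  out <- numeric(n)
  for (j in seq_len(n)) {
    off <- (j - seq_len(n)) %% n
    out[j] <- sum(h * pdf[((peak - 1 + off) %% n) + 1])
  }
  out
}

## test-local rotation (element 1 -> position 1 + s)
rot <- function(x, s) {
  n <- length(x)
  s <- s %% n
  if (s == 0) x else c(x[(n - s + 1):n], x[seq_len(n - s)])
}

## test-local construction of the fit model curve: decay components and
## SHG spike anchored at the IRF peak, blurred by the IRF, plus background
oracle_model <- function(tb, irf, taus, f0, p1, shg, bg) {
  tc <- (seq_len(tb$n_channels) - 0.5) * tb$channel_width_ns
  d1 <- exp(-tc / taus[1])
  d2 <- exp(-tc / taus[2])
  spike <- c(1, numeric(tb$n_channels - 1))
  s <- irf$peak_channel - 1L
  f0 * (p1 * rot(brute_conv(d1, irf$pdf, irf$peak_channel), s) +
          (1 - p1) * rot(brute_conv(d2, irf$pdf, irf$peak_channel), s)) +
    shg * rot(brute_conv(spike, irf$pdf, irf$peak_channel), s) + bg
}

## chi-square goodness of fit against expected counts, pooling bins with
## small expectation
gof_pvalue <- function(obs, expected, min_exp = 5) {
  keep <- expected >= min_exp
  obs <- c(obs[keep], sum(obs[!keep]))
  expected <- c(expected[keep], sum(expected[!keep]))
  nz <- expected > 0
  x2 <- sum((obs[nz] - expected[nz])^2 / expected[nz])
  stats::pchisq(x2, df = sum(nz) - 1, lower.tail = FALSE)
}
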