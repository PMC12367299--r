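test_that("decay populations match closed-form component splits and means", {
  ## slow-component photon fraction of the FRET sensor, truncation-corrected:
  ## integral of each exponential over one cycle
  T <- 12.5
  frac_oracle <- (0.5854 * 2.14 * (1 - exp(-T / 2.14))) /
    (0.5854 * 2.14 * (1 - exp(-T / 2.14)) +
       0.4146 * 0.69 * (1 - exp(-T / 0.69)))
  expect_equal(frac_oracle, 0.814, tolerance = 1e-3)

  pop <- build_decay_population(decay_model("double", 2.14, 0.69, 0.5854),
                                tb256, 1e6)
  tc <- channel_centers(tb256)
  slow <- sum(round(1e6 * 0.5854 * exp(-tc / 2.14))) / pop$size
  expect_equal(slow, frac_oracle, tolerance = 2e-3)

  ## single-component limit of the double model: truncated-exponential mean
  pop1 <- build_decay_population(decay_model("double", 2.14, 0.69, 1), tb256)
  mean_arrival <- sum(pop1$pdf * tc)
  expect_lt(abs(mean_arrival - truncated_exp_mean(2.14, 12.5)), w256 / 2)

  ## 50 ns cycle: truncation negligible at cycle/tau = 25
  tb50 <- time_base(1024L, 50)
  pop2 <- build_decay_population(decay_model("single", 2.0), tb50)
  m <- sum(pop2$pdf * channel_centers(tb50))
  expect_lt(abs(m - truncated_exp_mean(2.0, 50)), tb50$channel_width_ns / 2)
  expect_equal(m, 2.0, tolerance = 0.02)

  expect_error(decay_model("double", -1, 0.69, 0.5), "tau1")
  expect_error(decay_model("double", 2.14, Inf, 0.5), "tau2")
  expect_error(decay_model("double", 2.14, 0.69, 1.2), "p1")
})

test_that("photon sampling reproduces the population distribution", {
  pop <- build_decay_population(decay_model("double", 2.14, 0.69, 0.5),
                                tb256)
  expect_identical(sample_photons(pop, 0), integer(0))
  expect_error(sample_photons(pop, -1))

  ## population concentrated in the first channel
  narrow <- build_decay_population(decay_model("single", 0.005), tb256)
  expect_true(all(narrow$counts[-1] == 0))
  set.seed(1)
  expect_identical(unique(sample_photons(narrow, 100)), 1L)

  ## binomial sampling bound at n = 1e6
  set.seed(42)
  n <- 1e6
  draws <- sample_photons(pop, n)
  freq <- tabulate(draws, nbins = 256) / n
  bound <- 4 * sqrt(pop$pdf * (1 - pop$pdf) / n)
  expect_gte(mean(abs(freq - pop$pdf) <= bound), 0.99)
})

test_that("gaussian IRF has the exact FWHM/sigma geometry and unit mass", {
  irf340 <- make_gaussian_irf(340, 26, tb256)
  expect_equal(irf340$sigma_ps, 144.4, tolerance = 1e-3)
  irf120 <- make_gaussian_irf(120, 26, tb256)
  expect_equal(irf120$sigma_ps, 51.0, tolerance = 1e-3)
  for (irf in list(irf340, irf120)) {
    expect_equal(irf$fwhm_ps / irf$sigma_ps, 2 * sqrt(2 * log(2)),
                 tolerance = 1e-12)
    expect_equal(sum(irf$pdf), 1, tolerance = 1e-12)
  }
  expect_warning(make_gaussian_irf(10, 26, tb256), "narrower")
  expect_error(make_gaussian_irf(-5, 26, tb256))
  expect_error(make_gaussian_irf(340, 0, tb256))
})

test_that("empirical IRF loading validates and round-trips through files", {
  tb4 <- time_base(4L, 12.5)
  irf <- load_irf_histogram(c(0, 10, 0, 0), tb4)
  expect_equal(irf$pdf, c(0, 1, 0, 0))
  expect_identical(irf$peak_channel, 2L)
  expect_equal(load_irf_histogram(c(1, 1, 1, 1), tb4)$pdf, rep(0.25, 4))
  expect_error(load_irf_histogram(c(0, 0, 0, 0), tb4), "zero")
  expect_error(load_irf_histogram(c(1, 2), tb4), "length")
  expect_error(load_irf_histogram(c(1, -2, 0, 0), tb4), "non-negative")

  path <- withr::local_tempfile(fileext = ".tsv")
  counts <- c(3, 17, 5, 1)
  write_histogram(counts, path, tb4)
  back <- read_histogram(path)
  expect_equal(back$counts, counts)
  expect_equal(back$time_base$cycle_ns, 12.5)
  expect_equal(load_irf_histogram(path, tb4)$pdf, counts / sum(counts))
})

test_that("stochastic IRF convolution is an identity for a delta kernel and wraps", {
  tb8 <- time_base(8L, 12.5)
  delta <- load_irf_histogram(c(0, 0, 1, 0, 0, 0, 0, 0), tb8)
  arr <- c(1L, 4L, 8L, 3L)
  expect_identical(convolve_photons_with_irf(arr, delta, tb8), arr)

  ## kernel concentrated 2 channels after its peak: photons near the cycle
  ## end wrap to the start of the next cycle
  shift2 <- load_irf_histogram(c(0, 0, 0, 0, 1, 0, 0, 0), tb8)
  shift2$peak_channel <- 3L
  expect_identical(convolve_photons_with_irf(c(7L, 8L), shift2, tb8),
                   c(1L, 2L))

  ## a photon at 12.4 ns shifted by +0.3 ns lands at ~0.2 ns of the next
  ## cycle (channel arithmetic on the 256-channel base)
  ch_124 <- which.min(abs(channel_times(tb256) - 12.4))
  off_03 <- round(0.3 / w256)
  pdf <- numeric(256); pdf[26 + off_03] <- 1
  k <- load_irf_histogram(pdf, tb256); k$peak_channel <- 26L
  out <- convolve_photons_with_irf(ch_124, k, tb256)
  expect_equal(channel_times(tb256)[out], 12.4 + 0.3 - 12.5,
               tolerance = w256)

  ## count conservation
  irf <- make_gaussian_irf(340, 26, tb256)
  set.seed(7)
  arr <- sample.int(256, 5000, replace = TRUE)
  expect_length(convolve_photons_with_irf(arr, irf, tb256), 5000)
})

test_that("stochastic convolution converges to the analytic convolution", {
  irf <- make_gaussian_irf(340, 26, tb256)
  pop <- build_decay_population(decay_model("double", 2.14, 0.69, 0.5),
                                tb256)
  set.seed(11)
  arr <- sample_photons(pop, 1e6)
  hist_in <- tabulate(arr, nbins = 256)
  expected <- convolve_histogram_analytic(hist_in, irf)
  obs <- tabulate(convolve_photons_with_irf(arr, irf, tb256), nbins = 256)
  expect_equal(sum(obs), sum(hist_in))
  expect_gt(gof_pvalue(obs, expected), 0.001)
})

test_that("analytic convolution matches a brute-force oracle and conserves mass", {
  tb8 <- time_base(8L, 12.5)
  h <- c(5, 0, 2, 7, 1, 0, 0, 3)
  pdf <- c(0.1, 0.5, 0.2, 0.1, 0.05, 0.05, 0, 0)
  irf <- load_irf_histogram(pdf * 100, tb8)
  out <- convolve_histogram_analytic(h, irf)
  expect_equal(out, brute_conv(h, irf$pdf, irf$peak_channel),
               tolerance = 1e-12)
  expect_equal(sum(out), sum(h), tolerance = 1e-9)

  ## delta kernel leaves the histogram unchanged
  delta <- load_irf_histogram(c(0, 0, 0, 1, 0, 0, 0, 0), tb8)
  expect_equal(convolve_histogram_analytic(h, delta), h, tolerance = 1e-12)
  expect_error(convolve_histogram_analytic(c(1, 2), irf), "different")
})
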