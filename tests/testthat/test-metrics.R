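irf_m <- make_gaussian_irf(340, 26, tb256)

test_that("empirical lifetime follows the re-zeroing convention", {
  ## uniform counts over the 1.8-11.5 ns window: mean of the re-zeroed
  ## times w * (1..m), m in-window channels
  m <- sum(channel_times(tb256) >= 1.8 & channel_times(tb256) <= 11.5)
  expect_identical(m, 199L)
  expect_equal(empirical_lifetime(rep(1, 256), tb256,
                                  analysis_window(1.8, 11.5)),
               w256 * (m + 1) / 2, tolerance = 1e-12)

  ## all photons in the first in-window channel -> one channel width
  h <- numeric(256)
  first_in <- which(channel_times(tb256) >= 0.489)[1]
  h[first_in] <- 123
  expect_equal(empirical_lifetime(h, tb256), w256, tolerance = 1e-12)

  ## two equal spikes average their re-zeroed times
  h2 <- numeric(256)
  h2[first_in + c(10, 30)] <- 50
  expect_equal(empirical_lifetime(h2, tb256), w256 + 20 * w256,
               tolerance = 1e-12)

  expect_error(empirical_lifetime(numeric(256), tb256), "no photons")
  expect_error(analysis_window(5, 2))
  expect_error(empirical_lifetime(rep(1, 256), tb256,
                                  analysis_window(0.489, 20)),
               "beyond")
})

test_that("pure single-exponential lifetime matches the truncated mean", {
  ## delta IRF at channel 1 (identity, no anchoring shift), full window
  tb <- tb256
  delta <- load_irf_histogram(c(1, numeric(255)), tb)
  tc <- channel_centers(tb)
  h <- 1e6 * exp(-tc / 2.0)
  lt <- empirical_lifetime(h, tb, analysis_window(0, 12.5 - w256))
  ## the re-zero convention labels the first channel with one full channel
  ## width, half a width above its center: the metric sits exactly that
  ## half-width above the truncated-exponential mean
  expect_lt(abs(lt - truncated_exp_mean(2.0, 12.5)), w256 / 2 + 1e-3)
  expect_equal(lt, truncated_exp_mean(2.0, 12.5) + w256 / 2,
               tolerance = 1e-3)
})

test_that("fixed-tau fitting recovers noise-free parameters exactly", {
  for (p1 in c(0.3, 0.5, 0.7)) {
    truth <- oracle_model(tb256, irf_m, c(2.14, 0.69),
                          f0 = 4e4, p1 = p1, shg = 30, bg = 15)
    fit <- fit_double_exp(truth, irf_m, tb256, taus = c(2.14, 0.69))
    expect_true(fit$converged)
    expect_lt(abs(fit$p1 - p1), 1e-4)
    expect_equal(fit$f0, 4e4, tolerance = 1e-3)
    expect_equal(fit$background, 15, tolerance = 1e-3)
    expect_equal(fit$shg, 30, tolerance = 0.05)
  }
  expect_error(fit_double_exp(numeric(256), irf_m, tb256), "empty")
  expect_error(fit_double_exp(rep(1, 256), irf_m, tb256,
                              taus = c(2, 2)), "distinct")
})

test_that("fitting is invariant to uniform count scaling", {
  truth <- oracle_model(tb256, irf_m, c(2.14, 0.69), 3e4, 0.55, 10, 12)
  f1 <- fit_double_exp(truth, irf_m, tb256)
  f2 <- fit_double_exp(5 * truth, irf_m, tb256)
  expect_lt(abs(f1$p1 - f2$p1), 1e-5)
  expect_equal(f2$f0 / f1$f0, 5, tolerance = 1e-4)
  expect_equal(f2$background / f1$background, 5, tolerance = 1e-3)
})

test_that("a uniform offset moves only the fitted background", {
  truth <- oracle_model(tb256, irf_m, c(2.14, 0.69), 3e4, 0.55, 10, 12)
  f1 <- fit_double_exp(truth, irf_m, tb256)
  f2 <- fit_double_exp(truth + 50, irf_m, tb256)
  expect_equal(f2$background - f1$background, 50, tolerance = 1e-3)
  expect_lt(abs(f2$p1 - f1$p1), 1e-4)
})

test_that("Gauss-Newton agrees with a derivative-free optimizer", {
  set.seed(20)
  for (i in 1:20) {
    p1 <- runif(1, 0.35, 0.65)
    f0 <- runif(1, 5e3, 5e4)
    bg <- runif(1, 5, 40)
    mu <- oracle_model(tb256, irf_m, c(2.14, 0.69), f0, p1, 0, bg)
    y <- rpois(256, mu)
    fit <- fit_double_exp(y, irf_m, tb256)
    ## independent route: Nelder-Mead on the same least-squares objective
    idx <- which(channel_times(tb256) >= 0.489 & channel_times(tb256) <= 11.5)
    b1 <- oracle_model(tb256, irf_m, c(2.14, 0.69), 1, 1, 0, 0)
    b2 <- oracle_model(tb256, irf_m, c(2.14, 0.69), 1, 0, 0, 0)
    b3 <- oracle_model(tb256, irf_m, c(2.14, 0.69), 0, 0.5, 1, 0)
    obj <- function(par) {
      mu_w <- exp(par[1]) * (plogis(par[2]) * b1[idx] +
                               (1 - plogis(par[2])) * b2[idx]) +
        par[3] + par[4] * b3[idx]
      sum((y[idx] - mu_w)^2)
    }
    par <- c(log(f0), 0, bg, 0)
    for (restart in 1:4)
      par <- stats::optim(par, obj, method = "Nelder-Mead",
                          control = list(maxit = 5000,
                                         reltol = 1e-14))$par
    expect_lt(abs(fit$p1 - plogis(par[2])), 1e-3)
  }
})

test_that("free-tau fitting recovers the generating time constants", {
  truth <- oracle_model(tb256, irf_m, c(2.14, 0.69), 4e4, 0.5854, 0, 12)
  fit <- fit_double_exp(truth, irf_m, tb256, taus = c(1.8, 0.9),
                        free_tau = TRUE, max_iter = 300)
  expect_equal(fit$taus[1], 2.14, tolerance = 0.02)
  expect_equal(fit$taus[2], 0.69, tolerance = 0.02)
  expect_equal(fit$p1, 0.5854, tolerance = 5e-3)
})

test_that("photon counts per component follow the decomposition identity", {
  tb <- tb256
  tc <- channel_centers(tb)
  truth <- oracle_model(tb, irf_m, c(2.14, 0.69), 4e4, 1, 0, 5)
  fit <- fit_double_exp(truth, irf_m, tb)
  comps <- photons_per_component(fit, tb)
  ## P1 = 1: everything in component 1
  expect_lt(comps[["component2"]] / sum(comps), 1e-3)

  ## single-exponential toy: channel sum equals the geometric series
  f0 <- 1234.5; tau <- 2.0
  geo <- f0 * exp(-w256 / (2 * tau)) * (1 - exp(-256 * w256 / tau)) /
    (1 - exp(-w256 / tau))
  expect_equal(sum(f0 * exp(-tc / tau)), geo, tolerance = 1e-9)

  ## components sum to the F0-scaled model total (minus SHG and background)
  truth2 <- oracle_model(tb, irf_m, c(2.14, 0.69), 4e4, 0.6, 0, 8)
  fit2 <- fit_double_exp(truth2, irf_m, tb)
  comps2 <- photons_per_component(fit2, tb)
  expect_equal(sum(comps2),
               fit2$f0 * (fit2$p1 * sum(exp(-tc / 2.14)) +
                            fit2$p2 * sum(exp(-tc / 0.69))),
               tolerance = 1e-9)
})
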