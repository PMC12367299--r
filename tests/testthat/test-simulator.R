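cfg_small <- simulation_config(
  decay = decay_model("double", 2.14, 0.69, 0.5),
  n_sensor_photons = 60000, n_repeats = 5, seed = 101)

test_that("simulated histograms decompose exactly and are reproducible", {
  h <- simulate_histogram(cfg_small, 1)
  expect_equal(h$counts, colSums(h$breakdown))
  expect_equal(sum(h$breakdown["sensor", ]), 60000)
  expect_equal(sum(h$breakdown["afterpulse", ]), round(60000 * 0.0032))
  expect_true(sum(h$breakdown["autofluor", ]) >= 4332 &&
                sum(h$breakdown["autofluor", ]) <= 4788)

  ## determinism: same seed and repeat index give bit-identical histograms
  h2 <- simulate_histogram(cfg_small, 1)
  expect_identical(h$counts, h2$counts)
  h3 <- simulate_histogram(cfg_small, 2)
  expect_false(identical(h$counts, h3$counts))

  ## all noise flags off: the histogram is the convolved sensor sample only
  cfg_off <- simulation_config(
    decay = cfg_small$decay, n_sensor_photons = 60000, seed = 101,
    sources_enabled = c(autofluor = FALSE, afterpulse = FALSE,
                        background = FALSE))
  hoff <- simulate_histogram(cfg_off, 1)
  expect_equal(hoff$counts, as.numeric(hoff$breakdown["sensor", ]))
  expect_true(all(hoff$breakdown[c("autofluor", "afterpulse", "background"), ]
                  == 0))
})

test_that("hybrid detector presets have no afterpulse and a narrow IRF", {
  hbd <- detector_preset("hbd")
  expect_identical(hbd$afterpulse_ratio, 0)
  expect_identical(hbd$fwhm_ps, 120)
  expect_error(detector_preset("hbd", afterpulse_ratio = 0.001), "afterpulse")
  cfg <- simulation_config(detector = hbd, n_sensor_photons = 50000,
                           seed = 1)
  h <- simulate_histogram(cfg, 1)
  expect_true(all(h$breakdown["afterpulse", ] == 0))
})

test_that("grid runs tabulate every condition with means and STDs", {
  g <- run_grid(cfg_small, p1_values = 0.5, photon_values = 50000,
                n_repeats = 3)
  expect_equal(nrow(g$results), 3)
  expect_equal(nrow(g$summary), 1)
  expect_true(all(c("p1_fit", "empirical_lifetime_ns", "seed") %in%
                    names(g$results)))

  g21 <- run_grid(cfg_small, p1_values = seq(0.4, 0.6, by = 0.01),
                  photon_values = 20000, n_repeats = 2)
  expect_equal(nrow(g21$summary), 21)

  ## mean fitted P1 is monotone in the simulated P1
  g3 <- run_grid(cfg_small, p1_values = c(0.4, 0.5, 0.6),
                 photon_values = 100000, n_repeats = 40)
  m <- g3$summary$mean_p1_fit[order(g3$summary$p1_sim)]
  expect_true(all(diff(m) > 0))
  expect_error(run_grid(cfg_small, p1_values = numeric(0)), "empty")
})

test_that("fitted-P1 noise shrinks and bias follows the noise sources", {
  ## with autofluorescence on, fitted P1 is biased low and the bias
  ## shrinks as sensor photons grow; STDs shrink too
  g <- run_grid(cfg_small, p1_values = 0.5,
                photon_values = c(50000, 400000), n_repeats = 80)
  s <- g$summary[order(g$summary$photons), ]
  expect_lt(s$mean_p1_fit[1], 0.5)
  expect_lt(abs(s$mean_p1_fit[2] - 0.5), abs(s$mean_p1_fit[1] - 0.5))
  expect_lt(s$sd_p1_fit[2], s$sd_p1_fit[1])
  expect_lt(s$sd_lifetime_ns[2], s$sd_lifetime_ns[1])

  ## with every noise source off the fit is unbiased (within 2 SE)
  cfg_off <- simulation_config(
    decay = cfg_small$decay, n_sensor_photons = 100000, seed = 77,
    sources_enabled = c(autofluor = FALSE, afterpulse = FALSE,
                        background = FALSE))
  g0 <- run_grid(cfg_off, n_repeats = 80)
  se <- g0$summary$sd_p1_fit / sqrt(g0$summary$n - g0$summary$n_excluded)
  expect_lt(abs(g0$summary$mean_p1_fit - 0.5), 2 * se)
})

test_that("noise isolation separates photon noise from IRF noise", {
  cfg <- simulation_config(
    decay = decay_model("double", 2.14, 0.69, 0.5),
    n_sensor_photons = 100000, seed = 55)
  iso <- isolate_noise_sources(cfg, n_repeats = 60)
  sd_ph <- attr(iso$photon_sampling, "sd")
  sd_irf <- attr(iso$irf_sampling, "sd")
  expect_gt(sd_ph[["p1_fit"]], sd_irf[["p1_fit"]])
  expect_gt(sd_ph[["empirical_lifetime_ns"]],
            sd_irf[["empirical_lifetime_ns"]])

  ## a delta IRF leaves nothing to the IRF-sampling mode: STD exactly 0
  suppressWarnings({
    cfg_delta <- simulation_config(
      decay = cfg$decay, n_sensor_photons = 20000, seed = 55,
      detector = detector_preset("gaasp", fwhm_ps = 1e-3))
    iso0 <- isolate_noise_sources(cfg_delta, n_repeats = 10)
  })
  expect_identical(attr(iso0$irf_sampling, "sd")[["p1_fit"]], 0)

  ## reproducibility of both modes under the same seed
  iso2 <- isolate_noise_sources(cfg, n_repeats = 5)
  iso3 <- isolate_noise_sources(cfg, n_repeats = 5)
  expect_identical(iso2$photon_sampling$p1_fit, iso3$photon_sampling$p1_fit)
  expect_identical(iso2$irf_sampling$p1_fit, iso3$irf_sampling$p1_fit)
})

test_that("grid results round-trip through the results writer", {
  g <- run_grid(cfg_small, p1_values = 0.5, photon_values = 30000,
                n_repeats = 2)
  dir <- withr::local_tempdir()
  write_grid_results(g, dir)
  expect_true(file.exists(file.path(dir, "grid_results.tsv")))
  back <- utils::read.table(file.path(dir, "grid_results.tsv"),
                            header = TRUE, sep = "\t")
  expect_equal(nrow(back), 2)
  expect_equal(back$p1_fit, g$results$p1_fit, tolerance = 1e-6)
  side <- jsonlite::read_json(file.path(dir, "grid_config.json"))
  expect_equal(side$seed, 101)
  expect_equal(side$decay$tau1_ns, 2.14)
})

test_that("config files reconstruct an equivalent simulation", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "decay:", "  kind: double", "  tau1_ns: 2.14", "  tau2_ns: 0.69",
    "  p1: 0.55", "n_sensor_photons: 40000", "seed: 9",
    "n_repeats: 3", "detector: hbd"), path)
  cfg <- simulation_config_from_file(path)
  expect_equal(cfg$decay$p1, 0.55)
  expect_identical(cfg$detector$name, "hbd")
  expect_equal(cfg$noise$afterpulse_ratio, 0)
  h <- simulate_histogram(cfg, 1)
  expect_equal(sum(h$breakdown["sensor", ]), 40000)
})
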