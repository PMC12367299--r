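#' Two-sensor multiplexing configuration
#'
#' Two intensity-modulated sensors of the same color but different
#' single-exponential lifetimes are imaged together on a 50 ns laser cycle
#' (long enough to capture the slower decay); their combined histogram is
#' later deconvolved by fixed-tau double-exponential fitting.  The channel
#' width is kept equal to the 256-channel / 12.5 ns base, giving 1024
#' channels, and the autofluorescence and background counts are scaled
#' 3.2-fold to reflect the longer acquisition time a 50 ns cycle needs to
#' collect the same sensor photons.
#'
#' @param tau1_ns sensor-1 decay constant (default 2.0 ns).
#' @param tau2_ns sensor-2 decay constant, larger than `tau1_ns`
#'   (reference values 2.5, 3.0, 3.5, 4.0 or 6.0 ns).
#' @param n_photons_sensor1,n_photons_sensor2 detected photons per sensor.
#' @param noise a [noise_model()]; its `noise_scale` is forced to
#'   `noise_scale`.
#' @param noise_scale count multiplier for autofluorescence and
#'   background (default 3.2).
#' @param time_base the 50 ns cycle (default 1024 channels / 50 ns).
#' @param detector a [detector_preset()].
#' @param n_repeats repeats per condition (default 500).
#' @param seed master seed.
#' @param sources_enabled named logical flags as in [simulation_config()].
#' @return an object of class `flim_multiplex_config`.
#' @export
multiplex_config <- function(tau1_ns = 2.0, tau2_ns = 2.5,
                             n_photons_sensor1 = 800000,
                             n_photons_sensor2 = 500000,
                             noise = noise_model(), noise_scale = 3.2,
                             time_base = flimsim::time_base(1024L, 50),
                             detector = detector_preset("gaasp"),
                             n_repeats = 500L, seed = 1L,
                             sources_enabled = c(autofluor = TRUE,
                                                 afterpulse = TRUE,
                                                 background = TRUE)) {
  if (!(tau2_ns > tau1_ns) || tau1_ns <= 0)
    stop("need tau2_ns > tau1_ns > 0")
  if (n_photons_sensor1 < 0 || n_photons_sensor2 < 0)
    stop("photon counts must be non-negative")
  stopifnot(inherits(noise, "flim_noise_model"),
            inherits(time_base, "flim_time_base"),
            inherits(detector, "flim_detector"))
  noise$noise_scale <- noise_scale
  noise$afterpulse_ratio <- detector$afterpulse_ratio
  flags <- c(autofluor = TRUE, afterpulse = TRUE, background = TRUE)
  flags[names(sources_enabled)] <- sources_enabled
  peak <- max(1L, round(time_base$n_channels * 0.025))
  irf <- make_gaussian_irf(detector$fwhm_ps, peak, time_base)
  pop1 <- build_decay_population(decay_model("single", tau1_ns), time_base)
  pop2 <- build_decay_population(decay_model("single", tau2_ns), time_base)
  structure(
    list(tau1_ns = tau1_ns, tau2_ns = tau2_ns,
         n_photons_sensor1 = as.integer(n_photons_sensor1),
         n_photons_sensor2 = as.integer(n_photons_sensor2),
         noise = noise, time_base = time_base, detector = detector,
         irf = irf, population1 = pop1, population2 = pop2,
         n_repeats = as.integer(n_repeats), seed = as.integer(seed),
         sources_enabled = flags,
         window = analysis_window(0.489, 0.92 * time_base$cycle_ns)),
    class = "flim_multiplex_config"
  )
}

#' Simulate a combined two-sensor histogram
#'
#' Samples and IRF-convolves each sensor independently, adds the two
#' histograms, then appends autofluorescence and background at the scaled
#' counts and afterpulse proportional to the summed sensor photons.
#'
#' @param config a [multiplex_config()].
#' @param repeat_index repeat number (seeds the sub-stream).
#' @return a `flim_simulated_histogram` whose breakdown rows are
#'   `sensor1`, `sensor2`, `autofluor`, `afterpulse`, `background`.
#' @export
simulate_combined_histogram <- function(config, repeat_index = 1L) {
  stopifnot(inherits(config, "flim_multiplex_config"))
  tb <- config$time_base
  n <- tb$n_channels
  sub_seed <- derive_seed(config$seed, 3L, repeat_index)
  set.seed(sub_seed)
  shift <- config$irf$peak_channel - 1L
  anchor <- function(arr) ((arr - 1L + shift) %% n) + 1L
  s1 <- tabulate(convolve_photons_with_irf(
    anchor(sample_photons(config$population1, config$n_photons_sensor1)),
    config$irf, tb), nbins = n)
  s2 <- tabulate(convolve_photons_with_irf(
    anchor(sample_photons(config$population2, config$n_photons_sensor2)),
    config$irf, tb), nbins = n)
  n_sensor <- config$n_photons_sensor1 + config$n_photons_sensor2
  autof <- if (config$sources_enabled[["autofluor"]])
    tabulate(sample_autofluorescence(config$noise, tb, config$irf), nbins = n)
  else numeric(n)
  after <- if (config$sources_enabled[["afterpulse"]])
    tabulate(sample_afterpulse(n_sensor, config$noise, tb), nbins = n)
  else numeric(n)
  bg <- if (config$sources_enabled[["background"]])
    tabulate(sample_background(config$noise, tb), nbins = n)
  else numeric(n)
  breakdown <- rbind(sensor1 = s1, sensor2 = s2, autofluor = autof,
                     afterpulse = after, background = bg)
  structure(
    list(counts = colSums(breakdown), breakdown = breakdown,
         config = config, repeat_index = as.integer(repeat_index),
         seed = sub_seed),
    class = "flim_simulated_histogram"
  )
}

#' Deconvolve a combined histogram into per-sensor photon counts
#'
#' Fits the combined histogram with the fixed-tau double-exponential model
#' (time constants equal to the two sensors' decay constants) and converts
#' the fitted amplitudes into per-sensor photon counts with
#' [photons_per_component()].
#'
#' @param hist a `flim_simulated_histogram` (or raw counts).
#' @param config a [multiplex_config()].
#' @return named vector `c(sensor1, sensor2, converged)` where the counts
#'   are fitted photons (sensor 1 = shorter lifetime).
#' @export
deconvolve_two_sensors <- function(hist, config) {
  stopifnot(inherits(config, "flim_multiplex_config"))
  counts <- if (inherits(hist, "flim_simulated_histogram")) hist$counts
  else hist
  ## SHG fixed at 0: simulated combined histograms carry no SHG component
  fit <- fit_double_exp(counts, config$irf, config$time_base,
                        taus = c(config$tau1_ns, config$tau2_ns),
                        window = config$window, fit_shg = FALSE)
  comps <- photons_per_component(fit, config$time_base)
  c(sensor1 = unname(comps[1]), sensor2 = unname(comps[2]),
    converged = as.numeric(fit$converged))
}

#' Statistical power to detect an intensity change
#'
#' `beta = 1 - pnorm(1.96 - delta_photons / se_diff)`: the power of a 5%
#' two-sided test to detect an intensity (photon-count) change
#' `delta_photons` when the fitted-count difference has standard error
#' `se_diff`.
#'
#' @param delta_photons intensity change to detect (photons).
#' @param se_diff standard error of the fitted-count difference.
#' @return power in `[0, 1]`.
#' @export
detection_power <- function(delta_photons, se_diff) {
  if (any(se_diff <= 0)) stop("se_diff must be positive")
  1 - stats::pnorm(1.96 - delta_photons / se_diff)
}

## 5PL evaluation: beta(x) = D + (A - D) / (1 + (x/C)^B)^E
logistic5 <- function(x, A, B, C, D, E) D + (A - D) / (1 + (x / C)^B)^E

#' Fit a 5-parameter logistic power curve
#'
#' Fits `beta = D + (A - D) / (1 + (dff/C)^B)^E` to a power-versus-dF/F0
#' curve by nonlinear least squares (multi-start Levenberg-Marquardt,
#' initialized from the data extremes), and solves the fitted curve for
#' `beta = 0.8` to obtain the minimum detectable dF/F0.
#'
#' @param dff_values fractional intensity changes (dF/F0, > 0).
#' @param power_values detection power at each `dff` value.
#' @param target_power power level defining detectability (default 0.8).
#' @return an object of class `flim_power_curve`: list with
#'   `logistic_params` (A, B, C, D, E), `min_detectable_dff`, the input
#'   data and `fitted` values.
#' @export
fit_power_logistic <- function(dff_values, power_values,
                               target_power = 0.8) {
  stopifnot(length(dff_values) == length(power_values))
  if (length(dff_values) < 6)
    stop("need at least 6 points spanning the rise of the power curve")
  if (any(dff_values <= 0)) stop("dff values must be positive")
  if (stats::sd(power_values) < 1e-4)
    stop("power curve is degenerate (nearly constant)")
  ord <- order(dff_values)
  x <- dff_values[ord]
  yv <- power_values[ord]
  dat <- data.frame(x = x, y = yv)
  a0 <- min(yv)
  d0 <- max(yv)
  c0 <- x[which.min(abs(yv - (a0 + d0) / 2))]
  starts <- list(c(B = 1, C = c0, E = 1),
                 c(B = 2, C = c0, E = 1),
                 c(B = 1, C = stats::median(x), E = 2))
  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ logistic5(x, A, B, C, D, E), data = dat,
        start = list(A = a0, B = st[["B"]], C = st[["C"]],
                     D = d0, E = st[["E"]]),
        lower = c(A = 0, B = 1e-3, C = 1e-6, D = 0, E = 1e-3),
        upper = c(A = 1, B = 50, C = 100, D = 1.5, E = 50),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      rss <- sum(stats::resid(fit)^2)
      if (is.null(best) || rss < best$rss)
        best <- list(fit = fit, rss = rss)
    }
  }
  if (is.null(best)) {
    ## steep curves with few points on the rise cannot support all five
    ## parameters: pin the plateaus at the data extremes and fit B, C, E
    for (st in starts) {
      fit <- tryCatch(
        minpack.lm::nlsLM(
          y ~ logistic5(x, a0, B, C, d0, E), data = dat,
          start = list(B = st[["B"]], C = st[["C"]], E = st[["E"]]),
          lower = c(B = 1e-3, C = 1e-6, E = 1e-3),
          upper = c(B = 50, C = 100, E = 50),
          control = minpack.lm::nls.lm.control(maxiter = 200)),
        error = function(e) NULL)
      if (!is.null(fit)) {
        rss <- sum(stats::resid(fit)^2)
        if (is.null(best) || rss < best$rss)
          best <- list(fit = fit, rss = rss, pinned = TRUE)
      }
    }
  }
  if (is.null(best)) stop("5PL fit failed from all starts")
  p <- as.list(stats::coef(best$fit))
  if (!is.null(best$pinned)) p <- c(p, list(A = a0, D = d0))
  p <- p[c("A", "B", "C", "D", "E")]
  mdd <- solve_logistic5(p, target_power)
  structure(
    list(logistic_params = unlist(p), min_detectable_dff = mdd,
         target_power = target_power, dff_values = x, power_values = yv,
         fitted = logistic5(x, p$A, p$B, p$C, p$D, p$E)),
    class = "flim_power_curve"
  )
}

## invert the 5PL at a given power level (increasing curve: A low, D high)
solve_logistic5 <- function(p, beta) {
  if (beta <= min(p$A, p$D) || beta >= max(p$A, p$D)) return(NA_real_)
  base <- ((p$A - p$D) / (beta - p$D))^(1 / p$E) - 1
  if (base <= 0) return(NA_real_)
  p$C * base^(1 / p$B)
}

#' @export
print.flim_power_curve <- function(x, ...) {
  cat(sprintf(
    "<5PL power curve: min detectable dF/F0 at %.0f%% power = %.3g>\n",
    100 * x$target_power, x$min_detectable_dff))
  invisible(x)
}

#' Power curve for detecting sensor-1 intensity changes
#'
#' Simulates repeats at the sensor-1 baseline and at
#' `baseline * (1 + dff)` for every value of a dF/F0 ladder, deconvolves
#' every histogram, and converts the fitted sensor-1 count distributions
#' into detection power via [detection_power()]: the intensity change is
#' the difference of the fitted means, its standard error
#' `sqrt(s_base^2 + s_changed^2) / sqrt(n_group)` with `n_group = 1` by
#' default (single-measurement detection).  The resulting curve is
#' summarized with [fit_power_logistic()].
#'
#' @param config a [multiplex_config()].
#' @param dff_ladder dF/F0 values; default a geometric ladder from 0.2%
#'   to 100%.
#' @param n_repeats repeats per point (default: the config's).
#' @param n_group comparison group size entering the SE (default 1).
#' @param target_power power level defining detectability.
#' @return a `flim_power_curve` with an extra `detail` data.frame
#'   (per-dff fitted means, STDs and power).
#' @export
multiplex_power_curve <- function(config, dff_ladder = NULL,
                                  n_repeats = NULL, n_group = 1,
                                  target_power = 0.8) {
  stopifnot(inherits(config, "flim_multiplex_config"))
  n_repeats <- n_repeats %||% config$n_repeats
  dff_ladder <- dff_ladder %||%
    exp(seq(log(0.002), log(1), length.out = 12))
  fitted_counts <- function(cfg, seed_tag) {
    cfg$seed <- derive_seed(config$seed, 4L, seed_tag)
    out <- vapply(seq_len(n_repeats), function(r) {
      deconvolve_two_sensors(simulate_combined_histogram(cfg, r), cfg)
    }, numeric(3))
    ok <- out[3, ] > 0
    out[1, ok]
  }
  base <- fitted_counts(config, 0L)
  detail <- data.frame(dff = dff_ladder, delta_fit = NA_real_,
                       se_diff = NA_real_, power = NA_real_)
  for (i in seq_along(dff_ladder)) {
    cfg <- config
    cfg$n_photons_sensor1 <-
      as.integer(round(config$n_photons_sensor1 * (1 + dff_ladder[i])))
    ch <- fitted_counts(cfg, i)
    delta <- mean(ch) - mean(base)
    se <- sqrt(stats::sd(base)^2 + stats::sd(ch)^2) / sqrt(n_group)
    detail$delta_fit[i] <- delta
    detail$se_diff[i] <- se
    detail$power[i] <- detection_power(delta, se)
  }
  curve <- fit_power_logistic(detail$dff, detail$power,
                              target_power = target_power)
  curve$detail <- detail
  curve
}

#' Minimum detectable dF/F0 over a parameter grid
#'
#' Tabulates the 5PL-derived minimum detectable sensor-1 intensity change
#' over grids of sensor-1 baseline, sensor-2 photons and sensor-2 decay
#' constant (lifetime separation).  Each cell runs a full
#' [multiplex_power_curve()].
#'
#' @param sensor1_baselines,sensor2_photons,tau2_values grids.
#' @param tau1_ns sensor-1 decay constant.
#' @param n_repeats repeats per dff point.
#' @param dff_ladder dF/F0 ladder passed through.
#' @param seed master seed.
#' @param ... further arguments to [multiplex_config()].
#' @return data.frame with one row per cell: the grids, lifetime
#'   separation and `min_detectable_dff` (`NA` where the 5PL fit failed).
#' @export
min_dff_surface <- function(sensor1_baselines, sensor2_photons,
                            tau2_values, tau1_ns = 2.0, n_repeats = 200L,
                            dff_ladder = NULL, seed = 1L, ...) {
  cells <- expand.grid(n1 = sensor1_baselines, n2 = sensor2_photons,
                       tau2 = tau2_values)
  out <- lapply(seq_len(nrow(cells)), function(i) {
    cfg <- multiplex_config(
      tau1_ns = tau1_ns, tau2_ns = cells$tau2[i],
      n_photons_sensor1 = cells$n1[i], n_photons_sensor2 = cells$n2[i],
      n_repeats = n_repeats, seed = derive_seed(seed, 5L, i), ...)
    mdd <- tryCatch(
      multiplex_power_curve(cfg, dff_ladder = dff_ladder,
                            n_repeats = n_repeats)$min_detectable_dff,
      error = function(e) NA_real_)
    data.frame(sensor1_baseline = cells$n1[i],
               sensor2_photons = cells$n2[i],
               tau1_ns = tau1_ns, tau2_ns = cells$tau2[i],
               tau_separation_ns = cells$tau2[i] - tau1_ns,
               min_detectable_dff = mdd)
  })
  do.call(rbind, out)
}
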