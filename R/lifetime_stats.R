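#' Power multiplier for a two-sided test
#'
#' `z = qnorm(1 - alpha/2) + qnorm(power)`, the multiplier entering the
#' minimum-detectable-difference formula.  At the conventional 5%
#' significance and 80% power this is 2.8016 (commonly printed as 2.806).
#'
#' @param alpha two-sided significance level in (0, 1).
#' @param power target power in (0, 1).
#' @return the multiplier.
#' @examples
#' z_for_power(0.05, 0.8)
#' @export
z_for_power <- function(alpha = 0.05, power = 0.8) {
  if (!is.finite(alpha) || alpha <= 0 || alpha >= 1)
    stop("alpha must lie in (0, 1)")
  if (!is.finite(power) || power <= 0 || power >= 1)
    stop("power must lie in (0, 1)")
  stats::qnorm(1 - alpha / 2) + stats::qnorm(power)
}

#' Minimum detectable difference from a simulation STD
#'
#' `MDD = z * sqrt(2) * STD / sqrt(n)`: the smallest difference between
#' two groups of `n` paired measurements detectable at the power and
#' significance encoded in `z`, under the equal-variance simplification
#' (the STDs of the lifetime metrics are nearly identical across nearby
#' `P1` conditions, so a single condition's STD is used for both groups).
#'
#' @param std metric STD across simulation repeats (fitted-P1 units or ns).
#' @param n_pairs number of data pairs per comparison group (>= 1).
#' @param z power multiplier, see [z_for_power()].
#' @return the MDD in the metric's units.
#' @export
mdd_from_std <- function(std, n_pairs, z = z_for_power()) {
  if (any(std < 0)) stop("std must be non-negative")
  if (any(n_pairs < 1)) stop("n_pairs must be >= 1")
  z * sqrt(2) * std / sqrt(n_pairs)
}

#' MDD curves from a simulation grid summary
#'
#' Converts the per-condition STDs of a [run_grid()] summary (simulated at
#' a single `P1`, typically 0.5, under the full noise model) into MDD
#' curves over sensor photon number, one per metric and per number of
#' pairs.
#'
#' @param summary a `flim_grid` or its `summary` data.frame (columns
#'   `photons`, `sd_p1_fit`, `sd_lifetime_ns`).
#' @param n_list numbers of pairs to tabulate (e.g. `c(1, 3, 5, 10)`).
#' @param z power multiplier.
#' @return data.frame with columns `metric`, `n_pairs`, `photons`, `std`,
#'   `mdd` (lifetime rows are in ns).
#' @export
build_mdd_curves <- function(summary, n_list = c(1, 3, 5, 10),
                             z = z_for_power()) {
  if (inherits(summary, "flim_grid")) summary <- summary$summary
  need <- c("photons", "sd_p1_fit", "sd_lifetime_ns")
  if (!all(need %in% names(summary)))
    stop("summary must contain columns ", paste(need, collapse = ", "))
  if (any(!is.finite(summary$sd_p1_fit)) ||
      any(!is.finite(summary$sd_lifetime_ns)))
    stop("summary contains conditions without valid STDs")
  grid <- expand.grid(metric = c("fitted_p1", "empirical_lifetime"),
                      n_pairs = n_list, i = seq_len(nrow(summary)),
                      stringsAsFactors = FALSE)
  std <- ifelse(grid$metric == "fitted_p1",
                summary$sd_p1_fit[grid$i], summary$sd_lifetime_ns[grid$i])
  data.frame(metric = grid$metric, n_pairs = grid$n_pairs,
             photons = summary$photons[grid$i], std = std,
             mdd = mdd_from_std(std, grid$n_pairs, z))
}

#' Threshold of statistical significance for a metric change
#'
#' `1.96 * sqrt(std_a^2 / n + std_b^2 / n)`: the smallest difference in
#' group means that a two-sample test at 5% significance would call
#' significant, given the group STDs and per-group sample size.  Used to
#' judge whether a sensor-expression-induced apparent lifetime change is
#' statistically detectable.
#'
#' @param std_a,std_b the two group STDs.
#' @param n_per_group per-group sample size (>= 2).
#' @param z_crit critical value (1.96 for 5% two-sided).
#' @return the threshold in the metric's units.
#' @export
significance_change_threshold <- function(std_a, std_b, n_per_group,
                                          z_crit = 1.96) {
  if (any(std_a < 0) || any(std_b < 0)) stop("stds must be non-negative")
  if (any(n_per_group < 2)) stop("n_per_group must be >= 2")
  z_crit * sqrt(std_a^2 / n_per_group + std_b^2 / n_per_group)
}

#' Minimum photon count where an apparent change stops being significant
#'
#' Finds the first crossing of a decreasing apparent-change curve with a
#' significance-threshold curve over a shared photon grid, interpolating
#' linearly with both axes on a log scale (exact when the curves are power
#' laws).  If the apparent change is below the threshold everywhere the
#' smallest grid value is returned (boundary convention); if it never
#' drops below the threshold the crossing lies outside the simulated range
#' and `NA` is returned with a warning.
#'
#' @param photons increasing photon grid (> 0).
#' @param apparent_change apparent metric change per photon count (> 0).
#' @param threshold significance threshold per photon count (> 0).
#' @return the interpolated minimum photon count, or `NA`.
#' @export
min_photons_for_tolerance <- function(photons, apparent_change, threshold) {
  stopifnot(length(photons) == length(apparent_change),
            length(photons) == length(threshold))
  if (any(photons <= 0) || is.unsorted(photons, strictly = TRUE))
    stop("photons must be a strictly increasing positive grid")
  if (any(apparent_change <= 0) || any(threshold <= 0))
    stop("curves must be positive for log-log interpolation")
  below <- apparent_change <= threshold
  if (below[1]) return(photons[1])
  if (!any(below)) {
    warning("apparent change stays above the threshold: ",
            "crossing lies outside the simulated photon range")
    return(NA_real_)
  }
  i <- which(below)[1]
  ## log-log linear interpolation of the sign change of log(app) - log(thr)
  d0 <- log(apparent_change[i - 1]) - log(threshold[i - 1])
  d1 <- log(apparent_change[i]) - log(threshold[i])
  frac <- d0 / (d0 - d1)
  exp(log(photons[i - 1]) + frac * (log(photons[i]) - log(photons[i - 1])))
}

#' Sensor-expression tolerance analysis
#'
#' How much can sensor expression (photon count) change before the
#' apparent lifetime change becomes statistically significant?  For each
#' expression change `delta` the apparent change of each metric between
#' simulations at `N` and `N + delta` sensor photons (same simulated `P1`)
#' is compared with the significance threshold across the photon grid, and
#' the crossing gives the minimum sensor photons required to tolerate that
#' `delta`.
#'
#' @param config a [simulation_config()] (fixed `P1`, full noise model).
#' @param photon_values baseline sensor-photon grid.
#' @param delta_photons expression changes to evaluate (photon counts).
#' @param n_repeats repeats per condition (default: the config's).
#' @param n_per_group sample size entering the threshold; defaults to
#'   `n_repeats` (the simulation-distribution reading), set it to an
#'   experimental group size to model real designs.
#' @return an object of class `flim_tolerance`: list with `curves` (per
#'   delta and metric: apparent change and threshold over the grid) and
#'   `tolerance` (per delta and metric: minimum sensor photons).
#' @export
expression_change_analysis <- function(config, photon_values, delta_photons,
                                       n_repeats = NULL,
                                       n_per_group = NULL) {
  stopifnot(inherits(config, "flim_simulation_config"))
  n_repeats <- n_repeats %||% config$n_repeats
  n_per_group <- n_per_group %||% n_repeats
  all_photons <- sort(unique(c(
    photon_values,
    as.vector(outer(photon_values, delta_photons, `+`)))))
  grid <- run_grid(config, p1_values = config$decay$p1,
                   photon_values = all_photons, n_repeats = n_repeats)
  s <- grid$summary
  look <- function(nph, col) s[[col]][match(nph, s$photons)]
  curves <- list()
  tol <- list()
  for (delta in delta_photons) {
    for (metric in c("fitted_p1", "empirical_lifetime")) {
      mcol <- if (metric == "fitted_p1") "mean_p1_fit" else "mean_lifetime_ns"
      scol <- if (metric == "fitted_p1") "sd_p1_fit" else "sd_lifetime_ns"
      apparent <- abs(look(photon_values, mcol) -
                        look(photon_values + delta, mcol))
      threshold <- significance_change_threshold(
        look(photon_values, scol), look(photon_values + delta, scol),
        n_per_group)
      curves[[length(curves) + 1L]] <- data.frame(
        delta_photons = delta, metric = metric, photons = photon_values,
        apparent_change = apparent, threshold = threshold)
      min_ph <- tryCatch(
        min_photons_for_tolerance(photon_values, pmax(apparent, 1e-12),
                                  pmax(threshold, 1e-12)),
        warning = function(w) NA_real_)
      tol[[length(tol) + 1L]] <- data.frame(
        delta_photons = delta, metric = metric,
        min_sensor_photons = min_ph)
    }
  }
  structure(list(curves = do.call(rbind, curves),
                 tolerance = do.call(rbind, tol),
                 grid = grid),
            class = "flim_tolerance")
}
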