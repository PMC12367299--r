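#' Analysis window for lifetime metrics
#'
#' Channels whose label time falls in `[start_ns, end_ns]` are retained for
#' fitting and empirical-lifetime calculation, and times are re-zeroed so
#' the first retained channel carries `rezero_ns` (one channel width,
#' 0.0488 ns on the 256-channel / 12.5 ns base).  The standard window is
#' 0.489-11.5 ns; 1.8-11.5 ns is used when the histogram edges must be
#' avoided (e.g. comparison against measured data).
#'
#' @param start_ns,end_ns window bounds in ns.
#' @param rezero_ns time assigned to the first in-window channel; `NULL`
#'   means one channel width of the time base in use.
#' @return an object of class `flim_window`.
#' @export
analysis_window <- function(start_ns = 0.489, end_ns = 11.5,
                            rezero_ns = NULL) {
  if (!is.finite(start_ns) || !is.finite(end_ns) ||
      start_ns < 0 || end_ns <= start_ns)
    stop("need 0 <= start_ns < end_ns")
  structure(list(start_ns = start_ns, end_ns = end_ns,
                 rezero_ns = rezero_ns),
            class = "flim_window")
}

## indices of channels whose label time lies in the window
window_channels <- function(tb, window) {
  stopifnot(inherits(tb, "flim_time_base"), inherits(window, "flim_window"))
  if (window$end_ns > tb$cycle_ns)
    stop("analysis window extends beyond the laser cycle")
  t <- channel_times(tb)
  which(t >= window$start_ns & t <= window$end_ns)
}

## re-zeroed times of the in-window channels
window_times <- function(tb, window) {
  idx <- window_channels(tb, window)
  rz <- window$rezero_ns %||% tb$channel_width_ns
  rz + (seq_along(idx) - 1) * tb$channel_width_ns
}

#' Empirical lifetime of a histogram
#'
#' Photon-weighted mean arrival time `sum(F(t) * t) / sum(F(t))` over the
#' analysis window, with in-window times re-zeroed per the window
#' convention.  This is the fitting-free lifetime readout.
#'
#' @param counts per-channel photon counts (full cycle), or a
#'   `flim_simulated_histogram`.
#' @param tb a [time_base()].
#' @param window an [analysis_window()].
#' @return lifetime in ns.
#' @examples
#' tb <- time_base()
#' empirical_lifetime(rep(1, 256), tb, analysis_window(1.8, 11.5))
#' @export
empirical_lifetime <- function(counts, tb, window = analysis_window()) {
  if (inherits(counts, "flim_simulated_histogram")) counts <- counts$counts
  if (length(counts) != tb$n_channels)
    stop("counts length does not match the time base")
  idx <- window_channels(tb, window)
  f <- counts[idx]
  if (sum(f) <= 0) stop("no photons in the analysis window")
  sum(f * window_times(tb, window)) / sum(f)
}

## transform keeping P1 in [0, 1]
logistic <- function(x) 1 / (1 + exp(-x))

## anchored analytic convolution: curve defined with its time origin at the
## IRF peak channel, blurred by the IRF offset kernel (the model-side twin
## of the simulator's anchoring)
conv_anchored <- function(x, irf) {
  rotate_channels(convolve_histogram_analytic(x, irf),
                  irf$peak_channel - 1L)
}

## convolved model bases: decay components and the SHG spike, circularly
## convolved with the IRF and anchored at the IRF peak channel (= time 0)
fit_bases <- function(taus, irf, tb) {
  tc <- channel_centers(tb)
  d1 <- exp(-tc / taus[1])
  d2 <- exp(-tc / taus[2])
  spike <- c(1, rep(0, tb$n_channels - 1L))
  list(c1 = conv_anchored(d1, irf),
       c2 = conv_anchored(d2, irf),
       c3 = conv_anchored(spike, irf))
}

#' Fixed-tau double-exponential fit of a lifetime histogram
#'
#' Fits the measured histogram with
#' \deqn{F(t) = [F_0 (P_1 e^{-t/\tau_1} + P_2 e^{-t/\tau_2}) + SHG]
#'       \otimes IRF + F_{background}}
#' by Gauss-Newton nonlinear least squares over the analysis window, with
#' the time constants held fixed (free-tau fitting is available for
#' parameter determination from measured data).  Free parameters are
#' `F0`, `P1` (with `P2 = 1 - P1`), the second-harmonic-generation spike
#' amplitude `SHG` (an instantaneous signal at time 0), and the uniform
#' `background` level.  `P1` is fitted on a logistic scale (so it stays in
#' `[0, 1]`) and `F0` on a log scale (positive total intensity); the `SHG`
#' and `background` amplitudes enter linearly and unconstrained, as in
#' plain Gauss-Newton fitting, so on noisy data they may come back
#' slightly negative when their true value is zero — constraining them
#' would bias `P1` upward whenever they sit at the zero boundary.  A
#' Levenberg damping fallback is applied whenever a plain Gauss-Newton
#' step would increase the residual.
#'
#' @param counts per-channel photon counts (full cycle) or a
#'   `flim_simulated_histogram`.
#' @param irf a `flim_irf` on the same time base.
#' @param tb a [time_base()].
#' @param taus length-2 vector of fixed time constants in ns (slow first).
#' @param window an [analysis_window()].
#' @param init optional named list overriding the data-driven starting
#'   values (`f0`, `p1`, `shg`, `background`).
#' @param weights `"none"` (plain least squares, the default) or
#'   `"poisson"` (weights `1/max(y, 1)`).
#' @param fit_shg if `FALSE` the SHG spike amplitude is fixed at 0 instead
#'   of fitted.  Fit it for measured two-photon data, where second
#'   harmonic generation is real; fix it when analyzing simulated
#'   histograms, which contain no SHG component by construction — a free
#'   SHG term only inflates the variance of the other parameters there.
#' @param free_tau if `TRUE` the time constants are fitted too (log scale).
#' @param tol relative residual-norm change declaring convergence.
#' @param max_iter iteration cap.
#' @return an object of class `flim_fit` with fields `f0`, `p1`, `p2`,
#'   `shg`, `background`, `taus`, `converged`, `residual_norm`,
#'   `n_iterations`, `n_damped` and `fitted` (full-cycle model curve).
#' @examples
#' cfg <- simulation_config(n_sensor_photons = 50000, n_repeats = 1)
#' h <- simulate_histogram(cfg, 1)
#' fit <- fit_double_exp(h, cfg$irf, cfg$time_base, taus = c(2.14, 0.69))
#' fit$p1
#' @export
fit_double_exp <- function(counts, irf, tb, taus = c(2.14, 0.69),
                           window = analysis_window(), init = NULL,
                           weights = c("none", "poisson"),
                           fit_shg = TRUE, free_tau = FALSE,
                           tol = 1e-8, max_iter = 100L) {
  weights <- match.arg(weights)
  if (inherits(counts, "flim_simulated_histogram")) counts <- counts$counts
  stopifnot(inherits(irf, "flim_irf"), inherits(tb, "flim_time_base"))
  if (length(counts) != tb$n_channels)
    stop("counts length does not match the time base")
  if (sum(counts) <= 0) stop("cannot fit an empty histogram")
  if (length(taus) != 2L || any(taus <= 0) || taus[1] == taus[2])
    stop("taus must be two distinct positive time constants")
  idx <- window_channels(tb, window)
  y <- counts[idx]
  w <- if (weights == "poisson") 1 / pmax(y, 1) else rep(1, length(y))
  sw <- sqrt(w)

  ## data-driven starting values
  m_tail <- min(10L, length(idx))
  bg0 <- max(mean(y[(length(y) - m_tail + 1L):length(y)]), 1e-3)
  p10 <- 0.5
  bases0 <- fit_bases(taus, irf, tb)
  mix0 <- (p10 * bases0$c1 + (1 - p10) * bases0$c2)[idx]
  f00 <- max((sum(y) - bg0 * length(y)) / max(sum(mix0), 1e-12), 1e-3)
  shg0 <- if (fit_shg) 1e-2 else 0
  if (!is.null(init)) {
    f00 <- init$f0 %||% f00
    p10 <- init$p1 %||% p10
    bg0 <- init$background %||% bg0
    if (fit_shg) shg0 <- init$shg %||% shg0
  }
  theta0 <- c(log(f00), stats::qlogis(min(max(p10, 1e-6), 1 - 1e-6)),
              shg0, bg0)
  if (free_tau) theta0 <- c(theta0, log(taus))
  active <- c(TRUE, TRUE, fit_shg, TRUE, rep(free_tau, 2 * free_tau))

  unpack <- function(theta) {
    list(f0 = exp(theta[1]), p1 = logistic(theta[2]),
         shg = theta[3], bg = theta[4],
         taus = if (free_tau) exp(theta[5:6]) else taus)
  }
  model_parts <- function(pp) {
    bases <- if (free_tau) fit_bases(pp$taus, irf, tb) else bases0
    mu <- pp$f0 * (pp$p1 * bases$c1[idx] + (1 - pp$p1) * bases$c2[idx]) +
      pp$shg * bases$c3[idx] + pp$bg
    list(mu = mu, bases = bases)
  }
  rss_of <- function(theta) {
    pp <- unpack(theta)
    r <- y - model_parts(pp)$mu
    sum(w * r^2)
  }

  gn_run <- function(theta) {
  rss <- rss_of(theta)
  converged <- FALSE
  n_damped <- 0L
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    pp <- unpack(theta)
    mp <- model_parts(pp)
    mu <- mp$mu
    b <- mp$bases
    r <- y - mu
    ## Jacobian of mu wrt transformed parameters
    J <- cbind(
      f0 = pp$f0 * (pp$p1 * b$c1[idx] + (1 - pp$p1) * b$c2[idx]),
      p1 = pp$f0 * pp$p1 * (1 - pp$p1) * (b$c1[idx] - b$c2[idx]),
      shg = b$c3[idx],
      bg = rep(1, length(idx))
    )
    if (free_tau) {
      tc <- channel_centers(tb)
      dd1 <- conv_anchored(exp(-tc / pp$taus[1]) * tc / pp$taus[1], irf)
      dd2 <- conv_anchored(exp(-tc / pp$taus[2]) * tc / pp$taus[2], irf)
      J <- cbind(J,
                 tau1 = pp$f0 * pp$p1 * dd1[idx],
                 tau2 = pp$f0 * (1 - pp$p1) * dd2[idx])
    }
    J <- J[, active, drop = FALSE]
    Jw <- J * sw
    rw <- r * sw
    g <- crossprod(Jw, rw)
    H <- crossprod(Jw)
    ## Jacobi column scaling: the amplitude and background columns differ
    ## by many orders of magnitude, so solve in the normalized metric
    d <- sqrt(pmax(diag(H), 1e-300))
    Hs <- H / tcrossprod(d)
    gs <- g / d
    step_ok <- FALSE
    lambda <- 0
    for (try in 0:12) {
      Hd <- Hs + lambda * diag(nrow(Hs))
      delta <- tryCatch(solve(Hd, gs) / d, error = function(e) NULL)
      if (!is.null(delta)) {
        step <- numeric(length(theta))
        step[active] <- as.numeric(delta)
        theta_new <- theta + step
        rss_new <- rss_of(theta_new)
        if (is.finite(rss_new) && rss_new <= rss) {
          step_ok <- TRUE
          if (lambda > 0) n_damped <- n_damped + 1L
          break
        }
      }
      lambda <- if (lambda == 0) 1e-4 else lambda * 10
    }
    if (!step_ok) break
    improvement <- (rss - rss_new) / max(rss, 1e-300)
    theta <- theta_new
    rss <- rss_new
    if (improvement < tol || rss < 1e-20) {
      converged <- TRUE
      break
    }
  }
  list(theta = theta, rss = rss, converged = converged, iter = iter,
       n_damped = n_damped)
  }

  ## two SHG starting values guard against a poor spike initialization
  runs <- list(gn_run(theta0))
  if (fit_shg) {
    theta_alt <- theta0
    theta_alt[3] <- max(1, 1e-3 * sum(y))
    runs[[2]] <- gn_run(theta_alt)
  }
  best <- runs[[which.min(vapply(runs, `[[`, numeric(1), "rss"))]]
  theta <- best$theta

  pp <- unpack(theta)
  bases <- if (free_tau) fit_bases(pp$taus, irf, tb) else bases0
  fitted_full <- pp$f0 * (pp$p1 * bases$c1 + (1 - pp$p1) * bases$c2) +
    pp$shg * bases$c3 + pp$bg
  structure(
    list(f0 = pp$f0, p1 = pp$p1, p2 = 1 - pp$p1, shg = pp$shg,
         background = pp$bg, taus = pp$taus, converged = best$converged,
         residual_norm = sqrt(best$rss), n_iterations = best$iter,
         n_damped = best$n_damped, fitted = fitted_full,
         window_channels = idx),
    class = "flim_fit"
  )
}

#' @export
print.flim_fit <- function(x, ...) {
  cat(sprintf(
    "<fit: P1 = %.4f, F0 = %.4g, SHG = %.3g, background = %.4g | %s in %d it>\n",
    x$p1, x$f0, x$shg, x$background,
    if (x$converged) "converged" else "NOT converged", x$n_iterations))
  invisible(x)
}

#' Photons attributed to each decay component
#'
#' Sums each fitted exponential component over the channels of one laser
#' cycle: component `i` contributes `F0 * Pi * sum_k exp(-t_k / tau_i)`
#' photons.  For two-sensor multiplexing this converts a fixed-tau fit of
#' the combined histogram into the fitted intensity of each sensor.
#'
#' @param fit a `flim_fit`.
#' @param tb the [time_base()] the fit was performed on.
#' @return named numeric vector `c(component1, component2)` of photon
#'   counts (slow component first, matching `taus[1]`).
#' @export
photons_per_component <- function(fit, tb) {
  stopifnot(inherits(fit, "flim_fit"), inherits(tb, "flim_time_base"))
  tc <- channel_centers(tb)
  c(component1 = fit$f0 * fit$p1 * sum(exp(-tc / fit$taus[1])),
    component2 = fit$f0 * fit$p2 * sum(exp(-tc / fit$taus[2])))
}
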