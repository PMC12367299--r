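#' Autofluorescence specification
#'
#' Tissue autofluorescence (NAD(P)H, flavins, aromatic amino acids) is
#' added to simulated histograms by sampling from a fixed per-channel
#' lifetime distribution.  The distribution may be `empirical` (a measured,
#' background-subtracted histogram supplied as a pdf) or `parametric` (a
#' double-exponential decay convolved with an IRF, rendered to a pdf on
#' whatever time base is in use).
#'
#' @param mode `"empirical"` or `"parametric"`.
#' @param pdf per-channel probabilities (empirical mode).
#' @param decay a [decay_model()] (parametric mode).
#' @param irf a `flim_irf` used to render the parametric pdf; if `NULL` the
#'   simulator's IRF is used at render time.
#' @return an object of class `flim_autofluor_spec`.
#' @export
auto_fluor_spec <- function(mode = c("parametric", "empirical"),
                            pdf = NULL, decay = NULL, irf = NULL) {
  mode <- match.arg(mode)
  if (mode == "empirical") {
    if (is.null(pdf)) stop("empirical autofluorescence requires a pdf")
    pdf <- as.numeric(pdf)
    if (any(!is.finite(pdf)) || any(pdf < 0) || sum(pdf) <= 0)
      stop("autofluorescence pdf must be non-negative with positive mass")
    pdf <- pdf / sum(pdf)
  } else {
    if (is.null(decay) || !inherits(decay, "flim_decay_model"))
      stop("parametric autofluorescence requires a decay model")
  }
  structure(list(mode = mode, pdf = pdf, decay = decay, irf = irf),
            class = "flim_autofluor_spec")
}

#' Noise model for simulated histograms
#'
#' Bundles the non-sensor photon sources: autofluorescence amount `f_auto`
#' and distribution, PMT afterpulse ratio, uniform background amount
#' `f_background`, the +/- fluctuation applied to the autofluorescence and
#' background counts, and a global scale applied to both (3.2 for the 50 ns
#' multiplexing cycle, reflecting its longer acquisition time).  Defaults
#' are the measured brain-slice values: `f_auto = 4560`,
#' `f_background = 3484`, afterpulse ratio 0.32%, 5% fluctuation.
#'
#' @param autofluor an [auto_fluor_spec()]; default is the calibrated
#'   parametric brain-tissue surrogate ([default_autofluorescence()]).
#' @param f_auto autofluorescence photons per acquisition.
#' @param afterpulse_ratio afterpulse photons as a fraction of sensor
#'   photons, in `[0, 1)`.
#' @param f_background background photons per acquisition.
#' @param fluctuation_fraction half-width of the uniform count fluctuation,
#'   in `[0, 1)`; 0.05 means counts are drawn from `f * (1 +/- 5%)`.
#' @param noise_scale multiplier applied to `f_auto` and `f_background`.
#' @return an object of class `flim_noise_model`.
#' @export
noise_model <- function(autofluor = default_autofluorescence(),
                        f_auto = 4560, afterpulse_ratio = 0.0032,
                        f_background = 3484, fluctuation_fraction = 0.05,
                        noise_scale = 1) {
  stopifnot(inherits(autofluor, "flim_autofluor_spec"))
  if (f_auto < 0 || f_background < 0)
    stop("photon counts must be non-negative")
  if (afterpulse_ratio < 0 || afterpulse_ratio >= 1)
    stop("afterpulse_ratio must lie in [0, 1)")
  if (fluctuation_fraction < 0 || fluctuation_fraction >= 1)
    stop("fluctuation_fraction must lie in [0, 1)")
  if (noise_scale <= 0) stop("noise_scale must be positive")
  structure(
    list(autofluor = autofluor, f_auto = f_auto,
         afterpulse_ratio = afterpulse_ratio, f_background = f_background,
         fluctuation_fraction = fluctuation_fraction,
         noise_scale = noise_scale),
    class = "flim_noise_model"
  )
}

#' Fluctuated photon count
#'
#' Uniform integer draw from `[round(f * (1 - fraction)),
#' round(f * (1 + fraction))]`, the count fluctuation applied to the
#' autofluorescence and background photon numbers (default 5%, i.e. up to
#' 10% total spread).
#'
#' @param f nominal count (>= 0).
#' @param fraction fluctuation half-width.
#' @return a single integer count.
#' @export
fluctuate_count <- function(f, fraction = 0.05) {
  if (f < 0) stop("count must be non-negative")
  lo <- round(f * (1 - fraction))
  hi <- round(f * (1 + fraction))
  if (hi <= lo) return(as.integer(lo))
  as.integer(lo + sample.int(hi - lo + 1L, 1L) - 1L)
}

## render an autofluorescence spec to a pdf on a given time base
autofluorescence_pdf <- function(spec, tb, irf = NULL) {
  stopifnot(inherits(spec, "flim_autofluor_spec"))
  if (spec$mode == "empirical") {
    if (length(spec$pdf) != tb$n_channels)
      stop("empirical autofluorescence pdf does not match the time base")
    return(spec$pdf)
  }
  use_irf <- spec$irf %||% irf
  if (is.null(use_irf))
    stop("parametric autofluorescence needs an IRF to render")
  if (length(use_irf$pdf) != tb$n_channels)
    use_irf <- make_gaussian_irf(
      use_irf$fwhm_ps %||% 340,
      peak_channel = max(1L, round(tb$n_channels *
                                     use_irf$peak_channel /
                                     use_irf$time_base$n_channels)),
      tb = tb)
  shape <- decay_curve(spec$decay, channel_centers(tb))
  out <- conv_anchored(shape, use_irf)
  out / sum(out)
}

#' Sample autofluorescence photons
#'
#' Draws `fluctuate_count(f_auto * noise_scale)` photons with replacement
#' from the autofluorescence lifetime distribution.
#'
#' @param noise a [noise_model()].
#' @param tb a [time_base()].
#' @param irf IRF used to render a parametric autofluorescence spec that
#'   does not carry its own.
#' @return integer vector of arrival channels.
#' @export
sample_autofluorescence <- function(noise, tb, irf = NULL) {
  stopifnot(inherits(noise, "flim_noise_model"))
  n <- fluctuate_count(round(noise$f_auto * noise$noise_scale),
                       noise$fluctuation_fraction)
  if (n == 0L) return(integer(0))
  pdf <- autofluorescence_pdf(noise$autofluor, tb, irf)
  sample.int(tb$n_channels, n, replace = TRUE, prob = pdf)
}

#' Sample background photons
#'
#' Background (PMT dark current plus ambient light leak) is uniform across
#' time channels; the count is `fluctuate_count(f_background * noise_scale)`.
#'
#' @inheritParams sample_autofluorescence
#' @return integer vector of arrival channels.
#' @export
sample_background <- function(noise, tb) {
  stopifnot(inherits(noise, "flim_noise_model"))
  n <- fluctuate_count(round(noise$f_background * noise$noise_scale),
                       noise$fluctuation_fraction)
  if (n == 0L) return(integer(0))
  sample.int(tb$n_channels, n, replace = TRUE)
}

#' Sample afterpulse photons
#'
#' PMT afterpulse counts are `round(n_sensor_photons * afterpulse_ratio)`
#' photons uniform across time channels.  No count fluctuation is applied
#' (the fluctuation models acquisition-to-acquisition variation of the
#' independent light sources; the afterpulse is slaved to the sensor).
#'
#' @param n_sensor_photons number of detected sensor photons this repeat
#'   (for multiplexing, the summed photons of both sensors).
#' @inheritParams sample_autofluorescence
#' @return integer vector of arrival channels.
#' @export
sample_afterpulse <- function(n_sensor_photons, noise, tb) {
  stopifnot(inherits(noise, "flim_noise_model"))
  if (n_sensor_photons < 0) stop("n_sensor_photons must be non-negative")
  n <- round(n_sensor_photons * noise$afterpulse_ratio)
  if (n == 0) return(integer(0))
  sample.int(tb$n_channels, n, replace = TRUE)
}

#' Derive the afterpulse ratio from an IRF histogram
#'
#' In an IRF measurement the true response is confined to a narrow peak, so
#' the flat level at the end of the histogram is afterpulse plus
#' background.  The per-channel mean over the tail window, minus the known
#' background per channel, times the channel count, divided by the total
#' photons of the histogram, is the afterpulse ratio.
#'
#' @param irf_counts per-channel counts of a measured IRF histogram.
#' @param background_per_channel known background photons per channel.
#' @param tail_fraction fraction of channels (from the end) used as the
#'   flat tail window; default 0.2.
#' @return the afterpulse ratio (clamped at 0).
#' @export
derive_afterpulse_ratio <- function(irf_counts, background_per_channel = 0,
                                    tail_fraction = 0.2) {
  counts <- as.numeric(irf_counts)
  n <- length(counts)
  if (n < 2L) stop("IRF histogram too short")
  total <- sum(counts)
  if (total <= 0) stop("IRF histogram has no photons")
  if (tail_fraction <= 0 || tail_fraction >= 1)
    stop("tail_fraction must lie in (0, 1)")
  m <- max(1L, floor(tail_fraction * n))
  tail_mean <- mean(counts[(n - m + 1L):n])
  max(0, (tail_mean - background_per_channel) * n / total)
}

#' Parametric autofluorescence surrogate
#'
#' Builds a parametric autofluorescence spec from a fast double-exponential
#' decay whose pdf is the analytic IRF convolution of the decay.  This is a
#' synthetic stand-in for a measured brain-slice autofluorescence
#' histogram; the shipped default parameters were calibrated once (1-D
#' search on `tau1`) so its empirical lifetime over the 1.8-11.5 ns
#' analysis window is ~1.69 ns, the value measured in acute brain slices.
#'
#' @param tau1_ns slow time constant (default the calibrated 1.81 ns).
#' @param tau2_ns fast time constant (default 0.40 ns).
#' @param p1 slow-component fraction (default 0.5).
#' @param irf optional `flim_irf` rendered into the pdf; if `NULL`, the
#'   simulator's IRF is used at sampling time.
#' @return an [auto_fluor_spec()] in parametric mode.
#' @export
make_synthetic_autofluorescence <- function(tau1_ns = 1.81, tau2_ns = 0.40,
                                            p1 = 0.5, irf = NULL) {
  auto_fluor_spec("parametric",
                  decay = decay_model("double", tau1_ns, tau2_ns, p1),
                  irf = irf)
}

#' Default brain-tissue autofluorescence
#'
#' The calibrated synthetic autofluorescence surrogate used throughout the
#' package defaults; see [make_synthetic_autofluorescence()].
#'
#' @return an [auto_fluor_spec()].
#' @export
default_autofluorescence <- function() make_synthetic_autofluorescence()
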