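#' Gaussian instrument response function
#'
#' Builds a discretized Gaussian IRF on a time base.  The width is given as
#' full width at half maximum (FWHM) and converted to the Gaussian sigma by
#' `FWHM = 2 * sqrt(2 * ln 2) * sigma`; the per-channel density is evaluated
#' at channel centers and normalized to sum to one.  Detector presets use
#' 340 ps (GaAsP PMT, matching a measured IRF) and 120 ps (hybrid detector).
#'
#' @param fwhm_ps full width at half maximum in picoseconds (> 0).
#' @param peak_channel channel index of the IRF peak (the time origin that
#'   per-photon redistribution is anchored to).
#' @param tb a [time_base()].
#' @return an object of class `flim_irf` with fields `pdf`, `peak_channel`,
#'   `source = "gaussian"`, `fwhm_ps`, `sigma_ps` and `time_base`.
#' @examples
#' irf <- make_gaussian_irf(340, peak_channel = 26, tb = time_base())
#' sum(irf$pdf)
#' @export
make_gaussian_irf <- function(fwhm_ps, peak_channel, tb) {
  stopifnot(inherits(tb, "flim_time_base"))
  if (!is.finite(fwhm_ps) || fwhm_ps <= 0)
    stop("fwhm_ps must be a positive width in ps")
  peak_channel <- as.integer(peak_channel)
  if (is.na(peak_channel) || peak_channel < 1L ||
      peak_channel > tb$n_channels)
    stop("peak_channel must be a valid channel index")
  width_ps <- tb$channel_width_ns * 1000
  if (fwhm_ps < width_ps)
    warning("IRF FWHM is narrower than one time channel; ",
            "mass will concentrate in the peak channel")
  sigma_ps <- fwhm_ps / (2 * sqrt(2 * log(2)))
  sigma_ch <- sigma_ps / width_ps
  k <- seq_len(tb$n_channels)
  g <- exp(-0.5 * ((k - peak_channel) / sigma_ch)^2)
  structure(
    list(pdf = g / sum(g), peak_channel = peak_channel, source = "gaussian",
         fwhm_ps = fwhm_ps, sigma_ps = sigma_ps, time_base = tb),
    class = "flim_irf"
  )
}

#' IRF from a measured histogram
#'
#' Normalizes a per-channel photon-count histogram (for example a second
#' harmonic generation measurement) to total one and uses it as the IRF
#' probability density; the peak channel is the argmax of the counts.
#'
#' @param counts per-channel photon counts (length `n_channels`, all >= 0,
#'   at least one positive), or a two-column data.frame / path accepted by
#'   [read_histogram()].
#' @param tb a [time_base()].
#' @return an object of class `flim_irf` with `source = "empirical"`.
#' @export
load_irf_histogram <- function(counts, tb) {
  stopifnot(inherits(tb, "flim_time_base"))
  if (is.character(counts)) counts <- read_histogram(counts)$counts
  if (is.data.frame(counts)) counts <- counts[[2]]
  counts <- as.numeric(counts)
  if (length(counts) != tb$n_channels)
    stop("IRF histogram length does not match the time base")
  if (any(!is.finite(counts)) || any(counts < 0))
    stop("IRF counts must be finite and non-negative")
  if (sum(counts) <= 0)
    stop("IRF histogram is all zero")
  structure(
    list(pdf = counts / sum(counts), peak_channel = which.max(counts),
         source = "empirical", fwhm_ps = NA_real_, sigma_ps = NA_real_,
         time_base = tb),
    class = "flim_irf"
  )
}

#' @export
print.flim_irf <- function(x, ...) {
  if (x$source == "gaussian")
    cat(sprintf("<gaussian IRF: FWHM %.4g ps, peak channel %d>\n",
                x$fwhm_ps, x$peak_channel))
  else
    cat(sprintf("<empirical IRF: peak channel %d>\n", x$peak_channel))
  invisible(x)
}

## offset kernel q with q[1] = probability of offset 0, q[j] = offset j-1
## (offsets are sampled channel minus peak channel, wrapped to the cycle)
irf_offset_kernel <- function(irf) {
  n <- length(irf$pdf)
  off <- ((seq_len(n) - 1 + irf$peak_channel - 1) %% n) + 1
  irf$pdf[off]
}

#' Per-photon stochastic IRF convolution
#'
#' Redistributes each photon by an independent draw from the IRF offset
#' distribution (sampled channel minus peak channel, so a delta IRF at its
#' peak is the identity), wrapping any photon pushed beyond the laser cycle
#' around to the start of the next cycle.
#'
#' @param arrivals integer vector of photon arrival channels.
#' @param irf a `flim_irf`.
#' @param tb a [time_base()]; must match the IRF's.
#' @return integer vector of redistributed channels, same length as
#'   `arrivals`.
#' @export
convolve_photons_with_irf <- function(arrivals, irf, tb) {
  stopifnot(inherits(irf, "flim_irf"), inherits(tb, "flim_time_base"))
  n <- tb$n_channels
  if (length(irf$pdf) != n)
    stop("IRF and time base have different channel counts")
  if (length(arrivals) == 0L) return(integer(0))
  if (any(arrivals < 1L | arrivals > n))
    stop("arrival channels out of range")
  offs <- sample.int(n, length(arrivals), replace = TRUE, prob = irf$pdf) -
    irf$peak_channel
  ((arrivals - 1L + offs) %% n) + 1L
}

#' Analytic (expected-value) IRF convolution of a histogram
#'
#' Circular discrete convolution of a per-channel histogram with the IRF
#' offset kernel, computed by FFT.  This is the expectation of
#' [convolve_photons_with_irf()] and is used to isolate photon-sampling
#' noise from IRF-sampling noise; total mass is conserved.
#'
#' @param hist numeric per-channel counts.
#' @param irf a `flim_irf` with the same number of channels.
#' @return numeric vector of expected counts, same length as `hist`.
#' @export
convolve_histogram_analytic <- function(hist, irf) {
  stopifnot(inherits(irf, "flim_irf"))
  if (length(hist) != length(irf$pdf))
    stop("histogram and IRF have different channel counts")
  q <- irf_offset_kernel(irf)
  out <- Re(stats::fft(stats::fft(hist) * stats::fft(q), inverse = TRUE)) /
    length(hist)
  ## clip FFT round-off so expected counts stay non-negative
  pmax(out, 0)
}
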