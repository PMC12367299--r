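#' Fluorescence decay model
#'
#' Single- or double-exponential model of a fluorophore's lifetime
#' distribution,
#' \deqn{F(t) = F_0 (P_1 e^{-t/\tau_1} + P_2 e^{-t/\tau_2}),}
#' with `p2 = 1 - p1`.  The double-exponential form describes a FRET-based
#' biosensor whose donor is either free (slow component, `tau1`) or
#' undergoing FRET (fast component, `tau2`); the FLIM-AKAR PKA sensor used
#' as the default case study has `tau1 = 2.14` ns and `tau2 = 0.69` ns.
#' Single-exponential models (`kind = "single"`) describe the
#' intensity-modulated sensors used for lifetime multiplexing.
#'
#' @param kind `"double"` or `"single"`.
#' @param tau1_ns slow time constant in ns (the only one for `"single"`).
#' @param tau2_ns fast time constant in ns; ignored for `"single"`.
#' @param p1 fraction of the slow component, in `[0, 1]`; forced to 1 for
#'   `"single"`.
#' @return an object of class `flim_decay_model`.
#' @examples
#' akar <- decay_model("double", tau1_ns = 2.14, tau2_ns = 0.69, p1 = 0.5854)
#' sensor1 <- decay_model("single", tau1_ns = 2.0)
#' @export
decay_model <- function(kind = c("double", "single"),
                        tau1_ns, tau2_ns = NULL, p1 = 1) {
  kind <- match.arg(kind)
  if (!is.finite(tau1_ns) || tau1_ns <= 0)
    stop("tau1_ns must be a positive finite time constant")
  if (kind == "single") {
    tau2_ns <- tau1_ns
    p1 <- 1
  } else {
    if (is.null(tau2_ns) || !is.finite(tau2_ns) || tau2_ns <= 0)
      stop("tau2_ns must be a positive finite time constant")
    if (!is.finite(p1) || p1 < 0 || p1 > 1)
      stop("p1 must lie in [0, 1]")
  }
  structure(
    list(kind = kind, tau1_ns = tau1_ns, tau2_ns = tau2_ns,
         p1 = p1, p2 = 1 - p1),
    class = "flim_decay_model"
  )
}

#' @export
print.flim_decay_model <- function(x, ...) {
  if (x$kind == "single")
    cat(sprintf("<single-exponential decay: tau = %.4g ns>\n", x$tau1_ns))
  else
    cat(sprintf(
      "<double-exponential decay: tau1 = %.4g ns (P1 = %.4g), tau2 = %.4g ns>\n",
      x$tau1_ns, x$p1, x$tau2_ns))
  invisible(x)
}

## model curve at arbitrary times, amplitude F0 (photons "at time 0")
decay_curve <- function(model, t_ns, f0 = 1) {
  f0 * (model$p1 * exp(-t_ns / model$tau1_ns) +
          model$p2 * exp(-t_ns / model$tau2_ns))
}

#' Build a photon population from a decay model
#'
#' Evaluates the decay model at the channel-center times of one laser cycle
#' with amplitude `population_f0` and rounds the expected counts to the
#' nearest integer, producing the deterministic per-channel photon
#' population from which photon arrival times are later sampled with
#' replacement.  The population is restricted to one cycle: the exponential
#' tail beyond `cycle_ns` is truncated, not wrapped.
#'
#' @param model a [decay_model()].
#' @param tb a [time_base()].
#' @param population_f0 amplitude of the generating curve (photons at time
#'   0); the reference configuration uses 1e6.
#' @return an object of class `flim_photon_population` with per-channel
#'   integer `counts`, the normalized `pdf`, total `size`, and references to
#'   the generating `model`, `population_f0` and `time_base`.
#' @examples
#' tb <- time_base()
#' pop <- build_decay_population(decay_model("double", 2.14, 0.69, 0.5), tb)
#' pop$size
#' @export
build_decay_population <- function(model, tb, population_f0 = 1e6) {
  stopifnot(inherits(model, "flim_decay_model"), inherits(tb, "flim_time_base"))
  if (!is.finite(population_f0) || population_f0 < 1)
    stop("population_f0 must be >= 1")
  counts <- round(decay_curve(model, channel_centers(tb), population_f0))
  if (sum(counts) <= 0)
    stop("population is empty; increase population_f0")
  structure(
    list(counts = counts, pdf = counts / sum(counts), size = sum(counts),
         source_model = model, population_f0 = population_f0, time_base = tb),
    class = "flim_photon_population"
  )
}

#' Sample photon arrival channels from a population
#'
#' Draws `n` arrival channels with replacement from the population's
#' per-channel distribution, emulating photon detection from a pool of
#' fluorophores.  Uses the current R random number stream; seed with
#' [set.seed()] (the simulator derives per-repeat sub-seeds itself).
#'
#' @param population a [build_decay_population()] result.
#' @param n number of photons to draw (>= 0).
#' @return integer vector of `n` channel indices in `1:n_channels`.
#' @export
sample_photons <- function(population, n) {
  stopifnot(inherits(population, "flim_photon_population"))
  n <- as.integer(n)
  if (is.na(n) || n < 0) stop("n must be a non-negative count")
  if (n == 0L) return(integer(0))
  if (population$size <= 0) stop("cannot sample from an empty population")
  sample.int(length(population$counts), n, replace = TRUE,
             prob = population$pdf)
}

#' Mean arrival time of a truncated exponential decay
#'
#' Closed-form mean of an exponential with time constant `tau_ns` truncated
#' at the cycle length `cycle_ns`:
#' `tau - T * exp(-T/tau) / (1 - exp(-T/tau))`.  Used as the reference value
#' for population means; a discretized population matches it to within half
#' a channel width.
#'
#' @param tau_ns time constant in ns.
#' @param cycle_ns truncation time in ns.
#' @return mean arrival time in ns.
#' @export
truncated_exp_mean <- function(tau_ns, cycle_ns) {
  r <- exp(-cycle_ns / tau_ns)
  tau_ns - cycle_ns * r / (1 - r)
}
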