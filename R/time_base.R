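#' TCSPC time base
#'
#' Discretization that every lifetime histogram lives on: the laser cycle is
#' split into `n_channels` equal time channels.  Channel `k` (1-based in R)
#' carries the label time `(k - 1) * channel_width_ns`; decay models are
#' evaluated at channel-center times `(k - 0.5) * channel_width_ns`.
#'
#' @param n_channels number of time channels per laser cycle (>= 2).
#' @param cycle_ns laser inter-pulse interval in ns (12.5 for an 80 MHz
#'   laser; 50 for the multiplexing cycle).
#' @return an object of class `flim_time_base` with fields `n_channels`,
#'   `cycle_ns` and `channel_width_ns`.
#' @examples
#' tb <- time_base(256, 12.5)
#' tb$channel_width_ns
#' @export
time_base <- function(n_channels = 256L, cycle_ns = 12.5) {
  n_channels <- as.integer(n_channels)
  if (length(n_channels) != 1L || is.na(n_channels) || n_channels < 2L)
    stop("n_channels must be a single integer >= 2")
  if (!is.finite(cycle_ns) || cycle_ns <= 0)
    stop("cycle_ns must be a positive finite duration in ns")
  structure(
    list(n_channels = n_channels,
         cycle_ns = cycle_ns,
         channel_width_ns = cycle_ns / n_channels),
    class = "flim_time_base"
  )
}

#' Label times of the channels of a time base
#'
#' Channel `k` maps to `(k - 1) * channel_width_ns` (the 0-based index times
#' the channel width); these are the times used for window selection and
#' re-zeroing.
#'
#' @param tb a [time_base()] object.
#' @return numeric vector of length `n_channels`.
#' @export
channel_times <- function(tb) {
  stopifnot(inherits(tb, "flim_time_base"))
  (seq_len(tb$n_channels) - 1) * tb$channel_width_ns
}

#' Channel-center times of a time base
#'
#' Times `(k - 0.5) * channel_width_ns` at which decay models are evaluated
#' when photon populations and fit model curves are built.
#'
#' @param tb a [time_base()] object.
#' @return numeric vector of length `n_channels`.
#' @export
channel_centers <- function(tb) {
  stopifnot(inherits(tb, "flim_time_base"))
  (seq_len(tb$n_channels) - 0.5) * tb$channel_width_ns
}

#' @export
print.flim_time_base <- function(x, ...) {
  cat(sprintf("<time base: %d channels over %.4g ns (width %.5g ns)>\n",
              x$n_channels, x$cycle_ns, x$channel_width_ns))
  invisible(x)
}

## circular left-to-right rotation: element 1 moves to position 1 + shift
rotate_channels <- function(x, shift) {
  n <- length(x)
  shift <- shift %% n
  if (shift == 0) return(x)
  c(x[(n - shift + 1L):n], x[seq_len(n - shift)])
}

## deterministic sub-seed derivation so each (condition, repeat) pair gets a
## reproducible stream; all arithmetic stays below 2^53 and the result below
## 2^31 - 1 so it is a valid set.seed() input
derive_seed <- function(seed, ...) {
  m <- 2147483647 # 2^31 - 1
  h <- as.numeric(seed) %% m
  for (idx in c(...)) {
    h <- (h * 69069 + (as.numeric(idx) + 1) * 104729) %% m
  }
  as.integer(h)
}
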