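# Morlet continuous wavelet analysis of concatenated nocturnal activity and
# the structure-curve scalars derived from it.

#' Concatenate the sleep activity of consecutive nights
#'
#' @param epochs a smoothed `epoch_series`.
#' @param periods sleep periods from [detect_sleep_periods()].
#' @param nights number of nights to concatenate (default 5); if fewer are
#'   available all of them are used with a warning, with a minimum of 2.
#' @return Numeric vector of smoothed ZCM values at the epoch resolution,
#'   the nights joined in time order.
#' @export
concatenate_sleep <- function(epochs, periods, nights = 5) {
  stopifnot(inherits(epochs, "epoch_series"))
  avail <- nrow(periods)
  if (avail < 2L)
    stop("need at least 2 detected sleep periods (", avail, " available)")
  if (avail < nights) {
    warning("only ", avail, " sleep periods available; requested ", nights)
    nights <- avail
  }
  periods <- periods[order(periods$start_epoch), , drop = FALSE]
  use <- periods[seq_len(nights), , drop = FALSE]
  unlist(lapply(seq_len(nrow(use)), function(i)
    epochs$counts[use$start_epoch[i]:(use$end_epoch[i] - 1L)]),
    use.names = FALSE)
}

# Morlet scale <-> Fourier period conversion (omega0 = 6 by default):
# period = 4*pi*s / (omega0 + sqrt(2 + omega0^2))
.period_to_scale <- function(period, omega0) {
  period * (omega0 + sqrt(2 + omega0^2)) / (4 * pi)
}

#' Morlet continuous wavelet transform
#'
#' Computes the CWT of a series with the Morlet mother wavelet (a
#' single-frequency complex sinusoid of centre frequency `omega0` inside a
#' Gaussian envelope), L2-normalized, on a linear grid of Fourier periods
#' (the "scale" axis reported in minutes). Implemented in the Fourier
#' domain with zero padding to the next power of two; the real part of the
#' coefficients is returned. When the series is shorter than twice the
#' largest requested period, the grid is truncated to the largest usable
#' period with a warning.
#'
#' @param x numeric series sampled at `dt`-minute resolution.
#' @param periods Fourier periods in minutes (default 1..200, linear).
#' @param omega0 Morlet centre frequency (default 6, the conventional
#'   admissible choice).
#' @param dt sampling step of `x` in minutes.
#' @return Object of class `wavelet_map`: list with `scales` (periods in
#'   minutes), `coefficients` (scales x time matrix of real coefficients)
#'   and `omega0`.
#' @export
morlet_cwt <- function(x, periods = 1:200, omega0 = 6, dt = 1) {
  n <- length(x)
  if (n < 4L) stop("series too short for a wavelet transform")
  max_ok <- floor(n * dt / 2)
  if (max(periods) > max_ok) {
    warning("series supports periods up to ", max_ok,
            " min only; map truncated")
    periods <- periods[periods <= max_ok]
    if (length(periods) == 0L) stop("no usable scale at this series length")
  }
  npad <- 2^ceiling(log2(n * 2))
  xf <- stats::fft(c(x, rep(0, npad - n)))
  k <- 0:(npad - 1)
  omega <- ifelse(k <= npad / 2, 2 * pi * k / (npad * dt),
                  -2 * pi * (npad - k) / (npad * dt))
  scales <- .period_to_scale(periods, omega0)
  co <- matrix(0, nrow = length(scales), ncol = n)
  norm0 <- pi^(-1 / 4)
  for (i in seq_along(scales)) {
    s <- scales[i]
    psi_hat <- norm0 * sqrt(2 * pi * s / dt) *
      (omega > 0) * exp(-((s * omega - omega0)^2) / 2)
    w <- stats::fft(xf * psi_hat, inverse = TRUE) / npad
    co[i, ] <- Re(w[seq_len(n)])
  }
  structure(list(scales = periods, coefficients = co, omega0 = omega0,
                 dt = dt), class = "wavelet_map")
}

#' Structure curve: per-scale squared coefficient sum
#'
#' @param map a `wavelet_map` from [morlet_cwt()].
#' @return Object of class `structure_curve`: list with `scales` (minutes)
#'   and `values` (sum over time of squared coefficients at each scale).
#' @export
structure_curve <- function(map) {
  stopifnot(inherits(map, "wavelet_map"))
  structure(list(scales = map$scales,
                 values = rowSums(map$coefficients^2)),
            class = "structure_curve")
}

#' Band scalars of a structure curve
#'
#' `structure_pm` is the trapezoidal integral of the structure curve over
#' the 20--100 min scale band; `structure_pm_stdev` is the population
#' standard deviation of the curve values over the 51--67 min band.
#'
#' @param curve a `structure_curve`.
#' @param pm_band,stdev_band scale bands in minutes.
#' @return Named list `structure_pm`, `structure_pm_stdev`.
#' @export
structure_band_features <- function(curve, pm_band = c(20, 100),
                                    stdev_band = c(51, 67)) {
  stopifnot(inherits(curve, "structure_curve"))
  for (band in list(pm_band, stdev_band))
    if (band[1] < min(curve$scales) || band[2] > max(curve$scales))
      stop("band [", band[1], ",", band[2], "] outside the curve domain")
  in_pm <- curve$scales >= pm_band[1] & curve$scales <= pm_band[2]
  in_sd <- curve$scales >= stdev_band[1] & curve$scales <= stdev_band[2]
  list(structure_pm = trapezoid(curve$scales[in_pm], curve$values[in_pm]),
       structure_pm_stdev = pop_sd(curve$values[in_sd]))
}
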