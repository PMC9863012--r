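# Diurnal rhythm features: nonparametric circadian metrics on the smoothed
# ZCM epoch series, clock-third summaries, and the Savitzky-Golay boundary
# (ceiling/floor envelope) features.

# epochs of complete calendar days as a days x (epochs/day) matrix
.full_day_matrix <- function(epochs) {
  stopifnot(inherits(epochs, "epoch_series"))
  per_day <- 86400 %/% epochs$epoch_seconds
  times <- epoch_times(epochs)
  day <- format(times, "%Y-%m-%d", tz = "UTC")
  minute_idx <- (as.numeric(times) %% 86400) %/% epochs$epoch_seconds + 1
  counts <- table(day)
  full <- names(counts)[counts == per_day]
  if (length(full) == 0L) return(NULL)
  m <- matrix(NA_real_, nrow = length(full), ncol = per_day,
              dimnames = list(full, NULL))
  keep <- day %in% full
  m[cbind(match(day[keep], full), minute_idx[keep])] <- epochs$counts[keep]
  m
}

# circular running means of all `w`-epoch windows within one day row
.circular_means <- function(row, w) {
  ext <- c(row, row[seq_len(w - 1)])
  cs <- c(0, cumsum(ext))
  (cs[(w + 1):(length(row) + w)] - cs[seq_along(row)]) / w
}

#' Nonparametric circadian activity profile: M10, L5, RA, ADAT
#'
#' For each complete calendar day, M10 (L5) is the mean epoch activity in
#' the contiguous 10 h (5 h) window maximizing (minimizing) activity;
#' windows slide in 1-epoch steps and may wrap across midnight within the
#' day's 24 h. Subject values are means over days. RA is the relative
#' amplitude (M10-L5)/(M10+L5) and ADAT the mean daily summed activity.
#'
#' @param epochs a smoothed `epoch_series` covering at least one full
#'   calendar day.
#' @return Named list with `M10`, `L5`, `RA`, `ADAT`.
#' @export
nonparametric_profile <- function(epochs) {
  m <- .full_day_matrix(epochs)
  if (is.null(m)) stop("need at least one full calendar day of epochs")
  per_hour <- 3600 %/% epochs$epoch_seconds
  m10 <- apply(m, 1, function(r) max(.circular_means(r, 10 * per_hour)))
  l5  <- apply(m, 1, function(r) min(.circular_means(r, 5 * per_hour)))
  M10 <- mean(m10); L5 <- mean(l5)
  RA <- if (M10 + L5 > 0) (M10 - L5) / (M10 + L5) else 0
  list(M10 = M10, L5 = L5, RA = RA, ADAT = mean(rowSums(m)))
}

# hourly-binned activity of complete days, as a days x 24 matrix
.hourly_matrix <- function(epochs) {
  m <- .full_day_matrix(epochs)
  if (is.null(m) || nrow(m) < 2L)
    stop("need at least two full calendar days of epochs")
  per_hour <- ncol(m) %/% 24
  hmat <- sapply(seq_len(24), function(h)
    rowMeans(m[, ((h - 1) * per_hour + 1):(h * per_hour), drop = FALSE]))
  matrix(hmat, nrow = nrow(m), ncol = 24)
}

#' Interdaily stability on an hourly matrix
#'
#' Core nonparametric statistic: `IS = (n * sum_h (xbar_h - xbar)^2) /
#' (p * sum_i (x_i - xbar)^2)` with `p = 24` clock-hour bins, `xbar_h` the
#' mean over days for hour `h` and `n` the number of hourly samples.
#' IS lies in [0, 1]; 1 for a perfectly repeated daily pattern, about
#' 1/days for structureless noise.
#'
#' @param hourly days x 24 matrix of hourly activity.
#' @return IS scalar.
#' @export
is_stat <- function(hourly) {
  x <- as.vector(hourly)
  n <- length(x); p <- ncol(hourly)
  xbar <- mean(x)
  tot <- sum((x - xbar)^2)
  if (tot == 0) stop("degenerate input: zero total variance")
  hmeans <- colMeans(hourly)
  (n * sum((hmeans - xbar)^2)) / (p * tot)
}

#' Intradaily variability on an hourly series
#'
#' `IV = (n * sum_{i>=2} (x_i - x_{i-1})^2) / ((n-1) * sum_i (x_i - xbar)^2)`
#' on the hourly activity sequence in time order. IV is about 2 for white
#' noise and small for slowly varying (e.g. sinusoidal) profiles.
#'
#' @param x hourly activity values in time order (>= 2 values).
#' @return IV scalar.
#' @export
iv_stat <- function(x) {
  n <- length(x)
  if (n < 2L) stop("need at least two hourly samples")
  tot <- sum((x - mean(x))^2)
  if (tot == 0) stop("degenerate input: zero variance")
  (n * sum(diff(x)^2)) / ((n - 1) * tot)
}

#' @rdname is_stat
#' @param epochs a smoothed `epoch_series` covering >= 2 full days.
#' @export
interdaily_stability <- function(epochs) is_stat(.hourly_matrix(epochs))

#' @rdname iv_stat
#' @param epochs a smoothed `epoch_series` covering >= 2 full days.
#' @export
intradaily_variability <- function(epochs) {
  h <- .hourly_matrix(epochs)
  iv_stat(as.vector(t(h)))      # rows are days; concatenate in time order
}

#' Clock-third and daily activity summaries
#'
#' Thirds are the clock windows 00-08, 08-16 and 16-24 (the pre-sleep
#' evening); each is the mean epoch activity in that window averaged over
#' complete days. `daily_activity_mean`/`_stdev` are the mean and
#' population standard deviation over all epochs of the series.
#'
#' @param epochs a smoothed `epoch_series` with >= 1 full day.
#' @return Named list `1_thrd`, `2_thrd`, `3_thrd`, `daily_activity_mean`,
#'   `daily_activity_stdev`.
#' @export
thirds_and_daily <- function(epochs) {
  m <- .full_day_matrix(epochs)
  if (is.null(m)) stop("need at least one full calendar day of epochs")
  per_third <- ncol(m) %/% 3
  thirds <- vapply(1:3, function(k)
    mean(rowMeans(m[, ((k - 1) * per_third + 1):(k * per_third),
                    drop = FALSE])), numeric(1))
  out <- list(thirds[1], thirds[2], thirds[3],
              mean(epochs$counts), pop_sd(epochs$counts))
  names(out) <- c("1_thrd", "2_thrd", "3_thrd",
                  "daily_activity_mean", "daily_activity_stdev")
  out
}

# strict local extrema of s over a +/-k neighborhood; points lacking a full
# two-sided neighborhood (the first/last k epochs) are not extrema
.local_extrema <- function(s, k) {
  n <- length(s)
  if (n < 2 * k + 1) return(list(ceiling = integer(0), floor = integer(0)))
  win <- embed(s, 2 * k + 1)                # rows = centred windows
  centre <- k + 1
  others <- win[, -centre, drop = FALSE]
  hi <- apply(others, 1, max)
  lo <- apply(others, 1, min)
  mid <- (k + 1):(n - k)
  list(ceiling = mid[s[mid] > hi], floor = mid[s[mid] < lo])
}

#' Savitzky--Golay boundary (envelope) features
#'
#' Smooths the epoch series with a Savitzky--Golay filter (window 61
#' epochs, cubic by default), takes the smoothed curve's strict local
#' maxima as the ceiling curve and strict local minima as the floor curve
#' (extrema over a +/-15 epoch neighborhood), and summarizes the two
#' boundary curves.
#'
#' @param epochs a smoothed `epoch_series` longer than `window`.
#' @param window,polyorder Savitzky--Golay filter length (odd) and degree.
#' @param halfwidth neighborhood half-width for strict extrema.
#' @return Named list of the 7 boundary features: `floor_sum_values`,
#'   `e_v_avg_value`, `avg_ceiling_value`, `avg_floor_value`,
#'   `avg_ceiling_floor_diff`, `std_avg`, `std_upper`.
#' @export
savgol_boundary_features <- function(epochs, window = 61, polyorder = 3,
                                     halfwidth = 15) {
  stopifnot(inherits(epochs, "epoch_series"))
  x <- epochs$counts
  if (length(x) <= window) stop("series not longer than the smoothing window")
  s <- signal::sgolayfilt(x, p = polyorder, n = window)
  ex <- .local_extrema(s, halfwidth)
  ceil_v <- s[ex$ceiling]; floor_v <- s[ex$floor]
  if (length(ceil_v) == 0L && length(floor_v) == 0L)
    stop("degenerate input: no local extrema on the smoothed curve")
  all_v <- c(ceil_v, floor_v)
  list(
    floor_sum_values       = sum(floor_v),
    e_v_avg_value          = mean(all_v),
    avg_ceiling_value      = mean(ceil_v),
    avg_floor_value        = mean(floor_v),
    avg_ceiling_floor_diff = mean(ceil_v) - mean(floor_v),
    std_avg                = pop_sd(all_v),
    std_upper              = pop_sd(ceil_v)
  )
}
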