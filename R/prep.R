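#' Per-epoch activity series
#'
#' @param counts per-epoch activity counts (raw ZCM are nonnegative
#'   integers, smoothed series are nonnegative reals).
#' @param start_time `POSIXct` timestamp of the first epoch's left edge
#'   (aligned to a whole minute).
#' @param epoch_seconds epoch length, 60 s by default.
#' @param smoothed logical flag carried for provenance.
#' @return Object of class `epoch_series`.
#' @export
epoch_series <- function(counts, start_time, epoch_seconds = 60,
                         smoothed = FALSE) {
  counts <- as.numeric(counts)
  if (any(counts < 0, na.rm = TRUE)) stop("activity counts must be >= 0")
  if (!inherits(start_time, "POSIXct"))
    start_time <- as.POSIXct(start_time, tz = "UTC")
  structure(list(counts = counts, start_time = start_time,
                 epoch_seconds = epoch_seconds, smoothed = smoothed),
            class = "epoch_series")
}

#' @export
print.epoch_series <- function(x, ...) {
  cat(sprintf("<epoch_series%s> %d x %ds epochs from %s\n",
              if (x$smoothed) " (smoothed)" else "", length(x$counts),
              x$epoch_seconds, format(x$start_time, usetz = TRUE)))
  invisible(x)
}

#' Clock timestamps of each epoch's left edge
#' @param epochs an `epoch_series`.
#' @return `POSIXct` vector, one per epoch.
#' @export
epoch_times <- function(epochs) {
  epochs$start_time + (seq_along(epochs$counts) - 1) * epochs$epoch_seconds
}

# forward-backward (zero-phase) application of an IIR design, with odd
# edge reflection to suppress start-up transients; the hot loop is in C++
.filtfilt_iir <- function(bf, x) {
  n <- length(x)
  pad <- min(n - 1L, 9L * (max(length(bf$a), length(bf$b)) - 1L))
  xp <- if (pad > 0L)
    c(2 * x[1] - x[(pad + 1L):2], x, 2 * x[n] - x[(n - 1L):(n - pad)])
  else x
  y <- .iir_filtfilt_core(bf$b, bf$a, xp)
  y[(pad + 1L):(pad + n)]
}

#' Zero-phase Butterworth band-pass filtering
#'
#' Applies an order-4 Butterworth band-pass (default 0.25--2.5 Hz, the
#' "maximally flat magnitude" filter) to each axis independently, forward
#' and backward so that the phase response is zero and epoch boundaries
#' are not shifted (the magnitude response is applied twice). The Earth's
#' 1 g gravity component is DC and is removed by the pass band. The
#' per-sample Euclidean norm of the filtered axes is returned as
#' `magnitude`.
#'
#' @param rec a [raw_recording()].
#' @param low,high pass-band corner frequencies in Hz.
#' @param order Butterworth design order (applied forward and backward).
#' @return Object of class `filtered_signal` with fields `x`, `y`, `z`,
#'   `magnitude`, `sampling_rate`, `start_time`.
#' @export
bandpass_filter <- function(rec, low = 0.25, high = 2.5, order = 4) {
  stopifnot(inherits(rec, "raw_recording"))
  fs <- rec$sampling_rate
  if (high >= fs / 2)
    stop("upper corner ", high, " Hz at or above Nyquist (", fs / 2, " Hz)")
  settle <- ceiling(fs / low)             # samples spanning one low-corner period
  if (rec$n_samples < 3 * settle)
    stop("recording shorter than 3x the filter settling length")
  bf <- signal::butter(order, c(low, high) / (fs / 2), type = "pass")
  x <- .filtfilt_iir(bf, rec$x)
  y <- .filtfilt_iir(bf, rec$y)
  z <- .filtfilt_iir(bf, rec$z)
  structure(list(x = x, y = y, z = z,
                 magnitude = sqrt(x^2 + y^2 + z^2),
                 sampling_rate = fs, start_time = rec$start_time),
            class = "filtered_signal")
}

# samples to skip so that epochs start at the first whole minute >= start_time
.minute_offset_samples <- function(start_time, sampling_rate) {
  sec_into_min <- as.numeric(start_time) %% 60
  skip_s <- (60 - sec_into_min) %% 60
  round(skip_s * sampling_rate)
}

#' Zero-crossing-method activity counts per 60 s epoch
#'
#' Counts, per axis, upward crossings of the +0.05 g threshold (a sample
#' below the threshold followed by one at or above it) on the band-passed
#' signed signal, and sums the three axial counts within each whole epoch.
#' Epochs are aligned to the first whole minute at or after the recording
#' start; the trailing partial epoch is dropped.
#'
#' @param sig a `filtered_signal` (see [bandpass_filter()]).
#' @param threshold crossing level in g.
#' @param epoch_seconds epoch length in seconds.
#' @return An `epoch_series` of raw ZCM counts.
#' @export
zcm_epochs <- function(sig, threshold = 0.05, epoch_seconds = 60) {
  stopifnot(inherits(sig, "filtered_signal"))
  fs <- sig$sampling_rate
  n <- length(sig$x)
  per_epoch <- round(fs * epoch_seconds)
  offset <- .minute_offset_samples(sig$start_time, fs)
  n_ep <- (n - offset) %/% per_epoch
  if (n_ep < 1L) stop("recording too short for a single whole epoch")
  counts <- integer(n_ep)
  # a crossing is attributed to the epoch of the sample at/above threshold
  for (axis in c("x", "y", "z"))
    counts <- counts + .count_crossings(sig[[axis]], threshold, offset,
                                        per_epoch, n_ep)
  start <- sig$start_time + offset / fs
  epoch_series(counts, start, epoch_seconds, smoothed = FALSE)
}

#' Sliding-window smoothing of an epoch series
#'
#' Replaces each epoch by the arithmetic mean of itself, up to `before`
#' predecessors and up to `after` successors; at the series boundaries the
#' window truncates to the available epochs.
#'
#' @param epochs an `epoch_series`.
#' @param before,after window half-widths in epochs (default 5 + 5).
#' @return A smoothed `epoch_series`.
#' @export
smooth_epochs <- function(epochs, before = 5, after = 5) {
  stopifnot(inherits(epochs, "epoch_series"))
  x <- epochs$counts
  n <- length(x)
  cs <- c(0, cumsum(x))
  lo <- pmax(seq_len(n) - before, 1L)
  hi <- pmin(seq_len(n) + after, n)
  sm <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  out <- epoch_series(sm, epochs$start_time, epochs$epoch_seconds,
                      smoothed = TRUE)
  out
}

#' Minimum-duration validity rule
#'
#' Accepts a recording or epoch series only if its continuous duration is
#' at least `min_days` x 24 h (inclusive bound); the series is trimmed to
#' whole minutes.
#'
#' @param x a [raw_recording()] or `epoch_series`.
#' @param min_days minimum number of days (default 2).
#' @return list(accepted = logical, x = trimmed input, duration_days).
#' @export
validity_filter <- function(x, min_days = 2) {
  if (inherits(x, "raw_recording")) {
    whole_min <- (x$n_samples %/% round(60 * x$sampling_rate)) *
      round(60 * x$sampling_rate)
    for (axis in c("x", "y", "z")) x[[axis]] <- x[[axis]][seq_len(whole_min)]
    x$n_samples <- whole_min
    x$duration_s <- whole_min / x$sampling_rate
    dur <- x$duration_s
  } else if (inherits(x, "epoch_series")) {
    dur <- length(x$counts) * x$epoch_seconds
  } else stop("need a raw_recording or epoch_series")
  list(accepted = dur >= min_days * 86400, x = x,
       duration_days = dur / 86400)
}

#' Write / read an epoch-series pair as TSV
#'
#' Tab-separated export with columns `timestamp` (ISO 8601, UTC),
#' `raw_zcm` and `smoothed_zcm`, the standard inspection format for
#' prepared recordings.
#'
#' @param prep a prepared list from [prep_recording()] (or any list with
#'   `raw_epochs` and `epochs`).
#' @param path file path.
#' @return `path` (write); for the reader, a list with `raw_epochs`,
#'   `epochs`, `subject_id`.
#' @export
write_epoch_series <- function(prep, path) {
  df <- data.frame(
    timestamp = format(epoch_times(prep$raw_epochs), "%Y-%m-%dT%H:%M:%SZ",
                       tz = "UTC"),
    raw_zcm = prep$raw_epochs$counts,
    smoothed_zcm = prep$epochs$counts)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_epoch_series
#' @param epoch_seconds epoch length of the stored series.
#' @export
read_epoch_series <- function(path, epoch_seconds = 60) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  start <- as.POSIXct(df$timestamp[1], format = "%Y-%m-%dT%H:%M:%SZ",
                      tz = "UTC")
  list(raw_epochs = epoch_series(df$raw_zcm, start, epoch_seconds),
       epochs = epoch_series(df$smoothed_zcm, start, epoch_seconds,
                             smoothed = TRUE),
       subject_id = sub("\\.[^.]*$", "", basename(path)))
}

#' Raw recording to smoothed ZCM epochs
#'
#' Convenience wrapper chaining [bandpass_filter()], [zcm_epochs()] and
#' [smooth_epochs()] under one configuration.
#'
#' @param rec a [raw_recording()].
#' @param cfg an [acti_config()].
#' @param keep_filtered retain the per-sample filtered signal (large;
#'   off by default — the epoch series are what downstream stages use).
#' @return list(raw_epochs, epochs, subject_id, group_label) where
#'   `epochs` is the smoothed series; plus `filtered` if requested.
#' @export
prep_recording <- function(rec, cfg = acti_config(), keep_filtered = FALSE) {
  validate_config(cfg, rec$sampling_rate)
  sig <- bandpass_filter(rec, cfg$bandpass_low, cfg$bandpass_high,
                         cfg$filter_order)
  raw <- zcm_epochs(sig, cfg$zcm_threshold, cfg$epoch_seconds)
  sm <- smooth_epochs(raw, cfg$smooth_before, cfg$smooth_after)
  out <- list(raw_epochs = raw, epochs = sm,
              subject_id = rec$subject_id, group_label = rec$group_label)
  if (keep_filtered) out$filtered <- sig
  out
}
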