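# Nocturnal features: sleep-period detection on the smoothed ZCM series,
# movement-bout ("hump") extraction and the grouped peak-shape families,
# the zero ratio, the fragmentation index and sleep length.

#' Detect nightly sleep periods
#'
#' Within each night window (18:00 to noon the next day, clock time), the
#' maximal contiguous run of epochs with smoothed ZCM between 0 and
#' `zcm_max` that is longest and at least `min_minutes` long is taken as
#' that night's sleep period. Nights without a qualifying run contribute no
#' period (they are "sleepless").
#'
#' @param epochs a smoothed `epoch_series`.
#' @param zcm_max inclusive upper activity bound for sleep (default 5).
#' @param min_minutes minimum qualifying run length (default 120).
#' @param night_start_hour,night_end_hour clock bounds of the night window.
#' @return data.frame with `night_index`, `start_epoch`, `end_epoch`
#'   (1-based, end exclusive) and `duration_minutes`; zero rows if no sleep
#'   was found.
#' @export
detect_sleep_periods <- function(epochs, zcm_max = 5, min_minutes = 120,
                                 night_start_hour = 18, night_end_hour = 12) {
  stopifnot(inherits(epochs, "epoch_series"))
  times <- as.numeric(epoch_times(epochs))
  ep_min <- epochs$epoch_seconds / 60
  first_mid <- (min(times) %/% 86400) * 86400 - 86400
  last_mid <- (max(times) %/% 86400) * 86400
  night_starts <- seq(first_mid, last_mid, by = 86400) + night_start_hour * 3600
  out <- list()
  k <- 0L
  for (ws in night_starts) {
    we <- ws + (24 - night_start_hour + night_end_hour) * 3600
    idx <- which(times >= ws & times < we)
    if (length(idx) == 0L) next
    ok <- epochs$counts[idx] <= zcm_max
    runs <- true_runs(ok)
    if (nrow(runs) == 0L) next
    len <- runs$end - runs$start
    best <- which.max(len)
    if (len[best] * ep_min < min_minutes) next
    k <- k + 1L
    out[[k]] <- data.frame(night_index = k,
                           start_epoch = idx[runs$start[best]],
                           end_epoch = idx[runs$start[best]] + len[best],
                           duration_minutes = len[best] * ep_min)
  }
  if (k == 0L)
    return(data.frame(night_index = integer(0), start_epoch = integer(0),
                      end_epoch = integer(0), duration_minutes = numeric(0)))
  do.call(rbind, out)
}

#' Extract movement peaks from a sleep slice
#'
#' A peak is a maximal run of epochs with smoothed ZCM > 0; two peaks are
#' separated by zero-valued epochs. The distance between consecutive peaks
#' is the number of zero epochs between them.
#'
#' @param values smoothed ZCM values of one sleep period.
#' @return data.frame with `start`, `end` (end exclusive, relative to the
#'   slice), `width`, `height` and `gap_to_next` (NA for the last peak).
#' @export
extract_peaks <- function(values) {
  runs <- true_runs(values > 0)
  if (nrow(runs) == 0L)
    return(data.frame(start = integer(0), end = integer(0),
                      width = integer(0), height = numeric(0),
                      gap_to_next = integer(0)))
  width <- runs$end - runs$start
  height <- vapply(seq_len(nrow(runs)), function(i)
    max(values[runs$start[i]:(runs$end[i] - 1L)]), numeric(1))
  gap <- c(runs$start[-1] - runs$end[-nrow(runs)], NA_integer_)
  data.frame(start = runs$start, end = runs$end, width = width,
             height = height, gap_to_next = gap)
}

# pool peaks over all sleep periods, tagging the period they belong to
.pool_peaks <- function(epochs, periods) {
  if (nrow(periods) == 0L)
    return(data.frame(period = integer(0), start = integer(0),
                      end = integer(0), width = integer(0),
                      height = numeric(0), gap_to_next = integer(0)))
  out <- lapply(seq_len(nrow(periods)), function(i) {
    sl <- epochs$counts[periods$start_epoch[i]:(periods$end_epoch[i] - 1L)]
    p <- extract_peaks(sl)
    if (nrow(p)) p$period <- periods$night_index[i]
    p
  })
  out <- out[vapply(out, nrow, integer(1)) > 0]
  if (length(out) == 0L)
    return(data.frame(period = integer(0), start = integer(0),
                      end = integer(0), width = integer(0),
                      height = numeric(0), gap_to_next = integer(0)))
  do.call(rbind, out)
}

# gaps (in epochs) between consecutive member peaks within the same period
.member_distances <- function(peaks) {
  if (nrow(peaks) < 2L) return(numeric(0))
  unlist(lapply(split(peaks, peaks$period), function(p) {
    if (nrow(p) < 2L) return(numeric(0))
    p <- p[order(p$start), ]
    p$start[-1] - p$end[-nrow(p)]
  }), use.names = FALSE)
}

# split pooled peaks into lower/upper groups by height
#  - median split: lower height <= median, upper height > median
#  - quartile split: lower height <= Q1, upper height >= Q3 (middle excluded)
split_peaks <- function(peaks, split = c("median", "quartile")) {
  split <- match.arg(split)
  if (nrow(peaks) == 0L) return(list(lower = peaks, upper = peaks))
  h <- peaks$height
  if (split == "median") {
    m <- stats::median(h)
    list(lower = peaks[h <= m, , drop = FALSE],
         upper = peaks[h > m, , drop = FALSE])
  } else {
    q <- stats::quantile(h, c(0.25, 0.75), names = FALSE)
    list(lower = peaks[h <= q[1], , drop = FALSE],
         upper = peaks[h >= q[2], , drop = FALSE])
  }
}

# {min,max,avg,median} of {distance,width,height} for one peak set, under
# the registry naming scheme
.quantity_stats <- function(peaks, prefix_grp = NULL, suffix = "") {
  d <- family_stats(.member_distances(peaks))
  w <- family_stats(peaks$width)
  h <- family_stats(peaks$height)
  if (is.null(prefix_grp)) {
    nm <- c(paste0("peaks_", names(d), "_distance"),
            paste0("peaks_width_", names(w)),
            paste0("peaks_height_", names(h)))
  } else {
    nm <- c(paste0(prefix_grp, "_humps_", names(d), "_distance", suffix),
            paste0(prefix_grp, "_humps_width_", names(w), suffix),
            paste0(prefix_grp, "_humps_height_", names(h), suffix))
  }
  stats::setNames(as.list(c(d, w, h)), nm)
}

#' Grouped and ungrouped peak family features
#'
#' Pools the peaks of all sleep periods, splits them into lower/upper
#' groups by height (median split: lower <= median; quartile split:
#' lower <= Q1, upper >= Q3, middle excluded) and computes
#' min/max/avg/median of the within-group gap distances, widths and
#' heights, per group and for all peaks, plus the hump counts. "Bigger"
#' features (`*_length_between_bigger`, `*_bigger_values`) refer to the
#' upper group of the median split. Statistics undefined for too few peaks
#' are `NA`.
#'
#' @param epochs a smoothed `epoch_series`.
#' @param periods sleep periods from [detect_sleep_periods()].
#' @return Named list of 73 peak-family features.
#' @export
peak_family_features <- function(epochs, periods) {
  peaks <- .pool_peaks(epochs, periods)
  out <- list()
  counts <- list()
  for (split in c("median", "quartile")) {
    suffix <- if (split == "quartile") "_qrt" else ""
    grp <- split_peaks(peaks, split)
    for (g in c("lower", "upper")) {
      out <- c(out, .quantity_stats(grp[[g]], g, suffix))
      counts[[paste0("number_of_", g, "_humps", suffix)]] <- nrow(grp[[g]])
    }
    if (split == "median") {
      big <- grp$upper
      bd <- family_stats(.member_distances(big))
      bh <- family_stats(big$height)
      out <- c(out,
        stats::setNames(as.list(bd),
                        paste0(names(bd), "_length_between_bigger")),
        stats::setNames(as.list(bh), paste0(names(bh), "_bigger_values")))
    }
  }
  out <- c(out, .quantity_stats(peaks, NULL))
  out$number_of_peaks <- nrow(peaks)
  c(out, counts)
}

#' Fraction of zero-activity epochs
#'
#' Computed over the whole smoothed recording; doubles as the baseline
#' "ZCM null-ratio".
#'
#' @param epochs an `epoch_series`.
#' @return Fraction in [0, 1].
#' @export
zero_ratio <- function(epochs) {
  stopifnot(inherits(epochs, "epoch_series"))
  if (length(epochs$counts) == 0L) stop("empty epoch series")
  mean(epochs$counts == 0)
}

#' Sleep fragmentation index
#'
#' Ratio of mobile time during sleep to total sleep time, averaged over
#' nights. A mobile epoch has raw (unsmoothed) ZCM above
#' `activity_threshold` (default 5, the sleep activity ceiling): sleep
#' periods are delimited on the smoothed series, within which individual
#' raw epochs may still spike above the ceiling — those are the mobile
#' minutes. Immobile runs shorter than one minute also count as mobile, a
#' clause that is vacuous at the default 60 s epoch length and only takes
#' effect for sub-minute epochs.
#'
#' @param epochs the raw `epoch_series` (same grid as the smoothed series
#'   the periods were detected on).
#' @param periods sleep periods from [detect_sleep_periods()].
#' @param activity_threshold mobility threshold on raw ZCM.
#' @return frg_index in [0, 1].
#' @export
fragmentation_index <- function(epochs, periods, activity_threshold = 5) {
  if (nrow(periods) == 0L) stop("no sleep period detected")
  ep_min <- epochs$epoch_seconds / 60
  per_night <- vapply(seq_len(nrow(periods)), function(i) {
    v <- epochs$counts[periods$start_epoch[i]:(periods$end_epoch[i] - 1L)]
    mobile <- v > activity_threshold
    if (ep_min < 1) {              # sub-minute epochs: short immobile runs count
      runs <- true_runs(!mobile)
      short <- runs[(runs$end - runs$start) * ep_min < 1, , drop = FALSE]
      if (nrow(short))
        for (i2 in seq_len(nrow(short)))
          mobile[short$start[i2]:(short$end[i2] - 1L)] <- TRUE
    }
    mean(mobile)
  }, numeric(1))
  mean(per_night)
}

#' Mean nightly sleep duration in minutes
#'
#' @param periods sleep periods from [detect_sleep_periods()].
#' @return Mean duration in minutes, or `NA` if no sleep was detected.
#' @export
sleep_length_minutes <- function(periods) {
  if (nrow(periods) == 0L) return(NA_real_)
  mean(periods$duration_minutes)
}
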