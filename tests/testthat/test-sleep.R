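# Sleep-period detection, peak extraction and the nocturnal feature families.

noon_start <- as.POSIXct("2023-01-02 12:00:00", tz = "UTC")

test_that("sleep periods are the longest low-activity nocturnal runs", {
  # 1.5 days from noon; smoothed ZCM <= 5 exactly 23:00-07:00
  n <- 36 * 60
  times <- as.numeric(noon_start) + (seq_len(n) - 1) * 60
  hour <- (times %% 86400) / 3600
  x <- ifelse(hour >= 23 | hour < 7, 3, 60)
  per <- detect_sleep_periods(make_epochs(x, start = noon_start))
  expect_equal(nrow(per), 1)
  expect_equal(per$duration_minutes, 480)

  # uniformly active recording has no sleep
  expect_equal(nrow(detect_sleep_periods(make_epochs(rep(60, n),
                                                     start = noon_start))), 0)

  # two qualifying runs in one night: the longer one wins
  x2 <- rep(60, n)
  x2[601:900] <- 2                    # 22:00-03:00, 300 min
  x2[991:1410] <- 2                   # 04:30-11:30, 420 min
  per2 <- detect_sleep_periods(make_epochs(x2, start = noon_start))
  expect_equal(nrow(per2), 1)
  expect_equal(per2$duration_minutes, 420)

  # runs shorter than the 120-min minimum are not sleep
  x3 <- rep(60, n); x3[which(hour >= 23)[1:90]] <- 0
  expect_equal(nrow(detect_sleep_periods(make_epochs(x3,
                                                     start = noon_start))), 0)
})

test_that("peaks are maximal nonzero runs with widths, heights and gaps", {
  p <- extract_peaks(c(0, 3, 4, 0, 0, 1, 0))
  expect_equal(nrow(p), 2)
  expect_equal(p$width, c(2, 1))
  expect_equal(p$height, c(4, 1))
  expect_equal(p$gap_to_next, c(2, NA))
  expect_equal(nrow(extract_peaks(rep(0, 10))), 0)
  expect_equal(nrow(extract_peaks(c(0, 2, 2, 0))), 1)
})

test_that("every sleep epoch belongs to exactly one peak or one gap", {
  set.seed(5)
  for (i in 1:20) {
    v <- rpois(300, 0.7)
    p <- extract_peaks(v)
    covered <- integer(0)
    if (nrow(p))
      covered <- unlist(lapply(seq_len(nrow(p)),
                               function(j) p$start[j]:(p$end[j] - 1)))
    expect_equal(sort(covered), which(v > 0))
    expect_false(anyDuplicated(covered) > 0)
  }
})

test_that("median and quartile splits follow the tie rules", {
  mk <- function(h) data.frame(period = 1, start = seq_along(h) * 10,
                               end = seq_along(h) * 10 + 1, width = 1,
                               height = h, gap_to_next = NA)
  sp <- actiphen:::split_peaks(mk(c(1, 2, 3, 4)), "median")
  expect_equal(sort(sp$lower$height), c(1, 2))
  expect_equal(sort(sp$upper$height), c(3, 4))
  # all equal heights -> everything lower (height <= median)
  sp2 <- actiphen:::split_peaks(mk(rep(4, 5)), "median")
  expect_equal(nrow(sp2$lower), 5)
  expect_equal(nrow(sp2$upper), 0)
  # quartile split keeps the tails, drops the middle
  sp3 <- actiphen:::split_peaks(mk(1:8), "quartile")
  expect_equal(sort(sp3$lower$height), c(1, 2))
  expect_equal(sort(sp3$upper$height), c(7, 8))
})

test_that("family statistics match brute-force recomputation", {
  set.seed(6)
  v <- rpois(720, 0.6) * rpois(720, 2)
  ep <- make_epochs(c(rep(60, 300), v, rep(60, 360)), start = noon_start)
  per <- data.frame(night_index = 1, start_epoch = 301, end_epoch = 1021,
                    duration_minutes = 720)
  fam <- peak_family_features(ep, per)
  expect_length(fam, 73)
  peaks <- extract_peaks(v)
  expect_equal(fam$number_of_peaks, nrow(peaks))
  expect_equal(fam$peaks_width_max, max(peaks$width))
  expect_equal(fam$peaks_median_distance,
               median(peaks$gap_to_next, na.rm = TRUE))
  m <- median(peaks$height)
  up <- peaks[peaks$height > m, ]
  expect_equal(fam$number_of_upper_humps, nrow(up))
  expect_equal(fam$min_bigger_values, min(up$height))
  expect_equal(fam$upper_humps_height_min, min(up$height))
  expect_equal(fam$avg_bigger_values, mean(up$height))
  # within-group distances: consecutive member gaps (end -> next start)
  up <- up[order(up$start), ]
  gaps <- up$start[-1] - up$end[-nrow(up)]
  expect_equal(fam$min_length_between_bigger, min(gaps))
  expect_equal(fam$upper_humps_avg_distance, mean(gaps))
  # degenerate: a single peak defines no distances
  fam1 <- peak_family_features(make_epochs(c(rep(60, 300), rep(0, 350), 3,
                                             rep(0, 369), rep(60, 360)),
                                           start = noon_start), per)
  expect_true(is.na(fam1$peaks_min_distance))
  expect_equal(fam1$number_of_peaks, 1)
})

test_that("zero ratio and sleep length follow their definitions", {
  expect_equal(zero_ratio(make_epochs(rep(0, 10))), 1)
  expect_equal(zero_ratio(make_epochs(rep(2, 10))), 0)
  expect_equal(zero_ratio(make_epochs(rep(c(0, 1), each = 30))), 0.5)
  expect_error(zero_ratio(make_epochs(numeric(0))), "empty")

  pd <- function(d) data.frame(night_index = seq_along(d),
                               start_epoch = rep(1, length(d)),
                               end_epoch = rep(2, length(d)),
                               duration_minutes = d)
  expect_equal(sleep_length_minutes(pd(480)), 480)
  expect_equal(sleep_length_minutes(pd(c(400, 500))), 450)
  expect_true(is.na(sleep_length_minutes(pd(numeric(0)))))
})

test_that("fragmentation index is the raw-mobile fraction of sleep", {
  raw <- make_epochs(c(rep(0, 45), rep(20, 10), rep(0, 45)), smoothed = FALSE)
  per <- data.frame(night_index = 1, start_epoch = 1, end_epoch = 101,
                    duration_minutes = 100)
  expect_equal(fragmentation_index(raw, per), 0.1)
  expect_equal(fragmentation_index(make_epochs(rep(0, 100)), per), 0)
  expect_equal(fragmentation_index(make_epochs(rep(30, 100)), per), 1)
  expect_error(fragmentation_index(raw, per[0, ]), "no sleep")
  # averaged over nights
  per2 <- rbind(per, data.frame(night_index = 2, start_epoch = 1,
                                end_epoch = 51, duration_minutes = 50))
  v <- c(rep(25, 10), rep(0, 90))
  expect_equal(fragmentation_index(make_epochs(v), per2),
               mean(c(0.1, 0.2)))
})

test_that("fragmentation rises with the generator's nocturnal event rate", {
  frg_at <- function(rate, seed) {
    p <- group_profile("C", nocturnal_bout_rate = rate, twitch_rate = rate,
                       subject_cv = 0)
    rec <- simulate_recording(p, days = 1, seed = seed,
                              start_time = noon_start)
    pr <- prep_recording(rec)
    per <- detect_sleep_periods(pr$epochs)
    if (nrow(per) == 0) return(NA_real_)
    fragmentation_index(pr$raw_epochs, per)
  }
  lo <- vapply(1:8, function(s) frg_at(0.3, s), numeric(1))
  hi <- vapply(1:8, function(s) frg_at(3, s), numeric(1))
  expect_gt(median(hi, na.rm = TRUE), median(lo, na.rm = TRUE))
})
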