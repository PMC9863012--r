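# Synthetic cohort generator: labeled raw wrist-accelerometer recordings
# with the statistical structure the analysis pipeline assumes (10 Hz,
# +/-8 g, a 24-h rest-activity cycle with a nightly low-activity window,
# sparse nocturnal movement bouts, gravity on +z, wide-band sensor noise)
# and group-dependent contrasts that downstream stages must recover.

#' Group-level generative profile
#'
#' @param group `"C"`, `"CTF"` or `"PSF"`.
#' @param day_mean_intensity dimensionless daytime activity drive (scales
#'   the daytime burst amplitude; 1 is a typical active day).
#' @param day_intensity_sd sdlog of the minute-scale lognormal intensity
#'   variation during the day.
#' @param sleep_onset_hour,sleep_duration_h clock hour of sleep onset and
#'   sleep duration in hours.
#' @param nocturnal_bout_rate movement bouts per hour of sleep.
#' @param nocturnal_bout_duration_mean mean bout duration in minutes
#'   (exponential durations).
#' @param nocturnal_bout_amplitude bout acceleration amplitude in g.
#' @param interdaily_jitter in [0, 1]; convex weight of day-specific noise
#'   against the fixed daily template in the hourly intensity profile
#'   (higher jitter -> lower interdaily stability).
#' @param noise_floor_sd wide-band sensor noise standard deviation in g.
#' @param evening_boost multiplier on the 16:00--24:00 intensity.
#' @param phase_sd_h between-subject circadian phase-shift standard
#'   deviation in hours (morning/evening types).
#' @param modulation_cv between-subject lognormal CV of the diurnal
#'   modulation depth (flat vs peaked day profiles).
#' @param intensity_cv between-subject lognormal CV of the overall day
#'   intensity.
#' @param bout_cluster_mean mean number of bouts per nocturnal bout
#'   cluster (1 = unclustered Poisson placement).
#' @param bout_cluster_spread within-cluster placement spread in minutes.
#' @param twitch_rate brief (~1 min) high-amplitude movement twitches per
#'   hour of sleep; they spike the raw per-minute crossing count above the
#'   sleep ceiling (driving the fragmentation index) while barely raising
#'   the smoothed profile, so fragmentation varies independently of the
#'   sustained-bout geometry.
#' @param twitch_duration_mean mean twitch duration in minutes
#'   (exponential, at least one minute).
#' @param twitch_amplitude twitch acceleration amplitude in g.
#' @param quiet_rate sedentary "quiet spells" per waking hour (Poisson),
#'   minutes in which movement drops below the crossing threshold; they
#'   inject subject-specific daytime zero epochs, as idiosyncratic
#'   sedentary behavior does in real cohorts.
#' @param quiet_duration_mean mean quiet-spell duration in minutes.
#' @param subject_cv between-subject coefficient of variation applied
#'   independently to bout rate, duration, amplitude and quiet-spell rate
#'   (lognormal multipliers), decoupling nocturnal intensity,
#'   fragmentation and zero-ratio within a group.
#' @param jitter_sd between-subject standard deviation of the jitter.
#' @return Named list of class `group_profile`.
#' @export
group_profile <- function(group = "C",
                          day_mean_intensity = 1.0,
                          day_intensity_sd = 0.35,
                          sleep_onset_hour = 23,
                          sleep_duration_h = 8,
                          nocturnal_bout_rate = 2.0,
                          nocturnal_bout_duration_mean = 3,
                          nocturnal_bout_amplitude = 0.020,
                          interdaily_jitter = 0.30,
                          noise_floor_sd = 0.01,
                          evening_boost = 1.0,
                          phase_sd_h = 1.0,
                          modulation_cv = 0.35,
                          intensity_cv = 0.25,
                          bout_cluster_mean = 1.5,
                          bout_cluster_spread = 8,
                          twitch_rate = 1.2,
                          twitch_duration_mean = 1,
                          twitch_amplitude = 0.0195,
                          quiet_rate = 1.2,
                          quiet_duration_mean = 15,
                          subject_cv = 0.5,
                          jitter_sd = 0.07) {
  p <- as.list(environment())
  stopifnot(p$nocturnal_bout_rate >= 0, p$nocturnal_bout_duration_mean >= 0,
            p$nocturnal_bout_amplitude >= 0, p$noise_floor_sd >= 0,
            p$interdaily_jitter >= 0, p$interdaily_jitter <= 1,
            p$sleep_duration_h > 0, p$sleep_duration_h < 24)
  class(p) <- "group_profile"
  p
}

#' Default group profiles
#'
#' Contrasts against control encode the recovery targets: the cyclothymia
#' profile has more and longer nocturnal movement bouts (higher L5 and
#' fragmentation index) and a less repeatable day-to-day profile (lower
#' IS); the positive-schizotypy profile has fewer and weaker bouts, longer
#' sleep (higher zero ratio, lower L5) and a more repeatable profile
#' (higher IS). Effect sizes are chosen for testability; the vignette
#' discusses them.
#'
#' @return Named list of `group_profile`s for `C`, `CTF`, `PSF`.
#' @export
default_group_profiles <- function() {
  list(
    C = group_profile("C",
                      nocturnal_bout_rate = 1.0,
                      nocturnal_bout_duration_mean = 2.5,
                      nocturnal_bout_amplitude = 0.016,
                      twitch_rate = 0.8,
                      interdaily_jitter = 0.38),
    CTF = group_profile("CTF",
                        day_mean_intensity = 0.88,
                        nocturnal_bout_rate = 1.0,
                        nocturnal_bout_duration_mean = 2.5,
                        nocturnal_bout_amplitude = 0.020,
                        twitch_rate = 1.2,
                        twitch_amplitude = 0.0215,
                        interdaily_jitter = 0.58),
    PSF = group_profile("PSF",
                        day_mean_intensity = 0.93,
                        evening_boost = 1.15,
                        sleep_duration_h = 8.6,
                        nocturnal_bout_rate = 0.7,
                        nocturnal_bout_duration_mean = 2.5,
                        nocturnal_bout_amplitude = 0.018,
                        twitch_rate = 1.2,
                        twitch_amplitude = 0.015,
                        quiet_rate = 1.6,
                        interdaily_jitter = 0.12)
  )
}

# fixed daytime template over clock hours 0..23 (unit mean over waking hours)
.day_template <- function() {
  h <- 0:23
  t <- 0.55 + 0.5 * sin(pi * pmax(h - 6, 0) / 17)
  t[h < 6] <- 0.55
  t
}

# band-limited unit-variance noise in the human voluntary-movement band
# (0.5-3 Hz, narrowed below Nyquist if needed), so simulated activity
# survives the 0.25-2.5 Hz analysis band-pass
.burst_noise <- function(n, fs) {
  hi <- min(3, 0.45 * fs)
  bf <- signal::butter(2, c(0.5, hi) / (fs / 2), type = "pass")
  e <- .filtfilt_iir(bf, .bulk_normal(n))
  s <- stats::sd(e)
  if (s > 0) e / s else e
}

# bulk standard-normal draws via the compiled generator, seeded from the
# R stream so reproducibility still follows set.seed / with_seed
.bulk_normal <- function(n) {
  .fast_rnorm(n, floor(stats::runif(1) * 9.007199e15))
}

#' Simulate one raw recording
#'
#' Piecewise-stationary generative model: a minute-resolution intensity
#' process (daytime template mixed with day-specific hourly noise by
#' `interdaily_jitter`, lognormal minute-scale variation; near-zero during
#' the sleep window except during Poisson-placed movement bouts) drives the
#' amplitude of band-limited (0.5--3 Hz) burst noise per axis; constant 1 g
#' gravity sits on +z and wide-band sensor noise with `noise_floor_sd` is
#' added everywhere. Samples are clipped to the +/-8 g envelope. Fully
#' reproducible from `seed`.
#'
#' @param profile a [group_profile()].
#' @param days recording length in days (may be fractional).
#' @param sampling_rate samples per second (default 10 Hz).
#' @param seed integer seed.
#' @param start_time recording start timestamp.
#' @param subject_id identifier.
#' @return A [raw_recording()]; realized subject-level parameters are
#'   attached as field `truth`.
#' @export
simulate_recording <- function(profile, days, sampling_rate = 10, seed = 1L,
                               start_time = as.POSIXct("2023-01-02 00:00:00",
                                                       tz = "UTC"),
                               subject_id = "sim") {
  stopifnot(inherits(profile, "group_profile"), days >= 1 / 24)
  if (!inherits(start_time, "POSIXct"))
    start_time <- as.POSIXct(start_time, tz = "UTC")
  fs <- sampling_rate
  n_min <- round(days * 1440)
  spm <- round(60 * fs)                     # samples per minute
  n <- n_min * spm
  with_seed(seed, {
    # subject-level heterogeneity
    cv <- profile$subject_cv
    mult <- function() if (cv > 0) stats::rlnorm(1, -cv^2 / 2, cv) else 1
    rate <- profile$nocturnal_bout_rate * mult()
    bdur <- profile$nocturnal_bout_duration_mean * mult()
    # amplitude heterogeneity kept small: crossing counts respond steeply to
    # amplitude near the threshold, and humps must stay under the sleep ceiling
    acv <- cv / 2.5
    bamp <- profile$nocturnal_bout_amplitude *
      (if (acv > 0) stats::rlnorm(1, -acv^2 / 2, acv) else 1)
    jit <- min(max(profile$interdaily_jitter +
                     stats::rnorm(1, 0, profile$jitter_sd), 0.02), 0.95)
    # independent trait axes: circadian phase, diurnal modulation depth,
    # overall intensity, bout clustering; they decorrelate the feature
    # families the way idiosyncratic behavior does in real cohorts
    phase_min <- stats::rnorm(1, 0, profile$phase_sd_h * 60)
    depth <- if (profile$modulation_cv > 0)
      stats::rlnorm(1, -profile$modulation_cv^2 / 2, profile$modulation_cv)
    else 1
    inten <- profile$day_mean_intensity *
      (if (profile$intensity_cv > 0)
        stats::rlnorm(1, -profile$intensity_cv^2 / 2, profile$intensity_cv)
      else 1)
    cl_mean <- max(1, profile$bout_cluster_mean *
                     (if (cv > 0) stats::rlnorm(1, -cv^2 / 8, cv / 2) else 1))
    twrate <- profile$twitch_rate * stats::rlnorm(1, -0.02, 0.2)
    twdur <- profile$twitch_duration_mean * mult()
    twamp <- profile$twitch_amplitude * stats::rlnorm(1, -0.0072, 0.12)
    boost <- profile$evening_boost *
      (if (cv > 0) stats::rlnorm(1, -(cv / 2)^2 / 2, cv / 2) else 1)
    isd <- profile$day_intensity_sd *
      (if (cv > 0) stats::rlnorm(1, -(cv / 2)^2 / 2, cv / 2) else 1)
    truth <- list(bout_rate = rate, bout_duration = bdur,
                  twitch_duration = twdur, twitch_amplitude_s = NA,
                  bout_amplitude = bamp, jitter = jit,
                  phase_min = phase_min, depth = depth, intensity = inten,
                  cluster_mean = cl_mean, twitch_rate = twrate,
                  evening_boost = boost, day_intensity_sd = isd)

    t_min <- as.numeric(start_time) + (seq_len(n_min) - 1) * 60
    clock_min <- t_min %% 86400             # seconds into the clock day
    hour <- clock_min %/% 3600
    day_idx <- (t_min - t_min[1]) %/% 86400 + 1

    # sleep mask: one window per night; subject-level chronotype shift
    # plus night-to-night onset/duration jitter
    asleep <- rep(FALSE, n_min)
    onset_base <- profile$sleep_onset_hour * 3600 +
      stats::rnorm(1, 0, 40 * 60)
    first_mid <- (t_min[1] %/% 86400) * 86400 - 86400
    night_anchors <- seq(first_mid, max(t_min) + 86400, by = 86400)
    sleep_len_min <- numeric(0)
    for (a in night_anchors) {
      on <- a + onset_base + stats::rnorm(1, 0, 30 * 60)
      len <- max(60, profile$sleep_duration_h * 3600 +
                   stats::rnorm(1, 0, 40 * 60))
      sel <- t_min >= on & t_min < on + len
      if (any(sel)) {
        asleep[sel] <- TRUE
        sleep_len_min <- c(sleep_len_min, sum(sel))
      }
    }
    truth$sleep_minutes <- sleep_len_min

    # day intensity: phase-shifted, depth-scaled template mixed with
    # day-specific hourly noise at weight `jit`
    t24 <- .day_template()
    tmean <- mean(t24)
    shifted_hour <- (floor((clock_min / 60 - phase_min) / 60)) %% 24
    templ <- tmean + depth * (t24[shifted_hour + 1] - tmean)
    templ <- pmax(templ, 0.05)
    # day-specific noise drawn per 3-hour block, so it reshapes the daily
    # profile (lowering IS) without inflating hour-to-hour variability
    vkey <- paste(day_idx, hour %/% 3)
    uv <- unique(vkey)
    vday <- stats::setNames(stats::rlnorm(length(uv), -0.5, 1.0), uv)
    lambda <- inten *
      ((1 - jit) * templ + jit * vday[vkey]) *
      stats::rlnorm(n_min, -isd^2 / 2, isd)
    lambda <- as.numeric(lambda)
    if (boost != 1) lambda[hour >= 16] <- lambda[hour >= 16] * boost

    # per-minute burst amplitude in g; 0.05 g per unit intensity keeps the
    # daytime crossing rate on the sensitive mid-slope of the threshold
    # response, so intensity variation maps onto ZCM variation
    amp <- 0.05 * lambda
    amp[asleep] <- 0

    # sedentary quiet spells during waking time (subject-specific rate):
    # movement drops below the crossing threshold for a few minutes
    qrate <- profile$quiet_rate * mult()
    if (qrate > 0 && profile$quiet_duration_mean > 0) {
      wake <- which(!asleep)
      n_spells <- stats::rpois(1, qrate * length(wake) / 60)
      if (n_spells > 0) {
        starts <- sort(sample(wake, min(n_spells, length(wake))))
        durs <- pmax(1L, round(stats::rexp(length(starts),
                                           1 / profile$quiet_duration_mean)))
        for (qi in seq_along(starts)) {
          idx <- starts[qi]:min(starts[qi] + durs[qi] - 1L, n_min)
          amp[idx[!asleep[idx]]] <- 0
        }
      }
    }
    sleep_runs <- true_runs(asleep)
    if (rate > 0 && bdur > 0 && bamp > 0 && nrow(sleep_runs) > 0) {
      for (i in seq_len(nrow(sleep_runs))) {
        s0 <- sleep_runs$start[i]; s1 <- sleep_runs$end[i] - 1L
        len_h <- (s1 - s0 + 1) / 60
        # Neyman-Scott placement: Poisson cluster centres, bouts scattered
        # around them; cl_mean = 1 degenerates to plain Poisson placement
        n_cl <- stats::rpois(1, rate * len_h / cl_mean)
        if (n_cl == 0) next
        centres <- sample.int(s1 - s0 + 1L, n_cl, replace = TRUE) + s0 - 1L
        per_cl <- 1L + stats::rpois(n_cl, cl_mean - 1)
        starts <- round(rep(centres, per_cl) +
                          stats::rnorm(sum(per_cl), 0,
                                       profile$bout_cluster_spread))
        starts <- pmin(pmax(starts, s0), s1)
        n_bouts <- length(starts)
        durs <- pmax(1L, round(stats::rexp(n_bouts, 1 / bdur)))
        amps <- pmin(bamp * stats::rlnorm(n_bouts, -0.045, 0.3), 0.022)
        for (b in seq_len(n_bouts)) {
          idx <- starts[b]:min(starts[b] + durs[b] - 1L, s1)
          amp[idx] <- pmax(amp[idx], amps[b])
        }
      }
    }
    # movement twitches: isolated 1-minute spikes during sleep
    if (twrate > 0 && profile$twitch_amplitude > 0 && nrow(sleep_runs) > 0) {
      for (i in seq_len(nrow(sleep_runs))) {
        s0 <- sleep_runs$start[i]; s1 <- sleep_runs$end[i] - 1L
        n_tw <- stats::rpois(1, twrate * (s1 - s0 + 1) / 60)
        if (n_tw == 0) next
        at <- s0 - 1L + sample.int(s1 - s0 + 1L, min(n_tw, s1 - s0 + 1L))
        tdur <- pmax(1L, round(stats::rexp(length(at), 1 / max(twdur, 0.01))))
        for (ti in seq_along(at)) {
          idx <- at[ti]:min(at[ti] + tdur[ti] - 1L, s1)
          amp[idx] <- pmax(amp[idx], twamp * stats::rlnorm(1, 0, 0.08))
        }
      }
    }

    A <- rep(amp, each = spm)
    any_burst <- any(A > 0)
    axis_signal <- function() {
      v <- if (any_burst) A * .burst_noise(n, fs) else numeric(n)
      if (profile$noise_floor_sd > 0)
        v <- v + profile$noise_floor_sd * .bulk_normal(n)
      v
    }
    rec <- suppressWarnings(
      raw_recording(axis_signal(), axis_signal(), axis_signal() + 1,
                    sampling_rate = fs,   # gravity on +z
                    start_time = start_time, subject_id = subject_id,
                    group_label = profile$group))
    rec$truth <- truth
    rec
  })
}

#' Cohort specification
#'
#' @param n_per_group named counts, default `c(C = 25, CTF = 22, PSF = 22)`
#'   (the analyzed cohort sizes).
#' @param days_per_subject recording length in days (default 10, the length
#'   of the deposited raw recordings).
#' @param sampling_rate samples per second (default 10 Hz).
#' @param seed cohort seed; per-subject seeds are derived deterministically.
#' @param profiles list of [group_profile()]s, one per group.
#' @param start_time common recording start.
#' @return List of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_group = c(C = 25, CTF = 22, PSF = 22),
                        days_per_subject = 10, sampling_rate = 10,
                        seed = 1L, profiles = default_group_profiles(),
                        start_time = as.POSIXct("2023-01-02 00:00:00",
                                                tz = "UTC")) {
  stopifnot(all(n_per_group >= 1), days_per_subject > 0)
  stopifnot(all(names(n_per_group) %in% names(profiles)))
  structure(list(n_per_group = n_per_group,
                 days_per_subject = days_per_subject,
                 sampling_rate = sampling_rate, seed = as.integer(seed),
                 profiles = profiles, start_time = start_time),
            class = "cohort_spec")
}

#' Simulate a labeled cohort
#'
#' @param spec a [cohort_spec()].
#' @param process optional function applied to each recording as it is
#'   generated; its value is stored in place of the raw recording. Passing
#'   e.g. [prep_recording()] keeps memory bounded on large cohorts (a full
#'   raw cohort at 10 Hz does not fit comfortably in memory).
#' @param verbose log progress.
#' @return list with `recordings` (raw recordings, or `process` results),
#'   `labels` (character vector) and `truth` (per-subject realized
#'   generative parameters).
#' @export
simulate_cohort <- function(spec, process = NULL, verbose = FALSE) {
  stopifnot(inherits(spec, "cohort_spec"))
  recs <- list(); labels <- character(0); truth <- list()
  k <- 0L
  for (g in names(spec$n_per_group)) {
    for (i in seq_len(spec$n_per_group[[g]])) {
      k <- k + 1L
      id <- sprintf("%s%02d", g, i)
      rec <- simulate_recording(spec$profiles[[g]],
                                days = spec$days_per_subject,
                                sampling_rate = spec$sampling_rate,
                                seed = child_seed(spec$seed, k),
                                start_time = spec$start_time,
                                subject_id = id)
      truth[[id]] <- rec$truth
      recs[[id]] <- if (is.null(process)) rec else process(rec)
      labels <- c(labels, g)
      if (verbose) message("simulated ", id)
    }
  }
  list(recordings = recs, labels = labels, truth = truth)
}
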