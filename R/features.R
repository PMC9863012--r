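#' Extract the full 96-feature registry from one recording
#'
#' Runs the preprocessing chain (band-pass, ZCM, smoothing) and all feature
#' families — circadian metrics, Savitzky--Golay boundary features, clock
#' thirds and daily summaries, nocturnal peak families, zero ratio,
#' fragmentation index, sleep length, and the Morlet structure scalars —
#' and returns them as one named vector in registry order. Features whose
#' preconditions fail on a given recording (e.g. no detected sleep) are
#' `NA`.
#'
#' @param rec a [raw_recording()], a prepared list from
#'   [prep_recording()], or a pre-computed smoothed `epoch_series` (in
#'   which case the fragmentation index falls back to the smoothed
#'   counts).
#' @param cfg an [acti_config()].
#' @return Named numeric vector of length 96 (registry order).
#' @export
extract_features <- function(rec, cfg = acti_config()) {
  if (inherits(rec, "raw_recording")) rec <- prep_recording(rec, cfg)
  if (inherits(rec, "epoch_series")) rec <- list(raw_epochs = rec, epochs = rec)
  epochs <- rec$epochs
  raw_epochs <- rec$raw_epochs
  reg <- feature_registry(cfg$registry_version)
  out <- stats::setNames(rep(NA_real_, length(reg)), reg)
  fill <- function(vals) {
    vals <- unlist(vals)
    out[names(vals)] <<- as.numeric(vals)
  }
  try_fill <- function(expr) tryCatch(fill(expr), error = function(e) NULL)

  try_fill(nonparametric_profile(epochs))
  try_fill(list(IS = interdaily_stability(epochs)))
  try_fill(list(IV = intradaily_variability(epochs)))
  try_fill(thirds_and_daily(epochs))
  try_fill(savgol_boundary_features(epochs, cfg$savgol_window,
                                    cfg$savgol_polyorder,
                                    cfg$extremum_halfwidth))
  out["zero_ratio"] <- zero_ratio(epochs)

  periods <- detect_sleep_periods(epochs, cfg$sleep_zcm_max,
                                  cfg$sleep_min_minutes,
                                  cfg$night_start_hour, cfg$night_end_hour)
  out["length_of_sleep_in_minutes"] <- sleep_length_minutes(periods)
  if (nrow(periods) > 0L) {
    try_fill(list(frg_index =
      fragmentation_index(raw_epochs, periods, cfg$frg_activity_threshold)))
    try_fill(peak_family_features(epochs, periods))
  }
  if (nrow(periods) >= 2L) {
    try_fill({
      sleep_series <- suppressWarnings(
        concatenate_sleep(epochs, periods, cfg$nights_concatenated))
      map <- suppressWarnings(morlet_cwt(
        sleep_series, cfg$wavelet_scale_min:cfg$wavelet_scale_max,
        cfg$wavelet_omega0, dt = epochs$epoch_seconds / 60))
      structure_band_features(structure_curve(map),
                              cfg$pm_band, cfg$pm_stdev_band)
    })
  }
  out
}

#' Build a feature table for a set of recordings
#'
#' Applies the validity rule, extracts the 96-feature registry per accepted
#' recording and assembles a [feature_table()]. Missing values (features
#' whose preconditions failed for a subject) are imputed with the column
#' median when `impute = "median"`.
#'
#' @param recordings list of [raw_recording()] objects or of prepared
#'   lists from [prep_recording()] (labels and ids are read from their
#'   `group_label` / `subject_id` fields).
#' @param cfg an [acti_config()].
#' @param impute `"median"` (default) or `"none"`.
#' @param verbose log per-stage counts.
#' @return A `feature_table`; rejected recordings are reported in the
#'   `rejected` attribute.
#' @export
build_feature_table <- function(recordings, cfg = acti_config(),
                                impute = c("median", "none"),
                                verbose = FALSE) {
  impute <- match.arg(impute)
  ok <- vapply(recordings, function(r) {
    v <- if (inherits(r, "raw_recording")) r else r$epochs
    validity_filter(v, cfg$min_valid_days)$accepted
  }, logical(1))
  if (verbose)
    message("validity filter: ", sum(ok), "/", length(ok),
            " recordings kept (>= ", cfg$min_valid_days, " days)")
  get_id <- function(r) as.character(r$subject_id)
  rejected <- vapply(recordings[!ok], get_id, character(1))
  recordings <- recordings[ok]
  if (length(recordings) == 0L) stop("no recording passed the validity rule")
  rows <- lapply(recordings, extract_features, cfg = cfg)
  m <- do.call(rbind, rows)
  if (impute == "median" && anyNA(m)) {
    for (j in seq_len(ncol(m))) {
      nas <- is.na(m[, j])
      if (any(nas)) m[nas, j] <- stats::median(m[, j], na.rm = TRUE)
    }
  }
  tab <- feature_table(m,
                       vapply(recordings, get_id, character(1)),
                       vapply(recordings, function(r)
                         as.character(r$group_label), character(1)),
                       registry_version = cfg$registry_version)
  attr(tab, "rejected") <- rejected
  tab
}

#' The 3-feature reference baseline
#'
#' Per-subject mean, population standard deviation and zero fraction of the
#' smoothed ZCM series — the minimal descriptor set every candidate model
#' must outperform.
#'
#' @param epoch_list named list of smoothed `epoch_series`, one per subject.
#' @param labels per-subject group labels.
#' @return Matrix (subjects x 3) with columns `zcm_mean`, `zcm_stdev`,
#'   `zcm_zero_ratio`.
#' @export
baseline_features <- function(epoch_list, labels = NULL) {
  rows <- t(vapply(epoch_list, function(e) {
    stopifnot(inherits(e, "epoch_series"))
    if (length(e$counts) == 0L) stop("empty epoch series")
    c(zcm_mean = mean(e$counts), zcm_stdev = pop_sd(e$counts),
      zcm_zero_ratio = mean(e$counts == 0))
  }, numeric(3)))
  rownames(rows) <- names(epoch_list)
  rows
}
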