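#' Pipeline configuration
#'
#' Collects every tunable constant of the pipeline in one validated list.
#' Defaults are the analysis constants: a 0.25--2.5 Hz Butterworth band,
#' a 0.05 g zero-crossing threshold summed into 60 s epochs, 5+5 sliding-window
#' smoothing, a 2-day validity bound, nocturnal sleep detection at smoothed
#' ZCM <= 5, Welch screening at alpha = 0.3, a |r| <= 0.3 low-correlation
#' graph with maximal cliques of at least 8 features, 1600 sampled feature
#' combinations, 10-fold cross-validation, and Morlet structure bands of
#' 20--100 min (integral) and 51--67 min (standard deviation) on a linear
#' 1--200 min scale grid over 5 concatenated nights.
#'
#' @param ... named overrides of any default listed below.
#' @return A named list of class `acti_config`.
#' @examples
#' cfg <- acti_config(n_combinations = 40)
#' cfg$zcm_threshold
#' @export
acti_config <- function(...) {
  cfg <- list(
    bandpass_low        = 0.25,   # Hz
    bandpass_high       = 2.5,    # Hz
    filter_order        = 4,      # Butterworth order, applied forward-backward
    zcm_threshold       = 0.05,   # g
    epoch_seconds       = 60,
    smooth_before       = 5,      # epochs
    smooth_after        = 5,      # epochs
    min_valid_days      = 2,
    sleep_zcm_max       = 5,      # smoothed counts/epoch
    sleep_min_minutes   = 120,    # minimum qualifying nocturnal run
    night_start_hour    = 18,     # night window 18:00 -> next-day noon
    night_end_hour      = 12,
    frg_activity_threshold = 5,   # mobile epoch = raw ZCM > this
    savgol_window       = 61,     # epochs
    savgol_polyorder    = 3,
    extremum_halfwidth  = 15,     # epochs; strict local extrema neighborhood
    wavelet_omega0      = 6,
    wavelet_scale_min   = 1,      # min (Fourier period)
    wavelet_scale_max   = 200,    # min
    pm_band             = c(20, 100),  # min
    pm_stdev_band       = c(51, 67),   # min
    nights_concatenated = 5,
    welch_alpha         = 0.3,
    corr_edge_threshold = 0.3,
    corr_method         = "pearson",
    min_clique_size     = 8,
    n_combinations      = 1600,
    cv_folds            = 10,
    algorithms          = c("lgr", "rf", "gb"),
    shap_exact_max      = 8,      # exact coalition enumeration up to this many features
    shap_n_perm         = 16,     # permutations for the sampling estimator
    shap_background_max = 8,      # background rows subsampled for replacement
    direction_r_cut     = 0.3,    # |cor| below which direction is '?'
    registry_version    = "1.0",
    rng_seed            = 1L
  )
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(cfg))
    if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
    cfg[names(over)] <- over
  }
  class(cfg) <- "acti_config"
  cfg
}

#' Validate a configuration against a sampling rate
#'
#' @param cfg an `acti_config` list.
#' @param sampling_rate samples per second of the recording the config will
#'   be applied to; needed for the Nyquist check.
#' @return `cfg`, invisibly, or an error.
#' @export
validate_config <- function(cfg, sampling_rate = NULL) {
  stopifnot(inherits(cfg, "acti_config"))
  if (!(cfg$bandpass_low > 0 && cfg$bandpass_low < cfg$bandpass_high))
    stop("require 0 < bandpass_low < bandpass_high")
  if (!is.null(sampling_rate) && cfg$bandpass_high >= sampling_rate / 2)
    stop("bandpass_high must be below the Nyquist frequency (",
         sampling_rate / 2, " Hz)")
  if (cfg$wavelet_scale_min >= cfg$wavelet_scale_max)
    stop("wavelet scale range is empty")
  for (band in list(cfg$pm_band, cfg$pm_stdev_band)) {
    if (band[1] < cfg$wavelet_scale_min || band[2] > cfg$wavelet_scale_max)
      stop("structure band outside the wavelet scale range")
  }
  counts <- c(cfg$epoch_seconds, cfg$smooth_before + cfg$smooth_after + 1,
              cfg$min_valid_days, cfg$sleep_min_minutes, cfg$min_clique_size,
              cfg$n_combinations, cfg$cv_folds, cfg$nights_concatenated)
  if (any(counts <= 0)) stop("all count-valued config entries must be positive")
  invisible(cfg)
}
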