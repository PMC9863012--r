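#' The versioned 96-feature registry manifest
#'
#' Enumerates, in canonical column order, every feature the extraction
#' pipeline emits per recording:
#' \itemize{
#'   \item 6 nonparametric circadian metrics (M10, L5, RA, ADAT, IS, IV);
#'   \item 7 Savitzky--Golay boundary (ceiling/floor envelope) features;
#'   \item 3 day-thirds means (`1_thrd`, `2_thrd`, `3_thrd`) and 2 whole-series
#'     daily activity summaries;
#'   \item `zero_ratio`, `frg_index`, `length_of_sleep_in_minutes`;
#'   \item 2 Morlet wavelet structure features (`structure_pm`,
#'     `structure_pm_stdev`);
#'   \item 48 grouped nocturnal peak ("hump") features: 3 quantities
#'     (distance, width, height) x 4 statistics (min, max, avg, median)
#'     x 2 groups (lower, upper) under 2 splits (median, quartile `_qrt`);
#'   \item 12 ungrouped all-peak features (3 quantities x 4 statistics);
#'   \item 4 hump counts (lower/upper under both splits) plus
#'     `number_of_peaks`;
#'   \item 4 gap statistics between consecutive "bigger" (upper-median)
#'     peaks and 4 statistics of their heights (`*_bigger_values`).
#' }
#'
#' @param version manifest version string; only `"1.0"` is defined.
#' @return Character vector of 96 feature names in registry order.
#' @examples
#' length(feature_registry())
#' @export
feature_registry <- function(version = "1.0") {
  if (!identical(version, "1.0"))
    stop("unknown registry version: ", version)
  stats <- c("min", "max", "avg", "median")

  grouped <- character(0)
  for (suffix in c("", "_qrt")) {
    for (grp in c("lower", "upper")) {
      grouped <- c(grouped,
        paste0(grp, "_humps_", stats, "_distance", suffix),
        paste0(grp, "_humps_width_", stats, suffix),
        paste0(grp, "_humps_height_", stats, suffix))
    }
  }

  c(
    # circadian
    "M10", "L5", "RA", "ADAT", "IS", "IV",
    # Savitzky-Golay boundary envelope
    "floor_sum_values", "e_v_avg_value", "avg_ceiling_value",
    "avg_floor_value", "avg_ceiling_floor_diff", "std_avg", "std_upper",
    # clock thirds and daily summaries
    "1_thrd", "2_thrd", "3_thrd",
    "daily_activity_mean", "daily_activity_stdev",
    # global ratios and sleep length
    "zero_ratio", "frg_index", "length_of_sleep_in_minutes",
    # wavelet structure
    "structure_pm", "structure_pm_stdev",
    # grouped peak families (48)
    grouped,
    # all-peak family (12)
    paste0("peaks_", stats, "_distance"),
    paste0("peaks_width_", stats),
    paste0("peaks_height_", stats),
    # counts
    "number_of_lower_humps", "number_of_upper_humps",
    "number_of_lower_humps_qrt", "number_of_upper_humps_qrt",
    "number_of_peaks",
    # bigger-peak gaps and heights
    paste0(stats, "_length_between_bigger"),
    paste0(stats, "_bigger_values")
  )
}
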