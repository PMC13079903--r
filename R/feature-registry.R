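# The 36 nightly features, in their canonical order, grouped into the five
# sets used throughout the importance and ablation analyses:
#   set 1 - HR and HRV summaries
#   set 2 - primary sleep (onset timing and device sleep-behaviour counters)
#   set 3 - secondary sleep (contiguous-sleep window phenotypes)
#   set 4 - primary temperature summaries
#   set 5 - secondary temperature (diurnal + multiscale complexity)

#' Feature sets for the nightly feature table
#'
#' Returns the grouping of the 36 per-night features into the five feature
#' sets used by the ablation and importance analyses.
#'
#' @return named list `set1`..`set5` of feature-name character vectors.
#' @export
feature_sets <- function() {
  list(
    set1 = c(
      "hr_low_duration", "hr_lowest", "breath_average", "breath_v_average",
      "hr_average", "rmssd", "rem_rmssd", "nrem_rmssd"
    ),
    set2 = c(
      "sleep_onset", "wake_onset", "total_sleep_time", "wake_up_count",
      "onset_latency", "midpoint_time", "restless", "got_up_count"
    ),
    set3 = c(
      "sleep_percentage", "ST_long", "WT_long", "ST_short", "WT_short",
      "LW_count", "SW_count", "LW_len", "SW_len"
    ),
    set4 = c(
      "temperature_max", "temperature_deviation", "temperature_trend_deviation"
    ),
    set5 = c(
      "sleep_mean", "wake_mean", "sleep_wake_difference",
      "diurnal_distal_body_temp_amp",
      "complexity_0", "complexity_1", "complexity_2", "complexity_3"
    )
  )
}

#' Canonical order of the 36 nightly features
#'
#' @return character vector of length 36.
#' @export
feature_names <- function() {
  unname(unlist(feature_sets()))
}

#' The four commonly used nightly features
#'
#' Average resting heart rate, RMSSD, total sleep time, and the diurnal
#' distal body temperature amplitude: the per-stream summaries typically
#' surfaced by consumer wearables.
#'
#' @return character vector of length 4.
#' @export
commonly_used_features <- function() {
  c("hr_average", "rmssd", "total_sleep_time", "diurnal_distal_body_temp_amp")
}
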