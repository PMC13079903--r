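# Sleep-window phenotyping from 30-s hypnograms.
#
# A night's hypnogram (epochs in W/L/D/R between sleep onset and final wake
# onset) is segmented into contiguous-sleep windows: long (> 6 h) and short
# (< 3 h) spans whose internal wake runs are brief, with distinct windows
# separated by at least 60 min of wake. Per-night aggregates of these
# windows (counts, sleep/wake time, lengths) form the secondary sleep
# feature set; onset timing and wake-run counters form the primary
# surrogate set.

SLEEP_STAGES <- c("L", "D", "R")
EPOCH_H <- 30 / 3600

#' Segment a hypnogram into contiguous-sleep windows
#'
#' Maximal spans of sleep are identified and then grouped: by default,
#' spans separated by less than 60 min of wake are merged into one window
#' (the intervening wake counted as the window's wake time), while spans
#' separated by 60 min or more stay distinct. In `strict` mode any wake run
#' longer than 10 min splits windows instead. Leading and trailing wake is
#' excluded from every window. Windows spanning more than 6 h are `long`,
#' less than 3 h `short`, otherwise `other`.
#'
#' @param hypnogram character vector of 30-s epochs in `{"W","L","D","R"}`.
#' @param strict logical; split at any wake run exceeding 10 min rather
#'   than merging sub-60-min gaps.
#' @return data.frame with columns `start`, `end` (0-based, half-open epoch
#'   indices), `kind` (`long`/`short`/`other`), `span_h`, `sleep_time_h`,
#'   `wake_time_h`. Zero rows if the night contains no sleep.
#' @export
extract_sleep_windows <- function(hypnogram, strict = FALSE) {
  if (length(hypnogram) == 0) {
    stop("hypnogram must be nonempty")
  }
  bad <- setdiff(unique(hypnogram), c("W", SLEEP_STAGES))
  if (length(bad) > 0) {
    stop(sprintf("unknown stage code(s): %s", paste(bad, collapse = ", ")))
  }
  runs <- rle(hypnogram %in% SLEEP_STAGES)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths # 0-based
  sleep_idx <- which(runs$values)
  if (length(sleep_idx) == 0) {
    return(data.frame(
      start = integer(0), end = integer(0), kind = character(0),
      span_h = numeric(0), sleep_time_h = numeric(0), wake_time_h = numeric(0)
    ))
  }
  # wake-gap epochs between consecutive sleep runs
  gap_threshold <- if (strict) 20L else 120L # 10 min vs 60 min in epochs
  n_sleep_runs <- length(sleep_idx)
  group <- integer(n_sleep_runs)
  group[1] <- 1L
  if (n_sleep_runs > 1) {
    for (k in 2:n_sleep_runs) {
      gap <- starts[sleep_idx[k]] - ends[sleep_idx[k - 1]]
      new_window <- if (strict) gap > gap_threshold else gap >= gap_threshold
      group[k] <- group[k - 1] + as.integer(new_window)
    }
  }
  out <- lapply(split(sleep_idx, group), function(idx) {
    w_start <- starts[idx[1]]
    w_end <- ends[idx[length(idx)]]
    sleep_epochs <- sum(runs$lengths[idx])
    span <- w_end - w_start
    data.frame(
      start = w_start, end = w_end,
      span_h = span * EPOCH_H,
      sleep_time_h = sleep_epochs * EPOCH_H,
      wake_time_h = (span - sleep_epochs) * EPOCH_H
    )
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out$kind <- ifelse(out$span_h > 6, "long",
    ifelse(out$span_h < 3, "short", "other")
  )
  out[, c("start", "end", "kind", "span_h", "sleep_time_h", "wake_time_h")]
}

#' Per-night sleep features from a hypnogram and onsets
#'
#' Aggregates the night's sleep windows into the secondary sleep features
#' (window counts, sleep/wake time and lengths for long and short windows,
#' sleep percentage) and computes the primary-sleep surrogates from onsets
#' and wake runs. Length/time features of a window kind that did not occur
#' are `NA`. `restless` (stage transitions into wake) and `got_up_count`
#' (wake runs of at least 5 min) are surrogates for proprietary device
#' counters with no published definition.
#'
#' @param hypnogram 30-s epochs, or `NULL` for a missing night (all fields
#'   `NA`, no error).
#' @param sleep_onset,wake_onset clock hours (fractional).
#' @param sleep_percentage_mode `"fraction"` (sleep / (sleep + wake), the
#'   default) or `"ratio"` (sleep time divided by wake time).
#' @param strict passed to [extract_sleep_windows()].
#' @return one-row data.frame with the primary and secondary sleep feature
#'   columns.
#' @export
sleep_features_for_night <- function(hypnogram, sleep_onset = NA_real_,
                                     wake_onset = NA_real_,
                                     sleep_percentage_mode = c("fraction", "ratio"),
                                     strict = FALSE) {
  sleep_percentage_mode <- match.arg(sleep_percentage_mode)
  cols <- c(
    "sleep_onset", "wake_onset", "total_sleep_time", "wake_up_count",
    "onset_latency", "midpoint_time", "restless", "got_up_count",
    "sleep_percentage", "ST_long", "WT_long", "ST_short", "WT_short",
    "LW_count", "SW_count", "LW_len", "SW_len"
  )
  row <- as.data.frame(as.list(stats::setNames(rep(NA_real_, length(cols)), cols)))
  if (is.null(hypnogram) || length(hypnogram) == 0) {
    return(row)
  }
  win <- extract_sleep_windows(hypnogram, strict = strict)

  agg <- function(kind, col) {
    v <- win[[col]][win$kind == kind]
    if (length(v) == 0) NA_real_ else sum(v)
  }
  row$LW_count <- sum(win$kind == "long")
  row$SW_count <- sum(win$kind == "short")
  row$ST_long <- agg("long", "sleep_time_h")
  row$WT_long <- agg("long", "wake_time_h")
  row$LW_len <- agg("long", "span_h")
  row$ST_short <- agg("short", "sleep_time_h")
  row$WT_short <- agg("short", "wake_time_h")
  row$SW_len <- agg("short", "span_h")

  is_sleep <- hypnogram %in% SLEEP_STAGES
  s <- sum(is_sleep)
  w <- length(hypnogram) - s
  row$sleep_percentage <- if (sleep_percentage_mode == "fraction") {
    s / (s + w)
  } else if (w > 0) s / w else NA_real_

  runs <- rle(is_sleep)
  wake_runs <- which(!runs$values)
  # interior wake runs only (leading/trailing wake is outside the sleep span)
  interior <- wake_runs[wake_runs > 1 & wake_runs < length(runs$values)]
  row$wake_up_count <- length(interior)
  row$got_up_count <- sum(runs$lengths[interior] >= 10) # >= 5 min
  row$restless <- sum(diff(as.integer(is_sleep)) == -1L)

  row$sleep_onset <- sleep_onset
  row$wake_onset <- wake_onset
  row$onset_latency <- 0
  if (!is.na(sleep_onset) && !is.na(wake_onset)) {
    row$total_sleep_time <- circular_diff(wake_onset, sleep_onset)
    row$midpoint_time <- circular_midpoint(sleep_onset, wake_onset)
  }
  row
}

#' Sleep features for every present night of a cohort
#'
#' @param cohort a `wd_cohort` with hypnograms.
#' @inheritParams sleep_features_for_night
#' @return data.frame keyed by `subject_id`, `night_date` with the sleep
#'   feature columns.
#' @export
sleep_features <- function(cohort, sleep_percentage_mode = "fraction",
                           strict = FALSE) {
  nights <- cohort$nights[cohort$nights$present, ]
  keys <- night_key(nights$subject_id, nights$night_date)
  rows <- lapply(seq_len(nrow(nights)), function(i) {
    sleep_features_for_night(
      cohort$hypnograms[[keys[i]]],
      sleep_onset = nights$sleep_onset[i],
      wake_onset = nights$wake_onset[i],
      sleep_percentage_mode = sleep_percentage_mode,
      strict = strict
    )
  })
  out <- do.call(rbind, rows)
  cbind(
    nights[, c("subject_id", "night_date")],
    out,
    row.names = NULL
  )
}
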