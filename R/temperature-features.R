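# Diurnal and multiscale-complexity features from minute-level distal
# temperature. Each 24-h day (anchored at local noon, 1440 minute slots) is
# percentile-filtered, then summarized into the diurnal amplitude and
# sleep/wake means; the complexity profile is computed from a 256-minute
# block centered on the midpoint of the night, coarse-grained at scales
# 0-3.

#' Percentile filter for a 24-h minute series
#'
#' Removes values strictly below the lower percentile or strictly above the
#' upper percentile of the day (linear-interpolation quantiles), excluding
#' non-wear and fever-like extremes. Survivors keep their original minute
#' positions; removed values become `NA`.
#'
#' @param series numeric vector of minute values (`NA` = missing minute).
#' @param lower,upper percentile bounds (default 0.05 / 0.95).
#' @param min_minutes minimum non-missing minutes required; below this the
#'   whole day is returned as `NA` (its temperature features are null).
#' @return numeric vector of the same length.
#' @export
percentile_filter <- function(series, lower = 0.05, upper = 0.95,
                              min_minutes = 20) {
  obs <- !is.na(series)
  if (sum(obs) < min_minutes) {
    return(rep(NA_real_, length(series)))
  }
  q <- stats::quantile(series[obs], c(lower, upper), names = FALSE, type = 7)
  out <- series
  out[obs & (series < q[1] | series > q[2])] <- NA_real_
  out
}

#' Diurnal temperature amplitude
#'
#' Daily maximum minus daily minimum of the surviving (filtered) values.
#'
#' @param filtered output of [percentile_filter()].
#' @return amplitude in the series' units, or `NA` if no values survive.
#' @export
diurnal_amplitude <- function(filtered) {
  v <- filtered[!is.na(filtered)]
  if (length(v) == 0) {
    return(NA_real_)
  }
  max(v) - min(v)
}

# Is the clock hour of minute index m (0-based, day anchored at noon)
# inside the circular sleep interval [sleep_onset, wake_onset)?
minute_in_sleep <- function(minute_index, sleep_onset, wake_onset) {
  hour <- (12 + minute_index / 60) %% 24
  dur <- circular_diff(wake_onset, sleep_onset)
  circular_diff(hour, sleep_onset) < dur
}

#' Sleep and wake mean temperature
#'
#' Means of the surviving minute values inside and outside the (circular)
#' sleep interval, and their difference.
#'
#' @inheritParams diurnal_amplitude
#' @param sleep_onset,wake_onset clock hours.
#' @return named list `sleep_mean`, `wake_mean`, `sleep_wake_difference`
#'   (any of them `NA` when the corresponding minute set is empty).
#' @export
sleep_wake_means <- function(filtered, sleep_onset, wake_onset) {
  if (is.na(sleep_onset) || is.na(wake_onset)) {
    return(list(sleep_mean = NA_real_, wake_mean = NA_real_,
                sleep_wake_difference = NA_real_))
  }
  idx <- seq_along(filtered) - 1L
  asleep <- minute_in_sleep(idx, sleep_onset, wake_onset)
  s <- filtered[asleep & !is.na(filtered)]
  w <- filtered[!asleep & !is.na(filtered)]
  sm <- if (length(s)) mean(s) else NA_real_
  wm <- if (length(w)) mean(w) else NA_real_
  list(
    sleep_mean = sm, wake_mean = wm,
    sleep_wake_difference = if (is.na(sm) || is.na(wm)) NA_real_ else sm - wm
  )
}

#' Coarse-grain a series at dyadic scale `s`
#'
#' Replaces the series by means of non-overlapping windows of width `2^s`;
#' a trailing remainder shorter than the window is dropped.
#'
#' @param series numeric vector.
#' @param s non-negative integer scale; the series must be at least `2^s`
#'   long.
#' @return numeric vector of length `floor(length(series) / 2^s)`.
#' @export
coarse_grain <- function(series, s) {
  if (s < 0 || s != round(s)) stop("scale s must be a non-negative integer")
  w <- 2L^s
  if (length(series) < w) stop("series shorter than the window 2^s")
  if (w == 1L) {
    return(series)
  }
  n <- length(series) %/% w
  colMeans(matrix(series[seq_len(n * w)], nrow = w))
}

#' Complexity index of a series
#'
#' The series is z-scored (population SD) and the root-sum-square of its
#' successive differences is divided by the series length. A roughness /
#' information proxy: white noise scores high, smooth trends near zero. By
#' construction invariant to affine rescaling of the input. A
#' zero-variance series scores 0 by convention; a series shorter than 2
#' returns `NA`.
#'
#' @param series numeric vector.
#' @return dimensionless non-negative scalar.
#' @export
complexity_index <- function(series) {
  n <- length(series)
  if (n < 2 || anyNA(series)) {
    return(NA_real_)
  }
  mu <- mean(series)
  sd_pop <- sqrt(mean((series - mu)^2))
  if (sd_pop == 0) {
    return(0)
  }
  z <- (series - mu) / sd_pop
  sqrt(sum(diff(z)^2)) / n
}

#' Multiscale complexity profile of a night
#'
#' Extracts the 256 sleep minutes centered on the midpoint of the night
#' (128 before, 128 after; midpoint from the onsets), coarse-grains at
#' scales 0-3 (lengths 256/128/64/32) and returns the complexity index of
#' each grain. If the centered block is not fully inside the sleep
#' interval, contains missing minutes, or falls off the day, all four
#' values are `NA` - blocks are never shifted, to avoid the variance around
#' the onsets.
#'
#' @param series 1440 minute values (day anchored at noon).
#' @param sleep_onset,wake_onset clock hours.
#' @return named numeric vector `complexity_0` .. `complexity_3`.
#' @export
complexity_profile <- function(series, sleep_onset, wake_onset) {
  out <- stats::setNames(rep(NA_real_, 4), paste0("complexity_", 0:3))
  if (is.na(sleep_onset) || is.na(wake_onset)) {
    return(out)
  }
  mid <- circular_midpoint(sleep_onset, wake_onset)
  center <- round(((mid - 12) %% 24) * 60)
  lo <- center - 128L
  hi <- center + 127L
  if (lo < 0 || hi > 1439) {
    return(out)
  }
  idx <- lo:hi
  block <- series[idx + 1L]
  if (anyNA(block)) {
    return(out)
  }
  if (!all(minute_in_sleep(idx, sleep_onset, wake_onset))) {
    return(out)
  }
  for (s in 0:3) {
    out[s + 1L] <- complexity_index(coarse_grain(block, s))
  }
  out
}

#' Temperature features for every present night of a cohort
#'
#' Computes the diurnal metrics (after percentile filtering), the
#' complexity profile (from the unfiltered series, which must be gap-free
#' around the night midpoint), and the primary-temperature surrogates:
#' `temperature_max` (max of the filtered day), `temperature_deviation`
#' (night mean minus the subject's trailing 30-night baseline mean) and
#' `temperature_trend_deviation` (deviation minus its trailing 3-night
#' moving average). The deviation features are surrogates for proprietary
#' device outputs.
#'
#' @param cohort a `wd_cohort` with temperature series.
#' @param lower,upper,min_minutes passed to [percentile_filter()].
#' @return data.frame keyed by `subject_id`, `night_date` with the
#'   temperature feature columns.
#' @export
temperature_features <- function(cohort, lower = 0.05, upper = 0.95,
                                 min_minutes = 20) {
  nights <- cohort$nights[cohort$nights$present, ]
  keys <- night_key(nights$subject_id, nights$night_date)
  rows <- lapply(seq_len(nrow(nights)), function(i) {
    temperature_features_for_night(
      cohort$temperature[[keys[i]]],
      nights$sleep_onset[i], nights$wake_onset[i],
      lower = lower, upper = upper, min_minutes = min_minutes
    )
  })
  out <- do.call(rbind, rows)
  out <- cbind(nights[, c("subject_id", "night_date")], out, row.names = NULL)
  # trailing-baseline surrogates need the subject's night history in order
  out <- out[order(out$subject_id, out$night_date), ]
  by_subj <- split(seq_len(nrow(out)), out$subject_id)
  out$temperature_deviation <- NA_real_
  out$temperature_trend_deviation <- NA_real_
  for (idx in by_subj) {
    nm <- out$night_mean[idx]
    dev <- vapply(seq_along(idx), function(j) {
      win <- nm[max(1, j - 29):j]
      win <- win[!is.na(win)]
      if (length(win) == 0 || is.na(nm[j])) NA_real_ else nm[j] - mean(win)
    }, numeric(1))
    trend <- vapply(seq_along(idx), function(j) {
      win <- dev[max(1, j - 2):j]
      win <- win[!is.na(win)]
      if (length(win) == 0 || is.na(dev[j])) NA_real_ else dev[j] - mean(win)
    }, numeric(1))
    out$temperature_deviation[idx] <- dev
    out$temperature_trend_deviation[idx] <- trend
  }
  out$night_mean <- NULL
  rownames(out) <- NULL
  out
}

#' Temperature features for a single night
#'
#' @param series 1440 minute values, or `NULL` for a missing night.
#' @inheritParams complexity_profile
#' @inheritParams percentile_filter
#' @return one-row data.frame (includes `night_mean`, used internally for
#'   the trailing-baseline surrogates).
#' @export
temperature_features_for_night <- function(series, sleep_onset, wake_onset,
                                           lower = 0.05, upper = 0.95,
                                           min_minutes = 20) {
  row <- data.frame(
    sleep_mean = NA_real_, wake_mean = NA_real_,
    sleep_wake_difference = NA_real_,
    diurnal_distal_body_temp_amp = NA_real_,
    complexity_0 = NA_real_, complexity_1 = NA_real_,
    complexity_2 = NA_real_, complexity_3 = NA_real_,
    temperature_max = NA_real_, night_mean = NA_real_
  )
  if (is.null(series)) {
    return(row)
  }
  filtered <- percentile_filter(series, lower, upper, min_minutes)
  if (all(is.na(filtered))) {
    return(row)
  }
  row$diurnal_distal_body_temp_amp <- diurnal_amplitude(filtered)
  swm <- sleep_wake_means(filtered, sleep_onset, wake_onset)
  row$sleep_mean <- swm$sleep_mean
  row$wake_mean <- swm$wake_mean
  row$sleep_wake_difference <- swm$sleep_wake_difference
  row$temperature_max <- max(filtered, na.rm = TRUE)
  row$night_mean <- mean(filtered, na.rm = TRUE)
  ci <- complexity_profile(series, sleep_onset, wake_onset)
  row$complexity_0 <- ci[["complexity_0"]]
  row$complexity_1 <- ci[["complexity_1"]]
  row$complexity_2 <- ci[["complexity_2"]]
  row$complexity_3 <- ci[["complexity_3"]]
  row
}
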