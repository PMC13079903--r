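# Synthetic cohort generator.
#
# Emulates the statistical structure the downstream analysis assumes: two
# classes (DM / no-DM-DX) whose nightly HR, RMSSD, total sleep time and
# diurnal temperature amplitude follow configured class-conditional
# truncated-normal distributions; insomnia-like hypnogram fragmentation
# that is more frequent in the DM class; minute-level distal temperature
# built from a diurnal waveform plus AR(1) noise whose smoothness differs
# by class; independent per-night missingness; age/sex strata; and an
# optional "other chronic condition" confound that shifts sleep/HR
# parameters toward DM values while leaving temperature untouched.

default_class_params <- function() {
  list(
    control = list(
      hr = c(62.713, 8.852),
      rmssd = c(42.944, 24.973),
      tst = c(7.946, 1.726),
      amplitude = c(7.261, 2.848),
      breath = c(15.4, 1.3),
      fragmentation = 0.002,
      temp_autocorr = c(0.55, 0.20),
      temp_noise = 0.35
    ),
    dm = list(
      hr = c(67.819, 9.569),
      rmssd = c(30.141, 17.180),
      tst = c(7.649, 1.990),
      amplitude = c(6.008, 2.438),
      breath = c(15.9, 1.5),
      fragmentation = 0.006,
      temp_autocorr = c(0.75, 0.20),
      temp_noise = 0.35
    )
  )
}

#' Configuration for the synthetic cohort generator
#'
#' Defaults reproduce the study conditions the analysis was designed around:
#' 300 subjects per class observed over the 129 nights from 2020-04-22 to
#' 2020-08-29 (final date exclusive), 35% independent per-night missingness,
#' and class-conditional nightly distributions whose pooled means and SDs
#' equal the published cohort moments for heart rate (62.713/8.852 vs
#' 67.819/9.569 BPM), RMSSD (42.944/24.973 vs 30.141/17.180 ms), total sleep
#' time (7.946/1.726 vs 7.649/1.990 h) and diurnal distal temperature
#' amplitude (7.261/2.848 vs 6.008/2.438 deg C).
#'
#' @param n_dm,n_control subjects per class.
#' @param date_start first night (Date or string).
#' @param n_nights number of calendar nights.
#' @param missingness probability a night is entirely missing, in `[0, 1)`.
#' @param class_params list with `control` and `dm` entries; each holds
#'   `hr`, `rmssd`, `tst`, `amplitude`, `breath` as `c(location, scale)`,
#'   plus `fragmentation` (per-epoch wake hazard location; subjects vary
#'   around it log-normally), `temp_autocorr` (AR(1) coefficient of the
#'   temperature noise as `c(location, between-subject SD)`, truncated to
#'   `[0, 0.95]`) and `temp_noise` (the noise's marginal SD, deg C).
#' @param night_icc fraction of each scalar's variance placed between
#'   subjects; the remainder is night-to-night jitter. Pooled nightly moments
#'   match the configured location/scale either way.
#' @param other_condition_rate fraction of control subjects carrying a
#'   non-DM chronic condition.
#' @param confound_shift fraction by which those subjects' sleep/HR
#'   locations are moved toward the DM locations (temperature parameters are
#'   never shifted).
#' @param age_probs_control,age_probs_dm sampling weights over the five
#'   retained age bins (30-39 ... 70-79).
#' @param sex_probs sampling weights over M/F/O.
#' @param temp_baseline distal temperature baseline (deg C).
#' @param temp_band physiological band for generated temperatures, deg C.
#' @param rng_seed integer root seed; all randomness descends from it.
#' @return a `wd_generator_config` list.
#' @export
generator_config <- function(n_dm = 300,
                             n_control = 300,
                             date_start = as.Date("2020-04-22"),
                             n_nights = 129,
                             missingness = 0.35,
                             class_params = default_class_params(),
                             night_icc = 0.7,
                             other_condition_rate = 0,
                             confound_shift = 0.5,
                             age_probs_control = c(0.262, 0.330, 0.249, 0.118, 0.042),
                             age_probs_dm = c(0.130, 0.263, 0.308, 0.218, 0.081),
                             sex_probs = c(M = 0.60, F = 0.395, O = 0.005),
                             temp_baseline = 33,
                             temp_band = c(20, 42),
                             rng_seed = 20200422) {
  cfg <- list(
    n_dm = n_dm, n_control = n_control,
    date_start = as.Date(date_start), n_nights = as.integer(n_nights),
    missingness = missingness, class_params = class_params,
    night_icc = night_icc,
    other_condition_rate = other_condition_rate,
    confound_shift = confound_shift,
    age_probs_control = age_probs_control, age_probs_dm = age_probs_dm,
    sex_probs = sex_probs,
    temp_baseline = temp_baseline, temp_band = temp_band,
    rng_seed = as.integer(rng_seed)
  )
  class(cfg) <- "wd_generator_config"
  validate_generator_config(cfg)
  cfg
}

validate_generator_config <- function(cfg) {
  if (cfg$n_dm < 0 || cfg$n_control < 0) {
    config_error("subject counts must be non-negative")
  }
  if (is.na(cfg$n_nights) || cfg$n_nights < 1) {
    config_error("date range must contain at least one night")
  }
  if (cfg$missingness < 0 || cfg$missingness >= 1) {
    config_error("missingness probability must lie in [0, 1)")
  }
  if (cfg$night_icc < 0 || cfg$night_icc > 1) {
    config_error("night_icc must lie in [0, 1]")
  }
  for (cl in c("control", "dm")) {
    p <- cfg$class_params[[cl]]
    for (nm in c("hr", "rmssd", "tst", "amplitude", "breath")) {
      if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 2 || p[[nm]][2] <= 0) {
        config_error(sprintf("class '%s': '%s' needs c(location, scale) with scale > 0", cl, nm))
      }
    }
    if (p$fragmentation < 0 || p$fragmentation >= 1) {
      config_error("fragmentation hazard must lie in [0, 1)")
    }
    if (abs(p$temp_autocorr[1]) >= 1) {
      config_error("temperature noise autocorrelation location must lie in (-1, 1)")
    }
    if (p$temp_noise < 0) config_error("temperature noise scale must be >= 0")
  }
  invisible(cfg)
}

age_bins <- function() c("30-39", "40-49", "50-59", "60-69", "70-79")

other_condition_vocabulary <- function() {
  c(
    "hypertension", "coronary_disease", "myocardial_infarction",
    "congestive_heart_failure", "stroke", "atrial_fibrillation",
    "sleep_apnea", "copd", "asthma", "cancer", "anemia", "immunodeficiency"
  )
}

#' Simulate an alternating sleep/wake hypnogram
#'
#' Sleep bouts end with a per-epoch geometric hazard; wake bouts are mostly
#' short (0.5-10 min), with an occasional detached-span gap of 60-110 min
#' whose probability grows with the hazard, so fragmented sleepers can show
#' both a main sleep span and a short detached span. Stages within sleep
#' cycle through light/deep/REM runs. First and last epochs are always
#' sleep, matching the onset semantics of the nightly records.
#'
#' @param fragmentation per-30-s-epoch probability that a sleep bout ends.
#' @param night_length_h sleep-period length in hours, in `(0, 16]`.
#' @param long_gap_prob probability a wake bout is a 60-110 min detachment
#'   gap; defaults to `min(0.15, 10 * fragmentation)`.
#' @return character vector of 30-s epochs in `{"W","L","D","R"}` of length
#'   `round(night_length_h * 120)`.
#' @export
simulate_hypnogram <- function(fragmentation, night_length_h,
                               long_gap_prob = min(0.15, 10 * fragmentation)) {
  if (night_length_h <= 0 || night_length_h > 16) {
    config_error("night_length_h must lie in (0, 16] hours")
  }
  if (fragmentation < 0 || fragmentation >= 1) {
    config_error("fragmentation hazard must lie in [0, 1)")
  }
  n <- max(2L, as.integer(round(night_length_h * 120)))
  out <- character(0)
  asleep <- TRUE
  while (length(out) < n) {
    if (asleep) {
      len <- if (fragmentation <= 0) {
        n - length(out)
      } else {
        1L + stats::rgeom(1L, fragmentation)
      }
      out <- c(out, sample_sleep_stages(len))
    } else {
      mins <- if (stats::runif(1L) < long_gap_prob) {
        stats::runif(1L, 60, 110)
      } else {
        stats::runif(1L, 0.5, 10)
      }
      out <- c(out, rep("W", max(1L, as.integer(round(mins * 2)))))
    }
    asleep <- !asleep
  }
  out <- out[seq_len(n)]
  # onset semantics: the record spans sleep onset to final wake onset
  if (out[1] == "W") out[1] <- "L"
  if (out[n] == "W") out[n] <- "L"
  out
}

# Light/deep/REM runs with geometric lengths (mean 10 min).
sample_sleep_stages <- function(len) {
  out <- character(0)
  while (length(out) < len) {
    stage <- sample(c("L", "D", "R"), 1L, prob = c(0.50, 0.22, 0.28))
    run <- 1L + stats::rgeom(1L, 1 / 20)
    out <- c(out, rep(stage, run))
  }
  out[seq_len(len)]
}

#' Simulate one 24-h minute-level distal temperature day
#'
#' The day is anchored at local noon (minute 0 = 12:00) so a sleep episode
#' sits wholly inside one day. The series is a baseline plus a sinusoid of
#' peak-to-trough height `amplitude` peaking during sleep (distal
#' temperature rises at night) plus stationary AR(1) noise.
#'
#' @param amplitude peak-to-trough height of the diurnal waveform, deg C,
#'   `>= 0`.
#' @param autocorrelation AR(1) coefficient of the noise, `(-1, 1)`.
#' @param noise_scale marginal SD of the noise (deg C).
#' @param baseline mean level (deg C).
#' @param peak_minute minute index (0-1439) of the waveform peak; integer
#'   so the realized range of the noiseless series is exactly `amplitude`.
#' @return numeric vector of 1440 minute values.
#' @export
simulate_temperature_day <- function(amplitude, autocorrelation = 0,
                                     noise_scale = 0, baseline = 33,
                                     peak_minute = 960L) {
  if (amplitude < 0) config_error("amplitude must be >= 0")
  if (abs(autocorrelation) >= 1) config_error("autocorrelation must lie in (-1, 1)")
  if (noise_scale < 0) config_error("noise_scale must be >= 0")
  t <- 0:1439
  peak_minute <- as.integer(round(peak_minute)) %% 1440L
  series <- baseline + (amplitude / 2) * cos(2 * pi * (t - peak_minute) / 1440)
  if (noise_scale > 0) {
    innov <- stats::rnorm(1440, 0, noise_scale * sqrt(1 - autocorrelation^2))
    noise <- stats::filter(innov, autocorrelation, method = "recursive",
                           init = stats::rnorm(1, 0, noise_scale))
    series <- series + as.numeric(noise)
  }
  series
}

#' Simulate a two-class cohort of subjects and nightly records
#'
#' Deterministic given `config$rng_seed`: a single root seed spawns one
#' child stream per subject, so each subject's records are invariant to the
#' presence of other subjects. Every subject has one slot per calendar
#' night; each night is independently missing with the configured
#' probability (payload absent, date present).
#'
#' @param config a [generator_config()].
#' @param streams if `FALSE`, only the scalar nightly summaries are
#'   generated (no hypnograms or temperature series); much faster when only
#'   set-1/set-2 style quantities are needed.
#' @return a `wd_cohort` list with elements `subjects` (one row per
#'   subject), `nights` (one row per subject x calendar night, scalar
#'   summaries `NA` on missing nights), and - when `streams = TRUE` - named
#'   lists `hypnograms` and `temperature` keyed by `"subject|date"`.
#' @export
simulate_cohort <- function(config = generator_config(), streams = TRUE) {
  validate_generator_config(config)
  n_total <- config$n_dm + config$n_control
  if (n_total == 0) config_error("cohort must contain at least one subject")
  dates <- config$date_start + seq_len(config$n_nights) - 1L

  with_preserved_seed(config$rng_seed, {
    subjects <- data.frame(
      subject_id = sprintf("S%04d", seq_len(n_total)),
      label = rep(c(1L, 0L), c(config$n_dm, config$n_control)),
      stringsAsFactors = FALSE
    )
    subjects$age_bin <- ifelse(
      subjects$label == 1L,
      sample(age_bins(), n_total, TRUE, config$age_probs_dm),
      sample(age_bins(), n_total, TRUE, config$age_probs_control)
    )
    subjects$sex <- sample(names(config$sex_probs), n_total, TRUE, config$sex_probs)
    conds <- character(n_total)
    if (config$other_condition_rate > 0) {
      affected <- subjects$label == 0L &
        stats::runif(n_total) < config$other_condition_rate
      conds[affected] <- vapply(which(affected), function(i) {
        k <- sample(1:2, 1L)
        paste(sample(other_condition_vocabulary(), k), collapse = ";")
      }, character(1))
    }
    subjects$other_conditions <- conds
    child_seeds <- sample.int(.Machine$integer.max - 1L, n_total)

    per_subject <- lapply(seq_len(n_total), function(i) {
      simulate_subject_nights(
        subjects[i, ], child_seeds[i], dates, config, streams
      )
    })

    nights <- do.call(rbind, lapply(per_subject, `[[`, "nights"))
    rownames(nights) <- NULL
    cohort <- list(subjects = subjects, nights = nights, config = config)
    if (streams) {
      cohort$hypnograms <- do.call(c, lapply(per_subject, `[[`, "hypnograms"))
      cohort$temperature <- do.call(c, lapply(per_subject, `[[`, "temperature"))
    }
    class(cohort) <- "wd_cohort"
    cohort
  })
}

simulate_subject_nights <- function(subject, child_seed, dates, config, streams) {
  set.seed(child_seed)
  cls <- if (subject$label == 1L) "dm" else "control"
  p <- config$class_params[[cls]]
  pc <- config$class_params$control
  pd <- config$class_params$dm
  confounded <- subject$label == 0L && nzchar(subject$other_conditions)

  # Subject-level trait draw + nightly jitter; pooled moments match the
  # configured location/scale. Confounded controls have their sleep/HR trait
  # locations partially shifted toward DM values; temperature is untouched.
  icc <- config$night_icc
  trait <- function(par, shift_target = NULL) {
    loc <- par[1]
    if (confounded && !is.null(shift_target)) {
      loc <- loc + config$confound_shift * (shift_target[1] - par[1])
    }
    stats::rnorm(1, loc, par[2] * sqrt(icc))
  }
  subj <- list(
    hr = trait(p$hr, pd$hr),
    rmssd = trait(p$rmssd, pd$rmssd),
    tst = trait(p$tst, pd$tst),
    amplitude = trait(p$amplitude),
    breath = trait(p$breath, pd$breath)
  )
  frag <- p$fragmentation
  if (confounded) frag <- frag + config$confound_shift * (pd$fragmentation - pc$fragmentation)
  # subject-level heterogeneity in fragmentation and noise smoothness, so
  # neither feature family separates the classes deterministically
  frag <- min(0.5, frag * exp(stats::rnorm(1, 0, 0.5)))
  ac <- p$temp_autocorr
  autocorr <- if (length(ac) > 1) {
    rtruncnorm(1, ac[1], ac[2], lower = 0, upper = 0.95)
  } else {
    ac[1]
  }

  n <- length(dates)
  present <- stats::runif(n) >= config$missingness
  jit <- sqrt(1 - icc)
  night <- function(par, subj_mean, lower = 0) {
    vals <- rep(NA_real_, n)
    vals[present] <- rtruncnorm(sum(present), subj_mean, par[2] * jit, lower = lower)
    vals
  }
  hr_average <- night(p$hr, subj$hr)
  rmssd <- night(p$rmssd, subj$rmssd)
  tst <- night(p$tst, subj$tst, lower = 2) # a sub-2-h "night" is no night
  tst <- pmin(tst, 15.9)
  amplitude <- night(p$amplitude, subj$amplitude)

  sleep_onset <- rep(NA_real_, n)
  sleep_onset[present] <- (23.5 + stats::rnorm(sum(present), 0, 0.9)) %% 24
  wake_onset <- (sleep_onset + tst) %% 24

  hr_lowest <- hr_average - rtruncnorm(n, 7, 2, lower = 2)
  rem_rmssd <- rmssd * rtruncnorm(n, 1.10, 0.15, lower = 0.2)
  nrem_rmssd <- rmssd * rtruncnorm(n, 0.95, 0.10, lower = 0.2)
  breath_average <- night(p$breath, subj$breath, lower = 6)
  breath_v_average <- ifelse(present, rtruncnorm(n, 1.6, 0.6, lower = 0.1), NA_real_)
  hr_low_duration <- ifelse(present, rtruncnorm(n, 300, 80, lower = 0), NA_real_)

  nights <- data.frame(
    subject_id = subject$subject_id,
    night_date = dates,
    present = present,
    hr_average = hr_average,
    hr_lowest = hr_lowest,
    rmssd = rmssd,
    rem_rmssd = rem_rmssd,
    nrem_rmssd = nrem_rmssd,
    breath_average = breath_average,
    breath_v_average = breath_v_average,
    hr_low_duration = hr_low_duration,
    tst_hours = tst,
    sleep_onset = sleep_onset,
    wake_onset = wake_onset,
    stringsAsFactors = FALSE
  )

  hypnograms <- list()
  temperature <- list()
  if (streams) {
    for (i in which(present)) {
      key <- night_key(subject$subject_id, dates[i])
      hyp <- simulate_hypnogram(frag, tst[i])
      # the hypnogram defines the sleep period; keep onsets consistent
      nights$wake_onset[i] <- (sleep_onset[i] + length(hyp) / 120) %% 24
      hypnograms[[key]] <- hyp
      mid <- circular_midpoint(nights$sleep_onset[i], nights$wake_onset[i])
      peak <- round(((mid - 12) %% 24) * 60)
      temp <- simulate_temperature_day(
        amplitude[i], autocorr, p$temp_noise,
        baseline = config$temp_baseline, peak_minute = peak
      )
      temperature[[key]] <- pmin(pmax(temp, config$temp_band[1]), config$temp_band[2])
    }
  }
  list(nights = nights, hypnograms = hypnograms, temperature = temperature)
}

#' Write a synthetic cohort to plain-text files
#'
#' Writes `subjects.csv`, `summaries.csv` (one row per subject-night, empty
#' cell = missing), `hypnograms.csv` (long, 0-based `epoch_index`, 30-s
#' epochs) and `temperatures.csv` (long, `minute_index` 0-1439) into `dir`.
#'
#' @param cohort a `wd_cohort`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(cohort$subjects, file.path(dir, "subjects.csv"), row.names = FALSE)
  utils::write.csv(cohort$nights, file.path(dir, "summaries.csv"), row.names = FALSE, na = "")
  if (!is.null(cohort$hypnograms)) {
    keys <- names(cohort$hypnograms)
    hyp <- data.frame(
      key = rep(keys, lengths(cohort$hypnograms)),
      epoch_index = unlist(lapply(cohort$hypnograms, function(h) seq_along(h) - 1L)),
      stage = unlist(cohort$hypnograms),
      stringsAsFactors = FALSE
    )
    parts <- strsplit(hyp$key, "|", fixed = TRUE)
    hyp$subject_id <- vapply(parts, `[[`, character(1), 1)
    hyp$night_date <- vapply(parts, `[[`, character(1), 2)
    utils::write.csv(
      hyp[, c("subject_id", "night_date", "epoch_index", "stage")],
      file.path(dir, "hypnograms.csv"), row.names = FALSE
    )
  }
  if (!is.null(cohort$temperature)) {
    keys <- names(cohort$temperature)
    tmp <- data.frame(
      key = rep(keys, each = 1440L),
      minute_index = rep(0:1439, length(keys)),
      temperature_c = unlist(cohort$temperature, use.names = FALSE),
      stringsAsFactors = FALSE
    )
    parts <- strsplit(keys, "|", fixed = TRUE)
    subj <- vapply(parts, `[[`, character(1), 1)
    date <- vapply(parts, `[[`, character(1), 2)
    tmp$subject_id <- rep(subj, each = 1440L)
    tmp$night_date <- rep(date, each = 1440L)
    utils::write.csv(
      tmp[, c("subject_id", "night_date", "minute_index", "temperature_c")],
      file.path(dir, "temperatures.csv"), row.names = FALSE
    )
  }
  invisible(dir)
}
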