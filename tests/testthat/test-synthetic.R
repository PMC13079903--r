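# Synthetic cohort generator: configuration guards, missingness and
# distributional behaviour, determinism, and the raw-stream simulators.

test_that("invalid configurations are rejected", {
  expect_error(generator_config(missingness = 1), class = "wd_config_error")
  expect_error(generator_config(n_nights = 0), class = "wd_config_error")
  expect_error(
    generator_config(class_params = local({
      p <- default_class_params()
      p$dm$hr <- c(67.8, -1)
      p
    })),
    class = "wd_config_error"
  )
  expect_error(simulate_temperature_day(-0.1), class = "wd_config_error")
  expect_error(simulate_hypnogram(0.01, 0), class = "wd_config_error")
})

test_that("per-night missingness matches its Bernoulli rate", {
  cfg <- generator_config(
    n_dm = 20, n_control = 20, n_nights = 129,
    missingness = 0.35, rng_seed = 11
  )
  co <- simulate_cohort(cfg, streams = FALSE)
  # every subject has one slot per calendar night
  expect_equal(nrow(co$nights), 40 * 129)
  expect_true(all(table(co$nights$subject_id) == 129))
  # observed present fraction within 3 binomial SDs of 0.65
  n <- 40 * 129
  p_hat <- mean(co$nights$present)
  expect_lt(abs(p_hat - 0.65), 3 * sqrt(0.65 * 0.35 / n))
  # expected nights present per subject ~ 83.9
  expect_equal(129 * 0.65, 83.85, tolerance = 1e-12)

  cfg0 <- generator_config(n_dm = 3, n_control = 3, n_nights = 129,
                           missingness = 0, rng_seed = 5)
  co0 <- simulate_cohort(cfg0, streams = FALSE)
  expect_true(all(co0$nights$present))
})

test_that("missing nights keep the date but no payload", {
  cfg <- generator_config(n_dm = 4, n_control = 4, n_nights = 30,
                          missingness = 0.5, rng_seed = 3)
  co <- simulate_cohort(cfg)
  absent <- co$nights[!co$nights$present, ]
  expect_gt(nrow(absent), 0)
  payload <- setdiff(names(absent), c("subject_id", "night_date", "present"))
  expect_true(all(is.na(absent[, payload])))
  expect_false(any(night_key <- paste(absent$subject_id, absent$night_date, sep = "|")
                   %in% names(co$hypnograms)))
})

test_that("generation is deterministic given the seed and invariant to cohort mates", {
  cfg <- generator_config(n_dm = 5, n_control = 5, n_nights = 20, rng_seed = 77)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a, b)
  # byte-identical files
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_cohort(a, d1)
  write_cohort(b, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
})

test_that("nightly scalars follow the configured class distributions", {
  # many subjects x few nights: the Monte-Carlo error of pooled moments is
  # governed by the number of subjects, not nights
  cfg <- generator_config(
    n_dm = 2500, n_control = 2500, n_nights = 4,
    missingness = 0, night_icc = 0.7, rng_seed = 101
  )
  co <- simulate_cohort(cfg, streams = FALSE)
  lab <- co$subjects$label[match(co$nights$subject_id, co$subjects$subject_id)]
  hr_dm <- co$nights$hr_average[lab == 1L]
  expect_gte(length(hr_dm), 1e4)
  # cluster-aware SEM: subjects are the independent units
  subj_means <- tapply(hr_dm, co$nights$subject_id[lab == 1L], mean)
  sem <- stats::sd(subj_means) / sqrt(length(subj_means))
  expect_lt(abs(mean(hr_dm) - 67.819), 3 * sem)

  # Kolmogorov-Smirnov distance against the configured normal shrinks with n
  ks_d <- function(x, mean, sd) {
    suppressWarnings(stats::ks.test(x, "pnorm", mean, sd)$statistic)
  }
  d_small <- ks_d(hr_dm[1:400], 67.819, 9.569)
  d_large <- ks_d(hr_dm, 67.819, 9.569)
  expect_lt(d_large, 0.03)
  expect_lt(d_large, d_small)
})

test_that("class effect sizes approach the nominal pooled-SD d", {
  cfg <- generator_config(
    n_dm = 2500, n_control = 2500, n_nights = 4,
    missingness = 0, rng_seed = 202
  )
  co <- simulate_cohort(cfg, streams = FALSE)
  lab <- co$subjects$label[match(co$nights$subject_id, co$subjects$subject_id)]
  p <- cfg$class_params
  nominal <- function(f) {
    (p$dm[[f]][1] - p$control[[f]][1]) /
      sqrt((p$dm[[f]][2]^2 + p$control[[f]][2]^2) / 2)
  }
  got_hr <- cohens_d(co$nights$hr_average[lab == 1L], co$nights$hr_average[lab == 0L])
  expect_equal(got_hr, nominal("hr"), tolerance = 0.05 / abs(nominal("hr")))
  # RMSSD inherits some truncation-at-zero bias (its scale is large
  # relative to its mean), so only direction and rough magnitude are
  # checked for it
  got_rmssd <- cohens_d(co$nights$rmssd[lab == 1L], co$nights$rmssd[lab == 0L])
  expect_lt(got_rmssd, -0.4)
})

test_that("hypnogram simulator honours the fragmentation hazard", {
  set.seed(1)
  h0 <- simulate_hypnogram(0, 7)
  expect_equal(length(h0), 840)
  expect_true(all(h0 %in% c("L", "D", "R")))
  runs <- rle(h0 %in% c("L", "D", "R"))
  expect_equal(length(runs$values), 1L)

  # higher hazard, more awakenings (distributional, 300 nights each)
  set.seed(2)
  n_wakes <- function(frag) {
    mean(replicate(300, {
      h <- simulate_hypnogram(frag, 7)
      r <- rle(h == "W")
      sum(r$values)
    }))
  }
  expect_gt(n_wakes(0.008), n_wakes(0.001))
})

test_that("high fragmentation can produce a detached short sleep span", {
  set.seed(3)
  found <- FALSE
  for (i in 1:300) {
    h <- simulate_hypnogram(0.01, 9)
    w <- extract_sleep_windows(h)
    if (nrow(w) >= 2) {
      found <- TRUE
      break
    }
  }
  expect_true(found)
})

test_that("temperature day is an exact sinusoid plus stationary AR noise", {
  flat <- simulate_temperature_day(0, 0, 0)
  expect_equal(length(flat), 1440L)
  expect_equal(max(flat) - min(flat), 0)

  wave <- simulate_temperature_day(3, 0, 0)
  expect_equal(max(wave) - min(wave), 3, tolerance = 1e-6)

  # white noise is rougher than strongly autocorrelated noise of the same
  # marginal scale: complexity at scale 0 is higher for the former
  set.seed(4)
  mean_ci <- function(ac) {
    mean(replicate(200, {
      x <- simulate_temperature_day(3, ac, 0.3)[601:856]
      complexity_index(x)
    }))
  }
  expect_gt(mean_ci(0), mean_ci(0.9))
})

test_that("subject strata respect the configured cohort structure", {
  cfg <- generator_config(n_dm = 150, n_control = 150, n_nights = 2,
                          other_condition_rate = 0.4, rng_seed = 15)
  co <- simulate_cohort(cfg, streams = FALSE)
  expect_true(all(co$subjects$age_bin %in%
    c("30-39", "40-49", "50-59", "60-69", "70-79")))
  expect_true(all(co$subjects$sex %in% c("M", "F", "O")))
  # conditions only on configured (control) subjects
  has_cond <- nzchar(co$subjects$other_conditions)
  expect_true(all(co$subjects$label[has_cond] == 0L))
  expect_gt(sum(has_cond), 0)
  cfg0 <- generator_config(n_dm = 30, n_control = 30, n_nights = 2, rng_seed = 15)
  co0 <- simulate_cohort(cfg0, streams = FALSE)
  expect_false(any(nzchar(co0$subjects$other_conditions)))
})
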