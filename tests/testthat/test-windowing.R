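# Nightly table assembly, window quality caps, anchored extraction and
# stratified subject splitting.

make_summaries <- function(n_subj = 3, n_nights = 10, start = as.Date("2020-04-22")) {
  grid <- expand.grid(
    subject_id = sprintf("S%02d", seq_len(n_subj)),
    night_date = start + seq_len(n_nights) - 1,
    stringsAsFactors = FALSE
  )
  for (f in feature_sets()$set1) grid[[f]] <- rnorm(nrow(grid), 50, 5)
  grid
}

fake_features <- function(summaries, cols) {
  out <- summaries[, c("subject_id", "night_date")]
  for (f in cols) out[[f]] <- rnorm(nrow(out))
  out
}

test_that("nightly table outer-joins the three inputs in canonical order", {
  set.seed(21)
  su <- make_summaries(3, 10)
  sf <- fake_features(su, c(feature_sets()$set2, feature_sets()$set3))
  tf <- fake_features(su, c(feature_sets()$set4, feature_sets()$set5))
  nt <- build_nightly_table(sf, tf, su)
  expect_equal(nrow(nt), 30L)
  expect_equal(names(nt), c("subject_id", "night_date", "night_present", feature_names()))
  expect_true(all(nt$night_present))

  # a night with no hypnogram keeps its row with sleep features null
  sf2 <- sf[-1, ]
  nt2 <- build_nightly_table(sf2, tf, su)
  expect_equal(nrow(nt2), 30L)
  dropped <- nt2[nt2$subject_id == sf$subject_id[1] & nt2$night_date == sf$night_date[1], ]
  expect_true(is.na(dropped$sleep_percentage))
  expect_false(is.na(dropped$sleep_mean))
  expect_true(dropped$night_present)

  # empty input: empty table, no error
  empty <- build_nightly_table(sf[0, ], tf[0, ], su[0, ])
  expect_equal(nrow(empty), 0L)

  # duplicate keys rejected
  expect_error(build_nightly_table(rbind(sf, sf[1, ]), tf, su), "duplicate")
})

test_that("window validity enforces the per-length and per-week caps", {
  m <- function(L, miss) {
    mask <- rep(TRUE, L)
    mask[miss] <- FALSE
    mask
  }
  expect_true(valid_window(m(21, c(3, 10)), 21))
  expect_false(valid_window(m(21, c(1, 2, 3)), 21)) # 3 missing in week 1
  expect_true(valid_window(m(21, c(1, 2, 8, 9, 15, 16)), 21)) # 2 per week, 6 total
  expect_false(valid_window(m(21, c(1, 2, 8, 9, 15, 16, 17)), 21)) # 7 total
  expect_true(valid_window(m(7, c(1, 5)), 7))
  expect_false(valid_window(m(7, c(1, 4, 5)), 7))
  expect_true(valid_window(m(3, c(1, 2)), 3))
  expect_false(valid_window(m(3, c(1, 2, 3)), 3))
  expect_true(valid_window(m(1, integer(0)), 1))
  expect_false(valid_window(m(1, 1), 1))
  expect_true(valid_window(m(14, c(2, 3, 9, 10)), 14))
  expect_false(valid_window(m(14, c(2, 3, 4, 9)), 14)) # 3 in week 1
  expect_false(valid_window(m(14, c(1, 2, 8, 9, 10)), 14)) # total 5 > 4
  expect_error(valid_window(rep(TRUE, 5), 5), "must be one of")
})

test_that("a fully observed subject yields 129 - 21 + 1 anchored windows", {
  set.seed(22)
  su <- make_summaries(1, 129)
  sf <- fake_features(su, c(feature_sets()$set2, feature_sets()$set3))
  tf <- fake_features(su, c(feature_sets()$set4, feature_sets()$set5))
  nt <- build_nightly_table(sf, tf, su)
  subjects <- data.frame(subject_id = "S01", label = 1L)
  an <- anchor_starts(nt)
  expect_equal(nrow(an), 109L)
  w21 <- extract_windows(nt, subjects, 21, an)
  expect_equal(nrow(w21), 109L)
  expect_equal(ncol(w21), 3L + 21L * 36L)
  w1 <- extract_windows(nt, subjects, 1, an)
  expect_equal(nrow(w1), 109L)
})

test_that("window datasets of every length share the 21-night anchor keys", {
  fx <- fixture_cohort()
  key_sets <- lapply(c(3, 7, 14, 21), function(L) {
    w <- extract_windows(fx$nightly, fx$cohort$subjects, L, fx$anchors)
    paste(w$subject_id, w$start_date)
  })
  for (k in key_sets[-1]) expect_setequal(k, key_sets[[1]])
  w1 <- extract_windows(fx$nightly, fx$cohort$subjects, 1, fx$anchors)
  expect_true(all(paste(w1$subject_id, w1$start_date) %in% key_sets[[1]]))
  # windows never cross subjects and labels follow the subject table
  w21 <- extract_windows(fx$nightly, fx$cohort$subjects, 21, fx$anchors)
  lab <- fx$cohort$subjects$label[match(w21$subject_id, fx$cohort$subjects$subject_id)]
  expect_equal(w21$label, lab)
})

test_that("a sparsely observed subject yields no 21-night windows", {
  su <- make_summaries(1, 40)
  keep <- c(1, 5, 9, 13, 17, 21, 25, 29, 33, 37) # 10 of 40 nights
  su[-keep, feature_sets()$set1] <- NA
  sf <- fake_features(su, feature_sets()$set3)[keep, ]
  tf <- fake_features(su, feature_sets()$set5)[keep, ]
  nt <- build_nightly_table(sf, tf, su)
  expect_equal(sum(nt$night_present), 10L)
  expect_equal(nrow(anchor_starts(nt)), 0L)
})

test_that("stratified split is subject-disjoint, proportional and deterministic", {
  fx <- fixture_cohort()
  subjects <- fx$cohort$subjects
  sp <- suppressWarnings(stratified_split(subjects, 0.8, seed = 123))
  expect_length(intersect(sp$train_ids, sp$test_ids), 0)
  expect_setequal(c(sp$train_ids, sp$test_ids), subjects$subject_id)
  sp2 <- suppressWarnings(stratified_split(subjects, 0.8, seed = 123))
  expect_identical(sp, sp2)
  # per-stratum proportions within one subject of the global fraction
  for (st in split(subjects, paste(subjects$label, subjects$age_bin))) {
    if (nrow(st) < 2) next
    n_train <- sum(st$subject_id %in% sp$train_ids)
    expect_lte(abs(n_train - 0.8 * nrow(st)), 1)
  }
})

test_that("uniform strata split exactly 80/20", {
  subjects <- expand.grid(
    label = c(0L, 1L), age_bin = age_bins(), i = 1:20,
    stringsAsFactors = FALSE
  )
  subjects$subject_id <- sprintf("U%03d", seq_len(nrow(subjects)))
  sp <- stratified_split(subjects, 0.8, seed = 9)
  expect_length(sp$train_ids, 160)
  expect_length(sp$test_ids, 40)
  for (st in split(subjects, paste(subjects$label, subjects$age_bin))) {
    expect_equal(sum(st$subject_id %in% sp$train_ids), 16)
  }
})

test_that("singleton strata go to train with a warning", {
  subjects <- data.frame(
    subject_id = c("A", "B", "C"),
    label = c(1L, 0L, 0L),
    age_bin = c("30-39", "40-49", "40-49")
  )
  expect_warning(sp <- stratified_split(subjects, 0.8, seed = 1), "single subject")
  expect_true("A" %in% sp$train_ids)
})

test_that("class-balanced sampling equalizes classes within age/sex cells", {
  fx <- fixture_cohort()
  subjects <- fx$cohort$subjects
  cohort <- stratified_class_sample(subjects, 12, seed = 31)
  expect_equal(sum(cohort$label == 1L), sum(cohort$label == 0L))
  cells <- split(cohort, paste(cohort$age_bin, cohort$sex))
  for (cell in cells) {
    expect_equal(sum(cell$label == 1L), sum(cell$label == 0L))
  }
  # deterministic
  expect_identical(cohort, stratified_class_sample(subjects, 12, seed = 31))
  # over-asking shrinks with a warning
  expect_warning(big <- stratified_class_sample(subjects, 1000, seed = 31), "support only")
  expect_equal(sum(big$label == 1L), sum(big$label == 0L))
})
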