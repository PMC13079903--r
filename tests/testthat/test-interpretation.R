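# Importance aggregation, feature-set ablation, and the nonparametric test
# chains.

test_that("planted informative feature ranks first in importance", {
  w <- planted_windows(300, "hr_average", effect = 3, seed = 61)
  for (fam in c("trees", "linear")) {
    m <- fit_window_model(model_spec(fam, 1), w, seed = 1)
    imp <- aggregate_importance(m)
    expect_equal(imp$feature[1], "hr_average")
    expect_equal(sum(imp$importance), 1)
    expect_equal(nrow(imp), 36L)
  }
})

test_that("importance is aggregated across night positions", {
  fx <- fixture_cohort()
  w <- extract_windows(fx$nightly, fx$cohort$subjects, 3, fx$anchors)
  tr <- w[w$subject_id %in% fx$split$train_ids, ]
  m <- fit_window_model(model_spec("trees", 3), tr, seed = 1)
  imp <- aggregate_importance(m)
  expect_setequal(imp$feature, feature_names())
  expect_equal(sum(imp$importance), 1)
})

test_that("ablation trains all 31 combinations and credits the signal set", {
  tr <- planted_windows(400, feature_sets()$set5, effect = 1.5, seed = 62)
  te <- planted_windows(200, feature_sets()$set5, effect = 1.5, seed = 63)
  ab <- ablation_sweep(tr, te, model_spec("linear", 1), seed = 1)
  expect_equal(nrow(ab$results), 31L)
  expect_false(any(is.na(ab$results$auroc)))
  expect_equal(ab$delta$n_additions, rep(16L, 5))
  best <- ab$delta$set[which.max(ab$delta$mean_delta_auroc)]
  expect_equal(best, "set5")
  # the full combination is present and strong
  full <- ab$results$auroc[ab$results$combo == "1,2,3,4,5"]
  expect_gt(full, 0.8)
})

test_that("all-noise features yield near-zero ablation deltas", {
  set.seed(64)
  deltas <- replicate(5, {
    seed <- sample.int(1e6, 1)
    tr <- planted_windows(250, character(0), seed = seed)
    te <- planted_windows(150, character(0), seed = seed + 1)
    ab <- ablation_sweep(tr, te, model_spec("linear", 1), seed = 1)
    # chance-level models hover at 0.5, so set deltas excluding the empty
    # prefix hover at 0
    ab$delta$mean_delta_auroc
  })
  expect_true(all(abs(deltas) < 0.05 + 0.5 / 16))
})

test_that("ablation of the full set matches the main pipeline fit exactly", {
  fx <- fixture_cohort()
  w <- extract_windows(fx$nightly, fx$cohort$subjects, 1, fx$anchors)
  tr <- w[w$subject_id %in% fx$split$train_ids, ]
  te <- w[w$subject_id %in% fx$split$test_ids, ]
  spec <- model_spec("linear", 1)
  ab <- ablation_sweep(tr, te, spec, seed = 3)
  direct <- roc_prc(
    predict_scores(fit_window_model(spec, tr, seed = 3), te), te$label
  )
  expect_equal(ab$results$auroc[ab$results$combo == "1,2,3,4,5"], direct$auroc)
})

test_that("Dunn test matches the brute-force oracle and stays BH-monotone", {
  set.seed(65)
  x <- c(rnorm(10, 0), rnorm(10, 0.8), rnorm(10, 2))
  g <- rep(c("a", "b", "c"), each = 10)
  got <- dunn_test(x, g)
  ref <- dunn_oracle(x, g)
  expect_equal(got$z, ref$z, tolerance = 1e-8)
  expect_equal(got$p, ref$p, tolerance = 1e-8)
  expect_equal(got$p_adj, ref$p_adj, tolerance = 1e-8)
  # with ties
  xt <- round(x, 0)
  expect_equal(dunn_test(xt, g)$z, dunn_oracle(xt, g)$z, tolerance = 1e-8)
  # BH preserves the raw p ordering
  expect_equal(order(got$p), order(got$p_adj))
})

test_that("frozen three-group fixture reproduces its Dunn statistics", {
  # 3 x 10 fixture; expected values computed with the independent oracle
  x <- c(
    1.2, 0.8, 1.5, 0.9, 1.1, 1.3, 0.7, 1.0, 1.4, 0.6,
    1.9, 2.1, 1.6, 2.4, 1.8, 2.0, 2.2, 1.7, 2.3, 2.5,
    3.1, 2.8, 3.4, 2.9, 3.0, 3.2, 2.7, 3.3, 3.5, 2.6
  )
  g <- rep(c("dm", "other", "none"), each = 10)
  got <- dunn_test(x, g)
  ref <- dunn_oracle(x, g)
  expect_equal(got$z, ref$z, tolerance = 1e-8)
  expect_equal(got$p_adj, ref$p_adj, tolerance = 1e-8)
  # ranks are exact here: group means 5.5 / 15.5 / 25.5, se = sqrt(155/3)
  se <- sqrt((30 * 31 / 12) * (2 / 10))
  expect_equal(got$z[got$comparison == "dm - none"], -20 / se, tolerance = 1e-12)
})

test_that("identical groups are not separated; shifted groups are", {
  set.seed(66)
  x_null <- rnorm(120)
  g <- rep(c("a", "b", "c"), each = 40)
  kw <- stats::kruskal.test(x_null, factor(g))
  expect_gt(kw$p.value, 0.05)
  dn <- dunn_test(x_null, g)
  expect_true(all(dn$p_adj > 0.05))

  x_shift <- x_null + c(rep(0, 40), rep(0, 40), rep(2, 40))
  kw2 <- stats::kruskal.test(x_shift, factor(g))
  expect_lt(kw2$p.value, 0.001)
})

test_that("chronic-condition analysis groups subjects and runs the chain", {
  set.seed(67)
  subjects <- data.frame(
    subject_id = sprintf("S%02d", 1:45),
    label = rep(c(1L, 0L, 0L), each = 15),
    other_conditions = rep(c("", "hypertension", ""), each = 15)
  )
  scored <- do.call(rbind, lapply(1:45, function(i) {
    mu <- if (subjects$label[i] == 1L) 0.7 else 0.35
    data.frame(
      subject_id = subjects$subject_id[i],
      score = pmin(pmax(rnorm(8, mu, 0.1), 0), 1)
    )
  }))
  res <- chronic_condition_analysis(scored, subjects)
  expect_equal(as.integer(res$group_sizes), c(15, 15, 15))
  expect_lt(res$kruskal$p.value, 0.001)
  dm_rows <- grepl("dm", res$dunn$comparison)
  expect_true(all(res$dunn$p_adj[dm_rows] < 0.01))
  # the two control groups are alike by construction
  expect_gt(res$dunn$p_adj[!dm_rows], 0.05)
  expect_true(all(res$probabilities$mean_probability >= 0 &
                    res$probabilities$mean_probability <= 1))
})

test_that("model probability comparison runs one-sided per group", {
  set.seed(68)
  subjects <- data.frame(
    subject_id = sprintf("S%02d", 1:30),
    label = rep(c(1L, 0L), each = 15),
    other_conditions = ""
  )
  mk <- function(shift) {
    do.call(rbind, lapply(1:30, function(i) {
      data.frame(subject_id = subjects$subject_id[i],
                 score = plogis(rnorm(5, subjects$label[i] + shift)))
    }))
  }
  pa <- chronic_condition_analysis(mk(1), subjects)$probabilities
  pb <- chronic_condition_analysis(mk(0), subjects)$probabilities
  cmp <- compare_model_probabilities(pa, pb, alternative = "greater")
  expect_true(all(c("dm", "no_condition") %in% cmp$group))
  expect_true(all(cmp$p < 0.05))
})

test_that("population-level tests recover closed-form effect sizes", {
  set.seed(69)
  # d = 1 between N(1,1) and N(0,1)
  x1 <- rnorm(1e4, 1)
  x0 <- rnorm(1e4, 0)
  expect_equal(cohens_d(x1, x0), 1.0, tolerance = 0.05)
  # identical distributions: d ~ 0
  expect_lt(abs(cohens_d(rnorm(5000), rnorm(5000))), 0.06)
  # U statistic against the pairwise-count oracle
  a <- round(rnorm(20), 1)
  b <- round(rnorm(20), 1)
  w <- unname(stats::wilcox.test(a, b, exact = FALSE)$statistic)
  expect_equal(w, mann_whitney_u_oracle(a, b))
})

test_that("nightly population tests apply the published preprocessing", {
  fx <- fixture_cohort()
  res <- nightly_population_tests(
    fx$nightly, fx$cohort$subjects,
    features = commonly_used_features()
  )
  expect_equal(sort(res$feature), sort(commonly_used_features()))
  # HR filtering drops ~10% of nights
  hr_row <- res[res$feature == "hr_average", ]
  n_nights <- sum(fx$nightly$night_present)
  expect_lt(hr_row$n_dm + hr_row$n_control, n_nights)
  # the generator's DM class has higher HR and lower RMSSD
  expect_gt(res$cohens_d[res$feature == "hr_average"], 0)
  expect_lt(res$cohens_d[res$feature == "rmssd"], 0)
  # per-age-bin rows appear on request
  res_bins <- nightly_population_tests(
    fx$nightly, fx$cohort$subjects,
    features = "hr_average", by_age_bin = TRUE
  )
  expect_true("all" %in% res_bins$age_bin)
  expect_gt(nrow(res_bins), 1)
})

test_that("false-negative windows profile between true groups", {
  set.seed(70)
  w <- planted_windows(200, "hr_average", effect = 1.5, seed = 71)
  m <- fit_window_model(model_spec("linear", 1), w, seed = 1)
  s <- predict_scores(m, w)
  th <- roc_prc(s, w$label)$youden$threshold
  prof <- false_negative_profile(w, s, th)
  if (!is.null(prof)) {
    expect_equal(names(prof$tests), commonly_used_features())
    expect_true(all(prof$group_sizes > 0))
    hr <- prof$tests$hr_average
    # false negatives sit between true negatives and true positives,
    # closer to TN by construction of the planted signal
    expect_lt(hr$medians[["FN"]], hr$medians[["TP"]])
  }
  # degenerate threshold: no FN at all
  expect_warning(res <- false_negative_profile(w, s, min(s) - 1), "skipped")
  expect_null(res)
})
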