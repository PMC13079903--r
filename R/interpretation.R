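# Feature importance aggregation over night positions, feature-set
# ablation, and the chronic-condition specificity analyses with the
# Kruskal-Wallis -> Dunn (Benjamini-Hochberg) test chain.

strip_night_suffix <- function(cols) sub("__n\\d+$", "", cols)

#' Per-feature importance aggregated over night positions
#'
#' Tree models: native gain importance per flattened column, summed across
#' the window's night positions of each base feature. Linear models: mean
#' absolute coefficient across night positions. Both are normalized to sum
#' to 1, so summing vs averaging over nights does not change the ranking.
#'
#' @param model a `wd_model` from [fit_window_model()].
#' @return data.frame `feature`, `importance`, sorted decreasing.
#' @export
aggregate_importance <- function(model) {
  cols <- model$feature_names
  base <- strip_night_suffix(cols)
  raw <- stats::setNames(numeric(length(cols)), cols)
  if (model$spec$family == "trees") {
    imp <- xgboost::xgb.importance(model = model$fit)
    raw[imp$Feature] <- imp$Gain
    agg <- tapply(raw, base, sum)
  } else {
    co <- as.numeric(stats::coef(model$fit))[-1] # drop intercept
    raw[] <- abs(co)
    agg <- tapply(raw, base, mean)
  }
  total <- sum(agg)
  if (total > 0) agg <- agg / total
  out <- data.frame(feature = names(agg), importance = as.numeric(agg))
  out <- out[order(-out$importance), ]
  rownames(out) <- NULL
  out
}

combo_key <- function(sets) paste(sort(sets), collapse = ",")

#' Feature-set ablation sweep
#'
#' Retrains the classifier on every nonempty combination of the five
#' feature sets (columns of excluded sets removed, not zeroed) and records
#' test AUROC/AUPRC. The marginal contribution of a set is the mean test
#' AUROC increase over the 16 subsets of the other four sets (including
#' the empty prefix, whose AUROC is 0.5: a featureless model is chance).
#'
#' @param train_windows,test_windows window tables.
#' @param spec a [model_spec()].
#' @param seed integer seed.
#' @return list with `results` (31 rows: `combo`, `auroc`, `auprc`) and
#'   `delta` (per set: mean, 25th and 75th percentile of the AUROC
#'   increase over its 16 additions).
#' @export
ablation_sweep <- function(train_windows, test_windows, spec, seed = 1) {
  sets <- feature_sets()
  combos <- unlist(lapply(1:5, function(k) {
    utils::combn(1:5, k, simplify = FALSE)
  }), recursive = FALSE)
  results <- data.frame(
    combo = vapply(combos, combo_key, character(1)),
    auroc = NA_real_, auprc = NA_real_
  )
  feat_cols <- window_feature_columns(train_windows)
  base <- strip_night_suffix(feat_cols)
  for (i in seq_along(combos)) {
    keep_feats <- unlist(sets[combos[[i]]], use.names = FALSE)
    cols <- feat_cols[base %in% keep_feats]
    tr <- train_windows[, c("subject_id", "start_date", "label", cols)]
    te <- test_windows[, c("subject_id", "start_date", "label", cols)]
    m <- fit_window_model(spec, tr, seed = seed)
    ev <- roc_prc(predict_scores(m, te), te$label)
    results$auroc[i] <- ev$auroc
    results$auprc[i] <- ev$auprc
  }
  auc_of <- stats::setNames(results$auroc, results$combo)
  lookup_auc <- function(key) if (nzchar(key)) auc_of[[key]] else 0.5
  delta <- do.call(rbind, lapply(1:5, function(s) {
    others <- setdiff(1:5, s)
    subsets <- c(list(integer(0)), unlist(lapply(1:4, function(k) {
      utils::combn(others, k, simplify = FALSE)
    }), recursive = FALSE))
    gains <- vapply(subsets, function(T) {
      lookup_auc(combo_key(c(T, s))) - lookup_auc(combo_key(T))
    }, numeric(1))
    data.frame(
      set = paste0("set", s),
      mean_delta_auroc = mean(gains),
      q25 = unname(stats::quantile(gains, 0.25)),
      q75 = unname(stats::quantile(gains, 0.75)),
      n_additions = length(gains)
    )
  }))
  rownames(delta) <- NULL
  list(results = results, delta = delta)
}

#' Dunn's post-hoc test of pairwise stochastic dominance after Kruskal-Wallis
#'
#' Pairwise z statistics on mean ranks with the tie correction, two-sided
#' p-values, adjusted by default with Benjamini-Hochberg.
#'
#' @param x numeric response.
#' @param g group factor (2+ levels).
#' @param p_adjust_method passed to [stats::p.adjust()].
#' @return data.frame `comparison`, `z`, `p`, `p_adj`.
#' @export
dunn_test <- function(x, g, p_adjust_method = "BH") {
  g <- factor(g)
  ok <- !is.na(x) & !is.na(g)
  x <- x[ok]
  g <- droplevels(g[ok])
  if (nlevels(g) < 2) stop("need at least two groups")
  r <- rank(x)
  N <- length(x)
  ties <- table(x)
  tie_corr <- sum(ties^3 - ties) / (12 * (N - 1))
  rbar <- tapply(r, g, mean)
  n <- tapply(r, g, length)
  lv <- levels(g)
  pairs <- utils::combn(lv, 2, simplify = FALSE)
  out <- do.call(rbind, lapply(pairs, function(p2) {
    i <- p2[1]
    j <- p2[2]
    se <- sqrt((N * (N + 1) / 12 - tie_corr) * (1 / n[[i]] + 1 / n[[j]]))
    z <- (rbar[[i]] - rbar[[j]]) / se
    data.frame(
      comparison = paste(i, j, sep = " - "),
      z = z, p = 2 * stats::pnorm(-abs(z))
    )
  }))
  out$p_adj <- stats::p.adjust(out$p, method = p_adjust_method)
  rownames(out) <- NULL
  out
}

#' Group subjects for the chronic-condition analysis
#'
#' @param subjects subject table with `label` and `other_conditions`.
#' @return factor: `"dm"`, `"other_condition"` (no DM DX but another
#'   chronic condition) or `"no_condition"`.
#' @export
condition_group <- function(subjects) {
  factor(
    ifelse(subjects$label == 1L, "dm",
      ifelse(nzchar(subjects$other_conditions), "other_condition", "no_condition")
    ),
    levels = c("dm", "other_condition", "no_condition")
  )
}

#' Chronic-condition specificity analysis of model probabilities
#'
#' Averages each test subject's predicted probability, partitions subjects
#' into DM / other-chronic-condition / no-condition groups, and runs the
#' Kruskal-Wallis omnibus test followed by two-sided Dunn post-hoc tests
#' with Benjamini-Hochberg adjustment.
#'
#' @param scored window-level scores (`subject_id`, `score`), e.g.
#'   `evaluate_model(...)$scores`.
#' @param subjects subject table (test subjects) with `label`,
#'   `other_conditions`.
#' @return list: `probabilities` (per subject: mean probability + group),
#'   `kruskal` (htest), `dunn` (data.frame), `group_sizes`.
#' @export
chronic_condition_analysis <- function(scored, subjects) {
  mp <- tapply(scored$score, scored$subject_id, mean)
  probs <- data.frame(subject_id = names(mp), mean_probability = as.numeric(mp))
  probs <- merge(probs, subjects[, c("subject_id", "label", "other_conditions")],
                 by = "subject_id")
  probs$group <- condition_group(probs)
  kw <- stats::kruskal.test(mean_probability ~ group, data = probs)
  dn <- dunn_test(probs$mean_probability, probs$group)
  list(
    probabilities = probs[, c("subject_id", "mean_probability", "group")],
    kruskal = kw, dunn = dn,
    group_sizes = table(probs$group)
  )
}

#' Compare two models' per-subject probabilities within each group
#'
#' One-sided Mann-Whitney U test per condition group, testing whether
#' model A's probabilities are shifted relative to model B's (e.g. feature
#' sets 1-5 vs 1-3).
#'
#' @param probs_a,probs_b outputs of [chronic_condition_analysis()]
#'   (`probabilities` element) from the two models, same subjects.
#' @param alternative passed to [stats::wilcox.test()]; `"greater"` tests
#'   whether model A's probabilities dominate.
#' @return data.frame `group`, `U`, `p`.
#' @export
compare_model_probabilities <- function(probs_a, probs_b,
                                        alternative = "greater") {
  m <- merge(probs_a, probs_b, by = "subject_id", suffixes = c("_a", "_b"))
  out <- do.call(rbind, lapply(levels(m$group_a), function(gr) {
    a <- m$mean_probability_a[m$group_a == gr]
    b <- m$mean_probability_b[m$group_a == gr]
    if (length(a) < 2) {
      return(NULL)
    }
    wt <- stats::wilcox.test(a, b, alternative = alternative, exact = FALSE)
    data.frame(group = gr, U = unname(wt$statistic), p = wt$p.value)
  }))
  rownames(out) <- NULL
  out
}

#' Cohen's d with pooled SD
#'
#' `(mean(x1) - mean(x0)) / sqrt(((n1-1) s1^2 + (n0-1) s0^2) / (n1+n0-2))`.
#'
#' @param x1,x0 numeric samples (positive class first).
#' @return signed effect size.
#' @export
cohens_d <- function(x1, x0) {
  x1 <- x1[!is.na(x1)]
  x0 <- x0[!is.na(x0)]
  n1 <- length(x1)
  n0 <- length(x0)
  sp <- sqrt(((n1 - 1) * stats::var(x1) + (n0 - 1) * stats::var(x0)) / (n1 + n0 - 2))
  (mean(x1) - mean(x0)) / sp
}

# The published preprocessing of the commonly used features before
# population-level testing: HR outside the 5/95% quantiles dropped, RMSSD
# above the 98% quantile dropped, TST outside the 1/99% quantiles dropped,
# amplitude unfiltered.
filter_commonly_used <- function(values, feature) {
  q <- function(p) stats::quantile(values, p, na.rm = TRUE, names = FALSE)
  keep <- switch(feature,
    hr_average = values >= q(0.05) & values <= q(0.95),
    rmssd = values <= q(0.98),
    total_sleep_time = values >= q(0.01) & values <= q(0.99),
    rep(TRUE, length(values))
  )
  values[!keep] <- NA
  values
}

#' Population-level per-feature class comparisons of nightly features
#'
#' Two-sided Mann-Whitney U test and pooled-SD Cohen's d per feature
#' (DM minus control), optionally within each age bin. The commonly used
#' features get their published quantile preprocessing first.
#'
#' @param nightly nightly feature table with `night_present` rows to use.
#' @param subjects subject table with `label` (and `age_bin`).
#' @param features feature columns to test (default: all 36).
#' @param by_age_bin also compute per-age-bin rows.
#' @return data.frame `feature`, `age_bin` (`"all"` for pooled), `U`, `p`,
#'   `cohens_d`, `n_dm`, `n_control`.
#' @export
nightly_population_tests <- function(nightly, subjects,
                                     features = feature_names(),
                                     by_age_bin = FALSE) {
  d <- merge(nightly[nightly$night_present, ],
             subjects[, c("subject_id", "label", "age_bin")],
             by = "subject_id")
  bins <- if (by_age_bin) c("all", sort(unique(d$age_bin))) else "all"
  out <- do.call(rbind, lapply(features, function(f) {
    vals <- filter_commonly_used(d[[f]], f)
    do.call(rbind, lapply(bins, function(b) {
      sel <- if (b == "all") rep(TRUE, nrow(d)) else d$age_bin == b
      x1 <- vals[sel & d$label == 1L]
      x0 <- vals[sel & d$label == 0L]
      x1 <- x1[!is.na(x1)]
      x0 <- x0[!is.na(x0)]
      if (length(x1) < 2 || length(x0) < 2) {
        return(NULL)
      }
      wt <- stats::wilcox.test(x1, x0, exact = FALSE)
      data.frame(
        feature = f, age_bin = b, U = unname(wt$statistic), p = wt$p.value,
        cohens_d = cohens_d(x1, x0),
        n_dm = length(x1), n_control = length(x0)
      )
    }))
  }))
  rownames(out) <- NULL
  out
}

#' Profile false-negative windows against true negatives and positives
#'
#' Partitions test windows at a threshold into true negative, false
#' negative and true positive groups and runs the Kruskal-Wallis + Dunn
#' (BH) chain on each commonly used feature, averaged within the window.
#'
#' @param windows test window table (with features).
#' @param scores model scores for those windows.
#' @param threshold operating threshold (e.g. the Youden threshold).
#' @return `NULL` (with a warning) when a group is empty; otherwise list
#'   with `group_sizes` and per-feature `tests` (kruskal p, dunn table,
#'   group medians).
#' @export
false_negative_profile <- function(windows, scores, threshold) {
  pred <- scores >= threshold
  grp <- rep(NA_character_, nrow(windows))
  grp[windows$label == 0L & !pred] <- "TN"
  grp[windows$label == 1L & !pred] <- "FN"
  grp[windows$label == 1L & pred] <- "TP"
  sizes <- table(factor(grp, levels = c("TN", "FN", "TP")))
  if (any(sizes == 0)) {
    warning("empty TN/FN/TP group; false-negative profile skipped")
    return(NULL)
  }
  feat_cols <- window_feature_columns(windows)
  base <- strip_night_suffix(feat_cols)
  tests <- lapply(commonly_used_features(), function(f) {
    v <- rowMeans(windows[, feat_cols[base == f], drop = FALSE], na.rm = TRUE)
    ok <- !is.na(grp) & !is.na(v)
    kw <- stats::kruskal.test(v[ok], factor(grp[ok]))
    list(
      feature = f,
      kruskal_p = kw$p.value,
      dunn = dunn_test(v[ok], grp[ok]),
      medians = tapply(v[ok], grp[ok], stats::median)
    )
  })
  names(tests) <- commonly_used_features()
  list(group_sizes = sizes, tests = tests)
}
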