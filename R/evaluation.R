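# ROC / PRC machinery with fixed tie semantics (thresholds at unique
# scores, predictions by >=), Youden-threshold confusion metrics, and the
# repeated-subsampling imbalanced-cohort protocol.

#' ROC and precision-recall curves with areas
#'
#' Thresholds are the unique scores (ties grouped); a window is predicted
#' positive when its score is at or above the threshold. AUROC is the
#' trapezoid area over FPR; AUPRC is the step-wise sum of precision times
#' recall increment. The optimal operating threshold maximizes Youden's J
#' (sensitivity + specificity - 1).
#'
#' @param scores numeric scores (higher = more positive).
#' @param labels 0/1 labels; both classes must be present.
#' @return a `wd_eval` list: `roc` and `prc` point tables, `auroc`,
#'   `auprc`, `youden` (threshold and J), `prevalence`, `n`.
#' @export
roc_prc <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(scores) != length(labels)) stop("scores and labels differ in length")
  P <- sum(labels == 1L)
  N <- sum(labels == 0L)
  if (P == 0 || N == 0) stop("both classes must be present")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  y <- labels[ord]
  # cumulative counts at each unique score (last index of each tie group)
  last <- cumsum(rle(s)$lengths)
  tp <- cumsum(y)[last]
  fp <- cumsum(1L - y)[last]
  threshold <- s[last]
  tpr <- tp / P
  fpr <- fp / N
  precision <- tp / (tp + fp)
  roc <- data.frame(threshold = c(Inf, threshold), fpr = c(0, fpr), tpr = c(0, tpr))
  prc <- data.frame(threshold = threshold, recall = tpr, precision = precision)
  auroc <- sum(diff(roc$fpr) * (utils::head(roc$tpr, -1) + utils::tail(roc$tpr, -1)) / 2)
  auprc <- sum(diff(c(0, tpr)) * precision)
  j <- tpr - fpr
  best <- which.max(j)
  structure(
    list(
      roc = roc, prc = prc, auroc = auroc, auprc = auprc,
      youden = list(threshold = threshold[best], J = j[best]),
      prevalence = P / (P + N), n = P + N
    ),
    class = "wd_eval"
  )
}

#' Confusion counts and derived metrics at a score threshold
#'
#' Predicted positive iff `score >= threshold`.
#'
#' @param scores,labels as in [roc_prc()].
#' @param threshold operating threshold.
#' @return list of counts (`tp`, `fp`, `tn`, `fn`) and metrics
#'   (`sensitivity`/`tpr`, `specificity`, `fpr`, `precision`, `recall`,
#'   `f1`).
#' @export
confusion_at_threshold <- function(scores, labels, threshold) {
  labels <- as.integer(labels)
  pred <- scores >= threshold
  tp <- sum(pred & labels == 1L)
  fp <- sum(pred & labels == 0L)
  tn <- sum(!pred & labels == 0L)
  fn <- sum(!pred & labels == 1L)
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  f1 <- if (!is.na(prec) && !is.na(sens) && prec + sens > 0) {
    2 * prec * sens / (prec + sens)
  } else {
    NA_real_
  }
  list(
    tp = tp, fp = fp, tn = tn, fn = fn,
    sensitivity = sens, tpr = sens, specificity = spec,
    fpr = if (is.na(spec)) NA_real_ else 1 - spec,
    precision = prec, recall = sens, f1 = f1
  )
}

#' Evaluate a trained model on a window table
#'
#' @param model a `wd_model`.
#' @param windows window table with labels.
#' @return a `wd_eval` augmented with the confusion metrics at the Youden
#'   threshold (`confusion`) and the scores themselves.
#' @export
evaluate_model <- function(model, windows) {
  scores <- predict_scores(model, windows)
  ev <- roc_prc(scores, windows$label)
  ev$confusion <- confusion_at_threshold(scores, windows$label, ev$youden$threshold)
  ev$scores <- data.frame(
    subject_id = windows$subject_id,
    start_date = windows$start_date,
    label = windows$label, score = scores
  )
  ev
}

#' Design of a prevalence-matched evaluation cohort
#'
#' Given the positive-subject pool size and a target prevalence, the number
#' of control subjects to sample and the window counts per repetition.
#'
#' @param n_positive_subjects positive (DM) subjects available.
#' @param prevalence target positive fraction.
#' @param windows_per_subject windows sampled per subject per repetition.
#' @return list `n_controls`, `achieved_prevalence`, `positive_windows`,
#'   `control_windows`.
#' @export
imbalanced_design <- function(n_positive_subjects, prevalence = 0.179,
                              windows_per_subject = 10) {
  if (prevalence <= 0 || prevalence >= 1) stop("prevalence must lie in (0, 1)")
  n_controls <- round(n_positive_subjects * (1 - prevalence) / prevalence)
  list(
    n_controls = n_controls,
    achieved_prevalence = n_positive_subjects / (n_positive_subjects + n_controls),
    positive_windows = n_positive_subjects * windows_per_subject,
    control_windows = n_controls * windows_per_subject
  )
}

# Interpolate a ROC (or PRC) curve onto a fixed grid, stepwise from the
# computed points.
curve_on_grid <- function(x, y, grid) {
  o <- order(x, y)
  stats::approx(x[o], y[o], xout = grid, method = "linear",
                ties = max, rule = 2)$y
}

#' Repeated-subsampling evaluation in a prevalence-matched cohort
#'
#' Per repetition: sample controls (age/sex-balanced by proportional
#' allocation to the positive pool's strata, largest-remainder rounding) so
#' the subject-level positive fraction equals the target prevalence, sample
#' a fixed number of windows per subject, score, and compute ROC/PRC.
#' Curves are summarized pointwise (median and 25-75% band) on fixed
#' 101-point FPR and recall grids.
#'
#' @param scored data.frame of test windows with `subject_id`, `label`,
#'   `score` (e.g. `evaluate_model(...)$scores`).
#' @param subjects subject table with `subject_id`, `age_bin`, `sex`; must
#'   cover the scored subjects and be disjoint from training.
#' @param prevalence target positive fraction.
#' @param reps repetitions.
#' @param windows_per_subject windows per subject per repetition (sampled
#'   with replacement when a subject has fewer).
#' @param seed integer seed.
#' @return list: `auroc`/`auprc` per-repetition vectors, their `median` and
#'   IQR, `roc_band` and `prc_band` grid tables, and the `design`.
#' @export
imbalanced_protocol <- function(scored, subjects, prevalence = 0.179,
                                reps = 100, windows_per_subject = 10,
                                seed = 1) {
  pos_ids <- unique(scored$subject_id[scored$label == 1L])
  ctrl_ids <- unique(scored$subject_id[scored$label == 0L])
  if (length(pos_ids) == 0 || length(ctrl_ids) == 0) {
    stop("both classes must be present in the scored pool")
  }
  design <- imbalanced_design(length(pos_ids), prevalence, windows_per_subject)
  if (length(ctrl_ids) < design$n_controls) {
    warning(sprintf(
      "control pool (%d) smaller than the %d the prevalence design asks for; achieved prevalence will be higher",
      length(ctrl_ids), design$n_controls
    ))
  }
  sinfo <- subjects[match(c(pos_ids, ctrl_ids), subjects$subject_id), ]
  cell <- stats::setNames(paste(sinfo$age_bin, sinfo$sex, sep = "/"), sinfo$subject_id)
  pos_cells <- table(cell[pos_ids])
  by_window <- split(seq_len(nrow(scored)), scored$subject_id)

  grid <- seq(0, 1, length.out = 101)
  roc_mat <- matrix(NA_real_, reps, length(grid))
  prc_mat <- matrix(NA_real_, reps, length(grid))
  aurocs <- auprcs <- numeric(reps)

  with_preserved_seed(seed, {
    for (r in seq_len(reps)) {
      ctrl <- sample_balanced_controls(ctrl_ids, cell, pos_cells, design$n_controls)
      take <- unlist(lapply(c(pos_ids, ctrl), function(id) {
        idx <- by_window[[id]]
        if (length(idx) >= windows_per_subject) {
          sample(idx, windows_per_subject)
        } else {
          sample(idx, windows_per_subject, replace = TRUE)
        }
      }))
      ev <- roc_prc(scored$score[take], scored$label[take])
      aurocs[r] <- ev$auroc
      auprcs[r] <- ev$auprc
      roc_mat[r, ] <- curve_on_grid(ev$roc$fpr, ev$roc$tpr, grid)
      prc_mat[r, ] <- curve_on_grid(ev$prc$recall, ev$prc$precision, grid)
    }
  })

  band <- function(mat, xname, yname) {
    q <- apply(mat, 2, stats::quantile, probs = c(0.25, 0.5, 0.75))
    out <- data.frame(grid, q[2, ], q[1, ], q[3, ])
    names(out) <- c(xname, paste0(yname, c("_median", "_q25", "_q75")))
    out
  }
  list(
    auroc = aurocs, auprc = auprcs,
    auroc_median = stats::median(aurocs),
    auroc_iqr = unname(stats::quantile(aurocs, c(0.25, 0.75))),
    auprc_median = stats::median(auprcs),
    auprc_iqr = unname(stats::quantile(auprcs, c(0.25, 0.75))),
    roc_band = band(roc_mat, "fpr", "tpr"),
    prc_band = band(prc_mat, "recall", "precision"),
    design = design
  )
}

# Proportional allocation of control draws to the positive pool's age/sex
# strata; strata short of controls spill over to the remaining strata.
sample_balanced_controls <- function(ctrl_ids, cell, pos_cells, n_controls) {
  strata <- names(pos_cells)
  pools <- lapply(strata, function(st) ctrl_ids[cell[ctrl_ids] == st])
  avail <- lengths(pools)
  alloc <- largest_remainder(as.numeric(pos_cells), n_controls)
  short <- sum(pmax(alloc - avail, 0))
  alloc <- pmin(alloc, avail)
  if (short > 0) {
    # spill into the leftover pool (controls outside the positive strata
    # first, then unused capacity within them)
    leftover <- setdiff(ctrl_ids, unlist(mapply(
      function(p, k) if (k > 0) p[seq_len(k)] else character(0),
      pools, alloc, SIMPLIFY = FALSE
    )))
  }
  picked <- unlist(mapply(function(p, k) {
    if (k > 0) sample(p, k) else character(0)
  }, pools, alloc, SIMPLIFY = FALSE))
  if (short > 0) {
    rest <- setdiff(ctrl_ids, picked)
    picked <- c(picked, sample(rest, min(short, length(rest))))
  }
  picked
}
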