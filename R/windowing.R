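# Nightly feature table assembly, rolling multi-night windows with
# missing-night quality caps, and subject-disjoint stratified splits.
#
# Quality rule: across all 21-night windows, a window is valid when no
# aligned week (nights 1-7, 8-14, 15-21) has more than 2 missing nights.
# The start dates of valid 21-night windows anchor the datasets of every
# other length, so all window-length datasets share their start dates, and
# each length additionally enforces its own total-missing cap (1-night: 0;
# 3-night: 2; 7-night: 2; 14-night: 4; 21-night: 6).

WINDOW_LENGTHS <- c(1L, 3L, 7L, 14L, 21L)

missing_cap <- function(L) {
  switch(as.character(L), "1" = 0L, "3" = 2L, "7" = 2L, "14" = 4L, "21" = 6L,
    stop("window length must be one of 1, 3, 7, 14, 21")
  )
}

#' Assemble the 36-feature nightly table
#'
#' Outer-joins the sleep features, temperature features and scalar
#' summaries on (subject, night). A night with no extractable feature at
#' all is flagged absent (`night_present = FALSE`); a night missing one
#' input (say the hypnogram) keeps its row with that block `NA`.
#'
#' @param sleep_df output of [sleep_features()].
#' @param temp_df output of [temperature_features()].
#' @param summaries data.frame with `subject_id`, `night_date`, the
#'   HR/HRV/respiration scalar columns, and (for the calendar) one row per
#'   subject-night slot including missing nights.
#' @return data.frame with `subject_id`, `night_date`, `night_present` and
#'   the 36 feature columns in canonical order.
#' @export
build_nightly_table <- function(sleep_df, temp_df, summaries) {
  for (d in list(sleep_df, temp_df, summaries)) {
    if (nrow(d) > 0 && anyDuplicated(d[, c("subject_id", "night_date")])) {
      stop("duplicate (subject_id, night_date) rows in input")
    }
  }
  set1 <- feature_sets()$set1
  base <- summaries[, c("subject_id", "night_date", intersect(set1, names(summaries)))]
  out <- merge(base, sleep_df, by = c("subject_id", "night_date"), all = TRUE)
  out <- merge(out, temp_df, by = c("subject_id", "night_date"), all = TRUE)
  for (f in setdiff(feature_names(), names(out))) {
    out[[f]] <- NA_real_
  }
  feats <- feature_names()
  out$night_present <- rowSums(!is.na(out[, feats, drop = FALSE])) > 0
  out <- out[order(out$subject_id, out$night_date),
             c("subject_id", "night_date", "night_present", feats)]
  rownames(out) <- NULL
  out
}

#' Is a window's missing-night pattern acceptable?
#'
#' @param present logical vector of length `L`: is each night present?
#' @param L window length (1, 3, 7, 14 or 21 nights).
#' @return `TRUE` iff the total number of missing nights is within the
#'   length-specific cap and, for `L >= 7`, every aligned 7-night block has
#'   at most 2 missing nights.
#' @export
valid_window <- function(present, L) {
  L <- as.integer(L)
  if (length(present) != L) stop("mask length must equal L")
  miss <- !present
  if (sum(miss) > missing_cap(L)) {
    return(FALSE)
  }
  if (L >= 7L) {
    for (b in seq_len(L %/% 7L)) {
      block <- miss[(7L * (b - 1L) + 1L):(7L * b)]
      if (sum(block) > 2L) {
        return(FALSE)
      }
    }
  }
  TRUE
}

#' Start dates of valid 21-night windows per subject
#'
#' @param nightly output of [build_nightly_table()].
#' @return data.frame `subject_id`, `start_date`.
#' @export
anchor_starts <- function(nightly) {
  out <- lapply(split(nightly, nightly$subject_id), function(d) {
    d <- d[order(d$night_date), ]
    n <- nrow(d)
    if (n < 21L) {
      return(NULL)
    }
    ok <- vapply(seq_len(n - 20L), function(i) {
      valid_window(d$night_present[i:(i + 20L)], 21L)
    }, logical(1))
    if (!any(ok)) {
      return(NULL)
    }
    data.frame(
      subject_id = d$subject_id[1],
      start_date = d$night_date[which(ok)]
    )
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(subject_id = character(0), start_date = as.Date(character(0)))
  }
  rownames(out) <- NULL
  out
}

#' Extract rolling window samples of length L at the 21-night anchors
#'
#' One candidate window per (subject, anchor start date); the candidate is
#' kept when it passes [valid_window()] for its own length. Features are
#' flattened night-major: night 1's 36 features, then night 2's, with
#' column names `<feature>__n<night>`. Missing nights stay `NA` until the
#' model-stage zero-fill.
#'
#' @param nightly output of [build_nightly_table()].
#' @param subjects subject table carrying `subject_id` and `label`.
#' @param L window length.
#' @param anchors data.frame from [anchor_starts()]; computed from
#'   `nightly` when `NULL`.
#' @return data.frame with `subject_id`, `start_date`, `label` and
#'   `L * 36` feature columns.
#' @export
extract_windows <- function(nightly, subjects, L, anchors = NULL) {
  L <- as.integer(L)
  missing_cap(L) # validates L
  if (is.null(anchors)) anchors <- anchor_starts(nightly)
  feats <- feature_names()
  col_names <- as.vector(vapply(
    seq_len(L), function(k) paste0(feats, "__n", k), character(length(feats))
  ))
  label_of <- stats::setNames(subjects$label, subjects$subject_id)

  blocks <- lapply(split(nightly, nightly$subject_id), function(d) {
    subj <- d$subject_id[1]
    starts <- anchors$start_date[anchors$subject_id == subj]
    if (length(starts) == 0) {
      return(NULL)
    }
    d <- d[order(d$night_date), ]
    date_index <- stats::setNames(seq_len(nrow(d)), as.character(d$night_date))
    fm <- as.matrix(d[, feats, drop = FALSE])
    rows <- lapply(starts, function(s) {
      i <- date_index[[as.character(s)]]
      if (is.null(i) || i + L - 1L > nrow(d)) {
        return(NULL)
      }
      span <- i:(i + L - 1L)
      if (!valid_window(d$night_present[span], L)) {
        return(NULL)
      }
      c(t(fm[span, , drop = FALSE]))
    })
    keep <- !vapply(rows, is.null, logical(1))
    if (!any(keep)) {
      return(NULL)
    }
    mat <- do.call(rbind, rows[keep])
    colnames(mat) <- col_names
    cbind(
      data.frame(
        subject_id = subj, start_date = starts[keep],
        label = unname(label_of[subj])
      ),
      as.data.frame(mat)
    )
  })
  out <- do.call(rbind, blocks)
  if (is.null(out)) {
    out <- cbind(
      data.frame(
        subject_id = character(0), start_date = as.Date(character(0)),
        label = integer(0)
      ),
      stats::setNames(as.data.frame(matrix(numeric(0), 0, length(col_names))), col_names)
    )
  }
  rownames(out) <- NULL
  out
}

#' Subject-disjoint stratified train/test split
#'
#' Splits subjects within each (label, age bin) stratum so per-stratum
#' train proportions stay within one subject of the global fraction.
#' Deterministic given `seed`; a singleton stratum goes to train with a
#' warning.
#'
#' @param subjects subject table with `subject_id`, `label`, `age_bin`.
#' @param train_fraction fraction of subjects assigned to train.
#' @param seed integer seed.
#' @return list with `train_ids` and `test_ids`.
#' @export
stratified_split <- function(subjects, train_fraction = 0.8, seed = 1) {
  with_preserved_seed(seed, {
    strata <- split(subjects$subject_id,
                    paste(subjects$label, subjects$age_bin, sep = "/"))
    train <- character(0)
    test <- character(0)
    for (ids in strata) {
      n <- length(ids)
      if (n == 1) {
        warning("stratum with a single subject assigned to train")
        train <- c(train, ids)
        next
      }
      n_train <- round(train_fraction * n)
      n_train <- min(max(n_train, 1L), n - 1L)
      picked <- sample(ids, n_train)
      train <- c(train, picked)
      test <- c(test, setdiff(ids, picked))
    }
    list(train_ids = sort(train), test_ids = sort(test))
  })
}

#' Age/sex-balanced class-matched subsample
#'
#' Within every (age bin, sex) cell, samples an equal number of subjects
#' from each class (at most the size of the smaller class in the cell),
#' allocating the per-class target across cells by largest remainder.
#'
#' @param subjects subject table with `subject_id`, `label`, `age_bin`, `sex`.
#' @param n_per_class desired subjects per class; shrunk with a warning if
#'   the strata cannot support it.
#' @param seed integer seed.
#' @return subject table restricted to the balanced cohort.
#' @export
stratified_class_sample <- function(subjects, n_per_class, seed = 1) {
  with_preserved_seed(seed, {
    cell <- paste(subjects$age_bin, subjects$sex, sep = "/")
    cells <- unique(cell)
    cap <- vapply(cells, function(cl) {
      min(
        sum(subjects$label == 1L & cell == cl),
        sum(subjects$label == 0L & cell == cl)
      )
    }, numeric(1))
    total <- sum(cap)
    target <- n_per_class
    if (total < target) {
      warning(sprintf(
        "strata support only %d subjects per class (requested %d)", total, target
      ))
      target <- total
    }
    take <- largest_remainder(cap, target)
    take <- pmin(take, cap)
    ids <- character(0)
    for (k in seq_along(cells)) {
      if (take[k] == 0) next
      for (lab in c(0L, 1L)) {
        pool <- subjects$subject_id[subjects$label == lab & cell == cells[k]]
        ids <- c(ids, sample(pool, take[k]))
      }
    }
    subjects[subjects$subject_id %in% ids, ]
  })
}
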