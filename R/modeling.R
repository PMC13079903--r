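# Classifier training on windowed features: standardization fitted on the
# observed training cells, zero-fill of missing cells (zero = the
# post-scaling train mean), then either L2-regularized logistic regression
# or gradient-boosted trees with the tuned hyperparameters.

#' Specify a window classifier
#'
#' Defaults are the tuned values used for every window length: trees with
#' 200 estimators, learning rate 0.01, max depth 3; logistic regression
#' with inverse-regularization C = 0.01 and an L2 penalty.
#'
#' @param family `"trees"` (gradient boosting) or `"linear"` (regularized
#'   logistic regression).
#' @param window_length nights per window (metadata; used by importance
#'   aggregation).
#' @param n_estimators,learning_rate,max_depth tree hyperparameters.
#' @param C,penalty linear hyperparameters (only `"l2"` is supported).
#' @return a `wd_model_spec`.
#' @export
model_spec <- function(family = c("trees", "linear"), window_length = 21L,
                       n_estimators = 200L, learning_rate = 0.01,
                       max_depth = 3L, C = 0.01, penalty = "l2") {
  family <- match.arg(family)
  if (penalty != "l2") stop("only the l2 penalty is supported")
  spec <- list(
    family = family, window_length = as.integer(window_length),
    n_estimators = as.integer(n_estimators), learning_rate = learning_rate,
    max_depth = as.integer(max_depth), C = C, penalty = penalty
  )
  class(spec) <- "wd_model_spec"
  spec
}

# Rough model-capacity ordering used only to break ties in tuning.
spec_capacity <- function(spec) {
  if (spec$family == "trees") {
    spec$n_estimators * 2^spec$max_depth
  } else {
    1 / spec$C
  }
}

#' Columns of a window table that are features
#' @param windows a window data.frame from [extract_windows()].
#' @return character vector of feature column names.
#' @export
window_feature_columns <- function(windows) {
  setdiff(names(windows), c("subject_id", "start_date", "label"))
}

window_matrix <- function(windows) {
  as.matrix(windows[, window_feature_columns(windows), drop = FALSE])
}

#' Fit a standardization scaler on training windows
#'
#' Per-column location (mean) and scale (SD) over observed cells only.
#' Columns with no observed cells, or zero spread, get location 0 / scale 1
#' (with a warning for all-missing columns), so transformed cells stay
#' finite and zero-filled cells sit at the train mean.
#'
#' @param X numeric matrix (rows = windows), `NA` = missing cell.
#' @return a `wd_scaler` with `center` and `scale` vectors.
#' @export
fit_scaler <- function(X) {
  center <- colMeans(X, na.rm = TRUE)
  scale <- apply(X, 2, stats::sd, na.rm = TRUE)
  all_missing <- !is.finite(center)
  if (any(all_missing)) {
    warning(sprintf("%d all-missing column(s); scaled to 0", sum(all_missing)))
    center[all_missing] <- 0
  }
  scale[!is.finite(scale) | scale == 0] <- 1
  structure(list(center = center, scale = scale), class = "wd_scaler")
}

#' Standardize and zero-fill a window matrix
#'
#' @param X numeric matrix with the scaler's columns.
#' @param scaler a `wd_scaler`.
#' @param zero_fill replace missing cells by 0 (the train mean) after
#'   scaling.
#' @return dense numeric matrix.
#' @export
apply_scaler <- function(X, scaler, zero_fill = TRUE) {
  Z <- sweep(sweep(X, 2, scaler$center), 2, scaler$scale, "/")
  if (zero_fill) Z[is.na(Z)] <- 0
  Z
}

#' Train a classifier on a prepared (scaled, dense) matrix
#'
#' @param spec a [model_spec()].
#' @param X dense numeric matrix.
#' @param y 0/1 labels; both classes must be present.
#' @param seed integer seed for the tree learner.
#' @return a `wd_model` emitting `P(label = 1)` via [predict_scores()].
#' @export
train_model <- function(spec, X, y, seed = 1) {
  if (length(unique(y)) < 2) stop("training data contains a single class")
  fit <- if (spec$family == "trees") {
    with_preserved_seed(seed, {
      xgboost::xgb.train(
        params = list(
          objective = "binary:logistic",
          eta = spec$learning_rate,
          max_depth = spec$max_depth,
          nthread = 1
        ),
        data = xgboost::xgb.DMatrix(X, label = y),
        nrounds = spec$n_estimators,
        verbose = 0
      )
    })
  } else {
    # sklearn-style C: minimize sum(loss) + |w|^2 / (2C)  <=>
    # glmnet ridge with lambda = 1 / (n * C)
    glmnet::glmnet(
      X, y,
      family = "binomial", alpha = 0,
      lambda = 1 / (nrow(X) * spec$C), standardize = FALSE
    )
  }
  structure(
    list(spec = spec, fit = fit, feature_names = colnames(X)),
    class = "wd_model"
  )
}

#' Fit scaler + classifier on a window table
#'
#' @param spec a [model_spec()].
#' @param windows training window table ([extract_windows()] output).
#' @param seed integer seed.
#' @return a `wd_model` carrying its scaler.
#' @export
fit_window_model <- function(spec, windows, seed = 1) {
  X <- window_matrix(windows)
  scaler <- fit_scaler(X)
  model <- train_model(spec, apply_scaler(X, scaler), windows$label, seed = seed)
  model$scaler <- scaler
  model
}

#' Predicted probabilities of the positive class
#'
#' @param model a `wd_model`.
#' @param windows window table or numeric matrix. Window tables are scaled
#'   with the model's own (train-fitted) scaler.
#' @return numeric vector of `P(label = 1)`.
#' @export
predict_scores <- function(model, windows) {
  X <- if (is.matrix(windows)) windows else window_matrix(windows)
  if (!is.null(model$scaler)) X <- apply_scaler(X, model$scaler)
  if (model$spec$family == "trees") {
    as.numeric(stats::predict(model$fit, xgboost::xgb.DMatrix(X)))
  } else {
    as.numeric(stats::predict(model$fit, X, type = "response"))
  }
}

#' Hyperparameter selection by subject-grouped cross-validation
#'
#' Folds are grouped by subject (no subject appears in two folds; windows
#' from one subject overlap heavily, so ungrouped folds would leak).
#' Selection is by mean validation AUROC; ties go to the
#' smallest-capacity spec.
#'
#' @param grid list of [model_spec()]s.
#' @param windows training window table.
#' @param k number of folds.
#' @param seed integer seed (fold assignment and tree training).
#' @return list with `best` (the winning spec), and `cv` (per-spec mean
#'   AUROC).
#' @export
tune_hyperparameters <- function(grid, windows, k = 3, seed = 1) {
  stopifnot(length(grid) >= 1)
  subjects <- unique(windows$subject_id)
  fold_of <- with_preserved_seed(seed, {
    stats::setNames(sample(rep_len(seq_len(k), length(subjects))), subjects)
  })
  folds <- fold_of[windows$subject_id]
  mean_auc <- vapply(grid, function(spec) {
    aucs <- vapply(seq_len(k), function(f) {
      tr <- windows[folds != f, , drop = FALSE]
      va <- windows[folds == f, , drop = FALSE]
      if (length(unique(tr$label)) < 2 || length(unique(va$label)) < 2) {
        return(NA_real_)
      }
      m <- fit_window_model(spec, tr, seed = seed)
      roc_prc(predict_scores(m, va), va$label)$auroc
    }, numeric(1))
    mean(aucs, na.rm = TRUE)
  }, numeric(1))
  best_auc <- max(mean_auc)
  contenders <- which(mean_auc >= best_auc - 1e-12)
  caps <- vapply(grid[contenders], spec_capacity, numeric(1))
  best <- grid[[contenders[which.min(caps)]]]
  list(best = best, cv = mean_auc)
}
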