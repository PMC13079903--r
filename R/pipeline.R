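# End-to-end orchestration: simulate -> extract -> window -> train ->
# evaluate (-> ablate -> chronic-condition report), with one root seed,
# validated configuration, and a config hash stamped into every artifact.

pipeline_config_fields <- function() {
  c(
    "generator", "window_lengths", "families", "train_fraction",
    "tune", "protocols", "imbalanced", "seed"
  )
}

#' Build and validate a pipeline run configuration
#'
#' @param generator a [generator_config()] (or a list of its arguments).
#' @param window_lengths subset of 1/3/7/14/21.
#' @param families subset of `"linear"`, `"trees"`.
#' @param train_fraction subject-level train fraction.
#' @param tune logical: run the subject-grouped 3-fold CV over a small grid
#'   before the final fit (off by default; the defaults are the tuned
#'   values).
#' @param protocols list of flags: `imbalanced`, `ablation`, `chronic`.
#' @param imbalanced parameters for [imbalanced_protocol()] (`prevalence`,
#'   `reps`, `windows_per_subject`).
#' @param seed root seed for splitting/training/evaluation.
#' @return a validated `wd_pipeline_config`.
#' @export
pipeline_config <- function(generator = generator_config(),
                            window_lengths = c(1, 3, 7, 14, 21),
                            families = c("linear", "trees"),
                            train_fraction = 0.8,
                            tune = FALSE,
                            protocols = list(imbalanced = FALSE,
                                             ablation = FALSE,
                                             chronic = FALSE),
                            imbalanced = list(prevalence = 0.179, reps = 100,
                                              windows_per_subject = 10),
                            seed = 1) {
  if (is.list(generator) && !inherits(generator, "wd_generator_config")) {
    generator <- do.call(generator_config, generator)
  }
  cfg <- list(
    generator = generator,
    window_lengths = as.integer(window_lengths),
    families = families, train_fraction = train_fraction,
    tune = isTRUE(tune),
    protocols = utils::modifyList(
      list(imbalanced = FALSE, ablation = FALSE, chronic = FALSE), protocols
    ),
    imbalanced = utils::modifyList(
      list(prevalence = 0.179, reps = 100, windows_per_subject = 10), imbalanced
    ),
    seed = as.integer(seed)
  )
  if (!all(cfg$window_lengths %in% WINDOW_LENGTHS)) {
    config_error("window_lengths must be a subset of 1, 3, 7, 14, 21")
  }
  if (!all(cfg$families %in% c("linear", "trees"))) {
    config_error("families must be a subset of 'linear', 'trees'")
  }
  if (cfg$train_fraction <= 0 || cfg$train_fraction >= 1) {
    config_error("train_fraction must lie in (0, 1)")
  }
  class(cfg) <- "wd_pipeline_config"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' Unknown keys (at the top level or inside `generator`) are rejected so a
#' typo cannot silently fall back to a default.
#'
#' @param path YAML file whose keys mirror [pipeline_config()] arguments.
#' @return a `wd_pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  unknown <- setdiff(names(raw), pipeline_config_fields())
  if (length(unknown) > 0) {
    config_error(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")))
  }
  if (!is.null(raw$generator)) {
    gen_unknown <- setdiff(names(raw$generator), names(formals(generator_config)))
    if (length(gen_unknown) > 0) {
      config_error(sprintf(
        "unknown generator key(s): %s", paste(gen_unknown, collapse = ", ")
      ))
    }
  }
  do.call(pipeline_config, raw)
}

#' Hash of a configuration (provenance stamp)
#'
#' @param config any serializable object.
#' @return md5 hex string.
#' @export
config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(config, f, version = 2)
  unname(tools::md5sum(f))
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' simulate -> extract sleep and temperature features -> nightly table ->
#' subject-disjoint stratified split -> per (window length, family):
#' window extraction at the shared 21-night anchors, training, held-out
#' evaluation; optionally the imbalanced-cohort protocol, the feature-set
#' ablation, and the chronic-condition analysis for the best model.
#'
#' @param config a [pipeline_config()].
#' @param out_dir if non-`NULL`, artifacts are written there (`metrics.json`,
#'   `curves.csv`, per-length window CSVs, split manifest).
#' @return list with `metrics` (per length x family), `models`, `split`,
#'   `counts` (row reconciliation per stage), `config_hash`, and the
#'   optional protocol results.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "wd_pipeline_config"))
  hash <- config_hash(config)
  t0 <- Sys.time()
  log_stage <- function(stage, ...) {
    message(sprintf("[%5.1fs] %s %s", as.numeric(Sys.time() - t0, units = "secs"),
                    stage, paste(..., collapse = " ")))
  }

  cohort <- simulate_cohort(config$generator)
  log_stage("simulate:", nrow(cohort$subjects), "subjects,",
            sum(cohort$nights$present), "present nights")

  sf <- sleep_features(cohort)
  tf <- temperature_features(cohort)
  nightly <- build_nightly_table(sf, tf, cohort$nights)
  log_stage("extract:", sum(nightly$night_present), "feature nights")

  split <- stratified_split(cohort$subjects, config$train_fraction, config$seed)
  stopifnot(length(intersect(split$train_ids, split$test_ids)) == 0)
  anchors <- anchor_starts(nightly)

  counts <- list(
    subjects = nrow(cohort$subjects),
    nights_total = nrow(cohort$nights),
    nights_present = sum(cohort$nights$present),
    nights_with_features = sum(nightly$night_present),
    nights_dropped = nrow(cohort$nights) - sum(nightly$night_present),
    anchors = nrow(anchors),
    train_subjects = length(split$train_ids),
    test_subjects = length(split$test_ids)
  )

  metrics <- list()
  models <- list()
  windows_by_length <- list()
  for (L in config$window_lengths) {
    win <- extract_windows(nightly, cohort$subjects, L, anchors)
    windows_by_length[[as.character(L)]] <- win
    tr <- win[win$subject_id %in% split$train_ids, ]
    te <- win[win$subject_id %in% split$test_ids, ]
    for (fam in config$families) {
      spec <- model_spec(fam, window_length = L)
      if (config$tune) {
        grid <- if (fam == "trees") {
          list(
            model_spec("trees", L, n_estimators = 100, max_depth = 2),
            spec,
            model_spec("trees", L, n_estimators = 400, max_depth = 5)
          )
        } else {
          list(
            model_spec("linear", L, C = 0.001), spec,
            model_spec("linear", L, C = 1)
          )
        }
        spec <- tune_hyperparameters(grid, tr, k = 3, seed = config$seed)$best
      }
      model <- fit_window_model(spec, tr, seed = config$seed)
      ev <- evaluate_model(model, te)
      key <- sprintf("L%d_%s", L, fam)
      models[[key]] <- model
      metrics[[key]] <- list(
        window_length = L, family = fam,
        auroc = ev$auroc, auprc = ev$auprc,
        youden_threshold = ev$youden$threshold,
        confusion = ev$confusion,
        n_train_windows = nrow(tr), n_test_windows = nrow(te),
        eval = ev
      )
      log_stage("model:", key, sprintf("AUROC %.3f AUPRC %.3f", ev$auroc, ev$auprc))
    }
  }

  best_key <- names(metrics)[which.max(vapply(metrics, `[[`, numeric(1), "auroc"))]
  result <- list(
    metrics = metrics, models = models, split = split, counts = counts,
    best_model = best_key, config_hash = hash, seed = config$seed,
    nightly = nightly, subjects = cohort$subjects,
    windows = windows_by_length
  )

  best_ev <- metrics[[best_key]]$eval
  test_subjects <- cohort$subjects[cohort$subjects$subject_id %in% split$test_ids, ]
  if (isTRUE(config$protocols$imbalanced)) {
    result$imbalanced <- imbalanced_protocol(
      best_ev$scores, test_subjects,
      prevalence = config$imbalanced$prevalence,
      reps = config$imbalanced$reps,
      windows_per_subject = config$imbalanced$windows_per_subject,
      seed = config$seed
    )
    log_stage("imbalanced:", sprintf("median AUROC %.3f", result$imbalanced$auroc_median))
  }
  if (isTRUE(config$protocols$ablation)) {
    L <- metrics[[best_key]]$window_length
    fam <- metrics[[best_key]]$family
    win <- windows_by_length[[as.character(L)]]
    result$ablation <- ablation_sweep(
      win[win$subject_id %in% split$train_ids, ],
      win[win$subject_id %in% split$test_ids, ],
      model_spec(fam, window_length = L),
      seed = config$seed
    )
    log_stage("ablation: done")
  }
  if (isTRUE(config$protocols$chronic)) {
    result$chronic <- chronic_condition_analysis(best_ev$scores, test_subjects)
    log_stage("chronic: done")
  }

  if (!is.null(out_dir)) {
    write_pipeline_artifacts(result, out_dir)
  }
  result
}

write_pipeline_artifacts <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  scalar_metrics <- lapply(result$metrics, function(m) {
    m$eval <- NULL
    m
  })
  jsonlite::write_json(
    list(
      config_hash = result$config_hash, seed = result$seed,
      counts = result$counts, best_model = result$best_model,
      metrics = scalar_metrics
    ),
    file.path(out_dir, "metrics.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  curves <- do.call(rbind, lapply(names(result$metrics), function(key) {
    ev <- result$metrics[[key]]$eval
    rbind(
      data.frame(model = key, curve = "roc", x = ev$roc$fpr, y = ev$roc$tpr),
      data.frame(model = key, curve = "prc", x = ev$prc$recall, y = ev$prc$precision)
    )
  }))
  utils::write.csv(curves, file.path(out_dir, "curves.csv"), row.names = FALSE)
  manifest <- list(
    config_hash = result$config_hash, seed = result$seed,
    train_ids = result$split$train_ids, test_ids = result$split$test_ids
  )
  jsonlite::write_json(manifest, file.path(out_dir, "split_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  for (L in names(result$windows)) {
    utils::write.csv(
      result$windows[[L]],
      file.path(out_dir, sprintf("windows_L%s.csv", L)),
      row.names = FALSE, na = ""
    )
  }
  invisible(out_dir)
}
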