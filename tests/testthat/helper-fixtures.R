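# Shared fixtures: hand-traced hypnograms with their expected windows, and
# a small cached cohort so expensive pipeline-level tests simulate once.

hyp <- function(...) {
  parts <- list(...)
  unlist(lapply(parts, function(p) rep(p[[1]], p[[2]])))
}
S <- function(n) list("L", n)
W <- function(n) list("W", n)

# Each case: hypnogram + the windows expected under the default
# (merge-below-60-min) rule, traced by hand. Epoch indices 0-based,
# half-open; 1 epoch = 30 s.
hand_traced_hypnograms <- function() {
  list(
    list( # uninterrupted 7 h
      h = hyp(S(840)),
      windows = data.frame(start = 0, end = 840, kind = "long",
                           sleep = 840, wake = 0)
    ),
    list( # 5-min embedded wake: still one long window
      h = hyp(S(100), W(10), S(730)),
      windows = data.frame(start = 0, end = 840, kind = "long",
                           sleep = 830, wake = 10)
    ),
    list( # 2-h gap splits into a long and a detached short window
      h = hyp(S(840), W(240), S(120)),
      windows = data.frame(start = c(0, 1080), end = c(840, 1200),
                           kind = c("long", "short"),
                           sleep = c(840, 120), wake = c(0, 0))
    ),
    list( # all wake
      h = hyp(W(100)),
      windows = data.frame(start = numeric(0), end = numeric(0),
                           kind = character(0), sleep = numeric(0),
                           wake = numeric(0))
    ),
    list( # edges excluded; 5-h span is neither long nor short
      h = hyp(W(60), S(600), W(40)),
      windows = data.frame(start = 60, end = 660, kind = "other",
                           sleep = 600, wake = 0)
    ),
    list( # 2.5 h nap
      h = hyp(S(300)),
      windows = data.frame(start = 0, end = 300, kind = "short",
                           sleep = 300, wake = 0)
    ),
    list( # 59.5-min gap merges: one 5-h window carrying the gap as wake
      h = hyp(S(240), W(119), S(240)),
      windows = data.frame(start = 0, end = 599, kind = "other",
                           sleep = 480, wake = 119)
    ),
    list( # exactly 60 min separates: two short windows
      h = hyp(S(240), W(120), S(240)),
      windows = data.frame(start = c(0, 360), end = c(240, 600),
                           kind = c("short", "short"),
                           sleep = c(240, 240), wake = c(0, 0))
    ),
    list( # leading/trailing wake plus a 65-min detachment gap
      h = hyp(W(100), S(840), W(130), S(120), W(50)),
      windows = data.frame(start = c(100, 1070), end = c(940, 1190),
                           kind = c("long", "short"),
                           sleep = c(840, 120), wake = c(0, 0))
    ),
    list( # 12.5-min gap: merged by default (split under strict mode)
      h = hyp(S(30), W(25), S(30)),
      windows = data.frame(start = 0, end = 85, kind = "short",
                           sleep = 60, wake = 25)
    )
  )
}

# Simulated night fragments for complexity comparisons etc.
random_hypnogram <- function(n_epochs = 900, p_wake = 0.08) {
  stages <- sample(c("W", "L", "D", "R"), n_epochs, TRUE,
                   prob = c(p_wake, (1 - p_wake) * c(0.5, 0.25, 0.25)))
  stages
}

# Cached small cohort + features + windows, shared by modeling-level tests.
.fixture_cache <- new.env(parent = emptyenv())

fixture_cohort <- function() {
  if (is.null(.fixture_cache$cohort)) {
    cfg <- generator_config(
      n_dm = 20, n_control = 20, n_nights = 50,
      other_condition_rate = 0.35, rng_seed = 424242
    )
    co <- simulate_cohort(cfg)
    nt <- build_nightly_table(sleep_features(co), temperature_features(co), co$nights)
    .fixture_cache$cohort <- list(
      cohort = co, nightly = nt, anchors = anchor_starts(nt),
      split = suppressWarnings(stratified_split(co$subjects, 0.8, seed = 99))
    )
  }
  .fixture_cache$cohort
}

# Window tables with a planted signal: `signal_features` differ between
# classes by `effect` SDs, everything else is noise. One night per window.
planted_windows <- function(n_per_class, signal_features, effect = 2,
                            seed = 1, n_subjects_per_class = NULL) {
  set.seed(seed)
  feats <- feature_names()
  n <- 2 * n_per_class
  X <- matrix(rnorm(n * length(feats)), n, length(feats),
              dimnames = list(NULL, paste0(feats, "__n1")))
  label <- rep(c(1L, 0L), each = n_per_class)
  for (f in signal_features) {
    X[, paste0(f, "__n1")] <- X[, paste0(f, "__n1")] + effect * label
  }
  if (is.null(n_subjects_per_class)) n_subjects_per_class <- n_per_class
  subj_pool <- c(
    sprintf("P%03d", seq_len(n_subjects_per_class)),
    sprintf("C%03d", seq_len(n_subjects_per_class))
  )
  subject_id <- c(
    sample(subj_pool[seq_len(n_subjects_per_class)], n_per_class, TRUE),
    sample(subj_pool[-seq_len(n_subjects_per_class)], n_per_class, TRUE)
  )
  cbind(
    data.frame(
      subject_id = subject_id,
      start_date = as.Date("2020-04-22") + seq_len(n) - 1,
      label = label
    ),
    as.data.frame(X)
  )
}
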