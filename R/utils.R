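#' @keywords internal
"_PACKAGE"

# Clock arithmetic on a 24-h dial. Onsets are fractional clock hours
# (hour + minute/60), so durations must be taken circularly: a night from
# 23.5 to 7.5 lasts 8 h, not -16 h.

#' Circular difference between two clock hours
#'
#' @param to,from clock hours in `[0, 24)`.
#' @return `(to - from) mod 24`, in hours.
#' @export
circular_diff <- function(to, from) {
  (to - from) %% 24
}

#' Circular midpoint of a sleep episode
#'
#' @param sleep_onset,wake_onset clock hours.
#' @return the clock hour halfway through the episode, moving forward from
#'   `sleep_onset`.
#' @export
circular_midpoint <- function(sleep_onset, wake_onset) {
  (sleep_onset + circular_diff(wake_onset, sleep_onset) / 2) %% 24
}

# Truncated-normal sampler via inverse CDF; used for all scalar nightly
# summaries (reported moments are mean/SD only, and HR/RMSSD/TST/amplitude
# must stay positive).
rtruncnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  u <- stats::runif(n, plo, phi)
  stats::qnorm(u, mean, sd)
}

# Largest-remainder (Hamilton) integer allocation of `total` over weights.
largest_remainder <- function(weights, total) {
  if (total == 0 || sum(weights) == 0) {
    return(integer(length(weights)))
  }
  quota <- weights / sum(weights) * total
  base <- floor(quota)
  rem <- total - sum(base)
  if (rem > 0) {
    take <- order(quota - base, decreasing = TRUE)[seq_len(rem)]
    base[take] <- base[take] + 1
  }
  as.integer(base)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards so library calls do not perturb user code.
with_preserved_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  force(expr)
}

config_error <- function(msg) {
  stop(structure(
    class = c("wd_config_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

night_key <- function(subject_id, night_date) {
  paste(subject_id, as.character(night_date), sep = "|")
}
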