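# Independent brute-force oracles: explicit loops, no shared code with the
# package implementations they check.

ci_oracle <- function(x) {
  n <- length(x)
  if (n < 2) return(NA_real_)
  mu <- 0
  for (v in x) mu <- mu + v
  mu <- mu / n
  ss <- 0
  for (v in x) ss <- ss + (v - mu)^2
  sd_pop <- sqrt(ss / n)
  if (sd_pop == 0) return(0)
  acc <- 0
  for (i in 1:(n - 1)) {
    zi <- (x[i] - mu) / sd_pop
    zj <- (x[i + 1] - mu) / sd_pop
    acc <- acc + (zj - zi)^2
  }
  sqrt(acc) / n
}

coarse_grain_oracle <- function(x, s) {
  w <- 2^s
  n_out <- length(x) %/% w
  out <- numeric(n_out)
  for (i in seq_len(n_out)) {
    acc <- 0
    for (j in 1:w) acc <- acc + x[(i - 1) * w + j]
    out[i] <- acc / w
  }
  out
}

# AUROC as the probability a random positive outscores a random negative
# (ties count half): the Mann-Whitney construction, all pairs enumerated.
auroc_oracle <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  acc <- 0
  for (p in pos) {
    for (q in neg) {
      if (p > q) acc <- acc + 1 else if (p == q) acc <- acc + 0.5
    }
  }
  acc / (length(pos) * length(neg))
}

# All-threshold precision/recall sweep with explicit counting.
auprc_oracle <- function(scores, labels) {
  ths <- sort(unique(scores), decreasing = TRUE)
  prev_recall <- 0
  area <- 0
  P <- sum(labels == 1)
  for (t in ths) {
    tp <- sum(scores >= t & labels == 1)
    fp <- sum(scores >= t & labels == 0)
    recall <- tp / P
    precision <- tp / (tp + fp)
    area <- area + (recall - prev_recall) * precision
    prev_recall <- recall
  }
  area
}

mann_whitney_u_oracle <- function(x, y) {
  u <- 0
  for (a in x) {
    for (b in y) {
      if (a > b) u <- u + 1 else if (a == b) u <- u + 0.5
    }
  }
  u
}

# Dunn's pairwise rank-sum z after Kruskal-Wallis, tie-corrected, written
# from the textbook formula with explicit rank bookkeeping.
dunn_oracle <- function(x, g) {
  g <- as.character(g)
  r <- rank(x)
  N <- length(x)
  tie_sum <- 0
  for (v in unique(x)) {
    t <- sum(x == v)
    tie_sum <- tie_sum + (t^3 - t)
  }
  correction <- tie_sum / (12 * (N - 1))
  lv <- sort(unique(g))
  out <- NULL
  for (i in seq_along(lv)) {
    for (j in seq_along(lv)) {
      if (j <= i) next
      ri <- mean(r[g == lv[i]])
      rj <- mean(r[g == lv[j]])
      ni <- sum(g == lv[i])
      nj <- sum(g == lv[j])
      se <- sqrt((N * (N + 1) / 12 - correction) * (1 / ni + 1 / nj))
      z <- (ri - rj) / se
      out <- rbind(out, data.frame(
        comparison = paste(lv[i], lv[j], sep = " - "),
        z = z, p = 2 * stats::pnorm(-abs(z))
      ))
    }
  }
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out
}
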