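# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's vectorized/closed-form code paths.

# random dataset with a mixed tie structure: scores rounded to 1 decimal so
# ties are frequent; both classes guaranteed present
random_dataset <- function(n, rounded = TRUE, signal = 1) {
  label <- rbinom(n, 1, 0.5)
  while (sum(label) == 0L || sum(label) == n) label <- rbinom(n, 1, 0.5)
  score <- rnorm(n) + signal * label
  if (rounded) score <- round(score, 1)
  labeled_scores(score, label, positive = 1)
}

# per-instance tally at one threshold under the score >= t rule
brute_confusion <- function(score, label, t) {
  tp <- fp <- fn <- tn <- 0L
  for (i in seq_along(score)) {
    pred <- score[i] >= t
    if (pred && label[i]) tp <- tp + 1L
    else if (pred && !label[i]) fp <- fp + 1L
    else if (!pred && label[i]) fn <- fn + 1L
    else tn <- tn + 1L
  }
  c(TP = tp, FP = fp, FN = fn, TN = tn)
}

# ROC vertex set by brute force: one vertex per distinct score + (0,0)
brute_roc <- function(score, label) {
  thr <- sort(unique(score), decreasing = TRUE)
  verts <- t(vapply(thr, function(t) {
    cc <- brute_confusion(score, label, t)
    c(FPR = unname(cc["FP"] / (cc["FP"] + cc["TN"])),
      TPR = unname(cc["TP"] / (cc["TP"] + cc["FN"])))
  }, c(FPR = 0, TPR = 0)))
  rbind(c(FPR = 0, TPR = 0), verts)
}

# maximum of min(TPR, 1 - FPR) over the interpolated polyline: per-segment
# dense grid search, iteratively refined (4 rounds of 1001 points bring the
# final spacing to ~8e-12, so the sampled max is within ~1e-11 of the true
# piecewise-linear peak); segments whose upper bound cannot beat the current
# best are pruned
polyline_maximin <- function(fpr, tpr) {
  best <- max(pmin(tpr, 1 - fpr))
  for (i in seq_len(length(fpr) - 1L)) {
    # min of two linear pieces: the segment max is bounded by each piece's max
    if (min(tpr[i + 1L], 1 - fpr[i]) <= best) next
    lo <- 0; hi <- 1
    for (round in 1:4) {
      s <- seq(lo, hi, length.out = 1001L)
      v <- pmin((1 - s) * tpr[i] + s * tpr[i + 1L],
                1 - ((1 - s) * fpr[i] + s * fpr[i + 1L]))
      k <- which.max(v)
      best <- max(best, v[k])
      step <- (hi - lo) / 1000
      new_lo <- max(lo, s[k] - step)
      hi <- min(hi, s[k] + step)
      lo <- new_lo
    }
  }
  best
}

# coarse uniform sampling of the polyline (lower bound on the maximum)
polyline_maximin_sampled <- function(fpr, tpr, n_pts = 1e4) {
  s <- seq(1, length(fpr), length.out = n_pts)
  f <- approx(seq_along(fpr), fpr, xout = s)$y
  t <- approx(seq_along(tpr), tpr, xout = s)$y
  max(pmin(t, 1 - f))
}
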