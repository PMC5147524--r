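toy <- labeled_scores(c(0.9, 0.7, 0.5, 0.6, 0.4, 0.2), c(1, 1, 1, 0, 0, 0))
toy_curve <- build_roc(toy)

test_that("toy curve's minimax point is the on-diagonal vertex, confirmed by enumeration", {
  p <- find_minimax_point(toy_curve)
  expect_equal(p$kind, "pure")
  expect_equal(p$FPR, 1/3)
  expect_equal(p$TPR, 2/3)
  expect_equal(p$threshold, 0.6)
  expect_equal(p$worst_case_utility, 2/3)
  # brute-force maximin over all 7 threshold intervals (the vertices) and
  # the interpolated segments between them
  expect_equal(p$worst_case_utility,
               polyline_maximin(toy_curve$FPR, toy_curve$TPR),
               tolerance = 1e-12)
})

test_that("separable data put the minimax point at the perfect corner", {
  d <- labeled_scores(c(5, 6, 7, 1, 2, 3), c(1, 1, 1, 0, 0, 0))
  p <- find_minimax_point(build_roc(d))
  expect_equal(c(p$FPR, p$TPR), c(0, 1))
  expect_equal(p$worst_case_utility, 1)
})

test_that("a bracketed diagonal crossing yields the hand-solved mixture", {
  curve <- roc_curve(c(Inf, 0.7, 0.3, -Inf),
                     FPR = c(0, 0.2, 0.5, 1), TPR = c(0, 0.6, 0.9, 1))
  p <- find_minimax_point(curve)
  expect_equal(p$kind, "mixed")
  expect_equal(p$weight, 2/3)         # on the first (higher-threshold) vertex
  expect_equal(p$t_hi, 0.7)
  expect_equal(p$t_lo, 0.3)
  expect_equal(p$FPR, 0.3, tolerance = 1e-12)
  expect_equal(p$TPR, 0.7, tolerance = 1e-12)
  # independent line-segment / diagonal intersection oracle
  seg_cross <- uniroot(function(s) {
    f <- (1 - s) * 0.2 + s * 0.5
    t <- (1 - s) * 0.6 + s * 0.9
    t + f - 1
  }, c(0, 1), tol = 1e-12)$root
  expect_equal(1 - p$weight, seg_cross, tolerance = 1e-9)
})

test_that("the returned minimax point always sits on the descending diagonal", {
  set.seed(303)
  for (i in 1:200) {
    d <- random_dataset(sample(4:60, 1), signal = runif(1, 0, 2))
    p <- find_minimax_point(build_roc(d, check_orientation = FALSE))
    expect_lt(abs(p$TPR + p$FPR - 1), 1e-12)
    expect_equal(p$worst_case_utility, 1 - p$FPR, tolerance = 1e-12)
  }
})

test_that("maximin vertex enumerates pure strategies with the documented tie-break", {
  p <- maximin_vertex(toy_curve)
  # three vertices tie at worst-case 2/3; the on-diagonal one wins
  u <- pmin(toy_curve$TPR, 1 - toy_curve$FPR)
  expect_equal(sum(u >= max(u) - 1e-9), 3L)  # 1 - 1/3 vs 2/3: last-bit ties
  expect_equal(c(p$FPR, p$TPR), c(1/3, 2/3))
  expect_equal(p$worst_case_utility, 2/3)

  # the random-classifier diagonal: the interpolated optimum (0.5, 0.5) has
  # worst case 0.5, but the only pure vertices are the endpoints, worst case 0
  diag_curve <- roc_curve(c(Inf, -Inf), FPR = c(0, 1), TPR = c(0, 1))
  pv <- maximin_vertex(diag_curve)
  expect_equal(pv$worst_case_utility, 0)
  pm <- find_minimax_point(diag_curve)
  expect_equal(pm$kind, "mixed")
  expect_equal(c(pm$FPR, pm$TPR), c(0.5, 0.5))
  expect_equal(pm$worst_case_utility, 0.5)

  sep <- build_roc(labeled_scores(c(5, 6, 1, 2), c(1, 1, 0, 0)))
  expect_equal(maximin_vertex(sep)$worst_case_utility, 1)
})

test_that("diagonal-segment degeneracy reduces to coincident vertices and is flagged", {
  # on a monotone curve a non-trivial diagonal segment would need
  # delta TPR = -delta FPR with both >= 0, i.e. both zero: the only
  # realizable degeneracy is two thresholds mapping to the same (FPR, TPR)
  curve <- roc_curve(c(Inf, 2, 1, -Inf),
                     FPR = c(0, 0.3, 0.3, 1), TPR = c(0, 0.7, 0.7, 1))
  p <- find_minimax_point(curve)
  expect_true(p$degenerate)
  expect_equal(p$kind, "mixed")
  expect_equal(c(p$FPR, p$TPR), c(0.3, 0.7))
  expect_equal(p$worst_case_utility, 0.7)
  # a single on-diagonal vertex next to an off-diagonal one stays pure
  curve2 <- roc_curve(c(Inf, 2, 1, -Inf),
                      FPR = c(0, 0.3, 0.6, 1), TPR = c(0, 0.7, 0.7, 1))
  p2 <- find_minimax_point(curve2)
  expect_equal(p2$kind, "pure")
  expect_false(p2$degenerate)
})

test_that("Youden point maximizes J with the documented tie-break", {
  sep <- build_roc(labeled_scores(c(5, 6, 1, 2), c(1, 1, 0, 0)))
  expect_equal(c(youden_point(sep)$FPR, youden_point(sep)$TPR), c(0, 1))
  # toy curve: J = 2/3 twice, at (0, 2/3) and (1/3, 1); neither is on the
  # diagonal, so the higher-TPR rule picks (1/3, 1)
  j <- toy_curve$TPR - toy_curve$FPR
  expect_equal(max(j), 2/3)
  expect_equal(sum(j >= max(j) - 1e-9), 2L)
  py <- youden_point(toy_curve)
  expect_equal(c(py$FPR, py$TPR), c(1/3, 1))
  # random classifier: J = 0 everywhere; tie-break gives the on-diagonal
  # interior ... the two-vertex diagonal has no on-diagonal vertex, so the
  # higher-TPR endpoint (1, 1) wins
  diag_curve <- roc_curve(c(Inf, -Inf), FPR = c(0, 1), TPR = c(0, 1))
  pd <- youden_point(diag_curve)
  expect_equal(pd$TPR, 1)
})

test_that("known-skew selection maximizes expected utility vertex-wise", {
  # balanced accuracy game: picks an accuracy-maximizing vertex
  p <- threshold_for_known_skew(toy_curve, 0.5)
  acc <- expected_utility(toy_curve$TPR, toy_curve$FPR, 0.5)
  expect_equal(expected_utility(p$TPR, p$FPR, 0.5), max(acc))
  # q_pos -> 1: TPR alone matters
  p1 <- threshold_for_known_skew(toy_curve, 1)
  expect_equal(p1$TPR, 1)
  # exhaustive oracle on random data at q_pos = 0.3: reweighted counts
  set.seed(55)
  for (i in 1:20) {
    d <- random_dataset(sample(8:40, 1))
    curve <- build_roc(d, check_orientation = FALSE)
    q <- 0.3
    pk <- threshold_for_known_skew(curve, q)
    u_all <- vapply(seq_len(nrow(curve)), function(j) {
      # reweight each threshold's counts to prevalence 0.3 and evaluate
      cc <- confusion_at_threshold(d, curve$threshold[j])
      n_p <- cc[["TP"]] + cc[["FN"]]; n_n <- cc[["FP"]] + cc[["TN"]]
      q * (cc[["TP"]] / n_p) + (1 - q) * (cc[["TN"]] / n_n)
    }, numeric(1))
    expect_equal(expected_utility(pk$TPR, pk$FPR, q), max(u_all),
                 tolerance = 1e-12)
  }
  expect_error(threshold_for_known_skew(toy_curve, 0.5, c(0, 1, 1, 0)),
               "degenerate")
})

test_that("interpolated minimax dominates every vertex and rival criterion", {
  set.seed(77)
  for (i in 1:200) {
    d <- random_dataset(sample(4:60, 1), signal = runif(1, 0, 2))
    curve <- build_roc(d, check_orientation = FALSE)
    pm <- find_minimax_point(curve)
    expect_gte(pm$worst_case_utility + 1e-12,
               max(pmin(curve$TPR, 1 - curve$FPR)))
    expect_gte(pm$worst_case_utility + 1e-12,
               youden_point(curve)$worst_case_utility)
    expect_gte(pm$worst_case_utility + 1e-12,
               maximin_vertex(curve)$worst_case_utility)
    q <- prevalence_from_labels(d)[["q_pos"]]
    expect_gte(pm$worst_case_utility + 1e-12,
               threshold_for_known_skew(curve, q)$worst_case_utility)
  }
})

test_that("for convex curves the best vertex is within one interpolation step of the optimum", {
  set.seed(404)
  for (i in 1:100) {
    d <- random_dataset(sample(6:60, 1), signal = runif(1, 0.5, 2))
    curve <- build_roc(d, check_orientation = FALSE)
    pm <- find_minimax_point(curve)
    pv <- maximin_vertex(curve)
    if (pm$kind == "mixed") {
      # the gap is at most the larger change of min(TPR, 1 - FPR) across
      # the bracketing segment
      f <- curve$TPR + curve$FPR - 1
      i_hi <- which(curve$threshold == pm$t_hi)
      i_lo <- which(curve$threshold == pm$t_lo)
      step <- max(abs(pmin(curve$TPR, 1 - curve$FPR)[c(i_hi, i_lo)] -
                        pm$worst_case_utility))
      expect_lte(pm$worst_case_utility - pv$worst_case_utility, step + 1e-12)
    } else {
      expect_equal(pm$worst_case_utility, pv$worst_case_utility)
    }
  }
})

test_that("hull-mode selection runs on the upper convex hull", {
  set.seed(21)
  d <- random_dataset(60, signal = 1)
  fit_raw <- roc_game(d)
  fit_hull <- roc_game(d, hull = TRUE)
  expect_gte(fit_hull$points$minimax$worst_case_utility,
             fit_raw$points$minimax$worst_case_utility - 1e-12)
  hull <- fit_raw$convexity$hull
  expect_gte(attr(hull, "auc"), attr(fit_raw$curve, "auc") - 1e-12)
})
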