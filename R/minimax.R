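op_point <- function(kind, criterion, fpr, tpr,
                     threshold = NA_real_, t_hi = NA_real_, t_lo = NA_real_,
                     weight = NA_real_, curve = NULL, degenerate = FALSE) {
  n_pos <- if (!is.null(curve)) attr(curve, "n_pos") else NA_integer_
  n_neg <- if (!is.null(curve)) attr(curve, "n_neg") else NA_integer_
  ppf <- if (!is.na(n_pos) && !is.na(n_neg))
    (tpr * n_pos + fpr * n_neg) / (n_pos + n_neg) else NA_real_
  structure(list(
    kind = kind, criterion = criterion,
    threshold = threshold, t_hi = t_hi, t_lo = t_lo, weight = weight,
    FPR = fpr, TPR = tpr,
    worst_case_utility = min(tpr, 1 - fpr),
    predicted_positive_fraction = ppf,
    degenerate = degenerate
  ), class = "operating_point")
}

fmt_threshold <- function(t) {
  if (is.na(t)) "NA" else if (is.infinite(t)) {
    if (t > 0) "+Inf" else "-Inf"
  } else format(t, digits = 6)
}

#' @export
print.operating_point <- function(x, ...) {
  cat(sprintf("Operating point [%s, %s strategy]%s\n", x$criterion, x$kind,
              if (isTRUE(x$degenerate)) " (degenerate diagonal segment: midpoint reported)" else ""))
  if (x$kind == "pure") {
    cat(sprintf("  threshold: score >= %s\n", fmt_threshold(x$threshold)))
  } else {
    cat(sprintf("  randomized threshold: %s with probability %.4f, %s with probability %.4f\n",
                fmt_threshold(x$t_hi), x$weight, fmt_threshold(x$t_lo), 1 - x$weight))
  }
  cat(sprintf("  FPR = %.4f, TPR = %.4f\n", x$FPR, x$TPR))
  cat(sprintf("  worst-case utility over prevalence [0,1]: %.4f\n",
              x$worst_case_utility))
  if (!is.na(x$predicted_positive_fraction))
    cat(sprintf("  predicted-positive fraction at training mix: %.4f\n",
                x$predicted_positive_fraction))
  invisible(x)
}

check_curve <- function(curve) {
  if (!inherits(curve, "roc_curve"))
    stop("expected a 'roc_curve' object; see build_roc()")
  invisible(curve)
}

# tie-break among candidate vertex indices: prefer an on-diagonal vertex,
# then higher TPR, then higher threshold (all deterministic)
break_tie <- function(curve, cand, tol = 1e-9) {
  if (length(cand) == 1L) return(cand)
  f <- abs(curve$TPR[cand] + curve$FPR[cand] - 1)
  on_diag <- f <= tol
  o <- order(-on_diag, -curve$TPR[cand], -curve$threshold[cand])
  cand[o[1L]]
}

#' Minimax operating point: ROC curve meets the descending diagonal
#'
#' Locates the unique point of the linearly interpolated ROC polyline where
#' `TPR + FPR - 1 = 0`. Utility there is indifferent to the prevalence of
#' positives and equals `1 - FPR`; by the minimax principle this point
#' maximizes the worst-case utility over all prevalences. If a vertex lies
#' exactly on the diagonal the result is a pure threshold; otherwise it is a
#' mixed strategy randomizing between the two bracketing thresholds (`t_hi`
#' with probability `weight`, `t_lo` with probability `1 - weight`). If a
#' whole segment of the curve lies on the diagonal, the segment midpoint is
#' returned and flagged degenerate.
#'
#' @param curve a [roc_curve()] object.
#' @param tol numeric tolerance for "on the diagonal" (default `1e-9`; the
#'   interpolation weight itself is solved in closed form, so the returned
#'   mixed point satisfies `|TPR + FPR - 1| <= 1e-12` up to rounding).
#' @return an `operating_point` object.
#' @examples
#' d <- labeled_scores(c(0.9, 0.7, 0.5, 0.6, 0.4, 0.2), c(1, 1, 1, 0, 0, 0))
#' find_minimax_point(build_roc(d))
#' @export
find_minimax_point <- function(curve, tol = 1e-9) {
  check_curve(curve)
  f <- curve$TPR + curve$FPR - 1       # non-decreasing along the curve
  on <- which(abs(f) <= tol)
  if (length(on) >= 2L) {
    i <- on[1L]; j <- on[length(on)]   # a whole sub-polyline on the diagonal
    fpr <- (curve$FPR[i] + curve$FPR[j]) / 2
    tpr <- (curve$TPR[i] + curve$TPR[j]) / 2
    return(op_point("mixed", "minimax", fpr, tpr,
                    t_hi = curve$threshold[i], t_lo = curve$threshold[j],
                    weight = 0.5, curve = curve, degenerate = TRUE))
  }
  if (length(on) == 1L) {
    i <- on
    return(op_point("pure", "minimax", curve$FPR[i], curve$TPR[i],
                    threshold = curve$threshold[i], curve = curve))
  }
  i <- max(which(f < 0))               # bracket: f[i] < 0 < f[i + 1]
  j <- i + 1L
  w <- f[j] / (f[j] - f[i])            # weight on the higher threshold
  fpr <- w * curve$FPR[i] + (1 - w) * curve$FPR[j]
  tpr <- w * curve$TPR[i] + (1 - w) * curve$TPR[j]
  op_point("mixed", "minimax", fpr, tpr,
           t_hi = curve$threshold[i], t_lo = curve$threshold[j],
           weight = w, curve = curve)
}

#' Best pure-threshold (vertex) maximin strategy
#'
#' Restricts the minimax search to actual vertices of the empirical curve -
#' thresholds a practitioner can deploy without randomizing - and returns
#' the vertex maximizing the worst-case utility `min(TPR, 1 - FPR)`. Ties
#' are broken in favour of an on-diagonal vertex, then higher TPR, then
#' higher threshold.
#'
#' @inheritParams find_minimax_point
#' @return an `operating_point` object of kind `"pure"`.
#' @export
maximin_vertex <- function(curve, tol = 1e-9) {
  check_curve(curve)
  u <- pmin(curve$TPR, 1 - curve$FPR)
  cand <- which(u >= max(u) - tol)
  i <- break_tie(curve, cand, tol)
  op_point("pure", "maximin vertex", curve$FPR[i], curve$TPR[i],
           threshold = curve$threshold[i], curve = curve)
}

#' Youden's J operating point
#'
#' The standard comparison criterion: the vertex maximizing
#' `J = TPR - FPR`, i.e. the point farthest above the ascending diagonal.
#' Unlike the minimax point it carries no worst-case guarantee.
#'
#' @inheritParams find_minimax_point
#' @return an `operating_point` object of kind `"pure"`.
#' @export
youden_point <- function(curve, tol = 1e-9) {
  check_curve(curve)
  j <- curve$TPR - curve$FPR
  cand <- which(j >= max(j) - tol)
  i <- break_tie(curve, cand, tol)
  op_point("pure", "Youden J", curve$FPR[i], curve$TPR[i],
           threshold = curve$threshold[i], curve = curve)
}

#' Utility-maximizing vertex for a known skew
#'
#' When the prevalence (and payoffs) are actually known, the iso-yield
#' reasoning picks the vertex maximizing [expected_utility()] at that
#' prevalence; with accuracy payoffs and the training prevalence this is the
#' accuracy-maximizing threshold. It is the skew-sensitive alternative the
#' minimax point is compared against.
#'
#' @inheritParams find_minimax_point
#' @param q_pos the assumed prevalence of positives.
#' @param payoffs a [payoff_matrix()] (validated: degenerate games rejected).
#' @return an `operating_point` object of kind `"pure"`.
#' @export
threshold_for_known_skew <- function(curve, q_pos, payoffs = payoff_matrix(),
                                     tol = 1e-9) {
  check_curve(curve)
  payoffs <- as_payoffs(payoffs, validate = TRUE)
  check_q(q_pos)
  u <- expected_utility(curve$TPR, curve$FPR, q_pos, payoffs)
  cand <- which(u >= max(u) - tol)
  i <- break_tie(curve, cand, tol)
  op_point("pure", sprintf("known skew (q_pos = %g)", q_pos),
           curve$FPR[i], curve$TPR[i],
           threshold = curve$threshold[i], curve = curve)
}
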