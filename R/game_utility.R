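#' Payoff matrix of the classifier-vs-nature game
#'
#' Utilities the classifier earns for each of the four outcomes: `a` for a
#' true positive, `b` for a false positive, `c` for a false negative and `d`
#' for a true negative (machine-learning yields Y_TP, Y_FP, Y_FN, Y_TN in
#' that order). Validation rejects degenerate games where an error outpays
#' the corresponding correct call: it requires `a - c >= 0` and `d - b >= 0`
#' with at least one strict, otherwise the optimum silently flips meaning.
#'
#' The default `a = d = 1`, `b = c = 0` reduces expected utility to
#' accuracy, the canonical case for the minimax analysis.
#'
#' @param a,b,c,d finite real payoffs for TP, FP, FN, TN.
#' @param validate reject degenerate games (default `TRUE`). The pure
#'   utility evaluators accept arbitrary finite payoffs (e.g. the null game
#'   with all payoffs zero); threshold *selection* always validates.
#' @return an object of class `payoff_matrix`: named numeric vector
#'   `c(a, b, c, d)`.
#' @examples
#' payoff_matrix()            # the accuracy game
#' payoff_matrix(5, -1, 0, 1) # asymmetric stakes
#' @export
payoff_matrix <- function(a = 1, b = 0, c = 0, d = 1, validate = TRUE) {
  p <- c(a = a, b = b, c = c, d = d)
  if (anyNA(p) || any(!is.finite(p)))
    stop("payoffs must be finite reals")
  if (isTRUE(validate) &&
      (a - c < 0 || d - b < 0 || (a - c == 0 && d - b == 0)))
    stop(paste0(
      "degenerate game: correct classification must never pay worse than the ",
      "corresponding error (need a >= c and d >= b, at least one strict)"))
  structure(p, class = "payoff_matrix")
}

as_payoffs <- function(pay, validate = FALSE) {
  if (!inherits(pay, "payoff_matrix")) {
    if (!(is.numeric(pay) && length(pay) == 4L))
      stop("payoffs must be a payoff_matrix() or a numeric vector a, b, c, d")
    pay <- payoff_matrix(unname(pay[1]), unname(pay[2]), unname(pay[3]),
                         unname(pay[4]), validate = validate)
  } else if (isTRUE(validate)) {
    pay <- payoff_matrix(pay[["a"]], pay[["b"]], pay[["c"]], pay[["d"]])
  }
  pay
}

#' @export
print.payoff_matrix <- function(x, ...) {
  cat("Payoff matrix (classifier utilities):\n")
  cat(sprintf("  TP (a) = %g   FP (b) = %g\n  FN (c) = %g   TN (d) = %g\n",
              x["a"], x["b"], x["c"], x["d"]))
  invisible(x)
}

check_q <- function(q_pos, what = "q_pos") {
  if (anyNA(q_pos) || any(q_pos < 0 | q_pos > 1))
    stop("'", what, "' must lie in [0, 1]")
  q_pos
}

#' Game utility from confusion counts
#'
#' The count-weighted mean payoff
#' `(a * TP + d * TN + b * FP + c * FN) / (TP + TN + FP + FN)`.
#' With the accuracy payoffs `a = d = 1`, `b = c = 0` this is exactly the
#' fraction of correct predictions.
#'
#' @param counts a `confusion_counts` object (or named TP/FP/FN/TN vector).
#' @param payoffs a [payoff_matrix()] (default: the accuracy game).
#' @return a single numeric utility.
#' @examples
#' utility_from_counts(confusion_counts(TP = 70, FP = 30, FN = 30, TN = 270))
#' @export
utility_from_counts <- function(counts, payoffs = payoff_matrix()) {
  payoffs <- as_payoffs(payoffs)
  req <- c("TP", "FP", "FN", "TN")
  if (!all(req %in% names(counts)))
    stop("counts must carry named elements TP, FP, FN, TN")
  n <- sum(counts[req])
  if (n <= 0) stop("zero total count: utility undefined")
  unname((payoffs["a"] * counts["TP"] + payoffs["d"] * counts["TN"] +
          payoffs["b"] * counts["FP"] + payoffs["c"] * counts["FN"]) / n)
}

#' Skew-sensitive utility from rates and prevalence (accuracy game)
#'
#' For the accuracy payoffs, expected utility at prevalence `q_pos` is
#' `1 - FPR + q_pos * (FPR + TPR - 1)`: affine in the prevalence, with
#' endpoint values `1 - FPR` (all-negative world) and `TPR` (all-positive
#' world). On the descending diagonal `TPR = 1 - FPR` the prevalence drops
#' out entirely. Vectorized over all arguments.
#'
#' @param tpr,fpr rates in \[0, 1\].
#' @param q_pos prevalence of positives in \[0, 1\].
#' @return numeric utility (recycled to the common length).
#' @examples
#' utility_from_rates(0.8, 0.2, c(0.1, 0.5, 0.9))  # skew-indifferent: 0.8
#' @export
utility_from_rates <- function(tpr, fpr, q_pos) {
  check_q(q_pos)
  if (any(tpr < 0 | tpr > 1 | fpr < 0 | fpr > 1))
    stop("rates must lie in [0, 1]")
  1 - fpr + q_pos * (fpr + tpr - 1)
}

#' Expected game utility for general payoffs
#'
#' `q_pos * (a * TPR + c * (1 - TPR)) + (1 - q_pos) * (b * FPR + d * (1 - FPR))`,
#' the rate-form of the count-weighted utility. Reduces exactly to
#' [utility_from_rates()] under the accuracy payoffs.
#'
#' @inheritParams utility_from_rates
#' @param payoffs a [payoff_matrix()].
#' @return numeric utility (vectorized).
#' @export
expected_utility <- function(tpr, fpr, q_pos, payoffs = payoff_matrix()) {
  payoffs <- as_payoffs(payoffs)
  check_q(q_pos)
  unname(q_pos * (payoffs[["a"]] * tpr + payoffs[["c"]] * (1 - tpr)) +
           (1 - q_pos) * (payoffs[["b"]] * fpr + payoffs[["d"]] * (1 - fpr)))
}

#' Skew ratio combining class skew and yield skew
#'
#' The slope of iso-yield lines in ROC space,
#' `q_neg * (Y_FP + Y_TN) / (q_pos * (Y_TP + Y_FN))`, i.e.
#' `(1 - q_pos) * (b + d) / (q_pos * (a + c))`. It measures the relative
#' importance of negatives versus positives regardless of whether the skew
#' comes from prevalence or from payoffs; for the accuracy game it is simply
#' the odds `q_neg / q_pos`.
#'
#' @param q_pos prevalence of positives, strictly between 0 and 1 for a
#'   finite positive ratio.
#' @param payoffs a [payoff_matrix()].
#' @return a positive real.
#' @examples
#' skew_ratio(0.2)  # 4: negatives four times as important
#' @export
skew_ratio <- function(q_pos, payoffs = payoff_matrix()) {
  payoffs <- as_payoffs(payoffs)
  check_q(q_pos)
  denom <- q_pos * (payoffs["a"] + payoffs["c"])
  if (any(denom == 0))
    stop("skew ratio undefined: q_pos = 0 or zero positive-class yield sum")
  unname((1 - q_pos) * (payoffs["b"] + payoffs["d"]) / denom)
}

#' Sensitivity of utility to the prevalence of positives
#'
#' The derivative of the accuracy-game utility with respect to `q_pos`,
#' `FPR + TPR - 1`. It vanishes exactly on the descending diagonal, is
#' negative below it and positive above it - which is why diagonal points
#' are nature's minima and the minimax optimum lies on the diagonal.
#'
#' @inheritParams utility_from_rates
#' @return numeric slope (vectorized).
#' @export
prior_sensitivity_slope <- function(tpr, fpr) {
  tpr + fpr - 1
}

#' Worst-case utility over a prevalence range
#'
#' Because utility is affine in the prevalence, the worst case over
#' `q_range` is attained at an endpoint. Over the full `[0, 1]` this is
#' `min(TPR, 1 - FPR)` - the guaranteed utility regardless of nature's
#' strategy.
#'
#' @inheritParams utility_from_rates
#' @param q_range length-2 prevalence interval (default `c(0, 1)`).
#' @return numeric worst-case utility (vectorized over rates).
#' @examples
#' worst_case_utility(0.8, 0.2)  # 0.8, the on-diagonal minimax value
#' @export
worst_case_utility <- function(tpr, fpr, q_range = c(0, 1)) {
  if (length(q_range) != 2L || q_range[1] > q_range[2])
    stop("'q_range' must be c(lo, hi) with lo <= hi")
  check_q(q_range, "q_range")
  pmin(utility_from_rates(tpr, fpr, q_range[1]),
       utility_from_rates(tpr, fpr, q_range[2]))
}
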