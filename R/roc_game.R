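#' Fit a game-theoretic threshold analysis to labeled scores
#'
#' The main entry point. Treats the classifier as a player in a zero-sum
#' game against nature (whose strategy is the prevalence of positives),
#' builds the empirical ROC curve, and selects the minimax operating point
#' at the intersection with the descending diagonal `TPR = 1 - FPR`, where
#' expected utility is indifferent to class skew and equals `1 - FPR`.
#' Conventional criteria (best pure maximin vertex, Youden's J, known-skew
#' utility maximization) are computed alongside for comparison, together
#' with prevalence-robustness profiles.
#'
#' @param x numeric scores, or a formula `label ~ score` evaluated in
#'   `data`.
#' @param ... passed between methods.
#' @return an object of class `roc_game` with components `data` (the
#'   [labeled_scores()]), `curve` (the [roc_curve()]), `convexity`
#'   ([convexity_report()]), `points` (the four operating points, on the
#'   hull curve if `hull = TRUE`), `comparison` ([compare_criteria()]
#'   table), `profiles` (a [utility_profile()] per criterion),
#'   `prevalence`, `skew_ratio`, `payoffs`, `q_range` and `call`. Supports
#'   `print()`, `summary()`, `coef()` (recommended threshold(s)), `plot()`
#'   (ROC space with diagonal and chosen points) and `predict()`.
#' @examples
#' d <- binormal_sample(n_neg = 200, n_pos = 200, mu_pos = 2, seed = 1)
#' fit <- roc_game(d$score, d$label, positive = TRUE)
#' fit
#' summary(fit)
#' coef(fit)
#' @export
roc_game <- function(x, ...) UseMethod("roc_game")

#' @rdname roc_game
#' @param formula a two-sided formula `label ~ score`.
#' @param data a data frame in which `formula` is evaluated.
#' @export
roc_game.formula <- function(formula, data, ...) {
  x <- formula  # S3 dispatch names the first argument x
  mf <- stats::model.frame(x, data, na.action = stats::na.fail)
  if (ncol(mf) != 2L)
    stop("formula must be of the form label ~ score")
  fit <- roc_game.default(mf[[2L]], mf[[1L]], ...)
  fit$call <- match.call()
  fit
}

#' @rdname roc_game
#' @param label class labels (see [labeled_scores()]); alternatively pass a
#'   `labeled_scores` object as `x` and omit `label`.
#' @param positive label value marking the positive class (default `1`).
#' @param flip negate scores before analysis (for anti-oriented scores).
#' @param payoffs a [payoff_matrix()]; validated, drives the known-skew
#'   criterion and the reported skew ratio.
#' @param q_range prevalence interval `c(lo, hi)` over which worst cases
#'   are taken (default the full `[0, 1]`, the pessimistic game).
#' @param q_grid_n number of grid points for robustness profiles
#'   (default 101; by linearity endpoints suffice, the grid is for
#'   reporting and plotting).
#' @param hull if `TRUE`, operating points are selected on the upper convex
#'   hull of the curve instead of the raw empirical staircase.
#' @param tol on-diagonal / tie tolerance (default `1e-9`).
#' @rdname roc_game
#' @export
roc_game.default <- function(x, label = NULL, positive = 1, flip = FALSE,
                             payoffs = payoff_matrix(), q_range = c(0, 1),
                             q_grid_n = 101L, hull = FALSE, tol = 1e-9, ...) {
  data <- if (inherits(x, "labeled_scores")) x
          else labeled_scores(x, label, positive = positive, flip = flip)
  payoffs <- as_payoffs(payoffs, validate = TRUE)
  if (length(q_range) != 2L || q_range[1] > q_range[2])
    stop("'q_range' must be c(lo, hi) with lo <= hi")
  check_q(q_range, "q_range")
  curve <- build_roc(data)
  convexity <- convexity_report(curve, tol)
  q_train <- prevalence_from_labels(data)[["q_pos"]]
  sel_curve <- if (isTRUE(hull)) convexity$hull else curve
  points <- criterion_points(sel_curve, q_train, payoffs, tol)
  q_grid <- seq(q_range[1], q_range[2], length.out = q_grid_n)
  profiles <- lapply(points, utility_profile, q_grid = q_grid)
  comparison <- compare_criteria(data, q_grid = q_grid, payoffs = payoffs,
                                 tol = tol)
  sr <- if (q_train > 0 && (payoffs["a"] + payoffs["c"]) != 0)
    skew_ratio(q_train, payoffs) else NA_real_
  structure(list(
    data = data, curve = curve, convexity = convexity,
    points = points, profiles = profiles, comparison = comparison,
    prevalence = q_train, skew_ratio = sr,
    payoffs = payoffs, q_range = q_range, hull = isTRUE(hull), tol = tol,
    call = match.call()
  ), class = "roc_game")
}

#' @export
print.roc_game <- function(x, ...) {
  cat("Game-theoretic threshold analysis\n")
  cat(sprintf("  %d instances (%d positive, %d negative), training prevalence %.4f\n",
              nrow(x$data), attr(x$data, "n_pos"), attr(x$data, "n_neg"),
              x$prevalence))
  cat(sprintf("  ROC: %d vertices, AUC = %.4f, %sconvex%s\n",
              nrow(x$curve), attr(x$curve, "auc"),
              if (x$convexity$convex) "" else "non-",
              if (x$hull) " (analysis on upper hull)" else ""))
  cat("\nMinimax operating point (ROC curve meets TPR = 1 - FPR):\n")
  p <- x$points$minimax
  if (p$kind == "pure") {
    cat(sprintf("  pure threshold: score >= %s\n", fmt_threshold(p$threshold)))
  } else {
    cat(sprintf("  randomized: score >= %s w.p. %.4f, score >= %s w.p. %.4f\n",
                fmt_threshold(p$t_hi), p$weight,
                fmt_threshold(p$t_lo), 1 - p$weight))
  }
  cat(sprintf("  FPR = %.4f, TPR = %.4f, guaranteed utility (1 - FPR) = %.4f\n",
              p$FPR, p$TPR, p$worst_case_utility))
  invisible(x)
}

#' @export
summary.roc_game <- function(object, ...) {
  structure(list(fit = object), class = "summary.roc_game")
}

#' @export
print.summary.roc_game <- function(x, ...) {
  fit <- x$fit
  print(fit)
  cat("\n")
  print(fit$comparison)
  cat(sprintf("\nSkew ratio at training prevalence: %s\n",
              if (is.na(fit$skew_ratio)) "undefined" else
                format(fit$skew_ratio, digits = 6)))
  if (!fit$convexity$convex)
    cat("Note: ROC staircase is non-convex; consider hull = TRUE.\n")
  if (fit$points$minimax$degenerate)
    cat("Note: a whole ROC segment lies on the descending diagonal; the midpoint is reported.\n")
  invisible(x)
}

#' @export
coef.roc_game <- function(object, criterion = c("minimax", "maximin",
                                                "youden", "known_skew"), ...) {
  criterion <- match.arg(criterion)
  p <- object$points[[criterion]]
  if (p$kind == "pure") c(threshold = p$threshold)
  else c(t_hi = p$t_hi, t_lo = p$t_lo, weight = p$weight)
}

#' Predict class membership at the fitted operating point
#'
#' Applies the decision rule "score >= t predicts positive" at the
#' threshold chosen by `criterion`. For a mixed minimax point the default
#' deterministic rule uses the bracketing threshold whose vertex has the
#' larger worst-case utility; `rule = "randomized"` instead draws a
#' threshold per instance (`t_hi` with probability `weight`), realizing the
#' mixed strategy exactly - supply `seed` for reproducibility.
#'
#' @param object a fitted [roc_game()] object.
#' @param newdata numeric vector of scores (flipped automatically if the
#'   fit used `flip = TRUE` ... pass scores on the original scale used at
#'   fit time).
#' @param criterion which operating point to deploy.
#' @param rule `"pure"` (deterministic) or `"randomized"` (mixed strategy).
#' @param seed optional seed for the randomized rule.
#' @param ... unused.
#' @return logical vector, `TRUE` = predicted positive.
#' @export
predict.roc_game <- function(object, newdata,
                             criterion = c("minimax", "maximin", "youden",
                                           "known_skew"),
                             rule = c("pure", "randomized"), seed = NULL, ...) {
  criterion <- match.arg(criterion)
  rule <- match.arg(rule)
  score <- as.numeric(newdata)
  p <- object$points[[criterion]]
  if (p$kind == "pure") return(score >= p$threshold)
  if (rule == "pure") {
    # fall back to the better of the two bracketing pure vertices
    cands <- c(p$t_hi, p$t_lo)
    wc <- vapply(cands, function(t) {
      r <- rates_from_counts(confusion_at_threshold(object$data, t))
      min(r["TPR"], 1 - r["FPR"])
    }, numeric(1))
    return(score >= cands[which.max(wc)])
  }
  if (!is.null(seed)) set.seed(seed)
  thr <- ifelse(stats::runif(length(score)) < p$weight, p$t_hi, p$t_lo)
  score >= thr
}

#' Plot an ROC curve with the game-theoretic operating points
#'
#' Draws the empirical ROC staircase, the descending diagonal
#' `TPR = 1 - FPR` (dashed), and marks the minimax intersection (open
#' circle) plus the Youden and maximin-vertex points.
#'
#' @param x a fitted [roc_game()] object.
#' @param ... further arguments to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.roc_game <- function(x, ...) {
  curve <- x$curve
  graphics::plot(curve$FPR, curve$TPR, type = "l", xlim = c(0, 1),
                 ylim = c(0, 1), xlab = "False positive rate",
                 ylab = "True positive rate", asp = 1, ...)
  graphics::abline(1, -1, lty = 2)          # descending diagonal
  graphics::abline(0, 1, lty = 3, col = "grey60")
  if (x$hull || !x$convexity$convex)
    graphics::lines(x$convexity$hull$FPR, x$convexity$hull$TPR,
                    col = "grey40", lty = 4)
  pm <- x$points$minimax
  graphics::points(pm$FPR, pm$TPR, pch = 21, bg = "white", cex = 1.6)
  graphics::points(x$points$youden$FPR, x$points$youden$TPR, pch = 17)
  graphics::points(x$points$maximin$FPR, x$points$maximin$TPR, pch = 15)
  graphics::legend("bottomright", bty = "n",
                   legend = c("ROC curve", "TPR = 1 - FPR",
                              "minimax point", "Youden J", "maximin vertex"),
                   lty = c(1, 2, NA, NA, NA), pch = c(NA, NA, 21, 17, 15))
  invisible(x)
}
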