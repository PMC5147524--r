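#' Utility profile of an operating point across prevalence
#'
#' Evaluates the accuracy-game utility of a fixed operating point on a grid
#' of prevalence values. Because utility is affine in the prevalence, the
#' minimum over any grid spanning an interval is attained at an endpoint;
#' for a grid spanning `[0, 1]` it equals `min(TPR, 1 - FPR)`. The profile
#' of the minimax point is flat - that is the robustness being bought.
#'
#' @param point an `operating_point` (or any list with `FPR` and `TPR`).
#' @param q_grid non-empty numeric grid of prevalence values in \[0, 1\]
#'   (default: 101 evenly spaced values).
#' @return an object of class `utility_profile`: list with the `point`, a
#'   data frame `grid` of `(q_pos, utility)` pairs, `min_utility` and
#'   `argmin_q_pos`.
#' @export
utility_profile <- function(point, q_grid = seq(0, 1, length.out = 101)) {
  if (length(q_grid) == 0L) stop("empty prevalence grid")
  check_q(q_grid, "q_grid")
  if (is.null(point$FPR) || is.null(point$TPR))
    stop("'point' must carry FPR and TPR")
  u <- utility_from_rates(point$TPR, point$FPR, q_grid)
  i <- which.min(u)
  structure(list(
    point = point,
    grid = data.frame(q_pos = q_grid, utility = u),
    min_utility = u[i],
    argmin_q_pos = q_grid[i]
  ), class = "utility_profile")
}

#' @export
print.utility_profile <- function(x, ...) {
  cat(sprintf("Utility profile over %d prevalence values in [%g, %g]\n",
              nrow(x$grid), min(x$grid$q_pos), max(x$grid$q_pos)))
  cat(sprintf("  min utility %.4f at q_pos = %g\n", x$min_utility, x$argmin_q_pos))
  invisible(x)
}

criterion_points <- function(curve, q_pos, payoffs, tol = 1e-9) {
  list(
    minimax    = find_minimax_point(curve, tol),
    maximin    = maximin_vertex(curve, tol),
    youden     = youden_point(curve, tol),
    known_skew = threshold_for_known_skew(curve, q_pos, payoffs, tol)
  )
}

point_threshold_label <- function(p) {
  if (p$kind == "pure") fmt_threshold(p$threshold)
  else sprintf("%s (w=%.4f) / %s", fmt_threshold(p$t_hi), p$weight,
               fmt_threshold(p$t_lo))
}

#' Compare threshold-selection criteria on one dataset
#'
#' Builds the empirical ROC curve and selects an operating point under each
#' of four criteria - the minimax diagonal intersection, the best pure
#' maximin vertex, Youden's J, and the known-skew utility maximizer at the
#' training prevalence - then reports for each its utility at the training
#' prevalence and its worst-case utility over the prevalence grid. The
#' divergence between those two columns under skew uncertainty is the whole
#' argument for the minimax choice: its row always carries the maximal
#' worst-case utility.
#'
#' @param data a [labeled_scores()] object.
#' @param q_grid prevalence grid (default 101 points on \[0, 1\]); the
#'   worst case is taken over this grid.
#' @param payoffs a [payoff_matrix()] used by the known-skew criterion
#'   (validated).
#' @param tol on-diagonal / tie tolerance.
#' @return a data frame of class `criteria_comparison` with one row per
#'   criterion: `criterion`, `kind`, `threshold` (display string), `FPR`,
#'   `TPR`, `utility_at_train` (accuracy-game utility at the sample
#'   prevalence) and `worst_case_utility` (minimum over `q_grid`).
#' @examples
#' d <- labeled_scores(c(0.9, 0.7, 0.5, 0.6, 0.4, 0.2), c(1, 1, 1, 0, 0, 0))
#' compare_criteria(d)
#' @export
compare_criteria <- function(data, q_grid = seq(0, 1, length.out = 101),
                             payoffs = payoff_matrix(), tol = 1e-9) {
  stopifnot_labeled(data)
  payoffs <- as_payoffs(payoffs, validate = TRUE)
  if (length(q_grid) == 0L) stop("empty prevalence grid")
  check_q(q_grid, "q_grid")
  curve <- build_roc(data, check_orientation = FALSE)
  q_train <- prevalence_from_labels(data)[["q_pos"]]
  pts <- criterion_points(curve, q_train, payoffs, tol)
  rows <- lapply(names(pts), function(nm) {
    p <- pts[[nm]]
    data.frame(
      criterion = nm,
      kind = p$kind,
      threshold = point_threshold_label(p),
      FPR = p$FPR, TPR = p$TPR,
      utility_at_train = utility_from_rates(p$TPR, p$FPR, q_train),
      worst_case_utility = min(utility_from_rates(p$TPR, p$FPR, q_grid)),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  attr(out, "points") <- pts
  attr(out, "q_train") <- q_train
  class(out) <- c("criteria_comparison", "data.frame")
  out
}

#' @export
print.criteria_comparison <- function(x, digits = 4, ...) {
  cat(sprintf("Threshold criteria compared at training prevalence q_pos = %.4f\n",
              attr(x, "q_train")))
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], round, digits = digits)
  print(df, row.names = FALSE, ...)
  invisible(x)
}
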