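#' Labeled classifier scores
#'
#' Bundles real-valued classifier scores with binary class labels, the raw
#' material of an empirical ROC analysis. Instances whose label equals
#' `positive` are the positive class; every other label value counts as
#' negative. Both classes must be present, otherwise the ROC curve is
#' undefined.
#'
#' @param score numeric vector of finite classifier scores (higher score =
#'   more positive-like under the default orientation).
#' @param label vector of class labels, same length as `score`. `NA` labels
#'   are an error, never silently dropped.
#' @param positive the label value identifying the positive class
#'   (default `1`).
#' @param flip if `TRUE`, negate the scores. Use when the scoring function is
#'   anti-oriented (low scores indicate positives).
#'
#' @return an object of class `labeled_scores`: a data frame with columns
#'   `score` (numeric) and `label` (logical, `TRUE` = positive), plus
#'   attributes `n_pos` and `n_neg`.
#' @seealso [build_roc()], [read_scores()], [binormal_sample()]
#' @examples
#' d <- labeled_scores(c(0.9, 0.7, 0.5, 0.6, 0.4, 0.2),
#'                     c(1, 1, 1, 0, 0, 0))
#' prevalence_from_labels(d)
#' @export
labeled_scores <- function(score, label, positive = 1, flip = FALSE) {
  if (length(score) != length(label))
    stop("'score' and 'label' must have equal length")
  if (length(score) == 0L)
    stop("no rows: need at least one scored instance")
  score <- as.numeric(score)
  if (anyNA(score) || any(!is.finite(score)))
    stop("scores must be finite reals")
  if (anyNA(label))
    stop("labels contain missing values")
  pos <- label == positive
  if (!any(pos) || all(pos))
    stop("ROC undefined without both classes: need at least one positive and one negative label")
  if (isTRUE(flip)) score <- -score
  structure(
    data.frame(score = score, label = pos),
    n_pos = sum(pos), n_neg = sum(!pos),
    class = c("labeled_scores", "data.frame")
  )
}

#' @export
print.labeled_scores <- function(x, ...) {
  cat(sprintf("Labeled scores: %d instances (%d positive, %d negative)\n",
              nrow(x), attr(x, "n_pos"), attr(x, "n_neg")))
  cat(sprintf("Score range: [%g, %g]\n", min(x$score), max(x$score)))
  invisible(x)
}

stopifnot_labeled <- function(data) {
  if (!inherits(data, "labeled_scores"))
    stop("expected a 'labeled_scores' object; see labeled_scores()")
  invisible(data)
}

#' Confusion counts at a single threshold
#'
#' Applies the decision rule "predict positive iff score >= t" and tallies
#' the four outcomes. The sentinel `t = -Inf` predicts everything positive;
#' `t = +Inf` predicts everything negative.
#'
#' @param data a [labeled_scores()] object.
#' @param threshold a single threshold (may be `-Inf` or `+Inf`).
#' @return an object of class `confusion_counts`: a named integer vector
#'   with elements `TP`, `FP`, `FN`, `TN`.
#' @examples
#' d <- labeled_scores(c(0.9, 0.6, 0.7, 0.2), c(1, 1, 0, 0))
#' confusion_at_threshold(d, 0.8)
#' @export
confusion_at_threshold <- function(data, threshold) {
  stopifnot_labeled(data)
  if (length(threshold) != 1L || is.na(threshold))
    stop("'threshold' must be a single non-missing number")
  pred <- data$score >= threshold
  counts <- c(
    TP = sum(pred & data$label),
    FP = sum(pred & !data$label),
    FN = sum(!pred & data$label),
    TN = sum(!pred & !data$label)
  )
  structure(as.integer(counts), names = names(counts),
            class = "confusion_counts")
}

#' Build a confusion-counts object from four tallies
#'
#' @param TP,FP,FN,TN non-negative integer counts; both class totals
#'   (`TP + FN` and `FP + TN`) must be positive.
#' @return a `confusion_counts` object.
#' @export
confusion_counts <- function(TP, FP, FN, TN) {
  counts <- c(TP = TP, FP = FP, FN = FN, TN = TN)
  if (anyNA(counts) || any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  if (TP + FN <= 0 || FP + TN <= 0)
    stop("both classes must be represented: need TP + FN > 0 and FP + TN > 0")
  structure(as.integer(counts), names = names(counts),
            class = "confusion_counts")
}

#' True and false positive rates from confusion counts
#'
#' `TPR = TP / (TP + FN)` (sensitivity) and `FPR = FP / (FP + TN)`
#' (1 - specificity).
#'
#' @param counts a `confusion_counts` object or a named vector with elements
#'   `TP`, `FP`, `FN`, `TN`.
#' @return named numeric vector `c(TPR = , FPR = )`.
#' @examples
#' rates_from_counts(confusion_counts(TP = 9, FP = 0, FN = 1, TN = 10))
#' @export
rates_from_counts <- function(counts) {
  req <- c("TP", "FP", "FN", "TN")
  if (!all(req %in% names(counts)))
    stop("counts must carry named elements TP, FP, FN, TN")
  counts <- counts[req]
  if (counts["TP"] + counts["FN"] <= 0 || counts["FP"] + counts["TN"] <= 0)
    stop("rate denominator zero: both class totals must be positive")
  c(TPR = unname(counts["TP"] / (counts["TP"] + counts["FN"])),
    FPR = unname(counts["FP"] / (counts["FP"] + counts["TN"])))
}

#' Sample prevalence of positives
#'
#' The fraction of positive instances, `q_P = (TP + FN) / N`, together with
#' its complement `q_N = 1 - q_P`. In the game view this is nature's mixed
#' strategy as observed in the training sample.
#'
#' @param data a [labeled_scores()] object.
#' @return named numeric vector `c(q_pos = , q_neg = )`.
#' @export
prevalence_from_labels <- function(data) {
  stopifnot_labeled(data)
  q <- attr(data, "n_pos") / nrow(data)
  c(q_pos = q, q_neg = 1 - q)
}

#' Construct an ROC curve object from vertex coordinates
#'
#' Low-level constructor validating the ROC-curve invariants: vertices run
#' from (FPR, TPR) = (0, 0) to (1, 1), both rates are non-decreasing, and
#' thresholds are strictly decreasing (the first may be `+Inf`, the last
#' `-Inf`). Most users should call [build_roc()] on data instead.
#'
#' @param threshold strictly decreasing numeric vector of thresholds.
#' @param FPR,TPR non-decreasing rates in \[0, 1\].
#' @param n_pos,n_neg optional class sizes behind the curve; needed for
#'   predicted-positive fractions of operating points.
#' @return an object of class `roc_curve`: a data frame with columns
#'   `threshold`, `FPR`, `TPR` and attributes `n_pos`, `n_neg`, `auc`.
#' @export
roc_curve <- function(threshold, FPR, TPR, n_pos = NA_integer_, n_neg = NA_integer_) {
  n <- length(threshold)
  if (n < 2L || length(FPR) != n || length(TPR) != n)
    stop("need >= 2 vertices with matching threshold/FPR/TPR lengths")
  if (any(diff(threshold) >= 0))
    stop("thresholds must be strictly decreasing")
  if (any(diff(FPR) < 0) || any(diff(TPR) < 0))
    stop("FPR and TPR must be non-decreasing along the curve")
  if (abs(FPR[1]) > 1e-12 || abs(TPR[1]) > 1e-12)
    stop("curve must start at (FPR, TPR) = (0, 0)")
  if (abs(FPR[n] - 1) > 1e-12 || abs(TPR[n] - 1) > 1e-12)
    stop("curve must end at (FPR, TPR) = (1, 1)")
  if (any(FPR < -1e-12 | FPR > 1 + 1e-12 | TPR < -1e-12 | TPR > 1 + 1e-12))
    stop("rates must lie in [0, 1]")
  auc <- sum(diff(FPR) * (TPR[-1] + TPR[-n]) / 2)
  structure(
    data.frame(threshold = threshold, FPR = FPR, TPR = TPR),
    n_pos = n_pos, n_neg = n_neg, auc = auc,
    class = c("roc_curve", "data.frame")
  )
}

#' Empirical ROC curve from labeled scores
#'
#' Sweeps the decision threshold over every distinct score value (tied
#' scores are inseparable and collapse into a single vertex) and records the
#' resulting (FPR, TPR) pairs. The first vertex is the all-negative corner
#' (0, 0) at the symbolic above-all-scores threshold `+Inf`; the lowest
#' finite threshold predicts every instance positive and realizes the
#' (1, 1) corner, so no further sentinel row is needed.
#'
#' If the empirical trapezoid AUC falls below 0.5 a warning suggests the
#' scores may be anti-oriented (see the `flip` argument of
#' [labeled_scores()]).
#'
#' @param data a [labeled_scores()] object.
#' @param check_orientation warn when AUC < 0.5 (default `TRUE`).
#' @return a [roc_curve()] object with one vertex per distinct score plus
#'   the (0, 0) sentinel.
#' @examples
#' d <- labeled_scores(c(0.9, 0.7, 0.5, 0.6, 0.4, 0.2), c(1, 1, 1, 0, 0, 0))
#' build_roc(d)
#' @export
build_roc <- function(data, check_orientation = TRUE) {
  stopifnot_labeled(data)
  n_pos <- attr(data, "n_pos")
  n_neg <- attr(data, "n_neg")
  o <- order(data$score, decreasing = TRUE)
  s <- data$score[o]
  y <- data$label[o]
  tp <- cumsum(y)
  fp <- cumsum(!y)
  last <- which(!duplicated(s, fromLast = TRUE))  # last index of each tie group
  curve <- roc_curve(
    threshold = c(Inf, s[last]),
    FPR = c(0, fp[last] / n_neg),
    TPR = c(0, tp[last] / n_pos),
    n_pos = n_pos, n_neg = n_neg
  )
  if (isTRUE(check_orientation) && attr(curve, "auc") < 0.5)
    warning(sprintf(
      "empirical AUC = %.3f < 0.5: scores may be anti-oriented; consider flip = TRUE",
      attr(curve, "auc")))
  curve
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("Empirical ROC curve: %d vertices, trapezoid AUC = %.4f\n",
              nrow(x), attr(x, "auc")))
  print.data.frame(x, row.names = FALSE, ...)
  invisible(x)
}

# upper staircase corners: max TPR per distinct FPR, (0,0) kept as the start
roc_corners <- function(curve) {
  idx <- vapply(split(seq_len(nrow(curve)), curve$FPR),
                function(i) i[which.max(curve$TPR[i])], integer(1))
  idx <- sort(unname(idx))
  if (curve$TPR[idx[1]] > 0) idx <- c(1L, idx)
  idx
}

#' Convexity report for an ROC curve
#'
#' An empirical ROC staircase is judged concave-down ("convex" in ROC
#' parlance) on its upper corners - the maximal TPR attained at each
#' distinct FPR - since the interior step vertices of any staircase
#' necessarily sit below the chords. The report flags whether every corner
#' lies on the upper convex hull (collinear corners count as on-hull) and
#' returns the hull vertex subset, usable for hull-mode analysis.
#'
#' @param curve a [roc_curve()] object.
#' @param tol tolerance for the collinearity / below-chord test.
#' @return an object of class `convexity_report`: a list with elements
#'   `convex` (logical), `hull` (a `roc_curve` restricted to hull vertices)
#'   and `hull_index` (row indices of the hull vertices in `curve`).
#' @export
convexity_report <- function(curve, tol = 1e-9) {
  if (!inherits(curve, "roc_curve")) stop("expected a 'roc_curve' object")
  ci <- roc_corners(curve)
  x <- curve$FPR[ci]
  y <- curve$TPR[ci]
  cross <- function(i, j, k)
    (x[j] - x[i]) * (y[k] - y[i]) - (y[j] - y[i]) * (x[k] - x[i])
  m <- length(ci)
  convex <- TRUE
  if (m >= 3L)
    convex <- all(vapply(2:(m - 1L), function(j) cross(j - 1L, j, j + 1L) <= tol,
                         logical(1)))
  # Andrew's monotone chain, upper hull; pops collinear points too
  hull <- integer(0)
  for (j in seq_len(m)) {
    while (length(hull) >= 2L &&
           cross(hull[length(hull) - 1L], hull[length(hull)], j) >= -tol)
      hull <- hull[-length(hull)]
    hull <- c(hull, j)
  }
  hull_index <- ci[hull]
  hull_curve <- roc_curve(curve$threshold[hull_index],
                          curve$FPR[hull_index], curve$TPR[hull_index],
                          n_pos = attr(curve, "n_pos"),
                          n_neg = attr(curve, "n_neg"))
  structure(list(convex = convex, hull = hull_curve, hull_index = hull_index),
            class = "convexity_report")
}

#' @export
print.convexity_report <- function(x, ...) {
  cat(sprintf("ROC curve is %s; upper convex hull has %d vertices\n",
              if (x$convex) "convex (concave-down staircase)" else "NOT convex",
              nrow(x$hull)))
  invisible(x)
}

#' Read labeled scores from a CSV/TSV file
#'
#' Reads a delimited table (header required; lines starting with `#` are
#' comments) and extracts the configured score and label columns.
#'
#' @param path file path. Separator defaults to tab for `.tsv`/`.tab`
#'   extensions, comma otherwise; override with `sep`.
#' @param score_col,label_col column names (defaults `"score"`, `"label"`).
#' @param positive the label value identifying positives (default `"1"`;
#'   compared after coercing labels to character).
#' @param sep field separator; `NULL` = infer from extension.
#' @inheritParams labeled_scores
#' @return a [labeled_scores()] object.
#' @export
read_scores <- function(path, score_col = "score", label_col = "label",
                        positive = "1", sep = NULL, flip = FALSE) {
  if (!file.exists(path)) stop("cannot read input file: ", path)
  if (is.null(sep))
    sep <- if (grepl("\\.(tsv|tab)$", path, ignore.case = TRUE)) "\t" else ","
  tab <- tryCatch(
    read.table(path, header = TRUE, sep = sep, comment.char = "#",
               stringsAsFactors = FALSE, check.names = FALSE),
    error = function(e) stop("no rows: input file is empty or unreadable (",
                             conditionMessage(e), ")"))
  if (nrow(tab) == 0L) stop("no rows in input file")
  for (col in c(score_col, label_col))
    if (!col %in% names(tab))
      stop(sprintf("column '%s' not found in %s", col, path))
  labeled_scores(tab[[score_col]], as.character(tab[[label_col]]),
                 positive = as.character(positive), flip = flip)
}
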