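#' Simulate binormal classifier scores
#'
#' Draws `n_neg` scores from Normal(`mu_neg`, `sigma_neg`) labeled negative
#' and `n_pos` from Normal(`mu_pos`, `sigma_pos`) labeled positive - the
#' binormal model, whose population ROC curve is continuous and convex and
#' admits a closed-form minimax operating point
#' ([binormal_analytic_minimax()]). The seed is a required argument so
#' samples are reproducible without touching global RNG state (the caller's
#' `.Random.seed` is restored on exit).
#'
#' @param n_neg,n_pos positive class sizes.
#' @param mu_pos positive-class mean. After standardizing to
#'   `mu_neg = 0, sigma_neg = 1`, a better-than-random classifier needs
#'   `mu_pos > 0`; a warning is issued otherwise.
#' @param sigma_pos,sigma_neg positive standard deviations (defaults 1).
#' @param mu_neg negative-class mean (default 0).
#' @param seed integer RNG seed (mandatory).
#' @return a [labeled_scores()] object with attribute `params` recording the
#'   generating parameters.
#' @examples
#' d <- binormal_sample(n_neg = 100, n_pos = 100, mu_pos = 2, seed = 7)
#' find_minimax_point(build_roc(d))
#' @export
binormal_sample <- function(n_neg, n_pos, mu_pos, sigma_pos = 1,
                            mu_neg = 0, sigma_neg = 1, seed) {
  if (missing(seed)) stop("'seed' is required: no hidden global RNG state")
  if (n_neg < 1 || n_pos < 1) stop("class sizes must be >= 1")
  if (sigma_pos <= 0 || sigma_neg <= 0) stop("sigmas must be positive")
  if (!all(is.finite(c(mu_pos, mu_neg, sigma_pos, sigma_neg))))
    stop("binormal parameters must be finite")
  if ((mu_pos - mu_neg) / sigma_neg <= 0)
    warning("mu_pos <= mu_neg: classifier is no better than random under the score >= t rule")
  old_seed <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(as.integer(seed))
  score <- c(rnorm(n_neg, mu_neg, sigma_neg), rnorm(n_pos, mu_pos, sigma_pos))
  label <- rep(c(FALSE, TRUE), c(n_neg, n_pos))
  out <- labeled_scores(score, label, positive = TRUE)
  attr(out, "params") <- list(n_neg = n_neg, n_pos = n_pos,
                              mu_neg = mu_neg, sigma_neg = sigma_neg,
                              mu_pos = mu_pos, sigma_pos = sigma_pos,
                              seed = as.integer(seed))
  out
}

#' Closed-form minimax operating point of the binormal model
#'
#' For standardized negatives (mean 0, sd 1) and positives with mean
#' `mu_pos > 0` and sd `sigma_pos`, the population ROC curve has
#' `TPR(t) = Phi((mu_pos - t) / sigma_pos)` and `FPR(t) = Phi(-t)`, so the
#' descending-diagonal condition `TPR = 1 - FPR = Phi(t)` gives
#' `t* = mu_pos / (1 + sigma_pos)` and a minimax utility `Phi(t*) = 1 - FPR`.
#' At that point `TPR + FPR = 1` exactly: the continuous-model
#' skew-indifference.
#'
#' @param mu_pos positive-class mean, strictly positive.
#' @param sigma_pos positive-class standard deviation (default 1).
#' @return a list with `threshold`, `FPR`, `TPR` and `utility`.
#' @examples
#' binormal_analytic_minimax(mu_pos = 2)  # t* = 1, utility = pnorm(1)
#' @export
binormal_analytic_minimax <- function(mu_pos, sigma_pos = 1) {
  if (sigma_pos <= 0) stop("'sigma_pos' must be positive")
  if (!is.finite(mu_pos) || mu_pos <= 0)
    stop("no informative optimum: need mu_pos > 0 on the standardized scale")
  t_star <- mu_pos / (1 + sigma_pos)
  list(threshold = t_star,
       FPR = pnorm(-t_star),
       TPR = pnorm((mu_pos - t_star) / sigma_pos),
       utility = pnorm(t_star))
}
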