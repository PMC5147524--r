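---
title: "Minimax threshold selection as a game against nature"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Minimax threshold selection as a game against nature}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rocgame)
```

## The model

A score-based binary classifier deployed at threshold $t$ (predict positive
iff score $\ge t$) occupies an operating point $(\mathrm{FPR}(t),
\mathrm{TPR}(t))$ in ROC space. We view its use as a zero-sum game: nature
plays a class — positive with probability $q_P$, negative with $1 - q_P$ —
and the classifier earns payoffs $a, b, c, d$ for a true positive, false
positive, false negative and true negative respectively. The realized
utility over a sample is the count-weighted mean payoff

$$U = \frac{a\,TP + d\,TN + b\,FP + c\,FN}{TP + TN + FP + FN},$$

which for the canonical payoffs $a = d = 1$, $b = c = 0$ is the accuracy.
Class skew and payoff skew are interchangeable — both enter decisions only
through the iso-yield slope $q_N (Y_{FP} + Y_{TN}) / (q_P (Y_{TP} +
Y_{FN}))$ — so the analysis is carried out on the canonical payoffs without
loss of generality; `expected_utility()` exposes the general-payoff form,
and general payoffs still drive the known-skew comparison criterion.

In expectation over nature's draw, the canonical utility of an operating
point is

$$U(q_P) = 1 - \mathrm{FPR} + q_P\,(\mathrm{FPR} + \mathrm{TPR} - 1),$$

affine in $q_P$. Its slope, $\mathrm{FPR} + \mathrm{TPR} - 1$
(`prior_sensitivity_slope()`), vanishes exactly on the descending diagonal
$\mathrm{TPR} = 1 - \mathrm{FPR}$, is negative below it and positive above
it. Nature, playing adversarially, pushes the prevalence to whichever
endpoint of $[0, 1]$ hurts: the worst case is $\min(\mathrm{TPR},
1 - \mathrm{FPR})$. The minimax prescription is therefore to operate where
the ROC curve crosses the descending diagonal; the utility there,
$1 - \mathrm{FPR}$, is guaranteed *regardless of prevalence*. This is the
decision-theoretic content of the empirical rule "set the cutoff where
sensitivity equals specificity": it maximizes robustness to skew
uncertainty, at the price of expected utility when the skew is actually
known.

## From the continuous curve to an empirical staircase

The derivation assumes a continuous, convex ROC curve. An empirical curve
is a staircase: one vertex per distinct score value (tied scores are
inseparable and collapse into one vertex) plus the all-negative corner
$(0,0)$ at the symbolic threshold $+\infty$; the lowest finite threshold
already realizes $(1,1)$. Because both rates are non-decreasing along the
sweep, $\mathrm{TPR} + \mathrm{FPR} - 1$ is non-decreasing and the
interpolated polyline crosses the diagonal exactly once. Our resolution of
the step-curve ambiguity, which the continuous theory leaves open:

* If a vertex lies on the diagonal (tolerance $10^{-9}$), the optimum is a
  deployable **pure** threshold.
* Otherwise the crossing lies inside a segment, and the exact optimum is a
  **mixed** strategy: apply the higher bracketing threshold with
  probability $w$ solved in closed form from the two vertices'
  diagonal residuals. This randomized threshold attains
  $|\mathrm{TPR} + \mathrm{FPR} - 1| \le 10^{-12}$ up to rounding.
  Practitioners unable to randomize get `maximin_vertex()`, the best pure
  vertex, reported alongside; for convex curves it is within one
  interpolation step of the mixed optimum.
* A whole segment lying *on* the diagonal cannot occur on a monotone
  curve (it would need $\Delta\mathrm{TPR} = -\Delta\mathrm{FPR}$ with both
  non-negative); the only realizable degeneracy is several thresholds
  mapping to one point, which is returned with a `degenerate` flag.

Ties among selected vertices are broken deterministically: prefer an
on-diagonal vertex (maximal skew-indifference), then higher TPR, then
higher threshold.

## Convexity

The continuous argument presumes a convex curve. A staircase's interior
step corners always sit below hull chords, so convexity is judged on the
*upper corners* — the maximal TPR at each distinct FPR: the curve is
flagged convex when no corner falls strictly below the chord of its
neighbours. `convexity_report()` also returns the upper convex hull, and
`roc_game(, hull = TRUE)` runs the selection on the hull polyline, whose
mixtures combine possibly non-adjacent thresholds. The default analysis
stays on the raw empirical curve: the diagonal crossing is unique either
way, and both behaviours should be inspectable.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `payoffs` | $a{=}d{=}1$, $b{=}c{=}0$ | outcome utilities (unitless); validation rejects games where an error outpays the matching correct call, which would silently invert the optimum |
| `q_range` | $[0, 1]$ | prevalence interval nature may play; worst cases are computed at its endpoints (utility is affine), a narrower interval encodes partial prevalence knowledge |
| `q_grid_n` | 101 | grid resolution for robustness profiles — reporting only, endpoints suffice mathematically |
| `positive` | `"1"` | label value marking positives; any other value is negative, `NA` errors |
| `flip` | `FALSE` | negate scores; `build_roc()` warns when the trapezoid AUC is below 0.5 (anti-oriented scores) |
| `tol` | $10^{-9}$ | on-diagonal and tie tolerance; empirical rates are ratios of small integers, so $10^{-9}$ separates genuine ties from rounding while absorbing last-bit float noise (e.g. $1 - 1/3$ versus $2/3$) |

## What the synthetic generator emulates

`binormal_sample()` draws negatives from $N(\mu_N, \sigma_N)$ (default
standard normal) and positives from $N(\mu_P, \sigma_P)$ — the binormal
model, chosen because it matches the theory's premises (continuous, convex
population ROC) and admits a closed form: standardizing the negatives, the
diagonal condition $\Phi((\mu_P - t)/\sigma_P) = \Phi(t)$ gives
$t^* = \mu_P / (1 + \sigma_P)$ with utility $\Phi(t^*)$
(`binormal_analytic_minimax()`, cross-checked in the tests by root-finding
rather than by the formula). The reference world used by the tests and the
acceptance script is $\mu_P = 2$, $\sigma_P = 1$, 20,000 scores per class —
a moderately good classifier (population AUC $\Phi(\sqrt{2}) \approx 0.92$)
at a sample size where the empirical threshold concentrates well within
$\pm 0.1$ of $t^* = 1$. A seed is a mandatory argument; the caller's RNG
stream is left untouched.

What a green simulation test does **not** establish: behaviour under
non-normal or multimodal score distributions, heavy class imbalance in the
*training* sample (the generator defaults to balanced classes), scores
with mass points, or any finite-sample optimism of the training ROC —
the generator validates the estimator against its own population optimum,
not against distribution-free guarantees.

## Numerical choices

* Rates are ratios of integer counts; identities such as the equality of
  count-based utility and the rate/prevalence form at the sample prevalence
  hold to $10^{-12}$ (and accuracy exactly, since the integer sums are
  exact in doubles).
* The mixed-point weight is solved in closed form, not by root-finding.
* Worst cases over a prevalence interval are evaluated at its endpoints by
  linearity; grids are cosmetic.
* Degenerate inputs fail loudly: single-class data, empty files, zero
  count totals, prevalence outside $[0,1]$, non-monotone hand-built curves.

## Known limitations

* No confidence intervals or resampling for the chosen threshold; the
  curve is taken at face value (the training-set-validity assumption of
  the underlying argument).
* Multi-class problems, score calibration and AUC-based model selection
  are out of scope.
* The known-skew criterion optimizes over vertices only; for a known skew
  far from the training mix a hull mixture could do slightly better.

## A compact session

```{r example}
d <- binormal_sample(n_neg = 2000, n_pos = 2000, mu_pos = 2, seed = 11)
fit <- roc_game(d)
summary(fit)
binormal_analytic_minimax(mu_pos = 2)$utility
```
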