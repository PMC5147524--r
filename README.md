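# rocgame

Game-theoretic minimax threshold selection for binary classifiers.

## The problem

Score-based binary classifiers — BLAST-style sequence matchers, diagnostic
biomarkers, motif scanners — are deployed by fixing a decision threshold
*t*: predict positive iff score ≥ *t*. Picking *t* is hard because two skews
of the application domain are usually uncertain and context-dependent: the
prevalence of positives in nature, *q<sub>P</sub>* (which rarely matches the
training set), and the yields/costs *Y<sub>TP</sub>, Y<sub>FP</sub>,
Y<sub>FN</sub>, Y<sub>TN</sub>* of the four outcomes. Both collapse into one
skew ratio, the slope of iso-yield lines in ROC space:

```
SKEW = q_N (Y_FP + Y_TN) / ( q_P (Y_TP + Y_FN) )
```

`rocgame` treats classification as a zero-sum game between the classifier
and nature, whose mixed strategy is *q<sub>P</sub>*. For the canonical
payoffs *a = d = 1, b = c = 0* the classifier's expected utility is its
accuracy, which as a function of the operating point (FPR, TPR) and the
prevalence is

```
U(q_P) = 1 − FPR + q_P (FPR + TPR − 1)
```

— affine in *q<sub>P</sub>*, with slope FPR + TPR − 1. Points on the
**descending diagonal** TPR = 1 − FPR are therefore *skew-indifferent*:
their utility does not depend on the prevalence at all. The minimax
principle (maximize the worst-case utility over nature's strategies) picks
the intersection of the ROC curve with that diagonal, where the guaranteed
utility is **1 − FPR**. This puts the familiar folk rule "choose the cutoff
where specificity equals sensitivity" on a decision-theoretic footing: it
maximizes robustness against skew uncertainty.

On an empirical step-shaped ROC curve the intersection generally falls
between two vertices; `rocgame` returns both the exact interpolated optimum
(operationally a *randomized* threshold mixing the two bracketing cutoffs)
and the best deployable pure threshold.

## Worked example

```r
library(rocgame)

d   <- labeled_scores(score = c(0.9, 0.7, 0.5, 0.6, 0.4, 0.2),
                      label = c(1, 1, 1, 0, 0, 0))
fit <- roc_game(d)
summary(fit)
```

```
Game-theoretic threshold analysis
  6 instances (3 positive, 3 negative), training prevalence 0.5000
  ROC: 7 vertices, AUC = 0.8889, convex

Minimax operating point (ROC curve meets TPR = 1 - FPR):
  pure threshold: score >= 0.6
  FPR = 0.3333, TPR = 0.6667, guaranteed utility (1 - FPR) = 0.6667

Threshold criteria compared at training prevalence q_pos = 0.5000
  criterion kind threshold    FPR    TPR utility_at_train worst_case_utility
    minimax pure       0.6 0.3333 0.6667           0.6667             0.6667
    maximin pure       0.6 0.3333 0.6667           0.6667             0.6667
     youden pure       0.5 0.3333 1.0000           0.8333             0.6667
 known_skew pure       0.5 0.3333 1.0000           0.8333             0.6667

Skew ratio at training prevalence: 1
```

Reading the output: the ROC vertex at (FPR, TPR) = (1/3, 2/3) lies exactly
on the descending diagonal, so the minimax threshold is the pure cutoff
0.6. Its utility, 2/3, is guaranteed for *every* prevalence. The Youden
point (threshold 0.5) looks better at the training prevalence (0.83) but
its guarantee over all prevalences is no higher — and on skewed data it is
typically strictly worse (here the two coincide because the toy curve is
tiny).

A synthetic run with known ground truth — negatives N(0,1), positives
N(2,1), where the population optimum is *t\** = 2/(1+1) = 1 with utility
Φ(1) ≈ 0.8413:

```r
d <- binormal_sample(n_neg = 20000, n_pos = 20000, mu_pos = 2, seed = 1)
find_minimax_point(build_roc(d))
```

```
Operating point [minimax, pure strategy]
  threshold: score >= 0.995172
  FPR = 0.1610, TPR = 0.8390
  worst-case utility over prevalence [0,1]: 0.8390
  predicted-positive fraction at training mix: 0.5000
```

(With equal class sizes an empirical vertex lands exactly on the diagonal,
so the point is pure here; unbalanced samples typically yield a randomized
mixture of two adjacent cutoffs.)

## Command line

```sh
rocgame analyze  --input scores.csv --output report.json --tsv table.tsv
rocgame simulate --output sim.csv --mu-pos 2 --n 1000 --seed 1
rocgame compare  --input scores.csv
```

`analyze` writes a JSON report (ROC vertex table, convexity/hull, minimax
point, criteria comparison, utility profiles); `simulate` writes a
binormal sample plus a JSON sidecar with the generating parameters and the
analytic optimum. Flags: `--score-col`, `--label-col`, `--positive-label`,
`--payoffs a,b,c,d`, `--qp-range lo,hi`, `--hull`, `--flip-scores`.

## Acceptance script

`scripts/acceptance.R` re-runs the pipeline from scratch: it simulates the
binormal world above at the given seed, fits the model, prints the
empirical versus analytic minimax operating point and the criteria
comparison, and writes the JSON summary:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
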