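Package: rocgame
Title: Game-Theoretic Minimax Threshold Selection for Binary Classifiers
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Chooses an operating point for a score-based binary classifier
    by treating classification as a zero-sum game against nature. Builds the
    empirical ROC curve from labeled scores, evaluates prevalence- and
    payoff-dependent expected utility, and returns the minimax operating
    point at the intersection of the ROC curve with the descending diagonal
    TPR = 1 - FPR, where utility is indifferent to class skew and equals
    1 - FPR. Includes conventional comparison criteria (Youden's J, best
    pure maximin vertex, known-skew utility maximization), robustness
    profiling of utility across prevalence, a binormal score simulator with
    closed-form ground truth, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
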