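Package: advpercept
Title: Adversarial Perturbations and Perceptual Bias in Forced-Choice Experiments
Version: 0.1.0
Authors@R:
    person("advpercept", "maintainers", email = "advpercept@example.org",
           role = c("aut", "cre"))
Description: A desk-scale, fully offline testbed for studying whether small
    L-infinity-bounded adversarial perturbations that bias image classifiers
    also bias forced-choice observers. Provides a synthetic labelled image
    population with fine classes nested in coarse categories, small
    differentiable classifier ensembles with exact input gradients,
    coarse-category log-sum-exp scoring, the iterative fast gradient sign
    method with expectation-over-transformation robustness and flipped
    perturbation controls, stimulus pair and session assembly for
    two-alternative forced-choice experiments, perturbation structure metrics
    (bilateral filtering plus Canny edge counts, multi-scale structural
    similarity), simulated Bernoulli observers, and the behavioral statistics
    pipeline (catch-trial exclusions, perceptual bias, one-sample t tests,
    mixed two-factor ANOVA with partial eta squared, tie-aware Spearman
    correlation, and permutation nulls).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
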