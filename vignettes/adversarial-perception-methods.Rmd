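---
title: "Methods: adversarial perturbations and forced-choice perceptual bias at desk scale"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: adversarial perturbations and forced-choice perceptual bias at desk scale}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## What this package models

Adversarial perturbations are small per-pixel deltas, bounded in the
L∞ norm (`max |delta| <= epsilon` intensity levels on the 0–255 scale), that
are optimized to change a classifier's output while leaving the image's
apparent class intact. The scientific question the machinery here supports is
whether such perturbations, built against an *ensemble of classifiers*, also
bias *human* two-alternative forced choice (2AFC) — and how one would measure
that bias, control for perturbation statistics, and attribute it to
perturbation structure.

Running that question at its native scale needs ImageNet-grade models and
hundreds of participants. This package replaces both with a fully synthetic,
seedable testbed so that every stage — stimulus generation, session assembly,
response analysis — is verifiable offline in CPU minutes. The testbed is a
*stated world*, not a knob: its defaults are fixed below and the test suite
treats them as frozen.

## The synthetic population and toy scorers

`generate_dataset()` draws six fine shape classes (ellipse, rectangle,
triangle, annulus, cross, bar) on 64×64 RGB grids. Each class carries a
class-specific texture frequency and orientation (fixed phase, so the cue is
linearly decodable), 10% position/size jitter, and additive Gaussian pixel
noise (SD 8 intensity levels). Fine classes nest in coarse categories the way
breeds nest in "dog": the default mapping is `round` = {ellipse, annulus} and
`angular` = {rectangle, triangle, bar}, with the cross deliberately assigned
to *no* category so the complement-sum rule below is always exercised.

Two differentiable scorer families satisfy one contract —
`score_logits(scorer, image)` and `input_gradient(scorer, image, dlogits)`:

* `linear`: multinomial logistic regression on raw pixels;
* `rf`: a fixed random projection (width 256) through `tanh`, with a trained
  linear readout — the stand-in for a second architecture family.

Both have closed-form input gradients, so attack gradients are exact and the
finite-difference checks in the test suite are genuine oracles rather than
self-comparisons. Training is full-batch gradient descent with momentum;
held-out top-1 accuracy on the default spec is ≈ 0.98 (linear) and 1.00 (rf),
against the ≥ 0.9 contract. What a green test here establishes is that the
*pipeline* behaves lawfully on a learnable population; it says nothing about
photographic realism, texture/shape cue conflict, or human vision — the
generator does not emulate those.

## Coarse-category scoring

With fine logits $S_i$ and a coarse category $c$, the coarse score is the
member/complement contrast

$$S_c = \log\sum_{i \in c} e^{S_i} - \log\sum_{j \notin c} e^{S_j},$$

computed with overflow-safe log-sum-exp, and `coarse_prob()` is its logistic
transform: the probability of the binary "is $c$ present?" classifier. Fine
classes outside every category count in the complement sum. One numerical
fact worth stating: this contrast absorbs any constant added to *all* fine
logits, whatever the category size — both log-sum-exp terms shift by the
constant and cancel. The regression tests assert exactly that, alongside
monotonicity in member logits and antitonicity in complement logits.

When two target categories with unequal fine support are pitted against each
other (the 120-dog vs 7-bottle situation), `subsample_mapping()` draws, per
image, a uniform seeded subsample of the larger category down to
$\min(n_A, n_{A'})$, so support alone cannot bias the paired objective. The
per-image seed is derived from (global seed, image id).

## The attack

The targeted objective is the binary cross entropy of the ensemble's coarse
probability, $J = -\log P_{ens}(y\,|\,X)$; untargeted replaces $P$ with
$1-P$. Each iterate takes a signed step on the gradient of $-J$ and clips
twice — to the ε-ball around the source, then to [0, 255]:

$$X_i = \mathrm{clip}\big(X_{i-1} + \alpha\,\mathrm{sgn}(\nabla_X(-J)),\; X-\epsilon,\; X+\epsilon\big).$$

Numerical choices:

* **Stable loss.** $-\log P$ is evaluated as the softplus of the coarse
  score. A literal probability clamp (the obvious alternative) flattens the
  loss when scorers saturate and silently kills finite-difference gradients;
  softplus is identical wherever $P$ is representable and finite everywhere.
* **sgn(0) = 0**: pixels without gradient evidence do not move.
* **Defaults** α = 1 intensity level, `n_iters = 2 epsilon` — standard
  sign-method practice, enough to reach the ball boundary with headroom.
* The [0,255] clip is applied after the ε-clip every iteration.

**Robustness to viewing conditions** (EOT) samples a fresh random geometric
transform per step — rotation θ ~ U(0, π/6), per-axis rescale
s ~ U(0.5 L, L) pixels, translation t ~ U(−L/4, L/4) pixels — and averages
the gradient through it. The rotation range is implemented one-sided exactly
as stated; a symmetric option exists behind a flag but is off by default,
since the one-sided reading is the printed one. Transforms use bilinear
interpolation with mirror-reflect out-of-frame fill (no artificial black
borders enter the objective) and are linear in pixels, so their adjoints give
exact gradients; the test suite checks the adjoint against a dense-matrix
construction. One step per iteration is the default (the stochastic-gradient
view of the expectation); `transforms_per_step` is configurable.

An optional foveated "retinal blur" layer can be prepended to the ensemble:
Gaussian smoothing whose SD grows linearly with eccentricity from a fixation
point, implemented as per-pixel interpolation between a bank of uniformly
blurred copies (linear, hence exactly differentiable). The exact profile of
the original layer is not published and it was reported as non-essential, so
the default is a no-op (σ_min = σ_max = 0) and any monotone profile is
configurable.

**Controls.** `flip_control()` mirrors a perturbation top-down or right-left:
all per-pixel magnitudes (hence all norms) are preserved as a multiset while
the pixel-to-image correspondence is destroyed. On the frozen testbed the
control's coarse-score gain is smaller than the attack's on 100% of the
batch, and a held-out scorer (never in the attack ensemble) prefers the
attack over the control on a majority — the black-box transfer analogue.

For the untargeted acceptance check, "flipping the prediction" is defined by
the binary-classifier semantics of the coarse score itself: success is a sign
change of the true category's score. With a non-exhaustive mapping an argmax
across categories would not be the ensemble's prediction, so it is not used.

## Experiments, sessions, observers

`build_pair()` assembles the five 2AFC designs from the same source image:
E1 (attack vs top-down-flipped control), E2 (targeted T↑ vs untargeted T↓),
E3 (A↑ vs right-left-flipped control), E4 (A↑ vs A′↑ with per-image support
subsampling), E5 (A↑ from two different ensembles). Side assignment is a
seeded coin flip; E4 pairs carry both questions, and `flip_question()` swaps
the consistency labelling. `build_session()` emits the canonical protocol:
104 trials of which 8 are catch trials (an unperturbed exemplar of the
queried class vs a wrong-class exemplar — an unambiguous answer) at seeded
random positions.

`simulate_observer()` is a Bernoulli observer with lapse: on non-catch trials
it chooses the adversarial-consistent side with probability
$(1-\lambda)\beta + \lambda/2$, and answers catch trials correctly with
probability `catch_accuracy`. β can vary by (question class, ε). This
observer is test scaffolding — the original study does not model
participants — and is flagged as such; it exists so that chance calibration
(β = 0.5 → 50% bias), convergence, and parameter recovery are provable
properties of the analysis pipeline.

## Analysis pipeline

`apply_exclusions()` drops every trial of participants whose failed-catch
count reaches the termination threshold: 1 for E2/E3/E5, 2 for E4.
`perceptual_bias()` is the proportion of non-catch trials on which the
consistent side was chosen, grouped as requested, with participant-level SEs
at condition level. `bias_ttest()` is the one-sample t against chance with
Cohen's d; `two_factor_anova()` is the mixed design (class between, ε
within) via `aov` error strata with partial η² from stratum sums of squares
(Greenhouse–Geisser is not applied; the design is balanced by construction).
`spearman_bias_correlation()` uses midranks with a t approximation
(df = n−2) and a Fisher-z CI. `ann_observer_bias()` scores a *held-out*
scorer's forced choices (provenance-checked; exact ties broken by a seeded,
logged coin flip; a continuous score-difference output is available behind a
flag since the per-image "model bias" is not operationally pinned down by the
source). `permutation_null()` reassigns which side counts as consistent by
permuting consistent-side labels within participant and recomputing the
indicator against actual choices — with balanced side assignment this
destroys stimulus-locked bias while preserving response habits such as a
left-button preference; permuting the indicator itself would leave every
participant mean untouched and test nothing.

## Perturbation-structure metrics

`edge_strength()` renders a perturbation about mid-gray, converts to
luminance, applies a bilateral filter (spatial σ 3 px, range σ 25 levels,
9 px window) and a Canny detector, and counts active edge elements. The
hysteresis thresholds default to low 15 / high 40 on the Sobel magnitude:
*perturbation-scale* values. After the default smoothing, a step of ~30
levels — an ε = 16 attack at full swing — peaks near magnitude 49, while
photographic-scale thresholds (50/150) would declare every bounded
perturbation edge-free. Counts are parameter-dependent; report them with
their `edge_params()`. `ms_ssim()` is standard multi-scale structural
similarity on luminance with the canonical five-scale weights (renormalized
when fewer scales fit the image; 64 px images support three).
`luminance_contrast()` returns mean intensity and RMS contrast (population
SD).

## What the acceptance suite establishes — and what it cannot

The acceptance tests pin: exact ε-ball and range constraint satisfaction
(with sub-second per-image cost at L = 64); equivalence of the coarse score
with its brute-force form to 1e-9 over 10,000 fuzzed vectors; the hand-worked
single-pixel iterates; attack efficacy on the frozen testbed (targeted ε = 16
raises the target probability on ≥ 95% of 100 images; untargeted ε = 32 flips
the binary coarse prediction on ≥ 90%); control and EOT superiority rates;
the 104/8 protocol; the 120→7 subsampling example; chance calibration and
type-I error of the full pipeline; and recovery of known observer biases
(β ∈ {0.52, 0.55, 0.60}) within 95% binomial CIs at 100 participants × 96
trials. The human effect sizes of the source study are *not* reproducible
here by construction — they require people and ImageNet-scale ensembles — and
no test in this package claims otherwise.

## Known limitations

* Scorers are shallow; transfer and EOT effects are qualitatively, not
  quantitatively, comparable to deep ensembles.
* The observer model is memoryless Bernoulli — no reaction times, learning,
  or sequential effects.
* `imagenet_nine_mapping()` documents the nine-category structure with the
  two published support counts; the remaining supports and all fine-class
  index assignments are synthetic placeholders.
* Edge counts depend on instrument parameters; only comparisons under
  identical `edge_params()` are meaningful.
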