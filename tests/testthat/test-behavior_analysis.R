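# Exclusions, bias, tests, ANOVA, correlations, permutation nulls.

make_responses <- function(beta = 0.6, n_part = 10, trials = 20, seed = 1L,
                           catch_acc = 1, classes = "round", epsilons = 8,
                           n_catch = 4L, design = "within") {
  simulate_observer(
    make_trials(n_part, trials, classes = classes, epsilons = epsilons,
                n_catch = n_catch, design = design, seed = seed),
    observer_config(beta, catch_accuracy = catch_acc,
                    seed = advpercept:::derive_seed(seed, "obs")))
}

test_that("apply_exclusions enforces the per-experiment thresholds", {
  r <- make_responses(catch_acc = 0.7, n_part = 40, seed = 3L)
  fails <- tapply(r$is_catch == 1L & r$catch_correct %in% 0L,
                  r$participant_id, sum)
  for (exp_tag in c("E2", "E3", "E5")) {
    kept <- apply_exclusions(r, exp_tag)
    expect_setequal(unique(kept$participant_id), names(fails)[fails == 0])
  }
  kept4 <- apply_exclusions(r, "E4")
  expect_setequal(unique(kept4$participant_id), names(fails)[fails < 2])
  # a participant with exactly 1 failure: dropped by E2, retained by E4
  one_fail <- names(fails)[fails == 1][1]
  expect_false(one_fail %in% apply_exclusions(r, "E2")$participant_id)
  expect_true(one_fail %in% apply_exclusions(r, "E4")$participant_id)
  # retained participants' rows are untouched
  keep_ids <- unique(kept4$participant_id)
  expect_identical(kept4[, names(r)],
                   `rownames<-`(r[r$participant_id %in% keep_ids, ], NULL))
  expect_error(apply_exclusions(r, "E9"), "exclusion rule")
})

test_that("perceptual_bias computes proportions and excludes catch trials", {
  r <- make_responses(beta = 1, n_part = 3, trials = 10, n_catch = 5L, seed = 4L)
  b <- perceptual_bias(r)
  expect_equal(b$bias, 1)
  expect_identical(b$n_trials, 30L)  # catch rows not counted
  # hand-built table: 60 of 100 consistent -> 0.6
  df <- data.frame(participant_id = "p1", pair_id = sprintf("x%d", 1:100),
                   question_class = "round", epsilon = 8,
                   chosen_side = "left",
                   chose_adversarial_consistent = rep(c(1L, 0L), c(60, 40)),
                   is_catch = 0L, catch_correct = NA_integer_)
  expect_equal(perceptual_bias(df)$bias, 0.6)
  # uniform-random observer over 10,000 trials: 0.5 within 3 binomial SE
  r2 <- make_responses(beta = 0.5, n_part = 1, trials = 10000, n_catch = 0L,
                       seed = 5L)
  expect_lt(abs(perceptual_bias(r2)$bias - 0.5), 0.015)
})

test_that("bias_ttest reproduces hand-computed values", {
  # symmetric around the null: t = 0
  expect_equal(bias_ttest(c(0.4, 0.5, 0.6))$value, 0)
  # {0.6, 0.7, 0.8} vs 0.5: t = 2 sqrt(3), df = 2, d = 2
  r <- bias_ttest(c(0.6, 0.7, 0.8))
  expect_equal(r$value, 2 * sqrt(3), tolerance = 1e-12)
  expect_identical(r$df, 2)
  expect_equal(r$effect, 2)
  # location equivariance: CI shifts, d unchanged in denominator
  r2 <- bias_ttest(c(0.6, 0.7, 0.8) + 0.1)
  expect_equal(r2$ci, r$ci + 0.1, tolerance = 1e-12)
  expect_error(bias_ttest(c(0.5, 0.5, 0.5)), "variance")
  expect_error(bias_ttest(0.7), "at least 2")
  expect_equal(bonferroni(c(0.01, 0.4), 4), c(0.04, 1))
})

test_that("two_factor_anova recovers a pure epsilon effect", {
  classes <- c("round", "angular")
  epsilons <- c(2, 4, 8, 16)
  bb <- expand.grid(question_class = classes, epsilon = epsilons,
                    stringsAsFactors = FALSE)
  bb$beta <- 0.45 + 0.015 * match(bb$epsilon, epsilons)  # epsilon effect only
  # 100 participants per class, as in the stated power construction
  r <- simulate_observer(
    make_trials(200, 24, classes = classes, epsilons = epsilons,
                design = "between", seed = 6L),
    observer_config(bb, seed = 7L))
  an <- two_factor_anova(participant_bias_table(r))
  expect_lt(an$epsilon$p, 0.01)
  expect_gt(an$class$p, 0.01)
  for (term in an) {
    expect_gte(term$effect, 0)
    expect_lte(term$effect, 1)
  }
  # all-equal cells: F = 0 (participants nested in class, crossed with eps)
  flat <- expand.grid(participant_id = sprintf("p%02d", 1:8),
                      epsilon = c(2, 8), stringsAsFactors = FALSE)
  flat$question_class <- ifelse(as.integer(sub("p", "", flat$participant_id)) <= 4,
                                "a", "b")
  flat$bias <- 0.5
  an0 <- suppressWarnings(two_factor_anova(flat))
  expect_true(is.nan(an0$class$value) || an0$class$value == 0)
  # within-participant class factor is rejected
  r_bad <- make_responses(n_part = 4, trials = 4, classes = classes,
                          epsilons = epsilons, design = "within", seed = 8L)
  expect_error(two_factor_anova(participant_bias_table(r_bad)), "between")
})

test_that("spearman correlation uses midranks and matches the rank oracle", {
  expect_equal(spearman_bias_correlation(1:10, (1:10)^3)$value, 1)
  expect_equal(spearman_bias_correlation(1:10, -(1:10))$value, -1)
  # tie case (1,2,2,3) vs (1,2,3,3): brute-force midrank oracle
  x <- c(1, 2, 2, 3); y <- c(1, 2, 3, 3)
  rx <- c(1, 2.5, 2.5, 4); ry <- c(1, 2, 3.5, 3.5)   # midranks by hand
  oracle <- sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  r <- spearman_bias_correlation(x, y)
  expect_equal(r$value, oracle, tolerance = 1e-12)
  expect_equal(r$value, 5 / 6, tolerance = 1e-12)
  expect_identical(r$df, 2)
  expect_error(spearman_bias_correlation(rep(1, 5), 1:5), "constant")
  expect_error(spearman_bias_correlation(1:3, 1:4), "paired")
})

test_that("ann_observer_bias picks higher-scoring sides and guards provenance", {
  ens <- fix_ensemble()
  holdout <- fix_scorer(2L)
  map <- fix_mapping()
  ds <- fix_dataset()
  idx <- which(ds$labels == 5L)[1:4]
  pairs <- lapply(seq_along(idx), function(k)
    build_pair("E3", ds$images[[idx[k]]], map, ens, "round",
               cfg = attack_config(epsilon = 16, seed = k),
               source_id = ds$ids[idx[k]], seed = 50L + k))
  ob <- ann_observer_bias(pairs, holdout, map)
  expect_identical(nrow(ob), length(pairs))
  # decision agrees with the sign of the score difference
  expect_identical(ob$choice == "left", ob$score_diff > 0)
  # the held-out scorer should mostly prefer the adversarial side
  expect_gt(mean(ob$consistent), 0.5)
  # a member of the generating ensemble is rejected
  expect_error(ann_observer_bias(pairs, fix_scorer(0L), map), "black-box")
})

test_that("permutation_null is calibrated under H0 and powered under H1", {
  # biased observer: small p
  r1 <- make_responses(beta = 0.75, n_part = 12, trials = 24, n_catch = 0L,
                       seed = 9L)
  pn1 <- permutation_null(r1, n_perm = 300, seed = 10L)
  expect_lt(pn1$p, 0.01)
  expect_equal(pn1$observed,
               mean(r1$chose_adversarial_consistent[r1$is_catch == 0L]))
  # chance observer: p not extreme, null centered at 0.5
  r0 <- make_responses(beta = 0.5, n_part = 12, trials = 24, n_catch = 0L,
                       seed = 11L)
  pn0 <- permutation_null(r0, n_perm = 300, seed = 12L)
  expect_gt(pn0$p, 0.05)
  expect_lt(abs(mean(pn0$null) - 0.5), 0.05)
  expect_warning(permutation_null(r0, n_perm = 50, seed = 1L), "coarse")
})

test_that("permutation p values are near-uniform under the null", {
  # moderate replicate count keeps this cheap; KS against U(0,1)
  ps <- vapply(1:60, function(k) {
    r <- make_responses(beta = 0.5, n_part = 6, trials = 16, n_catch = 0L,
                        seed = 100L + k)
    permutation_null(r, n_perm = 199, seed = 200L + k)$p
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("normality and signed-rank wrappers return sane results", {
  set.seed(13)
  x <- rnorm(50, 0.55, 0.05)
  expect_gt(shapiro_wilk(x)$p, 0.001)
  expect_lt(wilcoxon_signed_rank(x, null = 0.5)$p, 0.01)
  expect_gt(wilcoxon_signed_rank(rnorm(50, 0.5, 0.05), null = 0.5)$p, 0.01)
})
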