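# Synthetic dataset, toy scorer training, simulated observers.

test_that("generate_dataset is balanced, in range, and seed-deterministic", {
  spec <- dataset_spec(n_fine_classes = 6L, images_per_class = 5L, seed = 21L)
  ds <- generate_dataset(spec)
  expect_length(ds$images, 30L)
  expect_identical(as.vector(table(ds$labels)), rep(5L, 6L))
  ranges <- vapply(ds$images, range, numeric(2))
  expect_gte(min(ranges), 0)
  expect_lte(max(ranges), 255)
  ds2 <- generate_dataset(spec)
  expect_identical(ds$images, ds2$images)
  # different seed changes pixels
  ds3 <- generate_dataset(dataset_spec(n_fine_classes = 6L,
                                       images_per_class = 5L, seed = 22L))
  expect_gt(max(abs(ds$images[[1]] - ds3$images[[1]])), 0)
})

test_that("zero noise and zero jitter make within-class images identical", {
  spec <- dataset_spec(n_fine_classes = 2L, images_per_class = 3L,
                       noise_sd = 0, jitter = 0, seed = 4L,
                       fine_to_coarse = coarse_mapping(list(a = 1L), 2L))
  ds <- generate_dataset(spec)
  expect_identical(ds$images[[1]], ds$images[[2]])
  expect_identical(ds$images[[2]], ds$images[[3]])
  expect_gt(max(abs(ds$images[[1]] - ds$images[[4]])), 0)  # across classes
})

test_that("degenerate specs are rejected", {
  expect_error(dataset_spec(n_fine_classes = 1L), "n_fine_classes")
  expect_error(dataset_spec(images_per_class = 0L), "images_per_class")
  expect_error(dataset_spec(L = 8L), "L must be")
  expect_error(dataset_spec(noise_sd = -1), "noise_sd")
})

test_that("dataset specs round-trip through the config file", {
  spec <- dataset_spec(images_per_class = 7L, noise_sd = 3.5, seed = 9L)
  path <- tempfile(fileext = ".cfg")
  write_dataset_spec(spec, path)
  spec2 <- read_dataset_spec(path)
  expect_equal(spec2$images_per_class, 7L)
  expect_equal(spec2$noise_sd, 3.5)
  expect_identical(spec2$fine_to_coarse$sets, spec$fine_to_coarse$sets)
  unlink(c(path, paste0(path, ".mapping")))
})

test_that("toy scorers learn the fixture dataset and diagnose failure", {
  sc <- fix_scorer(0L)
  expect_gte(sc$accuracy, 0.9)
  # unreachable configured minimum -> diagnostic error naming the accuracy
  expect_error(fit_toy_scorer(fix_dataset(),
                              train_config(seed = 0L, epochs = 1L,
                                           min_accuracy = 0.99)),
               "accuracy")
})

test_that("a linearly separable 2-class spec is fit perfectly", {
  spec <- dataset_spec(n_fine_classes = 2L, images_per_class = 10L,
                       noise_sd = 1, jitter = 0.02, seed = 13L,
                       fine_to_coarse = coarse_mapping(list(a = 1L), 2L))
  ds <- generate_dataset(spec)
  sc <- fit_toy_scorer(ds, train_config(seed = 2L, holdout_frac = 0.2))
  X <- t(vapply(ds$images, function(im) as.vector(im) / 255, numeric(64 * 64 * 3)))
  pred <- vapply(ds$images, function(im) which.max(score_logits(sc, im)), integer(1))
  expect_identical(pred, ds$labels)  # training-set accuracy 1.0
  # independent linear oracle: nearest-centroid classifier also separates
  mu1 <- colMeans(X[ds$labels == 1L, ]); mu2 <- colMeans(X[ds$labels == 2L, ])
  w <- mu1 - mu2
  b <- -sum(w * (mu1 + mu2)) / 2
  oracle <- ifelse(X %*% w + b > 0, 1L, 2L)
  expect_identical(as.integer(oracle), ds$labels)
})

test_that("simulate_observer honors bias, lapse, and catch parameters", {
  # saturated bias: every non-catch choice is adversarial-consistent
  tr <- make_trials(2, 10, classes = "round", epsilons = 8, n_catch = 2, seed = 1L)
  r <- simulate_observer(tr, observer_config(1, lapse_rate = 0, seed = 2L))
  validate_responses(r)
  expect_true(all(r$chose_adversarial_consistent[r$is_catch == 0L] == 1L))
  expect_true(all(r$catch_correct[r$is_catch == 1L] == 1L))
  expect_true(all(is.na(r$catch_correct[r$is_catch == 0L])))
  # chance observer over 10,000 trials: within 3 binomial SE of 0.5
  tr2 <- make_trials(1, 10000, seed = 3L)
  r2 <- simulate_observer(tr2, observer_config(0.5, seed = 4L))
  expect_lt(abs(mean(r2$chose_adversarial_consistent) - 0.5), 0.015)
  # beta = 0.55 with lapse 0.2: converges to (1-lambda) beta + lambda / 2
  r3 <- simulate_observer(tr2, observer_config(0.55, lapse_rate = 0.2, seed = 5L))
  expected <- 0.8 * 0.55 + 0.2 * 0.5
  expect_lt(abs(mean(r3$chose_adversarial_consistent) - expected),
            3 * sqrt(expected * (1 - expected) / 10000))
  # pooled bias over 100 x 96 trials within 0.02 of beta = 0.55
  tr4 <- make_trials(100, 96, seed = 6L)
  r4 <- simulate_observer(tr4, observer_config(0.55, seed = 7L))
  expect_lt(abs(mean(r4$chose_adversarial_consistent) - 0.55), 0.02)
  # determinism
  r5 <- simulate_observer(tr, observer_config(0.7, seed = 9L))
  r6 <- simulate_observer(tr, observer_config(0.7, seed = 9L))
  expect_identical(r5, r6)
  # missing consistency label -> error
  tr_bad <- tr
  tr_bad$consistent_side[1] <- NA
  expect_error(simulate_observer(tr_bad, observer_config(0.5)), "consistent")
})

test_that("per-condition bias tables drive condition-dependent observers", {
  bb <- data.frame(question_class = c("round", "round"), epsilon = c(2, 16),
                   beta = c(0.5, 0.9))
  tr <- make_trials(20, 50, classes = "round", epsilons = c(2, 16), seed = 8L)
  r <- simulate_observer(tr, observer_config(bb, seed = 9L))
  b <- perceptual_bias(r)
  expect_lt(abs(b$bias[b$epsilon == 2] - 0.5), 0.05)
  expect_gt(b$bias[b$epsilon == 16], 0.8)
  expect_error(simulate_observer(make_trials(1, 2, epsilons = 4), observer_config(bb)),
               "no beta")
})
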