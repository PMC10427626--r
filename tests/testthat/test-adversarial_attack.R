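# iFGSM steps, transforms, attack generation, flip controls.

test_that("ifgsm_step reproduces the single-pixel worked examples exactly", {
  px <- function(v) array(v, c(1, 1, 1))
  # zero gradient: no movement (sgn(0) = 0)
  expect_equal(ifgsm_step(px(100), px(100), px(0), 1, 4), px(100))
  # current = source = 100, grad +0.7, alpha 1, eps 4 -> 101
  expect_equal(ifgsm_step(px(100), px(100), px(0.7), 1, 4), px(101))
  # current 103.8, source 100, grad +0.2, alpha 1, eps 4 -> 104 (eps clip)
  expect_equal(ifgsm_step(px(103.8), px(100), px(0.2), 1, 4), px(104))
  # [0,255] range clip after the eps clip
  expect_equal(ifgsm_step(px(254.5), px(254), px(1), 1, 4), px(255))
  expect_error(ifgsm_step(px(1), px(1), px(1), 0, 4), "alpha")
  expect_error(ifgsm_step(px(1), array(1, c(2, 1, 1)), px(1), 1, 4), "dimensions")
})

test_that("sample_transform draws stay in the stated ranges and are seeded", {
  cfg <- attack_config(eot = TRUE)
  L <- 64
  draws <- lapply(1:2000, function(i) sample_transform(cfg, L, seed = i))
  theta <- vapply(draws, `[[`, numeric(1), "theta")
  sx <- vapply(draws, `[[`, numeric(1), "s_x")
  tx <- vapply(draws, `[[`, numeric(1), "t_x")
  expect_true(all(theta >= 0 & theta <= pi / 6))
  expect_true(all(sx >= 0.5 * L & sx <= L))
  expect_true(all(tx >= -L / 4 & tx <= L / 4))
  # symmetric uniform translation: mean near 0 within 3 SE
  expect_lt(abs(mean(tx)), 3 * (L / 4) / sqrt(3 * length(tx)))
  expect_identical(sample_transform(cfg, L, seed = 7),
                   sample_transform(cfg, L, seed = 7))
  # symmetric rotation option
  cfgs <- attack_config(eot = TRUE, symmetric_rotation = TRUE)
  th2 <- vapply(1:500, function(i) sample_transform(cfgs, L, seed = i)$theta,
                numeric(1))
  expect_true(any(th2 < 0) && all(abs(th2) <= pi / 6))
})

test_that("apply_transform: identity, rotation round-trip, exact adjoint", {
  img <- fix_source()
  idt <- advpercept:::identity_transform(64L)
  expect_lt(max(abs(apply_transform(img, idt) - img)), 1e-6)
  # rotate theta then -theta: smooth-image interior recovered within 2 levels
  gx <- matrix(seq_len(64), 64, 64, byrow = TRUE)
  gy <- matrix(seq_len(64), 64, 64)
  smooth <- image_tensor(array(rep(
    128 + 60 * sin(2 * pi * gx / 64) * cos(2 * pi * gy / 64), 3), c(64, 64, 3)))
  rot <- function(theta) structure(list(theta = theta, s_x = 64, s_y = 64,
                                        t_x = 0, t_y = 0, L = 64),
                                   class = "transform_sample")
  # 10 degree rotation; a 12 px margin keeps every intermediate sample inside
  # the frame so no mirror-filled pixels enter the round trip
  back <- apply_transform(apply_transform(smooth, rot(pi / 18)), rot(-pi / 18))
  interior <- back[13:52, 13:52, ] - unclass(smooth)[13:52, 13:52, ]
  expect_lt(max(abs(interior)), 2)
  # adjoint identity <A x, y> = <x, A^T y> (transform is linear in pixels)
  tr <- sample_transform(attack_config(eot = TRUE), 64, seed = 12)
  set.seed(3)
  x <- array(runif(64 * 64 * 3, 0, 255), c(64, 64, 3))
  y <- array(runif(64 * 64 * 3), c(64, 64, 3))
  Ax <- apply_transform(image_tensor(x), tr)
  Aty <- advpercept:::transform_adjoint(y, tr, 64L)
  expect_equal(sum(unclass(Ax) * y), sum(x * Aty), tolerance = 1e-10)
  # input-gradient of mean output matches finite differences
  f <- function(z) mean(apply_transform(z, tr))
  g <- advpercept:::transform_adjoint(array(1 / length(x), dim(x)), tr, 64L)
  set.seed(14)
  for (k in 1:25) {
    i <- sample(64, 1); j <- sample(64, 1); ch <- sample(3, 1)
    fd <- fd_probe(f, image_tensor(x), i, j, ch, h = 1e-2)
    expect_lt(abs(g[i, j, ch] - fd) / max(abs(fd), 1e-9), 1e-3)
  }
})

test_that("attack objective gives the worked values and complement identity", {
  ens <- fix_ensemble()
  map <- fix_mapping()
  img <- fix_source()
  # independent evaluation of the binary cross entropy from the coarse score
  s <- coarse_score(ensemble_logits(ens, img), map, "round")
  expect_equal(attack_objective(img, "round", "targeted", ens, map),
               advpercept:::softplus(-s), tolerance = 1e-12)
  # stable softplus agrees with the naive -log(P) wherever P is representable
  for (sv in c(-20, -1, 0, 2.5, 20)) {
    expect_equal(advpercept:::softplus(-sv), -log(stats::plogis(sv)),
                 tolerance = 1e-7)
  }
  # P = 0.5 -> J = ln 2; P -> 1 -> J -> 0
  expect_equal(advpercept:::softplus(0), log(2))
  expect_equal(advpercept:::softplus(-1e4), 0, tolerance = 1e-12)
  # untargeted loss equals targeted with P replaced by 1 - P
  expect_equal(attack_objective(img, "round", "untargeted", ens, map),
               advpercept:::softplus(s), tolerance = 1e-12)
})

test_that("generate_adversarial obeys both clip constraints exactly", {
  ens <- fix_ensemble()
  map <- fix_mapping()
  img <- fix_source()
  for (eps in c(0.5, 4)) {
    res <- generate_adversarial(img, ens, map, "round",
                                attack_config(epsilon = eps, seed = 5))
    expect_lte(max(abs(res$delta)), eps + 1e-12)
    expect_gte(min(res$image), 0)
    expect_lte(max(res$image), 255)
    expect_equal(unclass(res$image) - unclass(img), res$delta, tolerance = 1e-12)
  }
})

test_that("targeted attacks raise the target coarse probability", {
  ens <- fix_ensemble()
  map <- fix_mapping()
  ds <- fix_dataset()
  idx <- which(ds$labels %in% c(2L, 5L))[1:6]
  for (i in idx) {
    src <- ds$images[[i]]
    p0 <- coarse_prob(coarse_score(ensemble_logits(ens, src), map, "round"))
    res <- generate_adversarial(src, ens, map, "round",
                                attack_config(epsilon = 16, seed = i))
    p1 <- coarse_prob(coarse_score(ensemble_logits(ens, res$image), map, "round"))
    expect_gt(p1, p0)
  }
})

test_that("flip controls mirror the delta and blunt the attack", {
  # mirror arithmetic on a tiny delta
  d <- array(0, c(2, 2, 3))
  d[, , 1] <- matrix(c(1, 3, 2, 4), 2, 2)  # [[1,2],[3,4]] row-major
  fh <- flip_control(d, "horizontal")
  expect_equal(fh[, , 1], matrix(c(2, 4, 1, 3), 2, 2))  # [[2,1],[4,3]]
  fv <- flip_control(d, "vertical")
  expect_equal(fv[, , 1], matrix(c(3, 1, 4, 2), 2, 2))  # [[3,4],[1,2]]
  # involution and norm preservation
  set.seed(6)
  delta <- array(rnorm(64 * 64 * 3), c(64, 64, 3))
  for (ax in c("horizontal", "vertical")) {
    expect_identical(flip_control(flip_control(delta, ax), ax), delta)
    expect_equal(max(abs(flip_control(delta, ax))), max(abs(delta)))
    expect_equal(sort(as.vector(abs(flip_control(delta, ax)))),
                 sort(as.vector(abs(delta))))
  }
  # control efficacy: flipped perturbation yields a smaller coarse-score gain
  ens <- fix_ensemble()
  map <- fix_mapping()
  ds <- fix_dataset()
  wins <- 0L
  idx <- which(ds$labels == 5L)[1:8]
  for (i in idx) {
    src <- ds$images[[i]]
    res <- generate_adversarial(src, ens, map, "round",
                                attack_config(epsilon = 8, seed = i))
    s0 <- coarse_score(ensemble_logits(ens, src), map, "round")
    gain_adv <- coarse_score(ensemble_logits(ens, res$image), map, "round") - s0
    ctrl <- image_tensor(advpercept:::clip(
      unclass(src) + flip_control(res$delta, "horizontal"), 0, 255))
    gain_ctl <- coarse_score(ensemble_logits(ens, ctrl), map, "round") - s0
    wins <- wins + (gain_adv > gain_ctl)
  }
  expect_gte(wins, 7L)
})

test_that("attacks transfer to a held-out scorer (black-box analogue)", {
  ens <- fix_ensemble()          # seeds 0 and 1
  holdout <- fix_scorer(2L)      # not in the ensemble
  map <- fix_mapping()
  ds <- fix_dataset()
  idx <- which(ds$labels == 5L)[1:8]
  prefers <- 0L
  for (i in idx) {
    src <- ds$images[[i]]
    res <- generate_adversarial(src, ens, map, "round",
                                attack_config(epsilon = 16, seed = i))
    ctrl <- image_tensor(advpercept:::clip(
      unclass(src) + flip_control(res$delta, "horizontal"), 0, 255))
    s_adv <- coarse_score(score_logits(holdout, res$image), map, "round")
    s_ctl <- coarse_score(score_logits(holdout, ctrl), map, "round")
    prefers <- prefers + (s_adv > s_ctl)
  }
  expect_gt(prefers, length(idx) / 2)
})
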