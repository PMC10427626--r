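# Synthetic testbed: labelled shape images, toy classifiers, 2AFC observers.
#
# The image population replaces a photographic dataset with parametric 2-D
# shapes: six fine classes (ellipse, rectangle, triangle, annulus, cross,
# bar), each carrying a class-specific texture frequency, with jittered
# position and size and additive Gaussian pixel noise. Fine classes nest in
# coarse categories with unequal support, mirroring the breeds-to-dog
# structure of large-scale label taxonomies while staying learnable by a
# small classifier in seconds.

FINE_SHAPES <- c("ellipse", "rectangle", "triangle", "annulus", "cross", "bar")

#' Specification of a synthetic labelled image population
#'
#' @param n_fine_classes number of fine classes (2..6, drawn from the shape
#'   catalogue in order).
#' @param images_per_class images generated per fine class.
#' @param L image side length in pixels (>= 16; default 64 keeps attacks in
#'   CPU-seconds).
#' @param noise_sd SD of additive Gaussian pixel noise, intensity units.
#' @param jitter relative position/size jitter of the shapes (0..0.5).
#' @param fine_to_coarse optional [coarse_mapping()]; default
#'   [default_coarse_mapping()] for `n_fine_classes = 6`.
#' @param seed integer RNG seed.
#' @return object of class `dataset_spec`.
#' @export
dataset_spec <- function(n_fine_classes = 6L, images_per_class = 50L, L = 64L,
                         noise_sd = 8, jitter = 0.1, fine_to_coarse = NULL,
                         seed = 1L) {
  n_fine_classes <- as.integer(n_fine_classes)
  images_per_class <- as.integer(images_per_class)
  if (n_fine_classes < 2L || n_fine_classes > length(FINE_SHAPES))
    stop_advpercept("n_fine_classes must be in 2..", length(FINE_SHAPES))
  if (images_per_class < 1L) stop_advpercept("images_per_class must be >= 1")
  if (L < 16L) stop_advpercept("L must be >= 16")
  if (noise_sd < 0) stop_advpercept("noise_sd must be >= 0")
  if (jitter < 0 || jitter > 0.5) stop_advpercept("jitter must be in [0, 0.5]")
  if (is.null(fine_to_coarse) && n_fine_classes == 6L)
    fine_to_coarse <- default_coarse_mapping()
  structure(list(n_fine_classes = n_fine_classes,
                 images_per_class = images_per_class, L = as.integer(L),
                 noise_sd = noise_sd, jitter = jitter,
                 fine_to_coarse = fine_to_coarse, seed = as.integer(seed)),
            class = "dataset_spec")
}

#' Default coarse mapping of the synthetic testbed
#'
#' Two coarse categories of unequal support over the six fine shapes:
#' `round` = \{ellipse, annulus\} and `angular` = \{rectangle, triangle,
#' bar\}. The cross (class 5) belongs to no coarse category and therefore
#' always counts in the complement sum, exercising the non-exhaustive
#' coverage rule.
#' @return a [coarse_mapping()] with K = 6.
#' @export
default_coarse_mapping <- function() {
  coarse_mapping(list(round = c(1L, 4L), angular = c(2L, 3L, 6L)), 6L)
}

# Binary mask of one shape instance on an L x L grid. cx, cy in pixels,
# size = half-extent in pixels, all parameters already jittered.
shape_mask <- function(shape, L, cx, cy, size) {
  rows <- matrix(seq_len(L), L, L)
  cols <- matrix(seq_len(L), L, L, byrow = TRUE)
  dx <- cols - cx
  dy <- rows - cy
  switch(shape,
    ellipse = (dx / size)^2 + (dy / (0.65 * size))^2 <= 1,
    rectangle = abs(dx) <= size & abs(dy) <= 0.6 * size,
    triangle = (dy <= 0.8 * size) & (dy >= -0.8 * size) &
      (abs(dx) <= (dy + 0.8 * size) * 0.625),
    annulus = {
      r2 <- (dx / size)^2 + (dy / size)^2
      r2 <= 1 & r2 >= 0.45^2
    },
    cross = (abs(dx) <= 0.3 * size & abs(dy) <= size) |
      (abs(dy) <= 0.3 * size & abs(dx) <= size),
    bar = abs(dx) <= 0.25 * size & abs(dy) <= size,
    stop_advpercept("unknown shape '", shape, "'"))
}

# One image of fine class k: background + textured shape + noise.
render_class_image <- function(k, spec) {
  L <- spec$L
  j <- spec$jitter
  cx <- (0.5 + stats::runif(1, -j, j)) * L
  cy <- (0.5 + stats::runif(1, -j, j)) * L
  size <- (0.30 + stats::runif(1, -j / 2, j / 2)) * L
  mask <- shape_mask(FINE_SHAPES[k], L, cx, cy, size)
  # class-specific texture: fixed-phase grating, frequency/orientation per class
  freq <- 2 + k                       # cycles per image
  ang <- (k - 1) * pi / spec$n_fine_classes
  rows <- matrix(seq_len(L), L, L)
  cols <- matrix(seq_len(L), L, L, byrow = TRUE)
  carrier <- cos(2 * pi * freq * (cos(ang) * cols + sin(ang) * rows) / L)
  img <- matrix(96, L, L)
  img[mask] <- 168 + 36 * carrier[mask]
  px <- array(rep(img, 3), c(L, L, 3))
  # mild channel tint so the three channels are not identical
  px[, , 1] <- px[, , 1] * 1.03
  px[, , 3] <- px[, , 3] * 0.97
  if (spec$noise_sd > 0)
    px <- px + array(stats::rnorm(length(px), 0, spec$noise_sd), dim(px))
  image_tensor(clip(px, 0, 255))
}

#' Generate a labelled synthetic image collection
#'
#' @param spec a [dataset_spec()].
#' @return object of class `synthetic_dataset`: list with `images` (list of
#'   image tensors), `labels` (integer fine labels), `ids` (character image
#'   ids) and the generating `spec`. Balanced by construction and
#'   bit-reproducible for a fixed seed.
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "dataset_spec"))
  n <- spec$n_fine_classes * spec$images_per_class
  labels <- rep(seq_len(spec$n_fine_classes), each = spec$images_per_class)
  images <- vector("list", n)
  with_seed(spec$seed, {
    for (i in seq_len(n)) images[[i]] <- render_class_image(labels[i], spec)
  })
  structure(list(images = images, labels = labels,
                 ids = sprintf("img%04d", seq_len(n)), spec = spec),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf("synthetic_dataset: %d images, %d fine classes, L = %d\n",
              length(x$images), x$spec$n_fine_classes, x$spec$L))
  invisible(x)
}

#' Training configuration for a toy scorer
#'
#' @param family `"linear"` (softmax regression on pixels) or `"rf"` (fixed
#'   random-feature tanh network; the stand-in for a different architecture
#'   family).
#' @param seed seed for initialization, feature draw, and the holdout split.
#' @param epochs full-batch gradient steps.
#' @param lr learning rate.
#' @param l2 ridge penalty on the weights.
#' @param n_features hidden width for the `rf` family.
#' @param holdout_frac fraction of images held out for validation accuracy.
#' @param min_accuracy training aborts with a diagnostic error if held-out
#'   top-1 accuracy falls below this.
#' @return object of class `train_config`.
#' @export
train_config <- function(family = c("linear", "rf"), seed = 0L, epochs = 300L,
                         lr = 0.5, l2 = 1e-4, n_features = 256L,
                         holdout_frac = 0.2, min_accuracy = 0.5) {
  family <- match.arg(family)
  structure(list(family = family, seed = as.integer(seed),
                 epochs = as.integer(epochs), lr = lr, l2 = l2,
                 n_features = as.integer(n_features),
                 holdout_frac = holdout_frac, min_accuracy = min_accuracy),
            class = "train_config")
}

#' Fit a small differentiable classifier to a synthetic dataset
#'
#' Full-batch gradient descent with momentum on the softmax cross-entropy.
#' Both families satisfy the differentiable-scorer contract
#' ([score_logits()] / [input_gradient()]) with exact analytic gradients.
#'
#' @param dataset a [generate_dataset()] result with at least 2 fine classes.
#' @param cfg a [train_config()].
#' @return a scorer (classes `<family>_scorer`, `toy_scorer`) carrying its
#'   held-out accuracy, family, seed-derived `id`, and parameter matrices.
#' @export
fit_toy_scorer <- function(dataset, cfg = train_config()) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  K <- dataset$spec$n_fine_classes
  if (K < 2) stop_advpercept("need at least 2 fine classes to fit a scorer")
  n <- length(dataset$images)
  L <- dataset$spec$L
  X <- t(vapply(dataset$images, flatten_image, numeric(L * L * 3)))
  y <- dataset$labels
  with_seed(cfg$seed, {
    holdout <- sort(unlist(lapply(split(seq_len(n), y), function(ix)
      sample(ix, max(1L, round(cfg$holdout_frac * length(ix)))))))
    A <- if (cfg$family == "rf")
      matrix(stats::rnorm(cfg$n_features * ncol(X), 0, 1 / sqrt(ncol(X))),
             cfg$n_features, ncol(X)) else NULL
    W0 <- matrix(stats::rnorm(K * if (cfg$family == "rf") cfg$n_features else ncol(X),
                              0, 0.01), K)
  })
  train <- setdiff(seq_len(n), holdout)
  feats <- function(Xm) if (cfg$family == "rf") tanh(Xm %*% t(A)) else Xm
  H <- feats(X[train, , drop = FALSE])
  Y <- diag(K)[y[train], , drop = FALSE]
  W <- W0
  b <- numeric(K)
  vW <- 0 * W; vb <- numeric(K)
  for (e in seq_len(cfg$epochs)) {
    Z <- H %*% t(W) + matrix(b, nrow(H), K, byrow = TRUE)
    Z <- Z - apply(Z, 1, max)
    P <- exp(Z); P <- P / rowSums(P)
    G <- (P - Y) / nrow(H)
    gW <- t(G) %*% H + 2 * cfg$l2 * W
    gb <- colSums(G)
    vW <- 0.9 * vW - cfg$lr * gW
    vb <- 0.9 * vb - cfg$lr * gb
    W <- W + vW
    b <- b + vb
  }
  Hv <- feats(X[holdout, , drop = FALSE])
  pred <- max.col(Hv %*% t(W) + matrix(b, nrow(Hv), K, byrow = TRUE))
  acc <- mean(pred == y[holdout])
  if (acc < cfg$min_accuracy)
    stop_advpercept(sprintf(
      "toy scorer reached held-out accuracy %.3f < configured minimum %.3f",
      acc, cfg$min_accuracy))
  sc <- list(W = W, b = b, A = A, K = K, L = L, family = cfg$family,
             id = sprintf("%s_s%d_e%d", cfg$family, cfg$seed, cfg$epochs),
             accuracy = acc, seed = cfg$seed)
  class(sc) <- c(paste0(cfg$family, "_scorer"), "toy_scorer")
  sc
}

#' @export
print.toy_scorer <- function(x, ...) {
  cat(sprintf("toy_scorer [%s] K=%d L=%d held-out accuracy=%.3f id=%s\n",
              x$family, x$K, x$L, x$accuracy, x$id))
  invisible(x)
}

#' Configuration of a simulated Bernoulli 2AFC observer
#'
#' On a non-catch trial the observer chooses the adversarial-consistent side
#' with probability `(1 - lapse) * beta + lapse * 0.5`: with probability
#' `lapse` it ignores the stimulus and guesses. Catch trials are answered
#' correctly with probability `catch_accuracy`. Scaffolding only: real
#' participants are not modelled by the source study.
#'
#' @param bias_by_condition either a single `beta` in `[0, 1]` applied to all
#'   conditions, or a data.frame with columns `question_class`, `epsilon`,
#'   `beta`.
#' @param lapse_rate lapse probability in `[0, 1]`.
#' @param catch_accuracy probability of answering a catch trial correctly.
#' @param seed RNG seed.
#' @return object of class `observer_config`.
#' @export
observer_config <- function(bias_by_condition = 0.5, lapse_rate = 0,
                            catch_accuracy = 1, seed = 1L) {
  if (is.numeric(bias_by_condition)) {
    if (any(bias_by_condition < 0 | bias_by_condition > 1))
      stop_advpercept("beta must lie in [0, 1]")
  } else if (is.data.frame(bias_by_condition)) {
    need <- c("question_class", "epsilon", "beta")
    if (!all(need %in% names(bias_by_condition)))
      stop_advpercept("bias table needs columns ", paste(need, collapse = ", "))
    if (any(bias_by_condition$beta < 0 | bias_by_condition$beta > 1))
      stop_advpercept("beta must lie in [0, 1]")
  } else stop_advpercept("bias_by_condition must be a scalar or a data.frame")
  if (lapse_rate < 0 || lapse_rate > 1) stop_advpercept("lapse_rate in [0, 1]")
  if (catch_accuracy < 0 || catch_accuracy > 1)
    stop_advpercept("catch_accuracy in [0, 1]")
  structure(list(bias_by_condition = bias_by_condition, lapse_rate = lapse_rate,
                 catch_accuracy = catch_accuracy, seed = as.integer(seed)),
            class = "observer_config")
}

lookup_beta <- function(cfg, question_class, epsilon) {
  bb <- cfg$bias_by_condition
  if (is.numeric(bb)) return(rep(bb[1], length(question_class)))
  key <- paste(question_class, epsilon)
  tab <- stats::setNames(bb$beta, paste(bb$question_class, bb$epsilon))
  beta <- unname(tab[key])
  if (anyNA(beta))
    stop_advpercept("no beta configured for condition(s): ",
                    paste(unique(key[is.na(beta)]), collapse = "; "))
  beta
}

#' Build a trial grid for simulated observers
#'
#' Balanced plan: consistent sides alternate 50/50 and `n_catch` catch
#' trials are appended per participant. With `design = "within"` each
#' participant sees every (class, epsilon) cell equally often; with
#' `design = "between"` each participant is assigned a single question class
#' (round-robin over `classes`) and sees all epsilon levels — the layout the
#' mixed two-factor ANOVA expects.
#'
#' @param n_participants number of simulated participants.
#' @param trials_per_cell non-catch trials per participant per
#'   (class, epsilon) cell.
#' @param classes character vector of question classes.
#' @param epsilons numeric vector of perturbation magnitudes.
#' @param n_catch catch trials per participant.
#' @param design `"within"` or `"between"` (class assignment; see above).
#' @param seed seed for the side-assignment shuffle.
#' @return data.frame of trials suitable for [simulate_observer()].
#' @export
make_trials <- function(n_participants, trials_per_cell, classes = "round",
                        epsilons = 16, n_catch = 0L,
                        design = c("within", "between"), seed = 1L) {
  design <- match.arg(design)
  out <- vector("list", n_participants)
  with_seed(seed, {
    for (p in seq_len(n_participants)) {
      p_classes <- if (design == "between")
        classes[(p - 1L) %% length(classes) + 1L] else classes
      grid <- expand.grid(question_class = p_classes, epsilon = epsilons,
                          rep = seq_len(trials_per_cell),
                          stringsAsFactors = FALSE)
      sides <- sample(rep(c("left", "right"), length.out = nrow(grid)))
      df <- data.frame(participant_id = sprintf("p%03d", p),
                       pair_id = sprintf("pair%05d", seq_len(nrow(grid))),
                       question_class = grid$question_class,
                       epsilon = grid$epsilon,
                       consistent_side = sides,
                       is_catch = 0L,
                       catch_correct_side = NA_character_,
                       stringsAsFactors = FALSE)
      if (n_catch > 0) {
        df_c <- data.frame(participant_id = sprintf("p%03d", p),
                           pair_id = sprintf("catch%03d", seq_len(n_catch)),
                           question_class = p_classes[1],
                           epsilon = 0,
                           consistent_side = NA_character_,
                           is_catch = 1L,
                           catch_correct_side = sample(c("left", "right"),
                                                       n_catch, replace = TRUE),
                           stringsAsFactors = FALSE)
        df <- rbind(df, df_c)
      }
      out[[p]] <- df
    }
  })
  do.call(rbind, out)
}

#' Simulate 2AFC responses for a trial table
#'
#' @param trials data.frame with columns `participant_id`, `pair_id`,
#'   `question_class`, `epsilon`, `consistent_side` (`"left"`/`"right"`, may
#'   be `NA` on catch trials only), `is_catch` (0/1), and
#'   `catch_correct_side` for catch rows.
#' @param config an [observer_config()].
#' @return a response table data.frame with the standard columns
#'   (`participant_id`, `pair_id`, `question_class`, `epsilon`,
#'   `chosen_side`, `chose_adversarial_consistent`, `is_catch`,
#'   `catch_correct`); see [validate_responses()].
#' @export
simulate_observer <- function(trials, config = observer_config()) {
  stopifnot(is.data.frame(trials))
  need <- c("participant_id", "pair_id", "question_class", "epsilon",
            "consistent_side", "is_catch")
  miss <- setdiff(need, names(trials))
  if (length(miss)) stop_advpercept("trials lacks columns: ",
                                    paste(miss, collapse = ", "))
  noncatch <- trials$is_catch == 0L
  if (any(noncatch & (is.na(trials$consistent_side) |
                      !trials$consistent_side %in% c("left", "right"))))
    stop_advpercept("every non-catch trial must label its adversarial-consistent side")
  n <- nrow(trials)
  chosen <- character(n)
  chose_cons <- rep(NA_integer_, n)
  catch_ok <- rep(NA_integer_, n)
  with_seed(config$seed, {
    if (any(noncatch)) {
      beta <- lookup_beta(config, trials$question_class[noncatch],
                          trials$epsilon[noncatch])
      p_cons <- (1 - config$lapse_rate) * beta + config$lapse_rate * 0.5
      pick <- stats::rbinom(sum(noncatch), 1L, p_cons)
      cons <- trials$consistent_side[noncatch]
      other <- ifelse(cons == "left", "right", "left")
      chosen[noncatch] <- ifelse(pick == 1L, cons, other)
      chose_cons[noncatch] <- pick
    }
    if (any(!noncatch)) {
      ok <- stats::rbinom(sum(!noncatch), 1L, config$catch_accuracy)
      corr <- trials$catch_correct_side[!noncatch]
      if (anyNA(corr))
        stop_advpercept("catch trials must carry catch_correct_side")
      chosen[!noncatch] <- ifelse(ok == 1L, corr,
                                  ifelse(corr == "left", "right", "left"))
      catch_ok[!noncatch] <- ok
    }
  })
  data.frame(participant_id = trials$participant_id,
             pair_id = trials$pair_id,
             question_class = trials$question_class,
             epsilon = trials$epsilon,
             chosen_side = chosen,
             chose_adversarial_consistent = chose_cons,
             is_catch = trials$is_catch,
             catch_correct = catch_ok,
             stringsAsFactors = FALSE)
}

#' Write / read a dataset spec as a key/value config file
#'
#' Versioned plain-text schema: `key: value` lines; the coarse mapping, if
#' present, is written next to it by [write_mapping()].
#' @param spec a [dataset_spec()].
#' @param path output file path.
#' @export
write_dataset_spec <- function(spec, path) {
  lines <- c("schema: advpercept-dataset-spec v1",
             sprintf("n_fine_classes: %d", spec$n_fine_classes),
             sprintf("images_per_class: %d", spec$images_per_class),
             sprintf("L: %d", spec$L),
             sprintf("noise_sd: %.17g", spec$noise_sd),
             sprintf("jitter: %.17g", spec$jitter),
             sprintf("seed: %d", spec$seed))
  writeLines(lines, path)
  if (!is.null(spec$fine_to_coarse))
    write_mapping(spec$fine_to_coarse, paste0(path, ".mapping"))
  invisible(path)
}

#' @rdname write_dataset_spec
#' @export
read_dataset_spec <- function(path) {
  lines <- readLines(path)
  if (!grepl("advpercept-dataset-spec v1", lines[1]))
    stop_advpercept("unrecognized dataset spec schema in ", path)
  kv <- strsplit(lines[-1], ": ", fixed = TRUE)
  vals <- stats::setNames(vapply(kv, `[`, character(1), 2),
                          vapply(kv, `[`, character(1), 1))
  mapping_path <- paste0(path, ".mapping")
  dataset_spec(n_fine_classes = as.integer(vals[["n_fine_classes"]]),
               images_per_class = as.integer(vals[["images_per_class"]]),
               L = as.integer(vals[["L"]]),
               noise_sd = as.numeric(vals[["noise_sd"]]),
               jitter = as.numeric(vals[["jitter"]]),
               fine_to_coarse = if (file.exists(mapping_path))
                 read_mapping(mapping_path) else NULL,
               seed = as.integer(vals[["seed"]]))
}
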