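# Differentiable-scorer contract, ensembling, calibration, retinal blur.
#
# A scorer maps an image tensor to a length-K vector of fine-class logits and
# exposes the exact vector-Jacobian product with respect to the input pixels.
# Both toy families shipped here (a linear softmax classifier and a fixed
# random-feature network) have closed-form input gradients, so attacks need
# no numerical differentiation; finite differences serve only as a test
# oracle.

#' Fine-class logits of a scorer on an image
#'
#' @param scorer a differentiable scorer (see [fit_toy_scorer()]).
#' @param image an `L x L x 3` image tensor on the 0-255 scale.
#' @return numeric vector of K unnormalized scores.
#' @export
score_logits <- function(scorer, image) UseMethod("score_logits")

#' Input gradient (vector-Jacobian product) of a scorer
#'
#' Given the gradient `dlogits` of some scalar loss with respect to the
#' scorer's logits, returns the gradient of that loss with respect to every
#' input pixel.
#'
#' @param scorer a differentiable scorer.
#' @param image the image at which to evaluate the Jacobian.
#' @param dlogits numeric length-K vector, upstream gradient.
#' @return `L x L x 3` array of per-pixel gradients.
#' @export
input_gradient <- function(scorer, image, dlogits) UseMethod("input_gradient")

flatten_image <- function(image) as.vector(image) / 255

#' @export
score_logits.linear_scorer <- function(scorer, image) {
  drop(scorer$W %*% flatten_image(image)) + scorer$b
}

#' @export
input_gradient.linear_scorer <- function(scorer, image, dlogits) {
  g <- drop(crossprod(scorer$W, dlogits)) / 255
  array(g, dim(image))
}

#' @export
score_logits.rf_scorer <- function(scorer, image) {
  h <- tanh(drop(scorer$A %*% flatten_image(image)))
  drop(scorer$W %*% h) + scorer$b
}

#' @export
input_gradient.rf_scorer <- function(scorer, image, dlogits) {
  h <- tanh(drop(scorer$A %*% flatten_image(image)))
  dh <- drop(crossprod(scorer$W, dlogits)) * (1 - h^2)
  g <- drop(crossprod(scorer$A, dh)) / 255
  array(g, dim(image))
}

#' Temperature calibration of a logit vector
#'
#' @param logits numeric vector of fine logits.
#' @param temperature positive scalar T.
#' @return `logits / T`; the argmax is invariant for any T > 0.
#' @export
calibrate <- function(logits, temperature) {
  if (!is.numeric(temperature) || length(temperature) != 1 || temperature <= 0)
    stop_advpercept("calibration temperature must be a positive scalar")
  logits / temperature
}

#' Build an ensemble of calibrated scorers
#'
#' @param members list of scorers sharing the same fine-class indexing.
#' @param temperatures per-member calibration temperatures (default all 1).
#' @param id optional identifier recorded in stimulus provenance.
#' @return object of class `scorer_ensemble`.
#' @export
scorer_ensemble <- function(members, temperatures = NULL, id = NULL) {
  if (length(members) < 1) stop_advpercept("ensemble needs at least one member")
  K <- members[[1]]$K
  if (any(vapply(members, function(m) m$K, integer(1)) != K))
    stop_advpercept("ensemble members disagree on the number of fine classes")
  temperatures <- temperatures %||% rep(1, length(members))
  if (length(temperatures) != length(members) || any(temperatures <= 0))
    stop_advpercept("need one positive temperature per member")
  id <- id %||% paste(vapply(members, function(m) m$id, character(1)), collapse = "+")
  structure(list(members = members, temperatures = temperatures, K = K, id = id),
            class = "scorer_ensemble")
}

ensemble_member_ids <- function(ens) vapply(ens$members, function(m) m$id, character(1))

#' Ensemble logits: unweighted mean of calibrated member logits
#'
#' @param ensemble a [scorer_ensemble()].
#' @param image image tensor.
#' @return numeric length-K logit vector.
#' @export
ensemble_logits <- function(ensemble, image) {
  M <- length(ensemble$members)
  out <- numeric(ensemble$K)
  for (m in seq_len(M))
    out <- out + calibrate(score_logits(ensemble$members[[m]], image),
                           ensemble$temperatures[m])
  out / M
}

# Vector-Jacobian product through the ensemble mean.
ensemble_input_gradient <- function(ensemble, image, dlogits) {
  M <- length(ensemble$members)
  g <- array(0, dim(image))
  for (m in seq_len(M))
    g <- g + input_gradient(ensemble$members[[m]], image,
                            dlogits / (M * ensemble$temperatures[m]))
  g
}

#' Configuration of the foveated ("retinal") blur layer
#'
#' Gaussian smoothing whose standard deviation grows linearly with
#' eccentricity (Euclidean pixel distance from the fixation point):
#' `sigma(e) = sigma_min + (sigma_max - sigma_min) * e / e_max`, with `e_max`
#' the largest corner eccentricity. Implemented as per-pixel linear
#' interpolation between a small bank of uniformly blurred copies, which
#' keeps the operator linear in the input and hence exactly differentiable.
#' The default `sigma_min = sigma_max = 0` is a no-op.
#'
#' @param fixation `c(row, col)` fixation point in pixels; `NULL` = center.
#' @param sigma_min,sigma_max blur SDs in pixels, `0 <= sigma_min <= sigma_max`.
#' @param n_levels size of the blur bank used for interpolation.
#' @return object of class `retinal_blur_config`.
#' @export
retinal_blur_config <- function(fixation = NULL, sigma_min = 0, sigma_max = 0,
                                n_levels = 4L) {
  if (sigma_min < 0 || sigma_max < sigma_min)
    stop_advpercept("need 0 <= sigma_min <= sigma_max")
  structure(list(fixation = fixation, sigma_min = sigma_min,
                 sigma_max = sigma_max, n_levels = as.integer(n_levels)),
            class = "retinal_blur_config")
}

# Precompute blur-bank operators and interpolation weights for side length L.
retinal_blur_plan <- function(cfg, L) {
  fix <- cfg$fixation %||% c((L + 1) / 2, (L + 1) / 2)
  if (any(fix < 1) || any(fix > L))
    stop_advpercept("fixation point outside image bounds")
  if (cfg$sigma_max == 0)
    return(list(identity = TRUE))
  rows <- matrix(seq_len(L), L, L)
  cols <- matrix(seq_len(L), L, L, byrow = TRUE)
  ecc <- sqrt((rows - fix[1])^2 + (cols - fix[2])^2)
  corners <- rbind(c(1, 1), c(1, L), c(L, 1), c(L, L))
  e_max <- max(sqrt((corners[, 1] - fix[1])^2 + (corners[, 2] - fix[2])^2))
  sig <- cfg$sigma_min + (cfg$sigma_max - cfg$sigma_min) * ecc / e_max
  n <- max(2L, cfg$n_levels)
  grid <- seq(cfg$sigma_min, cfg$sigma_max, length.out = n)
  if (cfg$sigma_max == cfg$sigma_min) { grid <- cfg$sigma_min; n <- 1L }
  mats <- lapply(grid, function(s) conv_matrix(L, gauss_kernel1d(s)))
  # per-pixel interpolation weights over the sigma grid (two adjacent levels)
  weights <- vector("list", n)
  for (k in seq_len(n)) weights[[k]] <- matrix(0, L, L)
  if (n == 1L) {
    weights[[1]][] <- 1
  } else {
    step <- grid[2] - grid[1]
    pos <- (sig - grid[1]) / step
    k0 <- pmin(floor(pos), n - 2)
    frac <- pos - k0
    for (k in seq_len(n)) {
      weights[[k]] <- weights[[k]] + (k0 == (k - 1)) * (1 - frac)
      weights[[k]] <- weights[[k]] + (k0 == (k - 2)) * frac
    }
  }
  list(identity = FALSE, mats = mats, weights = weights, n = n)
}

#' Apply eccentricity-dependent Gaussian blur to an image
#'
#' @param image image tensor.
#' @param cfg a [retinal_blur_config()].
#' @return blurred image tensor (range `[0, 255]` preserved).
#' @export
retinal_blur <- function(image, cfg = retinal_blur_config()) {
  plan <- retinal_blur_plan(cfg, image_side(image))
  retinal_blur_apply(image, plan)
}

retinal_blur_apply <- function(image, plan) {
  if (plan$identity) return(image)
  out <- array(0, dim(image))
  for (ch in 1:3) {
    acc <- matrix(0, dim(image)[1], dim(image)[2])
    for (k in seq_len(plan$n)) {
      w <- plan$weights[[k]]
      if (any(w != 0))
        acc <- acc + w * blur_matrix_apply(image[, , ch], plan$mats[[k]])
    }
    out[, , ch] <- acc
  }
  # convex per-pixel combination of convex averages: range preserved up to fp noise
  clip(out, 0, 255)
}

# Adjoint of the blur operator (for backpropagation through the layer).
retinal_blur_adjoint <- function(grad, plan) {
  if (plan$identity) return(grad)
  out <- array(0, dim(grad))
  for (ch in 1:3) {
    acc <- matrix(0, dim(grad)[1], dim(grad)[2])
    for (k in seq_len(plan$n)) {
      w <- plan$weights[[k]]
      if (any(w != 0)) {
        M <- plan$mats[[k]]
        acc <- acc + t(M) %*% (w * grad[, , ch]) %*% M
      }
    }
    out[, , ch] <- acc
  }
  out
}

#' Serialize / restore a toy scorer as a plain-text checkpoint
#'
#' Single-file text format with a schema-version header; full double
#' precision for all parameters.
#' @param scorer a toy scorer.
#' @param path file path.
#' @export
write_scorer <- function(scorer, path) {
  hdr <- sprintf("advpercept-scorer v1 family=%s K=%d L=%d id=%s accuracy=%.17g",
                 scorer$family, scorer$K, scorer$L, scorer$id, scorer$accuracy)
  blocks <- c(hdr,
              paste0("b ", paste(format(scorer$b, digits = 17), collapse = " ")),
              paste0("W ", paste(dim(scorer$W), collapse = " ")),
              apply(scorer$W, 1, function(r) paste(format(r, digits = 17), collapse = " ")))
  if (!is.null(scorer$A)) {
    blocks <- c(blocks, paste0("A ", paste(dim(scorer$A), collapse = " ")),
                apply(scorer$A, 1, function(r) paste(format(r, digits = 17), collapse = " ")))
  }
  writeLines(blocks, path)
  invisible(path)
}

#' @rdname write_scorer
#' @export
read_scorer <- function(path) {
  lines <- readLines(path)
  hdr <- lines[1]
  if (!startsWith(hdr, "advpercept-scorer v1"))
    stop_advpercept("not an advpercept scorer checkpoint: ", path)
  get_field <- function(key) sub(paste0(".*", key, "=([^ ]+).*"), "\\1", hdr)
  family <- get_field("family")
  K <- as.integer(get_field("K")); L <- as.integer(get_field("L"))
  b <- as.numeric(strsplit(trimws(sub("^b ", "", lines[2])), "\\s+")[[1]])
  wdim <- as.integer(strsplit(trimws(sub("^W ", "", lines[3])), "\\s+")[[1]])
  W <- t(vapply(lines[4:(3 + wdim[1])],
                function(l) as.numeric(strsplit(trimws(l), " +")[[1]]),
                numeric(wdim[2]), USE.NAMES = FALSE))
  A <- NULL
  pos <- 4 + wdim[1]
  if (pos <= length(lines) && startsWith(lines[pos], "A ")) {
    adim <- as.integer(strsplit(sub("^A ", "", lines[pos]), " +")[[1]])
    A <- t(vapply(lines[(pos + 1):(pos + adim[1])],
                  function(l) as.numeric(strsplit(trimws(l), " +")[[1]]),
                  numeric(adim[2]), USE.NAMES = FALSE))
  }
  sc <- list(W = W, b = b, A = A, K = K, L = L, family = family,
             id = get_field("id"), accuracy = as.numeric(get_field("accuracy")))
  class(sc) <- c(paste0(family, "_scorer"), "toy_scorer")
  sc
}
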