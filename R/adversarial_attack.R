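# Iterative fast gradient sign method (iFGSM) with L-infinity clipping,
# expectation-over-transformation (EOT) robustness, and flipped-perturbation
# controls.
#
# The targeted objective is the binary cross entropy of the ensemble's coarse
# probability for the target category,
#   J_targeted(X, y)   = -log P_ens(y | X)
#   J_untargeted(X, y) = -log(1 - P_ens(y | X)),
# and each iterate takes a signed step on the gradient of -J followed by two
# clips: to the epsilon ball around the source and to the [0, 255] range.

#' Attack configuration
#'
#' @param epsilon L-infinity budget in intensity levels (0-255 scale), > 0.
#' @param alpha step size in intensity levels, > 0 (default 1).
#' @param n_iters number of signed-gradient iterations (default `2 * epsilon`,
#'   enough to reach the ball boundary with headroom).
#' @param mode `"targeted"` (raise the target category) or `"untargeted"`
#'   (suppress it).
#' @param eot if `TRUE`, each step averages the gradient over freshly sampled
#'   geometric transforms (rotation `U(0, pi/6)`, per-axis rescale
#'   `U(0.5 L, L)` pixels, translation `U(-L/4, L/4)` pixels).
#' @param transforms_per_step EOT transform draws per iteration.
#' @param symmetric_rotation if `TRUE`, draw rotations from `U(-pi/6, pi/6)`
#'   instead of the one-sided default.
#' @param blur optional [retinal_blur_config()] prepended to the ensemble
#'   (default no-op).
#' @param seed RNG seed for the transform draws.
#' @return object of class `attack_config`.
#' @export
attack_config <- function(epsilon = 16, alpha = 1, n_iters = NULL,
                          mode = c("targeted", "untargeted"), eot = FALSE,
                          transforms_per_step = 1L, symmetric_rotation = FALSE,
                          blur = retinal_blur_config(), seed = 1L) {
  mode <- match.arg(mode)
  if (epsilon <= 0) stop_advpercept("epsilon must be > 0")
  if (alpha <= 0) stop_advpercept("alpha must be > 0")
  n_iters <- as.integer(n_iters %||% max(1, ceiling(2 * epsilon)))
  if (n_iters < 1L) stop_advpercept("n_iters must be >= 1")
  structure(list(epsilon = epsilon, alpha = alpha, n_iters = n_iters,
                 mode = mode, eot = eot,
                 transforms_per_step = as.integer(transforms_per_step),
                 symmetric_rotation = symmetric_rotation,
                 blur = blur, seed = as.integer(seed)),
            class = "attack_config")
}

#' Adversarial objective (binary cross entropy on the coarse probability)
#'
#' @param image image tensor.
#' @param category target coarse category name.
#' @param mode `"targeted"` or `"untargeted"`.
#' @param ensemble a [scorer_ensemble()].
#' @param mapping a [coarse_mapping()].
#' @param blur optional [retinal_blur_config()] applied before scoring.
#' @return scalar loss, always finite: `-log(p)` is evaluated as the
#'   numerically stable softplus of the coarse score, which is equivalent to
#'   clamping the probability away from exact 0/1 but keeps the correct
#'   gradient when the ensemble saturates.
#' @export
attack_objective <- function(image, category, mode, ensemble, mapping,
                             blur = NULL) {
  z <- if (!is.null(blur)) retinal_blur(image, blur) else image
  s <- coarse_score(ensemble_logits(ensemble, z), mapping, category)
  if (mode == "targeted") softplus(-s) else softplus(s)
}

# log(1 + exp(x)) without overflow: -log(plogis(-x)).
softplus <- function(x) ifelse(x > 30, x, log1p(exp(pmin(x, 30))))

# Loss and exact input gradient of J through (transform ->) blur -> ensemble
# -> coarse score -> logistic -> BCE. `transform` is a transform_sample or
# NULL; `blur_plan` a prebuilt retinal_blur_plan or NULL.
objective_with_gradient <- function(image, category, mode, ensemble, mapping,
                                    blur_plan = NULL, transform = NULL) {
  L <- image_side(image)
  z0 <- if (!is.null(transform)) apply_transform(image, transform) else image
  z <- if (!is.null(blur_plan)) retinal_blur_apply(z0, blur_plan) else z0
  S <- ensemble_logits(ensemble, z)
  s <- coarse_score(S, mapping, category)
  p <- coarse_prob(s)
  loss <- if (mode == "targeted") softplus(-s) else softplus(s)
  # dJ/ds: targeted p - 1, untargeted p (both via the logistic derivative)
  gs <- if (mode == "targeted") p - 1 else p
  dS <- gs * coarse_score_grad(S, mapping, category)
  gz <- ensemble_input_gradient(ensemble, z, dS)
  if (!is.null(blur_plan)) gz <- retinal_blur_adjoint(gz, blur_plan)
  if (!is.null(transform)) gz <- transform_adjoint(gz, transform, L)
  list(loss = loss, grad = gz)
}

#' One iFGSM iterate
#'
#' `next = clip(current + alpha * sgn(grad_negJ), source - epsilon,
#' source + epsilon)` followed by a clip to `[0, 255]`. The sign convention
#' `sgn(0) = 0` means pixels with no gradient evidence do not move.
#'
#' @param current current iterate (array).
#' @param source unperturbed source image.
#' @param grad_negJ gradient of `-J` with respect to the current iterate.
#' @param alpha step size (> 0).
#' @param epsilon L-infinity budget.
#' @return the next iterate.
#' @export
ifgsm_step <- function(current, source, grad_negJ, alpha, epsilon) {
  if (alpha <= 0) stop_advpercept("alpha must be > 0")
  if (!identical(dim(current), dim(source)) ||
      !identical(dim(current), dim(grad_negJ)))
    stop_advpercept("current, source and gradient must share dimensions")
  nxt <- current + alpha * sign(grad_negJ)
  nxt <- clip(nxt, source - epsilon, source + epsilon)
  clip(nxt, 0, 255)
}

#' Draw a random identity-preserving geometric transform
#'
#' Rotation `theta ~ U(0, pi/6)` (or symmetric if configured), per-axis
#' rescale `s_x, s_y ~ U(0.5 L, L)` in pixels, translation
#' `t_x, t_y ~ U(-L/4, L/4)` in pixels.
#'
#' @param cfg an [attack_config()] (for the rotation convention).
#' @param L image side length in pixels.
#' @param seed seed for this draw.
#' @return object of class `transform_sample` with fields `theta`, `s_x`,
#'   `s_y`, `t_x`, `t_y`.
#' @export
sample_transform <- function(cfg, L, seed = 1L) {
  with_seed(seed, {
    theta <- if (isTRUE(cfg$symmetric_rotation))
      stats::runif(1, -pi / 6, pi / 6) else stats::runif(1, 0, pi / 6)
    s <- stats::runif(2, 0.5 * L, L)
    tr <- stats::runif(2, -L / 4, L / 4)
    structure(list(theta = theta, s_x = s[1], s_y = s[2],
                   t_x = tr[1], t_y = tr[2], L = L),
              class = "transform_sample")
  })
}

identity_transform <- function(L) {
  structure(list(theta = 0, s_x = L, s_y = L, t_x = 0, t_y = 0, L = L),
            class = "transform_sample")
}

# Bilinear sampling plan: for each output pixel, the four source indices and
# weights. Source coordinates folded into frame by mirror reflection, so no
# artificial black borders enter the objective.
transform_plan <- function(tr, L) {
  ctr <- (L + 1) / 2
  xo <- matrix(seq_len(L), L, L, byrow = TRUE) - ctr   # columns = x
  yo <- matrix(seq_len(L), L, L) - ctr                 # rows = y (down)
  kx <- tr$s_x / L
  ky <- tr$s_y / L
  px <- xo - tr$t_x
  py <- yo - tr$t_y
  ct <- cos(-tr$theta); st <- sin(-tr$theta)
  qx <- (ct * px - st * py) / kx + ctr
  qy <- (st * px + ct * py) / ky + ctr
  qx <- reflect_coord(qx, L)
  qy <- reflect_coord(qy, L)
  x0 <- pmin(floor(qx), L - 1); y0 <- pmin(floor(qy), L - 1)
  wx <- qx - x0; wy <- qy - y0
  lin <- function(r, c) (c - 1L) * L + r
  list(i00 = lin(y0, x0), i01 = lin(y0, x0 + 1),
       i10 = lin(y0 + 1, x0), i11 = lin(y0 + 1, x0 + 1),
       w00 = as.vector((1 - wx) * (1 - wy)), w01 = as.vector(wx * (1 - wy)),
       w10 = as.vector((1 - wx) * wy), w11 = as.vector(wx * wy))
}

#' Apply a geometric transform to an image
#'
#' Rotation about the image center, anisotropic rescale, then translation,
#' with bilinear interpolation and mirror-reflect handling of out-of-frame
#' coordinates. Linear in the input pixels, hence exactly differentiable.
#'
#' @param image image tensor.
#' @param tr a `transform_sample` (see [sample_transform()]).
#' @return transformed image tensor.
#' @export
apply_transform <- function(image, tr) {
  L <- image_side(image)
  pl <- transform_plan(tr, L)
  out <- array(0, dim(image))
  for (ch in 1:3) {
    v <- as.vector(image[, , ch])
    out[, , ch] <- matrix(pl$w00 * v[pl$i00] + pl$w01 * v[pl$i01] +
                          pl$w10 * v[pl$i10] + pl$w11 * v[pl$i11], L, L)
  }
  out
}

# Adjoint of apply_transform: scatter-add the bilinear weights.
transform_adjoint <- function(grad, tr, L) {
  pl <- transform_plan(tr, L)
  out <- array(0, dim(grad))
  scatter <- function(idx, w, g) {
    acc <- numeric(L * L)
    s <- rowsum(w * g, as.vector(idx))  # rowsum needs a vector group
    acc[as.integer(rownames(s))] <- s
    acc
  }
  for (ch in 1:3) {
    g <- as.vector(grad[, , ch])
    acc <- scatter(pl$i00, pl$w00, g) + scatter(pl$i01, pl$w01, g) +
      scatter(pl$i10, pl$w10, g) + scatter(pl$i11, pl$w11, g)
    out[, , ch] <- matrix(acc, L, L)
  }
  out
}

#' Generate an adversarial image with iFGSM
#'
#' Runs `n_iters` signed-gradient steps on `-J`, each step's gradient
#' averaged over `transforms_per_step` fresh EOT transform draws when EOT is
#' enabled (gradients flow through the transform and the retinal blur, both
#' linear). The returned perturbation satisfies both the epsilon-ball and the
#' `[0, 255]` constraints exactly.
#'
#' @param source source image tensor.
#' @param ensemble a [scorer_ensemble()].
#' @param mapping a [coarse_mapping()].
#' @param category target coarse category.
#' @param cfg an [attack_config()].
#' @return list with `image` (adversarial image), `delta`
#'   (`image - source`), and `trace` (per-iteration loss of the identity-view
#'   objective; not guaranteed monotone for a sign-step method).
#' @export
generate_adversarial <- function(source, ensemble, mapping, category,
                                 cfg = attack_config()) {
  L <- image_side(source)
  blur_plan <- if (cfg$blur$sigma_max > 0) retinal_blur_plan(cfg$blur, L) else NULL
  x <- source
  trace <- numeric(cfg$n_iters)
  for (i in seq_len(cfg$n_iters)) {
    g <- array(0, dim(source))
    loss_i <- 0
    if (cfg$eot) {
      for (s in seq_len(cfg$transforms_per_step)) {
        tr <- sample_transform(cfg, L,
                               derive_seed(cfg$seed, i * 1000L + s))
        ow <- objective_with_gradient(x, category, cfg$mode, ensemble, mapping,
                                      blur_plan, tr)
        g <- g + ow$grad
        loss_i <- loss_i + ow$loss
      }
      g <- g / cfg$transforms_per_step
      loss_i <- loss_i / cfg$transforms_per_step
    } else {
      ow <- objective_with_gradient(x, category, cfg$mode, ensemble, mapping,
                                    blur_plan, NULL)
      g <- ow$grad
      loss_i <- ow$loss
    }
    # gradient of -J is -g
    x <- ifgsm_step(x, source, -g, cfg$alpha, cfg$epsilon)
    trace[i] <- loss_i
  }
  delta <- x - source
  stopifnot(max(abs(delta)) <= cfg$epsilon + 1e-9,
            min(x) >= -1e-9, max(x) <= 255 + 1e-9)
  list(image = image_tensor(clip(x, 0, 255)), delta = delta, trace = trace)
}

#' Spatially mirrored control perturbation
#'
#' Flipping a perturbation top-down or right-left preserves every per-pixel
#' magnitude (and hence all norms) while destroying the pixel-to-image
#' correspondence that carries the adversarial effect.
#'
#' @param delta `L x L x 3` perturbation array.
#' @param axis `"vertical"` (top-down flip, reverses rows) or `"horizontal"`
#'   (right-left flip, reverses columns).
#' @return the mirrored perturbation.
#' @export
flip_control <- function(delta, axis = c("vertical", "horizontal")) {
  axis <- match.arg(axis)
  if (axis == "vertical") delta[rev(seq_len(dim(delta)[1])), , , drop = FALSE]
  else delta[, rev(seq_len(dim(delta)[2])), , drop = FALSE]
}
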