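# Perturbation-structure and stimulus-level image statistics.
#
# Edge strength: render the perturbation about mid-gray, reduce to
# luminance, bilateral-filter (noise-suppressing, edge-preserving), run a
# Canny detector, and count active pixels of the binary edge map. Counts are
# parameter-dependent, so results should always travel with their params.

#' Edge-analysis parameters
#'
#' @param spatial_sigma bilateral filter spatial SD, pixels.
#' @param range_sigma bilateral filter range SD, intensity levels.
#' @param diameter bilateral filter window diameter, pixels (odd).
#' @param canny_sigma Gaussian smoothing SD inside the Canny detector.
#' @param low,high Canny hysteresis thresholds on the Sobel gradient
#'   magnitude (0-255 intensity rendering); `low < high`. The defaults are
#'   scaled for perturbation inputs (amplitudes bounded by the attack
#'   epsilon, at most a few tens of intensity levels, rendered about
#'   mid-gray), not for full-range photographs: after the default bilateral
#'   and Gaussian smoothing, a step of ~30 intensity levels (an epsilon = 16
#'   attack at full swing) peaks near Sobel magnitude 49, comfortably above
#'   `high = 40`, while bilateral-suppressed pixel noise stays mostly below
#'   `low = 15`.
#' @return object of class `edge_params`.
#' @export
edge_params <- function(spatial_sigma = 3, range_sigma = 25, diameter = 9L,
                        canny_sigma = 1.4, low = 15, high = 40) {
  if (spatial_sigma <= 0 || range_sigma <= 0 || canny_sigma <= 0)
    stop_advpercept("sigma parameters must be > 0")
  if (low >= high) stop_advpercept("Canny thresholds need low < high")
  structure(list(spatial_sigma = spatial_sigma, range_sigma = range_sigma,
                 diameter = as.integer(diameter), canny_sigma = canny_sigma,
                 low = low, high = high),
            class = "edge_params")
}

# Bilateral filter of a single-channel matrix (symmetric-padded window scan).
bilateral_filter <- function(X, spatial_sigma, range_sigma, diameter) {
  r <- (diameter - 1L) %/% 2L
  L1 <- nrow(X); L2 <- ncol(X)
  reflect_idx <- function(p, L) {
    p <- ifelse(p < 1L, 2L - p, p)
    ifelse(p > L, 2L * L - p, p)
  }
  num <- matrix(0, L1, L2)
  den <- matrix(0, L1, L2)
  for (dy in -r:r) for (dx in -r:r) {
    ws <- exp(-(dx^2 + dy^2) / (2 * spatial_sigma^2))
    shifted <- X[reflect_idx(seq_len(L1) + dy, L1),
                 reflect_idx(seq_len(L2) + dx, L2), drop = FALSE]
    wr <- exp(-((shifted - X)^2) / (2 * range_sigma^2))
    w <- ws * wr
    num <- num + w * shifted
    den <- den + w
  }
  num / den
}

# Canny edge detector on a single-channel matrix. Returns a binary map.
canny_edges <- function(X, sigma, low, high) {
  L1 <- nrow(X); L2 <- ncol(X)
  M <- conv_matrix(L1, gauss_kernel1d(sigma))
  Xs <- M %*% X %*% t(conv_matrix(L2, gauss_kernel1d(sigma)))
  shift <- function(A, dy, dx) {
    ri <- clip(seq_len(L1) + dy, 1L, L1)
    ci <- clip(seq_len(L2) + dx, 1L, L2)
    A[ri, ci, drop = FALSE]
  }
  # Sobel gradients
  gx <- (shift(Xs, -1, 1) + 2 * shift(Xs, 0, 1) + shift(Xs, 1, 1)) -
        (shift(Xs, -1, -1) + 2 * shift(Xs, 0, -1) + shift(Xs, 1, -1))
  gy <- (shift(Xs, 1, -1) + 2 * shift(Xs, 1, 0) + shift(Xs, 1, 1)) -
        (shift(Xs, -1, -1) + 2 * shift(Xs, -1, 0) + shift(Xs, -1, 1))
  mag <- sqrt(gx^2 + gy^2)
  ang <- atan2(gy, gx)
  # quantize to 4 directions and suppress non-maxima along the gradient
  sector <- (round(ang / (pi / 4)) %% 4)
  n1 <- matrix(0, L1, L2); n2 <- matrix(0, L1, L2)
  pick <- function(s, dy, dx, tgt) {
    sel <- sector == s
    tgt[sel] <- shift(mag, dy, dx)[sel]
    tgt
  }
  n1 <- pick(0, 0, 1, n1);  n2 <- pick(0, 0, -1, n2)     # horizontal gradient
  n1 <- pick(1, 1, 1, n1);  n2 <- pick(1, -1, -1, n2)    # diagonal /
  n1 <- pick(2, 1, 0, n1);  n2 <- pick(2, -1, 0, n2)     # vertical gradient
  n1 <- pick(3, 1, -1, n1); n2 <- pick(3, -1, 1, n2)     # diagonal \
  thin <- mag >= n1 & mag >= n2
  strong <- thin & (mag >= high)
  weak <- thin & (mag >= low) & (mag < high)
  # hysteresis: grow strong set through 8-connected weak pixels to fixpoint
  edges <- strong
  repeat {
    grown <- edges
    for (dy in -1:1) for (dx in -1:1) {
      if (dy == 0 && dx == 0) next
      grown <- grown | (shift(edges, dy, dx) & weak)
    }
    grown <- grown & (strong | weak)
    if (identical(grown, edges)) break
    edges <- grown
  }
  edges
}

#' Edge strength of a perturbation
#'
#' Renders the perturbation about mid-gray (128 + delta, clipped), converts
#' to luminance, bilateral-filters, applies the Canny detector, and returns
#' the count of active unit edge elements in the binary map.
#'
#' @param delta `L x L x 3` perturbation array (or `L x L` matrix).
#' @param params an [edge_params()].
#' @return integer edge-element count.
#' @export
edge_strength <- function(delta, params = edge_params()) {
  if (anyNA(delta) || any(!is.finite(delta)))
    stop_advpercept("perturbation must be finite")
  rendered <- if (is.matrix(delta)) clip(128 + delta, 0, 255)
  else luminance(clip(128 + delta, 0, 255))
  filt <- bilateral_filter(rendered, params$spatial_sigma, params$range_sigma,
                           params$diameter)
  sum(canny_edges(filt, params$canny_sigma, params$low, params$high))
}

# Gaussian-window local moments via operator matrices (symmetric padding).
ssim_channel <- function(a, b, C1, C2, win_sigma = 1.5) {
  M1 <- conv_matrix(nrow(a), gauss_kernel1d(win_sigma))
  M2 <- conv_matrix(ncol(a), gauss_kernel1d(win_sigma))
  f <- function(X) M1 %*% X %*% t(M2)
  mua <- f(a); mub <- f(b)
  va <- f(a * a) - mua^2
  vb <- f(b * b) - mub^2
  cab <- f(a * b) - mua * mub
  lum_con <- (2 * mua * mub + C1) / (mua^2 + mub^2 + C1)
  struct <- (2 * cab + C2) / (va + vb + C2)
  list(ssim = mean(lum_con * struct), cs = mean(struct))
}

downsample2 <- function(X) {
  L1 <- 2L * (nrow(X) %/% 2L); L2 <- 2L * (ncol(X) %/% 2L)
  X <- X[seq_len(L1), seq_len(L2), drop = FALSE]
  0.25 * (X[seq(1, L1, 2), seq(1, L2, 2)] + X[seq(2, L1, 2), seq(1, L2, 2)] +
          X[seq(1, L1, 2), seq(2, L2, 2)] + X[seq(2, L1, 2), seq(2, L2, 2)])
}

#' Multi-scale structural similarity (MS-SSIM)
#'
#' Standard multi-scale SSIM on the luminance channel: contrast/structure
#' terms at every scale, the luminance term at the coarsest, combined with
#' the canonical five-scale weights (0.0448, 0.2856, 0.3001, 0.2363, 0.1333).
#' With fewer scales (small images) the leading weights are renormalized.
#' Symmetric in its arguments.
#'
#' @param a,b image tensors of identical size.
#' @param scales number of dyadic scales (default 5; each scale halves the
#'   side length, and the coarsest scale must keep at least 8 pixels).
#' @return similarity value in (0, 1]; 1 iff the images are identical.
#' @export
ms_ssim <- function(a, b, scales = 5L) {
  if (!identical(dim(a), dim(b))) stop_advpercept("images must share dimensions")
  weights <- c(0.0448, 0.2856, 0.3001, 0.2363, 0.1333)
  if (scales < 1L || scales > 5L) stop_advpercept("scales must be in 1..5")
  w <- weights[seq_len(scales)] / sum(weights[seq_len(scales)])
  if (image_side(a) / 2^(scales - 1) < 8)
    stop_advpercept("image too small for ", scales, " scales (needs >= ",
                    8 * 2^(scales - 1), " px)")
  C1 <- (0.01 * 255)^2; C2 <- (0.03 * 255)^2
  xa <- luminance(a); xb <- luminance(b)
  val <- 1
  for (s in seq_len(scales)) {
    r <- ssim_channel(xa, xb, C1, C2)
    term <- if (s == scales) r$ssim else r$cs
    val <- val * max(term, 1e-12)^w[s]
    if (s < scales) { xa <- downsample2(xa); xb <- downsample2(xb) }
  }
  val
}

#' Mean luminance and RMS contrast of an image
#'
#' @param image image tensor.
#' @return named vector `c(mean, rms_contrast)`; RMS contrast is the
#'   population standard deviation of all pixel intensities.
#' @export
luminance_contrast <- function(image) {
  v <- as.vector(image)
  m <- mean(v)
  c(mean = m, rms_contrast = sqrt(mean((v - m)^2)))
}
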