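# Internal numerical helpers shared across modules.

#' Overflow-safe log-sum-exp
#'
#' @param x numeric vector (at least one finite element).
#' @return log(sum(exp(x))) computed without overflow.
#' @keywords internal
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Evaluate code with a temporary RNG seed
#'
#' Saves and restores the global RNG state so seeded operations do not
#' perturb the caller's random stream.
#' @keywords internal
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Derive a child seed from (seed, tag) that stays inside 32-bit range.
derive_seed <- function(seed, tag) {
  tag_num <- if (is.character(tag)) sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag))) else as.numeric(tag)
  as.integer((as.numeric(seed) * 48271 + tag_num * 16807 + 12345) %% 2147483647)
}

# Normalized 1-D Gaussian kernel; sigma = 0 degenerates to a delta tap.
gauss_kernel1d <- function(sigma) {
  if (sigma <= 0) return(1)
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k / sum(k)
}

# L x L matrix applying a 1-D convolution with symmetric (reflect) padding.
# Row-stochastic for a normalized kernel, so constants are fixed points.
conv_matrix <- function(L, kernel) {
  r <- (length(kernel) - 1L) %/% 2L
  M <- matrix(0, L, L)
  reflect <- function(p) {
    p <- ifelse(p < 1L, 2L - p, p)
    ifelse(p > L, 2L * L - p, p)
  }
  for (k in seq_along(kernel)) {
    off <- k - r - 1L
    idx <- reflect(seq_len(L) + off)
    M[cbind(seq_len(L), idx)] <- M[cbind(seq_len(L), idx)] + kernel[k]
  }
  M
}

# Separable 2-D Gaussian blur of one channel via explicit operator matrices.
blur_matrix_apply <- function(X, M) M %*% X %*% t(M)

# Fold real-valued coordinates into [1, L] by mirror reflection.
reflect_coord <- function(p, L) {
  period <- 2 * (L - 1)
  q <- (p - 1) %% period
  q <- ifelse(q > (L - 1), period - q, q)
  q + 1
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_advpercept <- function(...) stop(..., call. = FALSE)
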