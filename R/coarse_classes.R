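# Coarse-category scoring.
#
# Fine classifier classes (e.g. individual dog breeds) are grouped into named
# coarse categories (e.g. "dog"). The coarse score of category c contrasts the
# member logits against every non-member logit,
#
#   S_c = log sum_{i in c} exp(S_i)  -  log sum_{j not in c} exp(S_j),
#
# the logit of the binary "is the coarse category present?" classifier. Fine
# classes assigned to no category are allowed and always count in the
# complement sum.

#' Construct a coarse-category mapping
#'
#' @param sets named list; each element an integer vector of 1-based fine
#'   class indices belonging to that coarse category.
#' @param n_fine total number of fine classes K (length of a logit vector).
#' @return object of class `coarse_mapping`.
#' @details Categories must be nonempty, pairwise disjoint, and strict
#'   subsets of `1:K` (a category holding every fine class would leave an
#'   empty complement and an undefined score). Not every fine class needs a
#'   category; unassigned classes contribute to the complement only.
#' @export
coarse_mapping <- function(sets, n_fine) {
  if (is.null(names(sets)) || any(names(sets) == "") || anyDuplicated(names(sets)))
    stop_advpercept("coarse categories must have unique non-empty names")
  n_fine <- as.integer(n_fine)
  all_idx <- integer(0)
  for (nm in names(sets)) {
    s <- as.integer(sets[[nm]])
    if (length(s) == 0) stop_advpercept("coarse category '", nm, "' is empty")
    if (anyDuplicated(s)) stop_advpercept("duplicate fine indices in '", nm, "'")
    if (any(s < 1L) || any(s > n_fine))
      stop_advpercept("fine indices in '", nm, "' outside 1..", n_fine)
    if (length(s) >= n_fine)
      stop_advpercept("coarse category '", nm, "' must be a strict subset of the fine classes")
    sets[[nm]] <- sort(s)
    all_idx <- c(all_idx, s)
  }
  if (anyDuplicated(all_idx))
    stop_advpercept("coarse categories must be pairwise disjoint")
  structure(list(sets = sets, n_fine = n_fine), class = "coarse_mapping")
}

#' @export
print.coarse_mapping <- function(x, ...) {
  cat(sprintf("coarse_mapping: %d categories over %d fine classes\n",
              length(x$sets), x$n_fine))
  for (nm in names(x$sets)) {
    shown <- paste(utils::head(x$sets[[nm]], 8), collapse = ",")
    if (length(x$sets[[nm]]) > 8) shown <- paste0(shown, ",...")
    cat(sprintf("  %-10s n=%3d  {%s}\n", nm, length(x$sets[[nm]]), shown))
  }
  invisible(x)
}

#' Coarse-category score (binary logit) from fine logits
#'
#' @param logits numeric vector of K fine unnormalized scores.
#' @param mapping a [coarse_mapping()].
#' @param category coarse category name.
#' @return scalar score `logsumexp(logits[members]) - logsumexp(logits[others])`.
#' @export
coarse_score <- function(logits, mapping, category) {
  idx <- mapping_members(mapping, category)
  if (length(logits) != mapping$n_fine)
    stop_advpercept("logit vector length ", length(logits),
                    " does not match mapping K = ", mapping$n_fine)
  comp <- setdiff(seq_len(mapping$n_fine), idx)
  if (length(comp) == 0) stop_advpercept("empty complement for '", category, "'")
  logsumexp(logits[idx]) - logsumexp(logits[comp])
}

mapping_members <- function(mapping, category) {
  if (!category %in% names(mapping$sets))
    stop_advpercept("unknown coarse category '", category, "'")
  mapping$sets[[category]]
}

#' Coarse-category probability
#'
#' Logistic transform of the coarse score: the probability assigned by the
#' binary presence/absence classifier.
#' @param score finite scalar coarse score.
#' @return probability in (0, 1).
#' @export
coarse_prob <- function(score) {
  if (!all(is.finite(score))) stop_advpercept("coarse score must be finite")
  stats::plogis(score)
}

# Gradient of coarse_score with respect to the fine logits: softmax weights
# over the members, minus softmax weights over the complement.
coarse_score_grad <- function(logits, mapping, category) {
  idx <- mapping_members(mapping, category)
  comp <- setdiff(seq_len(mapping$n_fine), idx)
  g <- numeric(mapping$n_fine)
  sm <- function(v) { e <- exp(v - max(v)); e / sum(e) }
  g[idx] <- sm(logits[idx])
  g[comp] <- -sm(logits[comp])
  g
}

#' Equalize fine-class support between two paired coarse categories
#'
#' When two target categories with unequal fine-class support are pitted
#' against each other (e.g. 120 dog breeds vs 7 bottle types), the larger
#' category is randomly subsampled down to the size of the smaller one so
#' that support differences cannot bias the paired objective. The draw is
#' uniform and seeded; all other categories pass through untouched.
#'
#' @param mapping a [coarse_mapping()].
#' @param a,b names of the two paired categories (distinct).
#' @param seed integer seed for the subsample draw.
#' @return a new `coarse_mapping` in which both `a` and `b` have
#'   `min(n_a, n_b)` fine classes.
#' @export
subsample_mapping <- function(mapping, a, b, seed = 1L) {
  if (identical(a, b)) stop_advpercept("the two paired categories must differ")
  sa <- mapping_members(mapping, a)
  sb <- mapping_members(mapping, b)
  m <- min(length(sa), length(sb))
  sets <- mapping$sets
  with_seed(seed, {
    if (length(sa) > m) sets[[a]] <- sort(sample(sa, m))
    if (length(sb) > m) sets[[b]] <- sort(sample(sb, m))
  })
  coarse_mapping(sets, mapping$n_fine)
}

#' The nine-category ImageNet-style coarse mapping (documentation parity)
#'
#' Nine common object categories (sheep, dog, cat, elephant, bird, chair,
#' bottle, truck, clock) over a 1000-class fine label space. The dog (120
#' fine classes) and bottle (7 fine classes) supports are documented category
#' sizes; the remaining supports and all index assignments are synthetic
#' placeholders laid out consecutively, shipped so that support-dependent
#' logic (subsampling, complement sums) can be exercised at realistic sizes.
#' Not a reconstruction of any published class table.
#'
#' @return a `coarse_mapping` with nine disjoint categories, K = 1000.
#' @export
imagenet_nine_mapping <- function() {
  supports <- c(sheep = 3L, dog = 120L, cat = 13L, elephant = 2L, bird = 59L,
                chair = 4L, bottle = 7L, truck = 6L, clock = 5L)
  sets <- list()
  start <- 1L
  for (nm in names(supports)) {
    sets[[nm]] <- seq.int(start, start + supports[[nm]] - 1L)
    start <- start + supports[[nm]]
  }
  coarse_mapping(sets, 1000L)
}

#' Write / read a coarse mapping as a plain-text config
#'
#' One line per category, `name: i,j,k` with 0-based fine indices on disk
#' (the in-memory representation is 1-based; the shift is applied on IO).
#' A header line records the schema version and K.
#' @param mapping a [coarse_mapping()].
#' @param path file path.
#' @export
write_mapping <- function(mapping, path) {
  lines <- c(sprintf("# advpercept-mapping v1 K=%d (0-based indices)", mapping$n_fine),
             vapply(names(mapping$sets), function(nm)
               sprintf("%s: %s", nm, paste(mapping$sets[[nm]] - 1L, collapse = ",")),
               character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_mapping
#' @export
read_mapping <- function(path) {
  lines <- readLines(path)
  hdr <- lines[1]
  K <- as.integer(sub(".*K=(\\d+).*", "\\1", hdr))
  if (is.na(K)) stop_advpercept("missing K= header in mapping file: ", path)
  body <- lines[-1]
  body <- body[nzchar(trimws(body))]
  sets <- list()
  for (ln in body) {
    parts <- strsplit(ln, ":", fixed = TRUE)[[1]]
    if (length(parts) != 2) stop_advpercept("malformed mapping line: ", ln)
    nm <- trimws(parts[1])
    idx <- as.integer(strsplit(trimws(parts[2]), ",")[[1]]) + 1L
    sets[[nm]] <- idx
  }
  coarse_mapping(sets, K)
}
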