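# Shared small-scale fixtures, built once per test run.
# The dataset is deliberately smaller than the default spec (20 images per
# class instead of 50) to keep unit tests fast; the acceptance suite builds
# the full default testbed itself.

.fixtures <- new.env(parent = emptyenv())

fix_dataset <- function() {
  if (is.null(.fixtures$ds))
    .fixtures$ds <- generate_dataset(dataset_spec(images_per_class = 20L, seed = 11L))
  .fixtures$ds
}

fix_scorer <- function(seed = 0L, family = "linear") {
  key <- sprintf("sc_%s_%d", family, seed)
  if (is.null(.fixtures[[key]]))
    .fixtures[[key]] <- fit_toy_scorer(fix_dataset(),
                                       train_config(family = family, seed = seed))
  .fixtures[[key]]
}

fix_ensemble <- function() {
  if (is.null(.fixtures$ens))
    .fixtures$ens <- scorer_ensemble(list(fix_scorer(0L), fix_scorer(1L)))
  .fixtures$ens
}

fix_mapping <- function() default_coarse_mapping()

# a source image whose fine class (cross) belongs to no coarse category
fix_source <- function(i = 1L) {
  ds <- fix_dataset()
  ds$images[[which(ds$labels == 5L)[i]]]
}

# finite-difference probe of a scalar-valued image functional
fd_probe <- function(f, image, i, j, ch, h = 1e-3) {
  xp <- image; xp[i, j, ch] <- xp[i, j, ch] + h
  xm <- image; xm[i, j, ch] <- xm[i, j, ch] - h
  (f(xp) - f(xm)) / (2 * h)
}
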