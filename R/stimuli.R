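# Stimulus pairs, session plans, and stimulus artifact IO.
#
# Each 2AFC trial shows two modulations of the same source image. The
# experiment designs supported:
#   E1: adversarial image vs source + top-down flipped perturbation (control)
#   E2: T-up (targeted toward T) vs T-down (untargeted on T)
#   E3: A-up vs source + right-left flipped perturbation (control)
#   E4: A-up vs A'-up (two different target categories, support-equalized)
#   E5: A-up from ensemble 1 vs A-up from ensemble 2 (architecture pairing)

EXPERIMENTS <- c("E1", "E2", "E3", "E4", "E5")

#' Build one experiment-specific stimulus pair
#'
#' @param experiment one of `"E1"`..`"E5"`.
#' @param source source image tensor.
#' @param mapping a [coarse_mapping()].
#' @param ensembles a [scorer_ensemble()], or a list of two ensembles for E5.
#' @param question_class the queried coarse category (T for E2, A otherwise).
#' @param alt_class the third category A' (E4 only).
#' @param cfg an [attack_config()]; its mode is managed per design.
#' @param source_id identifier of the source image (drives the per-image
#'   subsample seed for E4/E5).
#' @param seed seed for side assignment and subsampling.
#' @return object of class `stimulus_pair`: left/right images, deltas
#'   relative to source, consistency labelling, and provenance.
#' @export
build_pair <- function(experiment, source, mapping, ensembles, question_class,
                       alt_class = NULL, cfg = attack_config(),
                       source_id = "img", seed = 1L) {
  experiment <- match.arg(experiment, EXPERIMENTS)
  ens1 <- if (inherits(ensembles, "scorer_ensemble")) ensembles else ensembles[[1]]
  mapping_used <- mapping
  atk <- function(ens, category, mode, map) {
    c2 <- cfg; c2$mode <- mode
    generate_adversarial(source, ens, map, category, c2)
  }
  if (experiment == "E4") {
    if (is.null(alt_class)) stop_advpercept("E4 needs alt_class (A')")
    if (identical(alt_class, question_class))
      stop_advpercept("A and A' must differ")
    mapping_used <- subsample_mapping(mapping, question_class, alt_class,
                                      seed = derive_seed(seed, source_id))
  }
  imgs <- switch(experiment,
    E1 = {
      up <- atk(ens1, question_class, "targeted", mapping_used)
      ctrl <- clip(unclass(source) + flip_control(up$delta, "vertical"), 0, 255)
      list(a = up$image, b = image_tensor(ctrl), label = "A_up_vs_vflip")
    },
    E2 = {
      up <- atk(ens1, question_class, "targeted", mapping_used)
      dn <- atk(ens1, question_class, "untargeted", mapping_used)
      list(a = up$image, b = dn$image, label = "T_up_vs_T_down")
    },
    E3 = {
      up <- atk(ens1, question_class, "targeted", mapping_used)
      ctrl <- clip(unclass(source) + flip_control(up$delta, "horizontal"), 0, 255)
      list(a = up$image, b = image_tensor(ctrl), label = "A_up_vs_hflip")
    },
    E4 = {
      up <- atk(ens1, question_class, "targeted", mapping_used)
      up2 <- atk(ens1, alt_class, "targeted", mapping_used)
      list(a = up$image, b = up2$image, label = "A_up_vs_Aprime_up")
    },
    E5 = {
      if (inherits(ensembles, "scorer_ensemble") || length(ensembles) < 2)
        stop_advpercept("E5 needs two ensembles")
      up1 <- atk(ensembles[[1]], question_class, "targeted", mapping_used)
      up2 <- atk(ensembles[[2]], question_class, "targeted", mapping_used)
      list(a = up1$image, b = up2$image, label = "ens1_vs_ens2")
    })
  # image "a" is the adversarial-consistent answer to the default question
  side_a <- with_seed(derive_seed(seed, paste0(source_id, "-side")),
                      sample(c("left", "right"), 1))
  left <- if (side_a == "left") imgs$a else imgs$b
  right <- if (side_a == "left") imgs$b else imgs$a
  ens_ids <- if (experiment == "E5")
    vapply(ensembles[1:2], function(e) e$id, character(1)) else ens1$id
  structure(list(
    experiment = experiment, left = left, right = right,
    delta_left = unclass(left) - unclass(source),
    delta_right = unclass(right) - unclass(source),
    source_id = source_id, question_class = question_class,
    alt_class = alt_class, consistent_side = side_a,
    epsilon = cfg$epsilon, design = imgs$label,
    provenance = list(ensemble_ids = ens_ids, seed = seed,
                      attack_seed = cfg$seed, epsilon = cfg$epsilon)),
    class = "stimulus_pair")
}

#' Flip the consistency labelling of an E4 pair to the other question
#'
#' The same E4 pair answers two questions: asked "more A-like" the
#' adversarial-consistent side is the A-up image; asked "more A'-like" it is
#' the A'-up image.
#' @param pair an E4 `stimulus_pair`.
#' @return the pair relabelled for the A' question.
#' @export
flip_question <- function(pair) {
  if (pair$experiment != "E4") stop_advpercept("only E4 pairs carry two questions")
  out <- pair
  out$question_class <- pair$alt_class
  out$alt_class <- pair$question_class
  out$consistent_side <- if (pair$consistent_side == "left") "right" else "left"
  out
}

#' Build a catch-trial pair
#'
#' An unambiguous trial: an unperturbed exemplar of the queried class paired
#' with an exemplar of a different class.
#' @param correct_image unperturbed exemplar of `question_class`.
#' @param wrong_image exemplar of a different class.
#' @param question_class the queried category.
#' @param id catch pair identifier.
#' @param seed side-assignment seed.
#' @return a `catch_pair` object.
#' @export
build_catch_pair <- function(correct_image, wrong_image, question_class,
                             id = "catch1", seed = 1L) {
  side <- with_seed(derive_seed(seed, id), sample(c("left", "right"), 1))
  structure(list(id = id, question_class = question_class,
                 left = if (side == "left") correct_image else wrong_image,
                 right = if (side == "left") wrong_image else correct_image,
                 correct_side = side),
            class = "catch_pair")
}

#' Assemble a session plan
#'
#' Exactly `n_trials` ordered trials of which `n_catch` are catch trials at
#' seeded random positions; experiment trials are drawn from `pairs` (cycled
#' if fewer pairs than slots).
#'
#' @param pairs list of `stimulus_pair` objects.
#' @param n_trials total trials per participant (default 104).
#' @param n_catch catch trials among them (default 8).
#' @param seed ordering / placement seed.
#' @param catch_pairs optional list of `catch_pair` objects; defaults to
#'   placeholder descriptors `catch01..` with seeded correct sides.
#' @return object of class `session_plan` with a `trials` data.frame.
#' @export
build_session <- function(pairs, n_trials = 104L, n_catch = 8L, seed = 1L,
                          catch_pairs = NULL) {
  n_trials <- as.integer(n_trials); n_catch <- as.integer(n_catch)
  if (n_catch > n_trials) stop_advpercept("n_catch cannot exceed n_trials")
  n_exp <- n_trials - n_catch
  if (length(pairs) < 1 && n_exp > 0) stop_advpercept("no stimulus pairs supplied")
  with_seed(seed, {
    order_idx <- rep_len(sample(seq_along(pairs)), n_exp)
    catch_pos <- sort(sample(n_trials, n_catch))
    catch_side <- sample(c("left", "right"), n_catch, replace = TRUE)
  })
  if (is.null(catch_pairs) && n_catch > 0)
    catch_pairs <- lapply(seq_len(n_catch), function(k)
      structure(list(id = sprintf("catch%02d", k),
                     question_class = pairs[[1]]$question_class,
                     correct_side = catch_side[k]), class = "catch_pair"))
  pair_ids <- vapply(pairs, function(p)
    sprintf("%s_%s_e%g", p$experiment, p$source_id, p$epsilon), character(1))
  trials <- data.frame(trial = seq_len(n_trials),
                       pair_id = NA_character_, is_catch = 0L,
                       question_class = NA_character_,
                       consistent_side = NA_character_,
                       catch_correct_side = NA_character_,
                       epsilon = NA_real_,
                       stringsAsFactors = FALSE)
  ei <- 1L; ci <- 1L
  for (t in seq_len(n_trials)) {
    if (t %in% catch_pos) {
      cp <- catch_pairs[[ci]]
      trials$pair_id[t] <- cp$id
      trials$is_catch[t] <- 1L
      trials$question_class[t] <- cp$question_class
      trials$catch_correct_side[t] <- cp$correct_side
      trials$epsilon[t] <- 0
      ci <- ci + 1L
    } else {
      p <- pairs[[order_idx[ei]]]
      trials$pair_id[t] <- pair_ids[order_idx[ei]]
      trials$question_class[t] <- p$question_class
      trials$consistent_side[t] <- p$consistent_side
      trials$epsilon[t] <- p$epsilon
      ei <- ei + 1L
    }
  }
  structure(list(trials = trials, n_trials = n_trials, n_catch = n_catch,
                 seed = seed, pair_ids = pair_ids),
            class = "session_plan")
}

#' @export
print.session_plan <- function(x, ...) {
  cat(sprintf("session_plan: %d trials (%d catch), seed %d\n",
              x$n_trials, x$n_catch, x$seed))
  invisible(x)
}

#' Write stimuli and a session manifest to a directory
#'
#' Each pair's left/right images are written as 8-bit PPM files (what an
#' observer would see) and the exact fractional deltas as plain-text grids.
#' The epsilon constraint of each pair's provenance is re-checked at write
#' time. The manifest (CSV) links pair ids to files, question, consistency
#' side, epsilon, and generator provenance.
#'
#' @param pairs list of `stimulus_pair` objects.
#' @param session a [build_session()] plan.
#' @param out_dir output directory (created if needed).
#' @return invisibly, the manifest data.frame (also written to
#'   `manifest.csv`).
#' @export
write_stimuli <- function(pairs, session, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ids <- session$pair_ids
  rows <- vector("list", length(pairs))
  for (i in seq_along(pairs)) {
    p <- pairs[[i]]
    if (max(abs(p$delta_left)) > p$epsilon + 1e-9 ||
        max(abs(p$delta_right)) > p$epsilon + 1e-9)
      stop_advpercept("pair ", ids[i], " violates its epsilon constraint")
    lf <- sprintf("%s_left.ppm", ids[i]); rf <- sprintf("%s_right.ppm", ids[i])
    write_ppm(p$left, file.path(out_dir, lf))
    write_ppm(p$right, file.path(out_dir, rf))
    write_delta(p$delta_left, file.path(out_dir, sprintf("%s_left.delta.txt", ids[i])))
    write_delta(p$delta_right, file.path(out_dir, sprintf("%s_right.delta.txt", ids[i])))
    rows[[i]] <- data.frame(pair_id = ids[i], experiment = p$experiment,
                            left_file = lf, right_file = rf,
                            question_class = p$question_class,
                            consistent_side = p$consistent_side,
                            epsilon = p$epsilon,
                            ensemble_ids = paste(p$provenance$ensemble_ids,
                                                 collapse = "|"),
                            seed = p$provenance$seed,
                            stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  utils::write.csv(session$trials, file.path(out_dir, "session.csv"),
                   row.names = FALSE)
  invisible(manifest)
}

RESPONSE_COLUMNS <- c("participant_id", "pair_id", "question_class", "epsilon",
                      "chosen_side", "chose_adversarial_consistent",
                      "is_catch", "catch_correct")

#' Validate a response table
#'
#' Checks the documented schema: required columns, `chosen_side` defined on
#' every row, `catch_correct` present exactly on catch rows, and consistency
#' indicators defined on non-catch rows.
#' @param responses data.frame.
#' @return the validated data.frame, invisibly.
#' @export
validate_responses <- function(responses) {
  miss <- setdiff(RESPONSE_COLUMNS, names(responses))
  if (length(miss))
    stop_advpercept("response table lacks columns: ", paste(miss, collapse = ", "))
  if (any(is.na(responses$chosen_side)) ||
      !all(responses$chosen_side %in% c("left", "right")))
    stop_advpercept("chosen_side must be 'left' or 'right' on every row")
  catch <- responses$is_catch == 1L
  if (any(is.na(responses$catch_correct[catch])) ||
      any(!is.na(responses$catch_correct[!catch])))
    stop_advpercept("catch_correct must be defined exactly on catch rows")
  if (any(is.na(responses$chose_adversarial_consistent[!catch])))
    stop_advpercept("chose_adversarial_consistent missing on non-catch rows")
  invisible(responses)
}

#' Read a response CSV and check it against a manifest
#'
#' @param path response CSV with the columns of [validate_responses()].
#' @param manifest optional manifest data.frame (or path to `manifest.csv`);
#'   when given, every non-catch `pair_id` must appear in it.
#' @return validated response data.frame.
#' @export
read_responses <- function(path, manifest = NULL) {
  responses <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_responses(responses)
  if (!is.null(manifest)) {
    if (is.character(manifest)) manifest <- utils::read.csv(manifest,
                                                            stringsAsFactors = FALSE)
    unknown <- setdiff(responses$pair_id[responses$is_catch == 0L],
                       manifest$pair_id)
    if (length(unknown))
      stop_advpercept("responses reference unknown pair ids: ",
                      paste(unique(unknown), collapse = ", "))
  }
  responses
}
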