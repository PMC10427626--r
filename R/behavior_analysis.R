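# Behavioral statistics: exclusions, perceptual bias, model-observer bias,
# tests, mixed ANOVA, correlations, permutation nulls.

CATCH_FAIL_THRESHOLDS <- c(E2 = 1L, E3 = 1L, E4 = 2L, E5 = 1L)

#' Apply catch-trial exclusion rules
#'
#' Drops every row of participants whose failed-catch count reaches the
#' experiment's termination threshold: one failed catch for E2, E3 and E5,
#' two for E4. Rows of retained participants are never altered.
#'
#' @param responses response table (see [validate_responses()]).
#' @param experiment `"E2"`, `"E3"`, `"E4"` or `"E5"`.
#' @return the filtered response table; attribute `excluded` lists the
#'   dropped participant ids.
#' @export
apply_exclusions <- function(responses, experiment) {
  if (!experiment %in% names(CATCH_FAIL_THRESHOLDS))
    stop_advpercept("no exclusion rule for experiment tag '", experiment, "'")
  thr <- CATCH_FAIL_THRESHOLDS[[experiment]]
  fails <- tapply(responses$is_catch == 1L & responses$catch_correct %in% 0L,
                  responses$participant_id, sum)
  bad <- names(fails)[fails >= thr]
  out <- responses[!responses$participant_id %in% bad, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "excluded") <- bad
  out
}

#' Perceptual bias summaries
#'
#' Per group, the proportion of non-catch trials on which the
#' adversarial-consistent side was chosen. When the grouping is coarser than
#' participants, the SE is the standard error of the participant-level
#' biases within the group; otherwise a binomial SE.
#'
#' @param responses response table.
#' @param group_by character vector of grouping columns (default
#'   `c("question_class", "epsilon")`).
#' @return data.frame with the grouping keys, `bias`, `n_trials`,
#'   `n_participants`, `se`.
#' @export
perceptual_bias <- function(responses, group_by = c("question_class", "epsilon")) {
  df <- responses[responses$is_catch == 0L, , drop = FALSE]
  if (nrow(df) == 0) stop_advpercept("no non-catch rows")
  keys <- df[, group_by, drop = FALSE]
  gid <- interaction(keys, drop = TRUE, lex.order = TRUE)
  rows <- lapply(levels(gid), function(g) {
    sub <- df[gid == g, , drop = FALSE]
    pb <- tapply(sub$chose_adversarial_consistent, sub$participant_id, mean)
    pb <- pb[!is.na(pb)]
    bias <- mean(sub$chose_adversarial_consistent)
    se <- if (!"participant_id" %in% group_by && length(pb) > 1)
      stats::sd(pb) / sqrt(length(pb))
    else sqrt(bias * (1 - bias) / nrow(sub))
    cbind(sub[1, group_by, drop = FALSE],
          data.frame(bias = bias, n_trials = nrow(sub),
                     n_participants = length(pb), se = se))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-participant bias table for ANOVA / t tests
#'
#' One row per participant per (class, epsilon) cell.
#' @param responses response table.
#' @return data.frame `participant_id`, `question_class`, `epsilon`, `bias`.
#' @export
participant_bias_table <- function(responses) {
  perceptual_bias(responses,
                  group_by = c("participant_id", "question_class", "epsilon"))
}

#' Forced-choice bias of a held-out (black-box) model observer
#'
#' For each stimulus pair, the model observer picks the side whose coarse
#' score for the question class is higher; exact ties are broken by a seeded
#' coin flip and flagged. The scorer must not appear in any pair's
#' generating-ensemble provenance.
#'
#' @param pairs list of `stimulus_pair` objects.
#' @param scorer a held-out scorer.
#' @param mapping a [coarse_mapping()].
#' @param score_diff if `TRUE`, also report the continuous left-minus-right
#'   coarse-score difference (the configurable alternative to the binary
#'   indicator).
#' @param seed tie-break seed.
#' @return data.frame with one row per pair: `pair_id`, `choice`,
#'   `consistent` (0/1), `score_diff`, `tie`.
#' @export
ann_observer_bias <- function(pairs, scorer, mapping, score_diff = TRUE,
                              seed = 1L) {
  for (p in pairs) {
    ids <- unlist(strsplit(p$provenance$ensemble_ids, "+", fixed = TRUE))
    if (scorer$id %in% ids)
      stop_advpercept("scorer ", scorer$id,
                      " was used to generate pair ", p$source_id,
                      ": black-box requirement violated")
  }
  rows <- vector("list", length(pairs))
  with_seed(seed, {
    for (i in seq_along(pairs)) {
      p <- pairs[[i]]
      sl <- coarse_score(score_logits(scorer, p$left), mapping, p$question_class)
      sr <- coarse_score(score_logits(scorer, p$right), mapping, p$question_class)
      tie <- isTRUE(all.equal(sl, sr))
      choice <- if (tie) sample(c("left", "right"), 1)
      else if (sl > sr) "left" else "right"
      rows[[i]] <- data.frame(
        pair_id = sprintf("%s_%s_e%g", p$experiment, p$source_id, p$epsilon),
        choice = choice,
        consistent = as.integer(choice == p$consistent_side),
        score_diff = if (score_diff) sl - sr else NA_real_,
        tie = tie, stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, rows)
}

stat_result <- function(statistic, value, df, p, effect_name = NA, effect = NA,
                        ci = c(NA, NA)) {
  structure(list(statistic = statistic, value = value, df = df, p = p,
                 effect_name = effect_name, effect = effect, ci = ci),
            class = "stat_result")
}

#' @export
print.stat_result <- function(x, ...) {
  cat(sprintf("%s = %.4f, df = %s, p = %.4g", x$statistic, x$value,
              paste(round(x$df, 2), collapse = ","), x$p))
  if (!is.na(x$effect_name)) cat(sprintf(", %s = %.3f", x$effect_name, x$effect))
  if (!anyNA(x$ci)) cat(sprintf(", 95%% CI [%.4f, %.4f]", x$ci[1], x$ci[2]))
  cat("\n")
  invisible(x)
}

#' One-sample t test of participant biases against chance
#'
#' @param biases numeric vector of per-participant biases.
#' @param null null value (default chance, 0.5).
#' @param tails 1 or 2.
#' @return a `stat_result` with t, df = n - 1, p, Cohen's d
#'   (`(mean - null) / sd`) and the 95% CI of the mean.
#' @export
bias_ttest <- function(biases, null = 0.5, tails = 2) {
  n <- length(biases)
  if (n < 2) stop_advpercept("need at least 2 biases")
  s <- stats::sd(biases)
  if (s == 0) stop_advpercept("zero variance in biases (all equal to ",
                              biases[1], ")")
  tt <- stats::t.test(biases, mu = null,
                      alternative = if (tails == 1) "greater" else "two.sided")
  stat_result("t", unname(tt$statistic), n - 1, tt$p.value,
              "cohens_d", (mean(biases) - null) / s,
              if (tails == 2) unname(tt$conf.int) else c(NA, NA))
}

#' Bonferroni correction
#' @param p vector of p values.
#' @param m number of comparisons (default `length(p)`).
#' @return corrected p values, capped at 1.
#' @export
bonferroni <- function(p, m = length(p)) pmin(1, p * m)

#' Mixed two-factor ANOVA with partial eta squared
#'
#' Between-participant factor `question_class`, within-participant factor
#' `epsilon` (each participant contributes one class at every epsilon
#' level). Classical mixed-design decomposition via `aov` with an
#' `Error(participant/epsilon)` stratum; partial eta squared is
#' `SS_effect / (SS_effect + SS_error)` within the effect's stratum.
#' Participants with missing epsilon cells are dropped listwise (logged via
#' a message).
#'
#' @param bias_table data.frame from [participant_bias_table()].
#' @return named list of `stat_result`s: `class`, `epsilon`,
#'   `class_x_epsilon`.
#' @export
two_factor_anova <- function(bias_table) {
  df <- bias_table
  df$participant_id <- factor(df$participant_id)
  df$question_class <- factor(df$question_class)
  df$epsilon <- factor(df$epsilon)
  classes_per_part <- tapply(df$question_class, df$participant_id,
                             function(x) length(unique(x)))
  if (any(classes_per_part > 1))
    stop_advpercept("mixed design requires one question class per participant ",
                    "(class is the between factor); see make_trials(design = 'between')")
  n_lev <- nlevels(df$epsilon)
  cells <- tapply(df$bias, df$participant_id, length)
  bad <- names(cells)[cells < n_lev]
  if (length(bad)) {
    message("dropping ", length(bad), " participant(s) with missing epsilon cells")
    df <- df[!df$participant_id %in% bad, , drop = FALSE]
    df$participant_id <- droplevels(df$participant_id)
  }
  fit <- stats::aov(bias ~ question_class * epsilon +
                      Error(participant_id / epsilon), data = df)
  sm <- summary(fit)
  pull <- function(stratum, term) {
    tab <- sm[[stratum]][[1]]
    row <- grep(paste0("^", term, "\\s*$"), rownames(tab))
    err <- grep("Residuals", rownames(tab))
    ss_e <- tab[row, "Sum Sq"]; ss_r <- tab[err, "Sum Sq"]
    stat_result("F", tab[row, "F value"],
                c(tab[row, "Df"], tab[err, "Df"]),
                tab[row, "Pr(>F)"],
                "partial_eta_sq", ss_e / (ss_e + ss_r))
  }
  list(class = pull("Error: participant_id", "question_class"),
       epsilon = pull("Error: participant_id:epsilon", "epsilon"),
       class_x_epsilon = pull("Error: participant_id:epsilon",
                              "question_class:epsilon"))
}

#' Tie-aware Spearman correlation with df, p, and CI
#'
#' Midrank-based rho (Pearson correlation of average ranks), t approximation
#' with df = n - 2, and a Fisher-z 95% CI.
#'
#' @param x,y paired numeric vectors, n >= 3.
#' @return a `stat_result` with statistic `"rho"`.
#' @export
spearman_bias_correlation <- function(x, y) {
  if (length(x) != length(y)) stop_advpercept("x and y must be paired")
  n <- length(x)
  if (n < 3) stop_advpercept("need n >= 3 pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop_advpercept("constant input: rho undefined")
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  tval <- rho * sqrt((n - 2) / max(1 - rho^2, 1e-15))
  p <- 2 * stats::pt(-abs(tval), n - 2)
  ci <- if (n > 3) tanh(atanh(clip(rho, -1 + 1e-12, 1 - 1e-12)) +
                        c(-1, 1) * 1.96 / sqrt(n - 3)) else c(NA, NA)
  stat_result("rho", rho, n - 2, p, ci = ci)
}

#' Permutation null via within-participant consistency shuffling
#'
#' Reassigns which side of each trial counts as adversarial-consistent by
#' permuting the consistent-side labels across each participant's non-catch
#' trials, recomputing `chose_adversarial_consistent` against the actual
#' choices. With side assignments balanced by design this destroys any
#' stimulus-locked bias while preserving each participant's response habits
#' (e.g. a left-button preference).
#'
#' @param responses response table.
#' @param statistic function mapping a response table to a scalar (default:
#'   mean non-catch consistency).
#' @param n_perm number of permutations (a warning below 100).
#' @param seed RNG seed.
#' @param alternative `"greater"` (default) or `"two.sided"`.
#' @return list with `observed`, `null` (length `n_perm`), and the
#'   rank-based `p = (1 + #{null >= observed}) / (n_perm + 1)`.
#' @export
permutation_null <- function(responses, statistic = NULL, n_perm = 1000L,
                             seed = 1L, alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  if (n_perm < 100) warning("n_perm < 100 gives a coarse null")
  statistic <- statistic %||%
    function(r) mean(r$chose_adversarial_consistent[r$is_catch == 0L])
  observed <- statistic(responses)
  noncatch <- which(responses$is_catch == 0L)
  cons_side <- ifelse(responses$chose_adversarial_consistent == 1L,
                      responses$chosen_side,
                      ifelse(responses$chosen_side == "left", "right", "left"))
  null <- numeric(n_perm)
  with_seed(seed, {
    by_part <- split(noncatch, responses$participant_id[noncatch])
    for (b in seq_len(n_perm)) {
      r2 <- responses
      for (ix in by_part) {
        perm <- ix[sample.int(length(ix))]
        r2$chose_adversarial_consistent[ix] <-
          as.integer(r2$chosen_side[ix] == cons_side[perm])
      }
      null[b] <- statistic(r2)
    }
  })
  p <- if (alternative == "greater") (1 + sum(null >= observed)) / (n_perm + 1)
  else (1 + sum(abs(null - mean(null)) >= abs(observed - mean(null)))) / (n_perm + 1)
  list(observed = observed, null = null, p = p)
}

#' Shapiro-Wilk normality check (thin wrapper)
#' @param x numeric vector.
#' @return a `stat_result` with statistic `"W"`.
#' @export
shapiro_wilk <- function(x) {
  r <- stats::shapiro.test(x)
  stat_result("W", unname(r$statistic), length(x), r$p.value)
}

#' Wilcoxon signed-rank test against a null value (thin wrapper)
#' @param x numeric vector.
#' @param null null location (default chance, 0.5).
#' @return a `stat_result` with statistic `"V"`.
#' @export
wilcoxon_signed_rank <- function(x, null = 0.5) {
  r <- suppressWarnings(stats::wilcox.test(x, mu = null))
  stat_result("V", unname(r$statistic), length(x), r$p.value)
}
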