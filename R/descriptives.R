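#' Dataset-level descriptive statistics
#'
#' Computes the headline rates of a dyad-game dataset: how often speakers
#' told the truth, how often guessers judged utterances truthful (clicked
#' the referent), and the guessers' truth-lie discrimination accuracy,
#' overall and conditional on veracity. Per-speaker variability (standard
#' error, minimum, maximum) is computed over speaker-level percentages,
#' with n equal to the number of speakers.
#'
#' The conditional accuracies recompose exactly:
#' `accuracy_overall = truth_rate * accuracy_given_truth +
#' (1 - truth_rate) * accuracy_given_lie` on the same trial counts.
#'
#' @param trials trial data.frame; normally the `cue_models` subset from
#'   [apply_exclusions()].
#' @return an object of class `"deception_descriptives"`: a list with
#'   percentages `truth_rate`, `perceived_truth_rate`, `accuracy_overall`,
#'   `accuracy_given_truth`, `accuracy_given_lie`, counts `n_trials` and
#'   `n_speakers`, and a `per_speaker` data.frame with SE/min/max for each
#'   rate.
#' @examples
#' sim <- simulate_dyads(dyad_config(n_dyads = 4, seed = 1))
#' descriptives(apply_exclusions(sim$trials, "cue_models")$included)
#' @export
descriptives <- function(trials) {
  if (!nrow(trials)) stop("no trials to summarise", call. = FALSE)
  truth   <- trials$veracity == "truth"
  perc    <- trials$response == "truth"
  correct <- trials$veracity == trials$response

  pct <- function(x) 100 * mean(x)
  by_speaker <- function(x) {
    m <- tapply(x, trials$dyad_id, mean) * 100
    c(se = stats::sd(m) / sqrt(length(m)), min = min(m), max = max(m))
  }
  per_speaker <- rbind(
    truth_rate = by_speaker(truth),
    perceived_truth_rate = by_speaker(perc),
    accuracy_overall = by_speaker(correct)
  )

  structure(list(
    truth_rate = pct(truth),
    perceived_truth_rate = pct(perc),
    accuracy_overall = pct(correct),
    accuracy_given_truth = pct(correct[truth]),
    accuracy_given_lie = pct(correct[!truth]),
    n_trials = nrow(trials),
    n_speakers = length(unique(trials$dyad_id)),
    per_speaker = as.data.frame(per_speaker)
  ), class = "deception_descriptives")
}

#' @export
print.deception_descriptives <- function(x, digits = 1, ...) {
  f <- function(v) formatC(v, digits = digits, format = "f")
  cat("Dyad-game descriptives (", x$n_trials, " utterances, ",
      x$n_speakers, " speakers)\n", sep = "")
  ps <- x$per_speaker
  cat(sprintf("  Speaker truth rate:    %s%% (SE = %s, min = %s, max = %s)\n",
              f(x$truth_rate), f(ps["truth_rate", "se"]),
              f(ps["truth_rate", "min"]), f(ps["truth_rate", "max"])))
  cat(sprintf("  Perceived truth rate:  %s%% (SE = %s, min = %s, max = %s)\n",
              f(x$perceived_truth_rate), f(ps["perceived_truth_rate", "se"]),
              f(ps["perceived_truth_rate", "min"]),
              f(ps["perceived_truth_rate", "max"])))
  cat(sprintf("  Discrimination accuracy: %s%% overall; %s%% given truth, %s%% given lie\n",
              f(x$accuracy_overall), f(x$accuracy_given_truth),
              f(x$accuracy_given_lie)))
  invisible(x)
}

#' Cohen's kappa for two binary coders
#'
#' Two-rater chance-corrected agreement with marginal-product expected
#' agreement: `kappa = (p_o - p_e) / (1 - p_e)`.
#'
#' @param coder_a,coder_b equal-length vectors of binary codes (any two
#'   levels; coerced with `factor` on their union).
#' @return a list of class `"kappa_result"` with elements `kappa`,
#'   `n_items`, `observed_agreement`, `expected_agreement`.
#' @examples
#' cohens_kappa(c(1, 1, 0, 0, 1), c(1, 0, 0, 0, 1))
#' @export
cohens_kappa <- function(coder_a, coder_b) {
  if (length(coder_a) != length(coder_b)) {
    stop("coder vectors must have equal length", call. = FALSE)
  }
  n <- length(coder_a)
  if (n < 2) stop("need at least 2 coded items", call. = FALSE)
  levs <- sort(unique(c(coder_a, coder_b)))
  if (length(levs) > 2) stop("more than two categories", call. = FALSE)
  a <- factor(coder_a, levels = levs)
  b <- factor(coder_b, levels = levs)
  tab <- table(a, b)
  p_o <- sum(diag(tab)) / n
  p_e <- sum(rowSums(tab) * colSums(tab)) / n^2
  if (p_e >= 1 - 1e-12) {
    stop("kappa undefined: both coders constant (expected agreement = 1)",
         call. = FALSE)
  }
  structure(list(kappa = (p_o - p_e) / (1 - p_e),
                 n_items = n,
                 observed_agreement = p_o,
                 expected_agreement = p_e),
            class = "kappa_result")
}

#' @export
print.kappa_result <- function(x, ...) {
  cat(sprintf("Cohen's kappa = %.3f (n = %d, p_o = %.3f, p_e = %.3f)\n",
              x$kappa, x$n_items, x$observed_agreement,
              x$expected_agreement))
  invisible(x)
}

#' Principal-component speech-rate composite
#'
#' A single combined speech-rate measure extracted as the first principal
#' component of a correlation-matrix PCA on three utterance measures:
#' utterance duration, total silent-pause duration, and syllable rate.
#' The component is oriented so that syllable rate loads positively, i.e.
#' higher scores mean faster, more fluent speech; only downstream
#' coefficient signs depend on this convention and it is recorded in the
#' returned object.
#'
#' @param durations utterance durations (ms).
#' @param pause_durations total silent-pause durations (ms).
#' @param syllable_rates syllables per second.
#' @return an object of class `"speech_rate_pca"`: list with `loadings`
#'   (named length-3 vector), `eigenvalue` (of the first component),
#'   `eigenvalues` (all three), `variance_share` (`eigenvalue / 3`),
#'   `scores` (one per trial), and `orientation`.
#' @examples
#' x <- rnorm(50); y <- x + rnorm(50, sd = 0.3); z <- -x + rnorm(50, sd = 0.3)
#' speech_rate_composite(x, y, z)$variance_share
#' @export
speech_rate_composite <- function(durations, pause_durations,
                                  syllable_rates) {
  m <- cbind(utterance_duration = durations,
             silent_pause_duration = pause_durations,
             syllable_rate = syllable_rates)
  if (nrow(m) < 3 || anyNA(m)) {
    stop("need at least 3 complete trials", call. = FALSE)
  }
  sds <- apply(m, 2, stats::sd)
  if (any(sds == 0)) {
    stop("constant column: ", paste(colnames(m)[sds == 0], collapse = ", "),
         call. = FALSE)
  }
  p <- stats::prcomp(m, center = TRUE, scale. = TRUE)
  load1 <- p$rotation[, 1]
  sign_fix <- if (load1["syllable_rate"] < 0) -1 else 1
  structure(list(
    loadings = load1 * sign_fix,
    eigenvalue = p$sdev[1]^2,
    eigenvalues = p$sdev^2,
    variance_share = p$sdev[1]^2 / 3,
    scores = as.numeric(p$x[, 1] * sign_fix),
    orientation = "positive syllable-rate loading (higher = faster speech)"
  ), class = "speech_rate_pca")
}

#' @export
print.speech_rate_pca <- function(x, ...) {
  cat(sprintf("Speech-rate composite: first PC eigenvalue %.3f (%.1f%% of variance)\n",
              x$eigenvalue, 100 * x$variance_share))
  cat("Loadings (", x$orientation, "):\n", sep = "")
  print(round(x$loadings, 3))
  invisible(x)
}
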