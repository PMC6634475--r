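#' Small-sample corrected Akaike information criterion
#'
#' `AICc = -2 log(L) + 2K + 2K(K + 1) / (n - K - 1)`, the AIC with the
#' Hurvich-Tsai small-sample correction. Undefined for `n <= K + 1`.
#'
#' @param loglik maximized log-likelihood.
#' @param K number of estimable parameters.
#' @param n sample size (rows fitted).
#' @return the AICc value.
#' @examples
#' aicc(-100, K = 3, n = 50) # 206 + 24/46
#' @export
aicc <- function(loglik, K, n) {
  stopifnot(is.finite(loglik), K >= 0)
  if (any(n <= K + 1)) {
    stop("AICc undefined: need n > K + 1 (n = ", n, ", K = ", K, ")",
         call. = FALSE)
  }
  -2 * loglik + 2 * K + 2 * K * (K + 1) / (n - K - 1)
}

#' Enumerate the additive candidate model set
#'
#' All `2^p` additive combinations of a predictor set, including the
#' intercept-only null model, in deterministic order: by model size, then
#' lexicographically by predictor position.
#'
#' @param predictors character vector of predictor names (at most 20).
#' @return a list of character vectors, each a fixed-effect set
#'   (`character(0)` is the null model).
#' @examples
#' length(enumerate_candidates(c("a", "b", "c"))) # 8
#' @export
enumerate_candidates <- function(predictors) {
  p <- length(predictors)
  if (anyDuplicated(predictors)) {
    stop("duplicate predictor names", call. = FALSE)
  }
  if (p > 20) stop("more than 20 predictors", call. = FALSE)
  if (p == 0) return(list(character(0)))
  sets <- list(character(0))
  for (k in seq_len(p)) {
    idx <- utils::combn(p, k, simplify = FALSE)
    sets <- c(sets, lapply(idx, function(i) predictors[i]))
  }
  sets
}

#' Multimodel-inference table from a set of fitted candidates
#'
#' Given maximum-likelihood fits of every candidate model on the same
#' data, computes per model: AICc, the difference to the best model
#' (Delta AICc), the Akaike weight `w_i = exp(-Delta_i/2) / sum_r
#' exp(-Delta_r/2)` (a conditional model probability), and the evidence
#' ratio `ER_i = w_best / w_i = exp(Delta_i/2)`; per predictor, the
#' cumulative Akaike weight (sum of weights over models containing it);
#' and the competitive subset (`Delta AICc < threshold`).
#'
#' Non-converged fits are dropped from the candidate set with a warning.
#' Ties for the minimum AICc are broken by smaller `K`, then by position
#' in the candidate list.
#'
#' @param fits list of [cue_fit] objects fitted to identical data.
#' @param threshold Delta-AICc bound defining the competitive subset.
#' @return an object of class `"selection_table"`: list with `models`
#'   (data.frame: model label, K, loglik, AICc, delta, weight, er,
#'   competitive, ordered by AICc), `parameter_weights` (named numeric),
#'   `threshold`, `n`, and `best` (index into `fits` of the best model).
#' @export
selection_table <- function(fits, threshold = 2) {
  stopifnot(length(fits) >= 2)
  conv <- vapply(fits, function(f) isTRUE(f$converged), logical(1))
  if (!all(conv)) {
    warning(sum(!conv), " non-converged fit(s) excluded from selection",
            call. = FALSE)
    fits <- fits[conv]
  }
  if (length(fits) < 2) stop("fewer than 2 converged fits", call. = FALSE)
  n <- vapply(fits, `[[`, numeric(1), "n")
  if (length(unique(n)) != 1) {
    stop("fits use differing n; models are not comparable", call. = FALSE)
  }
  K <- vapply(fits, `[[`, numeric(1), "K")
  ll <- vapply(fits, `[[`, numeric(1), "loglik")
  ic <- mapply(aicc, ll, K, n)

  # best model: minimum AICc; ties by smaller K, then candidate order
  ord <- order(ic, K, seq_along(fits))
  best <- ord[1]
  delta <- ic - ic[best]
  w <- exp(-delta / 2)
  w <- w / sum(w)
  er <- exp(delta / 2)

  label <- vapply(fits, function(f) {
    if (length(f$spec$fixed_effects)) {
      paste(f$spec$fixed_effects, collapse = " + ")
    } else "(null)"
  }, character(1))

  preds <- unique(unlist(lapply(fits, function(f) f$spec$fixed_effects)))
  pw <- vapply(preds, function(p) {
    sum(w[vapply(fits, function(f) p %in% f$spec$fixed_effects,
                 logical(1))])
  }, numeric(1))

  models <- data.frame(
    model = label, K = K, loglik = ll, AICc = ic, delta = delta,
    weight = w, er = er, competitive = delta < threshold,
    stringsAsFactors = FALSE
  )[ord, ]
  rownames(models) <- NULL

  structure(list(models = models, parameter_weights = pw,
                 threshold = threshold, n = n[1], best = best,
                 fits = fits),
            class = "selection_table")
}

#' @export
print.selection_table <- function(x, max_rows = 10, digits = 4, ...) {
  cat(sprintf("AICc model selection: %d candidate models, n = %d\n",
              nrow(x$models), x$n))
  m <- x$models
  m$loglik <- round(m$loglik, 2)
  m[c("AICc", "delta", "weight", "er")] <-
    round(m[c("AICc", "delta", "weight", "er")], digits)
  print(utils::head(m, max_rows))
  if (nrow(m) > max_rows) cat("  ... and", nrow(m) - max_rows, "more\n")
  cat("\nCumulative Akaike weights:\n")
  print(round(sort(x$parameter_weights, decreasing = TRUE), digits))
  invisible(x)
}

#' Exhaustive AICc cue-model selection
#'
#' The package's central analysis: for a binary game outcome (speaker
#' veracity or guesser response) and a cue family, fits every additive
#' combination of the cue predictors — `2^5 = 32` speech models (pauses,
#' repetitions, repairs, prolongations, speech rate) or `2^4 = 16`
#' gesture models (adaptors, illustrators, affect displays, eye
#' contact), each with crossed random intercepts for dyads and items —
#' and summarises the candidate set by AICc weights, evidence ratios,
#' cumulative parameter weights, and the competitive subset.
#'
#' Speech analyses use trials surviving the `cue_models` exclusion;
#' gesture analyses additionally drop trials without gesture video. The
#' `speech_rate` predictor is the standardized first-principal-component
#' composite of utterance duration, silent-pause duration and syllable
#' rate (computed here if not already a column; see
#' [speech_rate_composite()]).
#'
#' @param outcome `"speaker_veracity"` or `"guesser_response"`.
#' @param cue_set `"speech"` or `"gesture"`.
#' @param data trial data.frame (exclusions not yet applied is fine; the
#'   `cue_models` rule is applied internally unless
#'   `apply_exclusion = FALSE`).
#' @param threshold Delta-AICc bound for the competitive subset.
#' @param random random-effects structure passed to [fit_cue_glmm()].
#' @param apply_exclusion apply the `cue_models` exclusion rule first.
#' @return an object of class `"cue_selection"`: the [selection_table()]
#'   plus `outcome`, `cue_set`, `predictors`, `exclusion_log`, and the
#'   best model's [cue_fit].
#' @examples
#' \donttest{
#' sim <- simulate_dyads(dyad_config(n_dyads = 6, seed = 7))
#' sel <- cue_selection("guesser_response", "speech", sim$trials)
#' summary(sel)
#' }
#' @export
cue_selection <- function(outcome = c("speaker_veracity", "guesser_response"),
                          cue_set = c("speech", "gesture"),
                          data,
                          threshold = 2,
                          random = c("crossed", "none"),
                          apply_exclusion = TRUE) {
  outcome <- match.arg(outcome)
  cue_set <- match.arg(cue_set)
  random <- match.arg(random)

  excl_log <- NULL
  if (apply_exclusion) {
    ex <- apply_exclusions(data, "cue_models")
    data <- ex$included
    excl_log <- ex$log
  }
  if (!"pauses" %in% names(data)) data <- collapse_categories(data)

  if (cue_set == "speech") {
    predictors <- .speech_predictors
    if (!"speech_rate" %in% names(data)) {
      comp <- speech_rate_composite(data$utterance_duration,
                                    data$silent_pause_duration,
                                    data$syllable_rate)
      data$speech_rate <- as.numeric(scale(comp$scores))
    }
  } else {
    predictors <- .gesture_predictors
    data <- data[data$gesture_data_present == 1L, , drop = FALSE]
  }

  cand <- enumerate_candidates(predictors)
  fits <- lapply(cand, function(fx) {
    fit_cue_glmm(outcome, fx, data, random = random)
  })
  tab <- selection_table(fits, threshold = threshold)
  structure(c(tab,
              list(outcome = outcome, cue_set = cue_set,
                   predictors = predictors, exclusion_log = excl_log)),
            class = c("cue_selection", "selection_table"))
}

#' @export
print.cue_selection <- function(x, ...) {
  cat(sprintf("Cue selection: %s ~ %s cues (%d candidates)\n\n",
              x$outcome, x$cue_set, nrow(x$models)))
  NextMethod()
}

#' Best-model report for a cue selection
#'
#' Summarises the winning model: its Akaike weight, distance to and
#' evidence ratio of the runner-up, the competitive subset (how many
#' models fall within the Delta-AICc threshold and how many of those
#' contain each predictor), and the best model's coefficients with odds
#' ratios `exp(beta)`.
#'
#' @param object a `"cue_selection"` (or a `"selection_table"`).
#' @param ... unused.
#' @return a list of class `"cue_selection_summary"` with components
#'   `best_model`, `best_weight`, `delta_runner_up`, `er_runner_up`,
#'   `competitive` (data.frame of competitive models), `containment`
#'   (per-predictor counts within the competitive set),
#'   `parameter_weights` and `coefficients` (with `odds_ratio`).
#' @export
summary.cue_selection <- function(object, ...) {
  m <- object$models
  best_fit <- object$fits[[object$best]]
  coefs <- best_fit$coefficients
  coefs$odds_ratio <- exp(coefs$estimate)
  comp <- m[m$competitive, , drop = FALSE]
  containment <- vapply(object$predictors, function(p) {
    sum(vapply(strsplit(comp$model, " \\+ "),
               function(terms) p %in% terms, logical(1)))
  }, integer(1))
  structure(list(
    outcome = object$outcome, cue_set = object$cue_set,
    best_model = m$model[1],
    best_weight = m$weight[1],
    delta_runner_up = m$delta[2],
    er_runner_up = m$er[2],
    n_competitive = nrow(comp),
    competitive = comp,
    containment = containment,
    parameter_weights = object$parameter_weights,
    coefficients = coefs,
    threshold = object$threshold
  ), class = "cue_selection_summary")
}

#' @export
print.cue_selection_summary <- function(x, digits = 4, ...) {
  cat(sprintf("Best-supported %s model for %s: %s\n",
              x$cue_set, x$outcome, x$best_model))
  cat(sprintf("  Akaike weight %.3f; runner-up Delta AICc = %.2f, ER = %.2f\n",
              x$best_weight, x$delta_runner_up, x$er_runner_up))
  cat(sprintf("  %d model(s) within %g Delta AICc; containment:\n",
              x$n_competitive, x$threshold))
  print(x$containment)
  cat("\nBest-model coefficients (odds ratio = exp(beta)):\n")
  out <- x$coefficients
  out[c("estimate", "se", "statistic", "odds_ratio")] <-
    round(out[c("estimate", "se", "statistic", "odds_ratio")], digits)
  out$p <- signif(out$p, 2)
  print(out, row.names = FALSE)
  cat("\nCumulative Akaike weights:\n")
  print(round(sort(x$parameter_weights, decreasing = TRUE), digits))
  invisible(x)
}

#' @export
coef.cue_selection <- function(object, ...) {
  coef(object$fits[[object$best]])
}

#' Export a selection table as delimited text
#'
#' Writes the per-model table (terms, K, log-likelihood, AICc,
#' Delta AICc, weight, evidence ratio) and, alongside it, a
#' `*_parameter_weights.tsv` with the cumulative Akaike weights.
#'
#' @param x a `"selection_table"` or `"cue_selection"`.
#' @param path output path for the model table (TSV).
#' @return `path`, invisibly.
#' @export
write_selection_table <- function(x, path) {
  utils::write.table(x$models, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  pw <- data.frame(parameter = names(x$parameter_weights),
                   cumulative_weight = as.numeric(x$parameter_weights))
  pw_path <- paste0(tools::file_path_sans_ext(path),
                    "_parameter_weights.tsv")
  utils::write.table(pw, pw_path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
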