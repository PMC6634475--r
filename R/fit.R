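#' Fit a logistic mixed model for a binary game outcome
#'
#' Fits `outcome ~ predictors` by maximum likelihood (Laplace
#' approximation) with crossed random intercepts for participants
#' (dyads) and items — the target image concealing the treasure — via
#' [lme4::glmer()]. Both outcomes are coded 1 = truth: speaker veracity
#' (`"truth"`/`"lie"`) or guesser response (clicked referent = truth
#' judgement). With `random = "none"` the model is an ordinary
#' maximum-likelihood logistic regression, used when the grouping
#' structure carries no variance.
#'
#' @param outcome `"speaker_veracity"` or `"guesser_response"`.
#' @param predictors character vector of fixed-effect column names
#'   (possibly empty for the intercept-only null model). Binary cues
#'   enter as 0/1 presence dummies; `speech_rate` should be standardized.
#' @param data trial data.frame with collapsed categories (see
#'   [collapse_categories()]) and `dyad_id`, `item_id` columns.
#' @param random `"crossed"` (default) for `(1 | dyad_id) + (1 | item_id)`,
#'   or `"none"` for a plain logistic fit.
#' @return an object of class `"cue_fit"`; see [cue_fit] for contents.
#' @export
fit_cue_glmm <- function(outcome = c("speaker_veracity", "guesser_response"),
                         predictors = character(0),
                         data,
                         random = c("crossed", "none")) {
  outcome <- match.arg(outcome)
  random <- match.arg(random)
  ycol <- if (outcome == "speaker_veracity") "veracity" else "response"
  if (!ycol %in% names(data)) {
    stop("data lacks column ", ycol, call. = FALSE)
  }
  missing <- setdiff(predictors, names(data))
  if (length(missing)) {
    stop("unknown predictor(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  df <- data
  df$.y <- as.integer(df[[ycol]] == "truth")
  use <- stats::complete.cases(df[, c(".y", predictors), drop = FALSE])
  df <- df[use, , drop = FALSE]

  rhs <- if (length(predictors)) paste(predictors, collapse = " + ") else "1"
  if (random == "crossed") {
    fml <- stats::as.formula(
      paste0(".y ~ ", rhs, " + (1 | dyad_id) + (1 | item_id)"))
    converged <- TRUE
    fit <- withCallingHandlers(
      lme4::glmer(fml, data = df, family = stats::binomial(),
                  nAGQ = 1L,
                  control = lme4::glmerControl(
                    optimizer = "bobyqa",
                    check.conv.singular = "ignore")),
      warning = function(w) {
        if (grepl("converge", conditionMessage(w), ignore.case = TRUE)) {
          converged <<- FALSE
        }
        invokeRestart("muffleWarning")
      })
    if (length(fit@optinfo$conv$lme4$messages)) converged <- FALSE
    beta <- lme4::fixef(fit)
    se <- sqrt(diag(as.matrix(stats::vcov(fit))))
    vc <- as.data.frame(lme4::VarCorr(fit))
    varcomp <- stats::setNames(vc$vcov, vc$grp)
    K <- length(beta) + length(lme4::getME(fit, "theta"))
    ll <- as.numeric(stats::logLik(fit))
  } else {
    fml <- stats::as.formula(paste0(".y ~ ", rhs))
    fit <- suppressWarnings(
      stats::glm(fml, data = df, family = stats::binomial()))
    converged <- fit$converged
    beta <- stats::coef(fit)
    se <- sqrt(diag(stats::vcov(fit)))
    varcomp <- numeric(0)
    K <- length(beta)
    ll <- as.numeric(stats::logLik(fit))
  }

  sep <- abs(beta) > 15 & se > 50
  if (any(sep[-1])) {
    stop("apparent complete separation on predictor(s): ",
         paste(names(beta)[-1][sep[-1]], collapse = ", "), call. = FALSE)
  }

  z <- beta / se
  coefs <- data.frame(
    term = names(beta), estimate = unname(beta), se = unname(se),
    statistic = unname(z),
    p = unname(2 * stats::pnorm(-abs(z))),
    stringsAsFactors = FALSE
  )

  new_cue_fit(
    spec = list(outcome = outcome, fixed_effects = predictors,
                random = random, family = "binomial"),
    coefficients = coefs, varcomp = varcomp,
    loglik = ll, K = K, n = nrow(df), converged = converged,
    boundary = if (random == "crossed") lme4::isSingular(fit) else FALSE,
    fit = fit)
}

#' Fitted cue-model container
#'
#' A `"cue_fit"` bundles a fitted model with the quantities model
#' selection needs: `spec` (outcome, fixed effects, random structure,
#' family), `coefficients` (term, estimate, se, statistic, p),
#' `varcomp` (random-effect variances), `loglik` (maximized log
#' likelihood, ML), `K` (estimable parameters: fixed effects including
#' the intercept, plus one per random-effect covariance parameter, plus
#' one residual variance for gaussian fits), `n` (rows used),
#' `converged`, and `boundary` (singular random-effects fit).
#'
#' @name cue_fit
NULL

new_cue_fit <- function(spec, coefficients, varcomp, loglik, K, n,
                        converged, boundary, fit) {
  structure(list(spec = spec, coefficients = coefficients,
                 varcomp = varcomp, loglik = loglik, K = K, n = n,
                 converged = converged, boundary = boundary, fit = fit),
            class = "cue_fit")
}

#' @export
print.cue_fit <- function(x, digits = 3, ...) {
  fx <- if (length(x$spec$fixed_effects)) {
    paste(x$spec$fixed_effects, collapse = " + ")
  } else "1 (null)"
  cat(sprintf("%s %s model: %s ~ %s\n",
              if (x$spec$family == "binomial") "Logistic" else "Linear",
              if (x$spec$random == "none") "fixed-effects" else "mixed",
              x$spec$outcome, fx))
  cat(sprintf("  logLik = %.*f, K = %d, n = %d%s%s\n", digits, x$loglik,
              x$K, x$n,
              if (!x$converged) " [NOT CONVERGED]" else "",
              if (isTRUE(x$boundary)) " [singular fit]" else ""))
  print(cbind(round(x$coefficients[, c("estimate", "se", "statistic")],
                    digits),
              p = signif(x$coefficients$p, 2)),
        row.names = x$coefficients$term)
  invisible(x)
}

#' @export
coef.cue_fit <- function(object, ...) {
  stats::setNames(object$coefficients$estimate,
                  object$coefficients$term)
}

#' @export
logLik.cue_fit <- function(object, ...) {
  structure(object$loglik, df = object$K, nobs = object$n,
            class = "logLik")
}

#' Fit the time-locked trajectory model
#'
#' Linear mixed-effects regression of the per-bin empirical-logit
#' difference on (centred, second-scaled) time, a binary cue, and their
#' interaction. The full random structure has by-subject (dyad) and
#' by-item random intercepts and slopes for both predictors;
#' `random = "intercepts"` fits intercept-only random effects, which is
#' much faster and appropriate for repeated simulation studies. Fixed
#' effects are reported with t statistics (no p-values).
#'
#' @param data per-bin data.frame with columns `elogit_diff`, `time_c`
#'   (centred time in seconds), a 0/1 cue column, `dyad_id`, `item_id`.
#' @param cue name of the 0/1 cue column (e.g. `"pauses"`).
#' @param random `"slopes"` (default) or `"intercepts"`.
#' @param REML use REML (default) or ML.
#' @return a `"cue_fit"` with `family = "gaussian"`; `boundary` is `TRUE`
#'   when the random-effects covariance is singular.
#' @export
fit_trajectory_lmm <- function(data, cue, random = c("slopes", "intercepts"),
                               REML = TRUE) {
  random <- match.arg(random)
  stopifnot(cue %in% names(data), "elogit_diff" %in% names(data),
            "time_c" %in% names(data))
  re <- if (random == "slopes") {
    sprintf("(1 + time_c + %s | dyad_id) + (1 + time_c + %s | item_id)",
            cue, cue)
  } else {
    "(1 | dyad_id) + (1 | item_id)"
  }
  fml <- stats::as.formula(
    sprintf("elogit_diff ~ time_c * %s + %s", cue, re))
  converged <- TRUE
  fit <- withCallingHandlers(
    lme4::lmer(fml, data = data, REML = REML,
               control = lme4::lmerControl(
                 optimizer = "bobyqa",
                 check.conv.singular = "ignore")),
    warning = function(w) {
      if (grepl("converge", conditionMessage(w), ignore.case = TRUE)) {
        converged <<- FALSE
      }
      invokeRestart("muffleWarning")
    })
  if (length(fit@optinfo$conv$lme4$messages)) converged <- FALSE
  beta <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  vc <- as.data.frame(lme4::VarCorr(fit))
  coefs <- data.frame(
    term = names(beta), estimate = unname(beta), se = unname(se),
    statistic = unname(beta / se), p = NA_real_,
    stringsAsFactors = FALSE
  )
  K <- length(beta) + length(lme4::getME(fit, "theta")) + 1L
  new_cue_fit(
    spec = list(outcome = "trajectory_dv",
                fixed_effects = c("time_c", cue,
                                  paste0("time_c:", cue)),
                random = random, family = "gaussian"),
    coefficients = coefs,
    varcomp = stats::setNames(vc$vcov, paste(vc$grp, vc$var1, vc$var2)),
    loglik = as.numeric(stats::logLik(fit)), K = K,
    n = nrow(data), converged = converged,
    boundary = lme4::isSingular(fit), fit = fit)
}
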