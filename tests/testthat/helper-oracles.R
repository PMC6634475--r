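# Independent oracles used across the suite. These deliberately avoid the
# code paths they check: logistic regression by hand-rolled IRLS (not glm),
# OLS by the normal equations (not lm).

irls_logistic <- function(X, y, tol = 1e-12, max_iter = 100) {
  beta <- rep(0, ncol(X))
  for (i in seq_len(max_iter)) {
    eta <- as.vector(X %*% beta)
    mu <- 1 / (1 + exp(-eta))
    w <- mu * (1 - mu)
    z <- eta + (y - mu) / w
    beta_new <- solve(crossprod(X, w * X), crossprod(X, w * z))
    if (max(abs(beta_new - beta)) < tol) {
      return(as.vector(beta_new))
    }
    beta <- as.vector(beta_new)
  }
  as.vector(beta)
}

ols_solve <- function(X, y) {
  as.vector(solve(crossprod(X), crossprod(X, y)))
}

# a minimal hand-built trial table with every required column
make_trials <- function(n = 10,
                        veracity = rep("truth", n),
                        response = rep("truth", n),
                        dyad_id = rep("d01", n),
                        consistent = rep(1L, n),
                        disambiguation_ms = rep(1000, n),
                        filled_pause = rep(0L, n),
                        silent_pause = rep(0L, n),
                        affect_display = rep(0L, n),
                        gesture_present = rep(1L, n)) {
  df <- data.frame(
    dyad_id = dyad_id,
    trial_index = seq_len(n),
    item_id = sprintf("i%03d", seq_len(n)),
    target_side = rep(c("left", "right"), length.out = n),
    treasure = rep(c("gold", "silver"), length.out = n),
    veracity = veracity,
    response = response,
    filled_pause = filled_pause,
    silent_pause = silent_pause,
    repetition = rep(0L, n),
    restart = rep(0L, n),
    substitution = rep(0L, n),
    addition = rep(0L, n),
    prolongation = rep(0L, n),
    g_head = rep(0L, n), g_hand = rep(0L, n), g_body = rep(0L, n),
    g_shoulder = rep(0L, n), g_lip_mouth = rep(0L, n),
    g_eyebrow = rep(0L, n), g_smile_laugh = rep(0L, n),
    g_eye_contact = rep(0L, n),
    adaptor = rep(0L, n),
    illustrator = rep(0L, n),
    affect_display = affect_display,
    eye_contact = rep(0L, n),
    utterance_duration = rep(3000, n),
    silent_pause_duration = ifelse(silent_pause == 1L, 500, 0),
    syllable_rate = rep(3.8, n),
    disambiguation_ms = disambiguation_ms,
    pause_onset_ms = ifelse(filled_pause == 1L | silent_pause == 1L,
                            500, NA_real_),
    affect_onset_ms = ifelse(affect_display == 1L, 500, NA_real_),
    consistent_commitment = consistent,
    gesture_data_present = gesture_present,
    stringsAsFactors = FALSE
  )
  df
}

# straight-line cursor track builder: px positions at 20 ms steps
make_track <- function(x, step_ms = 20) {
  list(t_ms = seq(0, by = step_ms, length.out = length(x)), x_px = x)
}

# binary-outcome table for direct glm/IRLS comparisons: two balanced 0/1
# predictors, no group structure
make_logit_data <- function(n, beta0 = 0.2, beta1 = 0.5, beta2 = -0.4,
                            seed = 1) {
  set.seed(seed)
  x1 <- rbinom(n, 1, 0.5)
  x2 <- rbinom(n, 1, 0.4)
  eta <- beta0 + beta1 * x1 + beta2 * x2
  y <- rbinom(n, 1, plogis(eta))
  out <- make_trials(n)
  out$veracity <- ifelse(y == 1, "truth", "lie")
  out$response <- out$veracity
  out$filled_pause <- as.integer(x1)
  out$repetition <- as.integer(x2)
  out$silent_pause_duration <- 0
  collapse_categories(out)
}
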