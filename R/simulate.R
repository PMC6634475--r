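#' Configuration for the synthetic dyad-game generator
#'
#' Builds the parameter set that [simulate_dyads()] draws from. Defaults
#' describe a 24-dyad, 48-trial treasure-hunt game: speakers are truthful
#' with probability 0.539; each of the seven disfluency types and four
#' gesture categories occurs with a base rate matched to observed
#' per-utterance counts in games of this design, shifted on the logit
#' scale by the speaker's veracity; the guesser's click is drawn from a
#' logistic model on the collapsed cue categories with random intercepts
#' for guesser and item; and the guesser's cursor drifts toward the
#' to-be-clicked object after the utterance disambiguates, with extra
#' onset lag when the utterance contains a pause or lacks an affect
#' display.
#'
#' @param n_dyads number of speaker-guesser pairs.
#' @param trials_per_dyad trials (utterances) per dyad.
#' @param n_items number of images; images form `n_items / 2` fixed pairs
#'   and the treasure image of each pair is the item. Must be at least
#'   `2 * trials_per_dyad`.
#' @param truth_prob probability a speaker tells the truth.
#' @param veracity_re_sd SD of the by-speaker random intercept on the
#'   truth logit (captures the wide per-speaker spread of truth rates).
#' @param cue_base_prob named marginal occurrence probabilities for the
#'   7 disfluency types and 4 gesture categories.
#' @param cue_veracity_shift named logit shifts applied when the speaker
#'   tells the truth (positive = cue more common in truthful utterances).
#' @param response_intercept,response_coef intercept and named
#'   coefficients (on `pauses` and `affect_displays` category flags) of
#'   the guesser's click-the-referent logit.
#' @param response_re_sd length-2 named vector: random-intercept SDs for
#'   `guesser` and `item` in the response model.
#' @param duration_mean,duration_sd lognormal utterance duration moments (ms).
#' @param pause_dur_mean,pause_dur_sd marginal silent-pause duration
#'   moments (ms) including the zeros on trials without a silent pause.
#' @param syllable_mean,syllable_sd syllable rate moments (syll/s).
#' @param latent_corr magnitude of the latent equicorrelation among the
#'   three continuous measures (duration with pause duration positive,
#'   both negative with syllable rate). The latent correlation matrix has
#'   first eigenvalue `1 + 2 * latent_corr`.
#' @param disambig_frac_range disambiguation point as a uniform fraction
#'   of utterance duration.
#' @param inconsistent_rate probability a trial is flagged as
#'   inconsistent commitment (excluded from all analyses).
#' @param no_disambig_rate probability the disambiguation point is
#'   uncodable (excluded from mouse analyses).
#' @param pause_post_rate,affect_post_rate probability that the focal cue
#'   onsets after the disambiguation point, among trials carrying it.
#' @param video_lost_dyads number of dyads whose gesture video is lost
#'   (`gesture_data_present = 0`).
#' @param sample_rate_hz cursor sampling rate.
#' @param screen_width_px,object_offset_px display geometry: objects sit
#'   at `screen_width_px / 2 - object_offset_px` and `+ object_offset_px`.
#' @param jitter_sd_px per-sample cursor jitter SD.
#' @param drift_px_s post-onset drift speed toward the clicked object.
#' @param base_lag_ms,decision_lag_mean_ms fixed and exponential-mean
#'   components of the drift-onset delay after disambiguation.
#' @param pause_lag_ms extra drift-onset lag when the utterance contains
#'   a pause.
#' @param affect_lag_ms extra drift-onset lag when the utterance lacks an
#'   affect display.
#' @param seed default RNG seed used by [simulate_dyads()].
#' @return a list of class `"dyad_config"`.
#' @export
dyad_config <- function(n_dyads = 24,
                        trials_per_dyad = 48,
                        n_items = 96,
                        truth_prob = 0.539,
                        veracity_re_sd = 0.35,
                        cue_base_prob = c(
                          filled_pause = 288 / 1149,
                          silent_pause = 588 / 1149,
                          repetition   = 55 / 1149,
                          restart      = 109 / 1149,
                          substitution = 36 / 1149,
                          addition     = 12 / 1149,
                          prolongation = 334 / 1149,
                          adaptor        = 0.45,
                          illustrator    = 0.35,
                          affect_display = 0.30,
                          eye_contact    = 130 / 1101),
                        cue_veracity_shift = c(
                          filled_pause = 0.26,
                          silent_pause = 0.26,
                          repetition   = 0,
                          restart      = 0,
                          substitution = 0,
                          addition     = 0,
                          prolongation = 0,
                          adaptor        = -0.29,
                          illustrator    = 0,
                          affect_display = 0,
                          eye_contact    = 0),
                        response_intercept = 0.36,
                        response_coef = c(pauses = -0.39,
                                          affect_displays = 0.29),
                        response_re_sd = c(guesser = 0.3, item = 0.3),
                        duration_mean = 3008.92,
                        duration_sd = 1329.35,
                        pause_dur_mean = 651.65,
                        pause_dur_sd = 1080.5,
                        syllable_mean = 3.82,
                        syllable_sd = 1.42,
                        latent_corr = 0.595,
                        disambig_frac_range = c(0.2, 0.8),
                        inconsistent_rate = 0.003,
                        no_disambig_rate = 0.189,
                        pause_post_rate = 28 / 525,
                        affect_post_rate = 39 / 273,
                        video_lost_dyads = 1,
                        sample_rate_hz = 50,
                        screen_width_px = 1280,
                        object_offset_px = 320,
                        jitter_sd_px = 3,
                        drift_px_s = 250,
                        base_lag_ms = 100,
                        decision_lag_mean_ms = 250,
                        pause_lag_ms = 300,
                        affect_lag_ms = 300,
                        seed = 1L) {
  cfg <- as.list(environment())
  cue_names <- c(.disfluency_cols, .gesture_category_cols)
  stopifnot(
    n_dyads >= 1, trials_per_dyad >= 1,
    setequal(names(cfg$cue_base_prob), cue_names),
    setequal(names(cfg$cue_veracity_shift), cue_names),
    all(cfg$cue_base_prob > 0 & cfg$cue_base_prob < 1),
    truth_prob >= 0, truth_prob <= 1,
    inconsistent_rate >= 0, inconsistent_rate <= 1,
    no_disambig_rate >= 0, no_disambig_rate <= 1,
    latent_corr >= 0, latent_corr < 1,
    drift_px_s > 0, sample_rate_hz > 0,
    all(c("pauses", "affect_displays") %in% names(cfg$response_coef))
  )
  if (n_items < 2 * trials_per_dyad) {
    stop("infeasible config: need n_items >= 2 * trials_per_dyad ",
         "(each trial uses a fresh image pair)", call. = FALSE)
  }
  structure(cfg, class = "dyad_config")
}

#' Read a generator configuration from a YAML file
#'
#' Keys mirror the arguments of [dyad_config()]; nested maps (for the
#' named parameter vectors such as `cue_base_prob`) become named
#' vectors. Keys not present keep their defaults, and `overrides` given
#' in the call win over file values.
#'
#' @param path YAML file.
#' @param ... overrides passed on to [dyad_config()].
#' @return a `"dyad_config"`.
#' @export
dyad_config_from_yaml <- function(path, ...) {
  vals <- yaml::read_yaml(path)
  if (!is.list(vals)) stop("config file is not a key/value map",
                           call. = FALSE)
  unknown <- setdiff(names(vals), names(formals(dyad_config)))
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  vals <- lapply(vals, function(v) if (is.list(v)) unlist(v) else v)
  over <- list(...)
  vals[names(over)] <- over
  do.call(dyad_config, vals)
}

#' @export
print.dyad_config <- function(x, ...) {
  cat(sprintf("Dyad-game generator config: %d dyads x %d trials, truth_prob = %.3f, seed = %d\n",
              x$n_dyads, x$trials_per_dyad, x$truth_prob, as.integer(x$seed)))
  invisible(x)
}

# per-cue logit such that the marginal occurrence rate matches base_prob
# given the veracity mixture (first-order centring of the shift)
.cue_base_logit <- function(p, shift, truth_prob) {
  stats::qlogis(p) - truth_prob * shift
}

#' Simulate a dyad deception game
#'
#' Draws a complete synthetic dataset: a trial table (one row per
#' utterance with veracity, guesser response, all raw and category cue
#' flags, continuous speech measures, disambiguation point and cue onset
#' times) and long-format cursor logs sampled at the configured rate,
#' plus a ground-truth record of every generating parameter and drawn
#' random effect. The same seed reproduces the dataset bit for bit.
#'
#' Generation runs cause-to-cue: veracity is drawn first, cue flags are
#' drawn conditional on veracity, and the guesser's response is drawn
#' from the collapsed cue categories. The cursor starts at screen centre
#' and, after the disambiguation point plus a lag, drifts toward the
#' object the guesser eventually clicks; the lag grows when the utterance
#' contains a pause or lacks an affect display, so real-time referent
#' bias is weaker on those trials.
#'
#' @param config a [dyad_config()].
#' @param seed RNG seed; defaults to `config$seed`.
#' @param cursor generate cursor trajectories (default `TRUE`). Skipping
#'   them speeds up large trial-level simulation studies; the trial table
#'   is identical either way because cursor noise is drawn last.
#' @return an object of class `"dyad_sim"`: list with `trials` (trial
#'   data.frame), `cursor` (data.frame `dyad_id`, `trial_index`, `t_ms`,
#'   `x_px`, `y_px`, or `NULL`), `truth` (ground-truth record), and
#'   `config`.
#' @examples
#' sim <- simulate_dyads(dyad_config(n_dyads = 2, seed = 42))
#' head(sim$trials[, c("dyad_id", "veracity", "response", "pauses")])
#' @export
simulate_dyads <- function(config = dyad_config(), seed = config$seed,
                           cursor = TRUE) {
  stopifnot(inherits(config, "dyad_config"))
  set.seed(as.integer(seed))
  cfg <- config
  n_dyads <- cfg$n_dyads
  n_trials <- cfg$trials_per_dyad
  n_pairs <- cfg$n_items %/% 2L
  N <- n_dyads * n_trials

  dyad_id <- rep(sprintf("d%02d", seq_len(n_dyads)), each = n_trials)
  trial_index <- rep(seq_len(n_trials), times = n_dyads)

  # each trial presents one of the fixed image pairs (order randomised per
  # dyad); the item is the image concealing the treasure, chosen per dyad
  pair <- as.vector(vapply(seq_len(n_dyads),
                           function(i) sample(n_pairs, n_trials),
                           integer(n_trials)))
  which_of_pair <- stats::rbinom(N, 1, 0.5)
  item_id <- sprintf("i%03d", 2L * pair - which_of_pair)
  target_side <- sample(c("left", "right"), N, replace = TRUE)
  treasure <- ifelse(stats::rbinom(N, 1, 0.5) == 1, "gold", "silver")

  # speaker veracity with a by-speaker random intercept
  speaker_re <- stats::rnorm(n_dyads, 0, cfg$veracity_re_sd)
  ver_logit <- stats::qlogis(cfg$truth_prob) + speaker_re[match(dyad_id, unique(dyad_id))]
  is_truth <- stats::rbinom(N, 1, stats::plogis(ver_logit))
  veracity <- ifelse(is_truth == 1, "truth", "lie")

  # cue flags conditional on veracity
  cue_names <- c(.disfluency_cols, .gesture_category_cols)
  cue_flags <- matrix(0L, N, length(cue_names),
                      dimnames = list(NULL, cue_names))
  base_logit <- mapply(.cue_base_logit,
                       cfg$cue_base_prob[cue_names],
                       cfg$cue_veracity_shift[cue_names],
                       MoreArgs = list(truth_prob = cfg$truth_prob))
  for (cue in cue_names) {
    p <- stats::plogis(base_logit[[cue]] +
                         cfg$cue_veracity_shift[[cue]] * is_truth)
    cue_flags[, cue] <- stats::rbinom(N, 1, p)
  }
  # raw gesture types: descriptive annotations, drawn at fixed rates
  raw_gest_prob <- c(g_head = 651, g_hand = 280, g_body = 377,
                     g_shoulder = 26, g_lip_mouth = 85, g_eyebrow = 242,
                     g_smile_laugh = 156, g_eye_contact = 130) / 1101
  raw_gest <- vapply(raw_gest_prob,
                     function(p) stats::rbinom(N, 1, p), integer(N))

  pauses_cat <- as.integer(cue_flags[, "filled_pause"] |
                             cue_flags[, "silent_pause"])
  affect_cat <- cue_flags[, "affect_display"]

  # guesser response: logistic on cue categories with crossed random
  # intercepts for guesser (one per dyad) and item
  guesser_re <- stats::rnorm(n_dyads, 0, cfg$response_re_sd[["guesser"]])
  item_levels <- sprintf("i%03d", seq_len(cfg$n_items))
  item_re <- stats::rnorm(cfg$n_items, 0, cfg$response_re_sd[["item"]])
  names(item_re) <- item_levels
  resp_logit <- cfg$response_intercept +
    cfg$response_coef[["pauses"]] * pauses_cat +
    cfg$response_coef[["affect_displays"]] * affect_cat +
    guesser_re[match(dyad_id, unique(dyad_id))] +
    item_re[item_id]
  click_ref <- stats::rbinom(N, 1, stats::plogis(resp_logit))
  response <- ifelse(click_ref == 1, "truth", "lie")

  # continuous speech measures from a trivariate latent normal
  r <- cfg$latent_corr
  R <- matrix(c(1, r, -r,
                r, 1, -r,
                -r, -r, 1), 3, 3)
  L <- chol(R)
  z <- matrix(stats::rnorm(3 * N), N, 3) %*% L

  sdlog <- sqrt(log(1 + (cfg$duration_sd / cfg$duration_mean)^2))
  meanlog <- log(cfg$duration_mean) - sdlog^2 / 2
  utterance_duration <- exp(meanlog + sdlog * z[, 1])

  p_sp <- mean(cue_flags[, "silent_pause"])
  p_sp <- max(p_sp, 1e-6)
  m_c <- cfg$pause_dur_mean / p_sp
  v_c <- (cfg$pause_dur_sd^2 + cfg$pause_dur_mean^2) / p_sp - m_c^2
  v_c <- max(v_c, (0.1 * m_c)^2)
  sdlog_p <- sqrt(log(1 + v_c / m_c^2))
  meanlog_p <- log(m_c) - sdlog_p^2 / 2
  silent_pause_duration <- ifelse(
    cue_flags[, "silent_pause"] == 1L,
    pmin(exp(meanlog_p + sdlog_p * z[, 2]), 0.95 * utterance_duration),
    0)

  syllable_rate <- pmax(cfg$syllable_mean + cfg$syllable_sd * z[, 3], 0.3)

  # disambiguation point and cue onsets
  disambiguation_ms <- utterance_duration *
    stats::runif(N, cfg$disambig_frac_range[1], cfg$disambig_frac_range[2])
  no_dis <- stats::rbinom(N, 1, cfg$no_disambig_rate) == 1L
  onset_for <- function(has_cue, post_rate) {
    post <- stats::rbinom(N, 1, post_rate) == 1L
    onset <- ifelse(post,
                    disambiguation_ms +
                      stats::runif(N) * (utterance_duration - disambiguation_ms),
                    stats::runif(N) * disambiguation_ms)
    ifelse(has_cue, onset, NA_real_)
  }
  pause_onset_ms  <- onset_for(pauses_cat == 1L, cfg$pause_post_rate)
  affect_onset_ms <- onset_for(affect_cat == 1L, cfg$affect_post_rate)

  consistent_commitment <-
    as.integer(stats::rbinom(N, 1, 1 - cfg$inconsistent_rate))
  lost <- if (cfg$video_lost_dyads > 0) {
    unique(dyad_id)[seq_len(min(cfg$video_lost_dyads, n_dyads))]
  } else character(0)
  gesture_data_present <- as.integer(!(dyad_id %in% lost))

  trials <- data.frame(
    dyad_id = dyad_id, trial_index = trial_index, item_id = item_id,
    target_side = target_side, treasure = treasure,
    veracity = veracity, response = response,
    as.data.frame(cue_flags[, .disfluency_cols, drop = FALSE]),
    as.data.frame(raw_gest),
    as.data.frame(cue_flags[, .gesture_category_cols, drop = FALSE]),
    utterance_duration = utterance_duration,
    silent_pause_duration = silent_pause_duration,
    syllable_rate = syllable_rate,
    disambiguation_ms = ifelse(no_dis, NA_real_, disambiguation_ms),
    pause_onset_ms = pause_onset_ms,
    affect_onset_ms = affect_onset_ms,
    consistent_commitment = consistent_commitment,
    gesture_data_present = gesture_data_present,
    stringsAsFactors = FALSE
  )

  trials <- collapse_categories(validate_trials(trials))
  cursor <- if (cursor) {
    simulate_cursor(trials, disambiguation_ms, click_ref, cfg)
  } else NULL

  truth <- list(
    config = cfg,
    cue_base_logit = base_logit,
    cue_veracity_shift = cfg$cue_veracity_shift,
    response_intercept = cfg$response_intercept,
    response_coef = cfg$response_coef,
    speaker_re = speaker_re,
    guesser_re = guesser_re,
    item_re = item_re,
    latent_disambiguation_ms = disambiguation_ms
  )

  structure(list(trials = trials, cursor = cursor, truth = truth,
                 config = cfg),
            class = "dyad_sim")
}

# cursor trajectories: centre start, jitter, post-onset constant drift
# toward the clicked object, click on arrival
simulate_cursor <- function(trials, disamb_true, click_ref, cfg) {
  N <- nrow(trials)
  step_ms <- 1000 / cfg$sample_rate_hz
  centre <- cfg$screen_width_px / 2
  drift_step <- cfg$drift_px_s * step_ms / 1000

  ref_side <- referent_side(trials)
  clicked_side <- ifelse(click_ref == 1L, ref_side,
                         ifelse(ref_side == "left", "right", "left"))
  obj_x <- ifelse(clicked_side == "left",
                  centre - cfg$object_offset_px,
                  centre + cfg$object_offset_px)

  has_pause <- trials$pauses == 1L
  lacks_affect <- trials$affect_displays == 0L
  lag <- cfg$base_lag_ms +
    stats::rexp(N, 1 / cfg$decision_lag_mean_ms) +
    ifelse(has_pause, cfg$pause_lag_ms, 0) +
    ifelse(lacks_affect, cfg$affect_lag_ms, 0)
  onset_ms <- disamb_true + lag

  out <- vector("list", N)
  for (i in seq_len(N)) {
    travel_ms <- cfg$object_offset_px / cfg$drift_px_s * 1000
    t_end <- onset_ms[i] + travel_ms + 600
    t <- seq(0, t_end, by = step_ms)
    nt <- length(t)
    jit <- stats::rnorm(nt, 0, cfg$jitter_sd_px)
    drift <- ifelse(t >= onset_ms[i], drift_step, 0) *
      sign(obj_x[i] - centre)
    x <- centre + cumsum(jit + drift)
    # clamp at the object and truncate shortly after arrival (the click)
    if (obj_x[i] > centre) {
      arrived <- which(x >= obj_x[i])
      x <- pmin(x, obj_x[i])
    } else {
      arrived <- which(x <= obj_x[i])
      x <- pmax(x, obj_x[i])
    }
    if (length(arrived)) {
      keep <- seq_len(min(arrived[1] + 5L, nt))
      t <- t[keep]; x <- x[keep]
    }
    y <- 400 + cumsum(stats::rnorm(length(t), 0, cfg$jitter_sd_px))
    out[[i]] <- data.frame(
      dyad_id = trials$dyad_id[i], trial_index = trials$trial_index[i],
      t_ms = t, x_px = x, y_px = y, stringsAsFactors = FALSE)
  }
  cursor <- do.call(rbind, out)
  rownames(cursor) <- NULL
  cursor
}

#' @export
print.dyad_sim <- function(x, ...) {
  cat(sprintf("Synthetic dyad game: %d dyads, %d trials, %d cursor samples (seed %d)\n",
              x$config$n_dyads, nrow(x$trials),
              if (is.null(x$cursor)) 0L else nrow(x$cursor),
              as.integer(x$config$seed)))
  cat(sprintf("  truth rate %.1f%%, perceived truth %.1f%%\n",
              100 * mean(x$trials$veracity == "truth"),
              100 * mean(x$trials$response == "truth")))
  invisible(x)
}

#' Ground-truth parameter summary of a simulated dataset
#'
#' Reports the generating parameters in the parameterisation the fitting
#' functions estimate, so parameter-recovery checks can compare like with
#' like: the guesser-response coefficients are the logistic coefficients
#' on the `pauses` and `affect_displays` category flags, and the
#' veracity-model entries are the per-cue log odds ratios implied by the
#' conditional cue model (for a single binary cue the cue-given-veracity
#' and veracity-given-cue log odds ratios coincide).
#'
#' @param sim a `"dyad_sim"` object (or its `$truth` record).
#' @return a data.frame with columns `outcome`, `parameter`, `value`.
#' @export
ground_truth_summary <- function(sim) {
  truth <- if (inherits(sim, "dyad_sim")) sim$truth else sim
  shifts <- truth$cue_veracity_shift
  ver <- data.frame(
    outcome = "speaker_veracity",
    parameter = names(shifts),
    value = unname(unlist(shifts)),
    stringsAsFactors = FALSE
  )
  resp <- data.frame(
    outcome = "guesser_response",
    parameter = c("(Intercept)", names(truth$response_coef)),
    value = unname(c(truth$response_intercept,
                     unlist(truth$response_coef))),
    stringsAsFactors = FALSE
  )
  rbind(ver, resp)
}
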