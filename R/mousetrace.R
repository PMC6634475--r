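#' Bin a cursor track relative to the disambiguation point
#'
#' Slices one trial's cursor samples into fixed-width time bins
#' time-locked to the utterance's disambiguation point (bin 0 starts at
#' it; earlier samples fall in negative bins) and accumulates x-axis
#' displacement toward the referent and toward the distractor. Each
#' per-sample displacement is assigned to the bin containing the later
#' sample. The cumulative total distance is the sum of absolute x
#' displacements from the start of the track, regardless of direction,
#' so the proportion-of-movement measures are defined from the first
#' post-disambiguation bin even before any post-disambiguation movement.
#'
#' @param t_ms,x_px sample timestamps (strictly increasing) and x
#'   coordinates for one trial.
#' @param referent_side `"left"` or `"right"`: side of the image the
#'   speaker named (see [referent_side()]).
#' @param disambiguation_ms disambiguation point, ms from trial onset;
#'   must lie within the sampled range.
#' @param bin_ms bin width (ms).
#' @return a data.frame of class `"binned_trajectory"` with one row per
#'   bin: `bin`, `time_rel` (bin start, ms relative to disambiguation),
#'   `d_ref`, `d_dist` (px moved toward referent/distractor within the
#'   bin), `cum_ref`, `cum_dist`, `cum_total` (running totals),
#'   `p_ref`, `p_dist` (cumulative proportions; `NA` while
#'   `cum_total = 0`), `zero_movement`.
#' @export
bin_track <- function(t_ms, x_px, referent_side, disambiguation_ms,
                      bin_ms = 20) {
  stopifnot(length(t_ms) == length(x_px), length(t_ms) >= 2,
            referent_side %in% c("left", "right"),
            is.finite(disambiguation_ms))
  if (any(diff(t_ms) <= 0)) {
    stop("timestamps must be strictly increasing", call. = FALSE)
  }
  if (disambiguation_ms < t_ms[1] || disambiguation_ms > t_ms[length(t_ms)]) {
    stop("disambiguation_ms outside the sampled range", call. = FALSE)
  }
  dx <- diff(x_px)
  t_later <- t_ms[-1]
  # positive x displacement approaches the right-hand object
  toward_ref <- if (referent_side == "right") dx > 0 else dx < 0
  step_ref <- ifelse(toward_ref, abs(dx), 0)
  step_dist <- ifelse(!toward_ref & dx != 0, abs(dx), 0)

  bin <- floor((t_later - disambiguation_ms) / bin_ms)
  bins <- seq(min(bin), max(bin))
  fbin <- factor(bin, levels = bins)
  d_ref <- as.numeric(tapply(step_ref, fbin, sum, default = 0))
  d_dist <- as.numeric(tapply(step_dist, fbin, sum, default = 0))
  d_ref[is.na(d_ref)] <- 0
  d_dist[is.na(d_dist)] <- 0

  cum_ref <- cumsum(d_ref)
  cum_dist <- cumsum(d_dist)
  cum_total <- cum_ref + cum_dist
  p_ref <- ifelse(cum_total > 0, cum_ref / cum_total, NA_real_)

  out <- data.frame(
    bin = bins,
    time_rel = bins * bin_ms,
    d_ref = d_ref, d_dist = d_dist,
    cum_ref = cum_ref, cum_dist = cum_dist, cum_total = cum_total,
    p_ref = p_ref, p_dist = 1 - p_ref,
    zero_movement = cum_total == 0
  )
  class(out) <- c("binned_trajectory", "data.frame")
  attr(out, "bin_ms") <- bin_ms
  attr(out, "referent_side") <- referent_side
  out
}

#' Empirical-logit difference for a binned trajectory
#'
#' The trajectory dependent variable: the difference between the
#' empirical logits of the cumulative proportion of movement toward the
#' referent and toward the distractor. With `N = cum_total` px as the
#' effective count, `elogit(p) = ln((p N + c) / ((1 - p) N + c))`, and
#' since `p_ref + p_dist = 1` the difference reduces to
#' `ln((cum_ref + c) / (cum_dist + c)) - ln((cum_dist + c) / (cum_ref + c))`.
#' Bins with no movement yet carry a DV of 0 (no evidence either way) by
#' default, or can be dropped.
#'
#' @param binned a `"binned_trajectory"` from [bin_track()].
#' @param c smoothing constant (> 0), default 0.5.
#' @param zero one of `"zero"` (DV = 0 on zero-movement bins) or
#'   `"drop"` (remove those bins).
#' @return `binned` with an `elogit_diff` column (possibly fewer rows).
#' @export
elogit_difference <- function(binned, c = 0.5, zero = c("zero", "drop")) {
  zero <- match.arg(zero)
  if (c <= 0) stop("smoothing constant c must be positive", call. = FALSE)
  dv <- log((binned$cum_ref + c) / (binned$cum_dist + c)) -
    log((binned$cum_dist + c) / (binned$cum_ref + c))
  dv[binned$zero_movement] <- if (zero == "zero") 0 else NA_real_
  binned$elogit_diff <- dv
  if (zero == "drop") {
    binned <- binned[!binned$zero_movement, , drop = FALSE]
  }
  binned
}

# bin every included trial's track and stack into one long table; a
# vectorized equivalent of bin_track + elogit_difference per trial
# (bins that contain no sample are omitted, which for regularly sampled
# logs never happens when bin_ms is at least the sampling interval)
bin_all_tracks <- function(cursor, trials, bin_ms = 20, c = 0.5) {
  key <- paste(trials$dyad_id, trials$trial_index, sep = "#")
  ckey <- paste(cursor$dyad_id, cursor$trial_index, sep = "#")
  m <- match(ckey, key)
  keep <- !is.na(m)
  t_ms <- cursor$t_ms[keep]
  x_px <- cursor$x_px[keep]
  m <- m[keep]
  ord <- order(m, t_ms)
  t_ms <- t_ms[ord]; x_px <- x_px[ord]; m <- m[ord]
  if (any(diff(t_ms)[diff(m) == 0] <= 0)) {
    stop("timestamps must be strictly increasing within trials",
         call. = FALSE)
  }

  first <- c(TRUE, diff(m) != 0)
  dx <- c(0, diff(x_px))
  # displacements belong to the later sample; a trial's first sample
  # carries none
  t_ms <- t_ms[!first]; dx <- dx[!first]; m <- m[!first]
  right_ref <- (referent_side(trials) == "right")[m]
  toward_ref <- ((dx > 0) == right_ref) & dx != 0
  step_ref <- ifelse(toward_ref, abs(dx), 0)
  step_dist <- ifelse(!toward_ref & dx != 0, abs(dx), 0)
  bin <- floor((t_ms - trials$disambiguation_ms[m]) / bin_ms)

  # collapse to one row per (trial, bin); rows are sorted, so group
  # boundaries are changes in either index
  chg <- c(TRUE, diff(m) != 0 | diff(bin) != 0)
  gid <- cumsum(chg)
  d_ref <- as.numeric(rowsum(step_ref, gid))
  d_dist <- as.numeric(rowsum(step_dist, gid))
  gm <- m[chg]
  gbin <- bin[chg]

  cum_ref <- stats::ave(d_ref, gm, FUN = cumsum)
  cum_dist <- stats::ave(d_dist, gm, FUN = cumsum)
  cum_total <- cum_ref + cum_dist
  p_ref <- ifelse(cum_total > 0, cum_ref / cum_total, NA_real_)
  dv <- log((cum_ref + c) / (cum_dist + c)) -
    log((cum_dist + c) / (cum_ref + c))
  dv[cum_total == 0] <- 0

  data.frame(
    dyad_id = trials$dyad_id[gm], trial_index = trials$trial_index[gm],
    item_id = trials$item_id[gm],
    bin = gbin, time_rel = gbin * bin_ms,
    d_ref = d_ref, d_dist = d_dist,
    cum_ref = cum_ref, cum_dist = cum_dist, cum_total = cum_total,
    p_ref = p_ref, p_dist = 1 - p_ref,
    zero_movement = cum_total == 0,
    elogit_diff = dv,
    stringsAsFactors = FALSE
  )
}

#' Time-locked trajectory analysis of guesser mouse movements
#'
#' The confirmatory real-time analysis: do guessers' cursor movements
#' diverge from the referent when the utterance carries the focal cue?
#' Cursor logs are time-locked to each utterance's disambiguation point,
#' binned (20 ms), and reduced to the per-bin empirical-logit difference
#' between movement proportions toward referent and distractor. The DV
#' is regressed on centred time (seconds), the cue flag, and their
#' interaction over a post-disambiguation window, with by-dyad and
#' by-item random effects. Trials with no codable disambiguation point,
#' and trials on which the focal cue occurred only after disambiguation,
#' are excluded first (see [apply_exclusions()]); for the affect
#' analysis, trials without gesture video are excluded too.
#'
#' Mean cumulative-proportion curves (with standard errors over trials)
#' are returned per condition out to `curves_to_ms` for plotting.
#'
#' @param cursor long-format cursor log: `dyad_id`, `trial_index`,
#'   `t_ms`, `x_px` (e.g. `simulate_dyads(...)$cursor`).
#' @param trials trial data.frame with collapsed categories.
#' @param cue `"pause"` or `"affect_display"`.
#' @param window_ms length-2 analysis window, ms post-disambiguation.
#' @param bin_ms bin width (ms).
#' @param c empirical-logit smoothing constant.
#' @param random,REML passed to [fit_trajectory_lmm()].
#' @param curves_to_ms how far the descriptive curves extend.
#' @return an object of class `"trajectory_fit"`: list with `fit` (a
#'   [cue_fit]), `curves` (data.frame: `time_rel`, `condition`,
#'   `mean_p_ref`, `mean_p_dist`, `se`, `n_trials`), `cue`, `window_ms`,
#'   `n_trials`, `exclusion_log`, and `interaction` (the time-by-cue
#'   estimate, SE and t).
#' @examples
#' \donttest{
#' sim <- simulate_dyads(dyad_config(n_dyads = 4, seed = 11))
#' ta <- trajectory_analysis(sim$cursor, sim$trials, "pause",
#'                           random = "intercepts")
#' ta$interaction
#' }
#' @export
trajectory_analysis <- function(cursor, trials,
                                cue = c("pause", "affect_display"),
                                window_ms = c(0, 800),
                                bin_ms = 20, c = 0.5,
                                random = c("slopes", "intercepts"),
                                REML = TRUE,
                                curves_to_ms = 4000) {
  cue <- match.arg(cue)
  random <- match.arg(random)
  if (!"pauses" %in% names(trials)) trials <- collapse_categories(trials)
  analysis <- if (cue == "pause") "mouse_pause" else "mouse_affect"
  ex <- apply_exclusions(trials, analysis)
  inc <- ex$included
  cue_col <- if (cue == "pause") "pauses" else "affect_displays"
  if (min(table(factor(inc[[cue_col]], levels = 0:1))) < 2) {
    stop("fewer than 2 trials at some level of ", cue_col, call. = FALSE)
  }

  long <- bin_all_tracks(cursor, inc, bin_ms = bin_ms, c = c)
  tkey <- paste(inc$dyad_id, inc$trial_index, sep = "#")
  long[[cue_col]] <-
    inc[[cue_col]][match(paste(long$dyad_id, long$trial_index,
                               sep = "#"), tkey)]

  win <- long[long$time_rel >= window_ms[1] &
                long$time_rel < window_ms[2], , drop = FALSE]
  # centre time on the window midpoint, in seconds (coefficient scale)
  mid <- mean(window_ms)
  win$time_c <- (win$time_rel + bin_ms / 2 - mid) / 1000
  fit <- fit_trajectory_lmm(win, cue_col, random = random, REML = REML)

  agg <- NULL
  if (curves_to_ms > 0) {
    cv <- long[long$time_rel >= 0 & long$time_rel <= curves_to_ms &
                 !is.na(long$p_ref), , drop = FALSE]
    cv$condition <- ifelse(cv[[cue_col]] == 1, cue, paste0("no_", cue))
    g <- factor(paste(cv$time_rel, cv$condition, sep = "|"))
    n_tr <- as.numeric(tapply(cv$p_ref, g, length))
    mean_p <- as.numeric(tapply(cv$p_ref, g, mean))
    se_p <- as.numeric(tapply(cv$p_ref, g, stats::sd)) / sqrt(n_tr)
    lab <- strsplit(levels(g), "|", fixed = TRUE)
    agg <- data.frame(
      time_rel = as.numeric(vapply(lab, `[`, "", 1)),
      condition = vapply(lab, `[`, "", 2),
      mean_p_ref = mean_p, mean_p_dist = 1 - mean_p,
      se = se_p, n_trials = n_tr, stringsAsFactors = FALSE)
    agg <- agg[order(agg$condition, agg$time_rel), ]
    rownames(agg) <- NULL
  }

  int_row <- fit$coefficients[grepl(":", fit$coefficients$term), ]
  structure(list(
    fit = fit,
    curves = agg,
    cue = cue,
    window_ms = window_ms,
    n_trials = length(unique(paste(win$dyad_id, win$trial_index))),
    exclusion_log = ex$log,
    interaction = c(estimate = int_row$estimate, se = int_row$se,
                    t = int_row$statistic)
  ), class = "trajectory_fit")
}

#' @export
print.trajectory_fit <- function(x, ...) {
  cat(sprintf("Trajectory analysis (%s), %d trials, window %g-%g ms post-disambiguation\n",
              x$cue, x$n_trials, x$window_ms[1], x$window_ms[2]))
  cat(sprintf("  time x %s interaction: beta = %.2f, SE = %.2f, t = %.2f\n",
              x$cue, x$interaction[["estimate"]], x$interaction[["se"]],
              x$interaction[["t"]]))
  invisible(x)
}

#' Write per-condition trajectory curves as delimited text
#'
#' @param x a `"trajectory_fit"`.
#' @param path output path (TSV): columns `time_rel`, `condition`,
#'   `mean_p_ref`, `mean_p_dist`, `se`, `n_trials`.
#' @return `path`, invisibly.
#' @export
write_curves <- function(x, path) {
  utils::write.table(x$curves, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
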