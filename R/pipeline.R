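#' Run the full analysis pipeline
#'
#' End-to-end orchestration: obtain a dataset (simulate one, or read
#' trial and cursor tables from disk), compute descriptives, run the
#' four exhaustive AICc cue selections (speech and gesture cues, each
#' for speaker veracity and guesser response), run the two time-locked
#' trajectory analyses (pauses, affect displays), and write every table
#' plus a machine-readable run manifest to `out_dir`. Stages log their
#' trial counts and exclusion tallies so the dataset funnel is auditable.
#'
#' @param config a [dyad_config()] used when simulating; ignored when
#'   `trials_path` is given.
#' @param trials_path,cursor_path optional paths to a trial table and a
#'   long-format cursor log; when supplied the generator is not used.
#'   Exactly one of `config` / `trials_path` provides the data.
#' @param out_dir output directory (created if needed); `NULL` skips all
#'   file output.
#' @param seed RNG seed for the simulation stage.
#' @param analyses subset of `c("speech", "gesture", "mouse")`.
#' @param threshold Delta-AICc bound for competitive subsets.
#' @param trajectory_random random structure for the trajectory fits
#'   (`"slopes"` or `"intercepts"`).
#' @param verbose print stage progress.
#' @return a list of class `"deception_pipeline"` with `descriptives`,
#'   `selections` (named list of [cue_selection()] results),
#'   `trajectories` (named list of [trajectory_analysis()] results),
#'   `exclusions`, `manifest`, and the `trials` used.
#' @export
run_pipeline <- function(config = dyad_config(),
                         trials_path = NULL, cursor_path = NULL,
                         out_dir = NULL,
                         seed = config$seed,
                         analyses = c("speech", "gesture", "mouse"),
                         threshold = 2,
                         trajectory_random = "slopes",
                         verbose = TRUE) {
  analyses <- match.arg(analyses, several.ok = TRUE)
  say <- function(...) if (verbose) message(sprintf(...))

  if (!is.null(trials_path)) {
    say("stage: read | %s", trials_path)
    trials <- collapse_categories(read_trials(trials_path))
    cursor <- if (!is.null(cursor_path)) {
      utils::read.table(cursor_path, header = TRUE, sep = "\t")
    } else NULL
    sim <- NULL
  } else {
    say("stage: simulate | %d dyads x %d trials, seed %d",
        config$n_dyads, config$trials_per_dyad, as.integer(seed))
    sim <- simulate_dyads(config, seed = seed)
    trials <- sim$trials
    cursor <- sim$cursor
  }

  ex <- apply_exclusions(trials, "cue_models")
  say("stage: exclusions | %d of %d trials retained for cue models",
      nrow(ex$included), nrow(trials))
  desc <- descriptives(ex$included)
  say("stage: descriptives | truth %.1f%%, perceived %.1f%%, accuracy %.1f%%",
      desc$truth_rate, desc$perceived_truth_rate, desc$accuracy_overall)

  selections <- list()
  if ("speech" %in% analyses || "gesture" %in% analyses) {
    for (cs in intersect(analyses, c("speech", "gesture"))) {
      for (oc in c("speaker_veracity", "guesser_response")) {
        key <- paste(cs, oc, sep = "_")
        say("stage: selection | %s", key)
        selections[[key]] <- cue_selection(oc, cs, trials,
                                           threshold = threshold)
      }
    }
  }

  trajectories <- list()
  if ("mouse" %in% analyses) {
    if (is.null(cursor)) {
      stop("mouse analysis requested but no cursor data available",
           call. = FALSE)
    }
    for (cue in c("pause", "affect_display")) {
      say("stage: mouse | %s", cue)
      trajectories[[cue]] <- trajectory_analysis(
        cursor, trials, cue, random = trajectory_random)
    }
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("deceptr")),
    r_version = as.character(getRversion()),
    seed = as.integer(seed),
    n_trials = nrow(trials),
    n_included_cue_models = nrow(ex$included),
    analyses = analyses,
    threshold = threshold,
    simulated = is.null(trials_path),
    config_hash = if (is.null(trials_path)) {
      sum(utils::head(utf8ToInt(paste(
        deparse(config[order(names(config))]), collapse = "")), 10000))
    } else NA
  )

  res <- structure(list(
    descriptives = desc, selections = selections,
    trajectories = trajectories, exclusions = ex,
    manifest = manifest, trials = trials
  ), class = "deception_pipeline")

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    say("stage: write | %s", out_dir)
    write_pipeline(res, out_dir, sim = sim)
  }
  res
}

# file output for a pipeline run
write_pipeline <- function(res, out_dir, sim = NULL) {
  p <- function(...) file.path(out_dir, ...)
  if (!is.null(sim)) {
    write_trials(sim$trials, p("trials.csv"))
    utils::write.table(sim$cursor, p("cursor.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  }
  d <- res$descriptives
  utils::write.table(
    data.frame(measure = c("truth_rate", "perceived_truth_rate",
                           "accuracy_overall", "accuracy_given_truth",
                           "accuracy_given_lie"),
               percent = c(d$truth_rate, d$perceived_truth_rate,
                           d$accuracy_overall, d$accuracy_given_truth,
                           d$accuracy_given_lie)),
    p("descriptives.tsv"), sep = "\t", row.names = FALSE, quote = FALSE)
  write_exclusion_log(res$exclusions, p("exclusions.tsv"))
  for (key in names(res$selections)) {
    write_selection_table(res$selections[[key]],
                          p(paste0("selection_", key, ".tsv")))
  }
  for (cue in names(res$trajectories)) {
    tr <- res$trajectories[[cue]]
    write_curves(tr, p(paste0("curves_", cue, ".tsv")))
    utils::write.table(tr$fit$coefficients,
                       p(paste0("trajectory_", cue, "_coefficients.tsv")),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  jsonlite::write_json(res$manifest, p("manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.deception_pipeline <- function(x, ...) {
  cat("Deception-game analysis pipeline\n")
  cat(sprintf("  %d trials (%d after cue-model exclusions), seed %d\n",
              x$manifest$n_trials, x$manifest$n_included_cue_models,
              x$manifest$seed))
  print(x$descriptives)
  for (key in names(x$selections)) {
    s <- summary(x$selections[[key]])
    cat(sprintf("  %-26s best: %s (w = %.3f)\n", key, s$best_model,
                s$best_weight))
  }
  for (cue in names(x$trajectories)) {
    tr <- x$trajectories[[cue]]
    cat(sprintf("  mouse (%s): time x cue t = %.2f\n", cue,
                tr$interaction[["t"]]))
  }
  invisible(x)
}
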