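#' Column vocabulary for trial tables
#'
#' A trial table holds one row per recorded utterance of a dyad game.
#' These constants name the columns the readers and analyses expect.
#'
#' @keywords internal
#' @name trial_columns
NULL

.disfluency_cols <- c("filled_pause", "silent_pause", "repetition",
                      "restart", "substitution", "addition", "prolongation")

.raw_gesture_cols <- c("g_head", "g_hand", "g_body", "g_shoulder",
                       "g_lip_mouth", "g_eyebrow", "g_smile_laugh",
                       "g_eye_contact")

.gesture_category_cols <- c("adaptor", "illustrator", "affect_display",
                            "eye_contact")

.speech_predictors  <- c("pauses", "repetitions", "repairs",
                         "prolongations", "speech_rate")
.gesture_predictors <- c("adaptors", "illustrators", "affect_displays",
                         "eye_contact")

.required_trial_cols <- c(
  "dyad_id", "trial_index", "item_id", "target_side", "treasure",
  "veracity", "response",
  .disfluency_cols, .raw_gesture_cols, .gesture_category_cols,
  "utterance_duration", "silent_pause_duration", "syllable_rate",
  "disambiguation_ms", "consistent_commitment", "gesture_data_present"
)

# optional timing columns used only by the mouse analyses
.optional_trial_cols <- c("pause_onset_ms", "affect_onset_ms")

.categorical_levels <- list(
  target_side = c("left", "right"),
  treasure    = c("gold", "silver"),
  veracity    = c("truth", "lie"),
  response    = c("truth", "lie")
)

#' Read a trial table from delimited text
#'
#' Reads a UTF-8 comma- or tab-delimited table with one row per utterance.
#' The delimiter is auto-detected from the header line. Binary annotation
#' flags are encoded 0/1; durations are in milliseconds; missing
#' disambiguation points are empty fields or `NA`.
#'
#' Rows whose required numeric fields cannot be parsed are dropped with a
#' warning that lists the offending row numbers; an invalid level in a
#' categorical column (for example a `veracity` other than `"truth"` or
#' `"lie"`) is an error naming the row and the allowed levels.
#'
#' @param path path to a CSV or TSV file.
#' @return a `data.frame` of trials, one row per utterance, with an
#'   attribute `"rejected"` holding row-numbered diagnostics for any
#'   dropped rows.
#' @seealso [write_trials()], [collapse_categories()]
#' @export
read_trials <- function(path) {
  if (!file.exists(path)) {
    stop("trial table not found: ", path, call. = FALSE)
  }
  header <- readLines(path, n = 1L)
  sep <- if (lengths(regmatches(header, gregexpr("\t", header))) >=
             lengths(regmatches(header, gregexpr(",", header)))) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, quote = "\"",
                           na.strings = c("NA", ""), comment.char = "",
                           colClasses = "character")
  missing <- setdiff(.required_trial_cols, names(raw))
  if (length(missing)) {
    stop("trial table is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  validate_trials(coerce_trials(raw))
}

# coerce character columns read from text to their analysis types,
# rejecting unparseable rows with row-numbered diagnostics
coerce_trials <- function(raw) {
  n <- nrow(raw)
  num_cols <- c("trial_index", .disfluency_cols, .raw_gesture_cols,
                .gesture_category_cols, "utterance_duration",
                "silent_pause_duration", "syllable_rate",
                "consistent_commitment", "gesture_data_present")
  derived <- c("pauses", "repetitions", "repairs", "prolongations",
               "adaptors", "illustrators", "affect_displays",
               "speech_rate")
  opt_num <- c("disambiguation_ms",
               intersect(c(.optional_trial_cols, derived), names(raw)))

  for (col in names(.categorical_levels)) {
    bad <- !is.na(raw[[col]]) & !(raw[[col]] %in% .categorical_levels[[col]])
    if (any(bad)) {
      stop(sprintf("invalid %s value %s in row(s) %s; allowed levels: {%s}",
                   col, dQuote(raw[[col]][which(bad)[1L]]),
                   paste(which(bad), collapse = ", "),
                   paste(.categorical_levels[[col]], collapse = ", ")),
           call. = FALSE)
    }
    if (anyNA(raw[[col]])) {
      stop(sprintf("missing %s value in row(s) %s; allowed levels: {%s}",
                   col, paste(which(is.na(raw[[col]])), collapse = ", "),
                   paste(.categorical_levels[[col]], collapse = ", ")),
           call. = FALSE)
    }
  }

  out <- raw
  bad_rows <- integer(0)
  for (col in c(num_cols, opt_num)) {
    vals <- suppressWarnings(as.numeric(raw[[col]]))
    newly_na <- is.na(vals) & !is.na(raw[[col]])
    if (col %in% num_cols) newly_na <- newly_na | is.na(raw[[col]])
    bad_rows <- union(bad_rows, which(newly_na))
    out[[col]] <- vals
  }
  if (length(bad_rows)) {
    bad_rows <- sort(bad_rows)
    warning(sprintf("rejected %d row(s) with unparseable required fields: %s",
                    length(bad_rows), paste(bad_rows, collapse = ", ")),
            call. = FALSE)
    out <- out[-bad_rows, , drop = FALSE]
  }
  flags <- c(.disfluency_cols, .raw_gesture_cols, .gesture_category_cols,
             "consistent_commitment", "gesture_data_present",
             intersect(setdiff(derived, "speech_rate"), names(out)))
  for (col in flags) out[[col]] <- as.integer(out[[col]])
  rownames(out) <- NULL
  attr(out, "rejected") <- bad_rows
  out
}

# internal consistency checks shared by the reader and the generator
validate_trials <- function(trials) {
  stopifnot(is.data.frame(trials))
  with(trials, {
    if (any(silent_pause_duration > utterance_duration + 1e-9)) {
      stop("silent_pause_duration exceeds utterance_duration", call. = FALSE)
    }
    if (any(silent_pause == 0L & silent_pause_duration != 0)) {
      stop("silent_pause flag is 0 but silent_pause_duration is nonzero",
           call. = FALSE)
    }
    ok <- is.na(disambiguation_ms) |
      disambiguation_ms <= utterance_duration + 1e-9
    if (!all(ok)) {
      stop("disambiguation_ms falls after the utterance end", call. = FALSE)
    }
  })
  trials
}

#' Write a trial table as delimited text
#'
#' @param trials a trial data.frame as returned by [read_trials()] or
#'   [simulate_dyads()].
#' @param path output path; extension `.tsv` selects tab separation,
#'   anything else comma.
#' @return `path`, invisibly.
#' @export
write_trials <- function(trials, path) {
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  utils::write.table(trials, path, sep = sep, row.names = FALSE,
                     quote = FALSE, na = "NA")
  invisible(path)
}

#' Collapse raw annotations into analysis cue categories
#'
#' Maps the seven disfluency types onto the four speech categories used as
#' model predictors: pauses (filled or silent), repetitions, repairs
#' (restart, substitution, or addition) and prolongations. Coding is binary
#' at the utterance level: multiple occurrences of a behaviour count the
#' same as one. Gesture categories (adaptors, illustrators, affect
#' displays, eye contact) are functional, per-instance judgements made at
#' annotation time, so they are copied from the annotation-level category
#' flags rather than derived from the eight raw gesture types.
#'
#' @param trials trial data.frame carrying the raw flag columns.
#' @return `trials` with added 0/1 columns `pauses`, `repetitions`,
#'   `repairs`, `prolongations`, `adaptors`, `illustrators`,
#'   `affect_displays` (and `eye_contact` retained as-is).
#' @export
collapse_categories <- function(trials) {
  need <- c(.disfluency_cols, .gesture_category_cols)
  missing <- setdiff(need, names(trials))
  if (length(missing)) {
    stop("missing raw flag column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  trials$pauses        <- as.integer(trials$filled_pause | trials$silent_pause)
  trials$repetitions   <- as.integer(trials$repetition)
  trials$repairs       <- as.integer(trials$restart | trials$substitution |
                                       trials$addition)
  trials$prolongations <- as.integer(trials$prolongation)
  trials$adaptors        <- as.integer(trials$adaptor)
  trials$illustrators    <- as.integer(trials$illustrator)
  trials$affect_displays <- as.integer(trials$affect_display)
  trials$eye_contact     <- as.integer(trials$eye_contact)
  trials
}

#' Apply the study's exclusion rules
#'
#' Three analysis stages use different subsets of the trials:
#' * `"cue_models"`: drops trials on which the speaker was inconsistent in
#'   their commitment to the treasure's location (intent undeterminable).
#' * `"mouse_pause"`: additionally drops trials with no codable
#'   disambiguation point, and trials whose pause began after the
#'   disambiguation point (the focal cue must be audible before the
#'   trajectory window opens).
#' * `"mouse_affect"`: as `"mouse_pause"` but for affect displays, and
#'   also drops trials without gesture video.
#'
#' @param trials trial data.frame (categories collapsed or not).
#' @param analysis one of `"cue_models"`, `"mouse_pause"`, `"mouse_affect"`.
#' @return a list with `included` (the retained rows) and `log`, a
#'   data.frame of per-rule exclusion counts with columns
#'   `rule`, `analysis`, `n_excluded`, plus an `excluded` data.frame keyed
#'   by dyad and trial with the rule that removed each row.
#' @export
apply_exclusions <- function(trials,
                             analysis = c("cue_models", "mouse_pause",
                                          "mouse_affect")) {
  analysis <- match.arg(analysis)
  rule_of <- rep(NA_character_, nrow(trials))

  mark <- function(cond, rule) {
    hit <- cond & is.na(rule_of)
    rule_of[hit] <<- rule
  }

  mark(trials$consistent_commitment == 0L, "inconsistent_commitment")
  if (analysis %in% c("mouse_pause", "mouse_affect")) {
    mark(is.na(trials$disambiguation_ms), "no_disambiguation")
    if (analysis == "mouse_pause") {
      if (!"pause_onset_ms" %in% names(trials)) {
        stop("mouse_pause exclusions need a pause_onset_ms column",
             call. = FALSE)
      }
      has_pause <- (trials$filled_pause | trials$silent_pause) == 1L
      post <- has_pause & !is.na(trials$pause_onset_ms) &
        !is.na(trials$disambiguation_ms) &
        trials$pause_onset_ms > trials$disambiguation_ms
      mark(post, "cue_post_disambiguation")
    } else {
      if (!"affect_onset_ms" %in% names(trials)) {
        stop("mouse_affect exclusions need an affect_onset_ms column",
             call. = FALSE)
      }
      mark(trials$gesture_data_present == 0L, "no_gesture_data")
      post <- trials$affect_display == 1L & !is.na(trials$affect_onset_ms) &
        !is.na(trials$disambiguation_ms) &
        trials$affect_onset_ms > trials$disambiguation_ms
      mark(post, "cue_post_disambiguation")
    }
  }

  keep <- is.na(rule_of)
  rules <- unique(rule_of[!keep])
  log <- data.frame(
    rule = rules,
    analysis = rep(analysis, length(rules)),
    n_excluded = vapply(rules, function(r) sum(rule_of == r, na.rm = TRUE),
                        integer(1)),
    stringsAsFactors = FALSE, row.names = NULL
  )
  excluded <- data.frame(
    dyad_id = trials$dyad_id[!keep],
    trial_index = trials$trial_index[!keep],
    rule = rule_of[!keep],
    analysis = rep(analysis, sum(!keep)),
    stringsAsFactors = FALSE
  )
  list(included = trials[keep, , drop = FALSE], log = log,
       excluded = excluded)
}

#' Side of the referent (the image the speaker names)
#'
#' When the speaker tells the truth the referent is the target image;
#' when lying it is the other image of the pair. Clicking the referent
#' indexes a truth judgement.
#'
#' @param trials trial data.frame with `veracity` and `target_side`.
#' @return character vector of `"left"` / `"right"`.
#' @export
referent_side <- function(trials) {
  ifelse(trials$veracity == "truth",
         trials$target_side,
         ifelse(trials$target_side == "left", "right", "left"))
}

#' Write an exclusion log as delimited text
#'
#' @param exclusions result of [apply_exclusions()].
#' @param path output path (TSV).
#' @return `path`, invisibly.
#' @export
write_exclusion_log <- function(exclusions, path) {
  utils::write.table(exclusions$excluded, path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
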