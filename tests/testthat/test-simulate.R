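test_that("same seed reproduces the dataset; different seeds differ", {
  cfg <- dyad_config(n_dyads = 3)
  a <- simulate_dyads(cfg, seed = 5)
  b <- simulate_dyads(cfg, seed = 5)
  expect_identical(a$trials, b$trials)
  expect_identical(a$cursor, b$cursor)
  c <- simulate_dyads(cfg, seed = 6)
  expect_false(identical(a$trials$veracity, c$trials$veracity))
})

test_that("degenerate configs behave analytically", {
  # all truths when truth_prob = 1 with no veracity shifts
  cfg <- dyad_config(n_dyads = 4, truth_prob = 1, veracity_re_sd = 0,
                     cue_veracity_shift = c(
                       filled_pause = 0, silent_pause = 0, repetition = 0,
                       restart = 0, substitution = 0, addition = 0,
                       prolongation = 0, adaptor = 0, illustrator = 0,
                       affect_display = 0, eye_contact = 0))
  sim <- simulate_dyads(cfg, seed = 2, cursor = FALSE)
  expect_true(all(sim$trials$veracity == "truth"))
  # empirical cue rates near their base rates (3 binomial SEs)
  n <- nrow(sim$trials)
  for (cue in c("filled_pause", "prolongation", "adaptor")) {
    p <- cfg$cue_base_prob[[cue]]
    col <- if (cue == "adaptor") "adaptor" else cue
    expect_lt(abs(mean(sim$trials[[col]]) - p),
              3 * sqrt(p * (1 - p) / n))
  }

  # null response model: referent-click rate near 50%
  cfg2 <- dyad_config(n_dyads = 8, response_intercept = 0,
                      response_coef = c(pauses = 0, affect_displays = 0),
                      response_re_sd = c(guesser = 0, item = 0))
  sim2 <- simulate_dyads(cfg2, seed = 3, cursor = FALSE)
  p_hat <- mean(sim2$trials$response == "truth")
  expect_lt(abs(p_hat - 0.5), 3 * sqrt(0.25 / nrow(sim2$trials)))
})

test_that("default cue incidences track their calibrated base rates", {
  sim <- simulate_dyads(dyad_config(seed = 4), cursor = FALSE)
  n <- nrow(sim$trials)
  p0 <- 288 / 1149
  se <- sqrt(p0 * (1 - p0) / n)
  expect_lt(abs(mean(sim$trials$filled_pause) - p0), 3 * se)
})

test_that("marginal cue prevalences converge to configured values", {
  cfg <- dyad_config(n_dyads = 200, seed = 12)
  sim <- simulate_dyads(cfg, cursor = FALSE)
  for (cue in c("filled_pause", "silent_pause", "prolongation",
                "adaptor", "affect_display")) {
    expect_lt(abs(mean(sim$trials[[cue]]) - cfg$cue_base_prob[[cue]]),
              0.02)
  }
})

test_that("ground-truth summary round-trips the generating parameters", {
  cfg <- dyad_config(n_dyads = 2)
  sim <- simulate_dyads(cfg, seed = 1, cursor = FALSE)
  gt <- ground_truth_summary(sim)
  expect_equal(gt$value[gt$parameter == "pauses"], -0.39)
  expect_equal(gt$value[gt$parameter == "affect_displays"], 0.29)
  expect_equal(gt$value[gt$outcome == "speaker_veracity" &
                          gt$parameter == "filled_pause"], 0.26)
  expect_equal(gt$value[gt$outcome == "speaker_veracity" &
                          gt$parameter == "adaptor"], -0.29)

  zero <- dyad_config(n_dyads = 2,
                      cue_veracity_shift = c(
                        filled_pause = 0, silent_pause = 0,
                        repetition = 0, restart = 0, substitution = 0,
                        addition = 0, prolongation = 0, adaptor = 0,
                        illustrator = 0, affect_display = 0,
                        eye_contact = 0),
                      response_intercept = 0,
                      response_coef = c(pauses = 0, affect_displays = 0))
  gt0 <- ground_truth_summary(simulate_dyads(zero, seed = 1,
                                             cursor = FALSE))
  expect_true(all(gt0$value == 0))
})

test_that("cursor tracks start at centre and end on the clicked side", {
  cfg <- dyad_config(n_dyads = 3, seed = 8)
  sim <- simulate_dyads(cfg)
  centre <- cfg$screen_width_px / 2
  ref <- referent_side(sim$trials)
  clicked <- ifelse(sim$trials$response == "truth", ref,
                    ifelse(ref == "left", "right", "left"))
  key <- paste(sim$trials$dyad_id, sim$trials$trial_index)
  ckey <- paste(sim$cursor$dyad_id, sim$cursor$trial_index)
  first_x <- tapply(sim$cursor$x_px, ckey, function(v) v[1])
  last_x <- tapply(sim$cursor$x_px, ckey, function(v) v[length(v)])
  # starts near centre (first sample includes one jitter step)
  expect_lt(max(abs(first_x - centre)), 20)
  # final sample in the clicked object's half of the screen
  on_right <- last_x[key] > centre
  expect_true(all(on_right == (clicked == "right")))
})

test_that("generated tables satisfy the trial invariants and sizes", {
  cfg <- dyad_config(n_dyads = 5, seed = 13)
  sim <- simulate_dyads(cfg, cursor = FALSE)
  t <- sim$trials
  expect_equal(nrow(t), 5 * 48)
  expect_true(all(t$silent_pause_duration <= t$utterance_duration))
  expect_true(all(t$silent_pause_duration[t$silent_pause == 0] == 0))
  ok <- is.na(t$disambiguation_ms) |
    t$disambiguation_ms <= t$utterance_duration
  expect_true(all(ok))
  # one dyad's gesture video lost by default
  expect_equal(sum(tapply(t$gesture_data_present, t$dyad_id, max) == 0), 1)
  expect_error(dyad_config(n_dyads = 2, trials_per_dyad = 60,
                           n_items = 96), "infeasible")
})

test_that("YAML config files round into dyad_config with overrides", {
  tmp <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("n_dyads: 6",
               "truth_prob: 0.6",
               "response_coef:",
               "  pauses: -0.5",
               "  affect_displays: 0.1"), tmp)
  cfg <- dyad_config_from_yaml(tmp, seed = 99L)
  expect_s3_class(cfg, "dyad_config")
  expect_equal(cfg$n_dyads, 6)
  expect_equal(cfg$truth_prob, 0.6)
  expect_equal(cfg$response_coef[["pauses"]], -0.5)
  expect_equal(cfg$seed, 99L)
  expect_equal(cfg$trials_per_dyad, 48) # untouched default

  writeLines("not_a_real_key: 3", tmp)
  expect_error(dyad_config_from_yaml(tmp), "unknown config key")
})
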