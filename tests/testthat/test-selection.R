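# hand-built fit stubs let selection arithmetic be tested in isolation
stub_fit <- function(fx, loglik, K, n = 500, converged = TRUE) {
  deceptr:::new_cue_fit(
    spec = list(outcome = "speaker_veracity", fixed_effects = fx,
                random = "crossed", family = "binomial"),
    coefficients = data.frame(term = c("(Intercept)", fx),
                              estimate = 0, se = 1, statistic = 0, p = 1),
    varcomp = c(dyad_id = 0.1, item_id = 0.1),
    loglik = loglik, K = K, n = n, converged = converged,
    boundary = FALSE, fit = NULL)
}

test_that("AICc follows the corrected-AIC formula", {
  expect_equal(aicc(-100, 3, 50), 206 + 24 / 46, tolerance = 1e-12)
  # asymptotic identity: correction vanishes for large n
  expect_lt(abs(aicc(-100, 3, 1e5) - (206)), 1e-3)
  expect_equal(aicc(-100, 0, 50), 200)
  expect_error(aicc(-100, 3, 4), "undefined")
})

test_that("candidate enumeration is exhaustive and deterministic", {
  speech <- enumerate_candidates(letters[1:5])
  expect_length(speech, 32)
  gesture <- enumerate_candidates(letters[1:4])
  expect_length(gesture, 16)
  expect_identical(speech[[1]], character(0)) # null model first
  expect_length(enumerate_candidates(character(0)), 1)
  sizes <- lengths(speech)
  expect_true(all(diff(sizes) >= 0)) # ordered by model size
  expect_identical(speech, enumerate_candidates(letters[1:5]))
  expect_error(enumerate_candidates(c("a", "a")), "duplicate")
})

test_that("selection table computes weights, ERs and cumulative weights", {
  fits <- list(stub_fit(character(0), -250, 3),
               stub_fit("a", -248, 4),
               stub_fit("b", -249.5, 4),
               stub_fit(c("a", "b"), -247.9, 5))
  tab <- selection_table(fits)
  expect_s3_class(tab, "selection_table")
  expect_equal(sum(tab$models$weight), 1, tolerance = 1e-10)
  expect_equal(tab$models$delta[1], 0)
  expect_equal(tab$models$er[1], 1)
  expect_equal(tab$models$er, exp(tab$models$delta / 2), tolerance = 1e-10)
  expect_true(all(tab$parameter_weights >= 0 &
                    tab$parameter_weights <= 1))

  # weights invariant to a constant AICc shift (same loglik shift)
  fits2 <- lapply(fits, function(f) { f$loglik <- f$loglik - 7; f })
  tab2 <- selection_table(fits2)
  expect_equal(tab$models$weight, tab2$models$weight, tolerance = 1e-10)

  # two equal-AICc models split the weight and tie on ER
  pair <- list(stub_fit("a", -100, 4), stub_fit("b", -100, 4))
  tp <- selection_table(pair)
  expect_equal(tp$models$weight, c(0.5, 0.5))
  expect_equal(tp$models$er, c(1, 1))

  expect_error(selection_table(list(stub_fit("a", -10, 4, n = 100),
                                    stub_fit("b", -10, 4, n = 101))),
               "differing n")
})

test_that("ties in AICc break by smaller K then candidate order", {
  fits <- list(stub_fit(c("a", "b"), -99, 5),
               stub_fit("a", -100, 4),
               stub_fit("b", -100, 4))
  # model 1: AICc = 208.12...; models 2 and 3 tie below it
  tab <- selection_table(fits)
  expect_equal(tab$best, 2)
  expect_equal(tab$models$model[1], "a")
})

test_that("a predictor present in every model has cumulative weight 1", {
  fits <- list(stub_fit("a", -250, 4),
               stub_fit(c("a", "b"), -249, 5),
               stub_fit(c("a", "c"), -248, 5))
  tab <- selection_table(fits)
  expect_equal(unname(tab$parameter_weights["a"]), 1, tolerance = 1e-12)
})

test_that("non-converged fits are dropped with a warning", {
  fits <- list(stub_fit(character(0), -250, 3),
               stub_fit("a", -240, 4, converged = FALSE),
               stub_fit("b", -249, 4))
  expect_warning(tab <- selection_table(fits), "non-converged")
  expect_equal(nrow(tab$models), 2)
  expect_false("a" %in% names(tab$parameter_weights))
})

test_that("cue selection fits the full candidate set and reports it", {
  sim <- simulate_dyads(dyad_config(n_dyads = 5, seed = 31),
                        cursor = FALSE)
  sel <- cue_selection("guesser_response", "gesture", sim$trials,
                       random = "none")
  expect_length(sel$fits, 16)
  expect_equal(sum(sel$models$weight), 1, tolerance = 1e-10)
  s <- summary(sel)
  expect_equal(s$er_runner_up, exp(s$delta_runner_up / 2),
               tolerance = 1e-10)
  expect_equal(s$coefficients$odds_ratio,
               exp(s$coefficients$estimate), tolerance = 1e-12)
  expect_true(all(s$containment <= s$n_competitive))
  # gesture analyses drop the video-less dyad
  expect_equal(sel$fits[[1]]$n,
               sum(sim$trials$gesture_data_present == 1 &
                     sim$trials$consistent_commitment == 1))
})

test_that("a strong injected predictor wins the cumulative weights", {
  shifts <- c(filled_pause = 1.2, silent_pause = 1.2, repetition = 0,
              restart = 0, substitution = 0, addition = 0,
              prolongation = 0, adaptor = 0, illustrator = 0,
              affect_display = 0, eye_contact = 0)
  wins <- vapply(1:100, function(s) {
    sim <- simulate_dyads(dyad_config(n_dyads = 30,
                                      cue_veracity_shift = shifts),
                          seed = 1000 + s, cursor = FALSE)
    sel <- cue_selection("speaker_veracity", "speech", sim$trials,
                         random = "none")
    names(which.max(sel$parameter_weights)) == "pauses"
  }, logical(1))
  expect_gte(mean(wins), 0.95)
})
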