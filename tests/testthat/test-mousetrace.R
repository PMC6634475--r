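test_that("pure approach gives proportion 1 in every movement bin", {
  tr <- make_track(seq(640, 540, by = -5)) # monotone leftward
  b <- bin_track(tr$t_ms, tr$x_px, "left", disambiguation_ms = 100)
  moved <- b[b$cum_total > 0, ]
  expect_true(all(moved$p_ref == 1))
  expect_true(all(moved$p_dist == 0))
})

test_that("cumulative proportions follow hand-computed sums", {
  # 100 px toward the referent, then 50 px back
  x <- c(seq(640, 740, by = 10), seq(730, 690, by = -10))
  tr <- make_track(x)
  b <- bin_track(tr$t_ms, tr$x_px, "right", disambiguation_ms = 0)
  last <- b[nrow(b), ]
  expect_equal(last$cum_ref, 100)
  expect_equal(last$cum_dist, 50)
  expect_equal(last$p_ref, 100 / 150, tolerance = 1e-12)

  # conservation: binned distances sum to total |dx|
  expect_equal(sum(b$d_ref + b$d_dist), sum(abs(diff(x))),
               tolerance = 1e-9)
})

test_that("a stationary pointer yields undefined proportions, DV 0", {
  tr <- make_track(rep(640, 20))
  b <- bin_track(tr$t_ms, tr$x_px, "left", disambiguation_ms = 100)
  expect_true(all(b$cum_total == 0))
  expect_true(all(is.na(b$p_ref)))
  expect_true(all(b$zero_movement))
  dv <- elogit_difference(b)
  expect_true(all(dv$elogit_diff == 0))
  dropped <- elogit_difference(b, zero = "drop")
  expect_equal(nrow(dropped), 0)
})

test_that("e-logit difference matches its closed form and symmetries", {
  x <- c(seq(640, 740, by = 10), seq(735, 710, by = -5))
  tr <- make_track(x)
  b <- bin_track(tr$t_ms, tr$x_px, "right", disambiguation_ms = 0)
  dv <- elogit_difference(b, c = 0.5)
  last <- dv[nrow(dv), ]
  expect_equal(last$cum_ref, 100)
  expect_equal(last$cum_dist, 30)
  expect_equal(last$elogit_diff,
               log(100.5 / 30.5) - log(30.5 / 100.5), tolerance = 1e-12)

  # symmetric movement: DV = 0
  xs <- c(640, 660, 640, 620, 640)
  bs <- bin_track(make_track(xs)$t_ms, xs, "right", 0)
  dvs <- elogit_difference(bs)
  expect_equal(dvs$elogit_diff[nrow(dvs)], 0, tolerance = 1e-12)

  # swapping referent and distractor negates the DV
  b2 <- bin_track(tr$t_ms, tr$x_px, "left", disambiguation_ms = 0)
  dv2 <- elogit_difference(b2, c = 0.5)
  expect_equal(dv$elogit_diff, -dv2$elogit_diff, tolerance = 1e-12)

  expect_error(elogit_difference(b, c = 0), "positive")
})

test_that("binning is invariant to rescaling and display mirroring", {
  set.seed(9)
  x <- cumsum(c(640, rnorm(60, 0.5, 4)))
  tr <- make_track(x)
  b <- bin_track(tr$t_ms, tr$x_px, "right", disambiguation_ms = 300)

  # uniform rescale of x leaves proportions unchanged
  b_scaled <- bin_track(tr$t_ms, 2.5 * tr$x_px, "right", 300)
  expect_equal(b$p_ref, b_scaled$p_ref, tolerance = 1e-12)

  # mirror the display and flip the referent side: everything matches
  b_mirror <- bin_track(tr$t_ms, -tr$x_px, "left", 300)
  expect_equal(b$d_ref, b_mirror$d_ref, tolerance = 1e-9)
  expect_equal(b$d_dist, b_mirror$d_dist, tolerance = 1e-9)
  expect_equal(elogit_difference(b)$elogit_diff,
               elogit_difference(b_mirror)$elogit_diff, tolerance = 1e-9)
})

test_that("bin assignment uses the later sample's bin, relative to
           disambiguation", {
  # samples at 0,20,40,60 ms; disambiguation at 30 ms: the 20->40 step
  # belongs to bin 0 (40 ms is in [30, 50)), the 40->60 step to bin 1
  b <- bin_track(c(0, 20, 40, 60), c(0, 0, 10, 30), "right", 30)
  expect_equal(b$bin, c(-1, 0, 1))
  expect_equal(b$d_ref, c(0, 10, 20))
  expect_equal(b$time_rel, c(-20, 0, 20))
})

test_that("malformed tracks are rejected", {
  expect_error(bin_track(c(0, 20, 20), c(1, 2, 3), "left", 10),
               "strictly increasing")
  expect_error(bin_track(c(0, 20), c(1, 2), "left", 50), "range")
})

test_that("trajectory analysis recovers injected drift asymmetries", {
  sim <- simulate_dyads(dyad_config(n_dyads = 6, seed = 41))
  ta <- trajectory_analysis(sim$cursor, sim$trials, "pause",
                            random = "intercepts")
  expect_s3_class(ta$fit, "cue_fit")
  expect_lt(ta$interaction[["estimate"]], 0)
  expect_true(all(c("pause", "no_pause") %in% ta$curves$condition))
  expect_true(all(ta$curves$time_rel <= 4000))
  expect_true(all(abs(ta$curves$mean_p_ref + ta$curves$mean_p_dist - 1)
                  < 1e-9))
  # exclusion funnel is logged
  expect_true("no_disambiguation" %in% ta$exclusion_log$rule)
})

test_that("identical trajectories across conditions give a zero
           interaction", {
  # two conditions with byte-identical binned DVs
  d <- expand.grid(time_c = seq(-0.4, 0.4, by = 0.05), trial = 1:12)
  d$cue <- as.integer(d$trial <= 6)
  d$dyad_id <- paste0("d", (d$trial - 1) %% 3)
  d$item_id <- paste0("i", (d$trial - 1) %% 4)
  d$elogit_diff <- sin(d$time_c * 2) # same curve in every trial
  fit <- fit_trajectory_lmm(d, "cue", random = "intercepts")
  expect_equal(unname(coef(fit)["time_c:cue"]), 0, tolerance = 1e-8)
  expect_equal(unname(coef(fit)["cue"]), 0, tolerance = 1e-8)
})

test_that("too few trials per cue level is an error", {
  sim <- simulate_dyads(dyad_config(n_dyads = 2, seed = 5))
  tr <- sim$trials
  tr$affect_display <- 0L
  tr <- collapse_categories(tr)
  expect_error(trajectory_analysis(sim$cursor, tr, "affect_display"),
               "fewer than 2 trials")
})

test_that("stacked binning matches per-trial bin_track on sampled logs", {
  sim <- simulate_dyads(dyad_config(n_dyads = 2, seed = 61))
  ex <- apply_exclusions(sim$trials, "mouse_pause")
  long <- deceptr:::bin_all_tracks(sim$cursor, ex$included)
  ref <- referent_side(ex$included)
  ckey <- paste(sim$cursor$dyad_id, sim$cursor$trial_index)
  set.seed(1)
  for (i in sample(nrow(ex$included), 8)) {
    rows <- which(ckey == paste(ex$included$dyad_id[i],
                                ex$included$trial_index[i]))
    b <- bin_track(sim$cursor$t_ms[rows], sim$cursor$x_px[rows],
                   ref[i], ex$included$disambiguation_ms[i])
    b <- elogit_difference(b)
    l <- long[long$dyad_id == ex$included$dyad_id[i] &
                long$trial_index == ex$included$trial_index[i], ]
    expect_equal(l$bin, b$bin)
    for (col in c("d_ref", "d_dist", "cum_total", "p_ref",
                  "elogit_diff")) {
      expect_equal(l[[col]], b[[col]], tolerance = 1e-9, info = col)
    }
  }
})
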