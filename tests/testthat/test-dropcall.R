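test_that("a healthy constant trace is never called", {
  tr <- traces_from_list(list(list(normalized = rep(1, 121),
                                   valid = rep(TRUE, 121))))
  expect_equal(call_drops(tr)$verdict, "no_drop")
})

test_that("a clean step drop is called at its first low frame", {
  tr <- traces_from_list(list(list(
    normalized = c(rep(1, 10), rep(0.2, 111)), valid = rep(TRUE, 121))))
  calls <- call_drops(tr)
  expect_equal(calls$verdict, "drop")
  expect_equal(calls$drop_frame, 10L)
})

test_that("the run-length requirement is sharp at 4 vs 5 frames", {
  mk <- function(dip_len) {
    x <- rep(1, 121)
    x[40:(39 + dip_len)] <- 0.5
    traces_from_list(list(list(normalized = x, valid = rep(TRUE, 121))))
  }
  expect_equal(call_drops(mk(4))$verdict, "no_drop")
  c5 <- call_drops(mk(5))
  expect_equal(c5$verdict, "drop")
  expect_equal(c5$drop_frame, 39L)
})

test_that("a dip too close to the end cannot complete a run", {
  x <- rep(1, 121)
  x[119:121] <- 0.1
  tr <- traces_from_list(list(list(normalized = x, valid = rep(TRUE, 121))))
  expect_equal(call_drops(tr)$verdict, "no_drop")
})

test_that("values exactly at the threshold do not count as below", {
  x <- rep(1, 121)
  x[30:60] <- 0.75
  tr <- traces_from_list(list(list(normalized = x, valid = rep(TRUE, 121))))
  expect_equal(call_drops(tr)$verdict, "no_drop")
})

test_that("invalid frames interrupt a sub-threshold run", {
  x <- rep(1, 50)
  x[20:28] <- 0.2
  v <- rep(TRUE, 50)
  v[24] <- FALSE     # splits the 9-frame dip into runs of 4 and 4
  tr <- traces_from_list(list(list(normalized = x, valid = v)))
  expect_equal(call_drops(tr)$verdict, "no_drop")
  v[24] <- TRUE
  tr2 <- traces_from_list(list(list(normalized = x, valid = v)))
  expect_equal(call_drops(tr2)$verdict, "drop")
})

test_that("short traces are excluded rather than scored", {
  tr <- traces_from_list(list(list(normalized = rep(0.1, 3),
                                   valid = rep(TRUE, 3))))
  expect_equal(call_drops(tr)$verdict, "excluded")
})

test_that("call_drops agrees with the brute-force window oracle", {
  traces <- random_trace_set(300, len = 121, seed = 11)
  calls <- call_drops(traces_from_list(traces))
  for (i in seq_along(traces)) {
    oracle <- brute_force_call(traces[[i]]$normalized, traces[[i]]$valid)
    expect_identical(calls$verdict[i], oracle$verdict)
    expect_identical(calls$drop_frame[i],
                     if (is.na(oracle$drop_frame)) NA_integer_
                     else as.integer(oracle$drop_frame))
  }
})

test_that("calls are monotone in threshold and run length", {
  traces <- random_trace_set(120, len = 60, seed = 12)
  tr <- traces_from_list(traces)
  drops <- function(th, rl) sum(call_drops(tr, threshold = th,
                                           run_length = rl)$verdict == "drop")
  # raising the threshold can only create more drops
  d <- vapply(c(0.5, 0.65, 0.75, 0.9), function(th) drops(th, 5), numeric(1))
  expect_true(all(diff(d) >= 0))
  # lengthening the run requirement can only remove drops
  d2 <- vapply(c(1, 3, 5, 9), function(rl) drops(0.75, rl), numeric(1))
  expect_true(all(diff(d2) <= 0))
})

test_that("per-trace monotonicity: a higher threshold never loses a drop", {
  traces <- random_trace_set(200, len = 60, seed = 13)
  tr <- traces_from_list(traces)
  lo <- call_drops(tr, threshold = 0.6)
  hi <- call_drops(tr, threshold = 0.85)
  expect_true(all(hi$verdict[lo$verdict == "drop"] == "drop"))
})

test_that("condition summaries report fraction and Wilson interval", {
  calls <- tibble::tibble(
    spot_id = 1:330, x = 0, y = 0,
    verdict = c(rep("drop", 255), rep("no_drop", 75)),
    drop_frame = c(rep(10L, 255), rep(NA_integer_, 75)),
    initial_intensity = 1000
  )
  s <- summarize_condition(calls, "ATP")
  expect_equal(s$fraction, 255 / 330)
  expect_equal(s$n_drops, 255)
  expect_equal(s$n_total, 330)
  expect_lt(s$ci_low, s$fraction)
  expect_gt(s$ci_high, s$fraction)
  g <- glance(s)
  expect_equal(g$fraction, 255 / 330)
})

test_that("zero drops give a zero fraction with a zero lower bound", {
  calls <- tibble::tibble(spot_id = 1:100, x = 0, y = 0,
                          verdict = "no_drop", drop_frame = NA_integer_,
                          initial_intensity = 1)
  s <- summarize_condition(calls, "blank")
  expect_equal(s$fraction, 0)
  expect_equal(s$ci_low, 0)
  expect_gt(s$ci_high, 0)
})

test_that("the Wilson interval attains nominal coverage at 48/413", {
  # Monte-Carlo coverage oracle at the observed proportion
  p <- 48 / 413
  set.seed(14)
  draws <- rbinom(4000, 413, p)
  covered <- vapply(draws, function(x) {
    ci <- wilson_ci(x, 413)
    ci["low"] <= p && p <= ci["high"]
  }, logical(1))
  expect_lt(abs(mean(covered) - 0.95), 0.02)
})

test_that("excluded calls leave the totals and replicates are summarized", {
  calls <- tibble::tibble(
    spot_id = 1:90, x = 0, y = 0,
    verdict = rep(c("drop", "no_drop", "excluded"), each = 30),
    drop_frame = c(rep(5L, 30), rep(NA_integer_, 60)),
    initial_intensity = 1
  )
  reps <- rep(1:3, 30)
  s <- summarize_condition(calls, "demo", replicate_ids = reps)
  expect_equal(s$n_total, 60)
  expect_equal(s$n_excluded, 30)
  expect_equal(nrow(s$replicates), 3)
  expect_equal(s$replicate_mean, mean(s$replicates$fraction))
  expect_equal(s$replicate_sd, sd(s$replicates$fraction))
  td <- tidy(s)
  expect_equal(nrow(td), 3)
})

test_that("control adjustment subtracts the baseline fraction", {
  mk <- function(nd, nt) {
    tibble::tibble(spot_id = seq_len(nt), x = 0, y = 0,
                   verdict = c(rep("drop", nd), rep("no_drop", nt - nd)),
                   drop_frame = c(rep(1L, nd), rep(NA_integer_, nt - nd)),
                   initial_intensity = 1)
  }
  atp <- summarize_condition(mk(255, 330), "ATP")
  ctrl <- summarize_condition(mk(44, 340), "no_protein")
  adj <- control_adjusted_fraction(atp, ctrl)
  expect_equal(adj$fraction_adjusted, 255 / 330 - 44 / 340)
})

test_that("perfect step traces evaluate to unit recall and precision", {
  sim <- quick_sim(seed = 15, n_spots = 10, n_frames = 40,
                   drop_probability = 0.7, shot_noise = FALSE,
                   read_noise_sd = 0, spot_amplitude_cv = 0,
                   drop_time_scale = 30)
  res <- suppressMessages(analyze_movie(sim$movie, register = FALSE))
  met <- evaluate_against_truth(res$calls, sim$truth, frame_tolerance = 0)
  if (met$n_should > 0) {
    expect_equal(met$recall, 1)
    expect_equal(met$precision, 1)
    expect_equal(met$median_frame_error, 0)
  }
})

test_that("an event-free movie produces almost no false calls", {
  sim <- quick_sim(seed = 16, n_spots = 12, n_frames = 60,
                   drop_probability = 0)
  res <- suppressMessages(analyze_movie(sim$movie, register = FALSE))
  met <- evaluate_against_truth(res$calls, sim$truth)
  expect_equal(met$n_should, 0)
  expect_lt(met$n_called / met$n_spots, 0.01 + 1e-9)
})

test_that("photobleach events are called and attributed separately", {
  cfg <- sim_config(field_shape = c(96, 96), n_spots = 12,
                    min_spacing = 10 * 0.16, n_frames = 60,
                    drop_probability = 0, photobleach_rate = 0.01,
                    drift_rate = c(0, 0), drift_rw_sd = 0)
  sim <- simulate_movie(cfg, seed = 17)
  res <- suppressMessages(analyze_movie(sim$movie, register = FALSE))
  met <- evaluate_against_truth(res$calls, sim$truth, frame_tolerance = 2)
  if (met$n_matched > 0) {
    expect_equal(met$photobleach_call_fraction, 1)
  }
})
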