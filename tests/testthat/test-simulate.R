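test_that("spot placement returns the empty set for n = 0", {
  expect_equal(nrow(sample_spot_positions(0, c(64, 64), 5)), 0)
})

test_that("spot placement respects the minimum spacing exhaustively", {
  pos <- sample_spot_positions(100, c(512, 512), 10, seed = 1)
  expect_equal(nrow(pos), 100)
  d <- as.vector(dist(cbind(pos$x, pos$y)))
  expect_length(d, choose(100, 2))
  expect_true(all(d >= 10))
  # inside the border margin
  expect_true(all(pos$x >= 8 & pos$x <= 503 & pos$y >= 8 & pos$y <= 503))
})

test_that("spot placement is deterministic for a fixed seed", {
  expect_identical(sample_spot_positions(20, c(128, 128), 8, seed = 42),
                   sample_spot_positions(20, c(128, 128), 8, seed = 42))
})

test_that("an infeasible placement fails with a crowding error, not a hang", {
  # Brute-force geometric feasibility oracle: place candidate centres on a
  # 2-px grid inside the margin box and look for any triple with pairwise
  # distance >= min_spacing - 3 (grid snapping slack). If none exists on
  # the relaxed grid, no real-valued triple at min_spacing can exist.
  min_spacing <- 60
  margin <- 8
  g <- expand.grid(x = seq(margin, 63 - margin, by = 2),
                   y = seq(margin, 63 - margin, by = 2))
  B <- as.matrix(dist(g)) >= (min_spacing - 3)
  triangles <- sum(diag(B %*% B %*% B))
  expect_equal(triangles, 0)
  expect_error(
    sample_spot_positions(3, c(64, 64), min_spacing, seed = 1,
                          max_attempts = 5000),
    "field too crowded"
  )
})

test_that("event schedule has no events when both channels are off", {
  cfg <- sim_config(drop_probability = 0, photobleach_rate = 0)
  ev <- sample_event_schedule(cfg, n = 500, seed = 1)
  expect_true(all(ev$event_type == "none"))
  expect_true(all(is.na(ev$event_frame)))
})

test_that("event frames follow the truncated exponential law", {
  cfg <- sim_config(drop_probability = 1, drop_time_scale = 100,
                    photobleach_rate = 0, n_frames = 121, frame_interval = 5)
  ev <- sample_event_schedule(cfg, n = 1e4, seed = 7)
  expect_true(all(ev$event_type == "drop"))
  t_end <- 120 * 5
  # closed-form truncated exponential CDF on the event times
  cdf <- function(t) (1 - exp(-t / 100)) / (1 - exp(-t_end / 100))
  times <- ev$event_frame * 5  # frame grid discretization of the draw
  for (q in c(60, 150, 300, 450)) {
    expect_lt(abs(mean(times <= q) - cdf(q)), 0.02)
  }
  expect_true(all(ev$event_frame >= 1 & ev$event_frame <= 120))
})

test_that("photobleaching competes with strand separation", {
  cfg <- sim_config(drop_probability = 0, photobleach_rate = 0.01,
                    n_frames = 121, frame_interval = 5)
  ev <- sample_event_schedule(cfg, n = 2000, seed = 3)
  # P(bleach within 600 s) = 1 - exp(-6)
  expect_lt(abs(mean(ev$event_type == "photobleach") - (1 - exp(-6))), 0.02)
  expect_true(all(ev$event_type %in% c("photobleach", "none")))
})

test_that("ATP-preset drop counts concentrate on the calibrated mean", {
  preset <- condition_preset("ATP")
  cfg <- sim_config(drop_probability = preset$drop_probability,
                    photobleach_rate = 0)
  counts <- vapply(1:200, function(s) {
    sum(sample_event_schedule(cfg, n = preset$n_total,
                              seed = s)$event_type == "drop")
  }, numeric(1))
  p <- preset$drop_probability
  se_mean <- sqrt(preset$n_total * p * (1 - p) / 200)
  expect_lt(abs(mean(counts) - 255), 3 * se_mean)
})

test_that("condition presets carry the recorded per-condition counts", {
  atp <- condition_preset("ATP")
  expect_equal(atp$drop_probability, 255 / 330)
  expect_equal(atp$n_total, 330L)
  adp <- condition_preset("ADP")
  expect_equal(adp$drop_probability, 48 / 413)
  expect_equal(adp$n_total, 413L)
  ctrl <- condition_preset("no_protein")
  expect_equal(ctrl$drop_probability, 44 / 340)
  expect_equal(ctrl$n_total, 340L)
  expect_error(condition_preset("XTP"), "Available")
  expect_equal(nrow(condition_presets()), 8)
})

test_that("empty-field render reproduces Poisson background moments", {
  cfg <- sim_config(field_shape = c(256, 256), n_spots = 0, n_frames = 121,
                    background_level = 100, camera_gain = 1,
                    read_noise_sd = 0)
  m <- render_movie(cfg, tibble::tibble(x = numeric(), y = numeric()),
                    tibble::tibble(spot_id = integer(), event_type = character(),
                                   event_frame = integer()), seed = 5)
  expect_lt(abs(mean(m$data) / 100 - 1), 0.02)
  expect_lt(abs(stats::var(as.vector(m$data)) / 100 - 1), 0.02)
})

test_that("a static noiseless spot renders identically in every frame", {
  cfg <- sim_config(field_shape = c(48, 48), n_spots = 1, n_frames = 10,
                    drift_rate = c(0, 0), drift_rw_sd = 0, shot_noise = FALSE,
                    read_noise_sd = 0, spot_amplitude_cv = 0,
                    spot_amplitude_mean = 1000, background_level = 10)
  pos <- tibble::tibble(x = 24, y = 24)
  ev <- tibble::tibble(spot_id = 1L, event_type = "none",
                       event_frame = NA_integer_)
  m <- render_movie(cfg, pos, ev, seed = 1)
  for (f in 2:10) expect_equal(m$data[, , f], m$data[, , 1])
  integrated <- sum(m$data[, , 1] - 10)
  expect_lt(abs(integrated - 1000) / 1000, 0.001)
})

test_that("a residual-zero drop renders as a perfect intensity step", {
  cfg <- sim_config(field_shape = c(48, 48), n_spots = 1, n_frames = 80,
                    drift_rate = c(0, 0), drift_rw_sd = 0, shot_noise = FALSE,
                    read_noise_sd = 0, spot_amplitude_cv = 0,
                    spot_amplitude_mean = 1000, background_level = 10,
                    residual_fraction = 0)
  pos <- tibble::tibble(x = 20, y = 30)
  ev <- tibble::tibble(spot_id = 1L, event_type = "drop", event_frame = 60L)
  m <- render_movie(cfg, pos, ev, seed = 1)
  roi_sum <- apply(m$data, 3, function(fr) sum(fr - 10))
  expect_equal(roi_sum[1:60], rep(roi_sum[1], 60))
  expect_equal(roi_sum[61:80], rep(0, 20))
})

test_that("noiseless rendering equals the analytic forward model pixelwise", {
  cfg <- sim_config(field_shape = c(40, 40), n_spots = 3, n_frames = 6,
                    min_spacing = 8 * 0.16, drift_rate = c(0.2, -0.1),
                    drift_rw_sd = 0, shot_noise = FALSE, read_noise_sd = 0,
                    background_level = 20, drop_probability = 1,
                    drop_time_scale = 10)
  sim <- simulate_movie(cfg, seed = 11)
  ev <- sim$truth
  attr(ev, "amps") <- attr(sim$movie, "amplitudes")
  drift <- attr(sim$movie, "drift")
  ref <- analytic_movie(cfg, sim$truth, ev, drift)
  # agreement down to the finite support of the rendered PSF patch
  # (truncated at ~5 sigma, i.e. < 1e-5 of a spot amplitude per pixel)
  expect_lt(max(abs(sim$movie$data - ref)), 0.01)
})

test_that("fixed seeds reproduce the movie and truth bit for bit", {
  a <- quick_sim(seed = 9)
  b <- quick_sim(seed = 9)
  expect_identical(a$movie$data, b$movie$data)
  expect_identical(a$truth, b$truth)
  c <- quick_sim(seed = 10)
  expect_false(identical(a$movie$data, c$movie$data))
})

test_that("empirical drop fraction converges to drop_probability", {
  p <- 255 / 330
  cfg <- sim_config(drop_probability = p, photobleach_rate = 0)
  ev <- sample_event_schedule(cfg, n = 1e4, seed = 2)
  expect_lt(abs(mean(ev$event_type == "drop") - p),
            3 * sqrt(p * (1 - p) / 1e4))
})

test_that("configuration validation rejects out-of-range parameters", {
  expect_error(sim_config(drop_probability = 1.2), "drop_probability")
  expect_error(sim_config(residual_fraction = 0.8), "residual_fraction")
  expect_error(sim_config(n_frames = 0), "n_frames")
  expect_error(sim_config(photobleach_rate = -1), "non-negative")
})

test_that("simulation config round-trips through YAML", {
  path <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(n_frames = 61L, n_spots = 5L,
                        drop_probability = 0.5), path)
  cfg <- read_sim_config(path)
  expect_equal(cfg$n_frames, 61L)
  expect_equal(cfg$drop_probability, 0.5)
  expect_equal(cfg$frame_interval, 5)
  yaml::write_yaml(list(bogus_field = 1), path)
  expect_error(read_sim_config(path), "Unknown configuration field")
})
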