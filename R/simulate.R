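#' Simulation configuration for synthetic TIRF movies
#'
#' Builds a validated configuration for the forward model of a
#' single-molecule TIRF strand-separation experiment: sparse immobile
#' diffraction-limited spots on a dark background, step-like intensity loss
#' when the labelled strand is released (a "drop"), competing
#' photobleaching, stage drift, and camera noise.
#'
#' Acquisition defaults follow the assay this package targets: frames every
#' 5 s for 10 min (121 frames), a 512 x 512 EMCCD field, and immobilized
#' scaffolds kept sparse (minimum spacing defaulting to the reported mean
#' inter-scaffold distance of 15.2 um). Pixel size, gain and spot
#' brightness are not reported by the assay and carry declared defaults
#' (0.16 um/px for a typical 100x TIRF objective on a 16-um-pixel EMCCD).
#'
#' @param field_shape Integer vector `(rows, cols)` of the field in pixels.
#' @param pixel_size Pixel size, micrometres per pixel.
#' @param n_frames Number of frames (>= 1).
#' @param frame_interval Seconds between frames.
#' @param n_spots Number of spots to place.
#' @param min_spacing Minimum centre-to-centre spacing between spots, in
#'   micrometres.
#' @param psf_sigma Gaussian PSF standard deviation, pixels.
#' @param spot_amplitude_mean Mean integrated spot intensity,
#'   photons/frame.
#' @param spot_amplitude_cv Coefficient of variation of spot amplitudes
#'   (log-normal across spots).
#' @param background_level Background, photons/pixel/frame.
#' @param camera_gain Conversion gain, ADU/photon.
#' @param read_noise_sd Gaussian read noise, ADU.
#' @param drift_rate Length-2 numeric `(dy, dx)`: linear stage drift,
#'   pixels/frame.
#' @param drift_rw_sd Random-walk drift step standard deviation,
#'   pixels/frame.
#' @param drop_probability Probability that a spot undergoes strand
#'   separation within the acquisition window.
#' @param drop_time_scale Waiting-time scale (seconds) of the truncated
#'   exponential governing when a drop occurs, given that it occurs.
#' @param photobleach_rate Photobleaching rate, 1/s (0 disables; the
#'   red-dye channel is stabilized with oxygen scavengers, so the default
#'   is 0).
#' @param residual_fraction Relative brightness remaining after a drop.
#'   Must be < 0.75 so simulated events fall below the calling threshold.
#' @param shot_noise Logical; if `FALSE`, Poisson photon noise is disabled
#'   and (with `read_noise_sd = 0`) the rendered movie equals the analytic
#'   forward model exactly.
#' @param seed Default master seed carried with the configuration.
#'
#' @return A list of class `sim_config`.
#' @seealso [simulate_movie()], [condition_preset()]
#' @export
sim_config <- function(field_shape = c(512L, 512L),
                       pixel_size = 0.16,
                       n_frames = 121L,
                       frame_interval = 5,
                       n_spots = 20L,
                       min_spacing = 15.2,
                       psf_sigma = 1.2,
                       spot_amplitude_mean = 2000,
                       spot_amplitude_cv = 0.2,
                       background_level = 100,
                       camera_gain = 1,
                       read_noise_sd = 2,
                       drift_rate = c(0.02, 0.02),
                       drift_rw_sd = 0.01,
                       drop_probability = 255 / 330,
                       drop_time_scale = 120,
                       photobleach_rate = 0,
                       residual_fraction = 0,
                       shot_noise = TRUE,
                       seed = 1L) {
  cfg <- list(
    field_shape = as.integer(field_shape), pixel_size = pixel_size,
    n_frames = as.integer(n_frames), frame_interval = frame_interval,
    n_spots = as.integer(n_spots), min_spacing = min_spacing,
    psf_sigma = psf_sigma, spot_amplitude_mean = spot_amplitude_mean,
    spot_amplitude_cv = spot_amplitude_cv,
    background_level = background_level, camera_gain = camera_gain,
    read_noise_sd = read_noise_sd, drift_rate = as.numeric(drift_rate),
    drift_rw_sd = drift_rw_sd, drop_probability = drop_probability,
    drop_time_scale = drop_time_scale, photobleach_rate = photobleach_rate,
    residual_fraction = residual_fraction, shot_noise = isTRUE(shot_noise),
    seed = seed
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  stopifnot(length(cfg$field_shape) == 2L, length(cfg$drift_rate) == 2L)
  if (any(cfg$field_shape < 1L)) abort("`field_shape` must be positive.")
  if (cfg$n_frames < 1L) abort("`n_frames` must be >= 1.")
  if (cfg$frame_interval <= 0) abort("`frame_interval` must be positive.")
  nonneg <- c("pixel_size", "min_spacing", "psf_sigma", "spot_amplitude_mean",
              "spot_amplitude_cv", "background_level", "camera_gain",
              "read_noise_sd", "drift_rw_sd", "drop_time_scale",
              "photobleach_rate")
  for (f in nonneg) {
    if (cfg[[f]] < 0) abort(sprintf("`%s` must be non-negative.", f))
  }
  if (cfg$drop_probability < 0 || cfg$drop_probability > 1) {
    abort("`drop_probability` must be in [0, 1].")
  }
  if (cfg$residual_fraction < 0 || cfg$residual_fraction >= 0.75) {
    abort("`residual_fraction` must be in [0, 0.75) so that events are callable.")
  }
  if (cfg$n_spots < 0L) abort("`n_spots` must be non-negative.")
  invisible(cfg)
}

#' Read a simulation configuration from a YAML file
#'
#' Any field of [sim_config()] may appear in the file; unspecified fields
#' take their defaults.
#'
#' @param path Path to a YAML file.
#' @return A `sim_config`.
#' @export
read_sim_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(sim_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) {
    abort(sprintf("Unknown configuration field(s): %s", toString(bad)))
  }
  do.call(sim_config, vals)
}

# registry of per-condition drop counts used as simulation presets
.preset_table <- function() {
  tibble(
    name = c("ATP", "ADP", "no_protein", "boxes_scr", "trios_scr",
             "R264A", "I190A", "domains_III_IV"),
    description = c(
      "DnaA-ATP on the wild-type basal unwinding system",
      "DnaA-ADP (inactive nucleotide state)",
      "No-protein control",
      "Scrambled DnaA-boxes",
      "Scrambled DnaA-trios",
      "DnaA arginine-finger mutant (oligomerization deficient)",
      "DnaA ssDNA-binding mutant",
      "DnaA lacking domains I-II (domains III-IV only)"
    ),
    n_drops = c(255L, 48L, 44L, 61L, 82L, 24L, 23L, 209L),
    n_total = c(330L, 413L, 340L, 609L, 706L, 353L, 309L, 387L)
  ) |>
    mutate(drop_probability = n_drops / n_total)
}

#' Per-condition presets calibrated to observed drop counts
#'
#' Each preset carries the number of immobilized scaffolds scored in one
#' experimental condition and the fraction of them that lost their
#' fluorescent spot, used as `n_spots` and `drop_probability` when
#' simulating that condition.
#'
#' @param name Preset name; see `condition_presets()` for the registry.
#' @return `condition_preset()`: a one-row tibble with columns `name`,
#'   `description`, `n_drops`, `n_total`, `drop_probability`.
#'   `condition_presets()`: the full registry.
#' @examples
#' condition_preset("ATP")
#' condition_presets()
#' @export
condition_preset <- function(name) {
  tab <- .preset_table()
  if (!name %in% tab$name) {
    abort(sprintf("Unknown condition preset '%s'. Available: %s.",
                  name, toString(tab$name)))
  }
  tab[tab$name == name, ]
}

#' @rdname condition_preset
#' @export
condition_presets <- function() .preset_table()

#' Place spot centres with a minimum-spacing constraint
#'
#' Rejection-samples `n` positions uniformly over the field, keeping a
#' candidate only if it is at least `min_spacing_px` from every accepted
#' position and at least `margin` pixels from the border (so the
#' measurement annulus never leaves the field). Sampling is bounded: if a
#' position cannot be placed within `max_attempts` draws the function
#' fails with a "field too crowded" error rather than looping forever.
#'
#' @param n Number of positions.
#' @param field_shape `(rows, cols)` in pixels.
#' @param min_spacing_px Minimum pairwise distance, pixels.
#' @param seed Optional integer seed.
#' @param margin Border margin, pixels (default 8: ROI plus annulus for
#'   the default geometry).
#' @param max_attempts Cap on total rejection-sampling draws.
#' @return A tibble with 0-based `x`, `y` columns (one row per spot).
#' @export
sample_spot_positions <- function(n, field_shape, min_spacing_px,
                                  seed = NULL, margin = 8,
                                  max_attempts = max(2000, 500 * n)) {
  stopifnot(n >= 0, min_spacing_px >= 0)
  if (n == 0L) return(tibble(x = numeric(), y = numeric()))
  lo <- margin
  hi_y <- field_shape[1] - 1 - margin
  hi_x <- field_shape[2] - 1 - margin
  if (hi_y < lo || hi_x < lo) {
    abort("field too crowded: border margin leaves no room for any spot")
  }
  with_seed(seed, {
    xs <- numeric(n)
    ys <- numeric(n)
    placed <- 0L
    attempts <- 0L
    min_sq <- min_spacing_px^2
    while (placed < n) {
      attempts <- attempts + 1L
      if (attempts > max_attempts) {
        abort(sprintf(
          "field too crowded: placed %d of %d spots after %d attempts (min spacing %.1f px)",
          placed, n, attempts - 1L, min_spacing_px
        ))
      }
      cx <- runif(1, lo, hi_x)
      cy <- runif(1, lo, hi_y)
      if (placed == 0L ||
          all((xs[seq_len(placed)] - cx)^2 + (ys[seq_len(placed)] - cy)^2 >= min_sq)) {
        placed <- placed + 1L
        xs[placed] <- cx
        ys[placed] <- cy
      }
    }
    tibble(x = xs, y = ys)
  })
}

#' Draw the per-spot event schedule
#'
#' Each spot independently undergoes strand separation ("drop") with
#' probability `drop_probability`; given a drop, its time is drawn from an
#' exponential of scale `drop_time_scale` truncated to the acquisition
#' window, so every scheduled drop falls inside the movie. Photobleaching
#' is an independent competing exponential with rate `photobleach_rate`;
#' whichever process fires first (if either fires within the window)
#' defines the event. Event frames are 0-based; a spot's intensity changes
#' at its event frame.
#'
#' @param config A [sim_config()].
#' @param n Number of spots (defaults to `config$n_spots`).
#' @param seed Optional integer seed.
#' @return A tibble with columns `spot_id`, `event_type`
#'   (`"drop"`, `"photobleach"` or `"none"`), `event_frame` (integer, `NA`
#'   iff `event_type == "none"`).
#' @export
sample_event_schedule <- function(config, n = config$n_spots, seed = NULL) {
  validate_sim_config(config)
  t_end <- (config$n_frames - 1) * config$frame_interval
  with_seed(seed, {
    has_drop <- runif(n) < config$drop_probability
    # inverse-CDF draw from Exp(scale) truncated to (0, t_end]
    t_drop <- rep(Inf, n)
    if (any(has_drop) && t_end > 0) {
      u <- runif(sum(has_drop))
      sc <- config$drop_time_scale
      t_drop[has_drop] <- if (sc > 0) {
        -sc * log(1 - u * (1 - exp(-t_end / sc)))
      } else {
        # degenerate scale: drop at the first opportunity
        rep(.Machine$double.eps, sum(has_drop))
      }
    }
    t_pb <- if (config$photobleach_rate > 0) {
      rexp(n, rate = config$photobleach_rate)
    } else {
      rep(Inf, n)
    }
    t_event <- pmin(t_drop, t_pb)
    fired <- is.finite(t_event) & t_event <= t_end
    type <- rep("none", n)
    type[fired & t_drop <= t_pb] <- "drop"
    type[fired & t_pb < t_drop] <- "photobleach"
    frame <- rep(NA_integer_, n)
    if (config$n_frames > 1L) {
      frame[fired] <- pmin.int(
        pmax.int(as.integer(ceiling(t_event[fired] / config$frame_interval)), 1L),
        config$n_frames - 1L
      )
    } else {
      type[] <- "none"
    }
    tibble(spot_id = seq_len(n), event_type = type, event_frame = frame)
  })
}

# cumulative (dy, dx) drift per frame: linear component + random walk
sample_drift_path <- function(config, seed = NULL) {
  nf <- config$n_frames
  with_seed(seed, {
    steps_y <- rnorm(nf, 0, config$drift_rw_sd)
    steps_x <- rnorm(nf, 0, config$drift_rw_sd)
    steps_y[1] <- 0
    steps_x[1] <- 0
    tibble(
      frame = 0:(nf - 1L),
      dy = (0:(nf - 1L)) * config$drift_rate[1] + cumsum(steps_y),
      dx = (0:(nf - 1L)) * config$drift_rate[2] + cumsum(steps_x)
    )
  })
}

# separable Gaussian factors per frame for one spot, as a
# (rows x cols x frames) patch plus its field placement
spot_patch <- function(field_shape, y, x, dy, dx, amps, sigma, radius) {
  cy <- y + dy + 1
  cx <- x + dx + 1
  r0 <- max(1L, floor(min(cy) - radius))
  r1 <- min(field_shape[1], ceiling(max(cy) + radius))
  c0 <- max(1L, floor(min(cx) - radius))
  c1 <- min(field_shape[2], ceiling(max(cx) + radius))
  if (r0 > r1 || c0 > c1) return(NULL)
  s2 <- 2 * sigma^2
  ry <- exp(-outer(r0:r1, cy, "-")^2 / s2)    # R x nf
  rx <- exp(-outer(c0:c1, cx, "-")^2 / s2)    # C x nf
  R <- r1 - r0 + 1L
  C <- c1 - c0 + 1L
  contrib <- ry[rep(seq_len(R), times = C), , drop = FALSE] *
    rx[rep(seq_len(C), each = R), , drop = FALSE]
  contrib <- contrib * rep(amps / (2 * pi * sigma^2), each = R * C)
  list(rows = r0:r1, cols = c0:c1,
       patch = array(contrib, c(R, C, length(amps))))
}

#' Render a synthetic TIRF movie
#'
#' Forward model: each frame is a constant photon background plus one 2-D
#' Gaussian per spot at its drifted position. A spot keeps its sampled
#' amplitude before its event frame; from the event frame on it renders at
#' `residual_fraction` of its amplitude (drop) or at zero (photobleach).
#' Per-pixel photon counts are Poisson-sampled, scaled by the camera gain,
#' and Gaussian read noise is added; with `shot_noise = FALSE` and zero
#' read noise the analytic expectation is returned unrounded.
#'
#' @param config A [sim_config()].
#' @param positions Tibble of spot centres (`x`, `y`), as from
#'   [sample_spot_positions()].
#' @param events Tibble of events, as from [sample_event_schedule()]; must
#'   have one row per position.
#' @param seed Optional integer seed (amplitudes, drift walk, noise).
#' @return A [tirf_movie()] carrying `frame_interval` and `pixel_size`
#'   from the configuration, with the realized drift path and sampled
#'   amplitudes attached as attributes `drift` and `amplitudes`.
#' @export
render_movie <- function(config, positions, events, seed = NULL) {
  validate_sim_config(config)
  if (nrow(positions) != nrow(events)) {
    abort("`positions` and `events` must have one row per spot.")
  }
  nr <- config$field_shape[1]
  nc <- config$field_shape[2]
  nf <- config$n_frames
  ns <- nrow(positions)
  with_seed(seed, {
    s_ln <- sqrt(log(1 + config$spot_amplitude_cv^2))
    amps <- if (ns) {
      config$spot_amplitude_mean * rlnorm(ns, -s_ln^2 / 2, s_ln)
    } else {
      numeric()
    }
    drift <- sample_drift_path(config)
    radius <- ceiling(4 * config$psf_sigma) + 1
    data <- array(config$background_level, dim = c(nr, nc, nf))
    frames0 <- 0:(nf - 1L)
    for (s in seq_len(ns)) {
      amps_f <- rep(amps[s], nf)
      if (!is.na(events$event_frame[s])) {
        post <- frames0 >= events$event_frame[s]
        amps_f[post] <- if (events$event_type[s] == "drop") {
          amps[s] * config$residual_fraction
        } else {
          0
        }
      }
      p <- spot_patch(config$field_shape, positions$y[s], positions$x[s],
                      drift$dy, drift$dx, amps_f,
                      config$psf_sigma, radius)
      if (!is.null(p)) {
        data[p$rows, p$cols, ] <- data[p$rows, p$cols, ] + p$patch
      }
    }
    if (config$shot_noise) {
      data[] <- rpois(length(data), lambda = data)
    }
    data <- data * config$camera_gain
    if (config$read_noise_sd > 0) {
      data <- data + rnorm(length(data), 0, config$read_noise_sd)
    }
    if (config$shot_noise || config$read_noise_sd > 0) {
      data <- pmax(round(data), 0)
    }
    m <- tirf_movie(data, frame_interval = config$frame_interval,
                    pixel_size = config$pixel_size, source = "simulated")
    attr(m, "drift") <- drift
    attr(m, "amplitudes") <- amps
    m
  })
}

#' Simulate a complete movie with ground truth
#'
#' Convenience wrapper chaining [sample_spot_positions()],
#' [sample_event_schedule()] and [render_movie()] with independent child
#' seeds derived from one master seed, so any stage can be varied while
#' the others are held fixed.
#'
#' @param config A [sim_config()]; `condition` (a preset name from
#'   [condition_presets()]) overrides its `n_spots` and
#'   `drop_probability`.
#' @param seed Master seed (defaults to `config$seed`).
#' @param condition Optional preset name.
#' @return A list with elements `movie` (a [tirf_movie()]), `truth` (a
#'   tibble `spot_id`, `x`, `y`, `event_type`, `event_frame`), and
#'   `config`.
#' @examples
#' sim <- simulate_movie(sim_config(field_shape = c(64, 64), n_spots = 4,
#'                                  min_spacing = 1.6, n_frames = 20), seed = 1)
#' sim$truth
#' @export
simulate_movie <- function(config = sim_config(), seed = config$seed,
                           condition = NULL) {
  if (!is.null(condition)) {
    preset <- condition_preset(condition)
    config$n_spots <- preset$n_total
    config$drop_probability <- preset$drop_probability
  }
  validate_sim_config(config)
  positions <- sample_spot_positions(
    config$n_spots, config$field_shape,
    min_spacing_px = config$min_spacing / config$pixel_size,
    seed = derive_seed(seed, 1)
  )
  events <- sample_event_schedule(config, n = nrow(positions),
                                  seed = derive_seed(seed, 2))
  movie <- render_movie(config, positions, events,
                        seed = derive_seed(seed, 3))
  truth <- tibble(
    spot_id = events$spot_id, x = positions$x, y = positions$y,
    event_type = events$event_type, event_frame = events$event_frame
  )
  list(movie = movie, truth = truth, config = config)
}
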