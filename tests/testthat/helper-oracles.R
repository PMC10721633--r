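# Independent oracles and fixture builders used across the suite.

# Spot amplitude giving a target peak signal-to-noise ratio
# (peak height above background over the background noise SD).
amp_for_snr <- function(snr, psf_sigma = 1.2, background = 100,
                        read_noise_sd = 2) {
  snr * sqrt(background + read_noise_sd^2) * 2 * pi * psf_sigma^2
}

# Brute-force drop-rule oracle: scan every window of `run_length` frames.
# Completely independent of the package's run-length-encoding path.
brute_force_call <- function(normalized, valid = rep(TRUE, length(normalized)),
                             threshold = 0.75, run_length = 5) {
  L <- length(normalized)
  if (L < run_length) return(list(verdict = "excluded", drop_frame = NA_integer_))
  below <- !is.na(normalized) & normalized < threshold & valid
  for (s in seq_len(L - run_length + 1L)) {
    if (all(below[s:(s + run_length - 1L)])) {
      return(list(verdict = "drop", drop_frame = s - 1L))
    }
  }
  list(verdict = "no_drop", drop_frame = NA_integer_)
}

# Random normalized traces mixing flat, stepped, noisy and partly invalid
# cases so both verdicts and edge behaviour are well represented.
random_trace_set <- function(n, len = 121, seed = 1) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    base <- 1 + rnorm(len, 0, runif(1, 0.02, 0.2))
    if (runif(1) < 0.6) {
      at <- sample.int(len, 1)
      base[at:len] <- runif(1, -0.1, 0.9) + rnorm(len - at + 1, 0, 0.05)
    }
    valid <- rep(TRUE, len)
    if (runif(1) < 0.2) valid[sample.int(len, sample.int(8, 1))] <- FALSE
    list(normalized = base, valid = valid)
  })
}

# Long trace tibble from a list of per-spot normalized vectors.
traces_from_list <- function(lst) {
  dplyr::bind_rows(lapply(seq_along(lst), function(i) {
    tibble::tibble(
      spot_id = i,
      frame = seq_along(lst[[i]]$normalized) - 1L,
      raw = lst[[i]]$normalized,
      normalized = lst[[i]]$normalized,
      valid = lst[[i]]$valid,
      usable = TRUE,
      initial_intensity = 1
    )
  }))
}

# Textured synthetic image (smoothed noise) for registration tests.
textured_image <- function(n = 64, seed = 1, sigma = 2) {
  set.seed(seed)
  tirfdrop:::gaussian_smooth(matrix(rnorm(n * n), n, n), sigma)
}

# Exact translation by integer pixels with wrap-around.
wrap_shift <- function(M, a, b) {
  M[((seq_len(nrow(M)) - 1 - a) %% nrow(M)) + 1,
    ((seq_len(ncol(M)) - 1 - b) %% ncol(M)) + 1]
}

# Exact subpixel translation via the Fourier shift theorem.
fourier_shift <- function(M, dy, dx) {
  n <- nrow(M); m <- ncol(M)
  fy <- c(0:(ceiling(n / 2) - 1), -(floor(n / 2)):-1) / n
  fx <- c(0:(ceiling(m / 2) - 1), -(floor(m / 2)):-1) / m
  ph <- exp(-2i * pi * (outer(fy * dy, rep(1, m)) + outer(rep(1, n), fx * dx)))
  Re(fft(fft(M) * ph, inverse = TRUE) / (n * m))
}

# Analytic forward model of a noiseless movie, computed pixel by pixel,
# independent of the renderer's patch accumulation.
analytic_movie <- function(config, positions, events, drift) {
  nr <- config$field_shape[1]; nc <- config$field_shape[2]
  nf <- config$n_frames
  out <- array(config$background_level, c(nr, nc, nf))
  for (f in seq_len(nf)) {
    for (s in seq_len(nrow(positions))) {
      a <- 1
      if (!is.na(events$event_frame[s]) && (f - 1) >= events$event_frame[s]) {
        a <- if (events$event_type[s] == "drop") config$residual_fraction else 0
      }
      if (a == 0) next
      cy <- positions$y[s] + drift$dy[f] + 1
      cx <- positions$x[s] + drift$dx[f] + 1
      amp <- attr(events, "amps")[s] * a
      for (r in seq_len(nr)) {
        for (cc in seq_len(nc)) {
          d2 <- (r - cy)^2 + (cc - cx)^2
          if (d2 <= (config$psf_sigma * 6)^2) {
            out[r, cc, f] <- out[r, cc, f] +
              amp / (2 * pi * config$psf_sigma^2) *
                exp(-d2 / (2 * config$psf_sigma^2))
          }
        }
      }
    }
  }
  out
}

# A small simulated movie used by several tests.
quick_sim <- function(seed = 1, n_spots = 12, n_frames = 40,
                      field = c(96, 96), drop_probability = 0.6, ...) {
  cfg <- sim_config(field_shape = field, n_spots = n_spots,
                    min_spacing = 10 * 0.16, n_frames = n_frames,
                    drop_probability = drop_probability,
                    drift_rate = c(0, 0), drift_rw_sd = 0, ...)
  simulate_movie(cfg, seed = seed)
}
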