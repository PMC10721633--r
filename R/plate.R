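#' Simulate a quencher strand-separation plate run
#'
#' Generates triplicate experimental and triplicate background wells on
#' the assay's acquisition grid (default every 30 s for 75 min, 151
#' points). Each experimental well follows
#' `baseline + baseline_drift * t + A * (1 - exp(-k * (t - t0)))` for
#' `t >= t0`, where `t0` is the second timepoint: the first point is
#' measured before the protein is added, so the reaction starts after it.
#' Background wells carry only the shared baseline (and its drift).
#' Gaussian noise of standard deviation `noise_sd` is added to every
#' reading.
#'
#' @param conditions A data frame with columns `condition`, `A`
#'   (amplitude, fluorescence units) and `k` (rate, 1/s), one row per
#'   condition.
#' @param noise_sd Measurement noise SD (fluorescence units).
#' @param seed Optional integer seed.
#' @param baseline Shared baseline fluorescence.
#' @param baseline_drift Shared linear baseline drift (units/s).
#' @param t_total Total acquisition time, seconds (default 4500 = 75 min).
#' @param dt Sampling interval, seconds (default 30).
#' @param n_replicates Wells per condition and for the background
#'   (default 3).
#' @return A long tibble: `well_id`, `role` (`"experimental"` or
#'   `"background"`), `condition`, `replicate`, `time_s`, `signal`.
#' @export
simulate_plate <- function(conditions, noise_sd = 0, seed = NULL,
                           baseline = 100, baseline_drift = 0,
                           t_total = 4500, dt = 30, n_replicates = 3) {
  stopifnot(all(c("condition", "A", "k") %in% names(conditions)),
            all(conditions$k >= 0), noise_sd >= 0)
  tt <- seq(0, t_total, by = dt)
  t0 <- if (length(tt) > 1) tt[2] else 0
  with_seed(seed, {
    rows <- list()
    for (i in seq_len(nrow(conditions))) {
      for (r in seq_len(n_replicates)) {
        resp <- conditions$A[i] *
          (1 - exp(-conditions$k[i] * pmax(tt - t0, 0)))
        rows[[length(rows) + 1L]] <- tibble(
          well_id = sprintf("%s_rep%d", conditions$condition[i], r),
          role = "experimental", condition = conditions$condition[i],
          replicate = r, time_s = tt,
          signal = baseline + baseline_drift * tt + resp +
            rnorm(length(tt), 0, noise_sd)
        )
      }
    }
    for (r in seq_len(n_replicates)) {
      rows[[length(rows) + 1L]] <- tibble(
        well_id = sprintf("background_rep%d", r),
        role = "background", condition = NA_character_,
        replicate = r, time_s = tt,
        signal = baseline + baseline_drift * tt +
          rnorm(length(tt), 0, noise_sd)
      )
    }
    bind_rows(rows)
  })
}

#' Subtract the averaged background wells per timepoint
#'
#' At each timepoint the mean of the background (no-protein) replicate
#' wells is subtracted from every experimental replicate, removing any
#' additive baseline shared by the plate (the correction is exact for any
#' shared baseline, including a drifting one). All wells must share the
#' same timepoint grid.
#'
#' @param plate A long plate tibble (see [simulate_plate()] /
#'   [read_plate()]).
#' @return A long tibble of corrected per-replicate traces: `condition`,
#'   `replicate`, `time_s`, `corrected`.
#' @export
subtract_background <- function(plate) {
  stopifnot(all(c("well_id", "role", "time_s", "signal") %in% names(plate)))
  grids <- plate |>
    group_by(well_id) |>
    summarise(grid = list(sort(time_s)), .groups = "drop")
  ref_grid <- grids$grid[[1]]
  for (i in seq_len(nrow(grids))) {
    g <- grids$grid[[i]]
    if (length(g) != length(ref_grid) || any(g != ref_grid)) {
      bad <- if (length(g) != length(ref_grid)) {
        ref_grid[min(length(g), length(ref_grid)) + 1]
      } else {
        ref_grid[which(g != ref_grid)[1]]
      }
      abort(sprintf(
        "Well '%s' timepoint grid differs from '%s' first at t = %s s.",
        grids$well_id[i], grids$well_id[1], format(bad)
      ))
    }
  }
  bg <- plate |>
    filter(role == "background") |>
    group_by(time_s) |>
    summarise(bg_mean = mean(signal), .groups = "drop")
  if (nrow(bg) == 0L) abort("No background wells in the plate table.")
  plate |>
    filter(role == "experimental") |>
    left_join(bg, by = "time_s") |>
    mutate(corrected = signal - .data$bg_mean) |>
    select(condition, replicate, time_s, corrected)
}

#' Initial rate of a corrected kinetic trace
#'
#' Least-squares slope of corrected signal versus time over an early
#' window. The first timepoint (measured before protein addition) is each
#' well's own zero reference and is excluded; the window spans
#' `rate_window` seconds starting at the second timepoint.
#'
#' @param trace A data frame with columns `time_s` and `corrected` (one
#'   trace).
#' @param rate_window Window length in seconds (default 600 = the first
#'   10 min of the reaction).
#' @return Slope in fluorescence units per second.
#' @export
initial_rate <- function(trace, rate_window = 600) {
  stopifnot(all(c("time_s", "corrected") %in% names(trace)))
  tr <- arrange(trace, time_s)
  t0 <- tr$time_s[2]
  win <- tr |> filter(time_s >= t0, time_s <= t0 + rate_window)
  if (nrow(win) < 3L) {
    abort("Fewer than 3 timepoints inside the rate window.")
  }
  unname(coef(lm(corrected ~ time_s, data = win))[2])
}

#' Analyze a strand-separation plate run
#'
#' Background-subtracts every experimental replicate, averages the
#' triplicates per condition (mean and SD per timepoint), and estimates a
#' per-replicate initial rate with its per-condition mean and SD.
#'
#' @param plate A long plate tibble.
#' @param rate_window Passed to [initial_rate()].
#' @return An object of class `ssa_result` with elements `traces`
#'   (condition, time_s, mean, sd), `replicate_traces`, `rates`
#'   (per replicate), `rate_summary` (per condition), `rate_window`.
#' @export
analyze_ssa <- function(plate, rate_window = 600) {
  corr <- subtract_background(plate)
  traces <- corr |>
    group_by(condition, time_s) |>
    summarise(mean = mean(corrected), sd = sd(corrected), .groups = "drop")
  rates <- corr |>
    group_by(condition, replicate) |>
    summarise(rate = initial_rate(tibble(time_s = time_s,
                                         corrected = corrected),
                                  rate_window),
              .groups = "drop")
  rate_summary <- rates |>
    group_by(condition) |>
    summarise(rate_mean = mean(rate), rate_sd = sd(rate),
              n_replicates = n(), .groups = "drop")
  structure(
    list(traces = traces, replicate_traces = corr, rates = rates,
         rate_summary = rate_summary, rate_window = rate_window),
    class = "ssa_result"
  )
}

#' @export
print.ssa_result <- function(x, ...) {
  cat(sprintf("<ssa_result> %d condition(s), rate window %g s\n",
              nrow(x$rate_summary), x$rate_window))
  print(x$rate_summary)
  invisible(x)
}

#' Melting temperature from a melt curve
#'
#' Tm is the temperature at the extremum of the smoothed first derivative
#' of fluorescence with respect to temperature, refined to sub-grid
#' resolution by a quadratic fit through the extremum and its neighbours.
#' The sign convention is configurable: quench-based probes gain
#' fluorescence on melting while intercalating-dye chemistry loses it;
#' `"auto"` picks the extremum of larger magnitude.
#'
#' @param curve A data frame with columns `temperature` (degrees C,
#'   monotone increasing, at least 5 points) and `fluorescence`.
#' @param smooth_window Odd moving-average window applied to the
#'   fluorescence before differentiation (default 5).
#' @param sign `"auto"`, `"increase"` (fluorescence rises at the
#'   transition) or `"decrease"`.
#' @return Tm in degrees C.
#' @export
melt_temperature <- function(curve, smooth_window = 5,
                             sign = c("auto", "increase", "decrease")) {
  sign <- match.arg(sign)
  stopifnot(all(c("temperature", "fluorescence") %in% names(curve)))
  curve <- arrange(curve, temperature)
  temp <- curve$temperature
  fl <- curve$fluorescence
  if (length(temp) < 5L) abort("Melt curve needs at least 5 points.")
  if (any(diff(temp) <= 0)) abort("`temperature` must be strictly increasing.")
  sm <- moving_average(fl, smooth_window)
  if (diff(range(sm)) <= 1e-9 * max(1, max(abs(sm)))) {
    abort("Flat melt curve: no melting transition detected.")
  }
  mid <- (temp[-1] + temp[-length(temp)]) / 2
  dfdt <- diff(sm) / diff(temp)
  i <- switch(sign,
              auto = which.max(abs(dfdt)),
              increase = which.max(dfdt),
              decrease = which.min(dfdt))
  if (abs(dfdt[i]) <= 1e-9 * max(1, max(abs(sm)))) {
    abort("Flat melt curve: no melting transition detected.")
  }
  # quadratic refinement through the extremum and its neighbours
  if (i > 1L && i < length(dfdt)) {
    xs <- mid[(i - 1):(i + 1)]
    ys <- abs(dfdt[(i - 1):(i + 1)])
    fit <- lm(ys ~ poly(xs, 2, raw = TRUE))
    b <- coef(fit)
    if (!is.na(b[3]) && b[3] < 0) {
      vertex <- -b[2] / (2 * b[3])
      if (vertex >= xs[1] && vertex <= xs[3]) return(unname(vertex))
    }
  }
  mid[i]
}
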