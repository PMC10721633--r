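#' Call strand-separation drops on normalized traces
#'
#' A spot is called a drop if its normalized intensity is strictly below
#' `threshold` for `run_length` consecutive frames; the reported
#' `drop_frame` is the first frame of the earliest qualifying run. Frames
#' flagged invalid by the drift correction are treated as
#' not-below-threshold (they can interrupt, but never extend, a run).
#' Values exactly at the threshold do not count towards a run. Recovery
#' after a qualifying run does not rescind the call: the rule is a
#' trigger, not a state classifier. Unusable traces and traces shorter
#' than `run_length` receive the verdict `"excluded"`.
#'
#' @param traces Normalized trace tibble from [normalize_traces()].
#' @param threshold Fraction of the initial intensity below which a frame
#'   counts towards a run (default 0.75).
#' @param run_length Required number of consecutive sub-threshold frames
#'   (default 5).
#' @return A tibble: `spot_id`, `x`, `y`, `verdict` (`"drop"`,
#'   `"no_drop"`, `"excluded"`), `drop_frame` (0-based, `NA` unless
#'   `verdict == "drop"`), `initial_intensity`.
#' @export
call_drops <- function(traces, threshold = 0.75, run_length = 5) {
  stopifnot(threshold > 0, threshold < 1, run_length >= 1)
  needed <- c("spot_id", "frame", "normalized")
  missing_cols <- setdiff(needed, names(traces))
  if (length(missing_cols)) {
    abort(sprintf("`traces` is missing column(s): %s (run normalize_traces()?)",
                  toString(missing_cols)))
  }
  if (!"valid" %in% names(traces)) traces$valid <- TRUE
  if (!"usable" %in% names(traces)) traces$usable <- !is.na(traces$normalized)
  has_xy <- all(c("x", "y") %in% names(traces))
  has_init <- "initial_intensity" %in% names(traces)
  traces |>
    arrange(spot_id, frame) |>
    group_by(spot_id) |>
    summarise(
      x = if (has_xy) first(x) else NA_real_,
      y = if (has_xy) first(y) else NA_real_,
      initial_intensity = if (has_init) first(initial_intensity) else NA_real_,
      verdict = {
        if (!all(usable) || n() < run_length) {
          "excluded"
        } else if (is.na(first_run_start(normalized < threshold & valid,
                                         run_length))) {
          "no_drop"
        } else {
          "drop"
        }
      },
      drop_frame = if (verdict == "drop") {
        frame[first_run_start(normalized < threshold & valid, run_length)]
      } else {
        NA_integer_
      },
      .groups = "drop"
    ) |>
    select(spot_id, x, y, verdict, drop_frame, initial_intensity)
}

# 1-based index of the first position starting a run of >= len TRUEs
first_run_start <- function(below, len) {
  below[is.na(below)] <- FALSE
  r <- rle(below)
  hit <- which(r$values & r$lengths >= len)
  if (length(hit) == 0L) return(NA_integer_)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  starts[hit[1]]
}

#' Wilson score interval for a binomial proportion
#'
#' @param x Number of successes.
#' @param n Number of trials.
#' @param conf Confidence level (default 0.95).
#' @return Named numeric vector `c(low = , high = )`.
#' @export
wilson_ci <- function(x, n, conf = 0.95) {
  stopifnot(n >= 1, x >= 0, x <= n)
  z <- qnorm(1 - (1 - conf) / 2)
  p <- x / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- (z / denom) * sqrt(p * (1 - p) / n + z^2 / (4 * n^2))
  c(low = max(0, centre - half), high = min(1, centre + half))
}

#' Summarize drop calls for one condition
#'
#' Computes the per-condition drop fraction (excluded spots removed from
#' the total), its Wilson 95% confidence interval, and, when replicate
#' membership is supplied, per-replicate fractions with their mean and
#' standard deviation, mirroring how the assay aggregates three
#' independent experiments.
#'
#' @param calls Call tibble from [call_drops()], optionally with a
#'   `replicate` column.
#' @param condition Condition label.
#' @param replicate_ids Optional vector of replicate labels, one per row
#'   of `calls` (ignored if `calls` has a `replicate` column).
#' @param conf Confidence level for the Wilson interval.
#' @return An object of class `condition_summary`; see [tidy()] and
#'   [glance()] methods, and [autoplot.condition_summary()].
#' @export
summarize_condition <- function(calls, condition = "condition",
                                replicate_ids = NULL, conf = 0.95) {
  if (!"replicate" %in% names(calls) && !is.null(replicate_ids)) {
    stopifnot(length(replicate_ids) == nrow(calls))
    calls$replicate <- replicate_ids
  }
  usable <- filter(calls, verdict != "excluded")
  if (nrow(usable) == 0L) {
    abort("No usable calls: every trace was excluded.")
  }
  n_total <- nrow(usable)
  n_drops <- sum(usable$verdict == "drop")
  ci <- wilson_ci(n_drops, n_total, conf)
  reps <- NULL
  if ("replicate" %in% names(usable)) {
    reps <- usable |>
      group_by(replicate) |>
      summarise(n_drops = sum(verdict == "drop"), n_total = n(),
                fraction = n_drops / n_total, .groups = "drop")
  }
  structure(
    list(
      condition = condition, n_drops = n_drops, n_total = n_total,
      n_excluded = nrow(calls) - n_total,
      fraction = n_drops / n_total,
      ci_low = unname(ci["low"]), ci_high = unname(ci["high"]),
      conf = conf,
      replicates = reps,
      replicate_mean = if (!is.null(reps)) mean(reps$fraction) else NA_real_,
      replicate_sd = if (!is.null(reps)) sd(reps$fraction) else NA_real_
    ),
    class = "condition_summary"
  )
}

#' @export
print.condition_summary <- function(x, ...) {
  cat(sprintf("<condition_summary> %s\n", x$condition))
  cat(sprintf("  %d drops / %d usable spots (%d excluded): fraction %.3f [%.3f, %.3f] (%d%% Wilson)\n",
              x$n_drops, x$n_total, x$n_excluded, x$fraction,
              x$ci_low, x$ci_high, round(100 * x$conf)))
  if (!is.null(x$replicates)) {
    cat(sprintf("  replicates: %s (mean %.3f, sd %.3f)\n",
                paste(sprintf("%.3f", x$replicates$fraction), collapse = ", "),
                x$replicate_mean, x$replicate_sd))
  }
  invisible(x)
}

#' Control-adjusted drop fraction
#'
#' Difference between a condition's drop fraction and a control's (for
#' example the no-protein baseline), with a Wald confidence interval on
#' the difference of proportions. Raw per-condition fractions remain the
#' default report; this adjustment is optional.
#'
#' @param summary,control `condition_summary` objects.
#' @param conf Confidence level.
#' @return A one-row tibble with the adjusted fraction and its CI.
#' @export
control_adjusted_fraction <- function(summary, control, conf = 0.95) {
  stopifnot(inherits(summary, "condition_summary"),
            inherits(control, "condition_summary"))
  p1 <- summary$fraction
  p2 <- control$fraction
  se <- sqrt(p1 * (1 - p1) / summary$n_total + p2 * (1 - p2) / control$n_total)
  z <- qnorm(1 - (1 - conf) / 2)
  tibble(
    condition = summary$condition, control = control$condition,
    fraction_adjusted = p1 - p2,
    ci_low = p1 - p2 - z * se, ci_high = p1 - p2 + z * se
  )
}

#' Match detected spots to ground-truth positions
#'
#' Greedy nearest-neighbour matching: candidate pairs within
#' `match_radius` pixels are accepted in order of increasing distance,
#' each spot and each truth entry used at most once.
#'
#' @param spots Tibble with `spot_id`, `x`, `y` (detections).
#' @param truth Tibble with `spot_id`, `x`, `y` (ground truth).
#' @param match_radius Maximum centre distance in pixels (default 2).
#' @return A tibble `spot_id`, `truth_id`, `distance`, one row per
#'   matched pair.
#' @export
match_spots <- function(spots, truth, match_radius = 2) {
  if (nrow(spots) == 0L || nrow(truth) == 0L) {
    return(tibble(spot_id = integer(), truth_id = integer(),
                  distance = numeric()))
  }
  d2 <- outer(spots$y, truth$y, "-")^2 + outer(spots$x, truth$x, "-")^2
  cand <- which(d2 <= match_radius^2, arr.ind = TRUE)
  if (nrow(cand) == 0L) {
    return(tibble(spot_id = integer(), truth_id = integer(),
                  distance = numeric()))
  }
  ord <- order(d2[cand])
  cand <- cand[ord, , drop = FALSE]
  used_s <- logical(nrow(spots))
  used_t <- logical(nrow(truth))
  keep_rows <- integer()
  for (i in seq_len(nrow(cand))) {
    si <- cand[i, 1]
    ti <- cand[i, 2]
    if (!used_s[si] && !used_t[ti]) {
      used_s[si] <- TRUE
      used_t[ti] <- TRUE
      keep_rows <- c(keep_rows, i)
    }
  }
  cand <- cand[keep_rows, , drop = FALSE]
  tibble(spot_id = spots$spot_id[cand[, 1]],
         truth_id = truth$spot_id[cand[, 2]],
         distance = sqrt(d2[cand]))
}

#' Evaluate drop calls against simulator ground truth
#'
#' Truth events of type `drop` or `photobleach` are both treated as
#' "should be called": the 75%/5-frame rule sees only an intensity loss
#' and cannot distinguish the two, which is why the assay relies on
#' no-protein and ADP controls. Calls are paired with truth entries by
#' position ([match_spots()]) when both tables carry coordinates, and by
#' `spot_id` otherwise; a call is correct when its paired truth entry has
#' a loss event and the called frame is within `frame_tolerance` of the
#' true frame. Reports recall (over truth events whose spot yielded a
#' usable call), precision, the median absolute frame error among
#' correct calls, and the fraction of correct calls attributable to
#' photobleaching.
#'
#' @param calls Call tibble from [call_drops()].
#' @param truth Ground-truth tibble (`spot_id`, `event_type`,
#'   `event_frame`, optionally `x`, `y`), as from [simulate_movie()].
#' @param frame_tolerance Maximum |called - true| frame difference for a
#'   correct call (default `Inf`: identity of the spot is enough).
#' @param match_radius Spatial match radius in pixels (default 2).
#' @return A one-row tibble: `n_spots`, `n_should`, `n_called`,
#'   `n_matched`, `recall`, `precision`, `median_frame_error`,
#'   `photobleach_call_fraction`.
#' @export
evaluate_against_truth <- function(calls, truth, frame_tolerance = Inf,
                                   match_radius = 2) {
  usable <- filter(calls, verdict != "excluded")
  by_position <- all(c("x", "y") %in% names(usable)) &&
    all(c("x", "y") %in% names(truth)) && !anyNA(usable$x) && !anyNA(truth$x)
  if (by_position) {
    pairs <- match_spots(usable, truth, match_radius)
    j <- usable |>
      left_join(pairs, by = "spot_id") |>
      left_join(
        select(truth, truth_id = spot_id, event_type, event_frame),
        by = "truth_id"
      )
    j$event_type[is.na(j$event_type)] <- "unmatched"
  } else {
    if (!all(usable$spot_id %in% truth$spot_id)) {
      abort("Some called spot_ids are absent from the truth table.")
    }
    j <- left_join(usable, select(truth, spot_id, event_type, event_frame),
                   by = "spot_id")
  }
  should <- j$event_type %in% c("drop", "photobleach")
  called <- j$verdict == "drop"
  matched <- called & should &
    (abs(j$drop_frame - j$event_frame) <= frame_tolerance)
  matched[is.na(matched)] <- FALSE
  tibble(
    n_spots = nrow(j),
    n_should = sum(should),
    n_called = sum(called),
    n_matched = sum(matched),
    recall = if (sum(should)) sum(matched) / sum(should) else NA_real_,
    precision = if (sum(called)) sum(matched) / sum(called) else NA_real_,
    median_frame_error = if (sum(matched)) {
      median(abs(j$drop_frame - j$event_frame)[matched])
    } else {
      NA_real_
    },
    photobleach_call_fraction = if (sum(matched)) {
      mean(j$event_type[matched] == "photobleach")
    } else {
      NA_real_
    }
  )
}

#' Run the full disappearing-spot pipeline on a movie
#'
#' Chains drift estimation and correction, reference building, spot
#' detection, trace extraction, normalization and drop calling with the
#' package defaults, returning every intermediate product.
#'
#' @param movie A [tirf_movie()].
#' @param register Estimate and correct drift first (default `TRUE`).
#' @param mode,upsample Passed to [estimate_drift()].
#' @param n_reference_frames Passed to [build_reference()].
#' @param smoothing_sigma,threshold,k,min_distance Passed to
#'   [detect_spots()].
#' @param n_initial_frames,min_snr Passed to [normalize_traces()].
#' @param drop_threshold,run_length Passed to [call_drops()].
#' @return A list of class `tirf_analysis`: `drift`, `corrected`
#'   (movie), `reference`, `spots`, `traces`, `calls`.
#' @export
analyze_movie <- function(movie, register = TRUE,
                          mode = "to_reference", upsample = 20,
                          n_reference_frames = 5,
                          smoothing_sigma = 1.2, threshold = "auto", k = 5,
                          min_distance = 5,
                          n_initial_frames = 5, min_snr = 3,
                          drop_threshold = 0.75, run_length = 5) {
  drift <- NULL
  corrected <- movie
  if (register && n_frames(movie) >= 2) {
    drift <- estimate_drift(movie, mode = mode, upsample = upsample)
    corrected <- apply_drift(movie, drift)
  }
  reference <- build_reference(corrected, n_reference_frames)
  spots <- detect_spots(reference, smoothing_sigma = smoothing_sigma,
                        threshold = threshold, k = k,
                        min_distance = min_distance)
  traces <- extract_traces(corrected, spots) |>
    normalize_traces(n_initial_frames = n_initial_frames, min_snr = min_snr)
  calls <- call_drops(traces, threshold = drop_threshold,
                      run_length = run_length)
  structure(
    list(drift = drift, corrected = corrected, reference = reference,
         spots = spots, traces = traces, calls = calls),
    class = "tirf_analysis"
  )
}

#' @export
print.tirf_analysis <- function(x, ...) {
  cat(sprintf("<tirf_analysis> %d spots, %d drops, %d excluded\n",
              nrow(x$spots), sum(x$calls$verdict == "drop"),
              sum(x$calls$verdict == "excluded")))
  invisible(x)
}
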