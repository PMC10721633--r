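#' @importFrom ggplot2 ggplot aes geom_line geom_point geom_hline
#'   geom_errorbar geom_ribbon geom_col labs theme_minimal autoplot
#'   facet_wrap
#' @export
ggplot2::autoplot

#' Plot normalized intensity traces
#'
#' Spaghetti plot of normalized traces against time with the drop
#' threshold drawn as a dashed line; called drops are coloured.
#'
#' @param traces Normalized trace tibble from [normalize_traces()].
#' @param calls Optional call tibble from [call_drops()] used to colour
#'   traces by verdict.
#' @param n_max Plot at most this many spots (first by `spot_id`).
#' @param threshold Threshold line position (default 0.75).
#' @return A ggplot object.
#' @export
plot_traces <- function(traces, calls = NULL, n_max = 30, threshold = 0.75) {
  ids <- head(sort(unique(traces$spot_id)), n_max)
  df <- filter(traces, spot_id %in% ids, !is.na(normalized))
  if (!is.null(calls)) {
    df <- left_join(df, select(calls, spot_id, verdict), by = "spot_id")
  } else {
    df$verdict <- "trace"
  }
  xvar <- if (all(is.na(df$time_s))) "frame" else "time_s"
  ggplot(df, aes(x = .data[[xvar]], y = normalized,
                 group = spot_id, colour = verdict)) +
    geom_line(alpha = 0.6) +
    geom_hline(yintercept = threshold, linetype = "dashed") +
    labs(x = if (xvar == "time_s") "time (s)" else "frame",
         y = "intensity relative to initial") +
    theme_minimal()
}

#' Plot a drift trajectory
#'
#' @param trajectory Tibble from [estimate_drift()].
#' @return A ggplot object.
#' @export
plot_drift <- function(trajectory) {
  df <- tidyr::pivot_longer(trajectory, c(dy, dx),
                            names_to = "axis", values_to = "shift")
  ggplot(df, aes(frame, shift, colour = axis)) +
    geom_line() +
    labs(x = "frame", y = "cumulative shift (px)") +
    theme_minimal()
}

#' @describeIn summarize_condition Bar-and-interval plot of a condition
#'   summary (replicate fractions as points when present).
#' @param object A `condition_summary`.
#' @param ... Unused.
#' @export
autoplot.condition_summary <- function(object, ...) {
  g <- glance(object)
  p <- ggplot(g, aes(condition, fraction)) +
    geom_col(fill = "grey70", width = 0.6) +
    geom_errorbar(aes(ymin = ci_low, ymax = ci_high), width = 0.15) +
    labs(y = "fraction of spots with intensity drop", x = NULL) +
    theme_minimal()
  if (!is.null(object$replicates)) {
    p <- p + geom_point(data = mutate(object$replicates,
                                      condition = object$condition),
                        aes(condition, fraction))
  }
  p
}

#' @describeIn analyze_ssa Mean corrected kinetic traces with an SD
#'   ribbon, one colour per condition.
#' @param object An `ssa_result`.
#' @param ... Unused.
#' @export
autoplot.ssa_result <- function(object, ...) {
  ggplot(object$traces,
         aes(time_s, mean, colour = condition, fill = condition)) +
    geom_ribbon(aes(ymin = mean - sd, ymax = mean + sd),
                alpha = 0.2, colour = NA) +
    geom_line() +
    labs(x = "time (s)", y = "background-corrected fluorescence (a.u.)") +
    theme_minimal()
}
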