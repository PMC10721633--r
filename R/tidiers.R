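#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a condition summary
#'
#' One row per replicate (or a single overall row when no replicate
#' structure was supplied).
#'
#' @param x A `condition_summary` from [summarize_condition()].
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.condition_summary <- function(x, ...) {
  if (is.null(x$replicates)) {
    tibble(condition = x$condition, replicate = NA_integer_,
           n_drops = x$n_drops, n_total = x$n_total, fraction = x$fraction)
  } else {
    mutate(x$replicates, condition = x$condition, .before = 1)
  }
}

#' @rdname tidy.condition_summary
#' @export
glance.condition_summary <- function(x, ...) {
  tibble(
    condition = x$condition, n_drops = x$n_drops, n_total = x$n_total,
    n_excluded = x$n_excluded, fraction = x$fraction,
    ci_low = x$ci_low, ci_high = x$ci_high,
    replicate_mean = x$replicate_mean, replicate_sd = x$replicate_sd
  )
}

#' Tidy a plate-assay result
#'
#' `tidy()` returns per-replicate initial rates; `glance()` returns the
#' per-condition rate summary in wide one-row-per-condition form.
#'
#' @param x An `ssa_result` from [analyze_ssa()].
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.ssa_result <- function(x, ...) x$rates

#' @rdname tidy.ssa_result
#' @export
glance.ssa_result <- function(x, ...) {
  mutate(x$rate_summary, rate_window = x$rate_window)
}
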