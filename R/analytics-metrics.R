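#' Per-session suppression metrics
#'
#' Summaries computable from any archived session log: mean tic frequency
#' (tics/minute), longest tic-free interval, the number of tic-free windows
#' of `window_s` seconds, reward count, the personal-record tic-free duration
#' and the inter-tic intervals. Tic-free windows are counted as disjoint
#' windows, left-aligned from session start and restarting after each tic —
#' i.e. each maximal tic-free segment of length `g` contributes
#' `floor(g / window_s)` windows.
#'
#' @param record a closed `session_record`.
#' @param window_s tic-free window length in seconds (default 10).
#' @return A `session_metrics` list with fields `duration_s`, `tic_count`,
#'   `mean_tic_frequency`, `longest_tic_free_s`, `n_tic_free_windows`,
#'   `reward_count`, `personal_record_s`, `window_s` and `iti_list`.
#' @export
#' @examples
#' rec <- simulate_session("DRO", tic_params = tic_process_params(
#'   baseline_rate = 6, duration_s = 120, seed = 7))
#' compute_metrics(rec)
compute_metrics <- function(record, window_s = 10) {
  stopifnot(inherits(record, "session_record"))
  if (record$open) stop("metrics require a closed session", call. = FALSE)
  duration <- session_duration(record)
  if (duration <= 0) stop("zero-duration session", call. = FALSE)
  if (!is.numeric(window_s) || window_s <= 0) {
    stop("window_s must be positive", call. = FALSE)
  }
  tics <- sort(tic_times(record))
  gaps <- diff(c(0, tics, duration))
  structure(
    list(duration_s = duration,
         tic_count = length(tics),
         mean_tic_frequency = 60 * length(tics) / duration,
         longest_tic_free_s = max(gaps),
         n_tic_free_windows = sum(floor(gaps / window_s)),
         reward_count = sum(record$events$kind == "reward"),
         personal_record_s = max(gaps),
         window_s = window_s,
         iti_list = diff(tics)),
    class = "session_metrics")
}

#' Flat key=value rendering of session metrics
#'
#' @param metrics a `session_metrics` object.
#' @return A character vector of `key=value` lines (ITIs joined by commas).
#' @export
format_metrics <- function(metrics) {
  stopifnot(inherits(metrics, "session_metrics"))
  scalars <- metrics[setdiff(names(metrics), "iti_list")]
  c(paste0(names(scalars), "=", vapply(scalars, format_num, "")),
    paste0("iti_list=", paste(vapply(metrics$iti_list, format_num, ""),
                              collapse = ",")))
}

#' @export
print.session_metrics <- function(x, ...) {
  cat("<session_metrics>\n")
  cat(sprintf("  duration          %.1f s\n", x$duration_s))
  cat(sprintf("  tics              %d (%.2f /min)\n", x$tic_count,
              x$mean_tic_frequency))
  cat(sprintf("  longest tic-free  %.1f s (personal record %.1f s)\n",
              x$longest_tic_free_s, x$personal_record_s))
  cat(sprintf("  %g-s tic-free windows  %d\n", x$window_s, x$n_tic_free_windows))
  cat(sprintf("  rewards           %d\n", x$reward_count))
  invisible(x)
}
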