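fano_factors_at <- function(times, duration, window_sizes) {
  vapply(window_sizes, function(T) {
    nwin <- floor(duration / T)
    if (nwin < 2) return(NA_real_)
    idx <- floor(times / T) + 1
    counts <- tabulate(idx[idx <= nwin], nbins = nwin)
    m <- mean(counts)
    if (m <= 0) return(NA_real_)
    stats::var(counts) / m
  }, numeric(1))
}

fano_slope <- function(times, duration, window_sizes) {
  f <- fano_factors_at(times, duration, window_sizes)
  ok <- is.finite(f) & f > 0
  if (sum(ok) < 4) return(NA_real_)
  unname(coef(stats::lm(log(f[ok]) ~ log(window_sizes[ok])))[2])
}

#' Fano-factor scaling analysis of a tic stream
#'
#' The Fano factor \eqn{F(T)} is the variance-to-mean ratio of event counts
#' in non-overlapping windows of length \eqn{T}. For a homogeneous Poisson
#' process \eqn{F(T) \approx 1} at every \eqn{T}; for fractal
#' (long-range-dependent or heavy-tailed) point processes \eqn{F(T)} grows as
#' a power of \eqn{T}, so the slope of \eqn{\log F} on \eqn{\log T} is a
#' fractal signature. The slope's uncertainty is assessed by an ITI bootstrap
#' (resampling inter-event intervals with replacement), and an optional
#' surrogate test shuffles the ITIs — destroying their serial ordering while
#' keeping their distribution — to ask whether the scaling exceeds what the
#' ITI histogram alone produces.
#'
#' @param x tic event times in seconds (sorted or not), or a
#'   `session_record`.
#' @param duration_s observation length in seconds; defaults to the last
#'   event time (rounded up) for numeric input.
#' @param window_sizes increasing window lengths in seconds; at least 4 are
#'   required for a slope, and all must be shorter than half the duration.
#'   Default: powers of 2 from 1 up to `duration_s / 8`.
#' @param n_surrogates ITI-shuffle surrogates for the scaling p-value
#'   (0 disables).
#' @param n_boot bootstrap replicates for the slope CI.
#' @param min_events minimum event count (default 30); below it an
#'   `insufficient`-flagged result is returned rather than numbers.
#' @param conf_level CI level for the bootstrap slope interval.
#' @param ... passed between methods.
#' @return A `fano_result`: `window_sizes_s`, `fano_factors`, `loglog_slope`,
#'   `slope_ci`, `surrogate_p`, `n_events` (or `insufficient = TRUE`).
#' @export
fano_curve <- function(x, ...) UseMethod("fano_curve")

#' @rdname fano_curve
#' @export
fano_curve.session_record <- function(x, ...) {
  fano_curve(tic_times(x), duration_s = session_duration(x), ...)
}

#' @rdname fano_curve
#' @export
fano_curve.numeric <- function(x, duration_s = NULL, window_sizes = NULL,
                               n_surrogates = 999, n_boot = 199,
                               min_events = 30, conf_level = 0.95, ...) {
  times <- sort(x)
  if (length(times) < min_events) {
    return(structure(list(insufficient = TRUE, n_events = length(times),
                          message = sprintf(
                            "insufficient events: %d < %d required",
                            length(times), min_events)),
                     class = "fano_result"))
  }
  duration_s <- duration_s %||% ceiling(times[length(times)])
  if (is.null(window_sizes)) {
    window_sizes <- 2^(0:floor(log2(duration_s / 8)))
  }
  window_sizes <- sort(unique(window_sizes))
  if (length(window_sizes) < 4) {
    stop("need at least 4 window sizes for a scaling slope", call. = FALSE)
  }
  if (max(window_sizes) >= duration_s / 2) {
    stop("window sizes must be shorter than half the session", call. = FALSE)
  }

  f <- fano_factors_at(times, duration_s, window_sizes)
  slope <- fano_slope(times, duration_s, window_sizes)
  itis <- diff(c(0, times))

  boot_slopes <- rep(NA_real_, n_boot)
  if (n_boot > 0) {
    for (b in seq_len(n_boot)) {
      tt <- cumsum(sample(itis, replace = TRUE))
      boot_slopes[b] <- fano_slope(tt, tt[length(tt)], window_sizes)
    }
  }
  alpha <- (1 - conf_level) / 2
  ci <- if (any(is.finite(boot_slopes))) {
    unname(stats::quantile(boot_slopes, c(alpha, 1 - alpha), na.rm = TRUE))
  } else c(NA_real_, NA_real_)

  surrogate_p <- NA_real_
  if (n_surrogates > 0 && is.finite(slope)) {
    surr <- vapply(seq_len(n_surrogates), function(i) {
      tt <- cumsum(sample(itis))
      fano_slope(tt, duration_s, window_sizes)
    }, numeric(1))
    surrogate_p <- (1 + sum(surr >= slope, na.rm = TRUE)) / (n_surrogates + 1)
  }

  structure(
    list(insufficient = FALSE,
         window_sizes_s = window_sizes, fano_factors = f,
         loglog_slope = slope, slope_ci = ci, conf_level = conf_level,
         surrogate_p = surrogate_p, n_surrogates = n_surrogates,
         n_events = length(times), duration_s = duration_s),
    class = "fano_result")
}

#' @export
print.fano_result <- function(x, ...) {
  if (isTRUE(x$insufficient)) {
    cat("<fano_result> ", x$message, "\n", sep = "")
    return(invisible(x))
  }
  cat(sprintf("<fano_result> %d events over %.0f s\n", x$n_events, x$duration_s))
  cat("  F(T): ", paste(sprintf("%g s: %.3f", x$window_sizes_s, x$fano_factors),
                        collapse = ", "), "\n", sep = "")
  cat(sprintf("  log-log slope %.3f [%.3f, %.3f] (%d%% bootstrap CI)",
              x$loglog_slope, x$slope_ci[1], x$slope_ci[2],
              round(100 * x$conf_level)))
  if (is.finite(x$surrogate_p)) cat(sprintf(", surrogate p = %.3g", x$surrogate_p))
  cat("\n")
  invisible(x)
}
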