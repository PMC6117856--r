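#' Generative model parameters for synthetic tic streams
#'
#' Describes the stochastic process producing tic times for one simulated
#' session. `poisson` is a homogeneous Poisson process at `baseline_rate`;
#' `suppressed_poisson` multiplies the hazard by `suppression_factor`
#' (modeling reinforced suppression while contingent reward is active);
#' `pareto_renewal` draws i.i.d. Pareto inter-tic intervals with shape
#' `pareto_alpha`, scaled so the mean rate equals `baseline_rate` — a fractal
#' positive control with heavy-tailed ITIs.
#'
#' @param baseline_rate tics per minute, > 0.
#' @param suppression_factor multiplicative hazard reduction in (0, 1]
#'   (1 = no suppression).
#' @param process_kind one of `"poisson"`, `"suppressed_poisson"`,
#'   `"pareto_renewal"`.
#' @param pareto_alpha Pareto shape (> 1 so the mean exists; default 1.5).
#' @param duration_s stream length in seconds.
#' @param seed integer seed fully determining the output, or `NULL` to use
#'   the current RNG stream.
#' @return A `tic_process_params` object.
#' @export
tic_process_params <- function(baseline_rate, suppression_factor = 1,
                               process_kind = c("poisson", "suppressed_poisson",
                                                "pareto_renewal"),
                               pareto_alpha = 1.5, duration_s = 600,
                               seed = NULL) {
  process_kind <- match.arg(process_kind)
  stopifnot(is.numeric(baseline_rate), baseline_rate > 0,
            is.numeric(suppression_factor),
            suppression_factor > 0, suppression_factor <= 1,
            is.numeric(pareto_alpha), pareto_alpha > 1,
            is.numeric(duration_s), duration_s > 0)
  structure(
    list(baseline_rate = baseline_rate,
         suppression_factor = suppression_factor,
         process_kind = process_kind,
         pareto_alpha = pareto_alpha,
         duration_s = duration_s,
         seed = seed),
    class = "tic_process_params")
}

draw_itis <- function(params, n) {
  rate_s <- params$baseline_rate / 60
  switch(params$process_kind,
    poisson = stats::rexp(n, rate_s),
    suppressed_poisson = stats::rexp(n, rate_s * params$suppression_factor),
    pareto_renewal = {
      mean_iti <- 1 / rate_s
      xm <- mean_iti * (params$pareto_alpha - 1) / params$pareto_alpha
      xm * stats::runif(n)^(-1 / params$pareto_alpha)
    })
}

#' Simulate a synthetic tic stream
#'
#' @param params a [tic_process_params()].
#' @return Strictly increasing tic times in seconds, all within
#'   `(0, duration_s)`.
#' @export
#' @examples
#' length(simulate_tic_stream(tic_process_params(6, duration_s = 600, seed = 1)))
simulate_tic_stream <- function(params) {
  stopifnot(inherits(params, "tic_process_params"))
  gen <- function() {
    times <- numeric(0)
    last <- 0
    repeat {
      expected <- params$duration_s * params$baseline_rate / 60
      itis <- draw_itis(params, max(32, ceiling(expected)))
      chunk <- last + cumsum(itis)
      times <- c(times, chunk)
      last <- chunk[length(chunk)]
      if (last >= params$duration_s) break
    }
    times[times < params$duration_s]
  }
  if (is.null(params$seed)) gen() else withr::with_seed(params$seed, gen())
}

#' Simulate a complete training session
#'
#' Generates a closed `session_record`: tic events from the generative model,
#' rewards from the DRO engine (or the NCR scheduler), heartbeats every
#' `heartbeat_every_s` seconds so the trainer-inactivity timeout never fires
#' spuriously, and a proper trainer-ended session end. In the NCR condition a
#' `suppressed_poisson` stream falls back to the baseline hazard (rewards are
#' noncontingent, so the model assumes no reinforced suppression), and reward
#' delays are drawn level-by-level from [next_reward_delay()].
#'
#' @param condition `"DRO"` or `"NCR"`.
#' @param tic_params a [tic_process_params()].
#' @param dro_config a [dro_config()].
#' @param ncr_config an [ncr_config()] (used when `condition = "NCR"`).
#' @param duration_s session length; defaults to `tic_params$duration_s`.
#' @param heartbeat_every_s trainer heartbeat period (default 30 s).
#' @param seed seed governing the whole session; defaults to
#'   `tic_params$seed`.
#' @param user_id,trainer_id,start_ms session identity fields.
#' @param masked mask the condition in user-facing exports.
#' @return A closed `session_record`.
#' @export
simulate_session <- function(condition = c("DRO", "NCR"), tic_params,
                             dro_config = ticdro::dro_config(),
                             ncr_config = ticdro::ncr_config(),
                             duration_s = tic_params$duration_s,
                             heartbeat_every_s = 30,
                             seed = tic_params$seed,
                             user_id = "u0001", trainer_id = "t0001",
                             start_ms = 0, masked = FALSE) {
  condition <- match.arg(condition)
  stopifnot(inherits(tic_params, "tic_process_params"))
  stream_params <- tic_params
  stream_params$seed <- NULL
  stream_params$duration_s <- duration_s
  if (condition == "NCR") stream_params$suppression_factor <- 1

  build <- function() {
    tics <- simulate_tic_stream(stream_params)
    links <- data.frame(trainer_id = trainer_id, user_id = user_id,
                        stringsAsFactors = FALSE)
    rec <- start_session(user_id, trainer_id, condition, links = links,
                         start_ms = start_ms, dro_config = dro_config,
                         ncr_config = if (condition == "NCR") ncr_config,
                         masked = masked)
    i_tic <- 1
    next_hb <- heartbeat_every_s
    next_ncr <- if (condition == "NCR") {
      next_reward_delay(ncr_config, rec$state$level)
    } else Inf
    repeat {
      t_tic <- if (i_tic <= length(tics)) tics[i_tic] else Inf
      t <- min(t_tic, next_hb, next_ncr)
      if (t >= duration_s) break
      ms <- start_ms + round(t * 1000)
      if (t == t_tic) {
        rec <- trainer_event(rec, "tic", ms)
        i_tic <- i_tic + 1
      } else if (t == next_ncr) {
        rec <- ncr_reward(rec, ms)
        next_ncr <- t + next_reward_delay(ncr_config, rec$state$level)
      } else {
        rec <- trainer_event(rec, "heartbeat", ms)
        next_hb <- next_hb + heartbeat_every_s
      }
    }
    trainer_event(rec, "end", start_ms + round(duration_s * 1000))
  }
  if (is.null(seed)) build() else withr::with_seed(seed, build())
}

#' Estimate the suppression factor from simulated (or real) sessions
#'
#' Pools tic counts and exposure time within each condition and estimates the
#' suppression factor as the ratio of pooled tic rates,
#' \eqn{\hat{s} = r_{contingent} / r_{noncontingent}}, with a percentile
#' bootstrap CI obtained by resampling whole sessions within each condition.
#'
#' @param records list of closed `session_record`s.
#' @param labels optional character vector of condition labels (defaults to
#'   each record's own `condition` field); the contingent group is `"DRO"`,
#'   the control group `"NCR"`.
#' @param n_boot bootstrap replicates (default 999).
#' @param conf_level CI level.
#' @return A `suppression_estimate`: `estimate`, `ci`, per-group rates and
#'   session counts.
#' @export
recover_suppression <- function(records, labels = NULL, n_boot = 999,
                                conf_level = 0.95) {
  stopifnot(is.list(records), length(records) > 0)
  labels <- labels %||% vapply(records, function(r) r$condition, "")
  stopifnot(length(labels) == length(records))
  tics <- vapply(records, function(r) length(tic_times(r)), numeric(1))
  mins <- vapply(records, function(r) session_duration(r) / 60, numeric(1))
  dro <- which(labels == "DRO"); ncr <- which(labels == "NCR")
  if (length(dro) < 2 || length(ncr) < 2) {
    stop("need at least 2 records in each condition (DRO and NCR)", call. = FALSE)
  }
  pooled_rate <- function(idx) sum(tics[idx]) / sum(mins[idx])
  est <- pooled_rate(dro) / pooled_rate(ncr)
  boot <- vapply(seq_len(n_boot), function(b) {
    d <- sample(dro, replace = TRUE)
    n <- sample(ncr, replace = TRUE)
    pooled_rate(d) / pooled_rate(n)
  }, numeric(1))
  alpha <- (1 - conf_level) / 2
  structure(
    list(estimate = est,
         ci = unname(stats::quantile(boot, c(alpha, 1 - alpha), na.rm = TRUE)),
         conf_level = conf_level,
         rate_dro = pooled_rate(dro), rate_ncr = pooled_rate(ncr),
         n_dro = length(dro), n_ncr = length(ncr), n_boot = n_boot),
    class = "suppression_estimate")
}

#' @export
print.suppression_estimate <- function(x, ...) {
  cat(sprintf("<suppression_estimate> s-hat = %.3f [%.3f, %.3f] (%d%% bootstrap CI)\n",
              x$estimate, x$ci[1], x$ci[2], round(100 * x$conf_level)))
  cat(sprintf("  DRO: %.2f tics/min over %d sessions; NCR: %.2f tics/min over %d sessions\n",
              x$rate_dro, x$n_dro, x$rate_ncr, x$n_ncr))
  invisible(x)
}
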