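#' Noncontingent-reward (NCR) control configuration
#'
#' In the masked control condition rewards arrive on a time-based schedule
#' that ignores tics entirely. The admin sets the initial mean inter-reward
#' interval (typically from the participant's previously recorded tic
#' frequency); thereafter the mean interval scales linearly with the achieved
#' level so the reward cadence tracks the DRO schedule's one-reward-per-level-
#' seconds cadence.
#'
#' @param initial_mean_interval mean seconds between rewards at level 1
#'   (admin-set, > 0).
#' @param points_per_reward_multiplier points per reward, per level squared
#'   (default 5, i.e. half the DRO rate cap — a mid-streak DRO payout).
#' @param rng_seed optional integer; if supplied, [next_reward_delay()] draws
#'   are taken from an internal seeded stream so a schedule replays exactly.
#' @return An `ncr_config` object.
#' @export
ncr_config <- function(initial_mean_interval = 10,
                       points_per_reward_multiplier = 5,
                       rng_seed = NULL) {
  if (!is.numeric(initial_mean_interval) || length(initial_mean_interval) != 1 ||
      !is.finite(initial_mean_interval) || initial_mean_interval <= 0) {
    stop("initial_mean_interval must be a positive number of seconds", call. = FALSE)
  }
  if (!is_count(points_per_reward_multiplier)) {
    stop("points_per_reward_multiplier must be a strictly positive integer", call. = FALSE)
  }
  if (!is.null(rng_seed) && !is_count(rng_seed, positive = FALSE)) {
    stop("rng_seed must be a single integer", call. = FALSE)
  }
  structure(
    list(initial_mean_interval = as.numeric(initial_mean_interval),
         points_per_reward_multiplier = as.numeric(points_per_reward_multiplier),
         rng_seed = rng_seed),
    class = "ncr_config")
}

#' Draw the delay until the next noncontingent reward
#'
#' Delays are exponential with mean `initial_mean_interval * level`:
#' memoryless, so the schedule carries no information about tic timing, with
#' the mean interval growing linearly in level to mirror the DRO interval
#' length of `level` seconds.
#'
#' @param config an [ncr_config()].
#' @param level current level (positive integer).
#' @return A strictly positive delay in seconds, drawn from the current RNG
#'   stream.
#' @export
#' @examples
#' set.seed(1)
#' mean(replicate(1000, next_reward_delay(ncr_config(1), level = 3)))  # ~ 3
next_reward_delay <- function(config, level) {
  stopifnot(inherits(config, "ncr_config"))
  if (!is_count(level)) stop("level must be a positive integer", call. = FALSE)
  d <- stats::rexp(1, rate = 1 / (config$initial_mean_interval * level))
  # rexp can in principle return 0; the dialect requires strictly positive gaps
  if (d <= 0) d <- .Machine$double.eps
  d
}

#' Apply one noncontingent reward to the engine state
#'
#' Adds `points_per_reward_multiplier * level^2` points regardless of tic
#' history (noncontingency is the defining property), then resolves level-ups
#' and coin awards exactly as the DRO engine does. The emitted reward event
#' has the same schema as a DRO reward event, so the user-facing stream does
#' not reveal the condition.
#'
#' @param state a `dro_state`.
#' @param ncr an [ncr_config()].
#' @param config a [dro_config()] (level-up thresholds are shared).
#' @return `list(state, events)` as for [advance_second()].
#' @export
apply_ncr_reward <- function(state, ncr, config = dro_config()) {
  stopifnot(inherits(ncr, "ncr_config"))
  delta <- ncr$points_per_reward_multiplier * state$level^2
  state$points <- state$points + delta
  events <- list(list(kind = "reward",
                      payload = c(points = format_num(delta),
                                  rate = format_num(state$rate))))
  lu <- process_level_ups(state, config)
  list(state = lu$state, events = c(events, lu$events))
}
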