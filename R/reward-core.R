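#' DRO engine configuration
#'
#' Parameters of the differential-reinforcement (DRO) reward algebra. With the
#' defaults, a user at level \eqn{L} is rewarded after every \eqn{L} tic-free
#' seconds: points increase by the current rate, the rate then increases by
#' \eqn{L^2} up to a cap of \eqn{10 L^2}, and a level-up fires whenever points
#' exceed \eqn{1000 L^2}, paying \eqn{L^2} coins.
#'
#' @param levelup_multiplier points-per-level-squared threshold for a level-up
#'   (default 1000; a user levels up when points strictly exceed
#'   `levelup_multiplier * level^2`).
#' @param cap_multiplier rate cap in rate-units per level squared (default 10).
#' @param interval_seconds_per_level seconds of tic-free time per level making
#'   up one reward interval (default 1, i.e. interval length = level seconds).
#' @param medal_cost_coins coins per medal at the redemption store (default 1).
#' @return A `dro_config` object (a validated list).
#' @export
#' @examples
#' cfg <- dro_config()
#' new_dro_state(cfg)
dro_config <- function(levelup_multiplier = 1000,
                       cap_multiplier = 10,
                       interval_seconds_per_level = 1,
                       medal_cost_coins = 1) {
  for (nm in c("levelup_multiplier", "cap_multiplier",
               "interval_seconds_per_level", "medal_cost_coins")) {
    v <- get(nm)
    if (!is_count(v)) stop(nm, " must be a strictly positive integer", call. = FALSE)
  }
  structure(
    list(levelup_multiplier = as.numeric(levelup_multiplier),
         cap_multiplier = as.numeric(cap_multiplier),
         interval_seconds_per_level = as.numeric(interval_seconds_per_level),
         medal_cost_coins = as.numeric(medal_cost_coins)),
    class = "dro_config")
}

#' Fresh DRO engine state
#'
#' The live engine state at the start of a session: level 1, zero points, and
#' a reward point rate of zero (the rate always starts at zero and resets to
#' zero after each tic).
#'
#' @param config a [dro_config()].
#' @return A `dro_state` with fields `level`, `points`, `rate`, `coins`,
#'   `medals`, `streak_seconds` (tic-free seconds since the last tic or
#'   session start) and `session_clock` (whole seconds since session start).
#' @export
new_dro_state <- function(config = dro_config()) {
  stopifnot(inherits(config, "dro_config"))
  structure(
    list(level = 1, points = 0, rate = 0, coins = 0, medals = 0,
         streak_seconds = 0, session_clock = 0),
    class = "dro_state")
}

rate_cap <- function(state, config) config$cap_multiplier * state$level^2

interval_length <- function(state, config) {
  state$level * config$interval_seconds_per_level
}

#' Advance the DRO engine by one tic-free second
#'
#' Called once per whole second during which no tic occurred. When the
#' tic-free streak completes an interval of `level * interval_seconds_per_level`
#' seconds, the point total increases by the current rate FIRST, and the rate
#' THEN increases by `level^2`, capped at `cap_multiplier * level^2`. Any
#' pending level-ups are resolved immediately via [process_level_ups()].
#'
#' @param state a `dro_state`.
#' @param config a [dro_config()].
#' @return `list(state = <updated state>, events = <list>)`; each event is a
#'   list with `kind` (`"reward"`, `"level_up"` or `"coin_award"`) and a named
#'   character `payload`.
#' @export
#' @examples
#' s <- new_dro_state()
#' for (i in 1:5) s <- advance_second(s)$state
#' s$points  # 0 + 1 + 2 + 3 + 4 = 10
#' s$rate    # 5
advance_second <- function(state, config = dro_config()) {
  state$session_clock <- state$session_clock + 1
  state$streak_seconds <- state$streak_seconds + 1
  events <- list()
  if (state$streak_seconds %% interval_length(state, config) == 0) {
    delta <- state$rate
    state$points <- state$points + delta
    state$rate <- min(state$rate + state$level^2, rate_cap(state, config))
    events[[1]] <- list(kind = "reward",
                        payload = c(points = format_num(delta),
                                    rate = format_num(state$rate)))
    lu <- process_level_ups(state, config)
    state <- lu$state
    events <- c(events, lu$events)
  }
  list(state = state, events = events)
}

#' Record a tic: reset the reward rate and the tic-free streak
#'
#' The rate resets to zero after each tic; points, level, coins and medals are
#' untouched.
#'
#' @param state a `dro_state`.
#' @return `list(state = <updated state>, event = <tic event>)`.
#' @export
register_tic <- function(state) {
  state$rate <- 0
  state$streak_seconds <- 0
  list(state = state, event = list(kind = "tic", payload = character(0)))
}

#' Resolve pending level-ups
#'
#' While points strictly exceed `levelup_multiplier * level^2` (with `level`
#' taken before the increment), the level increases by one and the user is
#' awarded coins equal to the square of the previous level. Points are never
#' reset; the rate persists, re-capped at the new (higher) cap.
#'
#' @inheritParams advance_second
#' @return `list(state, events)` with one `level_up` + `coin_award` event pair
#'   per level gained.
#' @export
process_level_ups <- function(state, config = dro_config()) {
  events <- list()
  while (state$points > config$levelup_multiplier * state$level^2) {
    prev <- state$level
    state$level <- prev + 1
    state$coins <- state$coins + prev^2
    events <- c(events,
                list(list(kind = "level_up",
                          payload = c(level = format_num(state$level))),
                     list(kind = "coin_award",
                          payload = c(coins = format_num(prev^2)))))
  }
  # cap can only grow with level, but keep the invariant explicit
  state$rate <- min(state$rate, rate_cap(state, config))
  list(state = state, events = events)
}

#' Trade coins for medals
#'
#' @param state a `dro_state`.
#' @param n_medals strictly positive integer number of medals to buy.
#' @param config a [dro_config()] (supplies `medal_cost_coins`).
#' @return The updated `dro_state`. Errors (leaving the state untouched) if
#'   `n_medals` is not a positive integer or the coin balance is insufficient.
#' @export
redeem_coins <- function(state, n_medals, config = dro_config()) {
  if (!is_count(n_medals)) {
    stop("n_medals must be a strictly positive integer", call. = FALSE)
  }
  cost <- n_medals * config$medal_cost_coins
  if (state$coins < cost) {
    stop(sprintf("insufficient coins: have %s, need %s",
                 format_num(state$coins), format_num(cost)), call. = FALSE)
  }
  state$coins <- state$coins - cost
  state$medals <- state$medals + n_medals
  state
}

#' Serialize / parse engine state as a flat key=value block
#'
#' Used in session-log headers and CLI output.
#'
#' @param state a `dro_state`.
#' @return `serialize_dro_state()`: a single string such as
#'   `"level=1;points=0;rate=0;..."`. `parse_dro_state()`: the `dro_state`.
#' @export
serialize_dro_state <- function(state) {
  stopifnot(inherits(state, "dro_state"))
  encode_kv(unclass(state))
}

#' @rdname serialize_dro_state
#' @param text a string produced by `serialize_dro_state()`.
#' @export
parse_dro_state <- function(text) {
  kv <- decode_payload(text)
  need <- c("level", "points", "rate", "coins", "medals",
            "streak_seconds", "session_clock")
  if (!all(need %in% names(kv))) {
    stop("state block missing fields: ",
         paste(setdiff(need, names(kv)), collapse = ", "), call. = FALSE)
  }
  structure(as.list(stats::setNames(as.numeric(kv[need]), need)),
            class = "dro_state")
}

#' @export
print.dro_state <- function(x, ...) {
  cat("<dro_state> ", serialize_dro_state(x), "\n", sep = "")
  invisible(x)
}

#' @export
print.dro_config <- function(x, ...) {
  cat("<dro_config> ", encode_kv(unclass(x)), "\n", sep = "")
  invisible(x)
}
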