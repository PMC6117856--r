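EVENT_KINDS <- c("session_start", "tic", "reward", "level_up", "coin_award",
                 "heartbeat", "session_end")

empty_events <- function() {
  data.frame(timestamp_ms = numeric(0), kind = character(0),
             actor = character(0), payload = character(0),
             stringsAsFactors = FALSE)
}

append_events <- function(record, timestamp_ms, kind, actor, payload) {
  n <- length(timestamp_ms)
  if (n == 0) return(record)
  record$events <- rbind(
    record$events,
    data.frame(timestamp_ms = as.numeric(timestamp_ms),
               kind = as.character(kind),
               actor = rep_len(as.character(actor), n),
               payload = as.character(payload),
               stringsAsFactors = FALSE))
  record$last_ms <- record$events$timestamp_ms[nrow(record$events)]
  record
}

#' Open a training session
#'
#' Creates an open session record for a mutually linked user/trainer pair.
#' Trainers specify the users they train and users specify their trainers; an
#' unlinked pair is refused. The engine state is fresh ([new_dro_state()])
#' unless a restored state is supplied (coins, medals and points persist
#' across an account's sessions).
#'
#' @param user_id,trainer_id opaque account IDs (never names).
#' @param condition `"DRO"` (contingent reinforcement) or `"NCR"`
#'   (noncontingent control).
#' @param links the trainer/user link table: a data frame with columns
#'   `trainer_id` and `user_id`.
#' @param start_ms session start, epoch milliseconds UTC.
#' @param dro_config a [dro_config()].
#' @param ncr_config an [ncr_config()]; required when `condition = "NCR"`.
#' @param state optional restored `dro_state`.
#' @param masked if `TRUE`, user-facing exports suppress the condition field.
#' @param session_id opaque session identifier; defaults to
#'   `<user_id>-<start_ms>`.
#' @return An open `session_record`.
#' @export
start_session <- function(user_id, trainer_id, condition = c("DRO", "NCR"),
                          links, start_ms,
                          dro_config = ticdro::dro_config(),
                          ncr_config = NULL,
                          state = NULL, masked = FALSE, session_id = NULL) {
  condition <- match.arg(condition)
  stopifnot(is.character(user_id), is.character(trainer_id),
            is.numeric(start_ms), start_ms >= 0)
  if (!is.data.frame(links) ||
      !all(c("trainer_id", "user_id") %in% names(links))) {
    stop("links must be a data frame with columns trainer_id and user_id",
         call. = FALSE)
  }
  if (!any(links$trainer_id == trainer_id & links$user_id == user_id)) {
    stop(sprintf("trainer '%s' and user '%s' are not linked", trainer_id, user_id),
         call. = FALSE)
  }
  if (condition == "NCR" && is.null(ncr_config)) {
    stop("an ncr_config is required for the NCR condition", call. = FALSE)
  }
  record <- structure(
    list(session_id = session_id %||% sprintf("%s-%s", user_id, format_ms(start_ms)),
         user_id = user_id, trainer_id = trainer_id,
         condition = condition, masked = isTRUE(masked),
         start_ms = as.numeric(start_ms), end_ms = NA_real_,
         end_reason = NA_character_, open = TRUE,
         dro_config = dro_config, ncr_config = ncr_config,
         state = state %||% new_dro_state(dro_config),
         final_state = NULL,
         last_ms = as.numeric(start_ms),
         last_trainer_ms = as.numeric(start_ms),
         events = empty_events(),
         warnings = character(0)),
    class = "session_record")
  append_events(record, start_ms, "session_start", "system", "")
}

# Advance the engine clock to the whole second containing `to_ms`. In DRO the
# engine accrues rewards second by second; in NCR the clock and streak advance
# but no contingent rewards are paid. A tic attributed to quantized second q
# (i.e. the interval [q, q+1) after start) never completes tic-free, so
# advancing to q before applying the tic realizes the tic-first rule.
advance_record <- function(record, to_ms) {
  target <- floor((to_ms - record$start_ms) / 1000)
  state <- record$state
  if (state$session_clock >= target) {
    record$state <- state
    return(record)
  }
  ts <- numeric(0); kind <- character(0); payload <- character(0)
  if (record$condition == "DRO") {
    cfg <- record$dro_config
    while (state$session_clock < target) {
      step <- advance_second(state, cfg)
      state <- step$state
      for (ev in step$events) {
        ts <- c(ts, record$start_ms + state$session_clock * 1000)
        kind <- c(kind, ev$kind)
        payload <- c(payload, encode_payload(ev$payload))
      }
    }
  } else {
    state$streak_seconds <- state$streak_seconds + (target - state$session_clock)
    state$session_clock <- target
  }
  record$state <- state
  append_events(record, ts, kind, "system", payload)
}

check_open <- function(record, timestamp_ms) {
  stopifnot(inherits(record, "session_record"))
  if (!record$open) stop("session is closed", call. = FALSE)
  if (timestamp_ms < record$last_ms) {
    stop(sprintf("out-of-order timestamp: %s < %s",
                 format_ms(timestamp_ms), format_ms(record$last_ms)),
         call. = FALSE)
  }
}

close_record <- function(record, end_ms, reason, actor) {
  record <- advance_record(record, end_ms)
  record <- append_events(record, end_ms, "session_end", actor,
                          encode_payload(c(reason = reason)))
  record$open <- FALSE
  record$end_ms <- as.numeric(end_ms)
  record$end_reason <- reason
  record$final_state <- record$state
  record
}

#' Record a trainer action
#'
#' The trainer's page has two buttons ("Tic Detected", "End Session") plus an
#' "I'm Here" heartbeat. A tic resets the engine rate and the tic-free streak
#' and restarts the inactivity timer (as the heartbeat does); `end` closes the
#' session with reason `trainer_end`. Point accrual for the tic-free seconds
#' elapsed since the previous event is applied before the action.
#'
#' @param record an open `session_record`.
#' @param kind `"tic"`, `"heartbeat"` or `"end"`.
#' @param timestamp_ms event time, epoch milliseconds UTC; must be
#'   non-decreasing within a session.
#' @return The updated `session_record`.
#' @export
trainer_event <- function(record, kind = c("tic", "heartbeat", "end"),
                          timestamp_ms) {
  kind <- match.arg(kind)
  check_open(record, timestamp_ms)
  record <- advance_record(record, timestamp_ms)
  if (kind == "tic") {
    rt <- register_tic(record$state)
    st <- rt$state
    # the whole second containing the tic is consumed: the tic-free streak
    # restarts at the next second boundary (tic-first, conservative)
    st$session_clock <- max(st$session_clock,
                            floor((timestamp_ms - record$start_ms) / 1000) + 1)
    record$state <- st
    record <- append_events(record, timestamp_ms, "tic", "trainer", "")
    record$last_trainer_ms <- as.numeric(timestamp_ms)
  } else if (kind == "heartbeat") {
    record <- append_events(record, timestamp_ms, "heartbeat", "trainer", "")
    record$last_trainer_ms <- as.numeric(timestamp_ms)
  } else {
    record <- close_record(record, timestamp_ms, "trainer_end", "trainer")
  }
  record
}

#' Close a session whose trainer has gone silent
#'
#' Trainers see a continuously progressing 1-minute timer; if neither the
#' heartbeat nor the tic button restarts it before it elapses, the session
#' ends. The boundary is inclusive: exactly `timeout_seconds` of silence ends
#' the session, and the session-end timestamp is the instant the timer
#' elapsed (last trainer activity + `timeout_seconds`), not `now_ms`.
#'
#' @param record an open `session_record`.
#' @param now_ms current wall clock, epoch milliseconds UTC.
#' @param timeout_seconds inactivity allowance (default 60 s).
#' @return The possibly-closed `session_record` (reason `timeout`).
#' @export
check_timeout <- function(record, now_ms, timeout_seconds = 60) {
  stopifnot(inherits(record, "session_record"))
  if (!record$open) return(record)
  if (now_ms - record$last_trainer_ms >= timeout_seconds * 1000) {
    end_ms <- record$last_trainer_ms + timeout_seconds * 1000
    record <- close_record(record, end_ms, "timeout", "system")
  }
  record
}

#' Deliver a scheduled noncontingent reward
#'
#' Session-level wrapper around [apply_ncr_reward()]: advances the engine
#' clock to the reward instant, applies the reward (plus any resulting
#' level-ups) and logs the events with `actor = "system"`.
#'
#' @param record an open NCR `session_record`.
#' @param timestamp_ms reward delivery time, epoch milliseconds UTC.
#' @return The updated `session_record`.
#' @export
ncr_reward <- function(record, timestamp_ms) {
  check_open(record, timestamp_ms)
  if (record$condition != "NCR") {
    stop("ncr_reward applies only to NCR sessions", call. = FALSE)
  }
  record <- advance_record(record, timestamp_ms)
  res <- apply_ncr_reward(record$state, record$ncr_config, record$dro_config)
  record$state <- res$state
  for (ev in res$events) {
    record <- append_events(record, timestamp_ms, ev$kind, "system",
                            encode_payload(ev$payload))
  }
  record
}

#' Anonymize a birthdate
#'
#' Account registration asks only for birth month and year; the system stores
#' a single date drawn uniformly from the 91 calendar days within 45 days of
#' the 15th of the supplied month (offset in -45..45, endpoints included).
#' The true day of birth is never collected or stored.
#'
#' @param birth_month integer 1-12.
#' @param birth_year integer year, bounded by `year_range`.
#' @param year_range allowed year interval (plausibility guard).
#' @return A [Date].
#' @export
#' @examples
#' set.seed(42)
#' anonymize_birthdate(3, 2007)
anonymize_birthdate <- function(birth_month, birth_year,
                                year_range = c(1900, 2100)) {
  if (!is_count(birth_month) || birth_month < 1 || birth_month > 12) {
    stop("birth_month must be an integer in 1..12", call. = FALSE)
  }
  if (!is_count(birth_year, positive = FALSE) ||
      birth_year < year_range[1] || birth_year > year_range[2]) {
    stop("birth_year outside the plausible range", call. = FALSE)
  }
  center <- as.Date(sprintf("%04d-%02d-15", birth_year, birth_month))
  center + (sample.int(91, 1) - 46)
}

#' Replay a closed session through a fresh engine
#'
#' Feeds the record's input events (tics, heartbeats, NCR reward deliveries
#' and the session end) back through the state machine. Engine outputs
#' (rewards, level-ups, coins in DRO; level-ups in NCR) are regenerated, so a
#' correct engine reproduces the original event table and final state
#' exactly — the determinism contract for archived logs.
#'
#' @param record a closed `session_record`.
#' @return A freshly rebuilt `session_record`.
#' @export
replay_session <- function(record) {
  stopifnot(inherits(record, "session_record"))
  if (record$open) stop("cannot replay an open session", call. = FALSE)
  links <- data.frame(trainer_id = record$trainer_id, user_id = record$user_id,
                      stringsAsFactors = FALSE)
  out <- start_session(record$user_id, record$trainer_id, record$condition,
                       links = links, start_ms = record$start_ms,
                       dro_config = record$dro_config,
                       ncr_config = record$ncr_config,
                       masked = record$masked, session_id = record$session_id)
  ev <- record$events
  for (i in seq_len(nrow(ev))) {
    k <- ev$kind[i]; t <- ev$timestamp_ms[i]
    if (k == "tic") {
      out <- trainer_event(out, "tic", t)
    } else if (k == "heartbeat") {
      out <- trainer_event(out, "heartbeat", t)
    } else if (k == "reward" && record$condition == "NCR") {
      out <- ncr_reward(out, t)
    } else if (k == "session_end") {
      reason <- decode_payload(ev$payload[i])[["reason"]]
      if (identical(reason, "timeout")) {
        out <- check_timeout(out, t, timeout_seconds = (t - out$last_trainer_ms) / 1000)
      } else {
        out <- trainer_event(out, "end", t)
      }
    }
  }
  out
}

#' Event-time accessors
#'
#' Times are reported in seconds relative to session start.
#'
#' @param record a `session_record`.
#' @return For `tic_times()`/`reward_times()`, a numeric vector of seconds;
#'   for `session_duration()`, the session length in seconds.
#' @export
tic_times <- function(record) {
  ev <- record$events
  (ev$timestamp_ms[ev$kind == "tic"] - record$start_ms) / 1000
}

#' @rdname tic_times
#' @export
reward_times <- function(record) {
  ev <- record$events
  (ev$timestamp_ms[ev$kind == "reward"] - record$start_ms) / 1000
}

#' @rdname tic_times
#' @export
session_duration <- function(record) {
  end <- if (!is.na(record$end_ms)) record$end_ms else record$last_ms
  (end - record$start_ms) / 1000
}

#' @export
print.session_record <- function(x, ...) {
  cat(sprintf("<session_record> %s  condition=%s%s  %s\n",
              x$session_id, x$condition, if (x$masked) " (masked)" else "",
              if (x$open) "open" else sprintf("closed (%s)", x$end_reason)))
  cat(sprintf("  events: %d (%d tics, %d rewards), duration %.1f s\n",
              nrow(x$events), sum(x$events$kind == "tic"),
              sum(x$events$kind == "reward"), session_duration(x)))
  cat("  state:  ", serialize_dro_state(x$state), "\n", sep = "")
  invisible(x)
}
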