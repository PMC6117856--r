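# Independent reference implementations used as oracles. These are written
# against the engine's *semantics*, not its code: the DRO oracle advances an
# explicit per-second trace with inline arithmetic, the metrics oracle walks
# the timeline with a window pointer instead of the gap formula.

# tic_at: whole seconds (1-based) during which a tic occurs; that second never
# completes tic-free. Returns the totals after total_s seconds.
oracle_dro_run <- function(tic_at, total_s, cfg = dro_config()) {
  level <- 1; points <- 0; rate <- 0; coins <- 0; streak <- 0
  for (sec in seq_len(total_s)) {
    if (sec %in% tic_at) {
      rate <- 0
      streak <- 0
    } else {
      streak <- streak + 1
      if (streak %% (level * cfg$interval_seconds_per_level) == 0) {
        points <- points + rate
        rate <- rate + level^2
        if (rate > cfg$cap_multiplier * level^2) rate <- cfg$cap_multiplier * level^2
        while (points > cfg$levelup_multiplier * level^2) {
          coins <- coins + level^2
          level <- level + 1
        }
        if (rate > cfg$cap_multiplier * level^2) rate <- cfg$cap_multiplier * level^2
      }
    }
  }
  list(level = level, points = points, rate = rate, coins = coins)
}

# Drive the same scenario through the full session machinery. A tic during
# oracle second `sec` (interval [sec-1, sec)) is fed at (sec-1)*1000 + 500 ms.
engine_dro_run <- function(tic_at, total_s, cfg = dro_config()) {
  links <- data.frame(trainer_id = "t", user_id = "u", stringsAsFactors = FALSE)
  rec <- start_session("u", "t", "DRO", links = links, start_ms = 0,
                       dro_config = cfg)
  hb_grid <- function(to_s) if (to_s < 30) numeric(0) else seq(30, to_s, by = 30)
  for (sec in sort(unique(tic_at))) {
    hb <- hb_grid(sec - 1)                   # keep the 60-s timer alive
    hb <- hb[hb > (rec$last_ms / 1000)]
    for (h in hb) rec <- trainer_event(rec, "heartbeat", h * 1000)
    rec <- trainer_event(rec, "tic", (sec - 1) * 1000 + 500)
  }
  hb <- hb_grid(total_s - 1)
  hb <- hb[hb * 1000 > rec$last_ms]
  for (h in hb) rec <- trainer_event(rec, "heartbeat", h * 1000)
  trainer_event(rec, "end", total_s * 1000)
}

# Timeline-walking metrics oracle: a window pointer advances in window_s
# jumps, restarting at every tic; the longest tic-free stretch is tracked by
# scanning consecutive event boundaries.
oracle_metrics <- function(tic_s, duration_s, window_s = 10) {
  tic_s <- sort(tic_s)
  pos <- 0; n_windows <- 0
  boundaries <- c(tic_s, duration_s)
  for (b in boundaries) {
    while (pos + window_s <= b) {
      n_windows <- n_windows + 1
      pos <- pos + window_s
    }
    pos <- b
  }
  longest <- 0; prev <- 0
  for (b in boundaries) {
    if (b - prev > longest) longest <- b - prev
    prev <- b
  }
  list(longest_tic_free_s = longest,
       n_tic_free_windows = n_windows,
       mean_tic_frequency = 60 * length(tic_s) / duration_s)
}
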