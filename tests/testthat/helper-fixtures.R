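# direct record builder: analytics only need event times, not engine history
make_record <- function(tic_s, reward_s = numeric(0), duration_s,
                        condition = "NCR", start_ms = 0) {
  ev <- rbind(
    data.frame(t = tic_s, kind = rep("tic", length(tic_s)),
               actor = rep("trainer", length(tic_s))),
    data.frame(t = reward_s, kind = rep("reward", length(reward_s)),
               actor = rep("system", length(reward_s))))
  ev <- ev[order(ev$t), , drop = FALSE]
  events <- data.frame(
    timestamp_ms = c(start_ms, start_ms + ev$t * 1000,
                     start_ms + duration_s * 1000),
    kind = c("session_start", ev$kind, "session_end"),
    actor = c("system", ev$actor, "trainer"),
    payload = c("", rep("", nrow(ev)), "reason=trainer_end"),
    stringsAsFactors = FALSE)
  structure(
    list(session_id = "fixture", user_id = "u", trainer_id = "t",
         condition = condition, masked = FALSE,
         start_ms = start_ms, end_ms = start_ms + duration_s * 1000,
         end_reason = "trainer_end", open = FALSE,
         dro_config = dro_config(), ncr_config = NULL,
         state = new_dro_state(), final_state = new_dro_state(),
         last_ms = start_ms + duration_s * 1000,
         last_trainer_ms = NA_real_, events = events,
         warnings = character(0)),
    class = "session_record")
}
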