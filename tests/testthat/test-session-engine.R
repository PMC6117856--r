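links1 <- data.frame(trainer_id = "t1", user_id = "u1",
                     stringsAsFactors = FALSE)

test_that("sessions open only for mutually linked pairs", {
  rec <- start_session("u1", "t1", "DRO", links = links1, start_ms = 1000)
  expect_true(rec$open)
  expect_equal(nrow(rec$events), 1)
  expect_equal(rec$events$kind, "session_start")
  expect_error(start_session("u2", "t1", "DRO", links = links1, start_ms = 0),
               "not linked")
  expect_error(start_session("u1", "t1", "NCR", links = links1, start_ms = 0),
               "ncr_config")
})

test_that("a restored state carries coins and points into the new session", {
  st <- new_dro_state()
  st$coins <- 4; st$points <- 500
  rec <- start_session("u1", "t1", "DRO", links = links1, start_ms = 0,
                       state = st)
  expect_equal(rec$state$coins, 4)
  expect_equal(rec$state$points, 500)
})

test_that("trainer tic resets the engine rate and restarts the timer", {
  rec <- start_session("u1", "t1", "DRO", links = links1, start_ms = 0)
  rec <- trainer_event(rec, "tic", 8500)      # 8 tic-free seconds first
  expect_equal(rec$state$rate, 0)
  expect_equal(rec$state$streak_seconds, 0)
  expect_gt(rec$state$points, 0)              # accrual before the tic stands
  expect_equal(rec$last_trainer_ms, 8500)
  expect_equal(sum(rec$events$kind == "tic"), 1)
})

test_that("end closes with reason trainer_end; events after close are rejected", {
  rec <- start_session("u1", "t1", "DRO", links = links1, start_ms = 0)
  rec <- trainer_event(rec, "end", 30000)
  expect_false(rec$open)
  expect_equal(rec$end_reason, "trainer_end")
  last <- rec$events[nrow(rec$events), ]
  expect_equal(last$kind, "session_end")
  expect_match(last$payload, "reason=trainer_end")
  expect_error(trainer_event(rec, "tic", 31000), "closed")
})

test_that("out-of-order timestamps are rejected", {
  rec <- start_session("u1", "t1", "DRO", links = links1, start_ms = 10000)
  rec <- trainer_event(rec, "heartbeat", 20000)
  expect_error(trainer_event(rec, "tic", 15000), "out-of-order")
})

test_that("one minute of trainer silence ends the session, boundary inclusive", {
  rec <- start_session("u1", "t1", "DRO", links = links1, start_ms = 0)
  expect_true(check_timeout(rec, 59000)$open)
  closed <- check_timeout(rec, 61000)
  expect_false(closed$open)
  expect_equal(closed$end_reason, "timeout")
  expect_equal(closed$end_ms, 60000)          # closes when the timer elapsed
  # exactly 60 s is enough
  expect_false(check_timeout(rec, 60000)$open)
  # a heartbeat restarts the timer
  rec2 <- trainer_event(rec, "heartbeat", 59000)
  expect_true(check_timeout(rec2, 100000)$open)
  expect_false(check_timeout(rec2, 119000)$open)
})

test_that("any finite event stream plus clock advance terminates the session", {
  withr::with_seed(505, {
    for (rep in 1:20) {
      rec <- start_session("u1", "t1", "DRO", links = links1, start_ms = 0)
      t <- 0
      for (i in seq_len(sample(0:15, 1))) {
        t <- t + runif(1, 0, 55) * 1000
        rec <- trainer_event(rec, sample(c("tic", "heartbeat"), 1), t)
      }
      rec <- check_timeout(rec, t + 61000)
      expect_false(rec$open)
    }
  })
})

test_that("anonymized birthdates are uniform whole-day jitter within +/- 45 days", {
  withr::with_seed(606, {
    d <- replicate(500, anonymize_birthdate(3, 2007))
    d <- as.Date(d, origin = "1970-01-01")
  })
  expect_true(all(d >= as.Date("2007-01-29")))
  expect_true(all(d <= as.Date("2007-04-29")))
  offsets <- as.numeric(d - as.Date("2007-03-15"))
  expect_true(all(abs(offsets) <= 45))
  expect_error(anonymize_birthdate(13, 2007), "1..12")
  expect_error(anonymize_birthdate(0, 2007), "1..12")
  expect_error(anonymize_birthdate(5, 1492), "plausible")
})

test_that("replaying a record reproduces events and final state exactly", {
  dro <- simulate_session("DRO", tic_params = tic_process_params(
    8, 0.6, "suppressed_poisson", duration_s = 240, seed = 21))
  ncr <- simulate_session("NCR", tic_params = tic_process_params(
    8, duration_s = 240, seed = 22), ncr_config = ncr_config(8))
  for (rec in list(dro, ncr)) {
    rebuilt <- replay_session(rec)
    expect_identical(rebuilt$events, rec$events)
    expect_identical(serialize_dro_state(rebuilt$final_state),
                     serialize_dro_state(rec$final_state))
  }
  # timeout-ended fixture replays too
  rec <- start_session("u1", "t1", "DRO", links = links1, start_ms = 0)
  rec <- trainer_event(rec, "tic", 12000)
  rec <- check_timeout(rec, 90000)
  rebuilt <- replay_session(rec)
  expect_identical(rebuilt$events, rec$events)
  expect_equal(rebuilt$end_reason, "timeout")
})

test_that("no personally identifying field appears in a serialized record", {
  rec <- simulate_session("DRO", tic_params = tic_process_params(
    6, duration_s = 60, seed = 31), user_id = "u0042", trainer_id = "t0007")
  path <- write_log(rec, withr::local_tempdir())
  lines <- readLines(path)
  hdr_keys <- sub("\t.*", "", sub("^# ", "", lines[grepl("^# ", lines)]))
  expect_setequal(hdr_keys, c("format_version", "session_id", "user_id",
                              "trainer_id", "condition", "masked", "start_ms",
                              "dro_config", "final_state"))
  expect_false(any(grepl("name|birth", lines, ignore.case = TRUE)))
})
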