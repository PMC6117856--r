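test_that("config validation rejects non-positive or fractional parameters", {
  expect_error(dro_config(levelup_multiplier = 0), "strictly positive")
  expect_error(dro_config(cap_multiplier = -1), "strictly positive")
  expect_error(dro_config(interval_seconds_per_level = 1.5), "strictly positive")
  expect_error(dro_config(medal_cost_coins = 0), "strictly positive")
})

test_that("a fresh state starts at level 1 with zero points and zero rate", {
  for (cfg in list(dro_config(), dro_config(levelup_multiplier = 10),
                   dro_config(cap_multiplier = 3))) {
    s <- new_dro_state(cfg)
    expect_equal(s[c("level", "points", "rate", "coins", "medals",
                     "streak_seconds", "session_clock")],
                 list(level = 1, points = 0, rate = 0, coins = 0, medals = 0,
                      streak_seconds = 0, session_clock = 0))
  }
})

test_that("points accrue before the rate increments (points-then-rate order)", {
  cfg <- dro_config()
  s <- advance_second(new_dro_state(cfg), cfg)
  expect_equal(s$state$points, 0)   # paid at the old rate (zero)...
  expect_equal(s$state$rate, 1)     # ...then the rate grows by level^2
  expect_equal(s$events[[1]]$kind, "reward")
})

test_that("five tic-free seconds at level 1 accrue 10 points at rate 5", {
  cfg <- dro_config()
  s <- new_dro_state(cfg)
  pts <- numeric(5)
  for (i in 1:5) {
    s <- advance_second(s, cfg)$state
    pts[i] <- s$points
  }
  expect_equal(pts, cumsum(c(0, 1, 2, 3, 4)))  # 10 points accrued
  expect_equal(s$points, 10)
  expect_equal(s$rate, 5)
})

test_that("the rate saturates at cap_multiplier * level^2 and stays pinned", {
  cfg <- dro_config()
  s <- new_dro_state(cfg)
  rates <- numeric(1000)
  for (i in 1:1000) {
    s <- advance_second(s, cfg)$state
    rates[i] <- s$rate
  }
  expect_equal(rates[1:10], 1:10)
  expect_true(all(rates[10:1000] <= cfg$cap_multiplier * 10^2))  # level <= 10 here
  # at level 1 specifically the cap is 10
  s1 <- new_dro_state(cfg)
  for (i in 1:15) s1 <- advance_second(s1, cfg)$state
  expect_equal(s1$rate, 10)
})

test_that("interval length equals level seconds: no mid-interval payout", {
  cfg <- dro_config()
  s <- new_dro_state(cfg)
  s$level <- 2
  one <- advance_second(s, cfg)
  expect_length(one$events, 0)               # 1 s into a 2-s interval
  two <- advance_second(one$state, cfg)
  expect_equal(two$state$points, 0)          # paid at rate 0
  expect_equal(two$state$rate, 4)            # increment is level^2 = 4
  expect_equal(two$events[[1]]$kind, "reward")
})

test_that("a tic resets rate and streak but never the totals", {
  s <- new_dro_state()
  s$points <- 958; s$rate <- 7; s$coins <- 2; s$streak_seconds <- 13
  r <- register_tic(s)
  expect_equal(r$state$rate, 0)
  expect_equal(r$state$streak_seconds, 0)
  expect_equal(r$state$points, 958)
  expect_equal(r$state$level, 1)
  expect_equal(r$state$coins, 2)
  expect_equal(r$event$kind, "tic")
  # idempotent on rate
  expect_equal(register_tic(r$state)$state$rate, 0)
})

test_that("level-ups fire on strict exceedance and pay previous-level^2 coins", {
  cfg <- dro_config()
  s <- new_dro_state(cfg)

  s$points <- 1000
  expect_equal(process_level_ups(s, cfg)$state$level, 1)  # boundary: not >

  s$points <- 1001
  r <- process_level_ups(s, cfg)
  expect_equal(r$state$level, 2)
  expect_equal(r$state$coins, 1)
  expect_equal(r$state$points, 1001)  # points are never reset
  expect_equal(vapply(r$events, `[[`, "", "kind"), c("level_up", "coin_award"))

  s2 <- new_dro_state(cfg); s2$level <- 2; s2$points <- 4001
  r2 <- process_level_ups(s2, cfg)
  expect_equal(r2$state$level, 3)
  expect_equal(r2$state$coins, 4)

  # chained level-ups resolve in one call, one event pair per level
  s3 <- new_dro_state(cfg); s3$points <- 4001
  r3 <- process_level_ups(s3, cfg)
  expect_equal(r3$state$level, 3)             # 4001 > 1000 and > 4000
  expect_equal(r3$state$coins, 1 + 4)
  expect_length(r3$events, 4)
})

test_that("coin redemption enforces the store preconditions", {
  cfg <- dro_config()  # medal_cost_coins = 1
  s <- new_dro_state(cfg); s$coins <- 3
  r <- redeem_coins(s, 2, cfg)
  expect_equal(r$coins, 1)
  expect_equal(r$medals, 2)
  s0 <- new_dro_state(cfg)
  expect_error(redeem_coins(s0, 1, cfg), "insufficient coins")
  s5 <- new_dro_state(cfg); s5$coins <- 5
  expect_error(redeem_coins(s5, 0, cfg), "positive integer")
  # configurable cost
  cfg3 <- dro_config(medal_cost_coins = 3)
  s6 <- new_dro_state(cfg3); s6$coins <- 7
  expect_equal(redeem_coins(s6, 2, cfg3)$coins, 1)
})

test_that("closed form: n uninterrupted intervals at level L pay L^2 n(n-1)/2", {
  cfg <- dro_config()
  for (L in 1:3) {
    for (n in c(1, 4, 10)) {  # below the cap while n <= cap_multiplier
      s <- new_dro_state(cfg); s$level <- L
      for (i in seq_len(L * n)) s <- advance_second(s, cfg)$state
      expect_equal(s$points, L^2 * n * (n - 1) / 2,
                   info = sprintf("L=%d n=%d", L, n))
    }
  }
})

test_that("rate never exceeds its cap over randomized event sequences", {
  cfg <- dro_config(levelup_multiplier = 50)  # frequent level-ups
  withr::with_seed(101, {
    for (rep in 1:25) {
      s <- new_dro_state(cfg)
      for (step in 1:200) {
        if (runif(1) < 0.1) {
          s <- register_tic(s)$state
        } else {
          s <- advance_second(s, cfg)$state
        }
        expect_lte(s$rate, cfg$cap_multiplier * s$level^2)
        expect_lte(s$points, cfg$levelup_multiplier * s$level^2)
      }
    }
  })
})

test_that("engine state serializes to and from a flat key=value block", {
  s <- new_dro_state()
  s$points <- 1234; s$level <- 3; s$rate <- 45; s$coins <- 5
  txt <- serialize_dro_state(s)
  expect_match(txt, "^level=3;points=1234;")
  expect_equal(parse_dro_state(txt), s)
  expect_error(parse_dro_state("level=1;points=2"), "missing fields")
})
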