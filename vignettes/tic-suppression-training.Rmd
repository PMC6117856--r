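---
title: "Reward-enhanced tic suppression training: the ticdro engine, control schedule, and session analytics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reward-enhanced tic suppression training}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ticdro)
```

## The problem

Exposure and response prevention (ERP) for tic disorders asks a patient to
suppress tics for progressively longer periods. Suppression is hard and
frustrating, especially early on, but immediate small rewards for brief
tic-free intervals make it attainable even for children who can initially
suppress for only a few seconds. `ticdro` is a headless, fully testable
implementation of the computational core of such a training platform: a
human trainer (parent or clinician) presses a button whenever the user tics,
and the software turns tic-free time into a video-game-like stream of
points, levels, coins and medals. Because every rule is a small piece of
integer arithmetic on a discrete clock, the entire system can be specified,
simulated and verified without human subjects — which is the point of this
package.

## The DRO reward algebra

The schedule is differential reinforcement of other behavior (DRO): reward
is contingent on the *absence* of the target behavior for a criterion
interval. The engine state is `(level L, points P, rate r, coins, medals)`
plus a tic-free streak clock. The rules, all on a 1-second engine clock:

* The rate starts at zero each session and **resets to zero after every
  tic**.
* Each time the user completes `L` tic-free seconds (the interval length
  equals the level), `P` increases by the current rate **first**, and the
  rate **then** increases by `L^2`, capped at `10 L^2`.
* When `P` strictly exceeds `1000 L^2` the user levels up and receives
  coins equal to the square of the previous level. Points are never reset.
* Coins buy medals at a store (default one coin per medal).

So at level 1 a fresh streak pays 0, 1, 2, ... points on successive seconds
until the rate pins at 10: short suppression is rewarded immediately, longer
suppression at an accelerating rate, and higher levels stretch the criterion
interval while raising the stakes — the DRO criterion fades as competence
grows. A useful closed form (and an engine invariant under test): `n`
uninterrupted intervals at fixed level `L`, starting from rate 0 and below
the cap, pay exactly `L^2 n(n-1)/2` points.

```{r}
s <- new_dro_state()
for (i in 1:5) s <- advance_second(s)$state
s$points   # 0+1+2+3+4: ten points accrued
s$rate     # now accruing 5 points per second
```

### Decisions where the rules are silent

The prose rules leave a few edges open; the package fixes them as follows
and treats them as its own design choices, not as claims about the original
deployment:

* **"Exceed" is strict**: `P = 1000 L^2` exactly does not level up.
* **Level-ups never reset points or rate**; the rate is re-capped at the new
  (higher) cap, which never binds. The growing threshold `1000 L^2` keeps
  progression monotone.
* **Cap after increment**: the increment rule applies, then `min` with the
  cap.
* **Tic-first second attribution**: the engine clock is discrete; a tic is
  attributed to the whole second containing it, that second never counts as
  tic-free, and the streak restarts at the next second boundary. An interval
  boundary landing in the same second as a tic therefore pays nothing. This
  is the conservative reading of "refrains from ticcing for a number of
  seconds", and it is pinned by an independent per-second oracle over 1,000
  random sessions in the test suite.
* **Streaks are measured from the most recent tic** (or session start), not
  on a session-absolute grid.

## The masked NCR control schedule

For controlled comparisons, a session can run under noncontingent reward
(NCR): rewards arrive on a time-based schedule that ignores behavior.
Inter-reward delays are exponential — memoryless, so the schedule carries no
predictive structure a user could learn — with mean
`initial_mean_interval × level`. The admin sets `initial_mean_interval`
(typically from the participant's previously recorded tic frequency, to make
the arms harder to distinguish); the linear level scaling mirrors the DRO
cadence of one reward per `level` seconds, so for a fully suppressing user
at level `L` both arms deliver `60/L` rewards per minute (a tested
invariant, with `initial_mean_interval = 1`). Each NCR reward pays
`5 × level^2` points — half the DRO cap, approximating a mid-streak DRO
payout — and feeds the identical level-up/coin algebra, so the user-facing
event schema is indistinguishable across arms; only a session metadata field
records the condition, and it can be masked.

One wording tension is worth flagging: the source platform describes NCR
reward frequency as *increasing* with level, while the DRO cadence (one
reward per `level` seconds) *slows* with level. The intended matching
function is not stated anywhere; this package matches the DRO cadence, which
is the only choice that satisfies "approximately matching reward frequency"
between arms, and exposes the multiplier and interval as plain
configuration.

## Sessions, timeouts, anonymity

A session is a state machine over timestamped events (epoch milliseconds
UTC; the engine quantizes to whole seconds). Trainers and users must be
mutually linked before a session opens. The trainer stream has three
actions: `tic`, `heartbeat` ("I'm Here"), and `end`. A continuously running
1-minute timer is restarted by tics and heartbeats; if it elapses the
session closes with reason `timeout` — the boundary is inclusive (exactly
60 s of silence closes), and the session-end timestamp is the instant the
timer elapsed, not the observation time. Closing a session freezes the
final engine state into the record.

Anonymity follows the platform's registration rule: only birth month and
year are requested, and the stored birthdate is drawn uniformly from the 91
calendar days within ±45 days of the 15th of that month (endpoints
included — "randomly chosen" is unqualified, so uniform whole-day jitter is
the natural reading). No name or true day-of-birth ever enters a record,
and a schema-walk test asserts serialized logs contain only the expected
fields.

Archived logs use a small versioned TSV dialect (`# key<TAB>value` headers,
then `timestamp_ms/kind/actor/payload` lines), written byte-deterministically
and read back with strict validation (monotone timestamps, terminal
`session_end`, line numbers in every error; unknown event kinds are
preserved and flagged for forward compatibility; gzip accepted
transparently). Replaying a log's input events through a fresh engine
reproduces the archived event table and final state exactly — the
determinism contract that makes archived logs a sufficient record.

## Session analytics

`compute_metrics()` reports the per-session measures an admin can derive
from any log: mean tic frequency (tics/min), longest tic-free interval
(also the "personal record"), reward count, inter-tic intervals, and the
number of 10-second tic-free windows. Windows are counted as *disjoint*
windows, left-aligned from session start and restarting after each tic —
each maximal tic-free segment of length `g` contributes `floor(g/10)` — the
reading that maximizes the count; a sliding-window reading would differ and
is deliberately not used.

`fano_curve()` operationalizes the "do inter-tic intervals fit a fractal
pattern" question via Fano-factor scaling: `F(T)` is the variance-to-mean
ratio of tic counts in windows of length `T`; a Poisson stream has
`F(T) ≈ 1` everywhere, while fractal or heavy-tailed streams show `F(T)`
growing as a power of `T`. The log–log slope is the scaling estimate, with
an ITI-bootstrap percentile CI and an optional ITI-shuffle surrogate test
(shuffling destroys serial order but keeps the ITI histogram, isolating
temporal correlation from tail weight). Fewer than 30 events returns an
explicit insufficient-events result, never a number. Window sizes must stay
below half the session; the Monte-Carlo tests fix windows at 1–16 s over
3600-s streams so every `F(T)` estimate averages ≥ 200 windows (standard
error ≤ 0.1 under Poisson theory) — chosen a priori, not tuned.

`reward_timing_test()` asks whether tics cluster or thin at particular lags
after rewards: conditional tic rates per post-reward lag bin, against a
null of circular time-shifts of the tic stream (ITI structure preserved,
tic–reward alignment destroyed). Because the per-bin statistic is a small
discrete count, a plain permutation p-value is super-uniform under ties and
its type-I error can fall well below nominal; the package therefore uses
the standard uniform tie-breaking randomization, making the p-value exactly
Uniform(0,1) under the null (the draw comes from the caller's seeded RNG
stream, so results are reproducible). Two-sided p-values are reported raw
and Benjamini–Hochberg-adjusted across bins. Null calibration over 1,000
simulated independent streams is part of the acceptance suite. One
geometric caveat, encoded in the tests: if rewards sit on a *regular* grid,
circular shifts preserve phase alignment and the test is powerless by
construction; detecting phase-locking requires irregular reward times
(which both the DRO and NCR schedules produce in practice).

## The simulator: a stated world, not a dial

`simulate_tic_stream()` generates three tic processes: homogeneous Poisson
at a baseline rate (in tics/minute); suppressed Poisson, where contingent
reinforcement multiplies the hazard by a constant `s ∈ (0, 1]` — the
simplest mechanism consistent with reward-enhanced suppression and with the
evidence against a rebound effect, so none is modeled; and a Pareto renewal
process (shape α = 1.5 by default, scaled to the target mean rate) as a
heavy-tailed positive control for the fractal analytics.
`simulate_session()` drives a full session through the real state machine —
tics from the stream, heartbeats every 30 s (exercising but never tripping
the 60-s timeout; a timeout fixture is built separately in the tests), DRO
rewards from the engine or NCR rewards from the scheduler — and the result
round-trips through the log layer byte-identically under a fixed seed.

Default scenario values, used throughout the tests: baseline 6 tics/min
(a moderate clinical presentation), suppression factor 0.5 (a strong but
realistic within-session reward effect), 600–1800-s sessions, NCR
`initial_mean_interval` 10 s. `recover_suppression()` closes the loop:
pooled tic-rate ratio between conditions with a session-level bootstrap CI;
the acceptance suite checks `|ŝ − 0.5| < 0.05` on one experiment of
10 + 10 × 1800-s sessions at 6 tics/min.

What the simulator does **not** emulate — so a green test does not establish
it: physiological tic generation, premonitory urges, habituation or learning
across sessions, trainer misclassification (missed or spurious tic
presses), and reactivity of tic rate to being observed. Green means the
*software* is correct under the stated stochastic world, not that the
therapy works.

## Numerical and format choices

* Engine quantities are exact small integers on a discrete clock; no
  floating-point accumulates in the reward algebra.
* Serialized numerics use `%.17g`, so configs and states round-trip exactly
  through the text dialect.
* Timeout boundary inclusive; level-up boundary strict; tie between tic and
  interval boundary resolves tic-first (all above).
* Bootstrap CIs are percentile intervals; surrogate p-values use the
  `(1 + #{s ≥ obs})/(n + 1)` convention; permutation p-values use uniform
  tie-breaking as described.
* All stochastic entry points accept a seed (or inherit the caller's RNG
  state); the CLI threads `--seed` through everything and echoes the
  resolved configuration to stderr.

## Limitations

The web transport, authentication, account files and admin console of the
original platform are out of scope by design; the package models the
session as a timestamped event stream and everything downstream of it. The
log dialect is this package's own (the original's concrete log syntax is
not public), versioned in the header, with no compatibility claim.
Clinical severity scales and inter-session self-report measures are not
modeled. The suppression estimator assumes a constant hazard ratio within
sessions; time-varying suppression would bias it toward the time-averaged
ratio.
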