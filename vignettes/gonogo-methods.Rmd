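---
title: "Simulating automated auditory go/no-go training: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating automated auditory go/no-go training: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gonogo)
```

## The task and the system being modeled

`gonogo` is a software re-implementation of an automated home-cage operant
conditioning system for auditory detection: groups of mice live with a
waterspout, a speaker and a lick sensor, and obtain all of their water by
performing a go/no-go tone-detection task around the clock. The package
models the *controller* and the *analysis*, not the hardware: a
discrete-event trial engine executes the training contingencies, a
parametric virtual mouse supplies lick streams, an event-log format records
everything, and a statistics suite computes the standard behavioral
measures. No audio is synthesized; tone frequency and level are metadata
labels on the protocol.

Training proceeds in three phases:

1. **Waterspout habituation** — 20 s trials in which water flows freely for
   the first 10 s; inter-trial intervals (ITIs) uniform on 30–300 s; trials
   run in alternating 90 min on / 90 min off blocks.
2. **Behavioral shaping** — detection trials: 0.5 s pre-stimulus silence, a
   1 s tone, and a 3 s response window opening at tone onset. A lick in the
   window triggers 2 s of water. ITIs are uniform on 5–9 s and a trial may
   only start after 5 s without licks (the *quiet period*). On 10% of
   trials water is delivered free at window close, to keep naive animals
   engaged. As performance develops, the response window is progressively
   *delayed* after tone onset in steps of 0, 0.25, 0.5, 0.75 s; a lick
   before the window opens (the *early window*, which spans the
   pre-stimulus silence, the tone and the delay) aborts the reward and adds
   a 20 s time-out to the next ITI. The free water is removed once the
   delay leaves zero.
3. **Operant task** — the tone shortens to 0.5 s, the window to 2 s, and
   silent *catch trials* are interleaved on 1/3 of trials to measure false
   alarms and hence d′.

Because cages in one room cannot be individually sound-isolated, four cages
take turns on a 60 min active / 180 min inactive rotation, tiling time
exactly; each cage trains 6 h per day. The vivarium light cycle (12 h
light, 12 h dark; epoch t = 0 is lights-on) modulates the virtual mice but
never gates the engine — the animals gate themselves by sleeping.

## Trial classification

Each trial is classified from its lick times by first-lick precedence:

* first lick in the early window `[0, win_open)` → `EARLY` (tone trial) or
  `EARLY_CATCH` (catch trial); a 20 s time-out is added to the next ITI;
* otherwise any lick in the response window `[win_open, win_close)` →
  `HIT` (rewarded) or `FALSE_ALARM`;
* otherwise `MISS` or `CORRECT_REJECTION`.

Licks after the window (e.g. drinking during reward delivery) are recorded
but never change the outcome. Catch trials keep identical window geometry
to tone trials, with a virtual tone onset. These six labels partition the
trials exactly, which the test suite asserts on every simulated session.

Three rules were genuinely open and are resolved as follows:

* **Early licks on catch trials** get their own label (`EARLY_CATCH`) and
  are punished like tone-trial earlies; they are excluded from the
  false-alarm numerator.
* **Quiet-period enforcement** defers the trial onset past each offending
  lick rather than resampling the ITI. A lick exactly `quiet_period`
  seconds before onset is admissible ("at least 5 s" is satisfied).
* **The 0.5 s pre-stimulus silence is retained in the operant phase**; a
  protocol flag can set it to zero.
* **Free-water trials** deliver their 0.5 s of water at window close
  regardless of licking and are still classified normally, so they
  contribute MISSes and HITs to the statistics like any other trial.

## The virtual mouse

The agent is explicitly synthetic: it makes no claim of fitting any real
animal. Its purpose is to generate lick streams with the qualitative
structure of home-cage data so the engine and statistics can be exercised
end to end, with known ground truth for parameter-recovery tests. Four
processes interact (all rates per second, all probabilities per trial):

* **Sleep/wake**: alternating exponential bouts; mean wake bout
  `1/sleep_bout_rate` (1500 s in the light, doubled by
  `dark_activity_gain = 2` in the dark), mean sleep bout
  `sleep_bout_duration = 2400` s. All mice in a cage share one timeline —
  cage-mates nest and sleep together, and with independent sleepers the
  fraction of habituation trials with licking (~52% in the modeled system)
  would be far too high. A sleeping mouse emits nothing and ignores tones.
* **Spontaneous licking**: a Poisson process at `baseline_lick_rate =
  0.002`/s while awake (doubled in the dark), thinned to zero during
  sleep. This is idle spout investigation, not drinking.
* **Tone detection**: an awake mouse responds on a tone trial with
  probability `p_detect * exp(-delay_suppression * delay)`, with one lick
  at the response-window opening plus a log-normal offset
  (`latency_median = 0.35` s, `latency_spread = 0.45` sdlog), truncated
  into the window. The log-normal gives the right-skewed, unimodal
  first-lick latency distributions seen in real data; any positive
  unimodal family would serve. The exponential factor is the cost of the
  enforced wait: longer required delays depress response rates
  (`delay_suppression = 0.5`/s, i.e. a 0.75 s delay retains ~69% of
  responses). Without this term the model cannot reproduce the
  characteristic *negative* dependence of hit rate on required delay,
  because the latency anchor alone moves with the window.
* **Impulsivity**: with per-trial probability `impulsivity` an awake mouse
  licks once, uniformly, inside the early window.

Learning is exponential approach across days,
`x(day) = final + (initial − final)·exp(−day/tau)` with `tau = 3` days.
The defaults put detection at asymptote from day 1
(`p_detect_initial = p_detect_final = 0.07`): in the modeled system the
animals demonstrably detect the tone on the first day of conditioning, and
what they acquire over the following week is *motor restraint* — expressed
here as impulsivity decaying from 0.04 to 0.012 while the latency anchor
tracks the advancing window. Reward (and habituation water) triggers a
drinking bout at `reward_lick_rate = 6` licks/s from the rewarded mouse;
those licks feed back into the quiet-period gating of the next trial.

### Why these defaults

The default cohort is 4 cages × 3 mice, 6 h of daily training. Working at
the cage level (the hardware cannot tell mice apart; the simulator logs
identity anyway), the expected per-type rates are, to first order:

* hit ≈ `P(awake) × [1 − (1 − p_detect·e^{−0.5·0.75})³]` ≈ 0.47 × 0.136 ≈ 6%,
* early ≈ `P(awake) × [1 − (1 − impulsivity − baseline·early_window)³]`
  ≈ 2%,
* false alarm ≈ `P(awake) × [1 − (1 − baseline·2 s)³]` ≈ 0.6%,

which lands the simulated cohort in the published regime of this paradigm:
hit rates of a few percent (ad libitum training means most trials pass
while the animals sleep, and missed trials cost little), false alarms well
under 1%, hits roughly three times as frequent as earlies, d′ near 1, and
median first-lick latencies ~1.5 s at the full 0.75 s delay. These values
were fixed from this arithmetic, not tuned against test outcomes.

## Delay advancement and the phase switch

At the end of each simulated day the engine computes the cage's peak
first-lick latency (the midpoint of the modal 0.1 s histogram bin over all
trials with a lick). If the peak falls inside the current response window,
the required delay advances one schedule step; it never exceeds 0.75 s.
Free-water trials stop as soon as the delay leaves zero, and the day after
a cage completes the schedule it switches to the operant configuration.
With the defaults the schedule completes in about 4 days (each advancement
check can only fire once per day); real cohorts take longer mostly because
early impulsive licking holds the peak outside the window — raising
`impulsivity_initial` reproduces that.

## Statistics

* **Rates** follow the standard signal-detection convention by default
  (`per_type`: hits / tone trials, false alarms / catch trials, earlies /
  all trials). A `per_total` convention (all numerators over total trials)
  is provided because published rate tables are often ambiguous about
  their denominator; the convention is recorded in every summary. The
  printed d′ values in the reference table shipped with the package are
  indeed not derivable from its printed percentages under any single
  obvious convention (`Z(0.041) − Z(0.005) ≈ 0.84`, not 1.1), so the table
  carries d′ as data and no agreement is forced.
* **d′** = `Z(hit) − Z(fa)` with `Z = qnorm`; rates of exactly 0 or 1 are
  replaced by `1/(2n)` and `1 − 1/(2n)` of the relevant denominator (the
  standard correction; the modeled study does not state its rule). The
  test suite certifies `compute_dprime` against an independent bisection
  inverse-CDF oracle to 10⁻⁶ over a 100 × 100 rate grid.
* **First-lick latency**: time of the first lick from trial onset. The
  distribution peak is the midpoint of the modal histogram bin (0.1 s
  default, a flag); ties break to the earliest bin; a single distinct
  latency is its own peak. No-lick sets leave median and peak flagged
  undefined rather than zero.
* **Lick-rate traces**: the probability of at least one lick per time bin,
  averaged across trials (binary indicators, so the trace is
  order-invariant and bounded by [0, 1]).
* **Learning curves**: per-day statistics averaged across cages, with
  Pearson correlations (two-sided t-transform p-values) between any two
  fields. False alarms are `NA` before catch trials are introduced.

## Numerical and format choices

Times are seconds on the session clock at fixed 1 ms resolution — lick
sensors operate at millisecond scale, and fixed-precision formatting makes
the JSONL logs byte-stable: one event per line, fixed field order, `NA`
fields omitted, a schema-version header line first. Every run seeds one
RNG per (cage, day) session through a documented splitting rule
(`split_seed`), with a fixed draw order inside the engine, so identical
seeds give byte-identical logs. `events_to_trials` re-classifies every
trial from its logged licks and refuses logs whose recorded outcomes
disagree — the log is self-checking.

Degenerate inputs are handled explicitly: zero-width ITI ranges are legal
(the ITI is then deterministic); a lick stream that never goes quiet
defers the trial past the session horizon and is reported as a deferral
marker rather than an infinite loop; empty trial tables and zero
denominators flag their statistics as undefined.

## What the simulation does and does not show

Passing tests demonstrate that the *controller logic* and the *statistics*
are correct, and that the closed loop (agent → engine → log → analysis)
reproduces the qualitative acquisition signatures of the paradigm: peak
first-lick latency rising in lockstep with the required delay (r > 0.9 on
default settings) and hit rates higher when the required delay is shorter
(r < 0, with substantial day-to-day variability because daily wake time is
dominated by a handful of long sleep bouts). They do not validate the
agent as a model of mouse behavior: real animals show richer circadian
structure, motivation and satiety dynamics, inter-individual variability
(every simulated mouse shares one parameter set), and social interaction
at the spout, none of which are modeled. Quantities that depend on live
animals — particular d′ values, particular median latencies — are carried
as a reference table, not re-derived.

Problem sizes used by the test suite and the acceptance script — a
10,000-trial operant session for the catch-fraction and log-audit checks,
10,000 trials for parameter recovery, and a 15-day, 4-cage cohort
(~115,000 trials) for the acquisition correlations — match the scale of
one cage-session and one cohort of the modeled system.

## A worked run

```{r, eval = FALSE}
protocol <- protocol_config()
prog <- run_training_program(protocol, n_days = 15, seed = 1)
curve <- learning_curve(prog$trials)
correlate_curve(curve, "delay", "peak_latency")  # r ~ 0.99
correlate_curve(curve, "delay", "hit_rate")      # r < 0
session_summary(subset(prog$trials, day_index == 15))
```

The same pipeline is scriptable from a shell via
`inst/cli/gonogo.R simulate ... | analyze ...`, and
`scripts/acceptance.R` re-runs all of the headline computations from
scratch and writes them as JSON.
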