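# gonogo

Simulation and analysis of automated home-cage auditory go/no-go training.

`gonogo` is for behavioral neuroscientists who run (or are building)
automated operant-conditioning rigs in which group-housed mice earn all of
their water by reporting tone detection with licks, around the clock and
without an experimenter. It provides:

* a **discrete-event trial engine** implementing the full three-phase
  paradigm — waterspout habituation, behavioral shaping with a
  progressively delayed response window (0 → 0.25 → 0.5 → 0.75 s), and the
  operant task with silent catch trials on 1/3 of trials — including
  quiet-period gating (5 s lick-free before each trial), reward (2 s
  water on a hit) and punishment (20 s time-out added to the ITI after an
  early lick) contingencies;
* a **multi-cage scheduler** (60 min active / 180 min inactive rotation of
  four cages, so cages sharing a room never play tones simultaneously);
* a **virtual mouse**: a parametric, explicitly synthetic lick-stream
  generator with spontaneous licking, shared cage-level sleep/wake bouts,
  circadian modulation, tone detection with log-normal latency, impulsive
  early licking, and multi-day learning — the stand-in for live animals
  that makes the whole pipeline testable with known ground truth;
* a **JSONL event-log format** (one timestamped event per line, 1 ms
  resolution, schema-versioned, byte-stable under a fixed seed) with trial
  table extraction and flat-CSV export;
* the **behavioral statistics** of the paradigm: hit / false-alarm /
  early-response rates under two denominator conventions, sensitivity
  d′ = Z(hit rate) − Z(false-alarm rate) with the 1/(2n) correction at
  extreme rates, first-lick latency distributions (median and
  histogram-mode peak), trial-aligned lick-rate traces, and daily learning
  curves with Pearson correlations.

Outcomes follow signal-detection convention with an early window: a first
lick before the response window opens is `EARLY`/`EARLY_CATCH` (punished),
a lick inside the window is `HIT`/`FALSE_ALARM`, no lick is
`MISS`/`CORRECT_REJECTION`.

## Worked example

```r
library(gonogo)

protocol <- protocol_config()                     # the standard paradigm
prog  <- run_training_program(protocol, n_days = 15, seed = 1)
curve <- learning_curve(prog$trials)

correlate_curve(curve, "delay", "peak_latency")[c("r", "p")]
#> $r [1] 0.9962  $p [1] 3.4e-15
correlate_curve(curve, "delay", "hit_rate")[c("r", "p")]
#> $r [1] -0.509  $p [1] 0.053

session_summary(subset(prog$trials, day_index == 15))
#> <session summary> 7943 trials (5273 tone, 2670 catch), convention per_type
#>   hit 0.082 | FA 0.0101 | early 0.025 | d' 0.929
#>   first-lick latency: median 1.525 s, peak 1.55 s
```

Fifteen simulated days of a default 4-cage cohort: the required response
delay advances to its 0.75 s maximum as the daily peak first-lick latency
shifts into the response window, so peak latency and required delay are
almost perfectly correlated (r = 0.996); hit rates are higher on days with
shorter required delays (r = −0.51). The final session sits in the regime
typical of ad libitum group training — hits on ~8% of tone trials (most
trials pass while the cage sleeps), false alarms at 1%, roughly three hits
per early response, d′ ≈ 0.93, and median first-lick latency 1.53 s, well
inside the delayed window.

The package also ships a benchmark per-cage final-session table from a
four-cage group-trained cohort:

```r
summarize_final_sessions(reference_final_sessions())
#> $hit_early_ratio [1] 3.04   $mean_dprime [1] 1.04 ...
```

From a shell:

```sh
Rscript inst/cli/gonogo.R simulate --days 15 --seed 1 --out run/
Rscript inst/cli/gonogo.R analyze --in run/trials.csv --out analysis/
```

`simulate` writes one JSONL event file per cage per day, a `trials.csv`
and a reproducibility manifest; `analyze` writes per-cage/day summaries,
the learning curve and a JSON report.

## Documentation

`vignettes/gonogo-methods.Rmd` describes the behavioral model, every
tunable parameter with units and defaults, the design decisions behind the
classification rules, and what the synthetic agent does and does not show
about real animals.
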