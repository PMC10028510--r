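# adaptloop

Dynamic difficulty adjustment for serious health games, built as a
decoupled personalization loop. The package targets developers and
researchers of rehabilitation games who need the game itself, the domain
expertise (what a signal *means* for a patient) and the adaptation logic to
evolve independently: a knowledge base holds per-feature expert functions,
feature/action transformers form the game-specific boundary, and a
game-agnostic interpreter plus pluggable rule models decide how the
challenge should change. A simulated Flappy-Bird-style shoulder-rehab game
— whose one personalizable action is its speed — and a set of deterministic
study scenarios make the whole loop runnable and testable end to end,
including the comparison of **offline** adaptation (applied between
sessions) with **real-time** adaptation (applied mid-session).

## The model

Two features drive personalization, each with a knowledge function:

- **Heart-rate ceiling.** The highest accepted heart rate is
  `hr_max = (220 − age) · intensity`, overridable by the clinician; the
  packaged scenarios pin `hr_max = 180` bpm. A post-session sample (the
  session-mean HR) is interpreted into a need
  `clip((HR − hr_max)/hr_max, −1, 1)` together with two flags:
  `over_limit` (mean above the ceiling) and `rising` (mean up by more than
  1 bpm against the previous session).
- **Score trend.** Over the last `N = 5` scores, the OLS slope `b` of score
  against game index is normalized by the window mean,
  `b* = b / max(ȳ, ε)`, and classified upward / constant / downward with a
  ±0.05 dead-band.

The offline score+HR rule model applies a strict precedence —
`over_limit` (Δ = −0.05) ≻ `rising` (Δ = 0, hold) ≻ trend (constant:
Δ = +0.01; else Δ = clip(0.5 · b*, ±0.08)) — so physiological safety always
dominates performance. The real-time model smooths the 1 Hz heart-rate
stream with an EWMA (α = 0.3, reseeded each session) and, at every 5 s
evaluation instant where the smoothed HR exceeds the ceiling, issues an
immediate Δ = −0.02, effective from the next tick. Difficulty is one
normalized speed scalar clamped to [0.2, 1.6], starting at 0.8.

## Worked example

```r
library(adaptloop)

scn <- make_scenario("rising_hr")   # constant score 90; mean HR 128 + 2g bpm
study <- run_study(scn)             # offline + real-time loops
glance(study)
#> # A tibble: 2 × 7
#>   mode     model_id          n_games first_decrease_game argmin_game min_difficulty reach_game
#>   offline  offline_score_hr      30                  28          30           0.65         NA
#>   realtime realtime_score_hr     30                  26          28           0.2          27
```

Reading the metrics: under offline adaptation the session-mean heart rate
first exceeds the 180 bpm ceiling in game 27 (mean 182 bpm), so the
difficulty first drops for game **28** and bottoms out (0.65) in game
**30**. Real-time adaptation reacts inside game **26**, the first session
whose instantaneous heart rate crosses the ceiling, and is already at or
below the offline run's whole-session minimum by game **27** — the
quantified payoff of adapting mid-session. `tidy(study)` returns the
per-game trace, `autoplot(study)` plots inputs above the difficulty trace,
and `write_outputs(study, "out/")` writes CSV traces, metrics JSON and a
hash manifest.

A closed-loop demo with a latent-skill player (skill 1.1, start difficulty
0.8) shows the score-trend rule steering the challenge toward the player's
ability:

```r
demo_latent(seed = 3, games = 12)
#> # A tibble: 12 × 4
#>     game difficulty score mean_hr
#>        1      0.800  61.3    116.
#>        2      0.800  58.1    116.
#>        3      0.773  56.1    115.
#>    ...
#>       12      0.863  74.0    119.
```

There is also a thin command-line interface (`inst/cli/adaptloop`):

```sh
Rscript inst/cli/adaptloop run-study --scenario rising_hr \
    --mode offline --mode realtime --out out/
```

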