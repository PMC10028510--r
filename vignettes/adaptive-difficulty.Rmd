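---
title: "Personalizing serious-game difficulty: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Personalizing serious-game difficulty: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adaptloop)
```

## The problem and the architecture

Serious games for rehabilitation only work when the challenge tracks the
patient's ability and physiological state: too easy bores, too hard
frustrates or — worse, in a cardiac-load setting — strains. adaptloop
implements that balancing act as a loop of strictly separated stages, so
that three different roles can each own their part without touching the
others:

1. the **game** emits native observations (a score at the end of a level,
   a heart-rate sample each second) and accepts one native action, its
   speed;
2. the **abstraction layer** (feature transformers, context locator,
   action transformer) converts between native values and generic tagged
   reals — it is the only game-aware code;
3. the **personalizer** (interpreter, model locator, rule models) is both
   game- and domain-agnostic: it sees only generic samples, the knowledge
   base's declarations, and located context.

The decoupling is an enforced contract, not an aspiration: the test suite
replays the same feature stream once through the simulated game and once
through a stub that fabricates samples directly, and requires bitwise-equal
commands. Generic values are pass-through reals rather than rescaled to
[0, 1]: any normalization would need game knowledge that the independent
modules must not hold.

## Knowledge functions

**Heart-rate ceiling.** `eval_hr_max()` defaults to the age-predicted
maximum scaled by prescribed intensity, `(220 − age) · intensity`, with an
explicit clinician override that wins unconditionally. The formula is the
standard exercise-physiology default; the override exists because a
therapist's prescription, not a population formula, should bound a
patient's effort. All packaged scenarios pin the override at 180 bpm.

**Score trend.** `eval_score_trend()` fits an ordinary-least-squares slope
of score against game index over the trailing window and normalizes it by
the window mean, making the classification invariant to the game's
arbitrary score scale (a property the tests assert under random rescaling).
How the recent scores should be aggregated is a genuinely open design
point — a mean-versus-baseline comparison or a robust slope would also be
defensible; we chose the OLS slope because it responds to *direction* of
change rather than level, which is what the three scenario shapes
(constant, improving, declining) distinguish.

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `d0` | 0.8 | speed | start difficulty of every study |
| `d_min`, `d_max` | 0.2, 1.6 | speed | clamp; a stopped or absurdly fast game is useless |
| `hr_max` | 180 | bpm | scenario override of the ceiling |
| `window` | 5 | games | trend memory; small enough to react within a session block |
| `dead_band` | 0.05 | — | flat-with-noise series must classify constant |
| `step_constant` | +0.01 | speed/game | slow confidence-building rise on a constant trend |
| `k_score`, `max_step_offline` | 0.5, 0.08 | — | slope gain and clip; a steep trend moves difficulty markedly but never jumps |
| `step_hr_offline` | 0.05 | speed | safety decrement after an over-ceiling session mean |
| `step_hr_realtime` | 0.02 | speed | per-instant immediate decrement |
| `t_eval` | 5 | s | real-time evaluation cadence |
| `ewma_alpha` | 0.3 | — | smoothing of the 1 Hz HR stream |
| `rising_threshold` | 1 | bpm/session | dead-band on the rising flag |

Session length (60 s at 1 Hz) and the difficulty bounds are pinned for
reproducibility and configurable; nothing in the rules depends on their
particular values. The step magnitudes are the package's calibration of
qualitative requirements — "slow increase", "significant decrease", "react
immediately" — chosen once so that the rising-heart-rate study exhibits its
characteristic timing: twelve 5-s evaluation instants per session make the
real-time response visibly faster than one offline step per game, and
`step_hr_offline > step_constant` makes safety outweigh encouragement.

## The rule models and their precedence

The offline score+HR model applies `over_limit ≻ rising ≻ trend`. The
ordering implements a qualitative priority — physiological load beats
performance — and has two consequences the tests pin down: with a constant
score and a rising sub-ceiling heart rate the difficulty *holds* (neither
rises with the score nor falls before the ceiling is actually crossed), and
once a session mean exceeds the ceiling the next session is strictly easier
unless already at `d_min`. The real-time model reacts only to the heart
rate in-session; scores exist only at session end in this game, so a
real-time score reaction would have nothing to consume. At session end a
real-time session that issued immediate decrements (or saw a rising mean)
takes no additional score adjustment — one stage, one responsibility.

## What the scenarios emulate

`make_scenario()` builds four deterministic 30-game scenarios. The three
score-only series realize the canonical shapes an adaptation engine must
answer — noisy-constant, sustained improvement, sustained decline — and the
`rising_hr` scenario combines a constant score of 90 with a per-game mean
heart rate of `128 + 2g` bpm, ramping ±2 bpm within each 60 s session.
That construction makes three facts exact by arithmetic: the instantaneous
heart rate first exceeds 180 bpm in game 26 (peak 182), the session mean
first exceeds it in game 27, and that mean is exactly 182 bpm. Those three
facts, not the particular ramp, are what the timing comparison rests on.

```{r}
study <- run_study(make_scenario("rising_hr"))
glance(study)
```

Offline adaptation can only act after the breaching session, so its first
decrease lands in game 28 and its minimum (0.65) in game 30; real-time
adaptation acts inside game 26 and is at or below that minimum by game 27.

What the scenarios deliberately do **not** model: physiological noise,
heart-rate recovery between sessions, fatigue, or any coupling from
difficulty back to heart rate (the scripts are open-loop). Passing tests
therefore demonstrate that the *loop logic* behaves as specified on clean
signals, not that the rule constants are clinically validated — closing
that gap needs real patients, not simulation. The latent-skill player
(`play_session_latent()`, `demo_latent()`) adds a toy closed loop — score
peaks where difficulty matches skill, heart rate plateaus with difficulty —
useful for demonstrating convergence, not for physiological claims.

## Numerical choices and degenerate inputs

- OLS over integer indices `0..w−1`; a flat window gives slope 0, class
  constant. The normalizing mean is floored at `ε = 10⁻⁹`.
- Classification thresholds are strict inequalities; a normalized slope of
  exactly ±0.05 is constant, a smoothed heart rate exactly at the ceiling
  triggers nothing (`over_limit` is strict exceedance).
- The EWMA is re-seeded with each session's first sample so one session's
  stress never bleeds into the next session's smoothing.
- Real-time commands take effect the tick after their evaluation instant —
  the recorded trace is never edited retroactively.
- Fewer than two scores (first session) yields no trend and no score
  command; histories shorter than the window use what exists.
- An empty scenario runs to an empty trace with no commands; metrics on an
  empty trace are an error rather than a silent `NA`.
- All difficulty arithmetic passes through one clamp; a command sequence
  can never leave `[d_min, d_max]`.

## Design decisions that were genuinely open

- **Difficulty ≡ speed.** The game's single action is its speed and the
  study traces plot difficulty; the package identifies the two as one
  normalized scalar rather than inventing a second axis.
- **Session summary.** The end-of-session difficulty is the per-game value
  traced and compared across modes; with offline adaptation the in-session
  value is constant anyway, and for real-time adaptation the session end
  reflects everything the session's stream caused.
- **"Reaching the minimum".** The cross-mode metric `reach_game` is the
  first game whose real-time end-of-session difficulty is ≤ the offline
  run's global minimum — an operationalization of comparing the two runs'
  minima.
- **Model choice per study.** The rising-heart-rate study uses the
  score+HR model for its whole offline run (it is the score-and-heart-rate
  experiment); before any ceiling event it behaves exactly like holding on
  rising heart rate, so the choice only matters after game 26.
- **Additive score shifts.** Because the trend is mean-normalized, adding
  a large constant to all scores damps the normalized slope; the monotone
  "greater scores never mean lower difficulty" intuition is therefore
  guaranteed under multiplicative rescaling (tested) but not under
  arbitrary additive shifts. We accepted this: scale invariance is what a
  game-agnostic trend needs, and a score offset that large is a different
  game.

## Problem sizes

Every packaged study is 30 games of 60 ticks; the whole simulation suite,
both loops included, runs in a few seconds. The latent-player demo defaults
to 10–12 sessions. These sizes are the study design: the timing phenomena
of interest (a two-game offline lag, a twelve-instant real-time response)
are fully visible at this scale, and determinism makes longer runs add
nothing.

## Known limitations

- The rule constants are calibrated to qualitative requirements, not fitted
  to patient data; treat them as defaults to be overridden per deployment.
- Heart rate is the only in-session feature; games with streaming scores
  would need a real-time score model (the registry accepts one, none is
  shipped).
- The knowledge base stores R functions and parameters; ontology-backed
  knowledge (OWL/RDF) is left as an interface hook.
- No wearable ingestion: heart rate arrives as scripted or simulated
  samples.
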