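---
title: "Methods: measuring movement in a step-based balance exergame"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: measuring movement in a step-based balance exergame}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exerstep)
```

## The measurement problem

Balance-training exergames for older adults ask players to shift weight,
step sideways and raise their arms. Whether a given game actually elicits
those movements -- and how game settings such as speed and added obstacles
change them -- can only be established by measuring the player. `exerstep`
implements the full measurement chain for a lateral-stepping exergame in
which an avatar mirrors the player's sideways position across a 2 x 2 m
active floor area: the player catches falling grapes by stepping under them,
catches stationary chickens by raising a wrist above head height within a
7 s window, and (in the obstacle condition) avoids falling branches.
Movement is captured with 22 reflective markers at 120 Hz.

The design under study is 15 participants x 8 two-minute trials: two game
speeds crossed with obstacles present/absent, each played twice, in an order
counterbalanced across participants with a Latin square. Because the
original recordings are not openly available, the package includes a
synthetic player/game simulator with full ground truth; every quantitative
claim a green test makes is therefore a claim about this *stated world*, not
about the original cohort (see "What the simulator does and does not
emulate").

## Event detection

**Steps.** A step is a displacement of the foot marker of at least
`min_displacement` = 0.03 m lasting at least `min_duration` = 0.05 s, with
initiation and termination defined by the horizontal marker speed leaving
and re-entering the stationary band 0 +/- 0.1 m/s. Candidate intervals are
maximal runs of frames with speed at or above the band; a candidate becomes
a step iff it passes both thresholds. Step *size* is the horizontal
Euclidean distance between the positions at interval start and end --
deliberately not decomposed into length and width, because players differ in
how much they rotate the trunk while side-stepping. The detector is defined
on the toe marker (the operational definition) but can be switched to the
ankle (lateral malleolus), which earlier protocols used.

Choices the protocol leaves open, made here and exposed in
`detection_config()`:

* *Differentiation scheme*: positions are low-pass filtered with a zero-lag
  (forward-backward) 2nd-order Butterworth filter at 6 Hz, then
  differentiated by central finite differences. 6 Hz sits well above
  voluntary stepping content (< 3 Hz) and suppresses marker noise enough
  that 2 mm jitter at 120 Hz stays far below the 0.1 m/s band. Setting
  `filter_cutoff = NA` disables filtering, which is the right choice on
  noise-free synthetic data and is what the "ideal detector" tests use.
* *Vertical velocity is excluded*: the step criterion is horizontal.
* *Band semantics*: "stationary" means speed strictly below 0.1 m/s, so
  threshold comparisons are `>=` on the moving side; a burst of exactly
  0.03 m and 0.05 s is a step.

**Arm lifts.** The game accepts a catch when at least one hand is above the
head; the detector mirrors this by comparing each wrist marker's height
against the mean height of the four head markers. A lift starts at the
upward crossing and ends once the wrist falls below head height minus a
2 cm hysteresis; events shorter than 0.1 s are discarded. Hysteresis and
minimum duration are additions against chatter at the boundary -- both are
far below any plausible real lift, and both can be set to zero to recover
the bare crossing rule. Overlapping left/right lifts merge to `side =
"both"`, but per-side events remain available because the statistical model
includes body side as a factor.

**Single-leg support.** While one foot is in swing (a detected step) and the
other is stationary, the stationary foot is in single support. For stance
foot F: the union of the contralateral step intervals minus overlap with
F's own steps. Whether the original analysis excluded the (rare)
double-swing overlap is not stated; the exclusion is declared here,
configurable via `exclude_double_swing`, and covered by tests either way.

## Per-trial movement characteristics

Per foot: mean single-support duration, single-support ratio (accumulated
single-support time over trial time), mean step size, cadence (steps/min).
Per arm and combined: arm lifts per minute. Trial-level: a 30 x 30 sternum
occupancy heatmap and the anterior drift statistic (mean sternum Y over the
last 10 s minus the first 10 s).

Trial time is the **full recording duration**, not active game time: when a
player leaves the active area the game pauses but motion capture keeps
running, so ratios and frequencies stay comparable across trials of unequal
active time. The heatmap's default extent is 3 x 3 m -- wider than the
active area -- because players do leave it; cells are half-open with a
closed top edge, so counts are conserved. The drift statistic
operationalizes "horizontal trunk displacement", which the protocol lists as
a calculated variable but never defines as a scalar; the 10 s end-window
mean difference is this package's declared definition (a linear 0 to 0.5 m
drift over 120 s yields 0.458 m, the value the tests pin).

## Game scoring and error messages

Game outcomes arrive as structured, per-event JSON-lines logs; the original
study recovered them by OCR from screen captures, which is explicitly out of
scope here. Scoring is +1 per grape caught, +3 per chicken caught, -2 per
branch hit, and `score_trial()` recounts outcomes rather than trusting a
stored total. Error messages (one per exit from the active area, with
direction and resolution time) aggregate into a speed x obstacles 2 x 2
table; `chi_square_2x2()` applies Pearson's test **without** continuity
correction -- the choice is verified by reproducing the published statistic
1.203 on the published table, which a Yates-corrected test would not
(~0.69). Trials without a log are invalid and excluded from the
per-trial error rate (matching the 113-of-120 accounting).

## The simulator: a stated world

`generate_object_schedule()` keeps the number of concurrently falling grapes
within 1-3 (low speed) or 3-5 (high), branches within 1-2 / 1-3 when
obstacles are on, draws fall times uniformly from 8-10 s (low) / 6-9 s
(high), and places exactly 11 chickens with disjoint 7 s windows uniformly
over the trial. Spawning maintains concurrency by respawning at every
landing that would drop the count below the range minimum, with occasional
extra spawns below the maximum. A branch spans 0.57 m; the source text also
says "35 %" of the 2 m area, which is arithmetically inconsistent
(0.57/2 = 28.5 %), so the absolute width is used and both are configurable.

`simulate_play()` moves a policy-driven player: lateral movement happens in
step *pairs* (a lead step in the travel direction, then a trailing step of
the other foot, each a minimum-jerk profile of the commanded displacement),
paced by a per-participant cadence preference unless an arrival is imminent.
The player targets the earliest reachable grape, moves under attempted
chickens and raises one or both arms after a reaction delay, and -- the
behaviour that makes obstacle trials slower -- *waits* rather than crossing
the path of a branch that will land within ~4 s, stepping out only when a
branch is about to land on them. A catch registers iff the avatar is within
`catch_half_width` (default 0.15 m; the game never quantifies this
tolerance) of the object at the decisive moment. Forward drift toward the
screen is delivered through small forward components of the steps; when the
trunk leaves the active area the game clock pauses, an error message with a
lognormal resolution time (median 2 s, motivated by the reported 2.44 s
mean) is logged, and the player steps back in. Active game time plus pause
time equals recording duration by construction.

`synthesize_markers()` renders the 22-marker set at 120 Hz from the plan
with a fixed-offset body model: foot markers follow their foot's commanded
steps exactly, wrist markers exceed mean head height exactly during
commanded lift intervals (a sine bump entered and left through smooth
ramps), trunk and head markers follow the body path, and white Gaussian
noise (default sd 2 mm, a realistic optical-capture figure) is added to all
coordinates.

**Ground truth** records what an *ideal* velocity-threshold detector would
see: for each commanded minimum-jerk step, the closed-form interval on which
its speed profile exceeds 0.1 m/s and the displacement accumulated inside
it. This is the right comparison target because the stationary band, not the
commanded interval, defines the event; on noise-free renders the detector
reproduces these boundaries to within one frame, which the suite asserts.

**What a green test does and does not establish.** The simulator reproduces
the study's design, object mechanics, scoring, clock accounting and marker
geometry, and its emergent condition effects have the directions the study
reports for its robust findings (obstacles reduce cadence and arm-lift
frequency via waiting; higher speed raises scores and error counts). It does
not model balance physics, fatigue, anticipatory strategies, soft-tissue or
occlusion artefacts, and its policy parameters are stylized. Green tests
therefore establish that the *measurement chain* is correct and calibrated,
not that the original cohort's numeric outcomes are reproduced -- those are
unavailable by design, and the package deliberately does not target Table-2
or Table-3 point estimates.

### Simulator defaults

Per-participant policies are drawn once per simulated participant (this is
exactly the between-participant heterogeneity the model's random intercept
absorbs): reaction delay U(0.3, 0.6) s; preferred step size N(0.25, 0.05) m
clamped to [0.12, 0.4]; preferred per-foot cadence N(28, 6) /min clamped to
[15, 45]; chicken attempt probability U(0.75, 1); arm style both-arms or
one-arm (60/40), with a 1-in-15 chance of a player who never lifts the arms
(one such participant was observed); forward drift lognormal(log 0.28, 0.5)
m/min; step placement noise U(0.01, 0.03) m. Values not fixed by the study
were chosen once for face plausibility for adults in their seventies and are
not tuned against any test.

## The mixed model

Each side-specific metric is modelled as

value ~ speed + obstacles + repetition + gender + side + (1 + side | participant)

fitted by REML via `lme4`, with treatment coding and reference levels low
speed, without obstacles, repetition 1, female, left side. All factors are
two-level, so each fixed effect has one coefficient and its conditional
F statistic is the squared t.

**Denominator degrees of freedom.** The reference analysis used the
Kenward-Roger approximation. Neither `pbkrtest` nor `lmerTest` is available
in this package's dependency footprint, and hand-rolling Kenward-Roger
invites subtle errors, so `exerstep` uses the between-within (containment)
rule instead -- the scheme `nlme` and SAS `DDFM=BW` use: effects varying
within participants get N - n_participants - p_within df (about 221 at the
design size, against ~229 reported), and the purely between-participant
gender effect gets n_participants - 2 = 13 (against ~17). At these sizes
the t distributions are nearly indistinguishable, and the package validates
the choice the only way that matters: by simulation calibration. With zero
injected effects the per-effect p-values are uniform (Kolmogorov distance
< 0.1 over 200 replicate cohorts), and 95 % CI coverage of injected effects
sits within [90 %, 99 %]. The df method is recorded in every fit.

**Calibration simulates from the generative model.** A 200-replicate
calibration cannot render 24,000 marker trials in any reasonable time, and
statistically it should not: the correct check of a test approximation
simulates from the model family being fitted. `recovery_experiment(level =
"metrics")` therefore draws metrics tables directly from the mixed model --
balanced design, participant intercepts, side slopes, Gaussian residuals --
with effect magnitudes defaulting to the midpoints of the study's reported
cadence CIs (speed 6.89, obstacles -9.30, repetition 0.875, gender 5.99,
side 1.03 steps/min) and variance components chosen once so the implied
standard errors match the reported CI widths (residual sd 6.6, intercept sd
3.7, side-slope sd 1). `level = "full"` runs entire cohorts through
simulate -> detect -> metrics -> fit; there the metric-scale truth is
emergent rather than injected, so the full level reports estimates and
directions, and the suite checks it at small scale.

## Numerical choices and degenerate inputs

* Missing samples are `NA`, never zero; `fill_gaps()` interpolates only
  interior gaps up to 0.1 s (shorter than any detectable step, so
  interpolation cannot fabricate events) and reports everything else.
* Durations compare on frame counts (`(i2 - i1)/rate`), not accumulated
  float time, so a 6-frame burst at 120 Hz is exactly 0.05 s.
* A trial with no steps reports cadence 0 and *missing* mean step size;
  models drop missing rows and report the count.
* Chi-square requires positive margins; empty logs score 0 with undefined
  percentages; a trial shorter than two drift windows refuses the drift
  statistic rather than extrapolating.
* All randomness flows from explicit integer seeds; per-trial seeds derive
  from the run seed, and identical seeds give byte-identical artifacts.

## Known limitations

* The C3D reader covers the modern Intel-format variant (float or scaled
  16-bit integer points) -- the overwhelmingly common case -- and was
  validated against an independent implementation; DEC/SGI byte orders are
  rejected with a clear error.
* The between-within df rule is an approximation; studies with richer
  random-effects structure than this design should prefer a dedicated
  Kenward-Roger implementation.
* The simulated speed effect on cadence is weakly positive (real players
  sped up more), because the simulated player saturates near their cadence
  preference; direction tests pin the robust effects instead.
* Jump-catching (players triggering the avatar's jump to catch grapes
  early) is modelled only as a widened catch tolerance behind a policy flag.
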