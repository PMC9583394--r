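---
title: "Adaptive JND measurement for two-dimensional sonification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive JND measurement for two-dimensional sonification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sonimlp)
```

## The measurement problem

A two-dimensional sonification maps two data dimensions to sound. Before
such a display can be trusted, three perceptual questions need
quantitative answers: how *finely* can listeners resolve each dimension
(perceptual resolution), whether moving *toward* the data origin sounds
different from moving *away* from it (hysteresis), and whether
simultaneous changes of both dimensions are harder or easier to hear
than changes of one (perceptual interference). `sonimlp` answers all
three with a standardized adaptive two-alternative forced-choice (2AFC)
experiment built on the maximum likelihood procedure (MLP), and reduces
the results to a small set of comparable scores.

All measurements happen in a normalized *mapping space*: two linear
dimensions, each scaled to $[-1, 1]$, divided into quadrants I–IV with
one *standard* (reference coordinate) at the center of each quadrant,
$S = (\pm 0.5, \pm 0.5)$. Raw application data enter this space through
a piecewise-linear transfer function ([`normalize_value()`]): a target
value maps to 0, the acceptable bounds map to $\pm 1$, values in
between map linearly (the two branches may have different slopes), and
values outside are clamped. Any nonlinear pre-transform of the raw data
(say, ion concentration to pH) is the caller's responsibility.

From each standard, five motions are probed: $\pm\Delta x$,
$\pm\Delta y$, and the positive diagonal ($+\Delta x, +\Delta y$). The
signs are defined relative to the coordinate origin: a *plus* direction
increases the absolute value of the component (moves away from the
origin), a *minus* direction decreases it. This convention makes all
four quadrants symmetric and extends unchanged to the axis standards of
the light experiment below.

## The psychometric model

A trial presents the standard and a *variable* offset from it by
$\alpha$ along the track's direction; the listener judges which of the
two lies further from the origin. The probability of a correct answer
as a function of the offset $x$ is modeled as a scaled logistic,

$$\Psi(x; \alpha, \beta, \gamma) = \gamma + (1 - \gamma)\,
  \frac{1}{1 + e^{\beta(\alpha - x)}},$$

with chance level $\gamma = 0.5$ in 2AFC (the floor), midpoint $\alpha$
and slope $\beta$. The hypotheses the MLP entertains carry no lapse
term — an attentional lapse lowers the ceiling of real listeners, and
the simulated listener can model it, but the candidate functions follow
the standardized definition exactly.

The MLP keeps $J$ candidate functions ("hypotheses") that share
$\beta$ and $\gamma$ but differ in midpoint. After every trial $n$,
each hypothesis $H_j$ is scored by the log-likelihood of the observed
answers,

$$L(H_j) = \sum_{i=1}^{n} C\,\log H_j(x_i) + W\,\log(1 - H_j(x_i)),$$

where $C = 1$ for a correct and $W = 1$ for a wrong answer. The
hypothesis with the highest likelihood is the current best estimate of
the listener's psychometric function. The next stimulus is placed at
that hypothesis's *sweet point*, the inverse function at the target
proportion correct,

$$\Psi^{-1}(p_\mathrm{target}) = \alpha_j - \frac{1}{\beta}
  \ln\!\left(\frac{1-\gamma}{p_\mathrm{target}-\gamma} - 1\right),$$

with $p_\mathrm{target} = 0.809$, the placement that minimizes the
variance of a 2AFC threshold estimate. After the final trial the same
quantity, clamped to the presentable range, is the track's JND.

### Standardized conventions and their defaults

`mlp_conventions()` fixes the experiment so that different sonifications
yield comparable numbers:

| parameter | default | meaning |
|---|---|---|
| `gamma` | 0.5 | 2AFC chance level (floor) |
| `beta` | 100 | shared logistic slope (dimensionless, per unit offset) |
| `alpha_min`–`alpha_max` | 0.001–0.1 | assumed JND range, in mapping-space units |
| `n_hypotheses` | 100 | midpoints linearly spaced over that range |
| `p_target` | 0.809 | sweet-point proportion correct |
| `n_trials` | 12 | trials per track |
| `initial_delta` | 0.07 | first stimulus: a clearly audible difference |
| `grid_step` | 0.001 | stimulus quantization |

With these values the hypothesis midpoints and the presentable stimuli
form the *same* grid (0.001, 0.002, …, 0.1), so every stimulus the
placement rule can ask for has a pre-renderable sound.

### Numerical choices

Several details are open where a procedure is only stated in prose; the
package fixes them as follows, and records each in the report metadata
where it matters:

* **Log base.** Likelihoods are accumulated in natural log. The argmax
  over hypotheses is invariant to the base (the suite verifies this
  against a base-10 recomputation), so this is purely a numerical
  convenience.
* **Stimulus quantization.** The raw sweet point is rounded half-up to
  the 0.001 grid and clamped to the presentable range; stimuli are only
  defined on that grid.
* **Tie-breaking.** When several hypotheses tie for the maximum
  likelihood (always the case before the first answer), the smallest
  midpoint wins. This is the conservative choice: it biases early
  placement toward finer differences, so claims of high resolution get
  tested harder rather than granted.
* **JND readout.** Two conventions circulate: the sweet point of the
  best hypothesis, and the best hypothesis's midpoint itself. They
  differ by a constant $\tfrac{1}{\beta}\ln(\cdot) \approx 0.0048$
  under the defaults. The package defaults to the sweet point, which is
  the quantity the placement rule tracks; `mode = "midpoint"` is
  available (and is the convention under which 0.001 is the smallest
  reportable JND). The readout mode is carried in every report.
* **Track order.** The 20 tracks of a full session run sequentially in
  a seeded random permutation; a round-robin `interleave` option exists
  for human sessions where adaptation across consecutive same-direction
  trials is a concern.
* **Pause placement.** Each sound lasts 3–5 s (default 4 s) and the
  equal-length silent pause is placed *between* the two sounds of a
  trial; whether the pause belongs within or after the pair is
  ambiguous in prose, and the within-pair reading is implemented.
* **Ramps.** Raised-cosine onset (50 ms) and a long raised-cosine
  offset (500 ms) prevent onset clicks and stop listeners comparing the
  pair by its final modulation phase. Sonifiers must be deterministic
  and start their modulators at a fixed phase for the same reason.

## The virtual observer

`virtual_observer()` is a parameterized stand-in for a listener: it
answers a trial at offset $\Delta$ correctly with probability

$$\gamma + (1 - \gamma - \lambda)\,f_\mathrm{logistic}(\Delta;
  \alpha_\mathrm{true}, \beta_\mathrm{true}),$$

where $\lambda$ is a lapse rate that lowers the ceiling (a lapsed trial
is a coin flip; the symmetric form above is the simplest
ceiling-reduction consistent with that reading). With $\lambda = 0$ the
response probability is exactly $\Psi$. Each observer owns a seeded
random stream, so simulated sessions replay bit-identically from their
configuration.

The observer emulates a stationary, order-insensitive listener. It does
**not** model learning or fatigue drift, inter-trial dependencies,
presentation-order bias, or any acoustical confound of a real playback
chain — so passing simulations demonstrate that the *procedure*
recovers known thresholds, not that any particular sonification will
behave this way with human listeners.

### Parameter recovery

The suite verifies recovery under the study conditions: for lapse-free
observers with $\beta = 100$ and true midpoints 0.01, 0.03 and 0.06,
the median sweet-point estimate over 500 seeded 12-trial tracks falls
within $\pm 0.01$ of the observer's true sweet point, and within
$\pm 0.003$ with 100-trial tracks. (Measured medians are within
0.004 at 12 trials and on the true value at 100 trials.) These problem
sizes — 500 tracks per condition, three conditions, both trial counts —
are the package's standing simulation study and run in under a minute.

## From JNDs to scores

A full session yields five JNDs per quadrant, summarized by:

* **Resolution** — the away-from-origin JNDs of each dimension and
  their reciprocals, the number of distinguishable steps along the unit
  axis: $1/0.001 = 1000$ steps at the grid floor, $1/0.1 = 10$ at the
  ceiling.
* **Hysteresis** — $h = 0.5\,\lg\frac{\mathrm{JND}(-\Delta)}
  {\mathrm{JND}(+\Delta)} \in [-1, 1]$ on the default grid; positive
  values mean larger steps are needed to be audible when approaching
  the origin.
* **Interference** — with $\mathrm{JND}^{\min}$/$\mathrm{JND}^{\max}$
  the smaller/larger single-dimension JND, the threshold
  $T = 0.5\,\lg\frac{\mathrm{JND}^{\max}}{\mathrm{JND}^{\min}} \in [0,1]$
  and the degree
  $\delta = 0.5\,\lg\frac{\mathrm{JND}(+\Delta x, +\Delta y)}
  {\mathrm{JND}^{\min}} \in [-1,1]$ classify into *positive*
  ($\delta < 0$), *none* ($\delta = 0$), *usual*
  ($0 < \delta \le T$), and *negative* ($\delta > T$) interference.

Exact equality $\delta = 0$ has measure zero in floating point, so the
classifier accepts an `epsilon` half-width for the "none" band; the
default 0 applies the four cases literally.

```{r scores}
q <- quadrant_jnds("I", plus_x = 0.01, minus_x = 0.02,
                   plus_y = 0.04, minus_y = 0.03, diagonal = 0.02)
resolution(q)[c("steps_x", "steps_y")]
hysteresis(0.02, 0.01)
interference(q)[c("threshold", "delta", "quality")]
```

`build_report()` assembles the standardized tables (resolution and
hysteresis as 2-row tables with one column per quadrant, interference
as one row per quadrant); quadrants outside the configured mask are
reported absent, never imputed.

## The light experiment

The full evaluation presumes the parameter mapping is perceptually
*linear* along each axis; the design-stage "light" session checks this
by measuring the away-from-origin JND at standards placed on the axis
tick marks. The tick spacing is configurable (default 0.1; tick marks
whose stimulus grid would leave the space, i.e. $|t| > 1 - 0.1$, are
excluded, leaving 9 ticks per polarity). `score_session()` then
compares the JNDs within each axis polarity by their max/min ratio;
mappings whose ratio exceeds the tolerance (default 1.5 — a deliberate,
configurable choice, since no canonical value exists) need adjustment
before the full experiment is meaningful. Which polarities are sampled
follows the quadrant mask, so a ratio-scale design (quadrant I only)
checks only the positive polarities.

## A complete simulated session

```{r session}
sim <- simulate_session(list(true_alpha = 0.03, seed = 7), seed = 42)
sim$report
```

Full mode runs $5 \times |\text{quadrants}|$ tracks of 12 trials (20
tracks, 240 trials with all four quadrants) in a seeded random order;
`(config, seed)` determines every trial of a simulated session, and
`write_session_log()` / `read_session_log()` round-trip the session
through JSON losslessly.

## Known limitations

* The slope $\beta$ is fixed, never estimated; listeners with much
  shallower slopes than the convention are estimated with more
  variance. Bayesian/QUEST-style posterior methods are out of scope.
* Per-participant scores only: aggregation across participants (means,
  CIs; and whether to pool JNDs before or after the log-ratio scores)
  is left to the analyst — `session_jnd_table()` exposes the raw JNDs
  for either choice.
* Audio output is plain uncompressed WAV through a deterministic
  sonifier callback; playback calibration, loudspeaker spatialization
  and online delivery are outside the package.
* The bundled `reference_sonifier()` (log-frequency carrier for $x$,
  amplitude-modulation rate for $y$) exists to exercise the pipeline
  and the demos; real evaluations plug in the sonification under test.
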