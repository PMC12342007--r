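---
title: "Circadian tracking by neural-network-encoded TF circuits: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Circadian tracking by neural-network-encoded TF circuits: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tfsde)
```

## The model

`tfsde` simulates a cell whose `n` transcription factor (TF) genes regulate
each other through an input-output function encoded by artificial neural
networks. Molecule counts of mRNA (`x_i`) and TF protein (`y_i`) follow

$$dx_i = \big(m_i f_i(\mathbf{y}) - \delta_i x_i\big)\,dt + g(x_i)\,dW,$$
$$dy_i = \big(s_i x_i - \gamma_i y_i\big)\,dt + g(y_i)\,dW,$$

with per-gene kinetic rates: maximal transcription $m_i$ (molecules/day),
mRNA decay $\delta_i$, translation $s_i$, and protein decay $\gamma_i$
(all 1/day). Each state variable receives its own independent Wiener
increment — the standard chemical-Langevin reading of demographic noise —
scaled by

$$g(z) = \begin{cases}\sqrt{z} & z > 16\\ z/4 & z \le 16,\end{cases}$$

which is the usual $\sqrt{z}$ birth-death amplitude except near zero, where
the linear branch keeps relative fluctuations bounded and prevents negative
excursions; the two branches agree at the threshold ($\sqrt{16} = 16/4 = 4$).

The regulatory function $f_i(\mathbf{y}) \in (0,1)$ is a separate two-layer
network per gene: the $n$ protein abundances enter as $\log(1+y)$, pass
through $5n$ hidden units with the mish activation
$r\,\tanh(\log(1+e^r))$, and a sigmoid head returns the relative
transcription rate. Every input-to-hidden edge and hidden-to-head edge
carries its own affine pair $(\alpha, \beta)$, giving $10n^3 + 10n^2$
scalar parameters in total. Per node the $\alpha$'s only enter through
their sum, so internally the package evaluates (and trains) the equivalent
dense form — one bias per node — and a unit test pins the equivalence. The
input offset in $\log(1+y)$ is a package decision: abundances can reach
zero, where a bare logarithm is undefined, and the offset merely
reparameterizes the learned weights. It is configurable
(`input_transform`), as is the width multiplier.

## The circadian task

TF 1 is the readout: protein abundance above the switch threshold
$S = 10^3$ molecules marks the cell's internal daytime state. The
environmental target is $v(t) = (\sin(2\pi t + \pi) + 1)/2$ with $t$ in
days; $v$ crosses $0.5$ at every integer (dusk) and half-integer (dawn)
day. An external light signal switches on and off with i.i.d. exponential
waiting times (mean `mean_wait = 2` days by default, the first wait drawn
from the same distribution with the signal starting off), and while on it
adds $u(t) = 10^6\, v(t)^4$ molecules/day to TF 2 production — a sharp
midday pulse. The exponent 4 and amplitude $10^6$ are the defaults of
`light_config()`; the exponent is configurable because the forcing shape is
a modeling choice (the alternative affine reading $10^6 v - 4$ is rejected
outright, as it would go negative at night).

Tracking quality is scored on a fixed grid ($t = 0, 0.02, 0.04, \ldots$,
half-open at the horizon: exactly 50 points per day) by

$$L = \sum_t \left(\frac{y_t^2}{S^2 + y_t^2} -
      \frac{v_t^2}{0.25 + v_t^2}\right)^2 ,$$

two Hill transforms that place both signals on a common $[0,1)$ scale with
half-points at $y = S$ and $v = 0.5$ respectively. The target-transform
constant is taken as $0.25 = 0.5^2$ so that its half-point coincides with
the day/night transition, exactly mirroring the abundance transform; it is
exposed as `target_half` because the constant's rendering is ambiguous at
face value ($0.5$ vs $0.5^2$) and both behave similarly. Loss values are
read from the integrator's own save points — the simulation step must
divide the 0.02-day grid — so no interpolation error enters the objective.

## Integration and its accuracy

The integrator is Euler–Maruyama with post-step clamping at the abundance
floor (default 0). Defaults: `dt = 1e-3` days for production simulation;
training examples in this package use `dt = 5e-3`, which resolves the
sub-day dynamics of the default kinetics while keeping reverse-mode
training cheap. A drift-implicit scheme is declared in the configuration
enum but not implemented: the clamped noise amplitude already prevents the
negativity that implicit methods are usually deployed against here, the
explicit path is what the pathwise gradients differentiate, and an implicit
step through the neural drift would require a Newton solve per step for
little benefit at these step sizes. Requesting `implicit_em` raises a clear
error rather than silently substituting.

Euler–Maruyama is first order in the drift, and the test suite verifies
the order empirically (halving `dt` halves the endpoint change) plus an
exact check: with zero network weights every $f_i = 0.5$, the system is
linear, and a noise-off run at `dt = 1e-3` must match the closed-form
solution to $10^{-4}$ relative error. That check starts the mRNA at its
fixed point so the comparison isolates the protein relaxation; with the
fast transients of an arbitrary start, the bound would instead measure the
(known, first-order) truncation of the transient.

Light-state changes are evaluated at each step's left endpoint under a
right-continuous schedule convention, and initial abundances default to 10
molecules for every species — a deliberately small, uninformative start;
both are configurable.

## Training

`train_grn()` minimizes the expected tracking loss by Adam (default
learning rate $10^{-2}$ — the optimizer and rate are package choices) over
the flattened free parameters: dense network weights plus, by default, the
kinetic rates in log space, which keeps every rate strictly positive
without constraints. Gradients are pathwise: at each optimizer step a
batch of light schedules and Wiener increment matrices is sampled, then
held fixed while the solution path is differentiated exactly by
reverse-mode accumulation through the unrolled integrator (the clamp
contributes a zero subgradient on clamped coordinates, and the
state-dependence of the noise amplitude is included). A unit test checks
the gradient against central finite differences at relative error
$10^{-3}$, restricted to coordinates whose gradient exceeds what central
differences of an order-one loss can resolve (about $10^{-11}$).

The curriculum grows the fitted horizon in stages — default 0.5, 1, 2, 3,
4 days, ending at the 4-day final training range; only the endpoints are
anchored by the problem statement, the intermediate rungs are package
defaults. Optionally a deterministic (noise-off, light-off) pretraining
stage at the first horizon precedes stochastic training; light-off is the
natural deterministic reference since the signal starts off and a random
schedule would make the "deterministic" stage stochastic through its
environment. The best-loss checkpoint is returned; non-finite losses abort
the stage with a warning, and a wall-clock budget stops training
gracefully. The packaged examples and tests use desk-scale runs (1-day
horizons, a few hundred steps, $n = 3$); full multi-day stochastic
optimization is the same code run longer.

## Deviation analytics

For a simulated realization, `daily_deviations()` measures circadian
tracking day by day: the target enters daytime at each half-integer day,
and the cell enters its daytime state when the readout abundance crosses
$S$ upward (linearly interpolated, strict-crossing convention). Each dawn
is paired with the nearest cell crossing within a ±12 h window; the
deviation is (cell − target) × 24 hours, negative when the cell runs
early. Days with no crossing in the window are *censored* — kept in the
accounting but excluded from percentiles. Nearest-crossing pairing and
censoring are package decisions: the underlying definition is silent on
days with zero or multiple crossings, so both choices are made explicit
and reported. The phrase "deviation divided by 24" in the source
description is treated as an erratum for multiplication (days to hours);
`make_shifted_tracking_trajectory()` provides the oracle — a trajectory
whose transformed readout equals the target delayed by a known shift — and
recovery of that shift (sign included) is pinned by tests.

`ensemble_deviations()` repeats this over `n_reps` independent stochastic
realizations of `d` days — fresh light schedule and Wiener path each —
yielding exactly `n_reps * d` samples, and `summarize_deviations()`
reports the 5/25/50/75/95th percentiles with the censored count. All
sampling is reproducible from a single master seed via derived
per-replicate seeds.

## Fixtures: what they emulate and what they don't

The package tests itself without any long optimization run, using
hand-built regulatory rules:

* `make_repressilator()` builds the cyclic-repression ring (gene $i$
  repressed by gene $i-1$), the classic synthetic oscillator;
  `fit_net_to_rules()` encodes any such Hill-rule set into the network
  architecture by least squares (L-BFGS with analytic gradients, random
  restarts, max-abs tolerance 0.05 on the training grid, held-out error
  checked at twice that).
* `repressilator_kinetics()` (m = 30000, δ = 12, s = 12, γ = 6 per day)
  places protein counts in the $10^2$–$10^4$ range and, more importantly,
  puts the ring's loop gain well past the Hopf threshold at Hill
  coefficient 2: the maximal protein level $sm/(\gamma\delta) = 5000$ is
  ten times the repression half-max $K = 500$. With weaker transcription
  the gain is subcritical and the ring damps to a fixed point — a
  quantitative constraint worth stating because plausible-looking slower
  kinetics silently fail it.
* `repressilator_init()` staggers initial abundances by decades across the
  ring. The symmetric state is an (unstable) invariant of the symmetric
  ring, so a uniform start would linger near the fixed point for many days
  before numerics break the tie; the staggered start is part of the
  fixture's definition, not a tuning knob.
* The 4-gene ring is constructed for surface tests only; an even ring has
  no guaranteed limit cycle and the fixture makes no oscillation claim
  for it.

Passing these tests shows the machinery is correct — integration,
gradients, crossing analytics, serialization. It does not show that any
particular biological network behaves this way: the fixtures are pure Hill
circuits with uniform kinetics, no transcriptional delay, no cell
division, no extrinsic noise, and the Langevin approximation itself
degrades at very low copy number (the clamped amplitude is a numerical
guard, not a mechanistic claim).

## Configuration and formats

Run configuration is a single YAML file (nested keys mirror the
constructors: `light.mean_wait_days`, `sim.dt_days`, `objective.S`,
`train.horizons`, ...) — YAML is the package's config format of choice for
flat, diff-friendly settings with a robust installed parser. Parameters
(per-edge network weights plus kinetics) serialize to schema-versioned
JSON with 17-significant-digit numbers, so round trips are exact for
finite doubles; trajectories, deviation tables and surface grids export as
CSV. Every CLI run writes a reproducibility manifest (command, config,
seeds, package version, timestamps) beside its output.

## Known limitations

* Euler–Maruyama only; no adaptive stepping, no exact (Gillespie)
  simulation — the model is the Langevin SDE by construction.
* Pathwise gradients are exact for the discretized path, not the
  continuous SDE; train and evaluate at the same `dt` when comparing
  losses.
* The deviation window (±12 h) silently censors cells that drift more
  than half a period out of phase; interpret censoring counts alongside
  percentiles.
* `fit_net_to_rules()` fits rules that depend on one regulator each;
  arbitrary multi-input rules would need a denser training grid.
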