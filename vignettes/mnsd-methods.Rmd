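---
title: "Latency-coded spike-sequence detection: model, learning rule and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Latency-coded spike-sequence detection: model, learning rule and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mnsd)
```

## The neuron model

The package simulates *Leaky Integrate-and-Fire with Latency* (LIFL) neurons.
Each neuron carries a dimensionless internal state $S \ge 0$ ($S = 0$ is
rest) and a threshold $S_{th} = 1 + d$ with threshold constant $d > 0$.
Two regimes govern the dynamics between afferent pulses:

* **passive** ($S < S_{th}$): linear decay at rate $L_d$ (1/ms), floored at
  rest, so over an interval $\Delta t$ the state loses
  $T_l = L_d\,\Delta t$ but never goes negative;
* **active** ($S \ge S_{th}$): the neuron is committed to fire, but not
  instantaneously. Its *spike latency* (time-to-fire) is
  $$t_f = \frac{1}{S - 1},$$
  strictly decreasing in $S$ and bounded by $t_{f,\max} = 1/d$, attained at
  threshold. Between pulses the state grows by the rise term
  $$T_r = \frac{(S_p-1)^2\,\Delta t}{1-(S_p-1)\,\Delta t},$$
  which is exactly the increment that keeps the countdown consistent:
  `firing_equation(S + rise_term(S, dt))` equals `firing_equation(S) - dt`.
  The test suite asserts this identity to $10^{-9}$ ms over random states.

A pulse of amplitude $A$ through a synapse of weight $w$ adds $A\,w$ to the
state of the receiving neuron. When the fire finally occurs the state resets
to 0 and, for a configurable absolute refractory period `t_arp` (default 0
ms — no value is prescribed by the source model), all input is discarded.

The latency mechanism is the computational point: an amplitude is converted
into a delay, so a synaptic weight acts as a *tunable transmission delay*
$1/(A\,w - 1)$, something a plain integrate-and-fire unit cannot express.

### Event-driven engine and its reference simulator

`run_lifl()` advances the network from pulse to pulse rather than on a
clock. Determinism is pinned down by three scheduling rules, chosen once and
tested:

* simultaneous pulse deliveries are processed in ascending (time, source)
  order, so a neuron hit by several coincident pulses accumulates them with
  $\Delta t = 0$ before any latency is resolved;
* a pulse arriving at the very instant a fire is due is delivered *first* —
  the latency can be altered up to the moment the spike leaves. Numerically
  the rise term then diverges; the engine treats the state as infinite and
  fires at that same instant;
* time comparisons use a $10^{-9}$ ms tolerance.

The engine is validated against an independent clock-driven simulator (in
the test helpers) that walks a fixed $10^{-4}$ ms grid applying the decay
and rise increments stepwise, with no event queue or fire scheduling. On
100 random networks (at most 5 neurons and 10 external pulses — small
enough that the reference stays cheap, large enough to exercise chains,
refractoriness and rescheduling) the two spike chronicles agree to
$10^{-3}$ ms.

## The detector

A multi-neuronal spike-sequence detector (MNSD) is $n$ parallel *delay
branches* $D_1,\dots,D_n$, one per input channel, converging on a single
*target* neuron $T$. Channel $n$'s external spike (unit amplitude) enters
$D_n$ through weight $w(D_n, ES_n)$; each branch output reaches $T$ through
a common weight $w(T, D_n)$. All couplings are instantaneous, so the only
delays are spike latencies.

Static analysis gives the admissible parameter region:

* **branch activation**: $A\,w(D_n,ES_n) \ge 1 + d$, or the branch never
  fires from rest (`check_branch_activation()`);
* **target weight**: $\tfrac{1+d}{n} \le w(T,D_n) < \tfrac{1+d}{n-1}$
  (`target_weight_bounds()`): all $n$ synchronous branch pulses must fire
  the target, while any $n-1$ (a partial sequence) must not;
* **simultaneity**: the input offsets that make all branch outputs reach
  $T$ at one instant are
  $\Delta t_{in}(D_1,D_n) = \tfrac{1}{w_1-1} - \tfrac{1}{w_n-1}$
  (`simultaneity_offsets()`); the round trip through the simulator
  reproduces coincidence to $10^{-6}$ ms;
* **tolerance**: `tolerance_condition()` evaluates the residual
  desynchronisation $r_n$ of each branch against a bound (default
  $(2-d)/L_d$ ms) using the concordant/discordant-sign case split.

### The tolerance bound and the target weight

The event-driven mechanics make the effective coincidence window explicit.
With target weight $w_T$ per branch and pulses spanning $\Delta$ ms, the
target's state at the last arrival is $n\,w_T - L_d\,\Delta$, so a
three-branch structure detects iff
$$\Delta < \frac{3 w_T - 1 - d}{L_d}.$$
The published closed-form bound $(2-d)/L_d$ coincides with this expression
only at $w_T = 1$ — a value *outside* the partial-sequence-safe interval
$[(1+d)/3, (1+d)/2)$. The package keeps the closed form as the documented
default of `tolerance_condition()` but lets the caller pass the bound
matching their actual target weight; the agreement test between the
analytic condition and the simulated detector does exactly that.

This exposes a structural trade-off worth stating plainly: with an
admissible target weight the coincidence window cannot exceed
$(1+d)/(2 L_d)$ — about 1.4 ms at $d = 0.04$, $L_d = 0.37$ — while any
$w_T \ge (1+d)/2$ opens a *two*-pulse window $(2 w_T - 1 - d)/L_d$ and the
detector partially degenerates into a pairwise coincidence detector.
Selectivity against partial sequences and robustness to multi-millisecond
jitter cannot both be had by tuning $w_T$; only lowering $L_d$ widens the
full-sequence window without the pairwise leak. The evaluation section
below quantifies the consequence for the synthetic benchmark.

### Geometry

Detection depends only on inter-spike intervals, never on the arrival time
of the first pulse (asserted as a property test), so the detected set in
$n$-dimensional spike-time space is a cylinder whose axis points along
$(1,\dots,1)/\sqrt{n}$ and whose radius grows as $L_d$ shrinks.
`hypervolume_axis()` reports the anchor in the published closed form
$t_{offset} + 1/(w_n-1)$. Note a sign subtlety: the inputs that actually
synchronise at the target have offsets $-1/(w_n-1)$ up to a constant
(the simultaneity offsets above), i.e. the published anchor traverses the
offsets with reversed sign; both cannot describe the detected set at
unequal weights. Wherever the package needs the detected patterns
themselves — `simulate.mnsd()`, the delay-learning test — it uses
`simultaneity_offsets()`; `hypervolume_axis()` is kept as the reporting
convention.

## Learning

Adjacent branches are coupled by weak lateral excitation, and the branch
input weights are updated by *heterosynaptic* STDP: the timing relation
between neighbouring branch outputs modifies the branch's afferent weight.
The window is the standard pair of exponentials
$$\Delta W = A_+ e^{-\Delta T/\tau_+}\ (\Delta T > 0),\qquad
  \Delta W = A_- e^{\Delta T/\tau_-}\ (\Delta T < 0),\qquad
  \Delta W = 0\ (\Delta T = 0),$$
with $\Delta T = t_{post} - t_{pre}$. For branch $n$ under the influence of
neighbour $m$ the package takes $\Delta T = t_{out}(D_n) - t_{out}(D_m)$:
the branch's own output is the postsynaptic event, the neighbour's
instantaneous lateral pulse the presynaptic one. Interior branches sum both
neighbours; the first and last have a single neighbour.

The sign convention deserves a note, because the source prose and equations
disagree and the package settles it empirically. Under the convention
above, a branch that fires *after* its neighbour is potentiated, its
latency shrinks, and the output gap closes: training on a fixed sequence is
contractive. Under the opposite convention the gap grows without bound.
The package defaults to the contracting convention and exposes
`convention = "neighbor_minus_self"` for comparison; a regression test
trains one detector under each and asserts the default synchronises while
the flip does not. A perfectly synchronous trial induces exactly zero
change (the window vanishes at $\Delta T = 0$), making the tuned state a
fixed point.

Three further choices:

* **trial batching.** All updates of a trial are computed from that trial's
  output times and applied after it ends. The time constants
  ($\tau_\pm = 9.6$ ms) are meant to couple spikes of one sequence and not
  of adjacent sequences; batching makes that guarantee structural rather
  than statistical.
* **pure modulation.** Lateral pulses default to zero amplitude
  (`lateral_amplitude = 0`): they drive the weight updates but do not
  perturb the neighbour's state, whose effect would be negligible at weak
  coupling anyway. A small nonzero amplitude is available for study.
* **clipping.** After each trial the branch weights are clipped to
  $[1 + d + 10^{-3},\ 2]$. The lower bound keeps every branch firing —
  below branch activation the branch falls silent and, since silent
  branches receive no update, learning would halt permanently. The upper
  bound keeps latencies at or above 1 ms. No bounds are prescribed by the
  source model; these are the package's own guard rails.

Near convergence the weights do not freeze: the window's magnitude does not
vanish at small lags ($|\Delta W| \to A_\pm$ as $\Delta T \to 0^\pm$), so
the weight path settles into a small limit cycle of amplitude about
$|A_\pm|$ per trial. Close to the lower clipping bound the latency
sensitivity $1/(w-1)^2$ amplifies this cycle into output-time oscillations
of order a millisecond. Tests therefore judge the plateau by trailing
windows (range of the last 20 trials, mean of the last 10
desynchronisations), not by a single final trial.

## Synthetic data

`generate_spike_classes()` emulates the benchmark the detector is evaluated
on: two labelled clouds of 3-channel spike-time patterns. Class 1 is an
isotropic Gaussian (default $\sigma = 1$ ms) around an anchor; class 2 is
the same Gaussian around a centroid displaced a perpendicular distance
$D_c$ from the class-1 axis (direction $(1,1,1)/\sqrt 3$ through the
anchor). Defaults are 120 and 20 patterns. The anchor is not prescribed by
the source description; the package uses $(12.5, 12.5, 12.5)$ ms, the
latency-range centre that the standard initialisation ($A = 1$,
$w = 1.08$, $d = 0.04$) is built around. The displacement direction is a
seeded random unit vector orthogonal to the axis — only the distance, not
the direction, is specified. Patterns falling outside $[0, 25]$ ms are
resampled rather than clipped, preserving the Gaussian shape near the
boundary (clipping would pile mass on the edges); a generous attempt cap
turns pathological configurations into errors.

What the generator does *not* emulate: real magnetoencephalography trials —
their non-Gaussian noise, inter-trial drift, artifacts, or the
channel-selection step that picks an informative sensor triad. Only the
encoding of a sampled time series into one spike per channel is provided
(`encode_peak_times()`: the within-window maximum, earliest sample on ties,
shifted to the window start and scaled — by default a 0.25 s window maps to
25 model ms), exercised on synthetic bump signals. Passing tests therefore
certify the detector and its learning dynamics on idealised Gaussian
timing classes, not performance on recorded brain data.

## The evaluation protocol

`run_mnsd_experiment()` follows the two-class protocol end to end:
generate 120 + 20 patterns, train on the first 100 of class 1 (weights
free), freeze, test on the remaining 20 + 20 with class 1 positive and a
target spike counting as a positive call. `classification_metrics()`
computes accuracy, precision and recall from the confusion counts, flagging
zero-denominator metrics as undefined (`NA`) rather than silently zero.
`mnsd_sweep()` crosses $D_c \in \{2, 3.5, 5\}$ with
$L_d \in \{0.25, 0.37, 0.55\}$ over five seeds by default, reusing the same
seeds in every cell (common random numbers, so cell contrasts are free of
generator noise).

The accuracy ceiling of this benchmark follows from the coincidence-window
analysis above. At $\sigma = 1$ ms the class-1 patterns have a mean
output-time range of about 1.7 ms, while an admissible target weight at
$L_d = 0.37$ caps the window at 1.4 ms: a large share of the trained class
falls outside its own hypervolume, and measured accuracy at
$(D_c = 5, L_d = 0.37)$ sits near 0.56–0.68 depending on $w_T$, improving
with $D_c$ but far from ceiling. Inadmissible target weights fare no
better: the two-pulse window then accepts class-2 patterns whose
displacement leaves one channel pair untouched. This is a property of the
detector's geometry at these study conditions, not a defect of the
implementation; the sweep's monotone improvement with $D_c$ — the
qualitative claim — holds robustly and is what the acceptance test can
assert truthfully.

## Numerical and interface conventions

* Model state at exactly threshold counts as active, with latency
  $t_{f,\max}$ — the boundary case of both regimes agrees there.
* State reset between trials: every presentation starts from rest. Trials
  in the motivating experiments are separated by intervals two orders of
  magnitude beyond $t_{f,\max}$, and the static analysis assumes rest.
* Partial sequences (missing channels) are legal at prediction time and
  rejected during learning.
* Sequence files are UTF-8 tab-separated text (`trial`, `channel`, `time`,
  `label`); models serialise to flat `key value` text. Numerics are written
  with 17 significant digits, so write–read–write cycles are byte-stable.
* The command-line wrapper (`inst/cli/mnsd`) exposes
  `generate | train | test | sweep | simulate` over the exported functions,
  with flag > config-file > default precedence and exit codes 0/1/2
  (success / user error / internal error).

## Problem sizes used by the shipped tests

Chosen as the package's own benchmark scale: 1000 random state–interval
pairs for the countdown identity; 100 random networks against the
clock-driven reference; 100-trial single-sequence training for the
stabilisation check (trailing-20-trial range under 10 % of the total
excursion, aggregated over branches — a per-branch ratio would be ill-posed
for a branch that starts at its equilibrium weight); the full
120 + 20-pattern protocol over five seeds for the classification sweep.

## Known limitations

* The selectivity/robustness trade-off described above: admissible target
  weights bound the jitter tolerance by $(1+d)/(2 L_d)$ ms; robust
  detection of widely jittered sequences requires small $L_d$.
* Learning assumes every branch fires each training trial; silent-channel
  trials would stall the affected junctions (they are rejected instead).
* The heterosynaptic rule couples nearest neighbours only; channel order
  therefore matters to the learning dynamics (though not to detection).
* Event-driven simulation is exact but pure R; it is sized for structures
  of a handful of neurons and thousands of trials, not for large networks.
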