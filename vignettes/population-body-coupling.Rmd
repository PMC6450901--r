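---
title: "Linking population coupling and body-movement coupling in motor cortex recordings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking population coupling and body-movement coupling in motor cortex recordings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(popcoupling)
```

## The question and the measures

Motor cortex contains neurons that fire in lockstep with the surrounding
population and neurons that fire almost independently of it. This package
implements an analysis chain that asks how a neuron's coupling to the
*population* relates to its coupling to the *body*: are the neurons that drive
movement the ones embedded most strongly in the collective activity, or the
more independent ones?

**Population coupling.** Spike trains are binned (default 0.25 s, half-open
bins, trailing partial bin dropped) and each unit's coupling is

$$C_{\mathrm{pop},i} \;=\; \frac{1}{N_i}\sum_{t=1}^{T} f_i(t)\,P_i(t),
\qquad P_i(t) \;=\; \sum_{j\neq i}\bigl(f_j(t)-\mu_j\bigr),$$

with $f_i(t)$ the spike count of unit $i$ in bin $t$, $N_i$ its total spike
count and $\mu_j$ the mean count of unit $j$. The statistic is a spike-weighted
average of the mean-subtracted summed activity of the rest of the recorded
group: dimensionless, typically positive, negative for units that fire against
the crowd. Because it is estimated from the recorded group, recordings with
fewer than 5 units are excluded, as are units firing below 0.5 Hz over the
session (whole-session rate; the analysis does not attempt sub-period rates).
Bin widths of 0.1, 0.05 and 0.01 s are exposed for robustness checks, and the
statistic can be recomputed on arbitrary bin subsets — first versus second
half of a session, or rest versus motion bins, where a bin counts as motion
when its mean body speed exceeds the whole-session mean (the split operates
on concatenated bins, not contiguous epochs).

**Body coupling.** Movement is measured by eight reflective beads tracked in
3D at 100 Hz. Positions are low-pass filtered at 5 Hz (4th-order Butterworth
run forward and backward, so zero phase) and differentiated by central
differences; the mean body speed is the arithmetic mean of the eight bead
speeds. Three per-unit measures quantify movement involvement, all built on
triggered averages over lags $\pm 1$ s at 10 ms resolution, low-pass filtered
at 1.5 Hz:

* **BC_M** — the SD of the movement-triggered-average spike rate, where
  triggers are movement onsets and cessations (upward and downward crossings
  of the session-mean speed), each waveform normalized by its own mean, and
  BC_M is the mean of the onset and cessation SDs.
* **BC_S** — the SD of the spike-triggered-average body speed, processed the
  same way.
* **BC_D** — the spike-triggered averages of 27 kinematic aspect series
  (center-of-mass speed; turning and rearing angular speeds from the body
  vector; and each bead's velocity relative to the center of mass, resolved
  along the rostrocaudal, right–left and vertical body axes), each z-scored
  per lag against 100 surrogate waveforms; BC_D is the largest across-time SD
  of the z-scored waveforms, and the argmax labels the unit's preferred
  movement aspect.

Significance of BC_M and BC_S compares the observed value with 1000 values
from circularly time-shifted spike trains (shift at least 30 s, modulo the
session), which preserve each train's rate and interval structure while
destroying its alignment with behavior; a unit is significant when it exceeds
95% of its surrogates, with ties not counting.

**The peaked-relationship test.** To test whether body coupling is a
non-monotonic, peaked function of population coupling, every observed
population-coupling value except the 10 smallest and 10 largest is tried as a
candidate peak $x^*$; Spearman correlations are computed to its left and
right; candidates failing $\rho_\mathrm{left}>0$ and $\rho_\mathrm{right}<0$
are discarded; the peakiness is $P=\min(\rho_\mathrm{left},
-\rho_\mathrm{right})$ at the best candidate, 1 for a noiseless perfect peak
and 0 when no candidate qualifies. The p-value comes from re-running the scan
on shuffled pairings. Per-session consistency is judged from a quadratic fit
(negative curvature with the maximum within 10% of the pooled peak, or a
one-sided slope pointing toward the peak when most of the session's range
lies on one side), and the count of consistent sessions gets its own
randomization p-value. Pooling across sessions can also be preceded by
dividing each session's values by their session medians, which removes
session-to-session scale variability.

## The network model

A 1000-neuron binary probabilistic model probes how population coupling
responds to inhibition and input. Neuron $i$ spikes at step $t$ with
probability $p_i(t)=\sigma\!\left([\eta + \sum_j W_{ij} s_j(t-1)]\,
r_i(t)\right)$, where $\sigma$ clips to $[0,1]$, $\eta$ is constant external
input, and $r_i(t)=(1+\chi+\alpha\sum_{\tau=t-T_r}^{t-1}s_i(\tau))^{-1}$ is an
activity-dependent divisive factor with $\alpha=0.1$ and $T_r=100$ steps;
$\chi$ shifts the divisor to model enhanced ($\chi>0$) or reduced ($\chi<0$)
local inhibition. The connectivity is built in four steps: lognormal weights
with variate mean 0.5 and variance 1 (underlying-normal parameters by moment
matching), 20% of columns negated (inhibitory neurons), per-row in-degrees
drawn lognormally (mean 20, variance 500; rounded, clipped to $[1, N-1]$,
retained inputs chosen uniformly, no self-connections), and finally division
by the spectral radius so the largest eigenvalue modulus is exactly 1.
Simulations start from silence, update synchronously, and truncate the
adaptation sum to the available history during warm-up. Population coupling
of model neurons is computed within 50 seeded disjoint subsets of 20 neurons
on 50-step count bins, mimicking the small recorded populations.

The spectral radius is found by power iteration on the sparse matrix with a
dense eigendecomposition as fallback (the dominant eigenvalue is real and
well separated for these ensembles, but the fallback guards the rare
complex-dominant draw). Sweeps hold one connectivity realization fixed per
seed across the grid and average summaries over seeds; three seeds at 20,000
steps reproduce the directional results stably, and the analysis scripts use
those sizes (the model's reference run length is 50,000 steps).

```{r model-demo, eval = FALSE}
p <- model_params(n_steps = 20000L)
run_model_preset("fig3c", p, seeds = 1:3)  # C_pop falls as chi rises
run_model_preset("fig3d", p, seeds = 1:3)  # C_pop falls as eta rises
```

## What the synthetic sessions emulate

`generate_session()` produces 30-minute sessions whose statistical structure
matches what the analysis assumes about the recordings: lognormal base rates
(median 2 Hz, floored just above the 0.5 Hz exclusion threshold), rest bouts
of mean 5 s alternating with movement bouts of mean 3 s, movement speed around
50 mm/s, and heading that swings during movement so the turning aspect is
exercised. Each unit's intensity is

$$\lambda_i(t) = \max\!\bigl(0,\; r_i\,[\,1 + a_i L(t) + g\, b_i u(t-\ell_i)\,]\bigr),$$

with $L(t)$ a shared low-pass-filtered unit-variance latent (300 ms
timescale) driving population coupling through the gains $a_i$, and $u(t)$
the standardized body speed driving body coupling through the gains $b_i$.
Spikes are drawn by thinning against the per-unit intensity ceiling, which is
exact given the rate bound; the rectification $\max(0,\cdot)$ guarantees a
valid intensity but biases the realized rate upward for gains near 1 (about
5–10%), which the tests account for.

Two generator choices deserve explanation:

* **Movement gain $g = 0.3$** (a unit with $b_i = 1$ modulates its rate by
  30% per SD of body speed). Movement-locked firing contributes to pairwise
  covariance exactly like the latent drive, so an equal-scale movement drive
  would let the planted body-coupling hump dominate $C_\mathrm{pop}$ itself
  and push the planted peak to the edge of the measured range — the opposite
  of the structure seen in vivo, where population coupling is set mainly by
  the network embedding. Tens-of-percent movement modulation against
  order-unity shared fluctuations is the realistic regime.
* **Within-bout speed structure.** Movement speed is the smoothed bout
  indicator multiplied by a lognormal envelope fluctuating on a sub-second
  timescale. Real locomotion is bursts of accelerations, not a plateau; and a
  plateau would be invisible to BC_S, whose waveform is normalized by its own
  mean — a unit firing only during featureless sustained movement has a flat
  spike-triggered speed waveform. That blind spot is a property of the
  measure, not of the implementation.

Because both drives genuinely induce population covariance and the generator
makes no attempt to orthogonalize them, parameter recovery is validated on
sessions that isolate one drive at a time ($a$ spanning 0–1 with $b=0$, and
vice versa). The multi-session fixture `generate_peaked_population()` spans
the latent gains evenly, makes the movement gains a Gaussian hump (width 0.2)
of the latent gain centred at a fractional position `peak_location`, adds
noise, and jitters each session's rate scale by a factor of 0.5–2 to give
median normalization something to correct. Since $C_\mathrm{pop}$ is close to
affine in the latent gain, the realized peak sits at about that fractional
position of the measured range.

What passing tests on these sessions do **not** show: the generator is
stationary, has no drug conditions, no electrode drift or sorting errors, no
postural idiosyncrasies, and its bead geometry is a rigid chain with jitter —
under rigid turning, the lateral relative-velocity aspects are perfectly
degenerate with the turning angular speed, so "preferred aspect" recovery is
only defined up to that family. Conclusions about real recordings need the
real data.

## Numerical choices

* **Filtering.** All low-pass steps use a 4th-order Butterworth applied
  forward–backward. The series is demeaned and padded by odd reflection
  before filtering; without this, the recursive filter's zero initial
  conditions leak a transient proportional to the absolute signal level
  (bead coordinates sit tens of millimetres from the origin).
* **Differentiation.** Central differences at the native 100 Hz, matching
  the filter bandwidth and avoiding a half-sample phase shift; azimuth is
  unwrapped before differencing so turning speed is continuous across
  $\pm\pi$.
* **Body vector.** The principal axis of the three centered points (center
  of mass, head bead, neck-base bead), computed by a vectorized power
  iteration warm-started at the head-minus-neck direction and oriented so
  the head projects positively; a vertical body vector leaves the azimuth
  undefined and is logged as a gap.
* **Relative bead velocity** subtracts the center-of-mass velocity before
  projecting onto the body axes; re-expressing lab-frame velocity without the
  subtraction would let whole-body translation leak into all 24 components.
* **Event detection** adds a 100 ms dwell requirement and a 0.5 s same-type
  refractory period to the mean-crossing rule; raw crossings chatter on
  realistic speed noise. A suppressed event removes its paired opposite
  event, so onsets and cessations always alternate. Events within 1 s of the
  session edges are dropped, as are triggered-average windows that would
  cross an edge.
* **Surrogate waveforms** are computed circularly: one FFT cross-correlation
  per unit and series yields every circular-shift surrogate waveform as a
  slice, which is what makes 1000-surrogate significance and 100-surrogate
  z-scoring affordable. The observed waveform drops edge windows; in a
  30-minute session the edge windows hold well under 1% of spikes, so the
  observed and surrogate statistics remain exchangeable to that order.
  Surrogate waveforms for BC_D are low-pass filtered exactly like the
  observed one before z-scoring; lags where the surrogate SD vanishes get
  z = 0 and are logged.
* **Peakiness details.** "At least 10 extreme points" is implemented as
  excluding exactly the 10 smallest and 10 largest observed values from the
  candidate set; points tied with a candidate belong to neither side;
  Spearman uses average ranks. The permutation p-value uses the add-one,
  tie-counting estimator $(1+\#\{P_\mathrm{shuffle}\ge
  P_\mathrm{obs}\})/(1+n)$: it cannot return zero, and counting ties keeps
  the p-values super-uniform under the null even though the peakiness has an
  atom at zero (a strictly-greater rule would cap null p-values around 0.77
  and overstate mid-range significance). The "within 10%"
  criterion of the session fit is measured against the pooled range of
  population coupling, the natural scale of the fit's x axis.
* **Significance** uses the strict fraction rule (`bc` must exceed 95% of
  surrogates), so ties at the threshold fail; under exchangeability the
  false-positive rate is $\lceil 0.05 n\rceil$-th-order-statistic exact,
  about 5%.
* **Degenerate inputs.** A waveform whose mean is zero (no spikes near any
  trigger, or identically zero speed) yields a zero coupling value with a
  degenerate flag; units with fewer than 5 events or 50 full-window spikes
  get `NA` with an explanatory flag; zero-spike units are an error in the
  user-facing population-coupling path and `NA` in the model path, where
  silent neurons are expected.

## Problem sizes used by the test suite

The suite exercises the full chain at sizes a desktop run completes in
minutes: the null calibration of the permutation test uses 200 datasets of 60
points at 200 shuffles; the surrogate false-positive calibration uses 500
null units in one 30-minute session at 200 surrogates; the model sweeps run
20,000 steps with three connectivity seeds; end-to-end peak recovery uses 20
cohorts of 5 sessions of 40 units. BC_D has no per-unit significance
criterion — only the score and the preferred-aspect argmax are reported.

## Known limitations

* The peakiness scan needs more than 20 points and at least 10 points on each
  side of any candidate, so very small pooled sets cannot be tested.
* BC_S cannot see firing locked to featureless sustained movement (see
  above); BC_M inherits the arbitrariness of the mean-crossing event
  definition, softened here by dwell and refractory rules.
* The rigid-chain generator cannot produce independent per-bead motion, so
  the 24 relative-velocity aspects carry less independent information than in
  real posture data.
* The model's population coupling at very low input is estimated from few
  spikes and is accordingly noisy; sweeps average over seeds.
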