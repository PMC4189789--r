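---
title: "Quantifying whisker-evoked cortical responses and gap-cross tactile learning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying whisker-evoked cortical responses and gap-cross tactile learning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(barrelgap)
```

`barrelgap` implements two measurement pipelines that are usually run on the
same animals: (i) Fourier quantification of whisker-evoked intrinsic optical
signals (OIS) in barrel cortex, and (ii) a closed-loop gap-cross assay of
whisker-dependent tactile learning, together with the statistics that compare
genotypes on both readouts. Because neither raw imaging stacks nor behavioral
rigs are available to a package, both pipelines are paired with generative
models — an imaging phantom and a behavioral agent — with exactly known ground
truth, so that every stage can be verified end to end.

## 1. The Fourier readout of intrinsic signals

### Model

Under periodic whisker stimulation (a brief deflection train delivered once
per repetition period, e.g. every 20 s, repeated ~35 times while imaging at
10 frames/s), active cortex modulates its reflectance at the known repetition
frequency $f_s = 1/T$. For a pixel time series $x_t$ ($t = 0,\dots,n-1$,
sampling rate $f_r$), the package computes the discrete Fourier coefficient
of the mean-subtracted series at the stimulus bin $k = f_s\,n/f_r$ and reports

$$\widehat{\Delta R/R} \;=\; \frac{2\,\lvert X(k)\rvert}{n\,\bar{x}},
\qquad \hat\varphi = \arg X(k),$$

i.e. the fractional amplitude of the stimulus-locked sinusoid, normalised by
the pixel's own temporal mean. The factor $2/n$ converts a one-sided DFT
coefficient into a sinusoid amplitude; per-pixel mean normalisation is the
standard convention for reflectance imaging and makes recovery on a phantom
exact. Two deliberate strictnesses:

* **Whole-cycle precondition.** The acquisition must span an integer number
  of repetition periods, so that $k$ is an integer bin. Off-bin stimulus
  frequencies are *rejected*, not estimated: spectral leakage would bias
  amplitudes silently, and with 35 repeats there is no reason to accept a
  truncated record.
* **Detrending.** Mean subtraction only, by default. A nonzero bin is already
  insensitive to constant offsets; a `detrend = "linear"` option exists for
  stacks with strong monotone drift (a ramp leaks $O(1/k)$ into every bin).

Pixels with numerically zero temporal mean cannot be normalised; they are
flagged `NaN` and excluded from all downstream counting.

The whole 35-repeat acquisition is analysed as one continuous series; no
per-cycle averaging is performed, since the single-bin readout already pools
all cycles with the correct phase alignment.

### The responsive region

The size of the responsive region is summarised as a *threshold curve*: for
an ascending grid of $\Delta R/R$ values, the number of pixels whose
magnitude strictly exceeds each threshold. No region-growing or contiguity
constraint is applied — the curve is a property of the full (optionally
ROI-masked) field. The default grid is 10 evenly spaced values between the
50th and 99.5th percentile of the magnitude map; published axes for such
curves are rarely reported exactly, so the grid is always overridable.
Genotype comparisons of curves use a two-way fixed-effects ANOVA on pixel
counts with group and threshold as factors.

### The imaging phantom

`generate_ois_stack()` builds a frames × rows × cols reflectance array where
pixel $(r,c)$ carries a stimulus-locked fractional amplitude

$$A(r,c) = A_{peak}\exp\!\big(-d^2/(2\sigma^2)\big),$$

with $d$ the distance to the blob centre — a compact, smooth response region
of the kind a single whisker's barrel produces — over baseline reflectance,
plus white sensor noise, a one-cycle-per-acquisition drift, and additive
"physiological" confound sinusoids on non-stimulus bins (respiration and
heartbeat surrogates). Defaults: 700 frames at 1 Hz with the stimulus at
0.05 Hz — i.e. 35 cycles of the 20 s repetition period on a compressed time
base, since the readout consumes only frequency ratios, never absolute
durations; 64×64 px; peak $\Delta R/R$ of $10^{-3}$ (the order of magnitude
of intrinsic signals); baseline 2000 camera units (mid-range of a 12-bit
sensor); noise SD 2 camera units.

Choices worth recording:

* The temporal waveform is a **pure sinusoid** at $f_s$, not a rectified
  on/off hemodynamic response, because the analysis reads only the
  fundamental component and a pure tone makes ground truth exact. A
  `waveform = "boxcar"` mode (on for a configurable duty fraction of each
  period) is available for more realistic episodic responses; its
  fundamental-frequency content is then only approximately the configured
  peak, so exactness tests use the sinusoid.
* Confound defaults sit at 7× and 9× the stimulus frequency. At the
  compressed default geometry the classic ~1.5 Hz heartbeat surrogate (30×
  a 0.05 Hz stimulus) would exceed Nyquist; at real 10 frames/s timing it
  fits, and any bin-aligned sub-Nyquist frequencies may be configured. The
  validator refuses confounds that collide with the stimulus bin.
* The blob must fit inside the image at $3\sigma$, so that the configured
  peak is actually realised in-field.

### What the phantom does and does not establish

Tests against the phantom establish *estimator* correctness: exact recovery
without noise (to ~$10^{-11}$ relative), bin-orthogonal rejection of
confounds and drift, and unbiased recovery under white noise. Real OIS data
differ in ways the phantom deliberately omits: correlated (vascular) noise,
hemodynamic waveform shape, photobleaching, motion. Passing tests therefore
validate the arithmetic of the readout, not robustness to every in-vivo
artifact — which is the appropriate scope for a reimplementation of the
analysis rather than of the preparation.

Two numerical facts shape the test design here. First, in double precision
the far Gaussian tail of the truth map (≈ $10^{-20}$ at the corners of a
64×64 field) sits below the FFT's round-off floor, so "exact recovery" is
checked on a 16×16 phantom whose dimmest pixel ($\sigma = 2.5$, peak 0.01)
stays well above that floor. Second, the *modulus* estimator is
Rice-distributed: where the true amplitude is comparable to the per-bin
noise, $E\lvert\hat A\rvert > A$ (bias $\approx \sigma^2/2A$), an intrinsic
property of magnitude estimators, not an implementation defect. Unbiasedness
is therefore checked on the in-phase projection
$\hat A \cos\hat\varphi$ (the phantom's tone has phase 0), whose sampling
distribution is Gaussian around truth. With 256 pixels checked
simultaneously, a bare per-pixel 2-SE band would be exceeded somewhere by
chance in essentially every run, so the per-pixel z-scores (which follow a
$t_{99}$ law, verified by a pooled-tail check during development) are held
to the Bonferroni band at ~0.1% familywise error, $|z| < 5$, while their
median must stay within 2 — the per-pixel statement for the typical pixel.

## 2. The gap-cross engine

### Assay structure

A mouse on an elevated home platform in darkness crosses a variable gap to a
target platform. Four motion sensors (1 home rear, 2 home edge, 3 target
edge, 4 target rear) segment behavior; the controller alternates two states:
*exploration* (sensors acquire one trial at the current distance) and
*adjustment* (doors close, platforms move to the next distance). A trial is
a **success** iff sensor 4 is reached, a **failure** iff the mouse reaches
the home edge (optionally touching the target edge) and returns to the home
rear without reaching 4; other sequences are incomplete and produce no
trial. Sessions run to 20 successes or 20 simulated minutes, 12 sessions per
experiment, every session opening at 3.0 cm.

### The adaptive distance algorithm

After each trial the next distance is drawn uniformly from the 0.5 cm grid
spanning 1.0 cm below to 1.5 cm above the *maximum distance successfully
crossed so far in the session*, clamped to [3.0, 7.0] cm. Decisions the
published rule leaves open, resolved here:

* Before the first success of a session the maximum is undefined; the
  engine substitutes the opening distance (3.0 cm), giving the early-session
  window [3.0, 4.5] — consistent with every session starting at 3.0 cm.
* The maximum updates on successes only; failures (even at distances above
  the current maximum) never move the window.
* Distances are held internally as integers (tenths of a cm), because exact
  set membership on the grid is load-bearing for the candidate window;
  floating-point grids invite membership bugs at e.g. 4.5 = 3×1.5.

### Clock and termination

Each trial charges the simulated clock its sensor-event span plus a drawn
inter-trial interval (uniform, mean ± jitter); the timeout test runs
*between* trials, so a trial in progress at the limit completes — published
descriptions do not specify mid-trial cutoff behavior, and completing the
trial keeps accounting simple (successes + failures = trials, rewards =
successes, always).

### The behavioral agent

The simulated mouse succeeds with probability

$$p = (1-\lambda)\,\mathrm{logistic}\big(\beta_0 - \beta_1 d + L_{c(d)}(s-1)\big)$$

at distance $d$ (cm) in session $s$, with lapse rate $\lambda$, and a
learning rate $L$ that depends on the distance class $c(d)$: *nose*
(≤ 4.5 cm, where the target is detectable by nose touch) or *whisker*
(≥ 5.0 cm, whiskers only). Linear-in-logit learning per session is the
simplest monotone model that yields block-wise improvement. Failures emit
the two canonical retreat shapes (1→2→1 and 1→2→3→2→1) with equal
probability, since both occur in practice.

Default parameters — chosen once, as a plausible cohort, and used by all
simulations: $\beta_0 = 2.7$, $\beta_1 = 0.6$/cm (session-1 success falls
from ~85% at 3.0 cm to ~30% at 6.0 cm, reproducing the characteristic
decline with distance), $\lambda = 0.02$, $L = 0.25$ logits/session at nose
distances for both genotypes, and at whisker distances 0.25 for WT but **0
for KO** — the whisker-specific learning deficit the assay was built to
detect. Between session blocks (1–6 vs 7–12) these rates produce mid-teens
to mid-twenties percentage-point improvements where learning is present.
Inter-trial interval 30 ± 10 s and 5 s crossings give sessions that
typically reach the 20-success quota in 25–35 trials, within the 20-minute
budget.

The agent is plumbing, not biology: it has no spatial memory, no fatigue,
no inter-individual variability beyond sampling noise. It exists so the
engine and statistics can be exercised against a known generative truth.

## 3. Learning statistics

Trial logs aggregate to a success table (counts per mouse × session ×
distance), then to block rates: percent successful crossings per mouse,
distance and session block, **pooling trials across the block's sessions**
(robust to sessions where the adaptive algorithm offered a distance only a
few times; per-session averaging is available via `pool = "per_session"`).
Analysis is restricted to 3.0–6.0 cm, the range with dense coverage; the
grid's 6.5/7.0 cm trials are recorded but not analysed. The per-mouse
improvement of a distance class is the late-minus-early rate difference
averaged over the class's distances that have data in both blocks; cells
with no trials are marked missing, warned about, and excluded.

The block × distance repeated-measures ANOVA treats each mouse-by-distance
cell as a matched subject measured in both blocks
(`aov(rate ~ block * distance + Error(mouse:distance))`), so the block
effect is tested on $F(1, k(n-1))$ for $n$ mice and $k$ distances — e.g.
$F(1,15)$ for 6 mice × 3 distances, $F(1,24)$ for 9 × 3. This df convention
matches how such designs are commonly analysed in prism-style behavioral
statistics, and with only two block levels the within factor has a single
degree of freedom, so no sphericity correction can alter it — which is why
the package offers none. Genotype contrasts use a two-sample, two-tailed
Student t-test on per-mouse class improvements.

One classification choice is configurable: 4.5 cm sits at the boundary of
nose reach. The default nose class is {3.0, 3.5, 4.0, 4.5} (exhaustive over
the analysed range); `default_classes(nose_includes_4.5 = FALSE)` gives the
strict three-distance classes.

## 4. Verification design and problem sizes

Every operation with a closed form or a cheap exhaustive counterpart is
tested against one: a literal DFT sum for the Fourier readout; pixel-wise
scans for threshold curves; grid enumeration for candidate sets; a
from-scratch sums-of-squares decomposition for the RM-ANOVA. Statistical
calibration is checked by simulation: under no-learning nulls the block
ANOVA and improvement t-test hold their 5% size (1,000 replicates of
6-mouse cohorts, binomial cell counts around the agents' stationary
distance profile); with the default two-genotype cohort (6 WT, 9 KO —
a realistic study's group sizes), 200 full-pipeline replicates reproduce
the four-way outcome structure (significant WT nose, KO nose and WT whisker
block effects; non-significant KO whisker; significant WT-vs-KO whisker
improvement difference) in well over half of replicates. Phantom exactness
uses 16×16 × 200-frame stacks, uniformity checks 40,000 draws per grid
point, and the session fuzz runs 1,000 random agents — sizes chosen so the
full suite completes in a few minutes on one CPU while leaving every check
statistically meaningful.

`scripts/acceptance.R` re-runs these measurements from scratch against the
installed package and writes them as JSON; see the README for invocation.

## 5. Known limitations

* The phantom's noise is white; vascular and motion artifacts of real OIS
  stacks are out of scope, as are registration and vessel masking.
* The agent's learning is deterministic in rate; real cohorts show
  inter-animal variability in both baseline and learning, which the
  statistics would absorb into the subject terms but the generator does not
  emit.
* The engine simulates the rig's logic, not its hardware: no servo/feeder
  timing, no sensor noise or missed triggers (replay validation exists to
  audit real logs for exactly such inconsistencies).
* `compare_threshold_curves()` treats per-threshold counts as independent
  observations, as fixed-effects ANOVA on such curves conventionally does;
  counts from a single map are in truth correlated across thresholds, so
  its p-values are calibrated under its own assumptions, not under map
  resampling.
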