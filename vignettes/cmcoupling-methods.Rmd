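---
title: "Estimating cortico-muscular coupling with kNN mutual information and transfer entropy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating cortico-muscular coupling with kNN mutual information and transfer entropy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cmcoupling)
```

## The problem

Pulsed transcranial ultrasound stimulation (pTUS) of motor cortex elicits
muscle activity, and the interaction between the cortical oscillation (local
field potential, LFP) and the evoked electromyogram (EMG) — cortico-muscular
coupling (CMC) — quantifies how strongly the motor command circuit is
engaged. Because the cortico-muscular system is nonlinear, model-free
information-theoretic measures are the natural tools: mutual information
(MI) measures the total (symmetric) statistical dependence between the two
signals, and transfer entropy (TE) measures directed, time-asymmetric
predictive information transfer, separately for the descending (cortex to
muscle) and ascending (muscle to cortex) pathways. The experimental design
this package supports varies the number of ultrasound tone bursts per train
(NTB, equivalently the sonication duration at a fixed 1 kHz pulse
repetition frequency) and asks how the coupling changes with it.

No public recordings accompany that design, so the package pairs the
analysis chain with a synthetic-data generator that emulates its structure;
all validation is property-based, against analytically known oracles and
simulated ground truth.

## Estimators

### Mutual information

For continuous samples the package uses the Kraskov–Stögbauer–Grassberger
(KSG) k-nearest-neighbor estimator, algorithm 1:

$$\widehat{MI} = \psi(k) + \psi(n) - \big\langle \psi(n_x + 1) + \psi(n_y + 1) \big\rangle,$$

where the neighborhood of each point is the max-norm ball reaching its
$k$-th joint neighbor and $n_x, n_y$ count strictly closer points in each
marginal. $k = 4$ throughout, matching standard practice. Internal units
are nats (the digamma form is natural in them); `couplingValue(est,
"bits")` converts. Negative estimates on weakly dependent data are
finite-sample bias and are deliberately not clipped, so that trial
averages remain unbiased. Exact ties are broken by a deterministic
micro-jitter (uniform, amplitude $10^{-10}$ SD, fixed internal sub-seed), so
every estimate is bit-reproducible. A discrete plug-in entropy/MI pair
(`entropyDiscrete`, `miPluginDiscrete`) provides exact oracles for testing.

Whether MI should be computed on raw samples or on embedded states is a
genuinely open choice; the package follows the simplest reading — raw
scalar samples within each trial — and exposes embeddings only through the
TE API. Serial correlation within a trial is handled with a Theiler
exclusion window (neighbors closer in time than the window are ignored).

### Transfer entropy

TE from source $x$ to target $y$ is computed as the conditional mutual
information

$$TE_{x \to y}(u) = I\!\big(y_{t+u};\, x^{d_x,\tau_x}_t \,\big|\, y^{d_y,\tau_y}_t\big),$$

with uniform delay embeddings $x^{d,\tau}_t = (x_t, x_{t-\tau}, \ldots,
x_{t-(d-1)\tau})$ and a prediction time $u$ that absorbs the physiological
conduction delay. The estimator is the Frenzel–Pompe/KSG nearest-neighbor
digamma form with max-norm neighborhoods in the joint space, projected
counts in the three marginal spaces, and Theiler exclusion. The
higher-order Markov formulation of TE is subsumed by these uniform
embeddings — the standard move for continuous signals.

Embedding parameters are selected by the Ragwitz criterion: minimize the
cross-validated mean-squared error of a k-nearest-neighbor local-constant
one-step predictor over a $(d, \tau)$ grid. Because that MSE is itself a
noisy estimate, selection applies the one-standard-error parsimony rule
familiar from cross-validation: the smallest $(d, \text{then } \tau)$ whose
MSE is within one standard error of the grid minimum wins. Without this
rule the argmin is decided by query noise on Markovian series and the
selected dimension is essentially random; with it, an AR(1) process almost
always selects $d \le 2$ while a deterministic period-4 cycle still forces
$d = 2$. Default search ranges are $d \in 1..6$, $\tau \in 1..10$ samples.

The prediction time is scanned over 10–49 ms in 1 ms steps (the
physiologically motivated conduction-delay range), and the $u$ maximizing
TE is selected, ties toward smaller $u$. Within the pipeline, TE profiles
are estimated per trial and averaged before the argmax — per-trial
estimation followed by aggregation is the package-wide policy.

### Theiler window

Default: the first zero crossing of the signal's autocorrelation, capped at
100 samples (50 ms at 2 kHz). This removes serially correlated neighbors
from all counts without discarding usable data.

### Statistics

Surrogate significance uses circular time shifts of the source (uniform
random shift of at least the Theiler window/prediction time), which
preserve each signal's autostructure while destroying the alignment;
$p = (1 + \#\{TE_{surr} \ge TE_{obs}\})/(1 + n_{surr})$ with at least 19
surrogates. Condition comparisons use classical one-way repeated-measures
ANOVA (subjects as blocks; $F = MS_{cond}/MS_{err}$ on
$(c-1, (c-1)(s-1))$ df). Amplitude–coupling association uses Pearson
correlation with the $t$-based two-sided p. The significance level is 0.05
everywhere; no multiple-testing correction and no sphericity correction are
applied by default, the prevailing convention in small-n CMC studies.

## The synthetic generator

`genCMCRecording` emulates a stimulus-locked paired recording at 2 kHz with
triggers every ITI = 3.6 s:

* **LFP** — a unit-SD broadband 0.5–200 Hz process $z_t$ (FFT-masked white
  noise; IIR designs are numerically ill-conditioned at such low normalized
  edges), a narrowband low-beta rhythm (13–19 Hz, amplitude 0.8), 1/f-like
  noise (amplitude 0.3), slow 0.2 Hz drift and 50 Hz line contamination at
  10% of signal RMS each.
* **EMG** — a rate-modulated broadband carrier: the motor activation
  $a_t = \max(1 + g_d \cdot 0.3 \cdot \text{drive}_{t}, 0.05)$ multiplies
  10–200 Hz muscle noise, where the drive is the conduction-delayed beta
  rhythm plus the delayed rectified broadband core (equal weights,
  normalized). Intrinsic muscle noise (SD 0.5) is added, and that intrinsic
  component feeds back into the LFP with gain $g_a$ at the same delay —
  the ascending pathway.
* **Stimulation effect** — in the post-stimulation phase both gains are
  multiplied by $1 + s \cdot NTB$ with slope $s = 0.006$ per tone burst
  (multipliers 1.6–2.8 across NTB = 100..300), and the same multiplier
  scales the beta-rhythm amplitude: stimulation raises cortical
  excitability, which is what makes the LFP amplitude co-vary with the
  coupling and gives the amplitude–MI/TE correlation analyses something
  real to detect. With slope 0 the pre and post records are bit-identical
  under the same seed.

Why this shape: EMG electrodes record motor-unit activity whose *rate* is
modulated by the descending drive, so a modulated-carrier model is the
physiologically standard choice, and — importantly for the analysis chain —
band-pass filtering followed by full-wave rectification demodulates it, so
the mandated preprocessing is exactly what makes the coupling visible. The
beta-band rhythm shared (with delay) between cortex and muscle is the
classic corticomuscular-coherence channel and is what zero-lag MI detects
after rectification; the broadband component, which decorrelates within a
couple of milliseconds, is what localizes the TE prediction-time peak at
the conduction delay. The 13–19 Hz band is chosen so the rhythm's
anti-phase ambiguity (half a period, ~31 ms) falls outside the 10–49 ms
scan window.

Defaults, fixed once: descending gain 1.0, ascending gain 0.3 (feedback
weaker than drive, as in vivo), conduction delay 25 ms (center of the scan
range, so the optimization is exercised away from grid edges), intrinsic
EMG noise SD 0.5, line/drift at 10% RMS, 30 trials per record.

**Known limitation — oscillatory sources bias the prediction-time scan.**
When the delayed drive is dominated by a narrowband rhythm, the TE profile
over $u$ is warped: the target's own past partially predicts the rhythm,
and that conditioning removes most information exactly where the rhythm's
self-correlation at lag $u$ peaks, producing sidelobes and a dip at the
true delay. This is a property of conditional-MI estimators on coherent
oscillations, not of this implementation. Conduction-delay recovery is
therefore validated on recordings with purely broadband descending
coupling (`oscAmp = 0`); with the default rhythm present, the scanned $u$
is reproducible but biased by a few milliseconds and should be read as an
effective, not anatomical, delay.

What the generator does *not* emulate: evoked-response transients locked to
sonication onset, nonstationarity across the session, electrode drift or
motion artifacts, spike contamination, and any acoustic physics. Passing
tests therefore demonstrate estimator correctness and pipeline wiring
under a realistic stationary coupling model, not performance on artifacted
in-vivo data.

## Pipeline and report

`runFullStudy` simulates (or loads) pre/post recordings for each subject
and NTB level, preprocesses (50 Hz notch → moving-average baseline removal
→ band-pass 0.5–200 Hz LFP / 10–200 Hz EMG → EMG rectification → trial
cutting; all filters zero-phase forward-backward), estimates per-trial MI
and bidirectional TE (embeddings Ragwitz-optimized once per recording),
and aggregates: per-condition mean ± SD across subjects, repeated-measures
ANOVAs (pre vs post per NTB; across NTB post-stimulation; descending vs
ascending), and pooled per-trial amplitude–coupling Pearson correlations.
Subject-level latent gain multipliers (log-normal, SD 0.1) are reused
across conditions, honoring the repeated-measures design. Reports are
regenerable bit-identically from the stored estimates table via
`buildReport`.

Preprocessing decisions where the upstream description is loose: the
"adaptive high-pass" is implemented as centered moving-average baseline
subtraction (window 0.5 s, edge-reflected) — transparent and exactly
zero-phase; the notch is an RBJ biquad (Q ≈ 36, 1.4 Hz bandwidth) applied
forward-backward; band-passes are 4th-order Butterworth, forward-backward;
rectification is the absolute value and happens before trial cutting (a
flag defers it). Trial windows default to 1 s before the trigger and 1 s
after sonication ends, fitting comfortably inside the 3.6 s ITI.

## Numerical choices

* kNN searches are brute-force $O(n^2)$ max-norm scans in C++ with a
  running k-best selection — at the per-trial sizes involved (a few
  thousand samples, $k=4$) this outperforms tree structures and is exact.
* Tie handling everywhere is the deterministic micro-jitter described
  above; user RNG state is never touched (seeded draws are sandboxed).
* Degenerate inputs error early: constant series, NaN, length mismatches,
  too-short series for the requested embedding, unbalanced ANOVA designs
  (the offending cells are named).
* `analyticLinearTE` computes the linear-Gaussian TE exactly from the
  stationary covariance of the companion VAR (Lyapunov equation solved by
  doubling); the independent check in the test suite fits the full and
  reduced regressions on simulated data.

## Problem sizes used in validation

The automated checks run at desk scale, chosen to keep the full suite
within minutes while leaving comfortable statistical margins: Gaussian MI
at $n = 10^4$; TE–Granger comparison over 20 seeds at $n = 10^4$;
direction recovery over 50 seeds at $n = 5000$; delay recovery over 20
seeds with 6 trials of 1.5 s per recording; null calibration over 200
surrogate tests at $n = 1000$; NTB monotonicity over 20 seeds per level
with 4 one-second trials each; and a compact 3-subject end-to-end study.
The same sizes are used by `scripts/acceptance.R`.
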