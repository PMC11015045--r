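---
title: "Models and methods behind placecode"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind placecode}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(placecode)
```

# The analysis problem

`placecode` analyzes population calcium imaging recorded while a
head-fixed mouse runs laps on a 360 cm circular textile belt with a
hidden 30 cm reward zone (default `[240, 270)` cm). Licking a spout
inside the zone triggers a liquid reward. The neural input is a
neurons x frames matrix of non-negative deconvolved calcium event
amplitudes ("S"), with a per-neuron label marking projection neurons
(e.g., dorsal hippocampal neurons projecting to the nucleus accumbens)
against the remaining population. The package implements the complete
post-deconvolution pipeline: behavioral event extraction, place-cell and
place-field statistics with permutation nulls, speed and lick tuning
classification, a Poisson encoding model that defines conjunctive coding,
and linear decoding of reward/anticipation zones — together with a
synthetic session generator that provides ground truth for every stage.

The central container is `SpatialSession`, a `SummarizedExperiment`:
assay `"S"` holds the events, `colData` the frame-aligned behavior
(time, belt position, velocity, analog lick signal, reward pump, lap),
`metadata` the task geometry. Everything downstream consumes this one
object.

# Behavioral processing

**Downsampling.** Raw signals are aggregated into imaging-frame windows
with a statistic per signal type: mean (velocity), median (position, lap,
camera/scanner counters), maximum (reward pump — a single high sample
marks the frame), standard deviation (analog licking).

**Velocity.** Positions are unwrapped across laps and filtered with a
1-D constant-velocity Kalman filter (state: position and velocity; white
acceleration noise, default SD 40 cm/s²; measurement noise, default SD
0.5 cm). The defaults make a 5 cm/s ramp converge to within 1% inside
one second at 15.2 Hz; both noise parameters are exposed because no
canonical values exist for this rig class.

**Lick events.** Discrete lick events are local maxima of the analog
trace above a threshold, at least 0.33 s apart (taller peaks win). The
original per-session thresholds were set by inspecting synchronized
video and are unrecoverable from the signal; the default rule is
median + 4 x MAD of the trace, overridable per session. Bouts group
events < 2 s apart; appetitive onsets are bout starts preceded by at
least 3 s of lick silence; the consummatory onset is the first event
0.5–5 s after a pump trigger.

**Laps, zones, success.** All zones are half-open `[start, end)` cm
intervals with wrap-aware arithmetic; the anticipation zone spans the
30 cm before the reward zone. Relative licking is the rectified
cumulative analog lick signal per zone divided by the lap total. A lap
is successful when it is rewarded and at least 50% of its relative
licking falls in reward + anticipation; a session is high-success when
at least 50% of laps are successful (boundaries inclusive). The
"trial" of the original terminology is a session here.

# Spatial coding

**Rate maps.** The belt is divided into 45 bins of 8 cm. Only movement
frames (velocity > 2 cm/s) enter: occupancy `o` is the per-bin share of
movement frames, activity `a` the per-bin mean event amplitude. Unvisited
bins are stored as missing, not zero — silence is not fabricated — and
contribute nothing to the sums below.

**Spatial information and sparsity.**
$$SI = \sum_i o_i a_i \log_2 (a_i / \bar a), \qquad
\bar a = \sum_i o_i a_i, \qquad
\mathrm{Sparsity} = \frac{(\sum_i o_i a_i)^2}{\sum_i o_i a_i^2}.$$
Terms with $a_i = 0$ contribute zero. $SI$ as printed is already
activity-weighted; the information *rate* multiplies it again by the
movement firing rate (frames with events > 0 per second of movement) and
both are reported. Whether $\bar a$ is the movement-frame mean or the
occupancy-weighted map mean is ambiguous in the source description; the
occupancy-weighted form is used — the two coincide under this occupancy
definition.

**Place-cell test.** A neuron is a place cell when its SI exceeds the
95th percentile of 1000 shuffles. Each shuffle circularly shifts the
event trace by at least 500 frames (uniform up to T − 500; bounds adapt
with a message below 1000 frames), cuts it into approximately twice as
many contiguous blocks as laps run, and permutes the block order before
recomputing SI against the unshuffled behavior. One RNG substream per
neuron keeps verdicts reproducible and order-independent. The shuffle
inner loop is compiled (Rcpp) because it dominates runtime at 1000
shuffles x hundreds of neurons.

**Fields.** The 45-bin map is doubled (circularity), smoothed with a
Savitzky–Golay filter (window 5, order 2), and searched for peaks with
prominence ≥ 1.5 SD of the smoothed trace and boundaries at 0.8 relative
height with interpolated crossings; the most prominent peak is the
primary field, translated back modulo 45 when it extends into the
replicated half. A place cell without a qualifying peak keeps its flag
but is excluded (with a message) from field-geometry analyses.
Reliability is the fraction of active laps whose binned-activity maximum
falls inside the field; Δin–out the mean in-field minus out-of-field
activity; stability the mean Pearson correlation of consecutive laps'
bin vectors (an all-pairs variant is exposed; the pairing is not
specified in the source description). The field center (COM) is the
angle of the two-dimensional centroid of the polar rate map. Note that
for conjunctive cells the COM reflects *all* spatially structured
activity, including lick- or speed-driven components, and can sit
outside the injected Gaussian field; only singly place-tuned synthetic
cells recover their injected centers bin-exactly.

**Boundary ratio.** Bins within ±1 bin of a texture boundary are
transition bins (the smallest symmetric window at analysis resolution;
the width is configurable because no numeric value is given). The
statistic is the ratio of field starts (ends) in transition bins over
middle bins, compared with 1000 joint circular shifts of each field's
start and end (lengths preserved), with the 99.9th-percentile verdict.

**Overdispersion.** For each place field, passes are contiguous
movement-frame traversals of the field within a lap. `exp` is the mean
of all non-zero in-field events, `obs` the per-pass mean of non-zero
events, $z = (obs - exp)/\sqrt{exp}$, and overdispersion the variance of
z over passes with activity (≥ 2 required). Under Poisson pass
statistics the population-mean variance is 1.

# Speed and lick tuning

Speed tuning regresses per-neuron mean activity in 1 cm/s velocity bins
over `[2, 30)` cm/s on the bin centers; p-values are Benjamini–Hochberg
adjusted across the session's neurons (the correction unit is
configurable; the source description does not state it), and the class is
the slope sign at adjusted p < 0.05. A velocity bin must be occupied for
at least 1 s to enter the regression: with realistic speed
distributions, tail bins visited for one or two frames otherwise
contribute noise-dominated means with high leverage and inflate the
false-positive rate — this is the finite-sample analogue of dropping
unoccupied bins.

Lick modulation compares each neuron's mean activity 2 s before vs 2 s
after each appetitive onset with Wilcoxon's paired test (two-sided,
normal approximation); the window length is a package default — the
source defines it only in supplementary material. The population null
re-detects onsets on 100 circularly shifted copies of the analog lick
trace and re-classifies every neuron, yielding a null distribution of
population proportions; shift 0 is available as an identity sanity case.

# The Poisson encoding model

The response is built in the printed order: events divided by their
signal-to-noise ratio, then by the resulting SD, Gaussian-smoothed
(0.5 s window, SD 2 samples), averaged down to 3 Hz, and non-zero
samples mapped to quintile ranks. The design matrix holds 45 position
indicators (median-downsampled position), mean-normalized velocity at 19
lags spanning ±3 s in 1/3 s steps, and the appetitive-lick-bout
indicator (bouts farther than 5 s from any reward) at the same lags.

Fitting is Poisson log-link regression with no penalty, by IRLS on the
working normal equations with a 10⁻⁸ numerical ridge (the indicator
block plus intercept is rank-deficient; the ridge replaces pivoting) and
the linear predictor clamped to ±30. The data are split 80/10/10 into
train/validation/test by a *seeded random row split* — matching the
default splitter of the modeling library the procedure was defined
with. A contiguous-in-time split is retained behind a flag for
autocorrelation-leakage sensitivity checks; it was not made the default
because a single contiguous 10% window is dominated by whichever
behavioral episode happens to fall in it (a long in-field rest can make
the test R² of a strongly tuned neuron negative). The score is
R² = 1 − SSE/SST on the test split; the squared-correlation variant is
available.

Significance of each predictor group (position, velocity, licking) comes
from 100 refits with only that group's columns circularly shifted by a
uniform 200–700 samples: the group is significant when at least 96 of
100 refits *strictly decrease* the test R² ("decreased" is read as
strict). The conjunctive class counts significant groups (none / single
/ dual / triple). Each neuron gets its own shuffle and split substream,
so verdicts are deterministic given the session seed and neuron id.

# Zone decoding

Non-zero events are quantile-normalized per neuron over the whole
session (rank/ECDF in (0, 1]; the order of operations places
normalization before splitting), movement frames are accumulated into
1 s bins (activity summed, position circularly averaged), and samples
are labeled by zone membership. The positive class defaults to
reward + anticipation (60 cm); reward-only and anticipation-only are
exposed because the source binarization covers both zones jointly while
one figure discusses the anticipation zone alone. A linear SVM (hinge
loss, L2 penalty, `e1071::svm` with a linear kernel, no scaling — the
quantile normalization already fixes the scale) is trained on even laps
and tested on odd laps and vice versa; the reported score is the mean
fold accuracy. The original text calls this score "R²"; the package
labels it accuracy, the natural score of a hinge-loss classifier, and
additionally reports balanced accuracy because the zone occupies only
about a quarter of the movement samples and no class reweighting is
applied. Neurons with fewer than 10 non-zero 1 s bins in a fold's train
or test half are excluded from that fold. Population comparisons score
population A in full against 100 random size-matched subsamples of the
larger population B, reporting A against the subsample mean.

# The synthetic generator

`simulateBehavior()` emulates what the analyses assume about behavior:

* lap-structured running at a configurable mean speed (default 15 cm/s)
  with AR(1) log-normal fluctuations, slowed by a configurable factor
  (default 0.55) from 60 cm before the reward zone to its end;
* stochastic **rest bouts** (roughly one per 40 s of running, lognormal
  with ~8 s median, sub-threshold speed). Head-fixed mice spend a large
  share of a session immobile, and two analysis components *presuppose*
  aperiodic running: the movement mask is vacuous without rests, and the
  circular-shift nulls of both the place-cell test and the encoding
  model lose their meaning when lap durations are so regular that a
  shifted trace stays phase-aligned with behavior;
* appetitive licking whose rate ramps from a 0.5 licks/s baseline to
  3.5 licks/s over the 30 cm before the zone; the first in-zone lick
  triggers the pump (at most one reward per lap; laps without an in-zone
  lick stay unrewarded), followed 0.6–1.2 s later by a consummatory bout.
  The spontaneous baseline is kept relatively high (typical of earlier
  training stages) so the appetitive-bout regressor of the encoding
  model has support across the whole belt and session;
* an analog lick signal synthesized at the imaging rate: the lick
  impulse train convolved with a short causal kernel plus Gaussian
  noise, so the event detector is exercised on realistic input. Licks
  are generated with a 0.4 s refractory period, keeping them resolvable
  at the detector's 0.33 s separation rule. The 10 kHz acquisition stage
  is not emulated; the downsampling operation accepts higher-rate input
  and is tested on it directly.

`simulateEvents()` draws per-frame Poisson events with rate
$\lambda(t) = \mathrm{baseline} \cdot g_{place} \cdot g_{speed} \cdot
g_{lick}$: a circular Gaussian place gain
$1 + (gain-1)e^{-d^2/2\sigma^2}$ (width = SD in cm, because the belt is
circular), a log-linear speed gain $e^{slope (v - 10)}$, and a lick gain
$e^{amp\,K(t)}$ with K a causal exponential kernel (default duration
2 s) triggered at appetitive onsets, saturating at 1 under overlapping
onsets. The speed and lick gains are log-linear rather than clipped
linear: over the analyzed 2–30 cm/s range the exponential is
approximately linear, so the marginal bin regression recovers the sign
and magnitude ordering, while the log-link encoding model sees exactly
its assumed functional form — a clipped linear gain would make that
model misspecified in precisely the regime (rests, bursts) the tests
probe. One RNG stream per session is split deterministically into
behavior and neural substreams, so the behavioral trace is invariant to
the neuron count.

**Scenario presets.** `null` (no tuning; calibration), `place_only`,
`projection_enriched` (place tuning in 60% of projecting vs 25% of
non-projecting neurons, projecting fields biased toward the reward
zone), and `mixed_conjunctive`: 30% untuned, 20% place, 10% speed, 10%
lick, 10% place+speed, 10% place+lick, 10% triple. Default gains are
chosen for *recoverability*, not biological calibration — the source
does not state tuning magnitudes, which are properties of real neurons.
Singly tuned cells use place gain 6 (width 12 cm), speed slope ±0.09
per cm/s, lick amplitude +1.5/−2. Triple-conjunctive cells are
deliberately strong (baseline 0.2 events/frame, gain 7, slope ±0.18,
lick-excited amplitude 4): they exist to verify that the grouped shuffle
test certifies all three drives of a clearly conjunctive cell.
Lick-*inhibited* tuning appears only in singly and dually tuned cells:
suppressing an already sparse event trace carries little usable
information ("fewer than few" events), and no encoding model reliably
certifies it — the marginal Wilcoxon classifier does, which is why
inhibited cells are still generated where that classifier is the target.

**What the generator does not emulate.** Calcium indicator dynamics and
deconvolution artifacts (events are ideal Poisson counts), sensory
texture responses, across-lap representational drift, correlated noise
between neurons, and pose/whisking covariates. Passing recovery tests
therefore demonstrates the pipeline's correctness and calibration on
data satisfying its assumptions, not robustness to deconvolution error
or drift in real recordings.

# Numerical choices and degenerate inputs

* Half-open intervals and 0-based bins everywhere; every belt statistic
  is invariant to a common translation of positions and zones (tested).
* Silent neurons: SI, sparsity undefined (`NA`), non-place by
  convention; all-zero responses are flagged and excluded from the GLM.
* Laps with zero licking have relative licking 0; laps without activity
  are skipped in stability with counts reported.
* Empty downsampling windows carry the previous value with a warning.
* Ties in peak prominence resolve to the first peak; quintile ties share
  an average rank (a constant trace maps to a single quintile).
* `rowSums`-style accumulations and the shuffle kernel use compiled
  code; everything else is plain R on vectorized primitives.

# Problem sizes used in the shipped checks

The calibration and recovery checks run on synthetic sessions of 15–30
laps (roughly 10–20 min of behavior) with 45–500 neurons, 1000
place-cell shuffles, 100 encoding-model shuffles on subsets of 20–45
neurons, and 50 decoding sessions; these sizes give binomial 99% bands
tight enough to detect miscalibration by a factor of two while keeping
the full suite comfortably runnable on a laptop.

# Known limitations

* The per-session dynamic lick thresholds of the original videos are
  unrecoverable; the MAD rule is a stand-in and should be overridden
  when video-derived thresholds exist.
* The encoding model's verdicts on weakly tuned conjunctive cells are
  split-sensitive: a group whose unique out-of-sample contribution is
  comparable to refit noise can fail the 96/100 rule on an unlucky
  split. This is a property of the published procedure (single random
  split, strict-decrease counting), not of this implementation.
* Marginal speed/lick classes of conjunctive cells reflect marginal,
  not conditional, tuning: a place+speed cell whose field sits in the
  pre-reward slowdown segment can carry a genuinely flat marginal
  speed relationship. Recovery is therefore assessed against singly
  tuned cells, and conjunctive structure against the encoding model.
* Bootstrap CIs are plain percentile CIs; no BCa correction.
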