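---
title: "Methods: recognizing shoulder-rehabilitation exercises from inertial sensor streams"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: recognizing shoulder-rehabilitation exercises}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Patients with frozen shoulder (adhesive capsulitis) are prescribed
repetitive rehabilitation exercises — scapula flexion, Codman's pendulum,
finger wall-climbing, back shoulder circling, towel stretches and spiral
rotations. A wrist-worn wireless inertial sensor node streams tri-axial
acceleration and angular velocity to a base station at 8 usable packets
per second; the recognition task is to decide, from 25-second stretches of
that stream, which of the six exercises the wearer is performing.
`rehabrecog` implements the complete chain: packet validation, ADC
conversion, feature extraction, a from-scratch back-propagation neural
network (BPNN), recognition scoring, and the two feature-engineering
analyses (characteristic space, enveloped spectrum). A seeded simulator
stands in for the wearable hardware, which is not publicly available.

## From packets to physical samples

Each packet carries, per channel, a block of 128 ADC counts whose
empirical distribution is approximately Gaussian around the true level.
The histogram (probability-density) mean of the block equals the
arithmetic sample mean, so the conversion is

    value = (mean(counts) - offset) * scale - baseline

with `baseline` holding the initial-placement reading so that measurements
are relative to the starting posture. A validation filter rejects packets
with incomplete blocks, out-of-range counts, or duplicated sequence
numbers (first occurrence kept); filtering reports rather than raises, and
is idempotent. ADC depth and physical ranges of the original node are not
public; the defaults map a 10-bit ADC to ±2 g and ±500 deg/s — typical
MEMS full scales — and every test is calibration-relative, so none of the
statistical results depend on this choice. The packet-log file dialects
(CSV and little-endian binary) are defined by this package, since only a
payload diagram of the original radio format exists.

## Features and window entries

The discriminative derivative feature is the *included angle* θ between
consecutive acceleration vectors, `acos(a1·a2 / |a1||a2|)` in degrees. The
raw θ series is one sample shorter than the stream; it is padded by
repeating its first value, keeping the four feature streams tick-aligned
(the alternative — trimming every stream by one — would silently shift
window boundaries). A zero acceleration vector has no direction; the
scalar function raises, while bulk processing substitutes 0° with a
warning so one corrupt tick cannot abort a session.

One data entry spans 25 s × 8 samples/s on four features
(`a_x, a_y, a_z, θ`), flattened in that block order to an
n = 25·8·(3+1) = 800 vector. Consecutive entries share one quarter of
their length: stride 150 of 200 ticks. The training set is a global motion
matrix of six per-exercise cells (800 × m, m ∈ {18, 36, 72}) with matching
6 × m one-hot target cells — target cells are sometimes written 800 × m by
analogy with the motion cells, but 6 × m is the only shape consistent with
the six-neuron output layer.

## The network and its training

Architecture 800-5-6: log-sigmoid hidden layer `s(t) = 1/(1+e^{-t})`,
linear output layer `l(t) = t`. Inputs are min-max scaled per feature row
to [−1, 1], fitted on the training split only and stored with the model so
recognition applies identical scaling. Training is plain batch gradient
descent on the MSE (learning rate 0.05, momentum 0 by default — the
closest match to the textbook BPNN), with three stopping rules:

* **performance goal (PG)**: training MSE ≤ PG (default 1e-5);
* **early stopping**: no new best validation MSE for `patience` (default
  6) consecutive epochs; weights are restored to the best-validation
  epoch. `patience = 1` mirrors stopping at the first rise exactly, but is
  noisy; 6 tolerates plateau jitter;
* **budget**: 5000 epochs, after which the model is returned flagged
  `"PG not reached"` rather than raising — non-convergence at tight PGs is
  an expected outcome, not an error.

The split is stratified per exercise at 70/15/15 (a common toolbox default
of the era), seed-reproducible, and recorded in the model. Weights are
initialized uniformly in [−0.5, 0.5]/√fan-in. The plain ±0.5 range, with
800 scaled inputs, puts hidden pre-activations at SD ≈ 4.7 — deep in
sigmoid saturation, where batch gradient descent stalls for thousands of
epochs; the fan-in scaling is the standard remedy and is this package's
deliberate deviation from the plainest reading. The correctness anchor for
the whole module is the gradient check: analytic back-propagated gradients
match central finite differences to 1e-5 relative error on random small
networks.

Recognition multiplies unlabeled 800-vectors through the network, clamps
the linear outputs into [0, 1] (the result-matrix contract; clamping never
changes the argmax) and decodes the exercise as the row with the largest
recognition index, ties broken toward the lower exercise number with a
warning. Per-exercise rates are fractions of correctly decoded windows;
an exercise absent from the truth scores `NaN`, not 0, matching blind-test
protocols in which participants may omit exercises.

## Characteristic space

Per window, the maximum and mean of one acceleration component form a
point in the (a_max, a_avg) plane; exercises cluster in separate regions.
Whether two cluster polygons overlap is decided by the slope /
intersection-point formulas for their boundary segments with strict
interval containment (intervals normalized to min/max order first, since
the printed strict inequalities fail for segments stated in descending
coordinates). Vertical segments go through the general two-line form
instead of dividing by a zero slope difference. Two extensions are
documented deliberately: a polygon wholly inside another has no boundary
intersections, so vertex-inside is tested; and *coincident* polygons have
parallel boundaries everywhere and vertices on (not strictly inside) each
other, so the centroid is tested too. The published wall-climbing cluster
triangle — vertices (0, −0.25), (0.24, −0.45), (0.25, −0.25) — is used as
a geometry fixture only: the calibration that produced it is not
recoverable, so the test parameterizes a template variant to that cluster
rather than claiming a physical replication.

## Enveloped spectrum

The spectrum is the one-sided FFT amplitude spectrum, `2|X_k|/N` with DC
and Nyquist unhalved, so a unit sinusoid reads ~1 at its bin; this fixes
the scaling in the Parseval test. The DC bin is excluded from peak
searches. The primary peak is the global maximum; local maxima above one
quarter of the primary's amplitude are secondary peaks, with bins adjacent
within one resolution step merged into one group at the taller bin.

The filtering stage is an order-20 (21-tap) Hamming-windowed-sinc FIR
low-pass — linear-phase, era-typical, unit DC gain — with cutoff ω₁ ×
Nyquist, followed by keeping one sample in five after dropping the
order/2-sample transients at both ends. No standard algorithm defines "the" envelope of a
magnitude histogram; the package uses the simplest construction
satisfying the definitional constraints: peak bins detected
on the Nyquist-normalized grid anchored at ω₁ with step Δω, connected by
linear interpolation, then raised pointwise to the original so the
envelope dominates everywhere and equals the original at retained peaks.
The magnitude difference ΔE = Σf²_enveloped − Σf²_original is then
nonnegative by construction and zero iff the envelope adds nothing.
Parameter selection computes ΔE for every (ω₁, Δω) grid pair and every
spectrum, takes the per-spectrum argmin and returns the modal winning pair
across the collection, ties toward smaller Δω then smaller ω₁ — reflecting
the two published criteria (minimal ΔE, most counts). Whether ΔE was
originally evaluated before or after downsampling is ambiguous; the
package computes it on whatever spectra are supplied and `cmd_spectrum`
exposes a `downsample` switch (default off).

## What the simulator emulates — and what it does not

No recording of the original participants is deposited, so all
quantitative replication runs on the generator, whose defaults *are* the
documented signal signatures:

| Ex. | family | peak θ | notes |
|----|---------|--------|-------|
| 1 scapula | gentle | 80° | all axes at 0.5 Hz (chosen; commensurate with the θ fundamental) |
| 2 pendulum | gentle | 20° | 0.70–0.75 Hz (chosen plausible swing rate) |
| 3 wall-climb | nodal | 80° | primaries (0.2, 0.25, 0.25) Hz, secondaries (0.4, 0.55, 0.55) Hz, minor 0.8 Hz on a_y — all documented |
| 4 back circle | impulse | 20° | 0.5 Hz spike rate (chosen) |
| 5 towel | nodal | 40° | 0.3 Hz (chosen) |
| 6 spiral | impulse | 160° | 0.6 Hz (chosen) |

Construction: the acceleration is a slowly tilting unit-gravity direction
(sinusoids at the template frequencies with per-axis phases and a seeded
±10 % per-session amplitude jitter, fixing the spectral signature) plus a
sign-alternating horizontal dither whose magnitude is tan(θ/2) of the
target angle waveform — the angle between consecutive total vectors then
traces that waveform. Because the slow tilt itself rotates the vector a
few degrees per tick, its per-tick angle is subtracted from the dither
target; without this the 20° templates overshoot to ~38°. The dither axis
has no z component, keeping the a_z spectrum clean for the spectral tests.
Gaussian noise (SD 0.02 g — modest sensor-plus-tremor noise for a wearable
accelerometer) is added to every channel; secondary-to-primary amplitude
ratios default to 0.35, comfortably above the quarter threshold.

Known departures from real data: no biomechanical limb model (the dither
is a mathematical device, and it leaves high-frequency content on a_x/a_y
that real slow movements would not have); no inter-subject variability
beyond noise and amplitude jitter; angular-velocity channels are schematic
(the selected features ignore them). Consequently a green recognition test
establishes that the *pipeline* — windowing, scaling, training, early
stopping, decoding, scoring — is correct and that the documented
signatures are separable by the 800-5-6 network; it does not establish the
published human-subject rates, which are not reproducible without the
original recordings. The scaled-down replication (`scripts/acceptance.R`)
reports the minimum per-class held-out rate over Ex.1–3 and over Ex.4–5,
averaged over five seeds; the package's own runs reach 100 % for Ex.1–5,
inside the published >95 % / ≥85 % bands, while Ex.6 fluctuates widely
across seeds (~45–100 %), echoing its published ~60 % weakness with
time-domain features alone. At the default optimizer settings the PG of
1e-5 is typically *not* reached within 5000 epochs (training MSE ~0.04);
the model is returned flagged, mirroring the non-convergence entries of
the original PG tables, and the rates above are achieved regardless.

## Numerical choices and degenerate inputs

* `acos` arguments are clamped to [−1, 1] against rounding overflow; θ is
  always in [0°, 180°].
* `logsig` is evaluated in the two-branch numerically stable form; the
  training loop never exponentiates a positive large argument.
* Segment intersection treats |denominator| < 1e-14 as parallel; interval
  containment uses strict inequalities with a 1e-12 degeneracy guard for
  axis-parallel segments.
* Fewer than 200 samples yields an empty window set with a warning (a
  short session is data shortage, not a programming error); an exercise
  supplying fewer than m windows to matrix assembly *is* an error, named
  per exercise.
* Duplicate sequence numbers keep the first occurrence; rejection reasons
  are counted with precedence incomplete > out-of-range > duplicate so
  every bad packet is counted once.
* All seeded helpers save and restore the caller's RNG state; identical
  seeds give bit-identical sessions, splits, weights and outputs.

## Limitations

The package recognizes the six documented exercises only; spiral-rotation
recognition would need angular-velocity-derived features, which are
generated by the simulator but not defined as network inputs here. The enveloped-spectrum
features are computed and exported but not fed back into network training
(the combined feature vector was never specified). Cluster regions are
convex hulls or user-supplied polygons; automatic cluster discovery is out
of scope.
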