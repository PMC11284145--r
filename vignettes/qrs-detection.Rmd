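---
title: "Heat-map QRS detection with a small 1-D feature pyramid network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Heat-map QRS detection with a small 1-D feature pyramid network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qrspeak)
```

## The detection model

`qrspeak` treats QRS detection as dense probability regression: the
network maps a canonical two-channel ECG segment of length $l$ (250 Hz,
0.5–35 Hz band-passed, per-lead z-scored) to three heat maps of lengths
$l$, $l/2$ and $l/4$, each entry the probability that the corresponding
time point lies inside a QRS complex. Beats are then read off the
full-resolution map as thresholded local maxima followed by greedy
non-maximum suppression (NMS).

The architecture (see `qrs_model_config()`) is an encoder–decoder:

* **Stem**: dense kernel-19 convolution, 2 → 32 channels, instance
  norm (IN), ReLU.
* **Encoder**: six residual blocks, two per scale at channel widths
  32, 64 and 128. Each block is one *depthwise* kernel-19 convolution +
  IN + ReLU with an identity skip; all channel mixing is delegated to
  the kernel-1 layers, which keeps the wide-kernel layers cheap.
  Between scales, a kernel-1 stride-2 convolution downsamples and
  doubles the width.
* **Decoder (FPN)**: kernel-1 lateral convolutions reduce each scale to
  a common width of 24; the top-down pathway upsamples by
  nearest-neighbour and adds; a depthwise kernel-19 smoothing
  convolution cleans each merged map.
* **Head** (shared across scales): dense kernel-5 convolution to one
  channel, sigmoid, then a width-9 stride-1 moving average with
  same-length zero padding — interpreted as smoothing rather than
  decimation precisely so the three heat maps keep lengths $l$, $l/2$,
  $l/4$.

Backbone convolutions carry no bias (an IN layer immediately follows
each one, making biases redundant) and IN carries no affine parameters;
the lateral and smoothing convolutions, which feed the head directly,
do carry biases. With the default configuration the model has exactly
**26,976 trainable parameters** (`count_parameters()`), and the deepest
head output has an analytic receptive field of 391 samples = **1.564 s**
(`receptive_field_s()`), wide enough to see neighbouring beats on
either side of the current one.

Several block-internal details admit more than one reading from the
architecture description alone (how many convolutions per residual
block, where biases and affine norms sit, the pyramid width, whether
the head is shared). We resolved them by treating the published
parameter count as an architecture oracle: one depthwise convolution
per block, bias-free backbone, affine-free IN, pyramid width 24,
biased lateral/smoothing convolutions and a single shared bias-free
head are the unique combination in this family that lands exactly on
26,976. The count is asserted by the test suite, so any future drift
breaks loudly.

Instance normalization uses per-instance statistics in training *and*
inference, so a forward pass is deterministic and the model is fully
convolutional — any input length ≥ 32 works (odd lengths are zero-padded
to a multiple of 4 internally and the outputs cropped back). One
consequence worth knowing: because IN statistics are global over the
segment, translation covariance of the output holds only up to an
$O(\mathrm{RF}/l)$ coupling with the segment edges; the test suite
quantifies this and checks it decays with length.

## Training targets and loss

Targets are generated per resolution on a left-aligned grid (coarse
sample $i$ sits at time $i\,r/f_s$, matching stride-2 downsampling):
label 1 where the distance to the nearest annotated beat is < 75 ms,
label 0 where it exceeds 150 ms *and* the point lies strictly between
the first and last annotation, −1 (ignore) everywhere else — the
75–150 ms border band, the unannotated span ends, and the first/last
200 ms of every map (incomplete edge beats). Both thresholds are
strict, so a distance of exactly 75 or 150 ms is ignored. With a single
annotation the "between" span is empty and only the positive
neighbourhood survives; with none, the whole vector is ignored.

The loss is masked binary cross-entropy: the mean BCE over non-ignored
samples per resolution, averaged over the resolutions that have any
valid samples (predictions clamped to $[10^{-7}, 1-10^{-7}]$). A
uniform prediction of 0.5 gives exactly $\ln 2$ whatever the mask, and
predictions at ignored positions never move the loss — both are
asserted as properties.

Optimization is Adam (learning rate $10^{-3}$, weight decay $10^{-8}$,
batch size 32, 5 epochs by default), on non-overlapping 60-s segments,
keeping the checkpoint with the lowest validation loss (ties to the
earlier epoch). Training is seeded end to end; per-segment gradients
are averaged within a batch.

## The simulator and the augmentation policy

The simulator renders beats at a regular RR interval of $60/\mathrm{bpm}$
seconds (first beat at half an interval, so a segment holds exactly
`round(bpm·duration/60)` beats), each as a biphasic pulse — a sharp
dominant R peak with a smaller trailing S dip, built from two Gaussians
over a compact support equal to the configured QRS duration. The pulse
shape is a package choice (the waveform function is pluggable); its
virtue is a sharp extremum at the annotated sample. The second lead is
the first scaled by 0.8. White noise is mixed at an exact segment-level
SNR, $10\log_{10}(P_\mathrm{clean}/P_\mathrm{noise})$. High-heart-rate
augmentation draws BPM from [200, 280], amplitude from [3, 5] mV,
duration from [50, 100] ms and SNR from [4, 12] dB.

Three noise processes model real-world artifacts: baseline wander (one
sinusoid, frequency drawn from an equal mixture of Gaussians centred at
0.05/0.15/0.25 Hz with sd one third of the mean, non-positive draws
rejected, random phase), muscle artifact (white noise) and electrode
motion (white noise band-passed 5–15 Hz). Their amplitude when mixed
into training segments is SNR-controlled, drawn uniformly from
[4, 12] dB — no absolute noise amplitudes are prescribed anywhere, so
reusing the white-noise SNR range keeps a single calibrated knob.

The augmentation policy per real training segment: with probability 0.3
mix one of {BW, MA, EM}; flip each channel with probability 0.5; swap
channels with probability 0.5. Ten percent of batches are replaced
outright by freshly simulated high-heart-rate segments. These rates are
package defaults (all arguments of `fit_qrs()`), chosen to keep clean
data dominant while guaranteeing steady exposure to every augmentation
family.

What the simulator does *not* emulate: P and T waves, heart-rate
variability, morphology changes (ectopy, bundle-branch shapes), real
recorded noise, or electrode dropout. Passing the synthetic end-to-end
test therefore demonstrates that the pipeline — preprocessing, targets,
loss, backprop, NMS, scoring — is internally correct and trainable, not
that the desk-scale model matches published cross-dataset accuracy on
real recordings; for that, train the full-width model on the real
arrhythmia split (`ar_ds2_split()`).

## Detection and evaluation conventions

Candidates are samples above the 0.5 threshold that are local maxima;
a plateau of equal values emits its centre (left-of-centre on even run
lengths). NMS sorts by descending probability, ties to the earlier
sample, and suppresses within a *closed* 200 ms window; a 1-ns numeric
guard keeps integer-sample offsets that land exactly on the window edge
suppressed regardless of floating-point rounding. Detection uses the
full-resolution map (the most precise timing); `detect_record()`
exposes `map` for the coarser ones. Detections are reported in the
record's native sample coordinates, inverting any resampling.

Matching processes detections in ascending time, each taking the
nearest still-unmatched annotation when the offset is strictly below
the tolerance (default 0.15 s; 0.075 s for the stricter convention),
equidistant ties to the earlier annotation. Margins are absolute
offsets in ms, reported mean ± sample sd (a single pair reports sd 0).
Degenerate metric denominators yield `NA` rather than errors, and `Err`
can legitimately exceed 100 when false positives dominate.

## Numerical choices and degenerate inputs

* Butterworth order 3, applied forward–backward (zero phase) so
  filtering never shifts annotations; odd-reflection edge padding of
  $3 f_s/f_\mathrm{low}$ samples suppresses the slow 0.5 Hz start-up
  transient.
* Resampling is polyphase at the reduced rational ratio; annotation
  indices rescale by the same ratio, rounding half away from zero.
* Zero-variance leads z-score to all zeros instead of dividing by zero.
* IN uses population variance with $\varepsilon = 10^{-5}$.
* Weights initialize uniform $\pm\sqrt{1/\mathrm{fan~in}}$, seeded.
* A flat (all-zero) record passes through the whole pipeline and yields
  no detections.

## Problem sizes used by the test suite

The suite trains the `"desk"` preset — identical architecture at
channel widths 8/16/32 and pyramid width 8 — because full-width
training is wasteful for correctness checks. The end-to-end acceptance
run uses 200 mixed-rate 60-s synthetic training records (10%
high-heart-rate) with 20 validation records, 2 epochs, 15-s training
windows, batch size 4 (≈ 400 Adam steps at the default learning rate),
then scores 40 held-out records: 20 clean, 10 at 6 dB, 10 at 200–280
BPM. Oracle-equivalence suites run 1000 random NMS instances, 200
target instances at all three resolutions, and 500 matching instances
against brute-force oracles.

## Known limitations

* Fixed 0.5 threshold and no search-back strategy: beats whose heat-map
  response stays below threshold are simply missed.
* No beat typing or delineation — the head locates QRS complexes only;
  AAMI types enter only through the evaluation report.
* The native-R training loop is CPU-bound and desk-scale; full-width,
  full-dataset training is supported but slow compared to GPU
  frameworks.
* WFDB support covers single-file records in formats 16 and 212 with
  MIT-format annotations — the common cases — not the full format zoo.
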