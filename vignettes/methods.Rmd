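---
title: "Methods: detectors, energy model, and synthetic benchmark"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detectors, energy model, and synthetic benchmark}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neurowatt)
```

## The problem

A responsive neurostimulator for focal epilepsy records EEG from a handful
of electrodes over the seizure onset zone, runs a seizure detector once per
second, and stimulates when a seizure is emerging. Such a device is battery
powered and implanted, so the detector must be accurate *and* cheap: both
detection quality and the energy cost of one classification matter. This
package implements three patient-specific detectors suited to that setting,
an instruction-counting energy model that compares them on equal,
hardware-independent terms, and the evaluation protocol for seizure
detection at a 1 Hz classification rate. Since clinical EEG with seizure
annotations cannot ship with a package, a synthetic generator reproduces the
statistical features the methods rely on, and every pipeline stage is tested
against it.

## Signal model and preprocessing

The expected input is a five-electrode montage sampled at 256 Hz, in
microvolts. The conditioning chain is fixed, in this order:

1. **Invalid-segment exclusion.** A per-sample validity mask travels with
   the recording; any 1 s analysis window that overlaps an invalid sample is
   skipped rather than imputed.
2. **Bandpass.** A 10th-order Chebyshev type-II IIR bandpass with 40 dB
   stopband attenuation and stopband edges at 0.1 and 48 Hz. The filter is
   designed with `signal::cheby2` and realized as cascaded second-order
   sections, applied causally in a single pass — an online embedded detector
   cannot filter backwards in time, so no zero-phase filtering is used.
   The 48 Hz edge subsumes power-line noise, so no separate notch exists.
3. **Amplitude artifact rejection.** Every 1 s period (aligned to the
   analysis grid) containing any sample with |x| strictly above 1 mV is
   marked invalid. The threshold is applied per electrode, before
   re-referencing, and after the bandpass (the narrative order of the
   conditioning chain); ordinary EEG (~100 uV) and interictal spikes
   (~140 uV) pass untouched. The operation is idempotent.
4. **Central re-referencing.** Each peripheral electrode minus the central
   electrode: five electrodes become C = 4 channels and common-mode
   components cancel.

## Detectors

All three classify one 1 s window (256 samples x 4 channels) per second.

**Random forest.** Input is a 64-dimensional feature vector: 16 features
per channel, 8 time-domain (maximum, mean, mean absolute deviation,
variance, skewness, kurtosis, line length, amplitude entropy) and 8
frequency-domain (spectral entropy, mean/max/variance of the Hann-windowed
one-sided power spectrum, theta/beta/gamma band powers, epileptogenicity
index `(P_beta + P_gamma) / (P_theta + P_alpha)`). Conventions worth
stating because they are easy to get differently:

* all moments use the 1/N convention, and skewness/kurtosis are normalized
  by the *population* standard deviation; both are defined as 0 for a
  constant window;
* the amplitude entropy is the base-2 Shannon entropy of a 16-bin histogram
  of the window samples over `[min, max]` (`0 log 0 := 0`); the histogram
  size is a parameter — the definition of the sample distribution is a
  choice this package makes, consistent with bounded embedded cost;
* band powers sum spectrum bins with *inclusive* integer limits at 1 Hz
  resolution, so adjacent bands share their boundary bin (8 Hz belongs to
  both theta and alpha). The one-sided spectrum is used without interior-bin
  doubling; entropies and band ratios are invariant to that scale, and band
  powers adopt it as the package's fixed convention;
* zero-mean samples and their squares are computed once per window and
  shared across features, exactly as the energy accounting assumes.

The forest has 100 trees, depth capped at 10, 4 candidate features per
split, bootstrap resampling, and class weights inversely proportional to
class frequency. It is fitted with `ranger`. One deliberate substitution:
the reference configuration uses entropy as the split criterion, which no
installed R random-forest implementation offers; `ranger` splits on Gini
impurity instead. For binary classification the two impurity measures are
monotonically very close and almost always select the same split, so the
stated tree shape, feature subsampling and weighting are preserved while
the impurity function differs. The per-node draw of 4 features is kept at
the stated value (the square root of 16, the per-channel feature count)
even though the default layout feeds all 64 channel-specific features; both
layouts are expressible through `mtry`.

**CNN.** Raw windows are divided by the training-set standard deviation
and squashed with `tanh(0.2 x)`; at inference the piecewise-linear
`lintanh` (slope 1/1.2, clipped at +-1; max deviation from tanh ~0.168)
replaces the hyperbolic tangent, as an embedded implementation would. The
architecture is fixed: three unpadded convolution blocks
(15 filters of 4x25, 15 of 1x11, 10 of 1x5, each with batch normalization,
ReLU, and for the first two blocks 1x4 max-pooling; dropout 0.2 during
training), then dense layers of 8 and 4 ReLU units and a 1-unit sigmoid
output — 5,614 parameters in total. Training: class-weighted binary
cross-entropy, Adam at 1e-3, batch 512, 500 epochs by default; a base
model can warm-start training (fine-tuning between patients).

**LSTM-RNN.** Input is the per-channel first difference of the raw window
(padded by repeating the first difference so the 256-step input length is
preserved — the source architecture is silent on the lost sample). The
derivative is divided by its training-set standard deviation purely for
numerical conditioning of training; the scale folds into the input weights
at inference and therefore costs nothing. The network is a 20-cell LSTM
over 256 steps, dropout 0.1, a time-distributed *linear* dense layer of 20
units, global average pooling over time, and a sigmoid unit — 2,441
parameters. Because the time-distributed layer is linear it commutes with
the average pooling; the implementation exploits that identity (the energy
model still counts the per-step computation as architected). Training uses
Adam, batch 256, and early stopping with patience 10 on the validation
loss of one reserved seizure segment. Predicted probability series are
median-filtered with a width-3 shrinking-window filter.

Both networks are implemented natively in this package (im2col convolution
and backward-through-time LSTM as compiled float32 kernels with an Adam
loop in R); at 5,614 and 2,441 parameters they need no external framework,
and float32 matches the arithmetic of the embedded targets being modelled.
Gradient correctness is pinned by central-difference checks in the test
suite. Window labels follow the rule: a window is ictal iff its start time
lies in `[onset, offset)`. Training strides are 16 samples for interictal
and 1 for ictal windows (oversampling the rare class); test windows stride
256 (1 Hz, non-overlapping).

## Energy model

Energy per classification is estimated by counting operations and pricing
them with per-operation costs for a 45 nm process: memory access 5 pJ,
float32 add 0.9, float32 multiply 3.7, compare 0.9, float32 divide 26.3,
int32 add 0.1, int32 multiply 3.1, generic one-cycle float op 3.7. Total
energy is `(N_load + N_store) * E_m + sum_x N_x * E_x`. Deliberate
conventions, centralized in one rule table (`R/energy.R`):

* a fused multiply-accumulate (MAC) counts as *one* arithmetic operation
  and is costed as one add plus one multiply (4.6 pJ);
* each operand fetched from a working array is one load, each scalar
  written back one store; register-resident accumulators and loop counters
  are free. Convolution and dense layers fetch operand and weight per MAC
  (no reuse modelled); the LSTM's recurrent state is treated as
  register-resident within a time step (fetched once per gate), while its
  input values and all weights are fetched per MAC;
* divide-by-constant is priced as a multiply; square root and runtime
  division as a float divide (equal FPU cycle counts on a Cortex-M4F);
  abs and ReLU as one compare; log2 as a one-cycle op plus a LUT load;
  sigmoid/tanh as a LUT load plus a one-cycle index computation;
* the power spectrum is costed as a radix-2 real FFT
  (`N/2 log2 N` butterflies at 4 multiplies + 6 adds, 10 memory accesses
  each) plus the Hann product and bin squaring;
* batch normalization is folded into convolution weights at inference
  (zero marginal cost); dropout is inference-free;
* the RF classifier stage is costed at its worst case: all 100 trees
  traversed to depth 10, each node one feature load, one threshold load,
  one compare; microprocessor instruction overhead is deliberately
  excluded — it surfaces as the slope of the hardware calibration below.

These conventions reproduce the reference per-classification totals
(RF ~0.48 uJ, CNN ~7.0 uJ, RNN ~7.4 uJ; CNN 472.8k convolution MACs and
~489k arithmetic operations), with the RF < CNN < RNN ordering. Exact
load/store bookkeeping differs between implementations, which is why the
package treats the rule table, not any single total, as the definitive
statement of the model.

`calibrateHardware()` relates estimates to measurements of a concrete
implementation by ordinary least squares (`measured = b0 + b1 * estimate`),
reporting slope, offset, adjusted R^2 and Pearson r; the slope absorbs
instruction overhead and the offset static consumption. No hardware
measurements ship with the package — the fit is exercised on synthetic
linear data in the tests.

## Evaluation protocol

Window-level, threshold-free: ROC AUC (pairwise concordance, ties half)
and precision-recall AUC (step integration over observed thresholds), each
verified in the test suite against exhaustive brute-force oracles on
hundreds of small random instances. The early-seizure variant relabels
windows so only the first 10 s after onset count as positive; later
in-seizure windows are excluded from that metric rather than counted as
false — a detection there is neither an early success nor a false alarm.

Event-level, at the F1-optimal threshold (computed on windows, scanning
the observed probability values, ties toward the higher threshold):
sensitivity (a seizure counts as detected if at least one in-seizure event
fires), false detections per hour with 5 s deduplication (greedy,
earliest-first: a counted false event suppresses all false events in the
following 5 s), and mean detection delay over detected seizures.
Deduplication applies to false events only, as the protocol describes it.

Cross-validation is leave-one-seizure-out: each fold holds out one
seizure's surrounding segment for testing and trains on the rest; the RNN
additionally reserves one training seizure's segment for early stopping.
Fold metrics are aggregated as mean and median.

## Synthetic benchmark

`syntheticConfig()` defines the simulated study conditions: five
electrodes at 256 Hz; interictal background synthesized as 1/f colored
noise (frequency-domain shaping of white noise — the simplest reproducible
method) at 20 uV RMS; inside each annotated seizure a rhythmic
amplitude-modulated chirp sweeping the middle of the 4-8 Hz theta band at
80 uV peak amplitude on peripheral electrodes and half that on the central
electrode, so re-referencing preserves the rhythm (a focal source near the
peripheral contacts); optional sparse >1 mV transients to exercise
artifact rejection. One master seed expands into per-electrode and
per-component substreams, so adding artifacts never perturbs the
background realization. Window placement around seizures is configurable
rather than hard-coded, since an "hour around each seizure" segmentation
admits several readings.

The default benchmark (`runConfig()`) uses a 110 s record with five 2 s
seizures spaced 18 s apart, leave-one-seizure-out over all three detectors,
the CNN at 50 epochs and the RNN capped at 15 epochs (early stopping with
patience 10 cannot halt before epoch 11). These desk-scale sizes are the package's choice for a benchmark
that a laptop reproduces in minutes; the ictal rhythm at four times the
background RMS is deliberately strong, because the benchmark's purpose is
to verify that every implementation link (simulation, preprocessing,
features, training, evaluation) transmits a known signal — the expected
leave-one-seizure-out median ROC AUC is at least 0.9 for all three
detectors. What this does *not* show: performance on clinical EEG, whose
seizure morphology, artifact taxonomy, and patient variability the
generator does not attempt to emulate (no per-patient morphology
libraries, no eye-blink/EMG artifacts, no sub-clinical seizures). Clinical
figures require clinical data.

## Numerical choices and degenerate inputs

* Constant windows: variance, MAD, line length, entropies, skewness and
  kurtosis all return 0 (the last two are undefined and guarded).
* All-zero spectra: spectral entropy 0; epileptogenicity index 0, with a
  warning when only the denominator vanishes.
* A sample at exactly 1000 uV is retained (strict inequality).
* The F1 threshold scan is exhaustive over observed values — no
  interpolation; the moving median shrinks symmetrically at the edges, so
  length-1 and length-2 series pass through unchanged.
* Seeds: every stochastic stage (noise, artifacts, weight initialization,
  shuffling, dropout, bootstrap) derives from explicit integer seeds;
  identical configurations are bitwise reproducible. Training logs record
  the seed used.
* Filter stability is checked at design time (pole moduli < 1) with an
  informative error, as very low stopband edges at low sampling rates can
  produce ill-conditioned designs.

## Known limitations

* The Gini-for-entropy substitution in the forest (above).
* The energy model's load/store conventions are one defensible reading of
  "count memory accesses"; totals shift by roughly +-10% under equally
  defensible alternatives (e.g. modelling operand reuse in convolutions).
* The LSTM energy assumes the original (non-fused) recurrence; compiler
  effects such as loop unrolling are out of scope and absorbed by the
  calibration slope.
* The synthetic generator is a test harness, not a patient simulator.
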