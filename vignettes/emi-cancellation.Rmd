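---
title: "Deep-learning EMI cancellation for shielding-free ultra-low-field MRI: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deep-learning EMI cancellation for shielding-free ultra-low-field MRI: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(ulfemi)
```

## The problem

Ultra-low-field (ULF) MRI at 0.055 T (proton Larmor frequency 2.32 MHz)
can operate without a radiofrequency shielding room only if the
electromagnetic interference (EMI) that the receive chain picks up from the
environment and from the scanner's own electronics is removed
computationally. The approach modelled here places ten small resonant
sensing coils around the scanner. These coils detect EMI but no MRI signal.
Within every repetition time (TR) the receiver samples two kinds of
windows: the MRI signal **acquisition windows** (one per echo) and one or
more **EMI characterization windows** in which no transverse magnetization
remains, so the receive coil also sees interference only. After each scan a
five-layer convolutional neural network (CNN) is trained on the
characterization windows to map the ten sensing-coil time series to the
receive-coil time series; the trained model then predicts the EMI component
of every frequency-encoding (FE) line in the acquisition windows, which is
subtracted before averaging and reconstruction.

`ulfemi` implements this method end to end inside a self-contained scan
simulator, so the canceller can be exercised and validated quantitatively
with no hardware: the simulator provides the ground truth (a "shielded
twin" of every scan with identical MRI signal and receiver noise but EMI
off) that a physical experiment can only approximate with a shielding cage.

## Signal models

Tissue contrast uses closed-form steady-state expressions with the 0.055 T
relaxation estimates (GM T1/T2 = 330/110 ms, WM = 260/100 ms, CSF given
T1 = 4000 ms and T2 = 2000 ms, consistent with its long-relaxation bounds
at this field; proton densities CSF/GM/WM = 1.0/0.9/0.8 and ADCs
3.0/0.8/0.7 x 10^-3 mm^2/s follow standard brain-phantom convention):

* spoiled GRE (T1W, TR/TE = 52/13 ms, FA = 40 deg):
  `pd sin(a) (1-E1)/(1-E1 cos(a)) exp(-TE/T2)`, `E1 = exp(-TR/T1)`;
* FSE saturation recovery at the effective TE (T2W 1500/202 ms; FLAIR-like
  500/129 ms): `pd (1-exp(-TR/T1)) exp(-TE/T2)`. The FLAIR-like contrast
  suppresses CSF purely through short-TR saturation of its long T1 — no
  inversion pulse;
* 2D spin-echo EPI DWI (TR/TE = 2800/102 ms, b = 500 s/mm^2,
  Delta/delta = 49/30 ms): monoexponential attenuation `exp(-b ADC)` per
  direction; three orthogonal b1 images are combined by geometric mean so
  the combined ADC is the arithmetic mean (trace/3) of directional ADCs.

T2\* is taken equal to T2: at 0.055 T with <250 ppm field inhomogeneity,
intravoxel dephasing is negligible at these voxel sizes. The GRE model
assumes perfect RF spoiling. The FSE model applies the effective-TE
amplitude to the whole echo train (no per-echo T2 modulation), which keeps
reconstruction round trips exact; echo-train k-space filtering is a
deliberate non-goal. The required diffusion gradient,
`gradientForB(500, 30e-3, 49e-3)` = 14.1 mT/m, sits below the scanner's
15 mT/m maximum — the analytic feasibility check for the DWI protocol.

## The phantom

`makePhantom()` builds a nested-ellipsoid "CSF shell - GM shell - WM core"
label grid (shell semi-axes 0.90/0.80/0.55 of the half-extent), optionally
with a spherical lesion and a smooth quadratic off-resonance map. The
geometry is analytic on purpose: per-tissue voxel counts are checkable by
brute-force point-in-ellipsoid enumeration, which the test suite does. It
is not an anatomical atlas, and passing tests on it says nothing about
anatomical realism — only about the correctness of the signal chain.

## Acquisition simulation

k-space conventions are fixed for bit-exact testing: DC at 0-based index
`floor(N/2)` on every axis, unitary centred FFT in both directions
(Parseval holds exactly), FE along the first axis. Each FE line of a scan
is the matching row of the 3D DFT of the contrast-weighted phantom, plus
circular complex-Gaussian receiver noise, plus coupled EMI sampled at the
window's absolute wall-clock time. Phase-encode ordering is center-out over
the (optionally elliptic) masked set, so the first echo of each shot
carries k-space center and the protocol TE applies there; echo `j` is read
at `TE + (j-1)(N_x dwell + gap)`. Characterization windows bracket the
acquisition: half sit at the very start of the TR (pre-excitation, where no
transverse magnetization exists) and half at end-of-TR (where it has fully
decayed). Sampling EMI on both sides of the acquisition keeps the training
windows close in time to the windows being cancelled, which matters when
the interference is nonstationary — with end-of-TR windows only, a swept
source is always characterized at spectral content systematically offset
from what the acquisition windows contain. The per-TR count is configurable
(the desk-scale condition uses 16 per TR to reach 256 windows in a 16-TR
scan). TR must exceed the total window time — the characterization
time-overhead — or the protocol is rejected.

The elliptic phase-encode mask keeps centred integer offsets with
`(k1/a)^2 + (k2/b)^2 <= 1`, `a = floor(n1/2)` (so a 9 x 9 grid keeps the 49
lattice points of the radius-4 circle, and a 128 x 32 grid keeps 77.9% ~
pi/4 of the grid).

EPI is simulated line by line: line `m` is the DFT row of the image
modulated by `exp(2 pi i f t_m)` with `t_m` the line's offset from the echo
(this is the geometric-distortion mechanism, displacing voxels by
`-f / bandwidth-per-pixel` along PE), and reversed (even) lines receive a
constant-plus-linear phase ramp in the hybrid readout domain (the
Nyquist-ghost mechanism of an odd/even timing mismatch). A 3-line
non-phase-encoded reference scan (+,-,+ polarity) is emitted for ghost
calibration.

## The EMI world

Interference is modelled at complex baseband within the 50 kHz receive
bandwidth. Source kinds: band-limited white noise (broadband), linear
sweeps traversing a band over the scan, pure tones, and powerline harmonic
combs (fundamental 50 Hz, 1/|n| amplitudes). Deterministic kinds are
continuous-phase functions of absolute time; broadband draws are keyed by
(seed, window start), so any window can be replayed exactly — that replay
is what makes the shielded twin possible. Coupling into the 11 channels
(receive + 10 sensing) is linear: per-(source, channel) complex FIR taps,
plus independent sensor noise on the sensing coils, plus optional slow
sinusoidal gain drift on the receive coupling (a phenomenological stand-in
for body-antenna and posture effects). With drift off the coupling is LTI,
and the receive-coil EMI is exactly a fixed FIR function of the sensing
coils — the analytic ground truth the cancellers must approach.

Study conditions were fixed once, before any end-to-end run, and are not
tuned: receiver noise std 0.01 (relative units), chosen so a single-average
T2W image has SNR ~ 20 on gray matter; the standard test world couples a
broadband source (rms 0.03 in the receive coil, band -15 to -5 kHz) and a
50 Hz harmonic comb (rms 0.015, harmonics to +/-2 kHz) through unit-norm
2-3-tap receive filters and single-tap sensing gains, giving an
EMI-to-receiver-noise power ratio of ~11 (the acceptance condition requires
>= 10); sensing-coil sensor noise std is 3e-4, about 1% of the sensing-coil
EMI rms — resonant pickup coils sited near strong sources are
high-SNR, but perfect sensors would make cancellation trivial. The swept
world replaces the broadband source with a -20 to +20 kHz sweep traversed
over the scan (the dynamic-EMI condition).

## The canceller

The CNN follows the published recipe exactly: five convolutional blocks
with kernels 11x11, 9x9, 5x5, 1x1, 7x7 and channels 128, 64, 32, 32, 2;
blocks 1-4 are convolution + batch normalization + ReLU, block 5
convolution only; input `N_x x 10 x 2` (readout samples x sensing coils x
real/imag), output `N_x x 2`; MSE loss minimized by Adam (beta1 = 0.9,
beta2 = 0.999, lr = 5e-4) with batch 16 for exactly 20 epochs on an 85/15
train/validation split of the characterization windows. Training is
per-scan: `cancelEmi()` refuses a model whose training-data hash does not
match the record.

Choices the recipe leaves open are declared here as this package's own:

* **Padding / geometry.** All five convolutions use same-padding on both
  axes, preserving the `N_x x 10` map.
* **Coil-axis reduction.** The final two-channel map is averaged across the
  10-wide coil axis to produce `N_x x 2`. The rule is stored in the model
  (`arch$coilReduction`) so alternatives can be swapped in.
* **Normalization.** Inputs are divided by the std of the training-portion
  sensing data, targets by the std of the training-portion receive data;
  both constants live in the model and are re-applied at prediction.
* **Initialization.** He-normal for the ReLU blocks, Xavier for the linear
  output block; biases, BN shifts zero, BN scales one.
* **Batch normalization.** eps = 1e-5; during training, batch statistics
  with a momentum-0.1 running average (biased variance). At the end of
  training the inference statistics are recomputed exactly — population
  statistics of the training inputs under the final weights — because the
  momentum average is noticeably noisy at batch size 16.
* **No early stopping.** Validation loss is recorded per epoch (plus an
  epoch-0 baseline), but final-epoch weights are returned.
* **Augmentation.** Each training example is, per epoch, rotated by a
  random global phase, superposed with a second randomly phased example
  (unit-norm weights, so the per-window noise level is preserved), and
  frequency-shifted by up to +/-400 Hz as a per-sample phase ramp. The
  first two operations map valid (sensing, receive) pairs to exactly valid
  pairs for any linear coupling — including a time-varying one, since
  windows are mixed as wholes; the frequency shift is valid to first order
  in the coupling's delay spread (error about 1% at 400 Hz for a two-tap
  coupling, below the residuals of interest). This matters for
  nonstationary sources: without it, FE lines whose interference is a
  near-constant phasor (a swept source crossing the carrier frequency) are
  poorly predicted, because only a handful of characterization windows ever
  look like that and a nonlinear network learns nothing about them from the
  rest. The optimizer, loss, epoch count, batch size and split are
  untouched by augmentation.

The implementation is compiled (Rcpp/RcppArmadillo), single precision,
with convolutions lowered to im2col + BLAS matrix products; weight
initialization and shuffling consume R's RNG, so `set.seed()` makes
training reproducible to floating-point tolerance.

The linear baseline (`fitLinearCanceller()`) solves the ridge-regularized
least-squares map from lagged sensing samples (one length-L FIR per coil,
default L = 5) to the receive samples over the characterization windows. In
a noiseless LTI world it is exact, which makes it the oracle: the CNN's
validation MSE is required (and tested) to come within 2x of the linear
residual under scalar coupling, and the residual floor of both is set by
receiver noise in the targets (label noise an unbiased fit cannot remove).

## Reconstruction and metrics

`averageNex()` complex-averages repeats onto the k-space grid (subtraction
always precedes averaging); `reconCartesian()` zero-pads centred k-space by
integer factors, inverse-FFTs and takes magnitudes, rescaling by
`sqrt(prod(pad))` so values at original voxel centres are preserved —
2 x 2 x 10 mm acquisition voxels displayed with pad (2,2,2) give the
1 x 1 x 5 mm display grid. Ghost correction fits a constant + linear phase
between the reversed reference line and the mean of its neighbours in the
hybrid domain (magnitude-weighted, after unwrapping) and removes it from
every reversed line; the correction also updates the stored reference, so
it is idempotent. Distortion correction resamples along PE at
`j - f/bw` with linear interpolation using the simulator's true field map;
field-map *estimation* is out of scope, and both corrections are standard
stand-ins for steps whose algorithms the hardware workflow does not pin
down.

The shielded-equivalence criterion is operationalized as: background-noise
std of the magnitude reconstruction (same estimator for every arm, mask of
at least 2000 background voxels so the estimator SE is well under the 5%
band), compared between the cancelled record and its shielded twin;
`pass5pct` is `|sigma_c - sigma_s| / sigma_s <= 0.05`. Because the twin
shares the receiver-noise realization, the deviation isolates residual EMI
plus any damage the canceller does to the lines. EMI-band suppression (dB)
is computed on the EMI component alone — record minus twin, the
transmit-off analogue — within the band declared by the EMI world, not
estimated from data.

## Problem sizes and determinism

The desk-scale condition used throughout the tests and the acceptance
script is a 64 x 64 single-slice T2W FSE scan, ETL 8, NEX 2, 16
characterization windows per TR (256 total, 218/38 split); one per-scan CNN
training at this size takes a few minutes on one CPU core. Unit tests use
32 x 32 or smaller geometries and few epochs. A single run seed fans out to
per-stage seeds (`phantom`, `emi`, `acquisition`, `split`, `init`) by a
fixed counter scheme, so any stage can be re-run in isolation; identical
configurations are bit-identical, and training losses are reproducible to
floating-point tolerance.

## Limitations

One measured limitation of the per-scan recipe at desk scale deserves
emphasis. Under the swept-frequency (dynamic) EMI world, the trained CNN
reaches shielded-equivalent image noise (deviation well under 5%) and
removes over 98% of the EMI energy, but the EMI-band suppression of the
magnitude-averaged spectra plateaus at roughly 12-16 dB rather than the
20 dB the linear oracle exceeds on the same records. The residual
concentrates on the handful of FE lines where the sweep crosses the
carrier: their interference is a near-constant phasor, the training set
contains few windows like them, and their prediction error is temporally
coherent, so it piles into a single spectral bin. The linearity-consistency
augmentation reduces this failure from catastrophic (140% residual on those
lines) to a few percent, but 20 epochs at 218 windows of 64 samples do not
eliminate it. Larger matrices (longer windows, more of them) shrink the gap
toward the oracle.

The simulator validates the *method*, not the scanner: coupling is linear
by construction (no nonlinear front-end effects), sensing coils are
noise-clean to ~1%, EMI sources are stationary in statistics within a
window, the phantom is geometric, and B1/gradient imperfections, eddy
currents and relaxation during the echo train are not modelled. A canceller
that passes here can still fail on hardware for reasons outside this model;
a canceller that fails here is wrong in a way no hardware can fix.
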