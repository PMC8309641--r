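---
title: "Motor-imagery EEG classification by time-frequency image subtraction: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Motor-imagery EEG classification by time-frequency image subtraction: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mibci)
```

## The problem

When a person imagines moving one hand, oscillatory power in the
sensorimotor mu (8–13 Hz) and beta (14–30 Hz) rhythms changes over the
contralateral and ipsilateral motor cortex: event-related
desynchronization (ERD) on one side, event-related synchronization
(ERS) on the other.  Electrodes C3 (left hemisphere) and C4 (right
hemisphere) sit mirror-symmetrically over these areas, so a two-class
(left vs. right hand) motor-imagery brain–computer interface can be
driven by the *lateralization* of band power across this single
electrode pair.

`mibci` implements a complete image-based classification pipeline for
such data:

1. **Preprocessing** — keep C3/C4, zero-phase 8–30 Hz band-pass,
   cue-locked epoching, baseline correction.
2. **Time–frequency imaging** — continuous Morlet wavelet transform of
   each channel, giving a frequency × time power map.
3. **Image subtraction (IS)** — the pixel-wise difference
   `power(C3) − power(C4)`, rescaled so that 0.5 encodes "no
   difference", as the single 64 × 64 classifier input.  Shared
   background energy cancels; the class-discriminative lateralization
   is what survives.
4. **Classification** — a compact CNN (two 7 × 7 convolution + 2 × 2
   max-pooling blocks) with a convolutional block attention module
   (CBAM) after each convolution, a 0.8-dropout layer, and a softmax
   head, trained with Adamax at learning rate 3 × 10⁻⁴.
5. **Evaluation** — 10 × 10-fold stratified cross-validation, accuracy
   and Cohen's kappa (κ = 2·p₀ − 1 for balanced two-class data).

A synthetic ERD/ERS trial generator makes every stage testable without
any external recordings.

## The wavelet transform

The transform is
$$W_x(a, \tau) = \frac{1}{\sqrt{|a|}} \int x(t)\,
  \psi^{*}\!\left(\frac{t - \tau}{a}\right)\,dt,
  \qquad
  \psi(u) = \pi^{-1/4} e^{i\omega_0 u} e^{-u^2/2},$$
with the Morlet centre parameter $\omega_0 = 6$ and the
scale–frequency map $a(f) = \omega_0 / (2\pi f)$.  `morlet_cwt()`
evaluates the integral as a Riemann sum carried out by FFT convolution
per analysis frequency; the wavelet is truncated at $|u| \le 5$, where
its Gaussian envelope is below $e^{-12.5}$.  The test suite verifies
the implementation against direct numerical quadrature of the integral
(relative error under $10^{-3}$; in practice about $10^{-7}$).

Choices the transform's definition leaves open:

* **Frequency grid** — 8–30 Hz in 0.5 Hz steps (45 rows), covering
  exactly the band-passed range.  Configurable via `cwt_config()`.
* **Edge handling** — implicit zero padding.  Each coefficient row
  carries a cone-of-influence attribute ($\sqrt{2}\,a$ seconds, the
  e-folding half-width) so users can discount edge-contaminated
  columns; the default 8-s trials leave the 4-s imagery window far
  from the edges at all analysed frequencies.
* **Power** — linear $|W|^2$ by default; `log1p` optionally.
* **Grayscale, not colormapped** — the classifier consumes the power
  matrix itself, resized and min–max scaled.  A colour rendering of
  the same matrix adds no information, so colormaps exist only in the
  PNG export (`export_png()`, `cmd_render()`).

## Image subtraction and the UD baseline

`image_subtract()` computes `D = power(C3) − power(C4)` *on the power
maps*, before any resizing or quantization, then rescales symmetrically
by `v ↦ 0.5 + v / (2·max|D|)` and resizes to 64 × 64 bilinearly.  Two
properties motivate the symmetric rescale instead of a plain min–max:

* 0.5 always encodes "zero difference", so a featureless trial is a
  flat grey image rather than amplified noise;
* the *sign* of the lateralization — the class information — is
  preserved: swapping the two input maps reflects the image about 0.5,
  which on simulated data maps a left-class input onto a right-class
  one.

The laterality convention is fixed throughout the package: a
left-hand trial raises C3 band power and depresses C4, so its
subtracted image sits *above* 0.5 in the post-cue mu/beta region;
right-hand trials mirror this.  Because the subtraction's sign is the
label encoding, `image_subtract()` refuses maps whose `channel` tags
are not (C3, C4) in that order.

The ablation baseline `stack_ud()` normalizes each channel's map
independently and stacks C3 above C4 before resizing — the "UD"
(up–down) input.  It retains all background energy in both maps, which
is exactly the redundancy the subtraction removes; the test suite
checks that on simulated trials the between-class distance of
class-mean images is strictly larger for the subtracted representation
at equal noise.

Normalization is strictly per-trial (no statistics across trials), so
classifier images can be computed once and reused across
cross-validation folds without leaking information between them.

The bilinear resize uses pixel-centre sampling with edge clamping.
This convention makes the geometry exact in two places the tests rely
on: a hot pixel maps to the proportionally corresponding output pixel,
and the UD stack of two identical maps yields identical top and bottom
halves.  A constant matrix has no contrast to scale and maps to a
uniform 0.5.

## The classifier

Input is a 64 × 64 single-plane image.  The forward path is

```
conv 7x7 (F1) -> ReLU -> CBAM -> maxpool 2x2/2
conv 7x7 (F2) -> ReLU -> CBAM -> maxpool 2x2/2
dropout(0.8) -> fully connected -> softmax(2)
```

CBAM applies channel attention
$M_c = \sigma(\mathrm{MLP}(\mathrm{avgpool}\,F) +
\mathrm{MLP}(\mathrm{maxpool}\,F))$ (shared two-layer MLP with
bottleneck ratio `r`, no biases) followed by spatial attention
$M_s = \sigma(f^{7\times 7}([\mathrm{avg}_c F'; \mathrm{max}_c F']))$,
each as a broadcast element-wise product.  The module never changes
tensor shape, and disabling it (`cbam = "none"`) reproduces the plain
CNN exactly — the IS-CNN ablation.  Because the architecture text
behind this design is ambiguous about whether attention sits after one
or both convolutions, `model_config(cbam = "first")` provides the
single-placement variant.

Fixed design points: 7 × 7 convolution kernels (same padding, stride
1), 2 × 2 max pooling with stride 2, dropout probability 0.8 read as
*drop* probability, Adamax with learning rate 3 × 10⁻⁴, cross-entropy
loss, and a direct flatten → 2-logit fully connected head.

Open parameters and their defaults in `model_config()`:

| parameter | default | note |
|---|---|---|
| `conv_filters` | 32, 64 | filter counts per block |
| `cbam_reduction` | 16 | channel-MLP bottleneck ratio |
| `batch_size` | 32 | minibatch size |
| `max_epochs` | 200 | training length |
| `cbam` | `"both"` | attention placement |

**Initialization.**  Convolution and fully connected weights are drawn
from a He-style normal, $\mathcal N(0, (2/\sqrt{\text{fan-in}})^2)$;
attention MLP and spatial-kernel weights use uniform fan-in draws; the
spatial-gate bias starts at +2.  The motivation is specific to this
architecture: every CBAM gate multiplies activations by roughly one
half at its neutral point, so two blocks attenuate the head's input
about sixteen-fold, and at the fixed small learning rate a unit-gain
initialization leaves the network on a long plateau before the logits
grow.  Starting the spatial gates nearly open (σ(2) ≈ 0.88, cf. the
LSTM forget-gate convention) and up-scaling the feed-forward weights
removes the plateau while keeping every gate trainable.  All biases
except the spatial gates start at zero.  Initialization, batch
shuffling, and dropout masks all derive from R's RNG, so a fitted
model is bit-reproducible from `config$seed`.

**Training accuracy in the log** is measured on-line under the active
0.8 dropout and therefore understates the fit; inference-mode accuracy
(`predict()`) is the meaningful number.

## The synthetic ERD/ERS generator

`simulate_trial()` builds each channel as the sum of

* a mu oscillation: unit-amplitude sinusoid at a per-trial random
  centre frequency (10.5 ± 1.25 Hz) and phase;
* a beta oscillation: the same construction at 22 ± 2 Hz with half the
  amplitude (beta rhythms are weaker than mu in sensorimotor
  recordings);
* 1/f "pink" background noise (white noise spectrally shaped to
  power ∝ 1/f, standardized, scaled by `noise_scale`).

During the motor-imagery window the two oscillations' *power* is
multiplied by `ers_gain` on the rising channel and `1 − erd_depth` on
the falling channel (amplitudes scale by the square roots), with a
0.25-s raised-cosine ramp at both ends so no spectral edge artifacts
appear.  Per-trial amplitude jitter (±20%) adds realistic variability
without touching the within-trial power ratio.

Defaults: 250 Hz sampling, 8-s trials, cue at 3 s, 4-s imagery window,
`erd_depth = 0.7`, `ers_gain = 1.5`, `noise_scale = 0.5`, 60 trials
per class.  The timing mirrors a standard cued motor-imagery paradigm;
the effect sizes are deliberately strong-but-noisy — a clean testbed
for the pipeline's mechanics, chosen once as plausible values for a
cooperative subject.  No published quantification of ERD depth backs
these numbers, and the generator makes no attempt at volume
conduction, ocular/muscular artifacts, non-stationary noise, or
between-subject variability.  Consequently, passing tests demonstrate
that the pipeline recovers the structure it is designed for; they do
not predict accuracy on real recordings, where the published
per-subject range on the standard benchmark spans roughly 68–95%.

The laterality convention (left ⇒ C3 power rises, C4 falls) is the
package-wide contract stated above; the opposite convention also
appears in the ERD/ERS literature, so the simulator documents and
tests it prominently rather than leaving it implicit.

## Evaluation protocol

`cross_validate()` implements repeated stratified k-fold
cross-validation (default 10 × 10).  Repetition *r* reshuffles the
stratified fold assignment with seed `seed + r − 1`; every trial is
tested exactly once per repetition.  The reported accuracy is the mean
over all 100 folds; the dispersion is the standard deviation across
the ten repetition means — the more conservative of the two common
readings of "10 × 10-fold".  Kappa is the linear image of accuracy
(κ = 2p₀ − 1, pe = 0.5 for balanced two-class data), and the kappa
dispersion is twice the accuracy dispersion, which is exactly how the
published accuracy and kappa benchmark tables for this method
reconcile.

`run_ablation()` evaluates UD-CNN, IS-CNN, and IS-CBAM-CNN under
identical fold assignments and identical per-fold model seeds, so
variant comparisons are paired.  A caveat the simulator makes visible:
at the package's strong-effect reference conditions *all* variants
approach ceiling accuracy, and the stacked baseline can edge out the
subtracted input by a percentage point or two — per-channel min–max
normalization yields higher-contrast images that optimize faster at
the fixed small learning rate, and with the class signal far above the
noise there is no redundancy penalty left for subtraction to remove.
The representational advantage of subtraction — strictly larger
between-class distance at equal noise — is a property of the images
themselves and is what the subtraction test suite verifies; an
accuracy advantage is expected only in noisier regimes like real
recordings, where background energy shared by C3 and C4 dominates the
stacked input.

All fold assignment, model initialization, and dropout randomness
descend deterministically from the protocol seed, so a report is
reproducible from its resolved configuration alone (`cmd_run()` writes
that file next to every result).

## Problem sizes used by the packaged tests

The test and acceptance runs use desk-scale sizes, chosen once as the
package's reference conditions: 120 simulated trials (one session's
worth), the 45 × 0.5 Hz frequency grid, and a reduced network —
`conv_filters = c(4, 8)`, `cbam_reduction = 4`, batch 8, 20 training
epochs (30 in the single-fit separability test) — with the
architecture-fixed learning rate, dropout, kernel and pooling sizes
unchanged.  Filter counts, batch size, and epochs are exactly the
parameters the architecture's description leaves open; at these
settings the full 10 × 10-fold evaluation of all three variants
completes in tens of minutes on one CPU, and the IS-CBAM pipeline
recovers the strong-effect synthetic classes at a mean accuracy above
0.9 with label-shuffled controls at chance.

## Known limitations

* The GDF/EDF formats of the public competition datasets are not read
  directly; recordings must be converted to the documented CSV format
  first.  Nothing in the package downloads or bundles those datasets,
  and the published per-subject accuracies are shipped only as
  reference tables for the aggregation and kappa arithmetic.
* The subtraction is defined for the logically symmetric C3/C4 pair
  only; it does not generalize to arbitrary channel pairs.
* Short-time Fourier and Hilbert–Huang time-frequency front ends are
  natural alternatives the interface leaves room for (any
  frequency × time power matrix can enter `to_image()` /
  `image_subtract()`), but they are not implemented.
* The dropout probability 0.8 follows the architecture's stated
  parameter read as a drop probability; if the original intent was a
  *keep* probability of 0.8, `model_config(dropout_rate = 0.2)`
  reproduces that reading.
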