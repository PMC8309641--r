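# mibci — motor-imagery EEG classification by time-frequency image subtraction

`mibci` classifies two-class (left vs. right hand) motor-imagery EEG
from the C3/C4 electrode pair.  Imagined movement desynchronizes the
mu (8–13 Hz) and beta (14–30 Hz) rhythms over one sensorimotor cortex
and synchronizes them over the other (ERD/ERS), and C3/C4 sit
mirror-symmetrically over those areas.  The package turns that
lateralization into an image-classification problem:

1. **Preprocess**: select C3/C4, zero-phase 8–30 Hz Butterworth
   band-pass, cue-locked epochs, baseline correction.
2. **Morlet wavelet transform** per channel:
   *W*(a, τ) = |a|<sup>−1/2</sup> ∫ x(t) ψ\*((t − τ)/a) dt with
   ψ(u) = π<sup>−1/4</sup> e<sup>iω₀u</sup> e<sup>−u²/2</sup>, ω₀ = 6,
   a(f) = ω₀/(2πf), giving frequency × time power maps.
3. **Image subtraction (IS)**: D = power(C3) − power(C4), rescaled so
   0.5 encodes zero difference, resized to 64 × 64 — background energy
   cancels, the class-discriminative lateralization survives (a
   vertically stacked "UD" image is provided as the ablation
   baseline).
4. **Attention CNN**: two 7 × 7 convolution + 2 × 2 max-pool blocks
   with a convolutional block attention module (channel attention
   σ(MLP(avgpool F) + MLP(maxpool F)), then spatial attention
   σ(conv7×7([avg<sub>c</sub>; max<sub>c</sub>]))) after each
   convolution, dropout 0.8, softmax head; trained with Adamax at
   lr = 3·10⁻⁴ (implemented in RcppArmadillo, bit-reproducible from a
   seed).
5. **Evaluation**: 10 × 10-fold stratified cross-validation; accuracy
   and Cohen's kappa, κ = (p₀ − pe)/(1 − pe) with pe = 0.5.

A synthetic ERD/ERS trial simulator (lateralized mu/beta power
modulation over 1/f noise) makes the whole pipeline testable without
external data.  Who this is for: BCI/neural-engineering researchers
who want a transparent, fully scripted reference implementation of the
subtraction + attention pipeline and its evaluation protocol.

## Worked example

```r
library(mibci)

trials <- simulate_dataset(sim_config(n_trials_per_class = 20, seed = 42))
trials
#> <mi_dataset> 40 trials (left: 20, right: 20)

imgs <- trials_to_images(trials, "subtract")   # 64 x 64 x 40 array
cfg  <- model_config(conv_filters = c(4, 8), cbam_reduction = 4,
                     batch_size = 8, max_epochs = 20, seed = 1)
fit  <- cbam_cnn(imgs, attr(imgs, "labels"), cfg)
fit
#> Attention CNN classifier (left vs right)
#>   conv filters 4/8, 7x7 kernels, CBAM: both
#>   trained 20 epochs (final loss 0.6712, accuracy 0.650)

mean(predict(fit, imgs) == attr(imgs, "labels"))
#> [1] 1

report <- cross_validate(imgs, attr(imgs, "labels"),
                         cnn_fit_predict(cfg),
                         folds = 5, reps = 2, seed = 1)
report
#> <mi_eval> IS-CBAM-CNN: 2x5-fold CV on 40 trials
#>   accuracy 71.2% +/- 1.8%   kappa 0.425 +/- 0.035

kappa_score(0.907)
#> [1] 0.814
```

Reading the numbers: the in-training log accuracy (0.650) is measured
under the active 0.8 dropout and understates the fit — inference-mode
accuracy on the same images is 1.  The small 40-trial, 2 × 5-fold run
above is deliberately tiny; at the package's reference conditions (120
trials, 10 × 10 folds, 20 epochs) the IS-CBAM pipeline exceeds 90%
mean cross-validated accuracy on strong-effect synthetic data, which
is what the acceptance suite verifies.  `kappa_score()` maps a
balanced-task accuracy to chance-corrected agreement (0.907 → 0.814).

The ablation harness compares the three input/architecture variants
under paired folds:

```r
reports <- run_ablation(trials, model = cfg, folds = 5, reps = 2, seed = 1)
sapply(reports, `[[`, "mean_accuracy")
```

## Command line

A thin front end over the same functions:

```sh
inst/cli/mibci simulate --config cfg.yaml --out simdir
inst/cli/mibci run --data simdir --variant IS-CBAM-CNN --out rundir
inst/cli/mibci render --data simdir --out pngdir
```

Every run writes a `resolved_config.yaml` with all defaults made
explicit; re-running from that file reproduces the report exactly.

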