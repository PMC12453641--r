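---
title: "Denoising low-dose CT with a hybrid CNN-transformer: model, simulator and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Denoising low-dose CT with a hybrid CNN-transformer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model

Quarter-dose CT acquisitions suffer from quantum noise that filtered
back-projection turns into correlated streaks and mottle. The network in
this package learns the mapping from a low-dose slice $X$ to its
normal-dose counterpart $Y$ as a residual: it predicts $R$ and returns
$Y = X + R$. The residual parameterisation means an untrained network with
a zero-initialised output head is exactly the identity, which both
stabilises early training and gives the test suite a bit-exact anchor.

The architecture is a three-scale U-shaped encoder–decoder:

* a shallow 3×3 convolution lifts the slice to `embed_dim` channels;
* each encoder stage applies `depths_per_stage[i]` fusion blocks (RSTB)
  and then a 4×4 stride-2 convolution that halves the resolution and
  doubles the channels;
* a bottleneck of RSTBs sits at the coarsest scale;
* decoder stages mirror the encoder with 2×2 stride-2 transposed
  convolutions, concatenate the encoder skip, reduce back with a 1×1
  convolution, and apply the same number of RSTBs;
* a final 3×3 convolution emits the residual.

**RSTB.** A 1×1 convolution is followed by a channel split into halves.
One half flows through a residual convolution block (two 3×3 convolutions
with ReLU and an identity skip) — the local branch. The other half flows
through a chain of combined attention transformer units — the non-local
branch. The halves are concatenated, merged by a second 1×1 convolution,
and added to the block input. Splitting (rather than running both
branches at full width) keeps the parameter and FLOP budget of a block
close to a single-branch transformer block.

**CATU.** Each unit computes
`X1 = WMSA(LN(X)) + alpha * CCAFL(LN(X)) + X` followed by
`Xout = X1 + MLP(LN(X1))` with a GELU MLP of expansion ratio 4. Window
attention uses `M x M` windows, per-head scaled dot-product attention with
a learnable relative position bias table covering all $(2M-1)^2$ offsets,
and alternates unshifted and half-window cyclically shifted layers;
shifted layers add a $-100$ bias to attention logits of position pairs
that originate from different image regions, which drives their softmax
weights to zero.

**CCAFL / CAL.** The channel-attention gate runs two 3×3 convolutions
(the first reduces channels to one third, the second restores them; the
stack uses a leaky ReLU). Both the reduced activation and the final
convolution output are globally average-pooled, passed through their own
1×1 convolution and feature normalisation, summed, ReLU-ed, and mapped by
a final convolution with a sigmoid to per-channel weights in $(0,1)$ that
multiply the last convolution's output. The plain channel attention layer
(CAL) used for comparison has the identical layer budget but both pooling
paths see only the final convolution's output.

**DFRM.** In encoder stages after the first, a parallel branch
patch-embeds the stage input to half resolution (2×2 stride-2
convolution), refines it with an RSTB, bilinearly upsamples, and applies a
merge projection before being summed with the stage's main output. The
merge projection is zero-initialised so that training starts from the
plain-encoder function; the branch for the first stage is omitted
entirely because its output would never be summed and its parameters
would be untrainable dead weight.

## Losses

The Charbonnier loss is implemented in its standard per-pixel form
$\mathrm{mean}\,\sqrt{d^2+\varepsilon^2}$ with $\varepsilon = 10^{-3}$;
it is symmetric, everywhere differentiable, bounded below by
$\varepsilon$, and behaves like mean absolute error for
$|d|\gg\varepsilon$. A formulation without the square on the norm and
without the pixel average would not be dimensionally consistent across
image sizes, so the package uses the established form throughout.

The multi-scale perceptual loss averages the same Charbonnier distance
over the feature maps of a *frozen* four-stage convolutional extractor.
Pretrained large-backbone weights (e.g. a ResNet-50) are an optional
external download that cannot be assumed; requesting them falls back,
with a warning, to a seeded random-weight extractor of the same stage
structure (`tiny_random`: four stride-2 3×3 convolutions with leaky
ReLU). Random deep features are a recognised, weaker but serviceable
perceptual signal, and they keep the package fully self-contained. The
compound loss is `L_char + lambda * L_per` with `lambda = 0.1` by
default; `lambda` is surfaced in `loss_spec()` because no single value is
canonical.

## Tunable parameters

| parameter | default | meaning / rationale |
|---|---|---|
| `embed_dim` | 32 | channels after the shallow conv; with three stages this spans 32→256 and trains in ~GB-scale memory |
| `depths_per_stage` | 2,2,2 | RSTBs per stage; three stages fit 64×64 patches (64→32→16→8) |
| `bottleneck_depth` | 2 | RSTBs at the coarsest scale |
| `window_size` M | 8 | must divide the padded patch size; 8 divides 64 and 512 |
| `alpha` | 0.01 | channel-attention scale; "small" is the only constraint, so it is exposed in the config |
| heads | `max(1, C/32)` | fixed head width of 32 channels |
| `eps` | 1e-3 | Charbonnier smoothing |
| `lambda` | 0.1 | perceptual weight |
| learning rate | 2e-4 | reference protocol; the compact desk-scale runs use 2e-3, appropriate for the much smaller model |
| betas | 0.9, 0.999 | the stated 0.9 matches the conventional first moment; the second uses the optimizer's standard default |
| batch size / epochs / patch | 12 / 100 / 64 | reference protocol defaults |

## The synthetic data generator

The licensed clinical dataset the architecture was designed around cannot
be redistributed, so the package generates its own study conditions:

* **Phantoms** are piecewise-smooth ellipse composites in $[0,1]$: a
  soft-tissue body outline, interior structures of varied contrast, and a
  low-contrast lesion-like ellipse that exercises edge preservation.
* **Dose simulation** forward-projects the phantom (parallel beam, 180
  views over 180°, unit detector spacing — the simplest geometry that
  produces streak noise), converts intensity to attenuation with a frozen
  scale of 0.05 per traversed pixel, draws Poisson counts around
  $I_0 e^{-\ell}$ with a small Gaussian electronic noise floor
  ($\sigma = 2$ counts), log-transforms, and reconstructs with
  ramp-filtered back-projection (discrete Ram–Lak kernel). The
  reconstruction of the noisy sinogram has the spatially *correlated*
  noise that distinguishes real low-dose CT from i.i.d. Gaussian
  corruption; the test suite verifies positive neighbour autocorrelation
  and a strictly monotone dose–variance ladder.
* **Default dose.** $I_0 = 200$ was chosen once so that the noisy input
  scores ≈ 18–22 dB PSNR against the clean slice on 64×64 phantoms —
  the band typical of quarter-dose inputs — and then frozen as a named
  constant (`ldct_constants()`).
* An `image_mixed` mode (signal-dependent Poisson + Gaussian in the image
  domain) provides a fast surrogate for unit tests that do not need
  projection-domain statistics.

What the generator does **not** emulate: fan-beam/helical geometry,
scatter, beam hardening, detector crosstalk, anatomical texture, or the
HU calibration of clinical scanners. Tests passing on this generator
therefore demonstrate that the architecture, optimization and metrics
behave as designed — not that any particular clinical image-quality
number would be reproduced on scanner data.

## Numerical and design choices

* **Attention input.** The unit's printed formulation applies attention
  to the raw residual stream, but the established convention for this
  block family is pre-norm attention; the package defaults to
  `MSA(LN(X))` and offers `msa_on_raw_input = TRUE` to honour the raw
  form. The channel-attention branch always sees the normalised tensor.
* **Window dimensionality.** Window features are treated as $M^2 \times
  C$ matrices ($M^2$ positions per window); the count of windows is
  $HW/M^2$, which is the only dimensionally consistent reading.
* **Padding.** All spatial handling uses reflect padding with exact
  cropping: the model pads to a multiple of `window_size * 2^stages`,
  partitioning pads to a window multiple, and the DFRM pads odd inputs
  rather than failing. Indices are 0-based in none of the public API —
  everything follows R's 1-based convention.
* **Initialisation.** Truncated normal (sd 0.02) for projections and
  convolutions, identity for norms, zeros for biases and the relative
  position bias table, zeros for the DFRM merge projection. Same config +
  seed gives bit-identical parameters.
* **Feature normalisation in the gate.** The pooled-path normalisation
  layers keep running mean/variance (momentum 0.1) that are used in both
  training and evaluation and treated as constants in the backward pass.
  The trainer normalises pooled channel vectors whose per-batch statistics
  at desk-scale batch sizes are too noisy to standardise on; running
  statistics are the stable choice and evaluation-time behaviour matches
  the convention of using stored statistics. Each of the two pooling
  paths has independent parameters and statistics.
* **Ablation skeleton.** All variants share the split/concat skeleton and
  differ only in the named component (identity conv branch for
  `baseline`/`catu_only`, no gate for `*_no_ccafl`, CAL for `rstb_cal`,
  DFRM only for `full`). This makes the ablations controlled comparisons
  and gives the parameter-count ladder baseline ≤ catu_only ≤
  rstb_no_ccafl ≤ rstb ≤ full by construction. A literal plain U-net
  baseline with full-width transformer layers would have *more*
  parameters than the half-width fusion variants and would confound the
  comparison.
* **CATU chains** inside one RSTB alternate unshifted/shifted starting
  unshifted; DFRMs are encoder-only.
* **Automatic differentiation.** The package implements a small
  tape-based reverse-mode engine on dense matrices (`N x C` feature
  layout). Every primitive's gradient is tested against central finite
  differences, structural ops (gather/scatter, depth-to-space, bilinear
  upsampling) have exact adjoints, and batches are row-stacked so one
  BLAS call serves the whole batch.
* **Optimizers.** AdamW (decoupled weight decay 0.01) is the default;
  Adam, NAdam and SGD-momentum are available for the optimizer
  comparison. No learning-rate schedule is applied by default; cosine
  decay is available behind `lr_schedule = "cosine"`.
* **Checkpoint selection** uses best validation PSNR, evaluated every
  epoch on the held-out split.

## Metrics

PSNR, SSIM and FSIM are computed on a configurable dynamic range
(`data_range = 255` by default; the simulator's `[0,1]` slices are scored
with `data_range = 1`, and FSIM internally rescales to the 0–255 scale on
which its stabilizers $T_1 = 0.85$, $T_2 = 160$ are defined). SSIM uses
the Gaussian-weighted 11×11 window with $\sigma = 1.5$ and matches
scikit-image's implementation to $10^{-10}$ on a frozen fixture. FSIM
combines log-Gabor phase congruency (4 scales from wavelength 6, factor
2, $\sigma_{onf} = 0.55$; 4 orientations; per-orientation noise threshold
from the finest-scale median amplitude) with Scharr gradient-magnitude
similarity, weighted by the maximum phase congruency; replicate-padded
gradients keep the index exactly invariant to a shared intensity offset.

## Problem sizes used by the tests and the acceptance script

The package's own verification runs at desk scale: the compact
configuration (`embed_dim = 16`, one RSTB in each of two stages and the
bottleneck, window 8) is trained for 200 AdamW steps at batch 4 and
learning rate 2e-3 on 16 simulated 64×64 pairs (12/2/2
train/val/test). That run lifts held-out PSNR from ≈ 19–20 dB (noisy
input) to ≈ 26–27 dB. These sizes were chosen as the smallest
configuration in which the method's defining behaviour — a clear
denoising gain from the full hybrid architecture — is reliably visible;
they are stated here so results are interpreted at the scale that
produced them.

## Known limitations

* CPU-only and desk-scale: the reference-scale model (≈ 5M parameters,
  100 epochs) is expressible but not practical to train in this engine.
* The perceptual extractor is a seeded random network unless external
  pretrained weights are supplied; absolute perceptual-loss values are
  therefore not comparable across seeds.
* The simulator's geometry and dose calibration are declared stand-ins;
  no claim of clinical noise realism beyond the verified statistical
  properties (dose monotonicity, spatial correlation) is made.
* DICOM support is read-only and limited to single-frame uncompressed
  little-endian files.
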