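---
title: "Removing gadolinium contrast from T1-weighted brain MRI: models, phantoms and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Removing gadolinium contrast from T1-weighted brain MRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Clinical imaging archives mix T1-weighted brain MRI acquired with and
without a gadolinium-based contrast agent (T1ce and T1nce).  Gadolinium
brightens vascularized and leaky structures (vessels, meninges, some
lesions) and perturbs the apparent contrast between gray matter, white
matter and CSF.  Standard neuroimaging tools — tissue segmentation in
particular — were built and validated on non-enhanced images, so features
extracted from T1ce images are unreliable and can bias downstream
analyses such as atrophy quantification or differential diagnosis.

`decontrast` implements an image-translation approach to this
harmonization problem: 3D U-Net-like generators map a T1ce volume onto a
synthetic T1nce volume, either trained directly with an L1 objective or
fine-tuned adversarially with a patch-based conditional GAN.  The package
also implements the two-tier validation used to judge such models:

1. **Synthesis accuracy** — brain-masked MAE, PSNR and SSIM between the
   synthetic and real T1nce, with the T1ce/T1nce similarity as the
   baseline, compared by paired t-tests with Bonferroni correction.
2. **Segmentation fidelity** — GM/WM/CSF volumes from a tissue
   segmentation of each image, compared via the absolute and signed
   volume differences normalized by the reference total intracranial
   volume (AVD/VD, reported in cm³ after rescaling by the mean TIV) and
   the Dice overlap of the binarized maps.

Because the clinical data the approach targets sits in access-restricted
warehouses, the package ships a first-class synthetic phantom generator
that emulates the statistical structure of such a paired data set and
lets every claim be tested end to end on a desk.

## The models

All three generators map a single-channel volume to a same-shape volume
through an encoder–decoder with a final hyperbolic tangent.  At the data
interface, $[0,1]$ intensities are mapped affinely to $[-0.9, 0.9]$ and
back: the 10% headroom keeps targets away from the tanh asymptotes, where
the gradient vanishes — background is the majority class of a head-sized
field of view, and placing it exactly at $-1$ makes the saturated
constant output an attractor.  Channel width doubles per level from
`base_channels`:

* **Res-U-Net** — descending blocks of strided $4^3$ convolution +
  instance normalization + LeakyReLU($\alpha = 0.2$), each followed by a
  residual module of 1–3 (conv + LeakyReLU) blocks with an additive skip;
  ascending blocks of transposed convolution + ReLU joined to the
  same-level encoder features by concatenation; final upsample ×2 +
  convolution + tanh.
* **Att-U-Net** — descending blocks of two (conv + norm + ReLU) with
  $2^3$ max pooling between levels; each ascending block upsamples ×2,
  convolves, gates the encoder skip features with an additive attention
  gate (two 1×1×1 convolutions, ReLU, a third convolution and a sigmoid,
  multiplying the skip features by coefficients in $(0,1)$), then applies
  two conv + norm + ReLU blocks.
* **Trans-U-Net** — four strided convolutional descending blocks, linear
  projection of the bottleneck voxels to token embeddings, four
  transformer layers (multi-head self-attention and a feed-forward
  network, each with a residual connection), reshaping, and ascending
  blocks with transposed convolutions.

The adversarial variant adds a conditional patch discriminator: the
conditioning T1ce patch and a candidate T1nce patch are
channel-concatenated and passed through three strided convolution +
LeakyReLU blocks, a final convolution and global average pooling; a
sigmoid bounds the score to $(0,1)$ so it reads as the probability that
the candidate is real.  On the reference 128³ grid the patch lattice is
the classic 8 × 64³ patches at stride 50; at other grid sizes the lattice
scales proportionally.

Two loss formulations are implemented because the descriptions of this
family of models alternate between them: the default least-squares form
($\mathrm{adv} = \overline{(p - \ell)^2}$, stabilizing in the LSGAN
sense) and the literal log form ($L_G = -\log p(\text{fake}) + \lambda
L_1$, $L_D = -\tfrac12 \log p(\text{real}) - \tfrac12 \log(1 -
p(\text{fake}))$, epsilon-guarded).  Soft labels draw adversarial
targets uniformly from narrow sub-intervals; the conventional direction
(real ∈ [0.7, 1], fake ∈ [0, 0.3]) is the default because the
discriminator loss is optimized at $p(\text{real}) = 1$, while the
swapped (`paper_literal`) direction is available behind a flag.  The
training protocol is the warm-started one: the generator is first
trained alone on the L1 loss (batch size 2), the discriminator is
pretrained against that frozen generator, and the two are then trained
jointly at batch size 1, keeping the checkpoint with the best training
loss at every stage.

### Implementation note

No deep-learning runtime is assumed: the networks run on a compact
reverse-mode automatic-differentiation tape over plain R arrays, with
compiled im2col/col2im kernels turning every 3D convolution into a dense
matrix product.  Every building block's analytic gradient is verified
against central finite differences in the test suite, which keeps the
hand-built backward passes honest.

## The phantom

`make_phantom()` builds a paired subject as nested ellipsoids — a WM
core, a GM ribbon, a CSF shell plus ventricles — with per-subject jitter
of the axes and centre, hard ground-truth tissue maps (probabilities sum
to one inside the brain mask), and an *enhancing compartment* made of
angular patches of the outer (meningeal) shell plus vessel-like random
tubes.  The T1ce member of a pair is
`clip01(t1nce + delta * enhancing + contrast_shift * GM)`, so the two
volumes differ only where enhancement (or quality degradation) acts.

Default study conditions (all configurable):

| Parameter | Default | Meaning |
|---|---|---|
| grid, voxel | 32³ at 6 mm | head-sized 19.2 cm field of view |
| tissue means | WM 0.75, GM 0.55, CSF 0.20 | bright-WM T1 contrast in [0,1] |
| `noise_sigma` | 0.01 | shared acquisition noise of a pair |
| `delta` | 0.30 | enhancement brightening |
| `contrast_shift` | +0.05 | GM shift under gadolinium |
| degradation | c₁ = 0.3, c₂ = 0.6; blur 0.6/1.2 vox; noise 0.02/0.05 | grade-1/2 contrast, motion, noise |

Quality grades follow the three-level scheme (0 good, 1 medium,
2 severe) per characteristic — contrast, motion, noise — and map to
image labels by the max-grade rule (`quality_label()`).  Simulated
cohorts give every T1nce a medium/good quality, draw T1ce grades in
{0, 1} except for a fixed number of subjects whose T1ce is forced low
quality, mirroring the pairing rule of the clinical cohort the phantom
emulates (a T1nce of usable quality, a minority of low-quality T1ce).
`delta` and `contrast_shift` are calibrated only to make the
*directional* findings reproducible — the enhancement is clearly visible
and biases an intensity-based segmenter — not to match any clinical
effect size, for which no quantitative model exists.

What the phantom deliberately does not model: real anatomy, lesions,
bias fields, scanner and field-strength effects, and independent noise
between the two acquisitions of a pair (the pair shares one noise field
so that it differs only where enhancement and degradation act; the
degradation operator then adds per-image noise).  Passing tests
therefore demonstrate that the machinery — architectures, losses,
training loops, metrics — behaves as specified on data with this
structure, not that the models reach clinical-grade synthesis.

## Desk-scale experiment

The end-to-end chain (`run_pipeline()`, also used by
`scripts/acceptance.R`) runs at problem sizes chosen so the whole
experiment fits in minutes of a single CPU: 32 phantom pairs (4 with a
low-quality T1ce), a 230/26-style split scaled to 20 training and 8
held-out good-quality pairs (test fraction 0.29), and an attention-gated
generator of depth 4 with 6 base channels trained for 30 epochs with
Adam at learning rate 1e-3 (the 2e-4 of the reference protocol is kept
as the package default for full-scale runs; the higher rate is the
appropriate choice for this few-step regime).  The expected outcome
mirrors the published directional findings: the synthetic T1nce is
closer to the real T1nce than the T1ce is (lower masked MAE, higher
SSIM), and GM/CSF volumes from the synthetic image are closer to the
reference than those from the T1ce, because the enhancement biases the
intensity-based segmenter on T1ce.

## Numerical choices and edge cases

* **Resampling** uses a corner-aligned trilinear convention (output
  sample $i$ reads input coordinate $i\,(n_{in}-1)/(n_{out}-1)$);
  constants are preserved exactly and affine ramps survive round trips
  to machine precision.  Centred crops break odd margins toward the
  origin.
* **Min-max rescaling** errors on (near-)constant images
  (range < `rescale_eps`).
* **SSIM** uses a 7³ uniform window, $K = (0.01, 0.03)$, biased
  (divide-by-N) window moments, masked intensities and masked-centre
  averaging over fully-contained windows, so voxels outside the brain
  mask can never influence the value.  PSNR of identical images returns
  `Inf`.
* **The stand-in segmenter** is a three-class Gaussian mixture EM on the
  masked intensities, quantile-initialized, with classes labelled
  CSF/GM/WM by their final means (so any initialization order converges
  to the same labelled maps); variances are floored at $10^{-3}$ to keep
  noise-free phantoms well-posed, and inputs with fewer than three
  distinct masked intensities are flagged degenerate rather than
  segmented.  It is plumbing, not a contribution: probability maps from
  full segmentation frameworks can be read from NIfTI instead.
* **Binarization ties** go GM > WM > CSF, fixed and documented.
* **AVD/VD** rescale by the mean reference TIV across the two test
  sets; this common constant does not affect comparisons, and
  `avd = |vd|` is asserted as an invariant.
* **Determinism**: a single master seed derives all stage seeds by fixed
  offsets; phantoms, splits, initializations, shuffling and soft-label
  draws are all reproducible bit for bit, and training trajectories are
  identical across reruns of the same configuration.
* **Degenerate cases**: empty masks error; an all-zero difference vector
  in the paired t-test reports $t = 0, p = 1$, while constant nonzero
  differences are flagged degenerate; pairs whose segmentation is
  degenerate are recorded as missing in the pipeline tables rather than
  aborting the run.

## Design choices where the design was open

* The transformer variant ends in a convolution + tanh rather than a
  softmax: a softmax over one output channel is degenerate for intensity
  regression, so the final stage matches the other two generators.
* Normalization layers compute per-sample statistics over the spatial
  dimensions (train and eval).  At the batch sizes this family of models
  uses (1–2), batch normalization effectively degenerates to this
  anyway, and it keeps inference deterministic and batch-independent.
* Decoder convolution blocks are normalized in all three variants, as in
  the reference architectures this family derives from (attention U-Net
  up-blocks, pix2pix-style decoders).  Without decoder normalization the
  unbounded ReLU chain lets activations grow until the final tanh
  saturates and training dies at a constant output — observed, not
  hypothetical.
* Patch scores enter the losses as independent samples (not averaged per
  volume first); the volume-level score is reported as their mean.
* The cGAN checkpoint rule selects on the total generator loss $L_G$.
* Exact per-layer channel widths of the reference architectures are not
  reproduced; widths are config-exposed and parameter counts are checked
  against closed-form per-layer formulas instead.

## Limitations

The phantom's geometry is far simpler than brain anatomy, so absolute
metric values on phantoms are not comparable to clinical ones — only
directions and orderings are meaningful.  Training at 32³ for tens of
epochs demonstrates learning and the directional findings, not
convergence; full-scale runs (128³, 300 epochs) use the same code paths
but are outside a desk budget.  Unpaired (cycle-consistent) training and
perceptual losses are out of scope.
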