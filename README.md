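# decontrast

Removing gadolinium contrast from 3D T1-weighted brain MRI by image
translation, in R.

## The problem

Large clinical imaging archives mix T1-weighted brain scans acquired
with and without a gadolinium-based contrast agent (T1ce / T1nce).
Gadolinium brightens vessels and meninges and shifts the apparent
gray–white contrast, so tissue segmentation tools built for non-enhanced
images produce biased volumes on T1ce — a problem for anyone extracting
volumetric features (atrophy, differential diagnosis) from heterogeneous
clinical data.  One remedy is to translate T1ce into a synthetic T1nce
before feature extraction.

`decontrast` implements that translation and its validation end to end:

* three 3D U-Net-like generators — residual (`res`), attention-gated
  (`att`) and transformer-bottleneck (`trans`) — trained with an L1
  objective, optionally fine-tuned as a conditional GAN with a
  patch-based discriminator (eight 64³ patches at stride 50 on the
  reference 128³ grid), least-squares or literal log losses, and soft
  labels;
* the two-tier validation: brain-masked MAE / PSNR / SSIM against the
  real T1nce (with the T1ce as baseline, paired t-tests, Bonferroni
  correction), and tissue-volume fidelity — GM/WM/CSF volumes from a
  3-class intensity segmenter, absolute/signed volume differences
  normalized by the reference total intracranial volume
  (AVD = |V_I − V_J| / TIV_I × TIV̄, in cm³) and Dice overlap;
* a seeded paired brain-phantom generator (nested ellipsoidal tissue
  compartments, an enhancing shell-and-vessels compartment, 0/1/2
  quality grades for contrast/motion/noise) that writes BIDS-like trees
  with ground-truth tissue maps, so the whole chain runs on a desk
  without clinical data.

The networks are implemented from first principles — a small
reverse-mode autodiff tape over R arrays with compiled im2col/col2im
convolution kernels — and every analytic gradient is tested against
finite differences.

## Worked example

```r
library(decontrast)

# one synthetic subject: paired T1ce/T1nce with ground truth
s <- make_phantom(phantom_params(seed = 7))
mae(s$t1ce, s$t1nce, s$brain_mask)    # baseline dissimilarity, percent
#> [1] 4.703817

# fit an attention-gated translator on a (deliberately tiny) cohort
pairs <- lapply(1:6, function(i)
  as_image_pair(make_phantom(phantom_params(seed = 100 + i))))
fit <- fit_translator(pairs, variant = "att",
                      gen_cfg = generator_config("att",
                                                 input_shape = c(32, 32, 32),
                                                 depth = 4, base_channels = 6),
                      train_cfg = train_config(epochs = 30, lr = 1e-3,
                                               seed = 1))
print(fit)
#> <mri_translator> att generator, 227413 parameters
#>   trained on 6 pairs, 30 epochs; best L1 loss 0.40592 (epoch 30)

# translate a held-out subject
t <- make_phantom(phantom_params(seed = 999))
synth <- predict(fit, t$t1ce)
mae(synth, t$t1nce, t$brain_mask)
#> [1] 9.293378
```

Six pairs are enough to exercise the API, not to beat the baseline: the
training loss is still falling at epoch 30 and the held-out MAE (9.3%)
remains above the 5.1% T1ce/T1nce baseline of that subject.  The actual
experiment — 32 pairs, a train/test_good/test_low split, 20 training
pairs for 30 epochs, both validation tiers with their statistics — is one
call:

```r
res <- run_pipeline(run_config(seed = 1, out_dir = "out"))
round(res$summary, 2)
#>          mae_t1ce     mae_synthetic         psnr_t1ce    psnr_synthetic
#>             13.50              5.96             16.23             22.51
#>         ssim_t1ce    ssim_synthetic       avd_gm_t1ce  avd_gm_synthetic
#>              0.89              0.95            299.85             93.27
#>       avd_wm_t1ce  avd_wm_synthetic      avd_csf_t1ce avd_csf_synthetic
#>             74.20             81.42            263.25             12.95
#>           tiv_bar           n_train       n_test_good        n_test_low
#>           2395.10             20.00              8.00              4.00
```

Read: the synthetic T1nce is much closer to the real T1nce than the T1ce
is (masked MAE 5.96% vs 13.50%, SSIM 0.95 vs 0.89 across the 12 test
pairs), and gray-matter and CSF volumes extracted from the synthetic
image are far closer to the reference (AVD 93 vs 300 cm³ and 13 vs
263 cm³) — the enhancement biases the intensity-based segmenter on T1ce,
and translation removes most of that bias.  The run writes
`similarity.csv`, `segmentation.csv` and `summary.json` under `out/` and
takes about 10 minutes on one CPU.  A thin CLI over the same functions is
installed at `inst/cli/decontrast` (subcommands `simulate`, `train`,
`translate`, `run-all`).

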