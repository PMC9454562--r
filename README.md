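# ecgan — self-supervised 3D adversarial electronic cleansing for CT colonography

Electronic cleansing (EC) removes contrast-tagged residual fluid and stool
from CT colonography (CTC) volumes so the colon surface can be read on a
virtual 3D fly-through. Segmentation-based EC is limited to voxel accuracy
and leaves artifacts at air/tissue/tagging partial-volume boundaries.
`ecgan` implements an alternative for researchers working on CTC image
analysis: a 3D image-to-image conditional adversarial network translates
uncleansed subvolumes directly into cleansed ones, and a self-supervised
loop fine-tunes the network to each input case without annotated truth.

The core is a 3D pix2pix-style GAN — a U-Net generator `G` (N stride-2
encoder stages, N transposed-conv decoder stages, skip connections, tanh
output) and a PatchGAN discriminator `D` scoring `(x, candidate)` pairs on
a grid of local patches — trained on the objective

    G* = arg min_G max_D [ L_GAN(G, D) + λ · L1(G) ]
    L_GAN(G, D) = E[log D(x, y)] + E[log(1 − D(x, G(x)))]
    L1(G)       = E[ ‖y − G(x)‖₁ ],   λ = 100

with the non-saturating surrogate for the generator's adversarial term.
Training data are *fixed-truth* VOI pairs (tagged phantom subvolume,
registered native subvolume). Case adaptation then runs T self-supervised
iterations: *dynamic-truth* pairs — the case's uncleansed VOIs paired with
targets first estimated by a threshold EC — are trained on together with
the fixed pairs, and after each iteration every dynamic target is replaced
by the evolving generator's own output `G(x)`. Cleansing quality is
quantified as PSNR (MAX = 1024 HU) between `G(x)` and the desired output
after scaling back from [−1, 1] to [−1024, 1024] HU, with paired t-tests
between conditions.

Because the reference datasets (physical anthropomorphic phantom scans and
clinical cases) are not publicly available, the package includes a digital
colon-phantom simulator producing registered native/tagged volume pairs
with ground-truth fluid masks and centerlines at three tagging levels —
the whole pipeline builds, trains and evaluates offline. The volumetric
conv-net engine (forward, backward, Adam) is implemented inside the
package on compiled im2col/col2im kernels plus BLAS; gradients are
verified against finite differences in the test suite.

## Worked example

A desk-scale end-to-end study — simulate phantoms, extract VOIs along
computed centerlines, pre-train on the low/high tagging levels, run three
self-supervised iterations on the held-out moderate level (about two and a
half minutes on one CPU core):

```r
library(ecgan)
res <- run_end_to_end(desk_config(seed = 101))
res$baseline   # PSNR of the uncleansed input against the native truth
#> <PSNR report> [condition=uncleansed] n = 4: 10.35 +/- 0.18 dB
res$curve      # PSNR after pre-training (iteration 0) and each iteration
#>   iteration mean_psnr    sd_psnr n
#> 1         0  19.79598 0.44466521 4
#> 2         1  23.50829 0.07766584 4
#> 3         2  23.68322 0.06803945 4
#> 4         3  23.83859 0.06536307 4
```

Reading the numbers: the uncleansed volumes sit at ~10 dB against the
clean truth (the tagged pool dominates the error); supervised pre-training
roughly doubles that; and the self-supervised iterations — which never see
the held-out level's truth — add a further ~4 dB. The run directory
contains `psnr_curve.csv`, `loss_history.csv`, network checkpoints, the
config and a manifest of derived seeds; rerunning with the same seed
reproduces all of them bit-identically.

Individual stages are available as plain functions (`generate_phantom()`,
`compute_centerline()`, `extract_vois()`, `make_fixed_pairs()`,
`pretrain()`, `selfsup_iteration()`, `apply_full_volume()`,
`evaluate_generator()`, `paired_ttest()`) for custom studies; full-scale
defaults (`default_run_config()`: N = 5, 128³ VOIs, 200 epochs, batch 3,
lr 2e-5, T = 6) are what the reference protocol prescribes.

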