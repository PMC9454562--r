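---
title: "Self-supervised 3D adversarial electronic cleansing: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Self-supervised 3D adversarial electronic cleansing: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

CT colonography (CTC) screens the colon for polyps on CT volumes. Residual
fluid and stool are tagged with an oral contrast agent so they appear bright
(several hundred HU), and *electronic cleansing* (EC) then removes the
tagged material computationally, so that a virtual 3D fly-through shows a
clean mucosal surface. Segmentation-based EC subtracts labelled voxels and
is therefore limited to voxel accuracy; most of its artifacts arise at
partial-volume boundaries where a voxel mixes air, soft tissue and tagging.

`ecgan` implements an EC scheme that avoids explicit segmentation: a 3D
image-to-image conditional adversarial network translates an uncleansed
subvolume directly into its cleansed counterpart, and a self-supervised
feedback loop adapts the network to each input case without annotated
clinical truth.

## Model

The generator `G` is a 3D U-Net: `N` stride-2 kernel-4³ convolutional
encoder stages (LeakyReLU 0.2) and `N` matching transposed-convolution
decoder stages (ReLU), with encoder-to-decoder skip connections and a final
`tanh`, so an `S³` input in `[-1, 1]` maps to an `S³` output in `[-1, 1]`.
Channel widths start at `base_channels` and double per stage, capped at
`8 * base_channels`. The discriminator `D` is a 3D PatchGAN: it sees the
2-channel concatenation of the uncleansed volume `x` with a candidate
cleansing (the registered truth `y`, or `G(x)`) and emits a grid of
per-patch probabilities through three stride-2 convolutions, two stride-1
convolutions and a sigmoid; with kernel 4 and padding 1 the patch grid has
side `S/8 - 2`.

Training alternates a discriminator ascent on

    L_GAN(G, D) = E[log D(x, y)] + E[log(1 - D(x, G(x)))]

with a generator descent on the non-saturating adversarial term
`-E[log D(x, G(x))]` plus `lambda_l1 * E[|y - G(x)|]`. The min–max form is
kept for `D`; the generator uses the non-saturating surrogate because the
saturating form provides vanishing gradients early in training — the
standard practice for this family of models. `lambda_l1 = 100` by default,
the classic image-to-image translation weight; the L1 term carries most of
the learning signal and the adversarial term sharpens boundary detail.

Volumes enter the network after clipping to `[-1024, 1024]` HU and scaling
by `1/1024`; image-quality numbers are computed after scaling back to HU.

### Pre-training and the self-supervised loop

Ground truth for EC exists only where a *registered* clean/tagged volume
pair exists — for a colon phantom scanned empty and partially filled.
`pretrain()` does supervised adversarial training on such *fixed-truth* VOI
pairs (uncleansed input, registered native target).

For a new input case there is no truth. The self-supervised loop
(`run_selfsup()`) instead: (1) estimates initial cleansing targets for the
case's VOIs with a simple, swappable initial-EC method; (2) trains on the
union of fixed-truth and these *dynamic-truth* pairs; (3) replaces every
dynamic target with the newly trained generator's own output `G(x)`; and
repeats (2)–(3) for `T` iterations. The fixed pairs anchor the loop — they
never change — while the dynamic targets drift toward the network's own,
progressively cleaner, estimates. `G` and `D` carry their weights across
iterations (the loop is continual fine-tuning, nothing is re-initialised),
which matches the reading of the procedure as iteratively *continued*
training. The initial-EC estimates seed iteration 1's training set and are
replaced at its end.

The default initial-EC is deliberately transparent: voxels above a
normalized threshold of 0.15 (≈150 HU, comfortably above soft tissue and
below tagging) are set to the air value −1, and the replaced region's
boundary voxels are smoothed with a one-voxel box mean so the cut edge is
not a hard step. Any VOI-to-VOI function can be plugged in instead.

### Whole-volume inference

A trained generator accepts `S³` tiles only, so `apply_full_volume()`
covers an arbitrary volume with overlapping tiles (default overlap 16
voxels) and blends overlapping predictions with cosine-ramp weights,
normalised so the weights sum to one at every voxel; constants therefore
pass through the blending exactly, and tile seams are feathered rather than
stitched.

## The digital phantom

The physical reference data for this kind of study — an anthropomorphic
colon phantom scanned empty and partially filled with tagged fluid at
increasing contrast concentrations, plus clinical cases — are not publicly
available, so the package ships a digital colon-phantom simulator
(`generate_phantom()`) that reproduces the *structure* of those datasets:

* a soft-tissue tube (default radius 6 mm, wall 2 mm) following a smooth
  random path, with sinusoidal haustral-fold radius modulation
  (amplitude 1.2 mm) that creates the thin-fold-next-to-fluid geometry EC
  methods find hard;
* registered native/tagged volumes that are voxel-identical outside the
  fluid region before degradation;
* tagged fluid pooling along −z (supine gravity) filling a configurable
  fraction (default 0.35) of each lumen cross-section;
* three tagging levels, 300/600/900 HU for low/moderate/high contrast
  concentration — the concentrations themselves are given in mg/mL in the
  reference protocol without HU values, so these defaults are stand-ins
  whose *ordering* is what matters;
* Gaussian partial-volume blur (FWHM 1.2 mm), optional distance-decayed
  pseudo-enhancement of tissue near tagging (off by default), and
  independent Gaussian noise (σ = 15 HU) per volume.

What the simulator does **not** model: beam hardening, scatter,
reconstruction kernels, dual-energy physics, deformable anatomy, or
heterogeneous stool texture. Passing the package's end-to-end tests
therefore shows the *scheme* works under controlled conditions — it says
nothing about clinical image quality, which in the reference study was
assessed by human readers on real cases.

The fluid mask and the generating tube path are returned as ground truth;
`compute_centerline()` recovers the path from the lumen mask alone, as a
minimal-cost path whose edge costs penalise proximity to the lumen wall
(double-BFS endpoints, Dijkstra interior, ends trimmed to the
high-clearance core). This replaces the external CAD software used in the
reference workflow; a morphological-thinning skeleton would serve equally,
but no 3D thinning implementation exists in the supporting libraries here
and the minimal-path formulation is self-contained and well behaved on
tubular masks.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `N` | 5 | generator depth; `S` must be divisible by `2^N`. The reference operating point is `N = 5` with six self-supervised iterations. |
| `base_channels` | 64 (full scale) | width of the first stage; desk-scale runs use 8 |
| `lambda_l1` | 100 | L1 weight in the generator objective |
| `epochs` | 200 | per training run (pre-training and each iteration) |
| `batch_size` | 3 | VOIs per optimiser step |
| `learning_rate` | 2e-5 | Adam step size, betas (0.5, 0.999) |
| `T` (`iterations`) | 6 | self-supervised iterations |
| VOI size `S` | 128 | cubic subvolume edge, voxels |

The full-scale protocol extracts 100 VOIs per volume along the lumen
centerline, pairs 100 low- and 100 high-concentration VOIs with the 100
native VOIs (200 fixed-truth pairs), and adds 100 dynamic-truth VOIs from
the held-out input case, giving 300 training pairs per iteration.

## Desk-scale study conditions

The package's own experiments (tests and `scripts/acceptance.R`) run the
same pipeline at desk scale, chosen once so a five-seed study completes in
minutes on one CPU core (`desk_config()`): 32³ VOIs, `N = 3`,
`base_channels = 8` for both networks, 30 epochs per run, batch 2, learning
rate 2e-4, `T = 3`, one phantom per tagging level on a 64×32×32 grid with
four VOIs per volume. Tagging 300 and 900 HU are used for pre-training and
the 600 HU level is held out to drive and evaluate the self-supervised
loop, mirroring the full-scale design. The learning rate is raised from
the full-scale 2e-5 because a thousand-fold smaller model on a far smaller
pair set underfits badly at the original rate; 2e-4 is the standard rate
of the model family this design follows.

Under these conditions a typical seed gives: uncleansed baseline ≈ 10 dB
PSNR against the native truth, ≈ 20 dB after pre-training, and a further
increase over the three self-supervised iterations — the qualitative shape
(self-supervision improves on pre-training, which hugely improves on no
cleansing) is what the acceptance tests assert, over four of five seeds.
At full scale the corresponding reported behaviour is a sub-dB but
statistically significant PSNR gain; the absolute numbers are not
comparable across scales because less than 1% of full-scale VOI voxels are
tagged, against several percent here.

## Numerical choices

* **Instance normalisation** in all but the first and last blocks of each
  network. The normalisation type is not pinned down by the reference
  description; instance norm is chosen because training runs with batch
  sizes 2–3, where batch statistics are too noisy.
* **Dropout** is supported in the inner decoder blocks (`dropout_rate`)
  but off by default: the desk-scale networks are small enough to underfit
  rather than overfit. Inference never applies dropout.
* **Eq. of the MSE:** the voxel sum runs over exactly `S³` voxels and is
  divided by `S³` (the printed index range `0..S` in the source material
  would count `(S+1)³` terms — a dimensional inconsistency read as a
  typo).
* PSNR of a perfect reconstruction is `Inf`; reports exclude infinite
  values from mean/sd and count them separately.
* Adversarial-loss logs are clamped at `1e-12`; discriminator targets are
  hard 0/1 grids (no label smoothing).
* Weight init N(0, 0.02), the pix2pix-family convention.
* Axial resampling to isotropic voxels uses linear interpolation (the
  interpolation kernel is unstated in the reference; linear is standard
  for CT intensities, cheap and monotone), preserving physical extent to
  within one voxel.
* Voxel indices are 1-based everywhere, the R convention; VOI centres use
  the floor convention for even `S`. (A 0-based convention would invite
  systematic off-by-one errors against R's native indexing.)
* All randomness flows through the R RNG; a run's stage seeds derive from
  one global seed by stable string hashing, so every run is bit-reproducible
  from `global_seed`.
* The engine itself is `im2col`/`col2im` (compiled) plus BLAS matrix
  products in double precision; gradients are verified against central
  finite differences in the test suite.

## Known limitations

* The simulator's realism limits (above) — results transfer to the scheme,
  not to clinical performance.
* Whether PSNR should be restricted to tagged regions rather than whole
  VOIs is left open in the reference; whole-VOI PSNR is implemented, which
  dilutes per-voxel differences by the untagged majority.
* DICOM-series ingestion is not implemented (no reader among the
  supporting libraries); NIfTI is the interchange format, MetaImage is
  supported for interoperability.
* The loop is not self-contained: the first dynamic targets still come
  from an (internal, threshold-based) initial-EC step, as in the reference
  design where that step is an external EC method.
* No early stopping: the iteration count is explicit, matching the fixed
  iteration sweep of the reference evaluation.
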