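---
title: "Unsupervised Poisson flow denoising: model, assumptions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Unsupervised Poisson flow denoising: model, assumptions, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pfct)
```

## The problem and the model

Photon-counting CT buys spatial and spectral resolution at the price of noise:
fewer photons per voxel or energy bin mean noisier reconstructed slices.
Supervised denoisers need registered low-dose/normal-dose pairs, which
clinical practice rarely provides. This package implements the unsupervised
alternative: learn a *generative prior* from clean images alone, then denoise
by steering the generative process toward a given noisy slice.

The prior is a Poisson flow generative model (PFGM++). The N pixels of an
image patch are treated as an electric charge on the `r = 0` hyperplane of an
(N + D)-dimensional space; by rotational symmetry only the scalar radius `r`
of the D augmented coordinates is tracked. The empirical electric field of
the data distribution defines an ODE,

    dx/dr = E(x~)_x / E(x~)_r = f*(x~) / sqrt(D),

whose trajectories connect an easy-to-sample prior on the `r = r_max`
hyper-cylinder with the data. A network is trained with a perturbation-based
objective: draw a clean patch `y`, a radius `r`, a perturbed point `x` from
the heavy-tailed kernel

    p_r(x | y) ∝ 1 / (||x - y||² + r²)^((N+D)/2),

and regress `(x - y) / (r / sqrt(D))`. The translation `r = sigma * sqrt(D)`
maps all of this onto the EDM diffusion formalism (`sigma(t) = t`), so one
code path serves every D; as `D -> Inf` the kernel converges to a Gaussian
and the model *is* a diffusion model. `D` is therefore an explicit
hyperparameter interpolating between heavy-tailed, robust flow dynamics
(small D) and diffusion (large D), and `geom_config(N, Inf)` is a first-class
branch, not a large-D numerical approximation.

Denoising is posterior sampling with two modifications of the deterministic
Heun sampler:

* **Hijacking** — instead of starting from the prior, start at step
  `tau < T` by injecting the noisy condition image `c` as the iterate,
  unscaled and without added noise.
* **Regularization (data consistency)** — after every solver step, mix the
  iterate with the condition: `x <- w x + (1 - w) c`. For pure denoising the
  identity map suffices as the consistency operator.

With `tau = T - 1` the single remaining step ends at `t = 0`, where the
second-order correction is skipped, so exactly **one** network evaluation is
spent (NFE = 1). `w = 1` disables regularization; `w = 0` returns the
condition unchanged.

## Parameters that matter

| parameter | meaning | default | why |
|---|---|---|---|
| `D` | augmented dimensions | 128 | the D that the method's authors found best on clinical data; `Inf` gives the diffusion special case |
| `T` | solver steps | 8 | selected by grid search over {4, 8, 16, 32, 64} upstream; only step `T-1` is run when hijacked |
| `tau` | hijack index | `T - 1` | makes NFE = 1 |
| `w` | mixing weight, [0, 1] | 0.5 | grid-searched over {0.5, ..., 1.0} upstream; 0.5 balances noise removal and fidelity |
| `sigma_min, sigma_max, rho` | schedule | 0.002, 80, 7 | the EDM schedule, inherited as configuration |
| `P_mean, P_std` | training log-sigma distribution | -1.2, 1.2 | the EDM training distribution; exposed, not asserted as publication values |
| `sigma_data` | assumed data SD (normalized) | 0.5 | EDM preconditioning constant |
| `r_max` | prior radius | `sigma_max * sqrt(D)` | valid when `r_max` dwarfs data norms; the prior treats the dataset as a point charge at the origin |
| HU normalization | affine map to network units | offset -500, scale 500 | maps [-1000, 0] HU onto [-1, 1]; stored in every checkpoint so training and inference agree |

Training defaults follow the upstream recipe where stated (batch 32, Adam at
2e-4, augmentation probability 15%, dropout 10%, patches); desk-scale runs
shrink iteration counts and patch sizes, never the mathematics.

## What the synthetic generator emulates — and what it does not

`generate_phantom()` renders piecewise-constant ellipse anatomy in HU
(air background, soft-tissue body, fat / blood-like / calcified inserts) with
seeded jitter of centers and HU values to emulate anatomical variation.
`degrade()` is a stationary correlated Gaussian field: white noise convolved
circularly with an isotropic Gaussian kernel of SD `correlation_length`
pixels, renormalized so a flat region has exactly the requested SD. This is a
deliberately generic stand-in for the "catch-all" degradation of
reconstructed CT slices; the true photon-counting noise spectrum is not
quantitatively characterized here, so `correlation_length` is a knob, not a
claim of realism. A projection-domain Poisson + filtered-backprojection
simulator, 3-D volumes, and spectral channels are out of scope.

Consequently, a green test establishes that the machinery is mathematically
correct (kernel law, field, sampler, NFE accounting, metric formulas) and
that the method behaves as designed on piecewise-constant anatomy with
stationary Gaussian noise. It does not establish clinical image quality,
which upstream required GPU-scale training on clinical data and a reader
study.

## Numerical choices

* **Kernel sampling.** The heavy-tailed kernel is sampled by the Beta
  change of variables: `u ~ Beta(N/2, D/2)`, radius `R = r sqrt(u/(1-u))`,
  uniform direction. This construction is *verified in-repo* against direct
  numerical integration of the radial density (Kolmogorov–Smirnov, 1e5
  draws) rather than taken on faith.
* **Field evaluation.** The exact field for a discrete dataset normalizes
  per-charge weights `||(x - y_j, r)||^-(N+D)` in the log domain
  (log-sum-exp); the unit-sphere surface constant cancels in the ratio and
  is never computed. This stays finite for N + D up to 1e6 and beyond.
* **Backbone.** No deep-learning framework exists in the target environment,
  so the trainable backbone is a fully-connected network (SiLU activations,
  sinusoidal noise-level embedding, EDM preconditioning, zero-initialized
  output layer) with hand-written backpropagation and Adam. The
  `backbone_config()` fields keep the U-Net vocabulary (base channels,
  multipliers) so paper-scale configurations round-trip, with hidden widths
  `base_channels * channel_multipliers`; attention is rejected explicitly.
  Training on 8x8 patches recovers the analytic field to ~11% median
  relative error (acceptance criterion A4 recomputes this at every run). A
  patch-trained model denoises larger slices by overlapping-tile averaging
  (stride = half patch); one tiled application counts as one NFE, since NFE
  counts denoiser evaluations, not tiles.
* **Augmentation conditioning.** Upstream used "nonleaky" augmentation with
  an augmentation-label input; here plain label-free flips and 90-degree
  rotations are used. The trick is a paper-scale regularizer, immaterial to
  the method's mathematics at desk scale.
* **Mixing orientation.** `x <- w x + (1 - w) c` is fixed by the ablation
  labels upstream (w = 1 means "regularization omitted") and their grid
  `w in [0.5, 1]`. Regularization applies after *every* solver step from
  `tau` onward — vacuously once when `tau = T - 1`; the upstream description
  is operational only for that case, so the per-step placement for
  `tau < T - 1` is this package's documented choice.
* **Hijack scaling.** The condition image enters unscaled and un-noised,
  exactly as specified; no attempt is made to match its noise level to
  `t_tau`. If the condition is much noisier than `t_tau`, the single-step
  estimate degrades — a known, documented risk of the method.
* **`w = 0` identity.** The output then equals the input up to one affine
  HU-normalization round trip (relative error at machine epsilon), which is
  what "exact" means here.
* **Degenerate inputs.** `r = 0` (the data hyperplane) is rejected wherever
  a field or target would divide by it; `T = 1` schedules degenerate to
  `{sigma_max, 0}`; jittered ellipses leaving the field of view are clipped
  with a warning; grid-search ties break deterministically toward smaller T,
  then smaller w.
* **Determinism.** Every stochastic entry point takes a seed and restores
  the caller's RNG state; training is bitwise reproducible single-threaded;
  hijacked sampling is a pure function of (model, condition, config).

## Known limitations

* The analytic field oracle covers discrete (empirical) data distributions
  only — that is its role: an exact reference at desk scale.
* The fully-connected backbone fixes the training patch shape; full
  convolutionality is approximated by tiling at inference.
* LPIPS, the upstream model-selection criterion, needs a pretrained feature
  extractor and is exposed only as an external hook (`lpips_fn` in
  `grid_search()`), with PSNR/SSIM as built-in fallbacks.
* Image I/O is plain-text HU matrices plus windowed ASCII PGM export
  ([-160, 240] HU default window); no DICOM or 16-bit PNG support in this
  environment.
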