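---
title: "Self-supervised ADMM-unrolled reconstruction of multi-shot diffusion MRI"
author: "dwiunroll"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Self-supervised ADMM-unrolled reconstruction of multi-shot diffusion MRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The reconstruction problem

High-resolution diffusion-weighted imaging (DWI) with multi-shot EPI splits
each diffusion volume's k-space over several excitations (shots). Each shot
is heavily undersampled, and bulk/physiological motion during the diffusion
encoding imprints a smooth, shot-specific image phase, so the shots cannot
simply be averaged. With simultaneous multi-slice (multi-band, MB)
excitation the collapsed slices additionally overlap in k-space.

The package models the acquisition with the linear encoding operator

$$\mathcal{A}(x) = P \sum_z \Theta \, F\, (S\, \Phi\, x),$$

where `x` is the complex image stack over (diffusion, slice, y, x), `Phi`
the unit-magnitude shot-to-shot phase maps, `S` the coil sensitivities, `F`
the centered orthonormal 2D FFT, `Theta` the per-slice CAIPI phase ramps
along ky, the sum collapses the simultaneously excited slices, and `P` the
binary sampling mask. Reconstruction solves the regularized least-squares
problem

$$\hat{x} = \arg\min_x \lVert y - \mathcal{A}(x)\rVert_2^2 + \lambda\,\mathcal{R}(x)$$

for three choices of the regularizer:

* **MUSE-style Tikhonov** (`muse_reconstruct()`): per-diffusion-volume
  CG-SENSE over the stacked shots, no coupling along diffusion;
* **locally low rank (LLR)** (`admm_llr()`): ADMM whose proximal step
  soft-thresholds the singular values of patchwise spatial-diffusion
  (Casorati) matrices;
* **learned, scan-specific** (`unroll_train()`): ADMM unrolled to a fixed
  depth with the proximal step replaced by a small residual convolutional
  network trained on the scan itself ("zero-shot" self-supervision).

## The unrolled algorithm

Eight ADMM iterations are unrolled; each data-consistency (x) update runs
six conjugate-gradient iterations on the normal equations
$(\mathcal{A}^H\mathcal{A} + \tfrac{\rho}{2} I)x = \mathcal{A}^H y +
\tfrac{\rho}{2}(v-u)$, started from zero. The auxiliary update is

$$v \leftarrow (\lambda/\rho)\,\mathcal{D}_\omega(x + u),$$

followed by the dual ascent `u <- u + x - v`. The `(lambda/rho)` scaling of
the denoiser output is implemented exactly as specified by the source
algorithm even though it differs from the conventional plug-and-play update
`v = D(x+u)`; the conventional variant is available for ablation via
`unroll_control(conventional_v = TRUE)`. `rho` is fixed at 0.05; `lambda`
is a trainable positive scalar (softplus parametrization) initialized at
0.05.

**Self-supervision.** The acquired mask `P` is split, 12 times, into three
disjoint random sets per (diffusion, shot) plane: `T` (data consistency
during training), `L` (training loss), `V` (validation loss), at ratios
(0.6, 0.2, 0.2) — the algorithm's description states only that more data
goes to training than to the loss masks; the exact ratios are this
package's choice. Each epoch loops the 12 repetitions, taking one ADAM
step per repetition on the loss

$$\mathcal{L}_M(y, \mathcal{A}x) =
\frac{\lVert M(\mathcal{A}x - y)\rVert_2^2}{\lVert M y \rVert_2^2},$$

a normalized masked k-space mean-squared error. The source algorithm never
defines its loss; normalized MSE makes the loss scale-free so the same
step size works across datasets. Validation reconstructs with data
consistency on `T ∪ L` and scores on `V`, averaged over all 12 repetitions
(the source pseudo-code is ambiguous about which repetition validates;
averaging is deterministic and low-variance). Training stops when the
validation loss has not improved for 12 consecutive epochs or after at
most 100 epochs, and the best-validation parameters are returned.

**Denoiser.** The complex stack is split into real/imaginary channels and
reshaped to `(Nz, 2*Ndiff, Ny, Nx)` so the multi-band slices ride along the
batch axis and 3x3 kernels mix the diffusion contrasts. The network is an
input conv + ReLU, `n_blocks` residual blocks, and a zero-initialized
output conv with a global skip, so training starts from the identity map.
The reference architecture is deferred to supplementary material not
available here; the default (3 blocks, 64 channels) follows common
compact ResNet denoisers, and the desk-scale studies below use a smaller
net (2 blocks, 8 channels).

**Gradients.** No autodiff framework is available in this stack, so the
reverse-mode pass is hand-derived: convolution forward/backward kernels are
compiled, ReLU masks and the unroll chain rule are explicit, and the CG
block is differentiated by the implicit-function rule — the gradient is
propagated through a CG solve on the same (self-adjoint) normal operator
with the same iteration budget, which is exact when CG converges and is
the standard treatment for unrolled data-consistency blocks. Gradients are
verified against finite differences in the test suite.

**Numerical choices.**

* FFT convention: centered, orthonormal. Under full sampling with
  sum-of-squares-normalized coils the operator is unitary, which keeps
  `lambda` and `rho` scale-stable. For power-of-two planes the centered
  transform is computed shift-free by folding the checkerboard phases into
  precomputed maps (exactly equivalent; verified against the generic
  path).
* CG starts from zero with a fixed budget and no tolerance exit,
  mirroring the unrolled usage; classical solvers may enable the exit.
* The k-space loss gradients occasionally explode on poorly conditioned
  mask splits (the unrolled dynamics amplify weight perturbations through
  eight iterations). A global gradient-norm clip (default 100) is applied
  before the ADAM step; this is an implementation safeguard on top of the
  source algorithm's plain "update via ADAM".
* The ADAM step size (not stated by the source) defaults to `1e-3`.
* A per-shot global phase is unobservable; phase-map comparisons are made
  up to that gauge.
* Ties in the validation loss count as improvement, matching the
  reference bookkeeping (`<=`).

## The synthetic study conditions

`simulate_kspace()` emulates the target acquisition at desk scale with
known ground truth: 1 b0 volume plus 20 diffusion directions at
b = 1000 s/mm² (the printed protocol), 3 shots per volume, combined
in-plane acceleration 2 (per-shot in-plane factor 6), multi-band 2 (total
per-shot acceleration 12), 5/8 partial Fourier, and a one-line ky shift
between adjacent diffusion volumes giving complementary k-q sampling. The
matrix defaults to 64x64 instead of 286x286 — every structural property
(mask residues, acceleration factors, split algebra) is preserved at toy
size. Choices the protocol tables do not print, fixed once here: the
diffusion direction table (electrostatically spread unit vectors,
deterministic under a seed), the CAIPI scheme (FOV/2 linear ky ramps), coil
maps (Gaussian-profile magnitudes, polynomial phases, SOS-normalized, 4-8
coils at toy scale vs 32 physical channels), shot-phase corruption (smooth
low-order polynomial fields plus linear ramps, RMS amplitude 0.6-0.9 rad),
and complex Gaussian noise set by a target k-space SNR (20 in the noisy
studies). b = 0 volumes carry unit shot phases by default (diffusion
encoding off implies no motion-induced phase); this is configurable.

What the phantom does *not* emulate: EPI distortion and off-resonance,
eddy currents, T2/T2* decay during the readout, gyral anatomy, and
realistic coil noise correlations. Passing tests therefore demonstrate the
correctness of the operators and the self-supervised machinery under the
modeled physics, not in-vivo image quality.

The desk-scale training study uses a 64x64, `Ndiff = 5`, 3-shot, MB-2,
SNR-20 phantom with 4 coils and the small denoiser, and caps training at 4
epochs (one epoch = 12 repetitions = 12 ADAM steps, preceded by an
epoch-0 validation pass of the untrained model); the early-stopping rules
remain active and the patience logic is additionally unit-tested on
synthetic loss sequences. With these sizes one training run takes a few
minutes on one CPU core.

## Classical comparators

`estimate_shot_phases()` implements self-gating: each shot's k-space alone
is reconstructed by Tikhonov-regularized CG-SENSE (no shot-phase term), the
shot image is smoothed by a Hann window over the central fraction of its
k-space (default 0.25; the reference smoothing operator is unspecified),
and only the phase is kept. At very high per-shot acceleration and few
coils the per-shot problem is underdetermined and self-gating degrades —
the regime where navigator acquisitions are used in practice; the
navigated mode passes supplied maps through unchanged.

`admm_llr()` uses Casorati matrices of `block_size`-square patches (default
8) whose columns are the diffusion volumes of one slice; slices are
processed independently, matching the spatial-diffusion description of the
reference; patch grids are cycle-spun with a seeded offset per iteration,
and the proximal threshold is `threshold / rho` (standard ADMM prox
scaling). The reference does not print its block size or threshold; the
defaults here are package choices, stated as such.

## Evaluation

`psnr()`, `ssim()` (standard constants K1 = 0.01, K2 = 0.03, 11-pixel
Gaussian window, dynamic range `max|ref|`, valid-region mean) and
`nrmse()` operate on magnitude images with the reference fixed, over the
reference support. `fit_dti()` is an unweighted log-linear least-squares
tensor fit (evaluation aid, not a contribution): signals clamped at
`1e-6 * S0`, eigenvalues sorted, FA by the standard formula, cFA =
`FA * |e1|` as RGB. On noiseless simulator output it inverts the signal
model exactly, which the tests assert to 1e-6.

## Known limitations

* No off-resonance/B0 term, non-Cartesian trajectories, or coil-map
  estimation from data; partial Fourier is handled through the mask only
  (zero-filled data consistency, no homodyne/POCS).
* Scan-specific training: one model per protocol geometry; inference on a
  different geometry is an explicit error.
* The desk-scale training study shares the simulator's true shot-phase
  maps across all compared reconstructions (the operator treats the phase
  maps as precomputed inputs). Self-gated estimation is validated
  separately at a geometry where the per-shot subproblem is determined; at
  the full 3-shot, per-shot-6x2 geometry with few coils it is
  underdetermined — the regime where navigator acquisitions are used in
  practice.
* **The undertrained regime.** One CPU core affords on the order of
  10^2 ADAM steps at the toy sizes above, versus ~10^3 GPU steps for full
  training. In that regime the trained model reliably gains several dB
  over the zero-filled adjoint and clearly reduces the self-supervised
  validation loss, but typically still trails a fully converged Tikhonov
  (MUSE-style) per-volume reconstruction by ~0.3-1.5 dB: with only five
  diffusion volumes the q-space redundancy a joint learned regularizer
  exploits is small, the per-volume SENSE problem at union factor 2x2
  with four coils is well determined, and the k-space training losses are
  sharp — training exhibits intermittent loss spikes (hence the gradient
  clipping) and early stopping selects the best validation epoch.
  Overtaking converged per-volume baselines requires training depth (and
  volume counts) beyond desk scale.

## A worked run

```{r example}
library(dwiunroll)

prot <- protocol_spec(bvals = c(0, rep(1000, 4)), n_shots = 3, r_inplane = 2,
                      mb_factor = 2, partial_fourier = 5/8, n_coils = 4,
                      phase_amplitude = 0.6, seed = 42)
sim <- simulate_kspace(prot, n_y = 64, n_x = 64)
prot$noise_sd <- noise_sd_for_snr(sim$kspace, snr = 20)
sim <- simulate_kspace(prot, n_y = 64, n_x = 64)

ctl <- unroll_control(denoiser_channels = 8, denoiser_blocks = 2,
                      n_epoch_max = 6, seed = 1)
fit <- unroll_train(sim$kspace, sim$enc, ctl, verbose = TRUE)
print(fit)
plot(fit)      # loss curves and learned lambda trajectory

x_hat <- predict(fit)                       # full-mask inference
psnr(x_hat, sim$truth)
psnr(apply_adjoint(sim$kspace$data, sim$enc), sim$truth)  # zero-filled
psnr(muse_reconstruct(sim$kspace, sim$enc), sim$truth)    # MUSE
```
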