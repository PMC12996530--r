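---
title: "Models and methods behind nanokymo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind nanokymo}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

nanokymo analyzes nanofluidic scattering microscopy (NSM) kymographs: 2-D
arrays of relative optical contrast, rows indexing camera frames and
columns indexing pixels along a nanochannel. This vignette explains the
physical models, the estimator, the numerical choices, and what the
simulation-based tests do and do not establish.

## Optical model

A biomolecule inside an illuminated nanochannel scatters coherently with
the channel; the detected intensity of a channel segment is approximately
`I_t = I_c + I_m - sqrt(2 I_c I_m)`. Since scattering of subwavelength
objects scales with volume squared, `I_m` is negligible against the
interference cross-term, so the differential image (channel-with-molecule
minus empty channel) shows a *negative* contrast dip proportional to the
molecular polarizability. `differential_contrast()` implements this
algebra exactly.

On the kymograph the molecule's response is a Gaussian dip of width `s_nm`
(the diffraction-limited point-spread scale; default 100 nm against a
27.4 nm pixel) whose integral along the channel axis is the *integrated
optical contrast* (iOC, contrast × nm). Responses multiply: each molecule
contributes a transmission-like factor `1 - ioc · g(x - x_i; s)` near one,
and the recorded stack is `I = I0 · prod(I_r)` with `I0` the empty-channel
background. Contrast conservation — the per-frame integrated deficit
equals the iOC for in-view molecules — is enforced to Riemann-sum accuracy
and tested to 0.1%.

### iOC to molecular weight

Mass enters through the polarizability: `MW = kappa * iOC * A / a`, with
`A` the channel cross-section area in nm², `a = 0.46` Å³/Da (used for all
analytes; the ≈8% bias for dsDNA, whose dn/dc differs slightly from the
protein value, is deliberately not corrected), and `kappa` the optical
calibration constant of the instrument. With the unit conventions used
here the Å³/nm³ and Da/kDa factors cancel. The default `kappa = 0.003` is
a *simulator calibration*: it places a 100 kDa molecule in the default
63 × 30 nm channel at a per-frame peak SNR of roughly 2–5 against the
simulated background's preprocessed fluctuation floor (which is dominated
by channel vibration and per-frame intensity jitter at the 1e-2 relative
level), while a 5 kDa molecule stays below the per-pixel noise floor. An
instrument calibration replaces `kappa` when analyzing measured data.

### Diffusivity to hydrodynamic radius

Free solution uses Stokes–Einstein, `Rs = kB T / (6 pi eta D)` (defaults
298.15 K, 0.89 mPa·s). In channels whose cross section approaches the
molecule size, wall collisions reduce the measured diffusivity:
`D = H(Rs) · D_free` with `H` in (0, 1], non-increasing in Rs.
`hindrance_model()` supports an identity mode, a Renkin-style parametric
centerline factor for an effective pore radius, and a lookup table for a
channel-specific calibration; `d_to_rs()` then solves for Rs by bracketed
root finding on [0.1, 100] nm (tolerance 1e-12).

## Trajectory and noise simulation

Positions follow the discrete Brownian recursion
`x_i = x_{i-1} + v dt + N(0,1) sqrt(2 D dt)` with D in µm²/s converted to
nm² internally and `dt = 0.005 s` (200 fps). Positions are neither
reflected nor clipped — the physical channel (80 µm) is much longer than
the imaged segment (≈14 µm at 512 pixels), so molecules drift out of view;
only in-view frames count toward the trajectory-point number N.

The empty-channel background is, per frame `t`,

```
b0  = exp(-(x - (x0 + x_l))^2 / lambda^2) * (1 + dirt) * (1 + A N(0,1))
x_l = (2 N(0,1) + sin((pi - 0.05) t)) * d_x
bf  = b0 * (1 + n_theta N(0,1)) + 0.4 n_theta N(0,1)
```

with a fresh normal draw per pixel in the last line. The dirt field is
white noise convolved (circularly, via FFT) with the normalized kernel
`(exp(-x²/C²) + x_l) / sum(exp(-x²/C²) + x_l)`; the scalar `x_l` enters
the kernel as an offset before normalization, which is how we resolve the
ambiguous placement of that term — the kernel is described as a
PSF-like, normalized object, so normalization must happen after the offset.
Two further choices are deliberate:

- the white-noise field behind the dirt term is drawn **once per
  kymograph** — channel imperfections are static in time, only the kernel
  offset follows the vibration; redrawing per frame would turn dirt into
  fast spatially-correlated noise, which the shot-noise term already
  provides;
- the imperfection factor `(1 + dirt)` is floored at 0.05 so that rare
  deep draws of the unbounded Gaussian dirt model cannot produce negative
  intensities, which the normalization step (and physics) forbids.

The numerical parameters are drawn per kymograph from configurable ranges
(`default_noise_ranges()`): the envelope center and width as fractions of
the view (Normal(0.5, 0.05) and Uniform(0.6, 1.2) of L), vibration
amplitude Uniform(0.002, 0.01)·L, dirt correlation length
Uniform(0.01, 0.05)·L, per-frame jitter Uniform(0, 1%), and shot-noise
level Uniform(1e-5, 4e-5) in relative contrast. These are calibration
choices, fixed once: together with `kappa` they realize the intended
regime in which a 100 kDa molecule is clearly visible per frame and a
5 kDa molecule is not. Multi-molecule kymographs combine response fields
multiplicatively, consistent with the `I = I0 · I_r` composition of
transmission-like factors near one.

## Preprocessing

Raw stacks (3-D regions of interest are first averaged across the
transverse axis) are normalized per position by the full-stack time
average, `(I - <I>)/<I>`, then a separable low-pass field — a unit-sum
moving average of 200 frames along time, then 200 pixels along position —
is subtracted. Sequential application (time first) was chosen over
averaging the two windows in parallel; the difference is second order and
covered by tests. Edges use truncated, renormalized windows rather than
invented padding, preserving the unit-sum property. The pipeline is
invariant under rescaling of the raw intensities.

## The hierarchical vision transformer

The model standardizes its input by the per-kymograph temporal standard
deviation. The scalar used is the **lower quartile** of the per-pixel
temporal standard deviations: a diffusing molecule and its response tails
can touch more than half the pixels, so the mean (and even the median)
per-pixel deviation is signal-contaminated and would self-normalize bright
molecules toward the noise floor, destroying the amplitude information the
MW head needs; the quietest quarter of pixels is essentially always
background.

The architecture follows the multi-scale design: an initial convolution of
kernel 7 with leaky-ReLU, then `n_scales` convolutional blocks with
increasing filter counts, each followed by 2×2 max pooling and a per-scale
scalar (MW, Rs) head on the globally averaged features. At the final scale
each coarse cell becomes a token: a linear patch encoder with learned
positional embeddings, plus the channel cross-section area as a
conditioning scalar (`area/area_ref - 1` projected and added to every
token — the area is a required input of any prediction, because the
iOC-to-MW conversion depends on it). Transformer blocks (pre-LayerNorm,
multi-head attention, leaky-ReLU MLP) refine the tokens; a sigmoid head
emits the per-bin probability map on the
`(frames/2^n) × (pixels/2^n)` grid and a softplus head the per-bin
property map (MW, Rs, N in normalized units). The property head also
receives the concatenated per-scale global-average features, folding the
multi-scale outputs into the final prediction stage. The final estimate is
the probability-weighted average `sum(P·theta)/sum(P)`; zero total mass is
reported as an undefined flag rather than NaN.

All forward and backward passes are written analytically in R (im2col
convolutions, max-pool argmax routing, LayerNorm and attention gradients)
and verified against central finite differences to better than 1e-3
relative error in the test suite. Design choices that matter for training
at small scale:

- **Loss.** Binary cross-entropy between probability map and the binary
  space-time occupancy of the ground-truth trajectories, plus `lambda`
  times L1 errors of the per-scale scalars and the final weighted
  estimates, in normalized units (`mw_scale` 30 kDa, `rs_scale` 3 nm,
  `n_scale` = frame count) so all terms are O(1). Occupied bins are a
  small minority of the map, so the cross-entropy supports a positive-class
  weight (`pos_weight`).
- **Stop-gradient readout.** The probability map is treated as a constant
  weight inside the readout: it learns from the cross-entropy alone, the
  property map from the L1 terms alone. Letting the property error flow
  into the probability head destabilizes localization at small sample
  counts; the exact full gradient remains available
  (`detach_prob = FALSE`) and is what the finite-difference check uses.
- **Optimizer.** Adam at learning rate 1e-4 by default, with an optional
  linear warmup; training data are re-generated on the fly every step, so
  no kymograph is ever seen twice. Validation against a held-out simulated
  set runs periodically and the best-validation parameters are kept.
- **Curriculum.** Stages of widening (MW, Rs) ranges advance when the loss
  plateaus; the rule (`plateau_reached()`) is a < 1% relative improvement
  of the mean loss over the last `patience` steps compared with the
  `patience` steps before, a concrete instantiation of "advance when the
  loss converges".

## Post-processing

Per kymograph the total probability mass is `P_total = sum P(x,t)`.
The detection threshold is half the average probability mass of
buffer-only control kymographs, and kymographs with `P_total` below it are
excluded. Surviving MW and Rs populations are pruned by a single-pass
moment-matched Gaussian fit (sample mean, sample standard deviation with
n−1) removing points strictly outside 3σ; points exactly on the boundary
are kept, there is no re-fit after removal, and the two properties are
pruned independently, a kymograph removed in either being excluded from
the joint population.

## Precision bounds

For `n` Gaussian increments the Fisher information of the diffusivity
gives `var(D_hat) >= 2 D²/n`, hence a relative bound `sqrt(2/n)`
independent of D; the increment-based estimator
`D_hat = sum((dx - v dt)²)/(2 n dt)` attains it and serves as the
reference estimator. Since Rs is inversely proportional to D, its relative
bound coincides to first order. For contrast amplitude, estimating a
known-shape response in additive white Gaussian noise obeys
`sigma_rel >= 1/(snr_eff sqrt(n))` with
`snr_eff = a sqrt(sum(g²))/sigma`; the matched filter attains it. The
white-noise model is an explicit simplification — `snr_eff` is an input,
not derived from the structured background model. `precision_vs_n()`
pairs empirical relative standard deviations (computed about the mean)
with these bounds over a grid of N.

## Desk-scale study conditions

The test suite and the acceptance script train a deliberately small model:
64 × 128 kymographs in the 63 × 30 nm channel, 3 scales with filters
(8, 12, 16), embedding 24, one transformer block; 200 Adam steps at
5e-3 with 20 warmup steps, batches of 8 freshly simulated kymographs, a
3-point MW grid {5, 15, 30} kDa with a 20% buffer-only fraction, fixed
D = 0.75 µm²/s (decoupled from Rs so the short 64-frame trajectories stay
in view), and a vibration- and jitter-free shot-noise background
(`n_theta = 4e-4`) giving per-frame peak SNRs of roughly 4–22 across the
grid. The CRLB benchmarks use 500 replicates at N ∈ {100, 1000, 10000}
and a 300-replicate matched filter at N = 10⁴. These sizes are chosen so
the full suite runs on a laptop-class single core in minutes.

What passing these tests shows: the simulator realizes the stated
statistics exactly; the estimator architecture can learn localization and
monotone amplitude-to-mass readout from scratch on in-distribution data;
the thresholding separates signal from buffer-only controls under the
trained model; and reference estimators reach their information bounds.
What it does not show: performance on experimental recordings (no camera
artifacts beyond the parametric model, no adsorption events, no
out-of-distribution noise), absolute MW accuracy at full scale (that
requires the ~640k-kymograph training regime and instrument calibration of
`kappa`), or the biased-estimator behavior at very small N beyond the
qualitative tendency of pure-noise predictions toward the bottom of the
training range (reported by the acceptance script, not asserted).

## Known limitations

- One spatial dimension: no transverse optical structure beyond averaging
  the region of interest.
- The h-ViT here is a compact re-implementation with analytic gradients in
  plain R; it is faithful in structure (multi-scale convolutions, patch
  encoding, attention, probability-weighted readout) but far smaller than
  a production configuration, and training at the published scale is out
  of scope.
- TIFF + JSON sidecar is the canonical on-disk format; values are stored
  as 32-bit floats affinely mapped to [0, 1], so round trips are exact to
  float32 precision of the value range.
- Estimates on multi-molecule kymographs are population averages; no
  mixture deconvolution is attempted.
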