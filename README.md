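# nanokymo

Simulation and deep-learning analysis of nanofluidic scattering microscopy
(NSM) kymographs.

NSM images single biomolecules diffusing freely inside nanochannels with a
cross section of only a few thousand nm². The molecule appears as a faint
optical-contrast dip: the total scattered intensity from a channel segment
with a molecule inside is approximately

```
I_t ≈ I_c + I_m − √(2 I_c I_m)
```

so subtracting the empty-channel image leaves the interference term
−√(2 I_c I_m), which dominates because the molecule scatters orders of
magnitude less than the channel. A time sequence of such differential
frames forms a **kymograph** (time × position along the channel). Two
molecular properties follow from it:

- **MW** from the integrated optical contrast: `MW = κ · iOC · A / a`, with
  `A` the channel cross-section area and `a = 0.46 Å³/Da` the
  polarizability-to-mass constant;
- **Rs** from the diffusivity via Stokes–Einstein,
  `Rs = k_B T / (6π η D)`, optionally with a channel-specific
  hindered-diffusion correction `D = H(Rs) · D_free`.

For molecules below ~10 kDa the trajectory is invisible in the raw
kymograph. The package therefore implements a compact **hierarchical vision
transformer** (multi-scale convolutions + patch-encoded transformer blocks)
that outputs a coarse-grid *probability map* of molecule presence and a
*property map* of per-bin (MW, Rs, N) predictions; the final estimate is
the probability-weighted average of the property map. Populations of
estimates are cleaned by probability-sum thresholding against buffer-only
controls (`P_thresh = ⟨P_control⟩ / 2`) and single-pass 3σ Gaussian outlier
pruning, and estimator precision is benchmarked against Cramér–Rao lower
bounds (`σ_rel ≥ √(2/N)` for diffusivity, `σ_rel ≥ 1/(snr_eff √N)` for
contrast amplitude).

The package is aimed at method developers: everything runs on simulated,
ground-truthed kymographs (Brownian trajectories, Gaussian point-spread
responses, a parametric background-noise model with envelope, vibration,
dirt and shot-noise terms), so detection and estimation behavior can be
studied quantitatively without an instrument.

## Worked example

```r
library(nanokymo)

geom  <- channel_geometry(63, 30, n_pixels = 128)   # area 1890 nm^2
quiet <- noise_params(d_x = 0, amp_A = 0, n_theta = 4e-4)

# train a desk-scale model on freshly simulated kymographs
cfg   <- hvit_config(input_shape = c(64, 128), n_scales = 3,
                     filters = c(8, 12, 16), embed_dim = 24, n_heads = 4,
                     n_transformer_blocks = 1)
model <- build_hvit(cfg, seed = 1)
gen   <- hvit_training_generator(cfg, geom, noise = quiet, s_nm = 100,
                                 d_um2_s = 0.75, mw_values = c(5, 15, 30),
                                 p_empty = 0.2)
fit   <- train_hvit(model, gen,
                    hvit_train_config(learning_rate = 5e-3, n_steps = 200,
                                      pos_weight = 6, warmup_steps = 20,
                                      validation_every = 50,
                                      n_validation = 24, seed = 2))

# predict fresh molecules of each class, plus a buffer-only control
set.seed(3)
ests <- predict_population(fit$model, lapply(c(5, 15, 30), function(mw)
  simulate_kymograph(mw_kDa = mw, rs_nm = 2, d_um2_s = 0.75, n_frames = 64,
                     geometry = geom, noise = quiet)),
  ids = c("mw5", "mw15", "mw30"))
as.data.frame(ests)
#>     id mw_kDa rs_nm n_points p_total undefined
#> 1  mw5   3.26  1.80     48.6    17.2     FALSE
#> 2 mw15   5.60  2.59    108.6    27.1     FALSE
#> 3 mw30   8.78  2.01     86.5    26.5     FALSE

ctl <- predict_hvit(fit$model, simulate_kymograph(n_molecules = 0,
         n_frames = 64, geometry = geom, noise = quiet))
ctl$estimate$p_total
#> [1] 0.2345276
```

Each row is a probability-weighted estimate for one kymograph. After only
200 training steps the absolute MW scale is still biased low — that
calibration needs the full-scale training regime — but the rank order of
the three classes is already correct (the acceptance suite checks Spearman
rank correlation 1 over class means), and the total probability mass
cleanly separates molecules (`P_total ≈ 17–27`) from the buffer-only
control (`P_total ≈ 0.2`), which is what the `P_thresh = ⟨P_control⟩/2`
detection threshold exploits.

Physical conversions and bounds are available directly:

```r
d_to_rs(160)                 # 1.53 nm  (Stokes-Einstein, water, 25 C)
dsdna_mw(200)                # 132 kDa  (660 g/mol per bp)
crlb_diffusivity(200)        # 0.1      (relative sigma bound at N = 200)
```

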