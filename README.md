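# synthrr

Post-reconstruction **resolution recovery (RR)** for PET images by
**synthesized image reconstruction**, with the full 2-D simulation and
evaluation framework used to validate it.

## The problem

Positron range blurs PET images — severely so for high-energy emitters such
as gallium-68 and in preclinical imaging. The reference remedy, PSF-based
reconstruction (MLEM+PSF), needs the scanner's proprietary projectors and
the raw sinogram, which users rarely have. The practical alternative,
Richardson–Lucy (RL) post-reconstruction deconvolution, needs only the image
and the PSF but amplifies noise within a few iterations.

The method implemented here takes an existing reconstruction
`θ⁽ᴷ⁾` (e.g. an MLEM image from the scanner's standard software), forward
projects it through a user-chosen **virtual scanner** `S` to synthesize
sinogram data

    m_syn = S θ⁽ᴷ⁾

and reconstructs `m_syn` with the positron-range PSF `P` inside the virtual
system model:

    θ ← θ / (Pᵀ Sᵀ 1) · Pᵀ Sᵀ ( m_syn / (S P θ) )

Like RL it needs only an image and a kernel; like MLEM+PSF it produces a
well-behaved sequence of iterates, because the synthetic data are exactly
consistent with the virtual system model. The package implements this
method, its no-PSF variant, and the comparators (MLEM, MLEM+PSF, RL) through
one shared EM loop, plus digital phantoms (modified Shepp–Logan,
Derenzo rods, thorax-like), Poisson acquisition simulation at configurable
count levels, and bias/standard-deviation/RMSE evaluation over noise
realizations and ROIs.

Audience: PET/medical-imaging methods researchers and anyone who wants a
compact, fully testable 2-D laboratory for EM-family reconstruction and
post-reconstruction deconvolution.

## Worked example

```r
library(synthrr)

truth <- make_shepp_logan(128, 1)          # 128x128, 1 mm pixels
psf   <- gaussian_kernel(2.9, 1)           # Ga-68 positron-range surrogate
geom  <- default_geometry(truth)           # 180 angles, 1 deg steps

# one noisy low-count acquisition, then the scanner-style MLEM input image
m     <- simulate_acquisition(truth, psf, geom, count_level("low", 1e5), seed = 1)
input <- get_iterate(mlem(m, geom, recon_config(64), grid_size = 128), 64)

# post-reconstruction RR: Richardson-Lucy vs synthesized reconstruction
rl <- richardson_lucy(input, psf, recon_config(500))
sy <- synthesized_recon(input, geom, psf, recon_config(500))

ref <- scaled_truth(truth, m)              # truth on the count scale
roi <- roi_mask(matrix(TRUE, 128, 128), "global")
min_rmse(compute_metrics(list(rl), ref, roi))
min_rmse(compute_metrics(list(sy), ref, roi))
```

The full study (`Q = 10` noise realizations per level) is one call:

```r
cfg <- experiment_config("shepp-logan",
                         count_levels = list(low = count_level("low", 1e5)),
                         Q = 10, K = 64, n_iterations = 500, base_seed = 1)
run_method_comparison(cfg)$summary
```

which prints (minimum RMSE over iterations, global ROI):

```
             method level    roi  Q min_rmse_pct min_rmse_iteration
1              mlem   low global 10     54.06142                 14
2          mlem_psf   low global 10     46.43624                 37
3   richardson_lucy   low global 10     91.04402                  1
4       synthesized   low global 10     45.47478                 48
5 synthesized_nopsf   low global 10     51.20965                 20
```

Reading it: at 10⁵ expected counts the best RL iterate is still twice as bad
(91%) as the best synthesized-reconstruction iterate (45%), which matches —
indeed slightly beats — the reference-standard MLEM+PSF (46%) without ever
touching the measured sinogram. Even without PSF modeling the synthesized
problem (51%) improves on plain MLEM (54%) and on RL. Hyperparameter studies
are available as `run_angle_sweep()`, `run_sigma_sweep()` and
`run_input_quality_sweep()`; the methods vignette
(`vignettes/synthesized-reconstruction.Rmd`) documents the model,
parameters, and design choices.

A thin CLI over the same functions ships in `inst/cli/synthrr`
(`synthrr phantom | psf | project | simulate | recon | run`).

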