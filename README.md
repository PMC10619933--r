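# calipr

Subspace-constrained compressed-sensing reconstruction and myelin water
mapping for multi-echo spin-echo (MESE) MRI.

## What this package is for

Myelin water imaging estimates the fraction of a voxel's MRI signal coming
from water trapped between myelin bilayers — the **myelin water fraction
(MWF)**, the spectral amplitude with T2 < 40 ms — together with the
geometric mean T2 of the intra/extracellular pool (**IET2**, 40–200 ms).
Resolving these pools needs a long multi-echo train (56 echoes, ΔTE 6 ms
for the brain protocol), so a fully sampled 3D acquisition takes hours.
This package implements the accelerated route end to end, for researchers
developing or validating quantitative T2 methods:

1. **Sampling** — temporally incoherent variable-density Poisson schemes
   on the phase × slice grid, a different random pattern per echo, with a
   fully sampled central calibration region at the first two echoes, an
   elliptical shutter, and a uniform factor-2 phase grid. Sample counts
   are exact, so a scheme at acceleration R retains exactly
   `round(N/R)/N` of the dataset (4.2% at R = 23.9 on the brain grid).
2. **Signal model** — extended phase graph (EPG) simulation of CPMG decay
   including stimulated echoes at reduced refocusing flip angles.
3. **Synthetic data** — digital tissue phantoms (WM/GM/CSF-like classes
   with known MWF/IET2), smooth complex coil maps, k-space simulation
   with complex Gaussian noise and per-echo undersampling.
4. **Reconstruction** — the two-stage scheme: a conventional CS pass
   (FISTA, L1 Daubechies-4 wavelet penalty) solving
   `min ½‖y − MFSx‖² + λ‖T(x)‖₁`, a data-driven SVD subspace Φ_K
   (K = 12), then a subspace-constrained pass solving
   `min ½‖y − MFSΦ_Kα‖² + λ‖T(α)‖₁`, and echo synthesis `x = Φ_K α`.
5. **Fitting** — voxelwise regularized NNLS over an EPG dictionary (40
   log-spaced T2 values, 8 ms–2 s) with per-voxel refocusing-flip
   refinement, automatic Tikhonov weight (χ² = 1.02 × minimum), optional
   two-pass 3×3 spatial regularization, and MWF/IET2/flip maps.
6. **Statistics** — scan–rescan reproducibility on ROI medians:
   Bland-Altman limits of agreement, repeatability coefficient,
   within-subject COV, ICC(2,1), paired bias tests, and table
   aggregation with mean rows.

## Worked example

Generate the brain-protocol sampling scheme and run the paired
CS-versus-subspace validation experiment on a digital phantom:

```r
library(calipr)

scheme <- generate_sampling_scheme(c(118, 59), 56, 23.9, seed = 1)
scheme
#> Cartesian MESE sampling scheme
#>   grid            : 118 x 59 (phase x slice), 56 echoes
#>   target R        : 23.9
#>   sampled fraction: 0.0418 (4.2%)
#>   calibration     : 12 x 12 at echoes 1-2
#>   shutter on, phase grid factor 2

v <- validation_experiment(grid_shape = c(64, 64), n_echoes = 32, n_coils = 4,
                           target_acceleration = 14.6, noise_sigma = 0.01,
                           seed = 1,
                           config = recon_config(lambda = 0.004, K = 12,
                                                 n_virtual_coils = 4,
                                                 max_iters = 50),
                           fit_maps = TRUE)
v
#> retrospective undersampling validation
#>   sampled fraction: 0.0685 (target R = 14.6)
#>   echo-image NRMSE: reference 0.0275 | CS 0.1586 | subspace 0.1030
#>   MWF map RMSE:     CS 0.0835 | subspace 0.0408
```

Reading the numbers: the scheme retains 6.85% of the data (R = 14.6).
Reconstructing the complete dataset (reference) leaves 2.8% echo-image
error against the noise-free truth. At 14.6× undersampling, conventional
CS reaches 15.9% error while the subspace-constrained reconstruction of
the *same* data with the *same* masks, coil maps and λ reaches 10.3% —
and the quantitative payoff is larger: the MWF map error halves (0.041 vs
0.084). The only difference between the two reconstructions is the
explicit low-dimensional subspace constraint.

A thin command-line interface over the same functions is installed at
`system.file("cli", "calipr.R", package = "calipr")` with subcommands
`mask`, `phantom`, `simulate`, `recon`, `fit`, `stats`, `validate`.

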