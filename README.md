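# dftensor

Simulation toolkit for assessing **linear tensor surrogate models of X-ray
and neutron dark-field anisotropy**, aimed at researchers working on
grating-interferometric (Talbot–Lau) dark-field tensor tomography.

Dark-field contrast from unresolved anisotropic microstructure depends
nonlinearly on *two* orientations — the optical axis n̂ and the
interferometer sensitivity axis ê — while tomographic reconstruction needs
a contrast model that is linear in the per-voxel unknowns. `dftensor`
quantifies what the linear approximation costs. It:

1. models a volume element's microstructure as a 3D Gaussian with precision
   tensor `T = R diag(σ₁⁻², σ₂⁻², σ₃⁻²) Rᵀ` and synthesizes noiseless
   dark-field signals from the nonlinear physical model
   `μ_DF = (T'_xx − T'²_xz / T'_zz) / √T'_zz`
   (instrument frame: ê → x, n̂ → z);
2. reconstructs the two linear rank-2 surrogates — `μ ≈ n̂ᵀ N n̂`
   (cross-section model) and `μ ≈ êᵀ E ê` (auto-correlation model) — by
   damped iterative back-projection (`λ_k = λ₀·2^(−k/τ)`, λ₀ = 0.2,
   25 sweeps) over circular acquisition trajectories (13 trajectories ×
   29 poses = 377 signals, or the reduced 3-trajectory subset, 87 signals);
3. compares surrogates against ground truth over an ensemble covering the
   full eigenvalue simplex (two linear ramps on a grid, trace-normalized)
   with Haar-uniform random orientations: NRMSE, angular deviation
   `Δθ = arccos|v̂_T · v̂_U|` of principal orientations, the width
   σ_Δθ of the inclination-angle error distribution
   (`PDF ∝ Δθ·exp(−Δθ²/2σ²)`, mode = σ), paired normalized eigenspectra,
   and mean-signal reproduction.

## Worked example

A scaled ensemble — 10×10 eigenvalue grid × 50 random orientations = 5000
instances — under the full 13-trajectory geometry:

```r
library(dftensor)
st <- run_study(study_config(grid_size = 10, rotations_per_triplet = 50,
                             geometry = "full", seed = 1))
s <- st$summary
cat(sprintf("sigma_dtheta (deg):  E = %.3f   N = %.3f\n",
            s$E$sigma_delta_theta_deg, s$N$sigma_delta_theta_deg))
cat(sprintf("NRMSE mode:          E = %.3f   N = %.3f   (max %.1f)\n",
            s$E$nrmse_mode, s$N$nrmse_mode, s$N$nrmse_max))
cat(sprintf("mean-signal slope:   E = %.3f   N = %.3f\n",
            s$E$mean_signal_slope, s$N$mean_signal_slope))
#> sigma_dtheta (deg):  E = 0.339   N = 0.801
#> NRMSE mode:          E = 0.092   N = 0.174   (max 19.3)
#> mean-signal slope:   E = 0.998   N = 0.988
```

Reading: both linear surrogates recover the dominant structural orientation
to about a degree or better (E slightly better than N), even though their
pointwise signal approximation is coarse — NRMSE distributions peak near
10–20% with a heavy tail beyond 100% — and both reproduce the mean observed
signal almost exactly (regression slope of trace(U)/3 on mean(μ) ≈ 1).
Rerunning with `geometry = "orthogonal"` degrades orientation recovery to
several degrees, the price of the minimal 3-trajectory acquisition.

`run_study()`'s defaults are the reference ensemble (20×20 grid × 300
rotations = 120 000 instances); `write_study()` exports results as CSV/JSON;
configurations can also be read from YAML/JSON files via
`read_study_config()`.

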