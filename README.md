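# mnecoh

Monte-Carlo evaluation of how much Tikhonov regularization a minimum-norm
estimate (MNE) should use when the goal is to detect **oscillatory source
power** versus **seed-based corticocortical coherence** in MEG source
space.

## The problem

MEG source reconstruction with the minimum-norm estimate solves the
ill-posed linear model

    M = L S + N

(`M` channels x time sensor data, `L` the lead field, `S` source
amplitudes, `N` noise) by the regularized operator

    W = R Lᵀ (L R Lᵀ + λ² Q)⁻¹ ,     Ŝ = W M

with source covariance `R` (identity for the classical MNE), noise
covariance `Q`, and Tikhonov weight `λ²`.  Practice is to pick one `λ` per
study and reuse it for every analysis.  But power mapping (per-vertex
alpha-band Welch power of `Ŝ`) and seed-based coherence mapping
(band-averaged magnitude-squared coherence

    Coh(r₁, r₂, f) = |Cs(r₁, r₂, f)|² / (P(r₁, f) P(r₂, f))

of every vertex against a reference vertex) respond very differently to
regularization: smoothing barely moves a power peak, but it spreads the
seed's time series across the cortex and floods a coherence map with
spurious coupling.  This package simulates pairs of coupled alpha
oscillators (9–14 Hz, coherence calibrated to prescribed levels) on
cortical patches, projects them through a single-sphere (Sarvas) forward
model, adds Frobenius-calibrated white noise, reconstructs with MNE over a
decade grid of weights, and scores detection with exact-threshold ROC/AUC
— power truth being both patches, coherence truth being the distant patch
with the reference patch excluded.  It also selects a weight per
simulation with the classic L-curve corner for comparison.

At desk scale (642-vertex folded spherical source space, 100
magnetometers, 50 location pairs × patch areas {0, 2, 4} cm² × couplings
{0.2, 0.4} × SNRs {0, −20} dB = 600 configurations), the study reproduces
the headline result: **coherence mapping wants about two orders of
magnitude less regularization than power mapping**, and the L-curve
under-regularizes for both.

## Worked example

```r
library(mnecoh)

cfg <- study_config()        # the desk-scale factorial design
res <- run_study(cfg)        # ~2 min on one core
print(res)
#> study_result
#>   cells: 600 ok, 0 failed
#>   optimal weight (power):     1e-07
#>   optimal weight (coherence): 1e-09
#>   mean L-curve corner: 1e-9.36
print(res$ttests)
#>    analysis weight_a weight_b mean_auc_a mean_auc_b        t  df             p
#> 1     power    1e-07    1e-09  0.8343453  0.7237123 20.29501 599  4.343439e-70
#> 2 coherence    1e-09    1e-07  0.8249253  0.5943657 28.99085 599 3.864516e-116
```

Reading this: averaged over the 600 simulated configurations, power
detection peaks (mean AUC 0.83) at weight 1e-7 of the nominal grid while
coherence detection peaks (mean AUC 0.82) two decades lower, at 1e-9;
applying either analysis with the *other* analysis' optimum costs 0.11 /
0.23 mean AUC (paired t-tests, p ≪ 0.001).  The per-simulation L-curve
corner averages 1e-9.4 — about 2.4 decades below the power optimum and
slightly below the coherence optimum — so the classic data-driven choice
under-regularizes both analyses here.  `write_study_report(res, dir)`
emits the aggregate tables (mean AUC by weight, overall and per factor;
optima with grid-edge flags; the t-tests; per-cell L-curve corners).

The numbered drivers under `analysis/` run the same workflow as a
narrative: `01_geometry_forward.R` (geometry and lead field),
`02_generator_calibration.R` (coupling and SNR calibration),
`03_run_study.R` (the study above), `04_example_maps.R` (one illustrative
configuration mapped at the L-curve, coherence-optimal and power-optimal
weights, thresholded at 20% of map maximum).  Each writes CSV/TSV tables
under `results/`.

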