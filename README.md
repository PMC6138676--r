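# igdyn

Comparative biophysics of protein domain variants in R: a tested pipeline
for the analysis chain used when a wild-type domain and a disease-associated
point mutant are compared residue by residue — ¹⁵N backbone relaxation and
rotational diffusion, chemical-shift perturbation, two-state DSC
calorimetry, and coordinate-ensemble statistics. The motivating system is
the lamin A Ig-fold domain (residues 428–552) and its skeletal-muscle
dystrophy mutant W514R, but every stage is generic.

## What it computes

**Relaxation → tumbling.** Per-residue R1/R2 from single-exponential fits
I(t) = I₀e^(−Rt) with Monte-Carlo errors driven by the RMS spectral noise;
heteronuclear NOE as I_sat/I_ref with propagated uncertainty. The global
rotational correlation time τc comes from inverting the rigid isotropic
rotor relation between the R2/R1 ratio and the spectral density
J(ω) = (2/5)τc/(1+(ωτc)²) entering the standard dipolar + CSA rate
expressions, after excluding residues whose R2/R1 deviates by more than one
SD from the mean (local dynamics/exchange) or whose NOE falls more than one
SD below the mean (flexibility).

**Chemical-shift perturbation.** Δδ_amide = √(Δδ_HN² + (Δδ_N/5)²) per
shared residue, strict-threshold classification (default 0.15 ppm), signed
Cα differences with their Pearson r², and mapping of any per-residue value
onto a structure's B-factor column.

**DSC.** Two-state excess heat capacity
Cp_exc = ΔH_cal·ΔH_vH·K/(R·T²·(1+K)²) with
K = exp[−(ΔH_vH/R)(1/T − 1/Tm)], whose temperature integral is exactly
ΔH_cal; trapezoidal integration with flank-fitted linear baselines, peak
finding with parabolic refinement, and full nonlinear fits returning Tm and
both enthalpies.

**Ensembles.** Kabsch superposition (SVD, proper rotation enforced),
per-frame RMSD, mean-structure RMSF, mass-weighted radius of gyration, PCA
of the Cα positional covariance with variance fractions, and porcupine
export of any principal mode as a two-model PDB.

A synthetic-data module generates all four input kinds — decay series, NOE
pairs, paired shift tables, thermograms, mode-based ensembles — with known
ground truth and bit-reproducible seeds, so the full chain is testable
without deposited data.

## Worked example

```r
library(igdyn)

## 125-residue wild-type-like domain, 2% spectral noise
prof <- ground_truth_profile()
sim  <- make_decay_series(prof, noise_rms = 0.02, seed = 1)
rec  <- fit_relaxation(sim$decays, sim$noe, mc_draws = 200, seed = 2)
round(summarize_records(rec), 3)
#>         mean    sd   n sd_defined
#> R1     1.702 0.081 125          1
#> R2    19.429 2.256 125          1
#> NOE    0.762 0.103 125          1
#> R2_R1 11.474 1.583 125          1
tauc_from_records(rec)
#> tau_c = 10.58 ns from mean R2/R1 = 11.83 +/- 0.58 (106 used, 19 excluded)
```

The fitted means recover the generating profile (core R1 1.682 s⁻¹, R2
20.09 s⁻¹, NOE 0.793; the flexible stretches pull the averages down), and
the surviving residues' mean ratio inverts to a ~10.6 ns tumbling time —
what a ~14 kDa monomer-oligomer mixture tumbles at. Nineteen residues are
excluded by the ±1-SD ratio rule or the low-NOE rule before inversion.

```r
## DSC: simulate a noisy wild-type-like thermogram and fit it back
fit <- fit_twostate(make_thermogram(two_state_model(61.9, 110.1,
                                    baseline = c(1.2, 0.003)),
                                    step = 0.05, noise_sd = 0.05, seed = 3))
fit
#> two-state model: Tm 61.90 C, dH_cal 110.2, dH_vH 110.0 kcal/mol
#>   rms residual 0.04963, converged: TRUE

## CSP: an 11-residue perturbed cluster over 0.02 ppm baseline noise
st <- make_shift_tables(100, c(470, 480), 0.3, 0.02, seed = 4)
sum(classify_csp(csp(st$a, st$b))$above_threshold)
#> [1] 11

## PCA: one planted collective mode carrying 75% of the variance
ref <- matrix(rnorm(60 * 3), 60, 3)
ens <- make_ensemble(ensemble_spec(ref, collective_modes(ref, 1, seed = 5),
                                   variances = 3 * (3 * 60 * 1e-4),
                                   jitter_sd = 0.01, n_frames = 1000, seed = 6))
pca_ensemble(ens)
#> ensemble PCA: 180 modes; PC1-3 variance fractions 76.1%, 0.3%, 0.3%
```

`run_compare()` ties the stages into the full two-variant workflow, writing
per-stage CSVs and a side-by-side summary table (NOE, R2/R1, τc, Tm, ΔH,
Rg); see the vignette in `vignettes/variant-biophysics.Rmd` for the model
details and design choices.

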