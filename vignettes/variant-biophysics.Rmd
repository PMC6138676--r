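---
title: "Comparing protein domain variants: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing protein domain variants: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(igdyn)
```

igdyn implements the quantitative analysis chain used to compare a
wild-type protein domain with a destabilizing point mutant — the running
example throughout is the lamin A Ig-fold domain (residues 428–552) and its
muscular-dystrophy-associated W514R variant — across four readouts:

1. **¹⁵N backbone relaxation** (R1, R2, heteronuclear NOE) extracted from
   peak-intensity decays, and a global rotational correlation time from the
   R2/R1 ratio;
2. **chemical-shift perturbation** of backbone amides plus Cα shift
   differences between the two variants;
3. **two-state DSC thermogram** simulation, integration and fitting;
4. **coordinate-ensemble statistics** (RMSD, RMSF, radius of gyration, PCA).

Every input kind can be generated synthetically with known ground truth, so
the whole chain is testable without any deposited dataset.

## Relaxation rate extraction

Peak intensities in a relaxation series decay as a single exponential,
$I(t) = I_0 e^{-Rt}$. `fit_decay()` fits the two parameters by
Levenberg–Marquardt least squares, seeded by a log-linear regression on
positive intensities (a coarse rate grid seeds the fit if no intensities are
positive). No offset term is fitted by default — the decays are modelled as
pure single exponentials — though `offset = TRUE` adds one.

Rate uncertainties come from Monte-Carlo resampling (`mc_errors()`): Gaussian
noise with the spectrum's RMS noise amplitude is added to the best-fit curve
and the fit repeated (500 draws by default; fewer than 100 is rejected as
unstable). This matches how errors propagate from spectral noise in
practice and is more robust than covariance-matrix errors for series of
only 6–8 points. The steady-state NOE is the intensity ratio
$I_\mathrm{sat}/I_\mathrm{ref}$ with the standard two-term error
propagation from one shared RMS noise.

Summary statistics (`summarize_records()`) average R2/R1 **per residue
first** (mean of ratios, not ratio of means), using the sample SD; a
component observed once reports SD 0 with an explicit flag.

## Rotational correlation time

The tumbling time $\tau_c$ is estimated from the mean R2/R1 ratio under the
rigid isotropic rotor model with dipolar and CSA relaxation and no exchange
term ($R_\mathrm{ex} = 0$), using the Lorentzian spectral density
$J(\omega) = \tfrac{2}{5}\,\tau_c/(1 + (\omega\tau_c)^2)$ and the standard
R1/R2/NOE expressions. `estimate_tauc()` inverts R2/R1 by bracketed root
finding on $\tau_c \in [0.1, 100]$ ns after verifying monotonicity of the
ratio on the bracket, so the root is unique.

Physical constants default to the community values used by standard
ratio-analysis tools — $r_\mathrm{NH} = 1.02$ Å, $\Delta\sigma = -160$ ppm,
$\gamma_\mathrm{H} = 2.67522\times10^8$,
$\gamma_\mathrm{N} = -2.7126\times10^7$ rad s⁻¹ T⁻¹, 600.13 MHz — and are
all overridable through `spin_params()`. At those defaults a mean ratio of
12.18 inverts to 10.75 ns, in agreement with the closed-form high-field
approximation $\tau_c \approx \sqrt{6\,\mathrm{ratio} - 7}/(4\pi\nu_N)$
(10.63 ns), which serves as an independent cross-check.

Before inversion, `filter_for_diffusion()` applies the standard exclusion
rules: residues whose ratio lies more than one sample SD above or below the
mean carry exchange or fast local dynamics, and residues whose NOE lies more
than one SD below the mean are flexible; either rule excludes. The two rules
are applied independently (the order is immaterial), inequalities are
strict so boundary ties are kept, and the surviving residues' **mean ratio**
— not an average of per-residue $\tau_c$ values — feeds the inversion.
Anisotropic diffusion tensors and Lipari–Szabo model-free fitting are out
of scope; high ratios are flagged qualitatively, never fitted as exchange.

## Chemical-shift perturbation

The combined amide perturbation is
$\Delta\delta_\mathrm{amide} = \sqrt{\Delta\delta_\mathrm{HN}^2 +
(\Delta\delta_\mathrm{N}/5)^2}$; the 1/5 nitrogen scaling is fixed because
it defines the statistic. Missing assignments propagate as `NA`, never as
zero — a destabilized mutant typically has many unobservable peaks, and
zero-filling would fabricate agreement. Cα differences are signed
(wild type minus mutant) and accompanied by the squared Pearson correlation
of the two Cα shift sets; near-unity r² indicates preserved secondary
structure. `classify_csp()` flags residues strictly above the threshold
(default 0.15 ppm, the conventional cutoff), and `map_to_structure()`
writes per-residue values into the B-factor column (fixed-width `%6.2f`,
sentinel −1.00 for absent residues) for rendering on a structure.

## DSC two-state analysis

With $K(T) = \exp[-(\Delta H_\mathrm{vH}/R)(1/T - 1/T_m)]$, the excess heat
capacity is
$$C_p^\mathrm{exc}(T) = \frac{\Delta H_\mathrm{cal}\,\Delta H_\mathrm{vH}}
{R\,T^2}\,\frac{K}{(1+K)^2},$$
whose temperature integral is exactly $\Delta H_\mathrm{cal}$ — the defining
link between peak area and calorimetric enthalpy, enforced by a quadrature
test for arbitrary parameters. $\Delta H_\mathrm{cal}$ and
$\Delta H_\mathrm{vH}$ are independent fit parameters: their ratio
diagnoses two-state behavior, and $\Delta H_\mathrm{vH} < \Delta
H_\mathrm{cal}$ is allowed (broad transitions from oligomer mixtures), but
no multi-transition deconvolution is attempted. Temperatures are kelvin
internally and Celsius at every interface; the unfolded fraction is
evaluated through `plogis()` so the expression cannot overflow far from
the transition. Scan rate and concentration are carried as metadata only
(equilibrium assumption).

Three numerical choices deserve note:

* **Baseline.** `integrate_enthalpy()` and `find_tm()` accept `"zero"`, an
  explicit line, or `"auto"`: a linear fit to the outer 15% flanks, refined
  twice by excluding points whose provisional excess exceeds 0.1% of peak
  height. The refinement matters because two-state tails decay slowly (scale
  $RT_m^2/\Delta H_\mathrm{vH}$, ≈ 2 °C for the sharp wild-type-like
  transition) and contaminate a naive flank fit by several percent of the
  area; with refinement a planted linear baseline is removed to better than
  1% of the enthalpy on a sharp transition.
* **Peak ≠ midpoint.** The maximum of $C_p^\mathrm{exc}$ lies below $T_m$ by
  $\approx 4R^2T_m^3/\Delta H_\mathrm{vH}^2$ because of the $1/T^2$ factor:
  about 0.05 °C for a 110 kcal/mol transition near 335 K but 0.26 °C for a
  45.6 kcal/mol one. `find_tm()` deliberately reports the peak (refined by
  parabolic interpolation through the three bracketing grid points, exact
  for a symmetric peak); users needing the thermodynamic midpoint of a broad
  transition should use `fit_twostate()`, which recovers the generating
  $T_m$, both enthalpies and the baseline to <0.1% on noiseless curves.
* **Degenerate inputs.** A peak within 3 grid points of a scan edge flags
  the integral as truncated; a monotonic thermogram is an error ("no
  transition"); fit non-convergence after three bounded restarts returns
  the initial estimates flagged, never an abort.

## Ensemble statistics

`kabsch_superpose()` computes the optimal rigid superposition via SVD of the
weighted covariance, with the determinant sign corrected so only proper
rotations are returned; collinear configurations are rejected. A
brute-force minimization over axis-angle rotation space reproduces its RMSD
to 10⁻⁹ in the tests. RMSF and PCA superpose all frames onto the ensemble
mean with one refinement iteration (mean → superpose → recompute mean) — a
deterministic reference that avoids frame-choice bias. PCA eigendecomposes
the 3N × 3N covariance of Cα coordinates by default (selection
configurable); mass weighting is off for PCA/RMSF (immaterial for Cα-only)
and on for Rg, with unit masses when elements are unrecognized.
`porcupine_export()` writes the mean structure and the mean displaced by
$\mathrm{scale}\cdot\sqrt{\lambda_k}$ along eigenvector $k$ as a two-model
PDB, from which any viewer can draw per-atom arrows.

## What the generators emulate — and what they do not

The synthetic-data module produces all four input kinds under one seed per
call, with Gaussian, per-point-independent noise (matching the
RMS-spectral-noise error model):

* **Relaxation decays** for a 125-residue domain: rigid core at the
  wild-type means (R1 1.682 s⁻¹, R2 20.09 s⁻¹, NOE 0.793) with smooth
  flexibility bumps across residues 444–448 and 471–479 (reduced R2 and
  NOE, slightly elevated R1) and an opt-in set of missing residues. The
  per-residue shapes are plausible, not reconstructions — no per-residue
  experimental table exists to reconstruct. Default delay schedules are the
  wild-type measurement schedules (R1 5–1200 ms, R2 8.5–101.8 ms).
* **Shift tables**: variant B is variant A plus baseline noise everywhere
  and an amide ¹H offset inside a perturbed cluster; Cα columns carry only
  baseline noise, so cluster perturbations never leak into the Cα
  correlation.
* **Thermograms**: baseline + excess Cp + noise over a 16–80 °C window.
* **Ensembles**: frames are reference + Σ aₘ·modeₘ + isotropic jitter with
  aₘ ~ N(0, σₘ²). `collective_modes()` draws random mode directions and
  removes their projection onto the six rigid-body motions of the reference
  before normalizing. This matters: superposition removes rigid-body
  displacement, so a mode with rigid content would not carry its nominal
  variance into the aligned covariance, and planted variance fractions
  would be biased by a few percent. With orthogonalized modes the planted
  fraction is exact by construction — a mode three times the summed
  residual jitter variance yields a 75% PC1 fraction.

None of the generators simulate spectra, line shapes, peak overlap,
scan-rate kinetics, or force-field physics; intensities are abstract and
ensembles are Gaussian. Passing tests therefore demonstrate that the
*analysis* chain is correct and self-consistent, not that it would be
robust to artifacts (peak overlap, baseline drift, anharmonic motions) that
real spectrometers, calorimeters and trajectories produce.

## Problem sizes and determinism

The test suite works at desk scale, chosen to keep the full run within a
few minutes while leaving comfortable statistical margins: Monte-Carlo
error checks use 500–1000 draws against a 1000-refit oracle; rate-recovery
checks use 25–30 residues at 2% noise; planted-mode recovery uses 60 atoms
× 1000 frames (the variance fraction then fluctuates by roughly ±1.5
percentage points across seeds, well inside the ±3 points asserted);
thermogram grids are 0.01–0.25 °C over 16–80 °C. Every stochastic step
takes an explicit integer seed and fixed seeds give bit-identical outputs,
which the suite asserts.

## Worked comparison

```{r compare, eval = FALSE}
cfg <- run_config(list(mc_draws = 200, seed = 1))
wt_prof <- ground_truth_profile()                       # wild-type-like
mu_prof <- ground_truth_profile(core_noe = 0.725,
                                missing = c(486:488, 500:503, 513:520))
shifts <- make_shift_tables(100, c(470, 480), 0.3, 0.02, seed = 2)
res <- run_compare(
  cfg,
  wildtype = list(relaxation = make_decay_series(wt_prof, seed = 3),
                  shifts = shifts$a,
                  dsc = make_thermogram(two_state_model(61.9, 110.1),
                                        step = 0.05)),
  mutant   = list(relaxation = make_decay_series(mu_prof, seed = 4),
                  shifts = shifts$b,
                  dsc = make_thermogram(two_state_model(50.5, 45.6),
                                        step = 0.05)),
  output_dir = tempfile("compare"))
res$summary
```

`run_compare()` writes per-stage CSVs, the comparative summary table
(NOE, R2/R1, τc, Tm, ΔH, Rg side by side), and a log recording package
version, seed and config hash; repeated runs with the same config and seed
are byte-identical. Stages with absent inputs are skipped with a notice and
a `"partial"` status — nothing is ever imputed.

## Known limitations

* Isotropic tumbling only; no diffusion-tensor anisotropy, no model-free
  parameters, no temperature/viscosity correction between variants measured
  at different temperatures (none is applied because none is defined for
  the workflow).
* The NOE error model assumes one shared RMS noise for the saturated and
  reference spectra.
* DSC analysis is strictly two-state with a linear baseline; oligomer
  dissociation appears only as $\Delta H_\mathrm{vH}/\Delta H_\mathrm{cal}
  < 1$, never as an explicit coupled model, and absolute heat-capacity
  normalization between samples is not attempted.
* Ensemble readers handle multi-model PDB only (no binary trajectory
  formats), and residue matching across tables assumes a single chain.
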