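# optoKPR

Kinetic proofreading (KPR) proposes that a T cell does not respond to the
*number* of ligand-bound T cell receptors (TCRs) but to the *duration* of the
individual binding events: signaling requires a ligand–TCR complex to survive
a set of receptor-proximal biochemical steps taking a time τ_KPR, so
short-lived complexes reset before they signal. Testing this is hard because
mutating a ligand to change its binding half-life changes other properties of
the interaction too.

An optogenetic route avoids that: the plant photoreceptor phytochrome B
(PhyB), presented as a streptavidin tetramer (PhyBt), binds a PIF-fused TCR
only in its 660 nm–induced ON state. Under continuous 660 nm light every PhyB
molecule cycles between ON and OFF at a rate proportional to the light
intensity, while the ON:OFF photoequilibrium stays fixed at 80:20. Intensity
therefore tunes the ligand–receptor half-life — and nothing else about the
binding interface. `optoKPR` implements the resulting model and the full
inference pipeline around it, for anyone fitting or power-analyzing this kind
of light-controlled dwell-time experiment.

## Model

Five free structural parameters:

| symbol | meaning | unit |
|---|---|---|
| k_c | total 660 nm photocycling rate constant | s⁻¹ per % intensity |
| k_off | light-independent off-rate of the bivalent PhyBt–TCR complex | s⁻¹ |
| K0 | dark-state effective dissociation constant | nM |
| τ_KPR | kinetic-proofreading time | s |
| A | calcium response amplitude (normalized scale) | a.u. |

with the photoequilibrium ON fraction fixed at φ_eq = 0.8. The light-driven
ON→OFF rate is k_i(I) = (1 − φ_eq) k_c I, giving

- effective off-rate: k_eff(I) = k_off + k_i(I) (affine in intensity),
- complex half-life: ln 2 / k_eff(I),
- effective affinity: 1/K_eff(I) with K_eff(I) = K0 · k_eff(I)/k_off
  (reciprocal of an affine function of intensity),
- occupancy: occ = L_on/(L_on + K_eff(I)) with L_on = φ_eq · L,
- proofreading survival: exp(−k_eff(I) · τ_KPR), which is exactly ½ when the
  complex half-life equals τ_KPR,
- steady-state calcium: A · occ · exp(−k_eff(I) · τ_KPR); at τ_KPR = 0 this
  is the occupancy (null) model,
- pulse response: a 660 nm pulse of duration d traps
  L_on(d) = L φ_eq (1 − e^(−k_c I d)) in the ON state, read out in the dark
  as A · L_on(d)/(L_on(d) + K0) · e^(−k_off τ_KPR).

Inference is joint Gaussian maximum likelihood over steady-state calcium,
steady-state binding and pulse-kinetics datasets (per-dataset variances and
the binding scale profiled analytically), with a likelihood-ratio test of
KPR against the occupancy null using the boundary-corrected ½χ²₀ + ½χ²₁ null
distribution, and profile-likelihood confidence intervals for τ_KPR.
Steady-state data alone pin only the product τ_KPR · k_off (a structural
non-identifiability the package can demonstrate); adding the pulse-kinetics
data pins k_c absolutely and separates the two.

## Worked example

```r
library(optoKPR)
truth <- ground_truth()                     # stated world: tau_KPR = 8 s
data  <- generate_dataset_bundle(truth, seed = 7)
lrt   <- likelihood_ratio_test(data, n_starts = 8, seed = 1)
print(lrt)
#> Likelihood-ratio test: KPR vs occupancy (tau_KPR = 0 on the boundary)
#>   D = 31.1848,  p = 1.17e-08 (mixture null),  p = 2.35e-08 (chi2_1)
prof  <- profile_likelihood_tau(data, fit = lrt$fit_kpr, seed = 1)
print(prof)
#> Profile likelihood of the KPR time: tau_hat = 8.78 s, 95% CI [5.41, 13] s
p_fit <- fitted_params(lrt$fit_kpr)
round(complex_half_life(p_fit, c(2, 100)), 1)
#> [1] 42.1  2.1
round(threshold_intensity(p_fit, 20), 2)
#> [1] 2.77
```

The test decisively rejects the occupancy null (the data were generated with
proofreading, τ_KPR = 8 s, and the profile CI covers it), the fitted complex
half-life spans ~40 s at 2% intensity down to ~2 s at 100%, and the
half-maximal-response intensity lands near 3% — the regime in which a
dwell-time threshold, not occupancy, governs activation.

## Analysis workflow

Numbered drivers under `analysis/` run the complete study and write their
tables under `results/`:

1. `01_simulate.R` — materialize the synthetic stand-in datasets (CSV).
2. `02_fit.R` — joint fits of both model variants, prediction tables.
3. `03_lrt_profile.R` — likelihood-ratio test and profile CI for τ_KPR.
4. `04_identifiability.R` — the τ_KPR·k_off ridge, with and without kinetics.
5. `05_recovery.R` — reduced-size calibration study (bias, coverage, type-I).

Run each as `Rscript analysis/0X_*.R` from the repository root, in order.

## Acceptance script

`scripts/acceptance.R` recomputes the package's acceptance target from
scratch: it simulates the two-state photoconversion model from an all-OFF
start to equilibrium at several 660 nm intensities, verifies the steady
state is intensity-independent and consistent with the per-molecule
stochastic oracle, and writes the steady-state ON percentage as JSON.

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

## Documentation

The methods vignette (`vignettes/opto-kpr-methods.Rmd`) describes the model
and its assumptions, the error model and optimizer, what the synthetic-data
generator does and does not emulate, and the package's design choices and
limitations.
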