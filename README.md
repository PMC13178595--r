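# fluorcorrect

Adaptive reflectance correction and constrained unmixing of tissue
fluorescence spectra.

## The problem

Fluorescence spectroscopy of endogenous fluorophores — above all the
metabolic coenzymes NADH and FAD — reports directly on the oxidative state
of tissue through the optical redox ratio
`c_FAD / (c_FAD + c_NADH)`. But the emission spectrum a fiber-optic probe
actually measures, `F_m(λ)`, is distorted by tissue absorption (chiefly
hemoglobin) and scattering. In applications such as machine perfusion of
liver grafts the tissue cycles between blood perfusion, transparent
preservation solution and ischemia, so absorption varies by an order of
magnitude within hours: any correction with fixed parameters is wrong part
of the time.

## The method

The package corrects each measurement with a power of the diffuse
reflectance `R(λ)` acquired from the same volume:

```
F_c(λ) = F_m(λ) / R(λ)^α,      0 ≤ α ≤ 1
```

`α = 1` is the linear, diffusion-theory correction appropriate when
absorption dominates (the Kim model); `α = 0` applies no correction; a
fixed phantom-calibrated intermediate value is the Valdes model. The
contribution implemented here fits `α` *per measurement*, jointly with a
constrained spectral unmixing of the corrected spectrum:

```
(α, C_i, μ_i, σ_i) = argmin | F_m(λ)/R(λ)^α − Σ_i C_i · b_i(λ,μ_i,σ_i) |²
```

subject to `C_i ≥ 0` and box constraints on the Gaussian components'
centers and widths. The basis `b_i` mixes fixed measured emission shapes
(NADH, FAD) with constrained Gaussians for fluorophores that cannot be
measured in phantoms (protein-bound FMN, lipopigments, the 620 and 636 nm
protoporphyrin IX peaks). The solver uses variable projection: amplitudes
are eliminated by an inner nonnegative linear least-squares solve
(Lawson–Hanson), and the bounded outer search runs over `α` and the
Gaussian shape parameters with seeded multi-start. Reported fractions are
`c_i = C_i / Σ C_i`.

Because no measured spectra are distributable, the package ships a
tissue-phantom simulator with full ground truth: seven liquid phantoms
(one dominant fluorophore plus a TiO2 scattering/emission component,
hemoglobin-mimicking Acid Red absorber mixes, per-phantom distortion
exponent, 2% multiplicative noise), raw acquisition bundles following the
background/repeat protocol, and an organ-perfusion timecourse
(hypothermic oxygenated perfusion → warm ischemia → normothermic machine
perfusion) with drifting NADH/FAD fractions.

## Worked example

```r
library(fluorcorrect)

suite <- generate_phantom_suite(seed = 0, noise_cv = 0.02)
entry <- suite[[5]]   # phantom 3 at the 375 nm tag: FAD + TiO2, strong absorber
fit <- fit_adaptive(entry$fm, entry$r, phantom_basis_library())
fit
#> <unmix_result> alpha=0.5190, mse=4.986e-08, converged=TRUE
#>   fractions: NADH=0.000, FAD=0.774, TiO2=0.226
entry$truth$alpha       # 0.523
entry$truth$fractions   # NADH 0.000, FAD 0.776, TiO2 0.224
```

The fitted exponent (0.519) recovers the generating distortion (0.523) and
the fractions match the ground truth to better than one point, with no
spurious NADH. Evaluating all three corrections over the whole suite:

```r
tab <- cmd_evaluate(suite)
attr(tab, "formatted")
#>  method excitation_nm sensitivity specificity   mae
#>     new           375       100.0       100.0 0.007
#>  valdes           375        85.7        57.1 0.036
#>     kim           375        71.4        57.1 0.110
#>     new           405       100.0        85.7 0.007
#>  valdes           405       100.0        42.9 0.050
#>     kim           405        85.7        57.1 0.115
```

Sensitivity/specificity are detection percentages over the 7 phantoms × 3
candidate fluorophores (threshold: fraction > 0.01); MAE is the mean
absolute error of the recovered fractions over the 21 pairs. The adaptive
fit detects exactly the present fluorophores and quantifies them an order
of magnitude more accurately than either fixed-α baseline, which
misattribute fractions whenever their frozen exponent differs from the
phantom's true one.

A command-line surface wraps the same functions
(`inst/scripts/fluorcorrect.R` with subcommands
`simulate | fit | calibrate | evaluate | monitor`).

## Scope

The package corrects normalized spectral shapes and recovers *relative*
fluorophore fractions; absolute concentration retrieval, probe geometry
modeling, instrument control and photon-transport simulation are out of
scope. The simulator's reflectance model is a smooth attenuation ansatz,
not diffusion theory — the correction consumes `R(λ)` as data, so only its
spectral structure matters. See the methods vignette
(`vignettes/adaptive-reflectance-correction.Rmd`) for the model's
assumptions, parameter choices and limitations.
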