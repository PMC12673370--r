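# mitoflux

Analysis toolkit for tissue-homogenate mitochondrial physiology
experiments: high-resolution respirometry under a
substrate-uncoupler-inhibitor titration (SUIT) protocol, fluorometric
hydrogen peroxide flux measurement with the Amplex UltraRed (AmR) assay,
citrate synthase (CS) activity for mitochondria-specific normalization,
relative gene expression by the ΔΔCt method, morphometry of stained
mitochondria in fluorescence micrographs, and the accompanying statistical
layer. It is written for bioenergetics labs that want the full chain from
raw instrument-style traces to publication-style summaries in one tested,
scriptable pipeline — together with a synthetic-data generator that
produces every input with recorded ground truth, so the whole chain is
validated as the inverse of a known generative model.

## The core quantities

A SUIT run resolves six respiratory states — N-linked LEAK (N_L), N-linked
OXPHOS (N_P), convergent NS-OXPHOS (NS_P), NS-electron-transfer capacity
(NS_E), S-linked ET capacity (S_E), and residual oxygen consumption (Rox).
From the O2 concentration trace c(t) (µM) the package computes, per state,

- volume-specific flux `J_V = −1000 · dc/dt` (pmol·s⁻¹·mL⁻¹),
- mass-specific flux `J_mass = J_V · V/m` and CS-specific flux
  `J_CS = J_V · V/IU`,
- Rox-corrected fluxes, flux control ratios `FCR = J / J(NS_E)`, and the
  coupling control efficiencies
  `E-P = 1 − NS_P/NS_E` and `P-L = 1 − N_L/N_P`.

The fluorometric channel is calibrated against known 0.1 µM H2O2
titrations (chemical background + time-resolved sensitivity), yielding
per-state H2O2 fluxes and the ratio `J_H2O2/J_O2` against a paired
AmR-free O2 measurement. CS activity follows
`v = (r_A/(l·ε_B·ν_B)) · (V_cuvette/V_sample)/ρ` from 412 nm absorbance
kinetics. Morphometry reports mean particle area, count per cell area and
percent area per cell after thresholding, 8-connected labelling and the
area ≤ 3 exclusion filter. Statistics cover ROUT outlier screening, t and
exact Mann-Whitney tests, and one-way ANOVA with Šidák correction.

See `vignettes/analysis-methods.Rmd` for the models, assumptions, and
every tunable parameter.

## Worked example

Simulate a brain-homogenate-like SUIT run near air saturation and analyze
it back:

```r
library(mitoflux)

truth <- physiologicalPreset()                       # recorded ground truth
tr <- simulateRespirometryTrace(suitSchedule(), truth, "air", seed = 7)
cs <- chamberCsUnits(csActivity(0.136), sampleMass(tr))  # 0.136/min -> 0.1 IU/mg
res <- analyzeTrace(tr, csUnits = cs)
res$fluxTable
#> FluxTable (Rox-corrected), V = 2 mL, m = 2 mg, CS = 0.2 IU
#>  state     j_v  j_mass    j_cs slope_se window_s negative
#>    N_L   8.653   8.653   86.53    1.659      120    FALSE
#>    N_P  43.488  43.488  434.88    1.850      120    FALSE
#>   NS_P  86.328  86.328  863.28    1.805      120    FALSE
#>   NS_E 105.560 105.560 1055.60    1.711      120    FALSE
#>    S_E  52.535  52.535  525.35    1.922      120    FALSE
#>    ROX   0.000   0.000    0.00    1.980      120    FALSE
round(res$efficiencies, 3)
#>   e_p   p_l
#> 0.182 0.801
```

The recovered Rox-corrected mass-specific fluxes sit within the fit noise
of the generator's truth (8, 43, 88, 108, 53 pmol·s⁻¹·mg⁻¹ after Rox
subtraction); `e_p = 0.182` says OXPHOS runs at ~82% of ET capacity and
`p_l = 0.801` indicates tight coupling. A two-group comparison in the
nonparametric reporting convention:

```r
compareTwo(c(54.2, 49.1, 60.3, 47.8, 52.5), c(41.0, 38.7, 45.2, 36.9),
           test = "mannwhitney", groupNames = c("Ctrl", "HPC"))
#> Mann-Whitney U ( median +/- IQR )
#>   Ctrl: 52.5 +/- 5.1 (n = 5)
#>   HPC: 39.85 +/- 3.8 (n = 4)
#>   U = 20, p = 0.01587
```

The p-value is exact (all 126 group assignments enumerated).

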