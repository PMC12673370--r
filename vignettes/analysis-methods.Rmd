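---
title: "Models and methods behind mitoflux"
author: "mitoflux maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind mitoflux}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitoflux)
```

# Scope

`mitoflux` implements the quantitative analysis chain of a tissue-homogenate
mitochondrial physiology experiment: high-resolution respirometry under a
substrate-uncoupler-inhibitor titration (SUIT) protocol, fluorometric H2O2
flux measurement with the Amplex UltraRed (AmR) assay, citrate synthase (CS)
activity for mitochondria-specific normalization, relative gene expression
by the delta-delta-Ct method, morphometry of stained mitochondria in
fluorescence micrographs, and the group-comparison statistics used to report
such experiments. A synthetic-data module generates every input with
recorded ground truth, so that each analysis step can be validated as the
exact or statistical inverse of a known generative model.

# Respirometry

## The flux model

The oxygraph chamber (volume $V$ in mL, wet tissue mass $m$ in mg) records
the O2 concentration $c(t)$ in $\mu$M. Between titration events the
metabolic flux is taken as constant, so $c(t)$ falls linearly:

$$ J_V = -1000 \cdot \frac{dc}{dt} \quad
   \left[\mathrm{pmol \, s^{-1} \, mL^{-1}}\right], $$

using $1\,\mu\mathrm{M} = 1000$ pmol/mL. Mass-specific and
mitochondria-specific fluxes follow as $J_{mass} = J_V \, V / m$
(pmol s$^{-1}$ mg$^{-1}$) and $J_{CS} = J_V \, V / \mathrm{IU}$
(pmol s$^{-1}$ IU$^{-1}$), where IU is the CS activity present in the
chamber (`chamberCsUnits()`).

The SUIT sequence resolves six states: `N_L` (LEAK on
pyruvate/malate/glutamate), `N_P` (OXPHOS after saturating ADP), `NS_P`
(convergent NADH- and succinate-linked OXPHOS), `NS_E` (ET capacity after
stepwise CCCP titration), `S_E` (succinate-linked ET after rotenone) and
`ROX` (residual oxygen consumption after antimycin A). A cytochrome c event
between ADP and succinate probes outer-membrane integrity.

## Window policy

Plateau marking is not published for the instrument software, so the
package defines its own reproducible rule (`windowPolicy()`): the flux of a
state is fitted on the **latest 120 s of its plateau, ending 30 s before
the next titration**, with a 10 s mixing artifact masked after every
injection. These defaults mirror common practice of marking the stable tail
of each plateau; all three are configurable. The fit is an ordinary
least-squares slope; when reoxygenations (or H2O2 calibration titrations)
fall inside a window, a common slope is fitted across the sub-segments with
separate intercepts, so concentration steps cannot bias it. Windows with
fewer than 10 usable samples are refused.

The `N_P` window is placed **between ADP and cytochrome c**, so the
integrity test (default flag threshold: 15% relative flux increase, a
conventional quality cutoff — no quantitative criterion is established for
this assay) cannot contaminate the OXPHOS estimate. For the uncoupler
titration, every step's flux is computed and the step with maximal flux
becomes `NS_E` (ties resolve toward the lower concentration); if flux is
still rising at the last step an under-titration flag is raised, since the
true maximum may not have been reached.

An optional instrumental O2 background correction
$J^\circ = a^\circ + b^\circ c$ can be subtracted from volume-specific
fluxes (`computeVolumeFlux(instrumentBackground=)`); it is off by default
because the generative model does not include sensor O2 consumption.

## Derived quantities

After Rox correction (subtraction of the `ROX` flux from every state under
every normalization — idempotent, and commuting with normalization since
both are affine in the flux), the package computes flux control ratios
$FCR(s) = J(s)/J(\mathrm{NS}_E)$ and the coupling control efficiencies

$$ \text{E-P} = 1 - \mathrm{NS}_P/\mathrm{NS}_E, \qquad
   \text{P-L} = 1 - \mathrm{N}_L/\mathrm{N}_P. $$

Negative Rox-corrected fluxes are retained and flagged rather than clamped,
so that downstream ratios remain faithful to the data. Both efficiencies
are invariant under uniform rescaling of all fluxes, and
$FCR(\mathrm{NS}_E) = 1$ identically.

# Amplex UltraRed H2O2 fluxes

The fluorescence channel obeys
$F(t) = b_0 + b_1 t + s(t)\, C(t)$, where $b_0 + b_1 t$ is the chemical
background (modelled linear in time; its functional form is not specified
by the assay literature, and a drifting linear baseline is the simplest
model consistent with slow reagent autoxidation), $s(t)$ the fluorophore
sensitivity in V/$\mu$M and $C(t)$ the cumulative H2O2 concentration.

**Background calibration.** Before the sample is added, known 0.1 $\mu$M
H2O2 titrations into the chelator/SOD/HRP/AmR medium identify $b_0$, $b_1$
and the initial sensitivity $s_0$ in a single least-squares fit of $F$
against time and the known cumulative titrated H2O2
(`fitBackgroundCalibration()`). At least two steps are required.

**Sensitivity drift.** The sensitivity of the assay decays over the run. In
the generator the decay is exponential and parameterized per hour:
$s(t) = s_0 (1-d)^{t/3600}$, so a 10%/h decay makes a titration at $t$ = 1 h
step exactly 0.9 times the initial step. On the analysis side each in-run
0.1 $\mu$M titration yields a sensitivity knot (step height / 0.1, with the
step height measured by local linear fits on both sides extrapolated to the
injection time, cancelling chemical and metabolic drift); between knots the
sensitivity is interpolated linearly, outside them the nearest knot value
is used. Linear interpolation at 20-minute titration spacing approximates
the exponential to about $10^{-4}$ relative, far below the assay's noise.
Because a large accumulated H2O2 pool multiplies any sensitivity error,
fitting windows must lie inside the knot span: the schedule generator
therefore always places a terminal calibration titration near the end of a
fluorometric run, and the residual-O2 window closes before it. Windows
outside the calibrated span (beyond a configurable extrapolation slack) are
refused.

**Fluxes and the H2O2/O2 ratio.** With the calibration in hand,
$c_{H2O2}(t) = (F - b_0 - b_1 t)/s(t)$, and the per-state H2O2 flux is its
slope scaled as for O2. The ratio $J_{H2O2}/J_{O2}$ uses a **paired
AmR-free measurement** of the same sample for the denominator, because the
dye and the fluorescence light themselves can perturb respiration; the
with-AmR O2 channel is never used for the ratio, which is reported only
where the Rox-corrected paired O2 flux is positive. The physiological
simulation preset keeps $J_{H2O2}/J_{O2} \times 100$ below 2% in every
state, the magnitude of electron leak expected under physiological
conditions. Amperometric settings (500 mV, gain 1,000) are run metadata
only and never enter computation.

# Citrate synthase activity

The DTNB-coupled assay yields a linear 412 nm absorbance increase sampled
every 10 s for 120 s. Specific activity is

$$ v = \frac{r_A}{l \, \varepsilon_B \, \nu_B} \cdot
       \frac{V_{cuvette}}{V_{sample}} \cdot \frac{1}{\rho}, $$

with slope $r_A$ (min$^{-1}$), path length $l$ = 1 cm, TNB extinction
coefficient $\varepsilon_B$ = 13.6 mM$^{-1}$cm$^{-1}$ at pH 8.1,
stoichiometric number $\nu_B$ = 1, $V_{cuvette}$ = 1 mL, $V_{sample}$ =
50 $\mu$L, and sample mass concentration $\rho$ = 2 mg/mL. Both volumes
are converted to mL before the ratio. A water-blank series, when supplied,
has its slope subtracted (whether published values are blank-corrected is
not stated; subtraction is the conservative default, and a blank of
distilled water has essentially zero slope anyway). The canonical worked
case: $r_A$ = 0.136 min$^{-1}$ at these defaults gives $v$ = 0.1 IU/mg.

# Relative gene expression

Per sample, $\Delta Ct = Ct_{target} - Ct_{ref}$ (reference gene `Actb` by
default); $\Delta\Delta Ct$ subtracts the **arithmetic mean** control-group
$\Delta Ct$ of the same gene (the baseline statistic is not specified in
common protocols; the arithmetic mean on the Ct scale corresponds to the
geometric mean of expression, the standard convention), and the fold change
is $2^{-\Delta\Delta Ct}$. Per-group folds are summarized as mean ± SD.
Plate offsets cancel in $\Delta Ct$, which the tests verify as an exact
invariance. No amplification-efficiency correction is applied — the plain
$2^{-\Delta\Delta Ct}$ model is deliberate. Reference-gene stability is
reported as per-group mean ± SD of raw Ct.

# Morphometry

The imaging pipeline mirrors a contrast/threshold/particle-count macro
whose exact parameters are unpublished; every choice below is therefore an
explicit, configurable assumption:

* **Contrast**: linear percentile stretch saturating 0.3% of pixels at
  each tail.
* **Despeckle**: radius-1 median filter, removing single-pixel noise.
* **Threshold**: Otsu's method on the enhanced image, guarded by a robust
  noise floor of median + 5 MAD. The floor is what makes blank images
  yield exactly zero detections: Otsu always splits a unimodal noise
  histogram, so some data-relative guard is required. Both candidates
  scale with the data, keeping segmentation invariant under uniform
  intensity scaling.
* **Connectivity**: 8-connected components, the particle-analysis default.
* **Area filter**: particles with area ≤ 3 calibrated units are excluded
  (inclusive cutoff); with no pixel calibration the unit is pixel².
* **Manual correction**: represented as a reproducible exclusion list of
  particle ids rather than interactive editing.

Per-cell metrics are the mean retained-particle area, particle count per
cell area, and total particle area per cell area (percent). Replicates
aggregate as in the study design: three cells per coverslip averaged, then
mean ± SD over four coverslips per condition.

The generator draws rod-shaped particles (blurred capsules, Poisson photon
noise plus Gaussian read noise) inside an elliptical cell mask. Its fusion
operation attaches particles end-to-end with zero pixel overlap, so the
true total area is conserved exactly while the component count drops by
one per merge. Measured by thresholding, the area fraction of a fused
image inflates by a few percent relative to its unfused twin — the point
spread function fills concave junction corners, a known bias of
threshold-based area estimation that affects real micrographs equally —
while the count halves and the mean size doubles, the characteristic
signature distinguishing fusion from biogenesis.

# Statistics

* **ROUT outlier screening** is implemented for the constant-location case
  relevant to scalar group data (the regression-model generality of the
  original method is out of scope): robust center = median, robust scale
  RSDR = 68.27th percentile of absolute residuals with small-sample
  correction $n/(n-1)$, two-tailed p-values of standardized residuals from
  a t distribution with $n-1$ df, and a Benjamini-Hochberg-style
  outside-in decision at the desired maximal FDR $Q$ (default 1%, the
  conventional default, configurable). Screening happens per group before
  testing, and removed values are reported with the result.
* **Two groups**: Student's t-test (mean ± SD summaries) or Mann-Whitney U
  (median ± IQR). The Mann-Whitney p-value is exact — complete enumeration
  of all $\binom{N}{n_1}$ assignments with midranks under ties — for
  combined $n \le 20$, and uses the tie-corrected normal approximation
  beyond. All tests are two-sided at $\alpha = 0.05$.
* **Three or more groups**: one-way ANOVA, with all pairwise comparisons on
  the pooled error term and Sidak adjustment $1-(1-p)^m$.

# The synthetic-data generator

The generator reproduces the statistical structure of the instruments, not
the biology: fluxes are imposed per state (no membrane potential, no
reverse electron transfer), reoxygenation is an instantaneous step to the
regime ceiling (chamber-opening kinetics are not reported), injection
artifacts are 10 s masked transients, and noise is Gaussian with defaults
of 0.5 $\mu$M (O2) and 0.002 V (fluorescence) — plausible instrument-scale
values, stated rather than derived, since no noise magnitudes are
published. Two O2 regimes are built in: near air saturation (150-200
$\mu$M) and intracellular tissue normoxia (30-40 $\mu$M), where frequent
reoxygenations exercise the segment-aware slope fitting. The uncoupler
titration rises to its maximum at the penultimate step by default, so the
optimum-selection logic is non-trivial. Passing tests on these simulations
demonstrates correct inversion of the stated generative model — they
cannot certify behaviour under instrument pathologies the model omits
(sensor drift, temperature transients, non-Gaussian artifacts).

# Validation problem sizes

The shipped validation suite uses 20 simulated runs per O2 regime with
180 s plateaus for flux recovery (mean relative error of Rox-corrected
mass-specific flux ≤ 5% for true fluxes ≥ 20 pmol s$^{-1}$ mg$^{-1}$),
noiseless drift-corrected H2O2 round trips (within 2%), 1,000 random
parameter draws for the CS closed form (10$^{-9}$ agreement), 100 particle
images and 100 blanks for segmentation (≥ 95% recovery at SNR 5, zero
false positives), and 10,000 replicates for the t-test type-I error
(within [0.04, 0.06]) and ROUT false-flag rate (≤ 3% of values at
$Q$ = 1%).

# Known limitations

* No oxygen-kinetics (p50) or membrane-potential modelling.
* The AmR channel's voltage-to-sensitivity mapping is treated as strictly
  run-specific; calibrations are never pooled across runs.
* Morphometry is 2-D only: no z-stacks, no skeleton/network topology
  metrics, no intensity-based membrane-potential readouts.
* Mann-Whitney beyond combined n = 20 relies on the asymptotic
  approximation; for the group sizes typical of these experiments the
  exact path is always taken.
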