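---
title: "Methods: oxygen-equilibrium analysis and the two-state simulator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: oxygen-equilibrium analysis and the two-state simulator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hemox)
```

## What the package computes

`hemox` analyses hemoglobin oxygen-equilibrium (tonometry) experiments of the
kind used in comparative studies of blood oxygen transport: a hemoglobin
solution is equilibrated with a small number of oxygen tensions, its
fractional saturation is recorded, and the experiment is repeated across pH,
temperature, and allosteric-effector conditions (no effectors = "stripped",
0.1 M KCl, 2,3-diphosphoglycerate at twofold molar excess over tetramer, or
both). From these measurements the pipeline estimates, per hemoglobin:

* **P50 and n50** — the half-saturation oxygen tension (mm Hg) and the Hill
  cooperativity coefficient, from a Hill-plot fit per series;
* **standardized P50** at a reference pH (7.20 for adult hemoglobins, 7.10
  for embryonic/fetal isoforms, matching the lower pH of prenatal blood),
  from a linear regression of log10 P50 on pH;
* the **Bohr coefficient** (dlogP50/dpH over pH 6.9–7.8);
* **effector effects** — differences of standardized log10 P50 between an
  effector condition and the stripped condition;
* the **apparent enthalpy of oxygenation** between 25 and 37 °C by the van't
  Hoff isochore, corrected for the heat of O2 solubilization;
* **relative solubility** from ammonium-sulfate salting-out curves.

A two-state (Monod–Wyman–Changeux, MWC) forward simulator generates
synthetic datasets with the same design and a plausible noise structure, so
that every pipeline stage can be validated by parameter recovery against
known ground truth. That closed loop is the package's testing strategy: the
estimators are exercised on data whose true P50, Bohr slope, effector
effects and oxygenation enthalpy are computable to machine precision.

## Hill-plot estimation

Each series (3–5 tensions, saturations kept between 30% and 70% by the
protocol) is transformed to Hill coordinates, `y = log10(S/(1-S))` against
`x = log10(PO2)`, and fitted by ordinary least squares. The slope is `n50`;
the x-intercept `-a/b` is `log10 P50`.

Two deliberate choices:

* **No weighting.** The logit transform makes the variance of `y` depend on
  `S`, but inside the 30–70% band the induced heteroscedasticity is mild
  (the derivative `1/(S(1-S) ln 10)` varies by only ~15% over the band), and
  the classical analysis of such experiments is an unweighted Hill fit.
* **Delta-method SE for log10 P50.** The x-intercept is a ratio of
  coefficients, so its SE is propagated from the full 2×2 coefficient
  covariance with gradient `(-1/b, a/b^2)`. The SE of P50 on the mm Hg scale
  follows from the log link, `se(P50) = ln(10) * P50 * se(log10 P50)`. These
  are per-fit regression SEs; whether a laboratory would instead report
  across-replicate SEMs is not inferable from a single series, so the
  per-fit quantity is computed and labelled as such.

Degenerate inputs are rejected rather than patched: saturations at exactly 0
or 1 (undefined logit) fail validation at read time, series with all
tensions identical are rank-deficient, and a non-positive fitted slope
(saturation falling with tension) is reported as an error. A P50 outside the
measured tension range is legitimate but extrapolated, so it is flagged with
a warning.

## pH standardization, Bohr effect, effector effects

Within one (condition, temperature) cell, `log10 P50` is regressed on pH and
evaluated at the reference pH; the SE of that interpolation is the classical
regression-prediction SE, smallest at the mean pH of the design. Regressions
are fitted separately per temperature because the thermal analysis needs
temperature-specific standardized values; an optional inverse-variance
weighting by the per-fit SEs exists behind the `weight_by_se` configuration
flag but is off by default (the conventional analysis is unweighted).

The Bohr coefficient is the slope of the same kind of regression restricted
to pH 6.9–7.8 (inclusive endpoints); all points inside the window are used,
not just the endpoint pair. Effector effects are computed from standardized
values — `logP50(effector, pH_ref) - logP50(stripped, pH_ref)` — rather than
from raw per-pH pairs, and their SEs combine the two prediction SEs under
independence, which is the defensible default when condition series come
from separate preparations and no covariance estimate exists.

## Thermal analysis

The apparent enthalpy of oxygenation between two absolute temperatures
`T1 < T2` is the van't Hoff isochore

```
dH = 2.303 R (log10 P50(T1) - log10 P50(T2)) / (1/T1 - 1/T2)   [kJ/mol O2]
```

with the conventional printed constant 2.303 (not ln 10; the 0.018%
difference is far below every tolerance used here). The orientation —
low-temperature value minus high-temperature value over `1/T1 - 1/T2` — is
the unique reading of the formula that yields negative (exothermic)
enthalpies for normal hemoglobins whose affinity falls with temperature,
matching the sign of every reported mammalian value.

Gas-tension-based P50 measurements fold the heat of dissolving O2 into the
apparent enthalpy. The correction is applied as `dH' = dH + 12.55` kJ/mol
O2, i.e. toward less exothermic values, the standard convention in this
literature (dissolution of O2 in water is exothermic at these temperatures,
and removing its heat from the apparent binding enthalpy moves the estimate
up). Because the operation's direction is a convention rather than printed
arithmetic, the constant — including its sign — is configurable
(`solubilization_correction_kj`).

`dH'` is reported at the reference pH per condition, and additionally for
the stripped condition at pH 7.8, where oxygenation-linked proton binding is
minimal and the value isolates the intrinsic (heme + conformational)
enthalpy. Both the pH 7.2 and pH 7.8 stripped values appear in the output,
labelled, since either may be the quantity of comparative interest.

## Solubility

Salting-out series are normalized to each sample's own 0 M ammonium-sulfate
control (relative solubility; absolute extinction coefficients are out of
scope). Percent precipitated at 3 M — the conventional comparison point — is
interpolated linearly between bracketing molarities when 3 M was not
measured exactly; small negative percentages (soluble signal slightly above
the control) are clamped to zero and logged. A two-parameter logistic,
`fraction = 1/(1 + exp((M - midpoint)/slope))`, summarizes the full 0–3.5 M
curve; a fitted midpoint beyond the highest measured molarity is flagged "no
transition observed" rather than reported as a trustworthy location.

## The two-state simulator

The generator is a tetramer MWC model. With `alpha = PO2/kR` and
`c = kR/kT`:

```
Y = [alpha (1+alpha)^3 + L c alpha (1+c alpha)^3] /
    [(1+alpha)^4 + L (1+c alpha)^4]
```

Heterotropic effectors act purely through the allosteric constant — the
simplest structure that reproduces every measured phenomenon:

```
L_eff = L0 * prod_e [(1 + [e]/K_T,e) / (1 + [e]/K_R,e)]^m_e
```

over DPG (1 site per tetramer), chloride (4 independent sites) and Bohr
protons (2 groups, `[H+] = 10^-pH`, `K = 10^-pKa`). A T-state-preferential
effector (`K_T < K_R`) stabilizes the deoxy conformation and raises P50; a
hemoglobin that has lost its organophosphate site is modelled by equal T-
and R-state DPG constants, which makes the DPG factor exactly 1 at any
concentration — the analogue of deleting the binding residue.

**Temperature.** Every equilibrium carries its own enthalpy (kJ/mol):
heme oxygenation `dh_o2` (−59), the T→R transition `dh_l`, effector binding
`dh_dpg`, `dh_cl`, `dh_h`, and O2 solution `dh_sol` (12.55, a property of
the measurement, not the protein). Dissociation constants scale by the
van't Hoff relation

```
K(T) = K(t_ref) * exp[(dh/R) (1/T - 1/t_ref)]
```

(so exothermic binding weakens with rising temperature), and `L0` scales
analogously with `dh_l`. Under this convention two identities hold exactly,
and the tests rely on them: with all non-heme enthalpies zero the pipeline's
raw van't Hoff estimate equals `dh_o2`; and adding an exothermically bound
T-state effector makes `dH'` less negative — the mechanism by which
cold-tolerant mammals blunt the thermal sensitivity of oxygen unloading.
That monotone reduction holds below the effector's allosteric saturation
point; at very high concentrations the T state becomes pinned at P50, the
oxygenation-linked effector release vanishes, and `dH'` rolls back toward
the stripped value. The property tests probe the monotone regime and the
roll-back separately.

**Defaults.** `L0 = 1e5`, `kR = 0.35`, `kT = 35` mm Hg (`c = 0.01`) give a
stripped P50 near 9.7 mm Hg and `n50` near 2.6 at pH 7.2/37 °C — typical
adult-mammalian cooperativity in the affinity range of sirenian
hemoglobins. DPG constants 6e-5/2e-2 M, chloride 0.125/0.5 M, Bohr pKa
7.45/6.75 produce effector shifts (chloride ~0.19, DPG ~0.13, combined
~0.31 log units) and a Bohr slope (~ -0.19 stripped) of realistic magnitude,
while keeping the combined condition cooperative (n50 ~ 1.8) rather than
allosterically saturated. Enthalpies default to `dh_o2 = -59`, `dh_l = +20`,
`dh_dpg = -30`, `dh_cl = -20`, `dh_h = -30` kJ/mol, with `t_ref = 310.15` K.
These are study conditions, not tuning knobs: recovery tests randomize the
parameters, and the calibration utility (below) replaces them with
target-matching values when a specific hemoglobin is being emulated.

**Measurement emulation.** `simulate_oec()` reproduces the protocol: `k`
target saturations equally spaced strictly inside the 30–70% band
(`s_i = 0.30 + 0.40 i/(k+1)`), tensions obtained by inverting the true
curve, and observed saturations equal to truth plus Gaussian noise of SD
0.005, redrawn (not clamped) outside (0.01, 0.99) so the logit stays
finite. The Gaussian-on-saturation choice is a modelling decision — the
thin-film method's published precision implies roughly this scale, but no
likelihood was stated for it — and is isolated behind the generator
interface. All randomness flows through one seeded generator;
`simulate_experiment()` builds a whole measurement panel (pH × temperature ×
condition) from a single seed.

**Calibration.** `calibrate_to_targets()` adjusts a chosen set of free
parameters (positive ones on the log10 scale; a joint `k_scale` degree of
freedom rescales `kR` and `kT` together, preserving cooperativity) by
bounded Levenberg–Marquardt least squares so that the model's *true*
summaries match required P50, Bohr, or `dH'` values, each residual scaled by
its tolerance (0.5% on P50, 0.5 kJ/mol on `dH'`). A tiny ridge toward the
starting values keeps underdetermined problems well-posed without masking a
missed target, and a deterministic multi-start pattern guards against local
minima. Calibration failure is an error that names the worst residual, never
a silent approximation.

## Numerical choices

* True P50: bisection (`uniroot`) on log10 PO2 over [1e-6, 1e4] mm Hg,
  tolerance 1e-12 on the log scale; the bracket is asserted first, so absurd
  parameters fail loudly.
* True n50: centered finite difference of the Hill transform at P50 with
  step 1e-4 in log10 PO2; the model Bohr slope uses a centered difference
  with step 1e-3 pH units.
* Duplicate oxygen tensions are legitimate replicates and enter the
  regression as independent observations; duplicate solubility molarities
  are likewise retained (flagged in the log), never averaged away.
* Temperatures convert with the 273.15 offset; R = 8.314 J/(mol K). Both are
  configurable but rarely should be.

**A systematic worth knowing about.** The Hill plot of a two-state curve is
not exactly straight, so the chord fitted over the 30–70% band carries a
deterministic offset from the true (Y = 1/2) crossing — about 0.2–0.7%
in P50 at the default cooperativity, shrinking rapidly as `c` falls. This is
a property of the Hill-plot method itself, not an estimator bug; it is far
inside the 5% recovery tolerances used in validation, but it is why
noiseless recovery is asserted to 1e-3 only in the high-cooperativity
regime, and why end-to-end statistical checks allow a small deterministic
allowance on top of 3 propagated SEs.

## What the synthetic data do and do not show

The generator emulates the design (3–5 tensions in band, pH 6.8–7.9, 25 and
37 °C, the four effector conditions), the concerted two-state allosteric
mechanism, and a homoscedastic Gaussian saturation error. It does not
emulate: tertiary-state or sequential binding (no Adair fitting is offered,
deliberately), instrument drift or pH-meter error (pH enters as exact),
correlated errors between conditions sharing a preparation (SEs combine
under independence; if preparations were shared the combined SEs are
conservative or not, depending on the sign of the covariance), hemoglobin
oxidation over the run, or concentration-dependent dimerization at the low
heme concentrations of embryonic isoform work. Passing recovery tests
therefore demonstrates estimator correctness under the stated error model,
not robustness to every laboratory pathology.

## Problem sizes

The validation suite runs at desk scale by design: 100-series benchmarks for
the fit-quality and precision bounds, four-pH panels per condition for
recovery runs, 1000 random draws for the saturation-function oracle, and
100-replicate Monte-Carlo comparisons for SE calibration. The full test
suite completes in about two minutes on one CPU; the acceptance script in
well under one.

## Known limitations

* Binding constants are not estimated from experimental data (effect sizes
  are reported on the logP50 scale only); the MWC structure lives entirely
  on the generator side.
* The measured `dH'` is not decomposed into conformational and
  effector components — that decomposition exists only as simulator ground
  truth, where it is exact.
* The solubility module fits a descriptive logistic, not Cohn salting-out
  thermodynamics, and reports solubility relative to each sample's own
  control.
* With only two pH points a regression is exact and its prediction SE is
  zero; degrees of freedom are reported so downstream users can see how much
  the SEs are worth.
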