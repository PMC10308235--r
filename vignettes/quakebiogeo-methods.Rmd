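---
title: "Methods: isotope systematics, contamination correction and bioenergetics of post-earthquake subseafloor sediments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: isotope systematics, contamination correction and bioenergetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(quakebiogeo)
```

## The scientific problem

Large subduction-zone earthquakes rupture rock along faults in the
accretionary wedge. The freshly exposed mineral surfaces react with pore
water at low temperature and release molecular hydrogen, a substrate that
hydrogen-consuming microorganisms — homoacetogens and hydrogenotrophic
methanogens — compete for. A drilling core through such a wedge therefore
carries several intertwined quantitative signals:

* sharp H2 concentration peaks near faults, superimposed on a background
  below the quantification limit;
* hydrogen-isotope ratios of that H2, which fingerprint its generation
  temperature;
* methane carbon and hydrogen isotopes recording its biological origin,
  age, and partial microbial consumption;
* multiple sulfur isotopes of sulfide minerals recording microbial sulfate
  reduction and admixture of mantle-derived ("juvenile") sulfur carried by
  coseismic hydrothermal fluids;
* pore-water ion profiles overprinted by seawater that leaked into the
  fragmented core during recovery; and
* the thermodynamic landscape that decides which hydrogen-consuming
  metabolism can run at a given H2 level.

This package implements each of those calculations as a tested, reusable
unit, together with seeded generators that produce synthetic tables with
the same structure, so the full pipeline can be exercised and validated
offline.

## Isotope algebra and equilibrium calibrations

Isotope compositions are handled in conventional delta notation (permil
deviation of an isotope ratio from the reference standard: VSMOW for H and
O, VPDB for C, VCDT for S). The fractionation factor between two coexisting
species is

$$\alpha_{A\text{-}B} = \frac{1000 + \delta_A}{1000 + \delta_B},$$

computed exactly (`alpha_from_deltas()`), with the inverse
`delta_via_alpha()`. Deltas at or below −1000 permil are rejected
everywhere, since they would imply a non-positive isotope ratio. The chain
rule $\alpha_{A\text{-}C} = \alpha_{A\text{-}B}\,\alpha_{B\text{-}C}$ holds
to machine precision and is enforced by test.

Two equilibrium calibrations ship as plain-text constant tables
(`inst/extdata/equilibrium_calibrations.tsv`), in the form
$\ln\alpha = a + b\,(1000/T) + c\,(1000/T)^2$ with $T$ in kelvin:

* **H2–H2O(l)** (hydrogen): a refit through the Horibe & Craig (1995)
  equilibrium values 0.23, 0.26, 0.31 at 4, 25, 55 °C. Three anchors
  determine the three coefficients exactly, so the curve reproduces the
  published values to numerical precision and evaluates to
  `r round(equilibrium_alpha("H2-H2O", 0)$alpha, 3)` at 0 °C — never below
  0.2, which is the key discriminant (see below).
* **CH4–H2O(l)** (hydrogen): the Horibe & Craig CH4–H2 expression
  ($\alpha = 0.8994 + 183540/T^2$) chained with the H2–H2O curve and refit
  in the same form. This is the "thermometer" used to read an apparent
  equilibration temperature off aged biogenic methane
  (`temperature_from_alpha()`).

Both curves are strictly increasing over their stated 0–100 °C validity
range; evaluation outside it raises an error rather than extrapolating.
The quadratic form is not trustworthy far above the anchors (at 300 °C it
would give ≈0.9 where hydrothermal observations show 0.6–0.7), which is
exactly why the range is capped and why `classify_h2_origin()` uses only
the high-temperature cutoff above 100 °C.

### Classifying the origin of H2

`classify_h2_origin()` compares an apparent α(H2–H2O) against the
equilibrium curve at the ambient temperature:

* within ±0.02 (configurable) of equilibrium → *equilibrated* (e.g.
  microbially cycled H2);
* below the curve by more than the band → *low-temperature water–rock*
  generation (strong kinetic D depletion, α ≈ 0.13–0.23 in Fe–H2O
  experiments at 4–55 °C);
* at or above 0.6 (configurable) → *high-temperature kinetic* signature
  (hydrothermal fluids show 0.6–0.7 at 300–400 °C, frictional melting
  about 0.8).

The decisive property is that the equilibrium value never falls below 0.2
even at 0 °C: D-rich H2 from hot processes cannot be re-labelled as
cold-generated merely by later isotopic re-equilibration, so an observed
α ≈ 0.15 can only mean low-temperature generation.

## Keeling-plot endmember estimation

Headspace gas sampling unavoidably admixes air H2 (0.5 ppmv with deltaD
about +150 permil). For a two-endmember mixture the observed delta is
exactly linear in the reciprocal total mixing ratio, so ordinary least
squares of deltaD on 1/c (`keeling_fit()`) recovers the source composition
as the intercept; the slope equals
$c_{bg}(\delta_{bg} - \delta_{src})$. OLS is the conventional Keeling
estimator and is exact on the mixing model; a geometric-mean (model II)
variant is provided for data with comparable errors in both coordinates.
The intercept's standard error comes from the usual linear-model theory;
with 20 samples the 3-standard-error interval covers the truth in 99.2%
of replicates (exact t with 18 degrees of freedom), which the test suite
verifies empirically with 10000 simulated fits.

## Fe–H2O batch experiments

In the anaerobic-corrosion experiments the water deltaD is manipulated up
to about +3000 permil with D2O, so the paired points
$(1000+\delta D_{H2O},\ 1000+\delta D_{H2})$ span a wide abscissa range and
fall on a line through the origin with slope α. `fit_alpha_origin()`
estimates that slope by regression through the origin, which weights all
batches equally, is exact on noise-free data, and is exactly invariant
under a joint rescaling of both shifted coordinates. With 8 spike levels
and 10 permil measurement noise the 25 °C factor (0.19) is recovered to
two decimals with a standard error of about 0.002.

## Multiple sulfur isotopes

The deviation from mass-dependent behaviour is

$$\Delta^{33}S = \delta^{33}S - \left[\left(1 +
\frac{\delta^{34}S}{1000}\right)^{0.515} - 1\right]\times 1000,$$

evaluated exactly (no linearisation). The reference exponent is fixed at
0.515; the mass-law exponent λ33 expressed by an actual process is a free
observable (microbial sulfate reduction typically shows ≈0.514) and is
computed from sulfide/sulfate pairs as a ratio of log ratio-changes.
`msr_forward()` is the exact forward model: the 34S ratio is scaled by
$(1-\varepsilon^{34}/1000)$ and the 33S ratio by that factor raised to
λ33, so `epsilon34()` and `lambda33()` recover the parameters to machine
precision.

Mixing of two sulfur reservoirs (`sulfur_mixing_curve()`) is performed by
mass balance on molar isotopologue abundances (32S-weighted), not by
averaging deltas. The absolute VCDT ratios used to convert deltas to
abundances ship in the constant table; results are insensitive to that
absolute scale (the ratios cancel), which is asserted by test against a
brute-force oracle. Two consequences matter scientifically: mixtures
between isotopically distant endmembers bow away from the straight line in
$(\delta^{34}S, \Delta^{33}S)$ space, and even a mixture of two perfectly
mass-dependent endmembers acquires a small *negative* Δ33S (about
−0.014 permil for a 21 permil separation) because the reference line is
concave. Tests assert the sign and magnitude of both effects.

## Pore-water contamination correction

Fragmented cores take up seawater during recovery. In the prism units the
indigenous pore water is sulfate-free (sulfate reduction exhausted it over
geological time), so measured sulfate is a conservative tracer of admixed
seawater: $f = \mathrm{SO_4^{obs}} / \mathrm{SO_4^{sw}}$, up to ~40% in
the worked profiles. Every ion is then extrapolated along the line through
the seawater point to zero sulfate, and the water isotopes unmixed with
the same fraction — two operations that are algebraically identical
(asserted by test). Design choices:

* The seawater reference (Cl 560 mM, SO4 28 mM, δ34S +21.3, Δ33S +0.050,
  δD = δ18O = 0) ships with per-entry provenance and is overridable.
* The correction is gated by a per-unit applicability mask (default U1–U4):
  in the underthrust units indigenous sulfate is real and the zero-sulfate
  assumption fails, which the corrected profiles themselves diagnose —
  negative extrapolated concentrations are reported with a flag, never
  clamped.
* The correction is idempotent (corrected tables have zero sulfate, hence
  f = 0 on a second pass), and corrected values always lie on the sample's
  side of seawater.

## Catabolic energetics

Three aqueous reactions are considered:

1. hydrogenotrophic methanogenesis: 4 H2 + CO2 = CH4 + 2 H2O
2. homoacetogenesis: 4 H2 + 2 CO2 = CH3COOH + 2 H2O
3. acetate exchange: CH4 + CO2 = CH3COOH (reverse = acetoclastic
   methanogenesis)

Each carries $\Delta G_r = \Delta G^\circ_r + RT\ln Q_r$ with $Q_r$ the
stoichiometric activity product. The standard energies ship with
provenance (Amend & Shock 2001 standard-state formation energies at
25 °C: −193.72, −169.78, +23.94 kJ/mol) and the trio is Hess-closed
exactly at load, so the identity
$\Delta G_r(3) = \Delta G_r(2) - \Delta G_r(1)$ holds to machine precision
for any activity set. The 1→500 bar pressure term on these ΔG° (−3 to
−4 kJ/mol, from partial molar volumes) is smaller than the spread between
published formation-energy sets, so it is deliberately not applied and is
absorbed into the stated order-of-magnitude precision of the thresholds.
The dissociation constants used in speciation *are* pressure-corrected
(pK1 6.13, pK2 10.10, pKa(acetic) 4.66 at 25 °C/500 bar), because
dissociation volume changes are well measured and the correction is
material there.

Activities: charged species use the B-dot extended Debye–Hückel model
($\log_{10}\gamma = -Az^2\sqrt I/(1+Ba\sqrt I) + \dot B I$, Helgeson
constants at 25 °C, Kielland ion sizes); neutral dissolved species (H2,
CO2, CH4, CH3COOH) default to unit activity coefficients; water activity
is 1; pH is on the activity scale. Default conditions follow the deep
prism: pH 7.9, total CO2 50 mM, CH4 5 mM, ionic strength 0.66 mol/kg
(seawater-like, consistent with 560 mM chloride), molality taken as
molarity.

Under these conditions 1 mM total acetate corresponds to a neutral
CH3COOH activity of `r signif(speciate_weak_acid(1, pH = 7.9)$a_HA, 3)`
(printed reference value 2.8e-7; the remaining factor of ~1.4 traces to
the acid-dissociation constant and acetate activity-coefficient
provenance, inside the stated factor-of-2 band), exactly linear in the
total at fixed pH. The zero-ΔGr hydrogen activities found by bisection
(`threshold_activity()`, tolerance 0.01 kJ/mol on a [1e-12, 1] bracket)
are ~1e-7 for homoacetogenesis (at 1 mM acetate) and ~1e-8 for
methanogenesis — one order of magnitude apart, so as H2 is drawn down
after an earthquake pulse, homoacetogens lose thermodynamic viability
first. A caveat the package states honestly: with these standard-state
constants, methanogenesis at exactly a[H2] = 1e-8 is marginally exergonic
(ΔGr ≈ −6 kJ/mol), i.e. the "~1e-8" threshold sits just below 1e-8 rather
than just above; only homoacetogenesis is strictly endergonic there. The
acetoclastic profile is flat in a[H2] (no H2 in the reaction) and
exergonic at 1 mM acetate across the whole sweep.

## The synthetic-data module

Generators mirror the study conditions and expose them as documented
defaults, not tuning knobs:

* `gen_gas_profile()`: 52 depths over 176–837 mbsf; lognormal H2 background
  below the 3 µM quantification limit with Gaussian peaks of 209 µM at
  695 mbsf and 26 µM at 818.5 mbsf (the peak *locations and amplitudes*
  are observed quantities; the Gaussian *shape* and 2 m width are
  generator choices for testability); CH4 uniform in 1–20 mM above the
  decollement and below 5 mM under it; δ13C(CH4) drifting −64 → −84 permil
  with depth at a fixed CH4–CO2 fractionation of 0.94; headspace deltaD of
  H2 from exact two-endmember mixing with air (0.5 ppmv, +150 permil) over
  a −850 permil source.
* `gen_porewater_table()`: 12 rows, convex combinations of a sulfate-free
  indigenous endmember with seawater at f ~ U(0, 0.4); noise-free by
  default so the correction recovers the endmember exactly; optional
  relative noise for realism.
* `gen_keeling_dataset()`: 20 samples, log-uniform added H2 over
  0.5–200 ppmv, Gaussian deltaD noise of 15 permil.
* `gen_fe_h2o_batches()`: 8 water-spike levels from 0 to +3000 permil per
  temperature, true α = 0.13/0.19/0.23 at 4/25/55 °C, 10 permil noise.
* `gen_sulfur_records()`: sulfide from seawater sulfate by the forward
  reduction model (ε34 ~ U(10, 68), λ33 = 0.514) mixed with juvenile
  (0, 0) sulfur by abundance mass balance.
* `gen_dilution_series()`: Poisson presence (≥1 organism in the step's
  inoculum volume) under the same dilution convention as the estimator.

One integer seed drives a named substream per generator (a string-hashed
offset), so adding a generator never perturbs existing streams, identical
configurations give byte-identical tables, and the caller's RNG state is
left untouched. What the generators do *not* emulate: measurement drift,
depth-correlated noise, core-recovery degassing, heterogeneous sulfur
aggregates, or real community ecology — passing tests demonstrate the
correctness of the estimators on their stated models, not the field
accuracy of the original measurements.

## Numerical choices and problem sizes

* All permil arithmetic in double precision; rounding only at presentation
  (2 decimals for α, 1 for permil values).
* Root finding by bisection (monotone quotients): 0.01 kJ/mol for
  free-energy thresholds, 1e-9 °C-scale tolerance for the calibration
  inverse.
* Degenerate designs (equal mixing ratios, single water-spike level,
  coincident δ34S) raise errors rather than returning NaN.
* Monte-Carlo test sizes: 10000 replicate Keeling fits for the 3-SE
  coverage check (the exact t coverage is 99.2%, so the replicate count is
  chosen to make binomial noise negligible against the 99% bar) and
  500 replicate dilution series for the within-one-step-factor check;
  the full suite runs in well under a minute.

## Known limitations

* No Rayleigh distillation or clumped-isotope systematics.
* No transport/diffusion modelling of the profiles and no Pitzer-level
  speciation or mineral saturation; the B-dot model with unit neutral
  coefficients is the intended fidelity.
* ΔG° values are fixed at the 25 °C standard state; no temperature or
  pressure extrapolation is offered, and threshold activities are
  order-of-magnitude statements by construction.
* The endpoint-dilution estimator quantises to powers of the step factor;
  printed cultivable densities can only be bracketed, not reproduced,
  because the original prep accounting is not fully specified.
* The anomalous sulfide sample with jointly positive δ34S and Δ33S seen in
  such settings has no model here; the mixing curve covers only the
  juvenile/biogenic plane.
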