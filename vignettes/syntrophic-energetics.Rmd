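---
title: "Energetics of syntrophic acid oxidation: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Energetics of syntrophic acid oxidation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(syntherm)
```

## The problem

In anaerobic digestion at high ammonia, propionate and acetate are degraded
by syntrophic partnerships: a propionate oxidizer converts propionate to
acetate, CO2 and 3 H2; an acetate oxidizer converts acetate to 2 CO2 and
4 H2; and a hydrogenotrophic methanogen consumes the H2 (4 H2 + CO2 ->
CH4 + 2 H2O). The two oxidations are endergonic at standard conditions
(+73.7 and +54.9 kJ/mol here) and only proceed because the methanogen holds
the hydrogen partial pressure at a few pascal. Whether degradation is
thermodynamically possible at a measured culture state is therefore a
quantitative question about the reaction free energy

$$\Delta G = \Delta G^\circ_T + R T \ln Q,$$

and about the *critical concentration* at which $\Delta G = 0$.

`syntherm` implements that calculation chain from raw batch-culture
measurements, plus the surrounding plumbing: headspace partial pressures,
venting-corrected cumulative methane, free-ammonia speciation, local
degradation rates and their correlation with hydrogen partial pressure, a
motif-based hydrogenase classifier for annotated proteomes, and synthetic
generators that stand in for culture data in tests.

## The free-energy chain

**Standard energies.** `delta_g_standard()` sums formation energies over the
signed stoichiometry. The bundled table (`formation_energies.tsv`) carries
$\Delta G_f$ and $\Delta H_f$ at 298.15 K for the seven species of the
three default reactions, each row annotated with its literature source
(Shock–Helgeson-style values for the two acids, Hanselmann-style values for
the gases and water). With this table the three reactions evaluate to
+54.96, +73.76 and −130.75 kJ/mol.

A deliberate convention: the standard state puts **every** species at unit
activity, including H⁺. The printed reference values for these reactions
are only mutually consistent under that convention — the proton-free
methanogenesis value matches either way, but the acetate-oxidation value
matches the unit-H⁺ sum, not a pH-7-referenced one. pH therefore enters the
calculation exclusively through the reaction quotient. The biochemists'
pH-7 view is available as `delta_g_standard_at_ph()` (acetate oxidation:
+94.9 kJ/mol at pH 7).

**Temperature.** `gibbs_helmholtz()` translates $\Delta G^\circ$ from
298.15 K to the cultivation temperature (default 310.15 K) by

$$\Delta G^\circ(T_2) = \Delta G^\circ(T_1)\,\frac{T_2}{T_1} +
  \Delta H^\circ(T_1)\left(1 - \frac{T_2}{T_1}\right),$$

the standard integrated Gibbs–Helmholtz relation under
temperature-independent enthalpy. The 12 K translation changes the
propionate-oxidation value from +73.8 to +68.6 kJ/mol.

**Reaction quotient.** Activity conventions in `reaction_quotient()`:
solutes are molar concentrations against 1 mol/L (ideal solution — no
activity-coefficient or ionic-strength model, and VFA are used as total
concentrations without acid–base speciation); gases are partial pressures
against 1 bar = 10⁵ Pa (the modern convention; `standard_pressure_Pa`
switches to atm, a 1.3% difference); water is 1; H⁺ is $10^{-\mathrm{pH}}$.
CO2 is treated as a gas-phase species via its partial pressure, matching
how the measurements are made, with no carbonate speciation.

**Degenerate states.** A timepoint where a *product* has zero measured
activity gives $Q = 0$; `compute_delta_g()` returns the sentinel
`delta_g = -Inf` flagged `unbounded_exergonic` rather than erroring,
because early samples legitimately pre-date measurable product. A zero
*reactant* leaves $\ln Q$ divergent and the free energy undefined; the
scalar API errors, and `gibbs_trace()` records `NA` for such rows by
default so one depleted timepoint does not kill a whole-series trace.

**Critical concentration.** `critical_concentration()` inverts
$\Delta G = 0$ for one aqueous species in closed form,
$c = \exp[(-\Delta G^\circ_T/RT - \ln Q_\mathrm{rest})/\nu]$. Only aqueous
species are inverted (gas-phase inversions are out of scope). The
round-trip through `compute_delta_g()` is exact to well below
$10^{-6}$ kJ/mol, and the test suite cross-checks the closed form against
an explicit bisection root-finder on randomized states. At the
plateau-phase reference state (propionate 58 mM, pH₂ 5.3 Pa, pCO₂
26,700 Pa, 310.15 K) the critical acetate concentration evaluates to:

```{r critical}
species <- load_formation_energies()
rxns <- load_reactions()
st <- chemical_state(solutes = c(propionate = 0.058),
                     gases = c(H2 = 5.3, CO2 = 26700),
                     pH = 7, temperature = 310.15)
critical_concentration(rxns$propionate_oxidation, st, species, "acetate")
```

about 4.1 M — orders of magnitude above anything a culture reaches, i.e.
acetate accumulation alone cannot render propionate oxidation endergonic.
The exact figure is sensitive to the enthalpy constants at the ~1 kJ/mol
level, which propagates to a few percent here; the bundled values are
literature compilations, recorded per-row in the constants file so they
can be swapped for a project's own table.

## Culture-state plumbing

Partial pressures are mole fraction times *absolute* total pressure.
Because venting thresholds are naturally reported as overpressure, pressure
columns default to gauge readings with a fixed 1013.25 mbar atmosphere
(per-row `gauge` flag; the choice is a documented default, not a claim
about any particular instrument). Water-vapor pressure is not subtracted.

Cumulative methane uses ideal-gas headspace accounting with constant
headspace volume (weekly ~4 mL liquid sampling against hundreds of mL of
headspace is ignored). A vented record stores its pre-vent reading plus the
post-vent pressure; the moles removed, computed at unchanged composition,
are credited to all later timepoints.

Free ammonia follows the ammonium dissociation constant parameterized as
$\mathrm{p}K_a(T) = 0.09018 + 2729.92/T$, so the unionized fraction is
$(1 + 10^{\mathrm{p}K_a - \mathrm{pH}})^{-1}$ — about 2% at pH 7.2 and
310 K, i.e. ~6 mM NH₃ from 0.3 M TAN. The two constants are arguments, not
magic numbers.

## Rates, correlation and phase labels

The degradation-rate statistic is the ordinary least-squares slope of
concentration against day in a window centred index-wise on the focal day.
The window width is genuinely unspecified in the field's usage; the default
is 2 points per side (a 5-point window), chosen because weekly sampling
makes wider windows smear phase boundaries, and it is a parameter
everywhere. `rate_pressure_correlation()` reports Pearson r with the
two-sided t-transform p-value, negating consumption slopes first so a
negative r reads "high hydrogen pressure, slow degradation".

`label_phases()` is operational plumbing: runs of sub-threshold |rate|
before any degradation are the lag, between degradation runs they are
plateaus, and a trailing sub-threshold run after the last degradation
(substrate depletion) is folded into that degradation label so the
partition keeps the ordering lag < degradation-1 < plateau <
degradation-2. The 0.5 mM/day threshold and 2-point minimum run are
labeling conveniences only and feed no thermodynamic computation.

## Hydrogenase classification

`scan_motifs()` applies regular-expression rules for the conserved
metal-binding motifs — the bundled defaults are the canonical FeFe
H-cluster L1/L2/L3 and the NiFe N-/C-terminal CxxC nickel-binding motifs
from the standard hydrogenase literature, and the rule file is
user-replaceable when a project has its own curated patterns. Genes
matching both metal classes are reported `ambiguous` with both hit sets,
never resolved by precedence. Binding motifs alone cannot resolve groups
below the metal class, so sub-class labels (NiFe 1a/3b/4e, FeFe C3) come
from an optional external table via `refine_groups()` — e.g. an HydDB
export; querying the web service is out of scope.

The one group the package does infer itself is bifurcating FeFe A3:
`assign_a3_by_proximity()` upgrades FeFe type-A calls that lie within 5
coding sequences (inclusive ordinal distance, same contig, strand-agnostic)
of a NuoF-annotated gene, recording the nearest NuoF and the distance. The
inclusive reading of "within 5" and the strand-agnostic, annotation-based
NuoF identification are documented defaults.

## The synthetic generators

`simulate_batch()` reproduces the *shape* and *stoichiometry* of observed
propionate batches with piecewise-linear kinetics — no Monod/ADM1 growth
model is fitted, deliberately, because the package's analyses only need
realistic trajectories, not mechanistic ones. Defaults emulate a 100 mM
propionate culture: 30-day lag; phase-1 degradation at 1.0 mM/day down to
a 58 mM plateau (day ~72); a 62-day plateau ending day 134; phase-2
degradation at 0.8 mM/day; acetate accumulating 1:1 with phase-1
consumption and oxidized at 0.67 mM/day once the acetate oxidizer is
active; hydrogen at a 3 Pa baseline rising to 5.3 Pa during
acetate-oxidizer activity; CO₂ fraction pinned at 0.267 by the bicarbonate
buffer; 0.5 L liquid / 0.5 L headspace at 310.15 K, sampled weekly for
210 days; venting to 100 mbar gauge beyond 1000 mbar. Methane follows the
electron stoichiometry (¾ CH₄ per propionate, 1 CH₄ per acetate oxidized),
so total carbon (VFA + CH₄ + net CO₂) is conserved exactly in the
noiseless limit — a property the tests assert to 1e-9. Gaussian noise
(1 mM VFA, 0.005 mole fraction, 5 mbar, 0.05 pH) is added last; a seed
fixes the entire table, and the generator restores the caller's RNG state.

These defaults were chosen once so that the propionate-oxidation free
energy over mid-degradation timepoints falls in the −25 to −10 kJ/mol
regime reported for such cultures; that regime membership is asserted in
the tests as a calibration check, not as a reproduction of any measured
time course. What the generator does *not* emulate: microbial community
composition, growth-limited (saturating) kinetics, H₂ dynamics beyond the
baseline/pulse shape, temperature excursions, or measurement dropout — so
passing tests demonstrate correctness of the calculation chain on
plausibly-shaped data, not agreement with any specific real culture.

`simulate_proteome()` plants motif exemplars in random background proteins
(300–600 aa, rejection-sampled so no background gene matches any rule) and
places a NuoF partner within the requested distance of every planted A3
(default distances cycle 1–5, so the inclusive boundary is always
exercised) and a decoy NuoF at distance 6 next to plain FeFe A plants as a
negative control. Planted FeFe genes are kept ≥ 12 CDS apart so no NuoF
can fall inside the proximity rule of a foreign plant — the emitted truth
table is therefore exact by construction.

## Numerical choices

* $R = 8.314462618 \times 10^{-3}$ kJ/(mol K); reference 298.15 K;
  cultivation default 310.15 K.
* Quotients are accumulated in log space; the critical solve is closed-form,
  no iteration.
* Problem sizes in the routine suite: 1000 randomized states for the
  algebraic property checks, 250 bisection cross-checks, 100 generator
  seeds for the stoichiometry calibration, 10 proteome seeds with 22
  planted calls each, 1000 replicates for the rate-estimator calibration.
* Ties and degenerate inputs: constant concentration windows report slope 0
  with `r2 = NA`; an all-slow trajectory is labeled a single lag; an empty
  series yields empty outputs, not errors.

## Known limitations

Ideal-solution activities overstate effective concentrations at the ionic
strengths of high-ammonia digesters; the package provides no Davies/Pitzer
correction, so absolute ΔG values carry a systematic uncertainty of a few
kJ/mol that does not affect comparisons across time within one culture.
Bicarbonate–CO₂ speciation is not modeled (pCO₂ is measured, pH is an
input). Motif-based hydrogenase detection cannot see divergent enzymes an
HMM would find, and sub-class assignment depends on external annotation.
The phase labeller is heuristic and intended for bookkeeping, not
inference.
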