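---
title: "A physiological oral-absorption model for IR and ER methylphenidate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A physiological oral-absorption model for IR and ER methylphenidate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mphpbpk)
```

## The problem

Oral methylphenidate (MPH) is marketed both as immediate-release (IR)
tablets and as a family of extended-release (ER) bead/pellet products
(multilayer-release beads, SODAS, Diffucaps, enteric-coated pellets) that
combine an IR fraction with a delayed, prolonged release of the remainder.
The products differ in their IR:ER split and release kinetics, and
consequently in the shape of the biphasic plasma concentration profile they
produce. `mphpbpk` implements a mechanistic description of what happens to
an oral dose between the mouth and the systemic circulation, resolved by
gut segment, so that the contribution of each region — and each
formulation design choice — can be quantified.

## Model structure

The gut is nine serial compartments: stomach, duodenum, two jejunal and
three ileal segments, caecum and ascending colon. Each intestinal segment
carries a luminal pH, volume, transit time, bile salt concentration, an
effective absorptive surface area derived from cylinder geometry with
anatomical enlargement factors, a fraction of cardiac output, and a wall
(enterocyte) mass. Transit between compartments is first-order with rate
`1/transit_time`; outflow from the ascending colon is fecal excretion. The
stomach only dissolves and empties — it has no absorptive wall.

Within each segment, four drug states are tracked per enantiomer: solid IR
particles, unreleased ER depot (intact beads), dissolved drug, and drug in
the enterocytes. The processes connecting them are:

* **Dissolution** (IR solids): the Noyes–Whitney diffusion-layer law for
  spherical particles,
  `dA/dt = 3 D / (rho r_p h V) * Csolid * (Solif − Cdiss) * 60 * 100`,
  with the diffusion coefficient in cm²/min, a fixed 5 µm particle radius,
  a 30 µm diffusion layer, and the trailing unit factor reproduced as
  printed. The driving force reverses under supersaturation.
* **Solubility**: the saturation solubility `Solif` is the
  Henderson–Hasselbalch aqueous term for a monoprotic base
  (`S0 (1 + 10^(pKa − pH))`, intrinsic solubility 9,109 mg/L, pKa 8.77)
  plus a bile-micelle term proportional to the local bile concentration.
  MPH is so soluble at gastric and intestinal pH that dissolution is never
  rate-limiting; the formulation, not the solubility, controls input.
* **ER release**: the Weibull law `W(t) = 1 − exp(−(t − Tlag)^b / A)` with
  a single 4 h lag for all products. See *The in-transit release rule*
  below for how this global law is applied to spatially distributed beads.
* **Absorption**: passive diffusion into enterocytes,
  `3600 HPeff ESA NI (Cdiss − Cmem/1000)`, using the unionized fraction
  `NI` at the segment pH and a calibrated effective permeability
  `HPeff = 0.963e-4` cm/s. The flux is bidirectional: drug can move from a
  drug-rich enterocyte back into an empty lumen.
* **Enterocyte fate**: drug in the gut wall either leaves with segment
  blood flow into the portal vein (flow-limited, venous concentration
  `Cmem / P_gut` with `P_gut = 5.66`) or is lost by a first-order
  non-specific process (`K5 = K5C BW^0.75`), which is ~48-fold faster for
  l- than d-MPH and is what suppresses circulating l-MPH after oral
  dosing.
* **Liver**: the pooled portal stream plus a hepatic arterial fraction
  perfuse the liver, where the two enantiomers compete for hydrolysis at a
  shared carboxylesterase (Michaelis–Menten with mutual competitive
  inhibition, driven by hepatic free concentration `C_liver / P_liver`)
  alongside a first-order oxidation clearance.
* **Systemic circulation**: a minimal flow-limited layer — plasma (the
  sampling compartment), liver, a richly and a slowly perfused lump — with
  venous return to plasma. This is deliberately the smallest structure
  able to carry first-pass metabolism and produce a plasma curve; the
  GI-side ledgers (release, absorption, fecal fate) are insensitive to its
  details, and the defaults (`P_liver = P_richly = 5.66`,
  `P_slowly = 2.0`, plasma volume `0.0424 BW`, cardiac output
  `5.2 L/min × (BW/70)^0.75`) are all user-configurable.

Units follow the mixed convention of the rate laws: amounts in µg, luminal
concentrations in µg/mL, tissue and plasma concentrations in µg/L (hence
the `/1000` in the absorption flux), times in hours. Plasma output in
ng/mL equals µg/L numerically. Marketed products are racemic, so the dose
is split 50:50 d:l by default.

## The in-transit release rule

The Weibull law is written as a single global function of time since
dosing, but the ER beads it describes are distributed over the gut. The
package applies the Weibull *density*
`w(t) = (b/A)(t − Tlag)^(b−1) exp(−(t − Tlag)^b / A)` as a first-order
release coefficient to the unreleased depot in each intestinal compartment
(beads do not release in the stomach). Because the density integrates to
exactly one, a bead exposed to the whole release window discharges
`1 − e^{−1} ≈ 63.2%` of its load; beads that exit the ascending colon
early escape with more, beads that enter the intestine late (fed stomach)
release along the way. Two consequences are worth stating plainly:

* The total released fraction of the ER component is ~61–62% for *every*
  product, nearly independent of `(A, b)` — which is exactly the pattern
  of the segment-resolved reference tables the model reproduces, with the
  bulk of release in the caecum and ascending colon for fasted products
  and shifted proximally under fed dosing.
* The plausible alternative — using the Weibull *hazard*
  `(b/A)(t − Tlag)^(b−1)`, which reproduces `W(t)` exactly for a static
  depot — releases essentially 100% of the depot in transit (the hazard
  grows without bound for `b > 1`), and cannot produce the observed
  unreleased-solid fecal excretion of ~19–27% of dose. Both functions are
  exported (`weibull_hazard()`, `weibull_release_rate()`); the simulator
  uses the density rule.

A corollary: if the release window is spent before the beads leave the
stomach (tiny `A` with `Tlag = 0`), the depot is stranded and almost
nothing is released. The hazard rule would instead release everything
instantly on intestinal entry. The package's tests assert the
density-rule behaviour.

## Numerical choices

* Stiff integration (`deSolve::lsoda`) with `rtol = 1e-8`,
  `atol = 1e-9` µg and a 0.05 h output grid by default. The integration is
  split at `Tlag` so the solver never steps across the release-onset
  discontinuity.
* The literal dissolution rate constant at gastric pH is astronomically
  large (the pH term exceeds `10^7`); the rate is therefore recast as a
  first-order coefficient on the solid pool and capped at `1e3`/h
  (dissolution half-life 2.5 s, versus a 15 min gastric half-emptying
  time). This preserves the instant-dissolution limit to within ~0.4% of
  any segment ledger while keeping the system integrable.
* Physical pools are clipped at zero after integration (with an error if
  the undershoot exceeds `1e-4` of the dose); the per-segment *cumulative*
  absorption ledgers are left untouched because a transient net-negative
  value is real physics (exsorption into an initially empty distal lumen),
  not a solver artifact.
* Mass balance is checked at every output time; the ledger closes to
  better than 0.1% (in practice to machine precision) for all built-in
  products in both prandial states.

## Parameters that matter

The local sensitivity layer (`nsc_curve()`, `sensitivity_screen()`)
implements the normalized sensitivity coefficient
`NSC(t) = (ΔO/O) / (ΔP/P)` under a +1% forward perturbation, with a
central-difference mode for verification. Coefficients are computed on the
plasma total-MPH curve; times where the baseline falls below 0.1 ng/mL —
the quantification limit typical of the underlying assays, and the BLQ
threshold used by the synthetic-study generator — are masked. This floor
is deliberate: on the sub-quantifiable tail every parameter that feeds the
colonic absorption trickle acquires a large *relative* coefficient, and
the qualitative structure of the analysis (proximal parameters matter for
IR; caecum/colon parameters additionally matter for ER) only emerges once
unmeasurable output is excluded.

With the defaults, small-intestinal pH values are sensitive-to-high-impact
for every product (ionization controls the absorptive driving force);
gastric pH and emptying matter for the IR fraction; the Weibull lag acts
inversely on the ER absorption phase; and caecum/colon geometry (surface
area, lumen volume) is sensitive for ER products but not for IR, because
only the ER depot delivers appreciable drug that far down the gut.

## Population variability

`run_population()` follows a conventional Monte Carlo protocol: normal
distributions for blood flows and tissue volumes; lognormal for cardiac
output (CV 9%), partition coefficients (CV 20%), chemical/biochemical
constants (CV 30%) and GI anatomy/physiology (CV 10%); every draw
truncated at ±1.96 SD (on the log scale for lognormal parameters, a
convention chosen because the lognormal's natural scale is the log);
fractional renormalization of flows and of tissue/gut-wall masses after
sampling so each virtual subject still balances cardiac output and body
mass; body weight 70 ± 12 kg unless set per study. The lognormal is
parameterized to preserve the arithmetic mean
(`sigma² = ln(1 + CV²)`, `mu = ln(mean) − sigma²/2`). Summaries are the
pointwise mean and 5th/95th percentiles of the plasma curve and
mean/SD/median of Cmax, Tmax and AUC. The distribution table is plain data
(`default_distribution_set()`) and can be replaced wholesale.

## The synthetic-study generator

`generate_study()` emulates the *statistical shape* of the comparison data
this class of model is evaluated against: mean ± SD total-MPH
concentration tables on 12–24 sampling times over 10–24 h, built by
simulating virtual subjects (population draws), adding mean-preserving
multiplicative lognormal residual error (default CV 0.25, similar in
magnitude to reported SD bars), and censoring values below 0.1 ng/mL. The
generating model is recorded as ground truth, which makes estimation
workflows testable: `recovery_experiment()` refits chosen parameters by
least squares on log concentrations and reports estimate, truth and
relative error, flagging parameters whose perturbation leaves the curve
unchanged as non-identifiable. What the generator does *not* emulate:
real between-study design differences, correlated parameter variation,
assay-specific error structure, or the actual digitized literature
curves — so passing recovery tests demonstrates internal consistency of
the estimation machinery, not clinical validity.

## Problem sizes used in the shipped tests

The package's test suite runs each built-in product once at reference
tolerance, exercises the population layer at 10⁴ sampling draws (no
integration) and 3–16 simulated subjects, uses 1–200 subjects in the
synthetic-study checks with a single shared base simulation where subjects
are identical, and screens ~10-parameter sensitivity sets at
`rtol = 1e-6`. These sizes were chosen so the whole suite completes in a
few minutes while leaving every statistical check at least ~2 significant
digits of resolution.

## Known limitations

* The systemic layer is minimal; terminal-phase kinetics (and therefore
  late-time sensitivity structure) depend on its lumped defaults more than
  any GI-side output does.
* Ritalinic-acid metabolite kinetics, renal clearance, enterohepatic
  recirculation, protein binding, active transport and monolithic
  (osmotic-pump) dosage forms are out of scope.
* The hepatic oxidation share realized by the default constants is
  reported as a diagnostic (`oxidation_fraction()`, ~0.30 for an IR dose)
  rather than asserted; the blended d/l share depends on systemic details
  that the minimal disposition layer does not pin down.
* Fed-state lumen volumes equal fasted ones (no meal-volume adjustment);
  only pH, gastric emptying and bile change with the prandial switch.
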