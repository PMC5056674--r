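# mphpbpk

A physiologically based oral-absorption model for immediate-release (IR)
and extended-release (ER) methylphenidate (MPH) in adults, written as a
tidyverse-style R package.

Oral MPH is marketed as IR tablets and as bead/pellet ER products
(multilayer-release, SODAS, Diffucaps, enteric-coated) that mix an IR
fraction with a delayed, prolonged release of the rest. The package
mechanistically tracks a dose through nine serial gut compartments
(stomach, duodenum, jejunum ×2, ileum ×3, caecum, ascending colon) and a
minimal flow-limited circulation, resolving *where* in the gut each
formulation releases and absorbs its drug and what fraction never makes it
in at all.

The core processes, per segment *i* and enantiomer:

* first-order transit, rate `1/τᵢ`; colonic outflow is fecal excretion;
* Noyes–Whitney dissolution
  `dA/dt = 3D/(ρ r_p h Vᵢ) · Csolidᵢ (Solifᵢ − Cdissᵢ) · 60·100`, against a
  Henderson–Hasselbalch + bile-salt solubility
  `Solifᵢ = S₀(1 + 10^{pKa−pHᵢ}) + SR·SCaq·MW·Bileᵢ`;
* Weibull ER release `W(t) = 1 − exp(−(t−T_lag)^b/A)`, applied in transit
  through its density as a first-order release coefficient (beads do not
  release in the stomach);
* passive absorption `3600·HPeff·ESAᵢ·NIᵢ·(Cdissᵢ − Cmemᵢ/1000)` with
  `NIᵢ = 1/(1+10^{pKa−pHᵢ})`;
* enterocyte non-specific loss (`K5·BW^0.75`, strongly l-selective) versus
  flow-limited portal uptake;
* competitive Michaelis–Menten hepatic hydrolysis of the two enantiomers at
  a shared carboxylesterase, plus first-order hepatic oxidation.

On top of the simulator sit non-compartmental metrics with the two-fold
adequacy assessment, a truncated-lognormal Monte Carlo population layer,
local sensitivity analysis (normalized sensitivity coefficients, +1%
perturbation), and a synthetic-study generator for testing estimation
workflows. See `vignette("oral-absorption-model")` for the science and the
design choices.

## Worked example

Simulate 20 mg of the 40:60 multilayer-release product, fasted adult:

```r
library(mphpbpk)

sim <- simulate_mph(builtin_formulation("MLR-MPH"))
sim
#> <mph_sim> MLR-MPH, 20 mg (fasted), 24 h
#>   Cmax 4.30 ng/mL; absorbed 68.0% of dose; balance 1.00000

report_segment_table(sim)
#>                       quantity Duodenum Jejunum1 Jejunum2 Ileum1 Ileum2 Ileum3 Caecum Ascending Colon Total
#> 1 Released (% of ER component)      0.0      0.5      1.3    2.0    2.2    2.0   35.0            18.2  61.2
#> 2   Absorbed (% of total dose)      2.4     10.6      9.9    8.3    6.9    5.1    4.5            20.4  68.0

pk_metrics(data.frame(time = sim$plasma$time, conc = sim$plasma$conc_total))
#> # A tibble: 3 × 6
#>   window     t1    t2  cmax  tmax   auc
#> 1 overall     0    24  4.30  2.15  47.1
#> 2 0-4 h       0     4  4.30  2.15  12.8
#> 3 4-24 h      4    24  3.26  6.2   34.3
```

Reading the output: the IR fraction (40% of the dose) dissolves in the
stomach and is absorbed almost entirely in the upper small intestine,
giving the 4.30 ng/mL peak at ~2 h. The ER beads hold their load until the
4 h lag has passed — by which time transit has carried them to the caecum
and ascending colon, where most of the release (35.0 + 18.2 of the 61.2%
total) and the second absorption phase (peak 3.26 ng/mL at ~6 h) occur.
The 32% of the dose that is never absorbed leaves in feces, mostly as
intact beads (`sim$fate`). The `balance` column confirms the mass ledger
closes.

`autoplot(sim)` draws the enantiomer-resolved plasma curves;
`run_population(mph_model(builtin_formulation("MLR-MPH")), n = 1000, seed = 1)`
adds the 90% population band; `sensitivity_screen()` ranks parameters by
their maximum |NSC|.

A command-line front end wrapping these functions ships at
`inst/cli/mphpbpk.R` (subcommands `simulate`, `population`, `sensitivity`,
`metrics`, `synth`, `report`).

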