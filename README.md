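# coldcomp

Does cold adaptation make enzymes faster? The *rate-compensation* model
predicts that enzymes from cold-adapted organisms show greater rate
enhancement — i.e. are faster at a common assay temperature — than their
warm-adapted orthologs, compensating for the rate-slowing effect of low
temperature. `coldcomp` implements a systematic statistical test of this
prediction from literature kinetic data, together with the mirrored analysis
of protein thermostability, for researchers in enzyme evolution and
molecular adaptation.

## The statistics at its core

Starting from a flat extract of kinetic constants (k<sub>cat</sub> or
k<sub>cat</sub>/K<sub>M</sub>, one row per measurement with organism,
substrate, EC number and wild-type/mutant status) and a curated table of
organismal optimal growth temperatures (T<sub>Growth</sub>):

1. **Curation.** Wild-type entries are matched by normalised organism name
   to T<sub>Growth</sub>; repeated measurements of one variant collapse to
   their median; a *reaction* is an EC number–substrate pair with variants
   from ≥ 2 organisms.
2. **Rate ratio.** Per reaction, k<sub>cold</sub>/k<sub>warm</sub> divides
   the rate constant of the variant from the coldest-growing organism by
   that from the warmest (medians when an extreme T<sub>Growth</sub> is
   shared). Rate compensation predicts ratios > 1.
3. **Control null.** Variants from *different* organisms with *identical*
   T<sub>Growth</sub> vary in rate for temperature-independent reasons;
   per such reaction the fold change k<sub>max</sub>/k<sub>min</sub> and its
   reciprocal enter a control distribution.
4. **Comparison.** The two distributions are compared with a two-sided
   Mann–Whitney U test; medians carry 95% bootstrap percentile confidence
   intervals (10,000 replications, seeded).
5. **Slope screen.** Per reaction with > 2 variants, OLS of
   log₁₀(rate) on T<sub>Growth</sub> gives a slope m<sub>rate</sub>,
   screened at the Bonferroni threshold α/m.
6. **Stability mirror.** Wild-type melting temperatures are regressed on
   T<sub>Growth</sub>, and protein families with a cold and a warm member
   get a T<sub>m,cold</sub>/T<sub>m,warm</sub> fold change.

A Michaelis–Menten fitter (`fit_michaelis_menten()`) turns initial-rate
series into per-variant constants that feed the slope analysis, and a
synthetic-data generator (`generate_kinetic_dataset()` and friends) draws
database-like tables from a hierarchical log-linear model with known ground
truth, so the whole pipeline is testable without any database download.

## Worked example

```r
library(coldcomp)

d  <- generate_kinetic_dataset(kinetic_sim_config(n_reactions = 300, beta = 0, seed = 42))
rx <- curate_entries(d$entries, d$t_growth)
compare_to_control(rate_ratios(rx), control_fold_changes(rx),
                   reps = 10000, seed = 42)
#> Rate-compensation test: k_cold/k_warm ratios vs same-T_Growth control
#>   data    (n =  299): median 1.028, 95% CI [0.879, 1.293]
#>   control (n =   24): median 1.000, 95% CI [0.549, 1.822]
#>   Mann-Whitney U = 3612, two-sided p = 0.957 (normal_approx)
#>   ratios > 1: 154, < 1: 145, = 1: 0
```

`beta = 0` simulates a world without temperature-dependent rate adaptation:
the data median sits near 1 with its CI straddling 1, the reciprocal-closed
control median is exactly 1, the U test finds no shift (p ≈ 0.96), and
ratios split almost evenly above and below 1 (154 vs 145). Setting
`beta = -0.02` (rates falling 10-fold per 50 °C of T<sub>Growth</sub>)
instead drives the ratio distribution above 1 and the comparison detects it
reliably. The per-reaction slope screen on the same null data fits 131
reactions and flags none at its Bonferroni threshold (0.05/131 ≈ 3.8e-4).

`run_full_analysis(config, out_dir)` orchestrates everything from file
inputs to TSV/JSON stage outputs plus a reproducibility manifest;
`inst/scripts/coldcomp.R` wraps it for shell use.

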