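---
title: "Testing rate and stability compensation: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testing rate and stability compensation: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coldcomp)
```

## The question and the statistic

Chemical reactions slow as temperature falls, and a long-standing
hypothesis holds that enzymes of cold-adapted organisms compensate by
evolving larger rate enhancements: measured at a common assay temperature,
the ortholog from the psychrophile should be faster than the one from the
thermophile. `coldcomp` operationalises this as a distributional test over
many reactions rather than a handful of anecdotal enzyme pairs.

A *reaction* is an EC number–substrate pair with wild-type kinetic
constants (k~cat~ or k~cat~/K~M~) from at least two organisms, each matched
by name to the organism's optimal growth temperature T~Growth~. Per
reaction the **rate ratio** is

$$\mathrm{ratio} = k_\mathrm{cold} / k_\mathrm{warm},$$

the rate constant of the variant from the organism with minimal T~Growth~
divided by that from the maximal one; when several variants share an
extreme temperature, the median of their rates is used. Under rate
compensation the ratio distribution shifts above 1.

Rates vary enormously between orthologs for reasons unrelated to
temperature, so "how far above 1 is meaningful" needs a null. The
**control distribution** uses reactions in which two or more variants come
from *different organisms with identical* T~Growth~: within such a group
the fold change $k_\mathrm{max}/k_\mathrm{min}$ and its reciprocal both
enter the control sample. By construction this captures
temperature-independent rate variation, symmetric about 1 on the log
scale. Data and control are compared with a two-sided Mann–Whitney U test;
each median carries a seeded bootstrap percentile confidence interval.
Finally, each reaction with more than two variants is screened by OLS of
$\log_{10}(k)$ on T~Growth~ (slope m~rate~, in log10 units per °C) at the
Bonferroni threshold $\alpha/m$.

The stability analysis mirrors this with melting temperatures: OLS of
T~m~ on T~Growth~ (both °C, untransformed) across wild-type proteins, and
per protein family with a cold and a warm member the fold change
T~m,cold~/T~m,warm~.

## Medians of fold-change distributions

Fold changes are summarised on the log scale: the reported median of a
ratio sample is `exp(median(log(x)))`. For odd sample sizes this is the
ordinary middle value; for even sizes it interpolates geometrically rather
than arithmetically. The choice matters for the control: the flattened
control multiset is closed under reciprocals, so its log values are
antisymmetric about 0 and its geometric-interpolated median is exactly 1
(up to floating-point rounding, asserted at 1e-12 in the tests). An
arithmetic midpoint would instead give $(x + 1/x)/2 \ge 1$ — a spurious
upward bias in precisely the quantity the control is meant to anchor.
Per-variant aggregation of repeated *measurements*, by contrast, uses the
standard arithmetic midpoint median; those are measurements of one
quantity, not ratios.

## Choices the data sources leave open

* **Organism matching** is by trimmed, whitespace-collapsed, case-folded
  name. Strain suffixes ("KT2440") block a match by default; an optional
  `strip_strains` mode retains only genus + species. Both modes exist
  because curations differ in granularity; matching granularity trades
  false merges against lost matches.
* **Substrate identity** is textual (trim + case-fold). No chemical
  synonym resolution is attempted; distinct names are distinct reactions.
* **Units.** Readers convert an optional units column to s^-1^ (k~cat~)
  and M^-1^s^-1^ (k~cat~/K~M~); rows with unconvertible units are rejected
  and logged, as are value ranges like "1.2-3.4" — guessing either would
  contaminate medians silently.
* **Control group selection.** A reaction can contain several distinct
  shared-temperature groups. One fold-change pair per reaction comes from
  the group with the most variants, ties broken toward the lowest
  temperature (deterministic and favouring the better-populated group);
  `groups = "all"` emits one pair per group instead. A reaction with both
  temperature spread and a shared-temperature group contributes to both
  the data and the control samples — the two selection criteria are
  independent.
* **Assay-temperature subsets** (25 °C or 37 °C, ±0.5 °C tolerance) and
  minimum T~Growth~-span subsets (> 20 °C, > 60 °C) re-aggregate variants
  from the qualifying source entries and re-apply the two-organism rule.
  Entries lacking an assay temperature stay in the main analysis, which
  pools all assay temperatures.
* **Stability deduplication.** Repeated T~m~ measurements of one
  (protein, organism) pair collapse to their median by default
  (`dedupe = FALSE` preserves them), consistent with the kinetic-side rule.

## Numerical and algorithmic details

* **Mann–Whitney U** is computed from rank sums with midranks. For
  $n_1 n_2 \le 400$ without ties the p-value is exact (complete null
  distribution of U); otherwise the normal approximation with tie
  correction and a 0.5 continuity correction is used. The two regimes
  agree to well under 0.01 in p where they overlap, and the exact branch
  matches exhaustive enumeration of all rank arrangements in the tests.
* **Bootstrap CIs** are simple percentile intervals over 10,000 resampled
  medians by default — the minimal reproducible choice, recorded in the
  output together with seed and replication count. All randomness flows
  from one user seed through counter-based substreams, so adding an
  analysis step never perturbs existing draws, and seeded helpers restore
  the caller's RNG state.
* **OLS fits** (per-reaction slopes, stability line) use `lm`; the
  two-sided slope p-value is the usual t test with $n-2$ df. Perfectly
  collinear inputs give $R^2 = 1$ and a p-value clamped into $(0, 1]$.
  Reactions with fewer than 3 variants or zero temperature variance return
  no fit — absence, not an error.
* **Michaelis–Menten fitting** uses Levenberg–Marquardt least squares on
  $v = k_\mathrm{cat} E S/(K_M + S)$ with both parameters
  log-parameterised (positivity by construction). Starting values:
  $k_{\mathrm{cat},0} = \max(v)/E$, $K_{M,0}$ the concentration nearest
  half-maximal velocity. Non-convergence, or a fitted $K_M$ driven outside
  three decades of the assayed concentration range (e.g. a fully saturated
  series), is reported as `converged = FALSE` rather than as a plausible
  number. Tests verify the fitter never exceeds the residual error of a
  dense grid-search oracle.
* **Display clipping** of ratio histograms to $[10^{-3}, 10^3]$ is
  presentation-only; statistics always use unclipped values.

## What the synthetic data emulate — and what they do not

`generate_kinetic_dataset()` draws from a hierarchical log-linear model:
per reaction a baseline $\mu_r \sim N(0, \sigma_\mathrm{reaction})$, per
variant at temperature $T_v$ (uniform on a 1 °C grid over 1–83 °C)

$$\log_{10} k = \mu_r + \beta T_v + \varepsilon,\qquad
\varepsilon \sim N(0, \sigma_\mathrm{noise})$$

per measurement. Defaults: $\sigma_\mathrm{reaction} = 1.5$ (baselines
spanning several orders of magnitude, as kinetic databases do),
$\sigma_\mathrm{noise} = 0.5$ (within-reaction spread comparable to the
~80-fold variation seen among orthologs of a single well-studied enzyme),
variants-per-reaction a truncated geometric dominated by 2-variant
reactions (P(2) = 0.57, matching the preponderance of two-variant
reactions in curated extracts), ~35% mutant rows and ~66% of wild-type
rows from organisms without a curated temperature — the funnel proportions
of a realistic curation. Temperatures sit on a grid and organisms are
reused across reactions, so distinct organisms can share a T~Growth~;
that is what populates the control path. $\beta = 0$ is the
no-adaptation null; $\beta = -0.02$ (10-fold per 50 °C) is strong
compensation. The stability generator uses
$T_m = a + b\,T_\mathrm{Growth} + N(0, \sigma)$ with defaults
$b = 0.4$ °C/°C, $a = 45$ °C, $\sigma = 11$ °C, chosen so growth
temperature explains roughly 40% of T~m~ variance, as in wild-type
stability surveys.

The generators do *not* simulate real database pathology beyond the
configured rates: no unit typos, no duplicated literature entries, no
taxonomy drift in organism names, no correlation between measurement
effort and enzyme importance. Passing tests therefore demonstrate that the
*pipeline* is correct and sensitive, not that any particular biological
dataset is clean.

## Calibration, power and a known limitation

The test suite and acceptance script run the full analysis over repeated
simulated datasets (100–200 replicates; null datasets of 200 reactions,
power datasets of 500 reactions with spans > 20 °C and
$\sigma_\mathrm{noise} = 0.3$, bootstrap replications reduced inside these
loops since only the U-test p is under study). Two findings matter for
interpretation:

* **Power.** Under strong compensation ($\beta = -0.02$) the
  data-vs-control comparison detects the shift in essentially every run —
  the design could not have missed an effect of the size the
  rate-compensation literature implies.
* **Conservatism of the null.** Under $\beta = 0$ the comparison rejects
  in far fewer than 5% of runs (the measured false-positive rate is ~0).
  This is structural: the control sample contains each fold change *and*
  its reciprocal — perfectly antithetic pairs — which violates the
  independence assumption behind the U test's variance and inflates its
  p-values. The U test itself is correctly calibrated on independent
  samples (its measured rejection rate in the suite's simulation is
  statistically indistinguishable from the nominal 0.05). The practical
  consequence is that a non-significant data-vs-control comparison is
  weaker evidence of "no difference" than its p-value suggests; the
  symmetric partition of ratios around 1 and the slope screen carry the
  interpretive weight.

Other limitations: organism-name matching has no taxonomic awareness;
textual substrate identity can split one chemical reaction into several;
T~Growth~ is a single number per organism and ignores thermal breadth;
and the stability fold change uses Celsius values, which is how such data
are conventionally plotted but makes the ratio scale-dependent (recorded
in the output metadata).
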