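# lichenmix

Partitioning lichen biomass between its two symbionts from nitrogen stable
isotopes.

A lichen thallus mixes a fungal partner (mycobiont) and an algal partner
(photobiont) whose biomass shares are difficult to measure directly. The two
partners differ strongly in nitrogen isotope composition (δ¹⁵N) and in
nitrogen content (mass C/N ≈ 55 for the fungus vs ≈ 13 for the alga), so the
whole-lichen δ¹⁵N is an N-weighted blend of the two end-members. `lichenmix`
implements the concentration-dependent two-end-member mass balance that
inverts this blend: with biomass fraction $f_{M,B}$ for the mycobiont,

$$f_{M,N} = \frac{f_{M,B}\,[N]_M}{f_{M,B}\,[N]_M + (1-f_{M,B})\,[N]_P},
\qquad
\delta^{15}N_L = f_{M,N}\,\delta^{15}N_M + (1-f_{M,N})\,\delta^{15}N_P ,$$

solved for $f_{M,B}$ by guaranteed-convergent bisection (the forward curve
is strictly monotone), with a closed-form rearrangement as an independent
numerical oracle. Around the model the package provides:

* validated tidy-CSV input/output for specimen-level isotope measurements
  (whole lichen, isolated photobiont, isolated mycobiont), with raw
  substrate names (bark, stone, ...) mapped onto the organic/minerogenic
  dichotomy;
* per-population biomass partitioning with per-substrate summaries, mixing
  lines for plotting, and explicit handling of clamped or unidentifiable
  populations;
* substrate-contrast statistics built on an in-package Mann–Whitney U test
  (exact by enumeration for pooled n ≤ 16, tie-corrected normal
  approximation otherwise), grouped summaries and biont Pearson
  correlations;
* a synthetic-data generator that emulates the survey and biont-separation
  designs from printed summary statistics (truncated normals with
  mean-matched parents), returning hidden ground truth for recovery tests;
* a pipeline (`run_analysis()`) and a thin CLI
  (`inst/cli/lichenmix`: `validate | simulate | summarize | contrast |
  partition | mixlines | run`) that emit CSVs plus a Markdown/JSON report.

Intended users are isotope ecologists and lichenologists who want a tested,
reproducible implementation of the partitioning calculation rather than a
spreadsheet.

## Worked example

```r
library(lichenmix)

cfg <- generator_config(seed = 1)       # study-condition defaults
sim <- generate_triplets(cfg)           # 10 populations + hidden truth
res <- partition_populations(sim$triplets)
res
#> biomass partition for 10 population(s)
#>   minerogenic: n = 5, f_M_B = 0.937 +/- 0.017 (0 clamped)
#>   organic: n = 5, f_M_B = 0.915 +/- 0.063 (0 clamped)
```

The recovered mycobiont biomass fractions — about 92% on organic and 94% on
minerogenic substrate here — say that the thallus is overwhelmingly fungal
by mass even though the alga supplies a large share of the nitrogen. A
survey-scale contrast shows the substrate signal in whole-lichen δ¹⁵N:

```r
substrate_contrast(generate_survey(cfg), "d15N")
#> Mann-Whitney U = 1330.0 (n = 44 vs 38), two-sided p = 4.453e-06 [normal_approx_tie_corrected]
#>   d15N: mean difference 2.825 (-7.209 vs -10.035)
```

i.e. lichens on minerogenic substrate are ~2.8 ‰ enriched in ¹⁵N relative
to those on bark in this simulated survey. Inverting the model at the
printed biont summary means (δ_L = −9.7, δ_M = −7.7, δ_P = −15.8 ‰, N ratio
55/12.9) gives a single consistency figure:

```r
invert_f_M_B(-9.7, end_members(-7.7, -15.8, N_M = 1/55, N_P = 1/12.9))
#> mixing solution: f_M_B = 0.9286 (f_P_B = 0.0714), f_M_N = 0.7531, fitted -9.700 permil, residual 4.69e-11, converged in 36 iterations
```

See `vignettes/biomass-partitioning.Rmd` for the model's assumptions, the
generator's design and its limits.

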