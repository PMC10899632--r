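# teckit

Quantifying RNA polymerase elongation kinetics through archaeal
histone-based chromatin, from simulated single-molecule kinetics all the way
to the gel-densitometry statistics a bench scientist would compute.

## The problem

In vitro transcription walk-out assays stall ternary elongation complexes
(TECs) at +58 nt by nucleotide deprivation, chromatinize the downstream DNA
with archaeal histone dimers, restart elongation, and resolve the nascent
RNA on denaturing gels at 15, 30, 60, 120 and 240 s. Lanes are quantified by
1-D densitometry: a linear regression of marker pixel positions on known
lengths calibrates the lane, signal is parsed into **seven RNA-length bins**
(bin 1 = the stalled +58 species, bin 7 = full-length +231), and three
statistics summarize each chromatin condition:

- **Mean transcript length** at time *t*:
  `L̄(t) = Σ_b f_b(t) · m_b`, with `f_b` the bin fractions and `m_b` the bin
  midpoints ("theoretical RNA lengths").
- **Average elongation rate** (nt/s):
  `r = mean_t [ (L̄(t) − 58) / t ]`, reported relative to the histone-free
  template.
- **Pause half-life at +58**: the two-point exponential fit
  `C2 = C1·e^(−k(t2−t1))` of the bin-1 fraction between t1 = 15 s and
  t2 = 240 s, `t_1/2 = ln2 / k`, tabulated relative to wild-type chromatin
  without transcription factor S (TFS).

Because each archaeal histone dimer protects ~30 bp and the polymerase
footprint is ~20 bp, a TEC restarting from +58 meets dimer barriers at
transcript positions **+70, +100, +130, +160, +190** — and in strong-binding
chromatin only the *first* encounter is a substantial pause.

`teckit` implements that entire quantification pipeline and, because the
underlying gel source data are not redistributable, drives it with a seeded
continuous-time Markov (Gillespie-type) simulator of single TECs traversing
configurable chromatin landscapes, plus a synthetic 1-D gel layer, so every
stage is testable end to end against exact oracles:

1. `tec_template()` / `make_landscape()` — template geometry and per-variant
   barrier landscapes (ten shipped conditions: histone-free, wild type, and
   eight HTkA point variants with illustrative barrier strengths).
2. `simulate_ensemble()` — exact stochastic sampling of the elongation birth
   chain; `transient_distribution()` — its deterministic master-equation
   oracle.
3. `synthesize_gel()` — length distributions to lane densitometry profiles
   with markers, point-spread and noise.
4. `quantify_gel()` — marker peak detection, size calibration by linear
   regression (`fit_size_calibration()`), background subtraction, seven-bin
   integration (`bin_lane()`), waterfall normalization.
5. `compute_kinetics()` — mean lengths, rates, relative rates, full-length
   fractions, pause half-lives with reference normalization, replicate
   standard errors; `tidy()`/`glance()`/`autoplot()` methods and
   `plot_bin_time_course()`, `plot_waterfall()`, `plot_relative_rates()`
   figures.

## Worked example

```r
library(teckit)

barrier_encounter_positions(default_template())
#> [1]  70 100 130 160 190

bt <- generate_study(
  conditions = tibble::tibble(variant = c("HTkA-free", "WT", "E19K/G52K"),
                              tfs = FALSE, n_replicates = 4L),
  params = sim_params(n_molecules = 5000),
  master_seed = 20
)
kin <- compute_kinetics(bt)
kin
#> <tec_kinetics> 3 condition(s)
#> # A tibble: 3 × 7
#>   condition tfs    rate rate_se     n rel_rate rel_rate_se
#>   <chr>     <lgl> <dbl>   <dbl> <int>    <dbl>       <dbl>
#> 1 E19K/G52K FALSE 0.324 0.00233     4    0.240     0.00173
#> 2 HTkA-free FALSE 1.35  0.00410     4    1         0.00303
#> 3 WT        FALSE 0.742 0.00315     4    0.549     0.00233
```

Histone-free DNA supports the fastest synthesis (1.35 nt/s by the
saturating mean-of-ratios statistic); wild-type chromatin slows the ensemble
rate to ~0.55 of histone-free, and the DNA-affinity double variant
E19K/G52K — whose first barrier at +70 captures most TECs — to ~0.24.

```r
kin$half_lives
#> # A tibble: 3 × 8
#>   condition tfs         k t_half defined    C1     C2 rel_t_half
#>   <chr>     <lgl>   <dbl>  <dbl> <lgl>   <dbl>  <dbl>      <dbl>
#> 1 E19K/G52K FALSE NA        NA   FALSE   0.455 0              NA
#> 2 HTkA-free FALSE NA        NA   FALSE   0.284 0              NA
#> 3 WT        FALSE  0.0224   31.0 TRUE    0.709 0.0046          1
```

The wild-type stall half-life (31 s here) is the normalization reference, so
its relative half-life is exactly 1; conditions whose stalled fraction has
fully decayed by the 240-s anchor are flagged `defined = FALSE` rather than
given a spurious number.

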