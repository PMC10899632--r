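---
title: "Modeling and quantifying TEC elongation through archaeal chromatin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling and quantifying TEC elongation through archaeal chromatin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(teckit)
library(dplyr)
```

## The assay being modeled

A ternary elongation complex (TEC) is stalled at +58 nt on a linear DNA
template by withholding CTP, the downstream DNA is saturated with archaeal
histone dimers, and elongation is restarted with all four rNTPs (with or
without the cleavage-stimulatory factor TFS). Aliquots at 15, 30, 60, 120
and 240 s are resolved on a denaturing gel next to single-stranded size
markers; lane densitometry, marker-based size calibration, and seven-bin
length parsing turn each lane into a transcript-length distribution from
which mean lengths, average elongation rates and the +58 pause half-life are
computed.

`teckit` reproduces that analysis chain and supplies its inputs from a
stochastic simulator, because the deposited source data for the published
gels are not packaged here. Everything downstream of the simulator — the
gel synthesis, the quantification and the statistics — treats the simulator
output exactly as it would treat digitized experimental lanes.

## The kinetic model

Each TEC is a continuous-time pure birth chain on transcript lengths
$L \in \{58, \dots, 231\}$:

* escape from the stalled state at rate $k_\mathrm{rel}$ (1/s);
* single-nucleotide addition at rate $k_\mathrm{step}$ (nt/s) at barrier-free
  positions;
* the step onto a barrier-encounter position $b_i$ is slowed to
  $k_\mathrm{step}/\beta_i$ with a dimensionless barrier factor
  $\beta_i \ge 1$;
* $L = 231$ (the template end) is absorbing: the full-length transcript.

Barrier-encounter positions derive from the template geometry: the leading
edge of the polymerase (RNA 3'-end plus `leading_edge_offset`) meets the
first positioned dimer at +70, and, because each dimer protects 30 bp,
again at +100, +130, +160 and +190. The geometry is parameterized rather
than hard-coded: the observed +70 first pause anchors
`hps_start - leading_edge_offset`, since the exact register of the RNA
3'-end against the dimer edge at the pause is not independently known.

There is no explicit backtracked state — pausing in this system is not
primarily backtracking-driven — and histone dissociation/exchange is not a
separate process: the effective escape rate $k_\mathrm{step}/\beta$ subsumes
waiting for a dimer to release, because transcript-length data constrain
only that effective rate. TFS enters phenomenologically as two multipliers:
`tfs_release_mult` $\ge 1$ on $k_\mathrm{rel}$ (TFS stimulates release of
stalled complexes into elongation) and `tfs_barrier_mult` $\ge 1$ dividing
$\beta_i$ (floored at 1; TFS partially relieves first-barrier pausing, with
no relief for the E19K/G52K double variant, whose default divisor is 1).

Sampling is exact: dwell times are exponential draws per position, arrival
times are their cumulative sums, and the length at an observation time is
the number of completed transitions — no time discretization. One seed
drives a fixed generation order, so ensembles are bit-reproducible.

### The exact oracle

`transient_distribution()` integrates the master equations of the same
chain (`deSolve::lsoda`, rtol 1e-10/atol 1e-12), giving a deterministic
transient law used three ways: as the reference in chi-square
goodness-of-fit tests of the sampler, as the source of exact monotonicity
checks (mean length non-decreasing in time, decreasing in barrier
strength), and as closed-form scaffolding — the stalled-state probability
is exactly $e^{-k_\mathrm{rel} t}$ for any landscape, which the two-point
half-life estimator must invert to machine precision.

## Default study conditions

The default design mirrors the emulated study: ten chromatin conditions
(histone-free DNA, wild-type HTkA, and the variants T55L, R20S, E3A, G52K,
E34A, G17D, E19K, E19K/G52K), four replicates without TFS and three with,
observation times 15/30/60/120/240 s (480 and 960 s in the extended
protocol), 5000 molecules per reaction.

Parameters were fixed once, as follows:

* **Per-condition stall release.** The published reference-normalized +58
  half-lives (wild type = 1.00, both TFS states) are treated as inputs:
  condition $c$ gets $k_\mathrm{rel}(c) = k_\mathrm{rel}(\mathrm{WT}) /
  \mathrm{rel}t_{1/2}(c)$, and its TFS release multiplier is the ratio of
  its −TFS to +TFS relative half-lives.
* **Absolute scale.** The absolute wild-type half-life is not recoverable
  from ratios; it is set to 30 s. This keeps the stalled fraction
  measurable at the 240-s anchor of the two-point fit (about 0.4% of
  5000 molecules) while letting most complexes restart within the time
  course. A consequence of the pure-exponential release model is honest and
  documented: conditions that release ~3.5x faster than wild type have an
  *empty* bin 1 by 240 s at this ensemble size, and their half-life is
  flagged undefined rather than fabricated. (Real gels avoid this because
  measured bin-1 decay reflects mixed populations, including complexes that
  never restart; this package deliberately models a single exponential.)
* **Stepping rate.** $k_\mathrm{step} = 2.5$ nt/s spreads the 173-nt run
  realistically across 15–240 s: full-length transcripts appear between the
  first and second timepoints on free DNA and accumulate to ~100% by 240 s.
* **Barrier factors.** The per-variant $\beta$ values are *illustrative*,
  not fitted to measured rates. They are ordered by the qualitative ranking
  of elongation impediment (free < T55L ≈ R20S ≈ E3A < WT < G52K < E34A <
  G17D < E19K < E19K/G52K) and were calibrated once against the oracle so
  that the simulated relative-rate ordering under the default kinetics
  respects that ranking — necessary because per-condition release
  differences also move the rate statistic, and naive $\beta$ ordering
  alone does not guarantee rate ordering. Strong-binding landscapes (G17D,
  E19K, E19K/G52K) restrict their barrier to the first encounter
  (`first_only`), reflecting first-contact dominance; the others carry a
  damped factor at later encounters.

```{r registry}
htka_variants()
```

## Gel synthesis and what it does and does not emulate

`synthesize_gel()` converts a length distribution into a 1-D lane profile:
each length contributes a Gaussian band at its mapped pixel with area
`gain x fraction` (areas computed exactly per unit pixel bin, so the
noiseless lane total equals the gain), plus optional truncated Gaussian
noise, a marker lane of equal-area standards, and a starting-material (SM)
lane of the pure stalled species.

The default mobility is *linear* in length (20 px/nt on a 4096-px lane),
matching the linear size regression the quantification stage fits. A log
mobility mode is provided because denaturing-PAGE mobility is classically
log-linear; fitting a linear calibration to a log-mobility gel produces
systematically curved residuals, which the calibration object surfaces
(`glance()`, residuals) rather than hides. The resolution default is
deliberately generous — adjacent single-nucleotide bands sit ten band-sigmas
apart — so that quantification error reflects the algorithms, not an
arbitrary blur choice; real gels compress high-length spacing and blur
bands, which this layer only emulates through its configurable `psf_sigma`,
`noise_sd` and mobility parameters. Smiles, streaks, lane-finding and other
2-D image pathologies are out of scope.

What passing round-trip tests show, therefore, is that the quantification
chain (peak detection with sub-pixel parabolic refinement, OLS calibration,
morphological-opening background subtraction, half-open pixel-interval bin
integration) is correct and stable under the stated noise model — not that
it would survive arbitrary real-gel artifacts.

## Quantification conventions

* **Bins.** Bin 1 is the single stalled length {58}; bins 2–7 partition
  (58, 231] with default interior edges 87/116/145/174/202 (a convention —
  the emulated study does not state numeric edges; fully configurable).
  Midpoints are 58 for bin 1 and interval midpoints otherwise, giving bin 7
  the midpoint 216.5.
* **Calibration direction.** Pixel is regressed on length (as in the
  emulated workflow) and the line inverted analytically for pixel-to-length
  lookup; with two markers the interpolating line has $R^2$ defined as 1.
* **Bin integration.** Length-bin boundaries are taken at half-integer
  lengths and mapped to pixel coordinates; pixel intervals are half-open
  toward increasing length so the seven bins exactly partition the lane,
  and fractions are normalized to the lane total inside the binned region
  (making them invariant to uniform lane scaling).
* **Background.** Default `rolling_min` is a morphological opening (running
  minimum then running maximum, width 301 px): a bare running minimum
  either lags sloped baselines by half a window or bites into inter-band
  valleys. Whether the emulated study quantified raw or background-
  subtracted volumes is unknown; `min` and `none` are provided.
* **Waterfall normalization.** Per-pixel lane intensities divided by the
  *total* SM-lane signal; sums are not constrained to 1, and signal
  conservation appears as normalized lane sums near 1.

## The statistics

`average_elongation_rate()` implements the published formula verbatim: the
unweighted mean over observation times of $(\bar L(t) - 58)/t$. This is a
biased estimator of the instantaneous stepping rate — once transcripts
saturate at the template end, $\bar L(t) - 58$ plateaus and the ratio
decays — and it is deliberately *not* corrected; comparisons between
conditions use the same statistic and are reported as ratios to the
histone-free template (matched for TFS state). Whether the published
relative rates are ratios or differences is not stated beyond "plotted with
respect to"; the ratio is implemented, and a difference is trivially
recoverable from the per-condition rates.

`pause_half_life()` is the two-point exponential inversion
$k = \ln(C_1/C_2)/(t_2-t_1)$, $t_{1/2} = \ln 2/k$. Anchors default to
replicate-mean bin-1 fractions at 15 and 240 s (per-replicate mode is
available), matching the tabulated-half-life convention. Degenerate cases
propagate as flags, never as negative numbers: $C_2 \ge C_1$ gives
$k \le 0$ and an undefined half-life; empty anchors (complete release) give
an undefined row excluded from relative tables. The reference row of
`relative_half_life()` is exactly 1 by construction.

Replicate summaries are mean ± SE ($s/\sqrt n$), flagged `NA` below two
replicates. No hypothesis testing is attached: the emulated analysis
performs none.

## Numerical choices and degenerate inputs

Observation time 0 is legal for the simulator (point mass at 58) but
rejected by the rate statistic (division by t). The ODE oracle clamps
negative round-off probabilities at zero; its sums are verified to 1e-8.
Peak detection refines discrete maxima by three-point parabolic
interpolation and reports positions in the pixel-index convention (a
constant half-pixel offset from continuous band centers that the
calibration absorbs, as both markers and samples share it). Chi-square
goodness-of-fit tests pool cells with expected counts below 5. Barrier
factors below 1 are rejected; a TFS-divided factor is floored at 1 so TFS
can never make a barrier step faster than a free step.

## Problem sizes

Defaults were chosen so the full pipeline runs interactively: 5000
molecules per reaction (70 reactions in the default study), 10^5 molecules
for half-life recovery checks, 10^4 for goodness-of-fit, 2000 for gel
round-trips. At these sizes the estimator-recovery errors are far inside
their tolerances (half-life within ~1% of $\ln 2/k_\mathrm{rel}$ across the
0.002–0.02 1/s grid; rate within ~0.5% of the oracle statistic).

## Known limitations

* The simulator has no never-restarting subpopulation, no sequence-specific
  pausing on free DNA, and no explicit histone exchange; all are
  deliberate reductions (see above) that limit realism for conditions where
  those effects dominate.
* Registry barrier factors are illustrative; measured per-variant rates are
  not claimed to be reproduced, only their qualitative ordering.
* The gel layer is 1-D and artifact-free by construction.
* The rate statistic saturates at long times by design (it is the published
  formula); it should not be read as a microscopic stepping rate.
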