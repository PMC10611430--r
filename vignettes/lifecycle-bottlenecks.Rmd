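---
title: "Genetic bottlenecks in clonal and aggregative multicellular life cycles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genetic bottlenecks in clonal and aggregative multicellular life cycles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snowfloc)
```

## The scientific question

Nascent multicellular organisms form groups in one of two ways. Under
*clonal* development ("snowflake" yeast is the model case), daughter cells
stay attached after division, so every group is genetically uniform and a
new mutation is confined to the cluster it arose in. Under *aggregative*
development ("floc" yeast), free cells come together into genetically
mixed groups, so a mutant lineage is scattered over many groups roughly in
proportion to its frequency.

When such populations evolve under alternating selection for growth (batch
culture) and for group survival (settling selection, where only biomass
reaching the tube bottom is transferred), the mode of group formation sets
the *genetic bottleneck* a new mutation must pass. This package provides
the quantitative machinery for studying that contrast: an analytic
extinction theory, a stochastic life-cycle simulator, the group-phenotype
and competition statistics used to characterize such experiments, and a
bootstrap test for detecting selection in mutation-class spectra. A
synthetic-data layer generates every input with known ground truth, so all
estimators are validated by parameter recovery rather than by reference to
any particular data set.

## Analytic extinction theory

Consider `N` equal groups of which `k` contain at least one mutant cell,
and let settling selection keep a fraction `f` of groups, drawn without
replacement. The mutant lineage dies in this round exactly when none of
the `k` marked groups is drawn, the zero-success probability of a
hypergeometric draw:

$$p_e \;=\; \prod_{i=0}^{fN-1} \frac{N-k-i}{N-i}
\;\;\xrightarrow[N\to\infty]{}\;\; e^{-kf/(1-f)}.$$

`extinction_prob_exact()` evaluates the product in log space (it would
underflow for large `N` otherwise); `extinction_prob_approx()` is the
exponential form. The number of draws is `f*N` rounded to the nearest
integer with a minimum of one draw; the rounding convention matters only
for tiny populations and is validated against literal subset enumeration
in the tests. Two limits are worth keeping apart: as `N` grows at fixed
`k` and `f`, the exact probability converges (at rate 1/N) to
$(1-f)^k$ — each marked group independently avoids a fraction-`f` draw —
while $e^{-kf/(1-f)}$ is the small-`f` simplification of that limit,
accurate to $O(kf^2)$. At the bottleneck strengths of interest
(`f` ≈ 0.01) the distinction is numerically negligible and the
exponential form is what the headline percentages use.

The life cycle enters through `k`. If a mutant arises at the start of a
growth phase and the population grows 100-fold, the lineage has `m = 100`
cells at settling. Clonal development packs them into
`k = ceiling(m / mean group size)` groups (ceiling, because a partially
filled propagule still carries the lineage — the convention is
indistinguishable from floor on the exactly divisible textbook case);
aggregative development, with rare mutants, puts each cell in its own
group, `k = m`:

```{r}
k_c <- mutant_group_count(100, 50, "clonal")       # 2
k_a <- mutant_group_count(100, 50, "aggregative")  # 100
c(clonal = extinction_prob_approx(k_c, 0.01),
  aggregative = extinction_prob_approx(k_a, 0.01))
```

A clonal lineage is lost 98% of the time; an aggregative one only 36.4% —
the bottleneck is the price of clonality, and it grows with organism size.

## The stochastic simulator

`run_lineage()` follows one mutant lineage through rounds of:

1. **Growth.** Ancestors and mutants grow exponentially from `I` total
   cells (`m` mutant) until the population has increased `growth_fold`
   times; the stopping time solves
   $(I-m)e^{\lambda t} + m e^{\lambda(1+s_c)t} = G \cdot I$
   (closed form when `s_c = 0`, bracketed root-finding otherwise,
   cross-checked against a plain bisection oracle in the tests).
   Fractional cell counts are rounded stochastically (floor plus a
   Bernoulli draw on the remainder), which keeps counts integral without
   bias.
2. **Group formation.** Group sizes are re-drawn from the size
   distribution each round until they tile the grown population exactly
   (the last group is trimmed); only surviving cell counts carry over
   between rounds, reflecting daily re-formation of groups from the
   transferred bottleneck. Clonal allocation fills uniformly chosen
   groups entirely, leaving at most one mixed group (the spatially
   constrained propagules of one ancestral cluster); aggregative
   allocation marks a uniform random subset of cells as mutant, so the
   expected mutant load of a group is proportional to its size.
3. **Settling selection.** Groups are drawn without replacement with
   probability proportional to the weight $n + (1+s_g)m$ until the drawn
   groups hold `survival_fraction` of all cells; the overshoot is removed
   by scaling every selected group by a common factor (with stochastic
   rounding, preserving the mutant:ancestral ratio in expectation). The
   without-replacement draw uses exponential sort keys (`rexp(N)/w`),
   which is distributionally identical to successive renormalized-weight
   sampling and makes runs seed-reproducible at `O(N log N)` cost.

Two conventions deserve note because the procedure they implement is
genuinely underdetermined. First, the "at most one mixed group" rule is
applied in *every* round; after round one the surviving propagules could
in principle seed several partially mutant groups, so this is an
idealization of perfect clonal packing. Second, the overshoot rescale is
applied to all selected groups rather than only the last-drawn one; the
choice is invisible at the default parameters (overshoot is at most one
group's worth of cells) and is validated by the conservation and
martingale tests.

Defaults mirror the experimental regime being modeled: 100-fold growth,
1/100 survival, five rounds, one initial mutant, mean group size 50 with
lognormal dispersion 0.5 (right-skewed and strictly positive, the shape
of observed cluster-size histograms; real measured distributions can be
supplied verbatim via `size_spec("empirical", sizes = ...)`). The
population scale is set by `n_groups = 1000` groups at carrying capacity
(~50,000 cells), large enough that the single-round extinction fraction
matches the analytic hypergeometric value and small enough that a
10,000-replicate ensemble runs in seconds.

```{r}
spec <- size_spec("lognormal", mean_size = 50, dispersion = 0.5)
run_ensemble(sim_params("clonal", s_g = 10, n_groups = 500),
             spec, n_replicates = 200, seed = 9)
```

Strongly group-beneficial clonal mutants are usually lost in the first
rounds — but fix rapidly when they survive. The qualitative orderings
(clonal extinction ≥ aggregative for growth-beneficial mutants; fix-or-die
dynamics for group-beneficial clonal mutants) are asserted over a
parameter grid and across bottleneck sizes 1/50–1/200 in the test suite.
Ensemble sizes there (a few hundred replicates per grid point; 10,000 for
the neutrality and theory-agreement checks) were chosen as the smallest
that give 3-standard-error resolution on the quantities asserted.

## Group-phenotype statistics

**Settling rate.** The synthetic settling video is a band of intensity 1
(background 0) moving down the frame at a programmed speed, with optional
additive Gaussian noise and conserved total intensity. `settling_rate()`
subtracts the per-column minimum of each frame (removing static
illumination structure) and regresses the intensity-weighted vertical
centroid on time. A centroid-displacement regression was chosen over
front-tracking as the simplest estimator of the biomass-displacement
rate; it is exact on noise-free stacks and recovers programmed speeds
within 5% at pixel-noise SD 0.05 (clipping noise at zero leaves a small
uniform background that attenuates the slope by roughly the ratio of
background to band mass — about 2–4% at that noise level; this, not
variance, dominates the error budget).

**Flocculation efficiency.** For a well-mixed frame the coefficient of
variation of pixel intensity is reported: flocs concentrate biomass into
dense patches, widening the intensity distribution. CV is used rather
than raw variance because it is invariant to exposure and illumination
scale; the raw variance is exposed as an option for comparison with
pipelines defined that way. The population (1/n) variance is used so the
two-level fixture (half zeros, half 2a) gives exactly 1.

**Biomass-weighted mean size.** Per-group size values (e.g. flow-cytometry
forward scatter as a cluster-size proxy) are binned into 100 equal-width
bins spanning the sample range; each bin is represented by its center and
weighted by the fraction of total biomass (sum of values) it contains.
The statistic is the size-biased mean $\sum_i s_i^2 / \sum_i s_i$ up to
binning error; it shifts by less than 1% between 50 and 200 bins on
realistic samples and always dominates the arithmetic mean.

## Competition statistics

`malthusian_fitness()` is the ratio of log growth factors of the two
competitors over the same interval, optionally normalized by an
ancestor-vs-ancestor control competition (exposed as an argument rather
than hard-wired, since the appropriate normalizer depends on the assay
design). `assortment()` is the frequency-controlled enrichment
$(f_{set}-f_{pop})/(1-f_{pop})$: 1 for perfectly assorted (clonal) groups,
0 when settling leaves the frequency unchanged, negative when the focal
strain is depleted. Synthetic competitions
(`gen_competition_counts()`) encode a programmed true fitness, which the
estimator recovers exactly without noise and without bias under Poisson
counting noise.

## Mutation-spectrum null test

To ask whether an observed spectrum of mutations departs from drift,
`simulate_snps()` draws substitutions uniformly over an annotated genome
(alternate base uniform over the three non-reference bases) and classifies
each by codon lookup: synonymous, missense (including start- and
stop-codon losses), nonsense (stop gained), upstream (within a
configurable window 5' of a start codon, strand-aware; 1000 bp by default,
matching common annotation practice) or intergenic — with upstream and
intergenic reported jointly as the fourth class.
`bootstrap_class_test()` then draws `n_boot` subsamples of the observed
pool size with replacement from the null (equivalently, multinomial draws
at the null class proportions) and reports per-class tail proportions
with ties counted in both tails ("at least as extreme").

The classifier is verified exhaustively: on compact synthetic genomes
every one of the $3L$ possible SNPs is compared against whole-protein
translation with Biostrings. Calibration is verified by simulation: when
the observed counts are themselves a null draw, the randomized tail
probability (ties broken uniformly, the standard correction for a
discrete test statistic) is uniform over repeated experiments
(Kolmogorov–Smirnov, 500 experiments at pool sizes 69 and 104 with 1000
resamples each). The raw tail proportion with ties included is
deliberately conservative (super-uniform), which the tests also assert at
the null expectation.

The synthetic genome generator packs non-overlapping single-CDS genes
(ATG start, clean stop, no internal stops) into random-background contigs
at a chosen GC content, on the forward strand by default or random
strands to exercise reverse-complement handling. It makes no attempt to
mimic real yeast genome composition — gene density, codon usage and the
absence of introns/UTRs are all idealized — so passing tests demonstrate
correctness of the machinery, not realism of the null for any particular
organism. Users with a real genome can supply it via `read_genome()`
(FASTA + GFF3).

## Degenerate inputs and numerical choices

* `extinction_prob_exact()` returns 1 for `k = 0` and 0 whenever the
  pigeonhole principle forces a mutant group into the draw; everything
  else is computed in log space.
* Growth with `s_c = 0` or a pure-mutant population bypasses the solver.
* `settle_select()` guards the (tiny-target) corner where stochastic
  rounding empties every selected group by retaining one cell of the
  first-drawn group's majority lineage.
* `biomass_weighted_mean_size()` returns the common value for constant
  samples (zero bin width would otherwise be degenerate).
* Generators clamp video intensities to [0, 1] and floor group sizes at
  one cell; both are documented sources of (small) bias, quantified in
  the parameter-recovery tests.

## What the synthetic data does and does not show

The generators reproduce the *structure* of the real inputs — size
distributions, annotated contigs, settling stacks, count tables — with
known ground truth, which is exactly what is needed to validate
estimators. They do not reproduce optical artifacts of cuvette imaging,
flow-cytometer measurement noise, real genome composition, or the
empirically observed group-size distributions of evolved populations
(which are not published as data). Quantities that depend on those
empirical inputs — for example the precise extinction percentage of
group-beneficial mutants under an observed size distribution — are
therefore checked qualitatively (orderings, bounds), not numerically.
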