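---
title: "Classifying somatic mutations to meristem layers: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying somatic mutations to meristem layers: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(periclinal)
```

## The model

A vegetatively propagated plant is a periclinal chimera: the epidermal L1
and the homogenized inner L2,3 compartment of the shoot apical meristem
accumulate somatic mutations independently. The package's quantitative
core is two small laws and a set of threshold rules built on them.

**Dilution law.** A fixed simplex mutation in an autotetraploid has
cell-level VAF $1/\mathrm{ploidy} = 0.25$. In a bulk tissue whose cells
descend from the meristem layers with fractions $f_{L1} + f_{L2,3} = 1$,
the expected observed VAF of a layer-$k$ mutation is
$0.25 \cdot f_k$. Trichome DNA is modelled as pure L1, adventitious-root
DNA as pure L2,3, and leaf DNA as a mixture. Read counts at a site are
modelled as depth $D \sim \mathrm{Poisson}(\mu)$ and alt reads
$A \mid D \sim \mathrm{Binomial}(D, \mathrm{E[VAF]})$.

**Rate normalization.** Compartment mutation rates are
$\hat r = n / (B \cdot t)$, with $n$ the classified count, $B$ the
callable positions of the genomic space (genic or intergenic) and $t$ the
clonal divergence time in years. All published-table ratios are quotients
of such rates; a regeneration episode is equated to one
generation-equivalent ($t = 1$) for regenerant-private rates.

## Classification rules and their thresholds

A sample shows *confident presence* of a mutation iff depth ≥ `min_depth`
(8) and VAF ≥ `min_vaf` (0.125, half the simplex expectation). *Presence
at any VAF* (used only for the mosaic leaf) requires `presence_min_alt`
(1) supporting read — the literal reading of "any VAF". *Not detected*
requires coverage (depth ≥ 8) and at most `absence_max_alt` (1) supporting
reads; a site with no coverage in a sample needed by an absence clause is
never given a positive class. We deliberately keep the presence floor (≥ 1
read) and the absence ceiling (≤ 1 read) as separate knobs: a single
shared threshold either forces the leaf-presence clause to demand two
reads — at leaf VAF 0.06 and 60× depth roughly one in eight true L1
mutations then fails the clause by chance, capping attainable sensitivity
near 0.87 — or forces absence claims to tolerate zero error reads in real
data. The split keeps both clauses honest at the stated study depth while
remaining configurable.

Where boundary read counts let two clauses hold simultaneously (e.g. one
alt read at depth 8 is both "confident presence" at VAF 0.125 and within
the absence ceiling), precedence is fixed and documented:
conflicted > L1/L23 > ancestral > root-unique. `conflicted` is a terminal
class we surface rather than silently drop.

Regenerant-panel calls require ≥ `min_regenerants` (4) confidently mutant
samples from one layer, coverage-backed absence in *every* sample of the
other layer, and absence in every covered ancestor clone. Contaminant
removal flags any site with ≥ 4 foreign-taxon reads summed over samples;
the mean mapping-quality filter removes sites whose across-sample mean MQ
is ≤ 40 (the boundary is removed, matching the inclusive rule). Both
filters run before classification.

## What the synthetic generator emulates

The generator is first-class, tested code; its defaults *are* the study
conditions the analysis is validated under:

* two mutation compartments with per-space rates in mutations·bp⁻¹·y⁻¹;
  defaults give an L1/L2,3 rate ratio of 4 and an intergenic/genic ratio
  of 2.5, at magnitudes producing several hundred fixed mutations on a
  1 Mb genome over 34 years (the published genome is ~680 Mb; we scale the
  rates up so counts, not densities, match working size);
* simplex dosage: every event has cell VAF 0.25 (`1/ploidy`);
* tissue compositions: trichome `{L1: 1}`, root `{L23: 1}`, leaf
  `{L1: 0.24, L23: 0.76}`. The leaf split is back-derived from the
  observed 0.06 vs 0.25 VAF means; it is a modelling default, not a
  measured quantity;
* depth 60× Poisson per site with binomial alt-read sampling; overdispersed
  depth can be emulated by lowering `depth_mean`, but is not modelled;
* regenerant panels of 6 (L1) and 7 (L2,3) single-layer clones, each with
  a private mutation burden uniform on [36, 984] whose base changes are
  C>A with probability `ros_bias` (0.5 by default) — the oxidative-damage
  signature of protoplast regeneration;
* residual classes (53 ancestral, 52 root-only events) injected directly
  rather than mechanistically modelled;
* artifacts: ~1% of sites get a low site-level mean MQ (≤ 40) and ~1% get
  ≥ 4 foreign-taxon reads, to exercise the two filters. Mapping quality is
  site-level (per-read MQ is not simulated) and base quality is honoured
  by construction: simulated read counts contain only quality-passing
  reads, so the callable-site depth tracks are already
  quality-filtered counts.

What it does **not** emulate — and what green tests therefore do not show
about real data: sequencing error (no stray alt reads in truly unmutated
samples), mapping bias near structural variation, the high-VAF (~1.0)
mutation class caused by collapsed haplotypes, mericlinal sectors or
stem-cell drift within a layer, linkage between sites, and indels (the
generator emits SNVs only; spectra exclude indels by design). Sensitivity
estimates from the simulator are therefore upper bounds for noisy real
libraries.

## Numerical and design choices

* Reference bases are assigned by a deterministic per-position hash
  (exact in doubles, O(1) memory), so a 1 Mb–1 Gb genome needs no stored
  sequence and trinucleotide contexts are reproducible from the seed
  alone. Genic intervals are placed on a 5 kb grid, so the genic fraction
  is honoured to one granule.
* Private-mutation positions are rejection-sampled so that the requested
  C>A fraction is achieved exactly in expectation regardless of base
  composition; all ref/alt pairs stay consistent with the hashed
  reference.
* VAF uses total depth DP as denominator (simulated DP contains no
  third-allele reads).
* χ² tests delegate to `stats::chisq.test` with no continuity correction
  (counts are large; the correction is an argument). In spectrum
  contrasts, classes empty in *all* groups are dropped before testing; a
  group with zero SNVs is an error.
* Rates are reported at full precision; printed-table comparisons round to
  3 significant figures (rates) or 2 decimals (ratios), matching the
  published formatting.
* The published regenerant-63 genic regenerant/L2,3 ratio is internally
  inconsistent with its printed count (the printed value equals the genic
  rate divided by the *intergenic* L2,3 rate); the package reproduces the
  count-based value and the inconsistent printed one is excluded from
  validation. Similarly, a discussion-level L2,3 genic rate of 5.9e-9
  for the 60-year clone differs from the table value 7.75e-9 reproduced
  here.
* Problem sizes: the test suite validates the dilution law on ≥ 500 sites,
  oracle equivalence on 250–300 random sites, and end-to-end recovery on
  20 seeded 1 Mb datasets (~10⁴ sites, 17 samples each) — sizes chosen so
  Monte-Carlo error is well below the tested margins while a full run
  stays interactive.

## Known limitations

Classification is per-site and ignores haplotype phase; the dosage assay
assumes marker sets are correct and disjoint; rate ratios carry no
confidence intervals (none are defined for the published comparisons);
and the L2,3 compartment is treated as a single endpoint — the package
cannot attribute its rate to L2 versus L3, which would require layer
separation the data do not provide.
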