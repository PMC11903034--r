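---
title: "Methods: one-pot single-cell eQTL mapping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: one-pot single-cell eQTL mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical models implemented in `onepot`, the
rationale for their default parameters, and the assumptions and limitations
of the bundled simulator. All empirical statements about the package's
behaviour are the ones computed by the test suite
(`tests/testthat/`) and the scoring script (`scripts/acceptance.R`); this
document explains *what* is computed and *why*, not new results.

## The one-pot design

A single scRNA-seq experiment on a pooled population of recombinant haploid
segregants provides three things per cell simultaneously:

1. **Genotypes.** Reads overlapping transcribed SNPs that distinguish the
   two cross parents ("informative sites") reveal which parental allele the
   cell carries at each site.
2. **Expression.** UMI counts per transcript.
3. **Cell state.** Stage of the cell cycle, classified from marker genes.

Everything downstream — eQTL scans, cell-cycle interactions, occupancy
QTLs, hotspots — is built from these three per-cell quantities.

## Genotyping: a two-state HMM

Per cell and per chromosome, the genotype at the ordered informative sites
is a two-state Markov chain (parent A / parent B).

- **Prior**: each chromosome starts in either state with probability 0.5,
  as expected for a haploid cross.
- **Transitions**: between adjacent sites separated by `d` cM the switch
  probability is the recombination fraction from the Haldane map function,
  `r = 0.5 (1 - exp(-2 d / 100))`. Genetic positions of sites are linearly
  interpolated from the marker map. Haldane (no crossover interference) was
  chosen because it is the standard single-parameter map function and is
  used self-consistently by the simulator and the inference; `kosambi` is
  available as an option.
- **Emissions**: with `r` reads supporting allele A out of `D` total at a
  site, the emission likelihood is `(1-e)^r * e^(D-r)` in state A and the
  swapped expression in state B, with sequencing error rate `e = 0.005`
  (a typical per-base error after UMI consensus). Masked sites and sites
  with zero coverage contribute a flat emission, i.e. they are imputed from
  their neighbours.
- **Inference**: posteriors are computed exactly by scaled forward–backward,
  vectorized across cells. Hard calls use a strict `P(A) > 0.5` rule, with
  exact ties going to B. The test suite verifies the forward–backward
  posteriors against brute-force enumeration of all `2^k` genotype paths.

Doublets are flagged before genotyping from the fraction of adjacent
informative-site pairs whose reads support different parents: two pooled
cells produce allele switches at a rate far above the recombination rate.
Sites with minor-allele frequency below 0.05 across cells are masked, as
extreme frequencies indicate mapping artifacts rather than segregating
variation.

## eQTL mapping: negative-binomial GLMs

Expression of transcript *t* in cell *c* is modelled as negative binomial
with log link:

```
log mu = b0 + b_g * g + b_u * log(totalUMIs) + batch terms
```

`g` is the genotype posterior mean at the tested marker, standardized to
unit variance so effects are comparable across markers; `log(totalUMIs)`
controls for compositional/depth effects; batch indicators absorb
technical variation. The NB size parameter `theta` is estimated once per
transcript under the no-marker null (alternating profile likelihood) and
held fixed across the genome scan — a standard, fast approximation that the
tests show does not distort calibration. The scan statistic is
`LOD = LR / (2 ln 10)`.

The inner IRLS loop (`src/scans.cpp`) is shared by the local scan
(each transcript at its closest marker) and the genome scan (all transcripts
by all pruned markers); markers are pruned at `r^2 > 0.999` to remove exact
duplicates. Peaks use the leftmost-maximum rule with 1.5-LOD-drop
confidence intervals clipped at chromosome ends.

**FDR** comes from permutations that respect the design: cells are permuted
at the segregant level within batch, so cells of one segregant always
receive genotypes of a single donor segregant and the within-cell
correlation structure survives the permutation. For a grid of LOD
thresholds, FDR(t) is the mean permutation exceedance count divided by the
observed exceedance count, capped at 1 and made monotone by a running
minimum; observed statistics are interpolated onto this map.

**Cell-cycle interactions** compare a marker's effect between two stage
scans via the contrast `z = (beta_i - beta_j) / sqrt(se_i^2 + se_j^2)`.
The bundled reference table (`reference_eqtl_counts`,
`cc_interaction_enrichment`) reproduces the published contingency test that
distant eQTLs interact with the cell cycle far more often than local ones.

## Cell-cycle stage and occupancy QTLs

Stages are assigned by a deterministic marker-score rule: log1p
counts-per-10k, per-gene z-scores (population SD), mean z per stage panel,
argmax with ties to the earliest stage. The haploid panel has five stages
(M/G1, G1, G1/S, S, G2/M); the diploid panel drops MFA1 and with it the
discrete G1 stage. The classifier is intentionally simple and transparent;
externally produced labels can be substituted everywhere.

An **occupancy QTL** shifts the fraction of cells in a stage by genotype.
Per stage and marker, membership is modelled by logistic regression with
`log(totalUMIs)` as covariate; `LOD = LR / (2 ln 10)`. Markers showing
quasi-separation (`|beta| > 15`) are refit with Firth's penalized
likelihood and flagged. Chromosome III is excluded by default because the
mating-type locus it carries distorts stage proportions in crosses.
Significance uses a family-wise threshold: the 95th percentile of the
genome-wide maximum LOD over segregant-level permutations (at least 100;
1000 by default).

## Allele-specific expression and noise

In an F1 hybrid diploid, both parental alleles share one nucleus, so allele
differences isolate cis-acting variation. The joint model stacks the two
allelic counts per cell and lets both NB parameters depend on the allele:

```
log mu    = b0 + b_a * allele (+ covariates)
log theta = tau0 + tau1 * allele
```

Overdispersion `1/theta` is the measure of expression noise;
`exp(-tau1)` is the allelic noise fold change. The likelihood is maximized
by BFGS with analytic gradients and an NB-IRLS warm start; standard errors
come from the numeric Hessian. The test suite verifies the fit against
`glmmTMB`'s equivalent dispersion model and checks Wald-test calibration on
null simulations.

Two caveats are built into the API:

- At very low per-allele counts the dispersion is weakly identified: the
  `theta` MLE can diverge (the NB boundary), and among identifiable fits
  the noise fold change is biased toward zero. `bias_simulation` exposes a
  `boundary` flag and the expected bias direction is asserted by the tests.
- Apparent noise differences track mean differences across genes;
  `noise_trend` fits a robust (Huber) regression of noise change on mean
  change and flags only genes whose noise effect leaves the trend's 95%
  band.

## Hotspots

Distant eQTLs (peak on a different chromosome than the transcript) are
assigned to 50-kb half-open genomic bins by peak position (a peak at
exactly the chromosome end is clamped into the last bin). Under the null
every bin receives `lambda = total / n_bins` eQTLs; per bin
`p = P(Poisson(lambda) >= count)` with Bonferroni control, and adjacent
significant bins merge into one region. A region's interval takes the up to
20 highest-LOD member peaks, the 10th/90th percentiles of their interval
endpoints, extended two markers outward and clipped to the chromosome.

## The simulator and its defaults

Simulator defaults mirror the experimental regime the methods target:

- per-cell depth is log-normal with median 1500 UMIs (`depth_meanlog =
  log(1500)`, `depth_sdlog = 0.35`), matching the scale of a typical yeast
  one-pot run;
- informative-site read rates default to `(2/3)/n_markers` of depth,
  giving on the order of 1000 genotype-informative UMIs per cell;
- sequencing error `e = 0.005`, doublet rate 5%, NB size `theta = 2`;
- doublets are sums of two independent cells' counts;
- the F1 generator's `"median"` and `"top5"` expression presets put about
  1 and 20 total allelic UMIs per cell, spanning the informative range of
  the noise test.

Ground truth (segregant genotypes, planted effects, stage labels, doublet
status) is always recorded, so every pipeline claim in the tests is checked
against truth rather than against another estimator.

**Realism limits.** Reads are not simulated at the FASTQ/BAM level; there
is no UMI collision, ambient RNA, or mapping bias. Per-site depths are
Poisson given cell depth, an assumption rather than a measured property.
Stage effects enter as log-mean shifts, not as a continuous cell-cycle
trajectory. Transcript totals are independent NB draws, so per-cell totals
are not strictly fixed — with few genes, strong same-signed planted effects
can leak into the `log(totalUMIs)` covariate (a compositional effect that
vanishes at genome scale; the tests plant balanced effects where this
matters).

## Numerical choices

- NB IRLS at fixed `theta`: tolerance 1e-8, at most 100 iterations,
  step-halving, linear predictors capped at ±30 to prevent overflow.
- `theta` profile optimization on `[1e-3, 1e5]`; estimates at the upper
  bound indicate effectively Poisson counts.
- ASE BFGS: relative tolerance 1e-12, analytic digamma gradients.
- Permutation-FDR threshold grid: 0.1 to 0.1 + max LOD in steps of 0.01.
- All randomness flows from explicit integer seeds; repeated runs are
  bit-identical.
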