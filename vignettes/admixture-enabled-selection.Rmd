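---
title: "Detecting admixture-enabled selection from local-ancestry calls"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting admixture-enabled selection from local-ancestry calls}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(admixscan)
```

## The question

Recently admixed populations — for example Latin American populations formed
within the last ~20 generations from African, European and Native American
source populations — offer a distinctive window on rapid adaptation. Admixture
introduces ancestry-specific haplotypes at intermediate frequency; if one of
them carries a variant favored in the new environment, selection can push the
local ancestry fraction at that locus away from the genome-wide background
much faster than new mutations could spread. `admixscan` implements a screen
for this *admixture-enabled selection* from phased local-ancestry calls
(RFMix-style output), with no genotype data required.

## The statistics

**Single-locus scan.** For each gene and population, a haplotype is assigned
to ancestry $A$ only if every local-ancestry tract overlapping the gene
interval has ancestry $A$ — haplotypes that switch ancestry inside the gene or
carry an unassigned (sub-confidence) segment are excluded from both the
numerator and the denominator. With $h_\mathrm{anc}$ assigned haplotypes of a
given ancestry out of $h_\mathrm{tot}$ total, the gene's ancestry fraction is
$f_\mathrm{anc} = h_\mathrm{anc} / h_\mathrm{tot}$, standardized against the
genome-wide distribution of gene-level fractions:

$$ z_\mathrm{anc} = \frac{f_\mathrm{anc} - \mu_\mathrm{anc}}{\sigma_\mathrm{anc}}, $$

with one-sided normal $p$-values for enrichment and depletion. Genes whose
$h_\mathrm{tot}$ falls outside one standard deviation of the genome-wide mean
are excluded from the genome-wide moments and from cross-population
combination (see *Design choices*).

**Cross-population combination.** True targets of selection should replicate
across independently admixed populations. Evidence is combined with Fisher's
method, $F_\mathrm{CS} = -2 \sum_{i=1}^{k} \ln P_i$, tested against
$\chi^2_{2k}$, and corrected by Benjamini–Hochberg FDR at $q < 0.05$.
Enrichment and depletion are combined separately: the one-sided $p$-values
keep opposite-direction signals from reinforcing each other across
populations.

**Admixture nulls.** Two simulation routes calibrate the combined score.
The *gene-wise* null redraws each gene's $h_\mathrm{tot}$ haplotype
ancestries iid from the population's genome-wide fractions, re-standardizes
within the replicate, and recombines across populations; it is fast and
carries no linkage. The *Wright–Fisher* null simulates whole admixed
populations forward — single-ancestry founders in the genome-wide
proportions, $N$ diploids, discrete generations, Poisson crossovers on the
genetic map — and pushes each replicate through the identical scan; it
carries both drift and linkage. Empirical $p$-values use the add-one
estimator $p = (1 + \#\{\mathrm{null} \ge \mathrm{obs}\}) / (1 + N)$, which
never returns zero; a max-statistic mode pools per-replicate genome-wide
maxima for family-wise control.

**Polygenic ancestry enrichment.** For a trait gene set, $\mathrm{PAE} =
\sum z_\mathrm{anc}$ over the set's genes. Significance comes from 10,000
size-matched random sets drawn without replacement from the same retained
universe: $z_\mathrm{PAE} = (\mathrm{PAE}_\mathrm{obs} - \mu_\mathrm{PAE}) /
\sigma_\mathrm{PAE}$, tested two-sided (both enriched and depleted tails are
of interest), FDR-corrected within each (population, ancestry) family. Traits
significant with the same ancestry and direction in at least two populations
form the consensus list.

**Selection model.** Observed enrichment is translated into a selection
coefficient with a tri-allelic recursive model: the three allelic states are
the ancestry components, the favored ancestry haplotype has genic
(multiplicative) fitness $1+s$, and one generation maps $p \mapsto
p(1+s)/(1+sp)$. The model starts from the genome-wide background fraction and
runs $t$ generations; because the map $s \mapsto z$ is strictly increasing,
bisection inverts an observed $z_\mathrm{anc}$ to $\hat{s}$ (to $10^{-8}$).
The recursion has the closed form $p_t/(1-p_t) = (1+s)^t\, p_0/(1-p_0)$,
which the tests verify to $10^{-10}$. Estimates are upper bounds: drift and
pre-admixture structure also move local ancestry, and the model credits all
of it to selection.

## The synthetic cohort generator

Real local-ancestry panels are large and access-controlled, so the package
ships a generator that emulates their statistical structure with known ground
truth:

- **Tract structure.** Along each haplotype, breakpoints form a Poisson
  process of rate $g$ per Morgan ($g$ = generations since admixture; default
  10, a lower-bound estimate for Latin American populations) and tract
  ancestries are iid draws from the population's genome-wide fractions
  $\theta$ — the classic pulse-admixture approximation, chosen because it
  gives closed-form expectations for every test. The Wright–Fisher simulator
  is the mechanistic alternative when pedigree-level drift matters.
- **Confidence filtering.** Each tract is independently relabelled
  `UNASSIGNED` with probability $u$ (default 0.02), emulating the dropped
  sub-confidence calls of a conservatively thresholded local-ancestry run.
- **Injected enrichment.** Inside chosen intervals the tract-ancestry
  probabilities are reweighted so the expected local fraction of a target
  ancestry equals $f_\mathrm{target}$; breakpoint density is untouched, so
  the injection changes exactly the quantity the scan measures and nothing
  else.
- **Negative-control traits.** Random trait sets are drawn from genes
  *outside* the injected intervals. They are the null traits of the
  polygenic test; drawing them across planted loci would contaminate the
  controls with true signal, and the screen would (correctly) flag them.

Two preset configurations are used throughout. The *neutral calibration
cohort* (`cohort_config()`) spreads 200 genes over a ~26-Morgan map — a
single concatenated map standing in for a genome-wide gene universe — so
neighboring genes are nearly independent and genome-wide moments are well
estimated. The *demo cohort* (`demo_cohort_config()`) is one 100-Mb
chromosome at 1 cM/Mb with 200 genes 0.5 Mb apart, where neighboring genes
are strongly linked (mean tract length 10 cM at $g = 10$), plus one 5-Mb
injected African-enrichment region ($f_\mathrm{target} = 0.45$ against a
background of 0.25) spanning ten genes — an MHC-like selected region. All
four demo populations share the 0.25 African fraction and differ in their
European/Native American profiles, mirroring the qualitative spread of real
Latin American cohorts.

What passing tests on these cohorts do *not* show: the generator has no
reference-panel bias, no correlated ancestry-call errors (unassignment is
independent per tract), no variable recombination hotspots unless a
piecewise map is supplied, and no background selection. Calibration on real
panels should be re-checked with the Wright–Fisher route and the empirical
nulls rather than assumed.

## Design choices

- **$h_\mathrm{tot}$ filter across populations.** The filter keeps genes
  with $h_\mathrm{tot}$ within one SD of the genome-wide mean — by
  construction roughly the central two thirds of genes per population.
  Requiring this in *every* population compounds to keeping only ~20% of
  genes with four populations and regularly discards genuinely enriched
  loci (selection itself does not perturb $h_\mathrm{tot}$, but the band is
  tight and membership is nearly independent across populations). The
  default therefore requires the filter to pass in *at least one*
  population (`finalize_gene_universe(rule = "any")`); the strict
  every-population rule is available as `rule = "every"`.
- **Sidedness.** One-sided $p$-values per direction, combined separately.
  Two-sided combination would mix enrichment in one population with
  depletion in another — the opposite of the replication logic the
  combination is meant to encode. Both directions are always reported.
- **Moments.** $\sigma_\mathrm{anc}$ and $\sigma_{h_\mathrm{tot}}$ use the
  $n-1$ (sample) denominator; stated so results are bit-reproducible.
- **Degenerate ancestries.** An ancestry with $\sigma_\mathrm{anc} = 0$
  (absent or fixed in a population) gets flagged `NA` scores with a warning
  and is skipped in combination — never an error that aborts the screen.
- **FDR families.** Combined scores are corrected across all gene ×
  ancestry rows within a direction; PAE within each (population, ancestry)
  family. The normal-theory PAE $p$ is primary (the permutation moments
  feed $z_\mathrm{PAE}$), with the empirical rank $p$ reported alongside.
- **LD pruning of trait sets.** Without genotypes, $r^2$-based pruning is
  replaced by greedy physical-distance pruning
  (`distance_prune_geneset()`, default 250 kb); pre-pruned GMT files pass
  through untouched.
- **Wright–Fisher conventions.** Monoecious random mating with selfing
  (parents drawn uniformly with replacement), no crossover interference
  (pure Poisson on the genetic map), largest-remainder rounding of the
  founding composition, and `-1`-coded unassignment never generated (the
  simulator models true ancestry, not caller uncertainty).
- **Selection-model form.** The recursion uses genic selection with the two
  non-favored ancestries selectively equivalent — the minimal standard
  choice for haplotype-frequency dynamics; $t$ defaults to 20 generations
  (the approximate age of the admixed populations), and both $t$ and the
  starting frequency are exposed because the appropriate values depend on
  the cohort.
- **Seeding.** Every stochastic stage takes a seed; the pipeline derives
  per-stage seeds by hashing stage labels into the global seed
  (`derive_seed()`), so stages are individually reproducible and two stages
  never share a stream.

## Numerical notes and problem sizes

Tract coordinates are 0-based half-open integers throughout (BED
convention); msp windows are read as half-open and adjacent equal-ancestry
windows merge into maximal tracts, making tract identity canonical and
round trips exact. Genetic positions come from a piecewise-linear map
(constant 1 cM/Mb imputed when absent). Gene--tract intersection uses
binary search over tract starts, so a scan is $O((n_\mathrm{hap} + m)\log
\cdot)$ per population. One-sided $p$-values are floored at `1e-320` inside
the null simulators to keep $\ln p$ finite; `fisher_score()` itself refuses
$p = 0$.

The validation suite runs at the sizes the statistics require rather than
token sizes: 1,000 random vectors against the closed-form $\chi^2$
survival; 100 random panels against per-base brute-force counting; a
four-population neutral cohort (200 genes, $n = 100$ diploids each) for
calibration with a $\ge 2\times10^4$-value null pool; 200 Wright–Fisher
replicates at $N = 100$, $g = 10$ (plus one $N = 10{,}000$ run for the
drift comparison); 10,000-permutation PAE nulls with 1,000 null traits; and
50 independently seeded end-to-end demo cohorts for signal recovery.

## Known limitations

- The pulse-admixture generator draws tract ancestries independently given
  breakpoints; real panels show correlated ancestry along chromosomes
  beyond tract scale (assortative mating, continuous migration).
- The normal approximation for gene-level $p$-values ignores the
  discreteness of $f_\mathrm{anc}$ at small $h_\mathrm{tot}$; an exact
  binomial alternative is deliberately not substituted because the
  z-standardization is the screen's defining statistic.
- $\hat{s}$ carries no confidence interval and inherits every caveat of the
  deterministic recursion (no drift, no dominance, constant $s$).
- The iHS overlay consumes externally computed score tracks; the package
  does not compute haplotype-homozygosity statistics.
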