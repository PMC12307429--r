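---
title: "Core collections and SNP fingerprints from synthetic genotype panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Core collections and SNP fingerprints from synthetic genotype panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

`snpcore` implements the computational workflow used to condense a
germplasm collection into a small *core collection* and a minimal
*SNP fingerprinting panel*: genotype simulation, variant filtering,
population structure analysis, diversity statistics, greedy
coverage-based core selection, and genetic-algorithm panel selection.
This vignette documents the underlying models and the numerical choices
the package makes.

```{r setup}
library(snpcore)
```

## The synthetic population model

Real genotyping panels are large and access-restricted, so the package
ships a generator whose populations have *known truth*: generating
allele frequencies, subpopulation labels, and injected filter failures
are all recoverable, which makes every downstream method testable
against ground truth.

Allele frequencies follow the **Balding–Nichols model**. An ancestral
frequency $p_l$ is drawn per locus (uniform above a configurable MAF
floor), and each of $K$ subpopulations draws its own frequency from

$$p_{kl} \sim \mathrm{Beta}\!\left(p_l\frac{1-F}{F},\;
(1-p_l)\frac{1-F}{F}\right),$$

which has mean $p_l$ and variance $F\,p_l(1-p_l)$. The drift parameter
$F$ therefore plays the role of the expected $F_{ST}$ between
subpopulations; the package's tests verify that Hudson's ratio-of-
averages estimator applied to the generated frequencies recovers $F$.

Genotypes are diploid dosages $g \in \{0, 1, 2\}$ drawn as
$\mathrm{Binomial}(2, p_{kl})$. A configurable fraction of accessions is
*admixed*: such an accession draws a home-subpopulation weight
$w \sim \mathrm{U}(0.5, 1)$ and picks, locus by locus, its home
subpopulation with probability $w$ and a foreign one otherwise. This
produces individuals intermediate between groups without introducing a
third frequency vector, and $w \ge 0.5$ keeps the home label
meaningful. Missing calls are injected uniformly at a configurable
rate, and the generator redraws any accession whose genotype row
collides with another (erroring loudly if a degenerate configuration
makes distinctness impossible), so fingerprinting is always
well-posed.

The default configuration — 100 accessions, 2 subpopulations,
$F = 0.1$, 5,000 SNPs plus 500 InDels, MAF floor 0.05, 5% missingness
— defines the package's reference study scale; all benchmarks and the
worked examples below use it.

```{r}
cfg <- pop_config(seed = 1)
gm <- simulate_population(cfg)
dim(gm$dosages)
```

## Variant-level and site-level filtering

`write_vcf()` emits VCF v4.2 with the usual quality annotations (QD,
SOR, FS, MQ, MQRankSum, ReadPosRankSum) and `simulate_info()` can
inject failures with truth labels. `apply_hard_filters()` implements
the standard GATK-style hard thresholds — for SNPs
`QD < 2.0 || QUAL < 30.0 || SOR > 3.0 || FS > 60.0 || MQ < 40.0 ||
MQRankSum < -12.5 || ReadPosRankSum < -8.0`, with the analogous InDel
set — with two deliberate conventions: comparisons are strict (a record
with QD exactly 2.0 passes) and absent annotations never fail a record.

`site_filter()` then keeps biallelic SNPs with MAF $\ge 0.05$ and
missingness $\le 20\%$; both boundaries are inclusive, and an audit
table records one reason per dropped locus (MAF first, then
missingness, then biallelic status).

## Distances, trees and structure

The accession-by-accession distance is the mean squared allele-sharing
difference over loci observed in both accessions,

$$d(i,j) = \frac{1}{|L_{ij}|}\sum_{l \in L_{ij}}
\left(\frac{g_{il} - g_{jl}}{2}\right)^2 \in [0, 1],$$

from which `nj_tree()` builds a neighbor-joining tree (negative
branches clamped to zero) and `bootstrap_support()` attaches clade
support from locus-resampled replicates. The genomic relationship
matrix follows VanRaden,

$$G_{ij} = \frac{1}{m}\sum_l
\frac{(g_{il} - 2p_l)(g_{jl} - 2p_l)}{2p_l(1-p_l)},$$

with missing dosages mean-imputed to $2p_l$; `pca_grm()`
eigendecomposes $G$ and scales coordinates by the square roots of the
eigenvalues.

```{r}
gf <- site_filter(gm)
pc <- pca_grm(grm(gf), k = 2)
head(pc$variance_explained, 2)
```

## Diversity indices

`locus_diversity()` reports, per locus and averaged: observed allele
count $N_a$, effective allele count $N_e = 1/\sum p^2$, observed
heterozygosity $H_o$, expected heterozygosity $H_e = 1 - \sum p^2$,
Shannon's index $I = -\sum p \ln p$, Nei's unbiased
$H = \frac{2n}{2n-1} H_e$, and the percentage of polymorphic loci
(PLN). Group comparisons use Welch's unequal-variance $t$-test over
per-locus values.

`sampling_evaluation()` re-estimates these indices on random fractions
(10/25/50/75/100%) of the core and the reserve. Fractional sample
counts are **floored** (25% of 22 accessions samples 5, not 6); this
matches how such sampling tables are conventionally reported and is
applied consistently.

## Greedy core selection

A core collection should preserve the genotype classes present in the
full collection. For each retained locus, the classes
$\{0, 1, 2\}$ actually observed define the coverage universe;
`genotype_coverage()` scores a subset by the percentage of
(locus, class) pairs it captures. This objective is a coverage
function — monotone and submodular — so `greedy_core()` adds, at each
step, the accession with the largest marginal gain (smallest index on
ties). Submodularity is asserted on every run (marginal gains must be
non-increasing) and guarantees the classical $(1 - 1/e)$ approximation
bound, which the test suite checks against exhaustive optima on small
instances. Stopping rules: a fixed size budget (always spent in full),
a coverage target, or a marginal-gain floor.

```{r}
core <- greedy_core(gf, target_size = 22)
core$final_coverage
```

## Minimal fingerprinting panels

A fingerprint panel is a set of SNPs whose dosage codes (written
A/H/B for 0/1/2) distinguish every pair of accessions.
`candidate_filter()` restricts to biallelic SNPs with MAF $\ge 0.05$
and **zero** missing calls, so every panel read is informative.
Finding the minimum discriminating set is NP-hard (it is set cover),
so the package offers three selectors:

- `exhaustive_min()` — guaranteed minimum, guarded to $\le 20$
  candidates;
- `greedy_select()` — the standard set-cover greedy with its
  $1 + \ln(\text{pairs})$ guarantee;
- `ga_select()` — a genetic algorithm over bitmask chromosomes with
  fitness $\text{(fraction of pairs resolved)} - \lambda\,|S|$,
  $\lambda = 1/n_{\text{candidates}}$.

The GA uses population 200, 300 generations, tournament selection of
size 3, uniform crossover at rate 0.9, per-bit mutation at rate $1/n$,
and elitism 2. Two additions improve robustness without changing the
search semantics: chromosomes are initialized sparsely (16 set bits
each), which starts the search near the interesting region of small
panels, and the run stops early after 60 generations without fitness
improvement. The best individual is greedily repaired to full pair
resolution if needed and then pruned so that no single locus can be
removed — the returned panel is always valid and locally minimal. Pair
resolution counting is the hot loop and is implemented in C++ with
early exit per pair.

```{r}
cand <- candidate_filter(simulate_population(pop_config(seed = 1,
                                                        missing_rate = 0.02)))
length(cand)
```

## Reproducibility

All stochastic steps are seeded. A single pipeline seed is expanded
into independent per-stage seeds via
`stage_seed(seed, stage) = (seed + 7919 \cdot stage) \bmod 2^{31}-1`,
and every seeded routine saves and restores the caller's RNG state.
`run_pipeline()` orchestrates the eight stages from a YAML or list
config and writes a manifest with MD5 checksums of every artifact, so
two runs with the same config are byte-identical.

## Limitations

- The generator models two-way admixture by locus-wise ancestry
  switching; it does not simulate linkage disequilibrium, so methods
  that exploit LD cannot be studied with it.
- InDel genotypes are simulated with the same dosage model as SNPs;
  only their VCF representation (anchored REF/ALT) differs.
- The GA is a heuristic: the package verifies agreement with the
  exhaustive optimum on small instances, but on large candidate sets
  only local minimality (pruning) is guaranteed.
- Distances treat dosages additively; no allele-size or multi-allelic
  distance is implemented because the site filter restricts analysis
  to biallelic SNPs.
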