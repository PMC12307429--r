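# snpcore

Core-collection selection and SNP fingerprinting from genotype data.

Germplasm banks hold far more accessions than can be phenotyped or
maintained intensively. Two standard condensations address this:

- a **core collection** — a small subset of accessions that preserves
  the genetic diversity of the whole collection, scored here as the
  percentage of per-locus genotype classes (homozygous reference,
  heterozygous, homozygous alternate) that the subset captures; and
- a **fingerprint panel** — a minimal set of SNPs whose genotype codes
  uniquely distinguish every accession, for variety identification and
  seed-lot authentication.

`snpcore` implements the full post-variant-calling workflow: VCF
reading and GATK-style hard filtering, site filtering
(MAF ≥ 0.05, missingness ≤ 20%, biallelic SNPs), neighbor-joining
trees with locus-bootstrap support, a VanRaden genomic relationship
matrix with PCA, per-locus diversity indices
(Na, Ne, Ho, He, Shannon's I, Nei's unbiased H, PLN) with Welch
comparisons, greedy coverage-maximizing core selection, and
genetic-algorithm selection of minimal discriminating SNP panels. A
Balding–Nichols two-subpopulation genotype simulator with known truth
(generating frequencies, subpopulation labels, injected filter
failures) makes every stage testable without external data.

## The two selection algorithms

**Greedy core selection.** For each locus, the genotype classes
observed in the full collection define a coverage universe; a subset's
coverage is the percentage of (locus, class) pairs it captures. This
objective is monotone submodular, so the greedy algorithm — repeatedly
add the accession with the largest marginal gain — carries the
classical (1 − 1/e) approximation guarantee, and the implementation
asserts diminishing marginal gains on every run. Stopping rules: fixed
size, coverage target, or marginal-gain floor.

**GA fingerprint selection.** Finding the minimum SNP set that
resolves all accession pairs is set cover, so `snpcore` combines a
genetic algorithm (bitmask chromosomes, fitness = resolved pair
fraction − |panel|/n_candidates, tournament selection, uniform
crossover, elitism, sparse initialization, stagnation stop) with a
greedy repair and a pruning pass that guarantees the returned panel is
valid and locally minimal. An exhaustive solver (≤ 20 candidates) and
the plain set-cover greedy are included as references; pair counting
runs in C++.

## Worked example

```r
library(snpcore)

cfg <- pop_config(n_accessions = 100, n_snps = 5000, n_indels = 500,
                  fst = 0.1, seed = 42)
gm <- simulate_population(cfg)
gm
#> genotype_matrix: 100 accessions x 5500 loci
#>   missing calls: 5.03%; locus metadata: chrom, pos, ref, alt, type

gf <- site_filter(gm)
gf
#> genotype_matrix: 100 accessions x 4654 loci
#>   missing calls: 5.03%; locus metadata: chrom, pos, ref, alt, type

core <- greedy_core(gf, target_size = 22)
core
#> Core collection: 22 accessions, coverage 93.94% (stop: target_size)
head(core$ids)
#> [1] "ACC092" "ACC013" "ACC053" "ACC030" "ACC069" "ACC021"
```

Twenty-two accessions (22% of the collection) retain about 94% of all
genotype classes. For fingerprinting, candidates must be biallelic,
common (MAF ≥ 0.05) and completely observed, so we simulate a
lower-missingness panel:

```r
cand_gm <- simulate_population(pop_config(seed = 42, missing_rate = 0.02))
cand <- candidate_filter(cand_gm)
length(cand)
#> [1] 602

panel <- ga_select(cand_gm, cand, ga_params(length(cand), seed = 42))
panel
#> Fingerprint panel (ga): 7 loci, resolved fraction 1.0000

fp <- fingerprint_table(cand_gm, panel$loci)
fp$codes[1:4]
#>    ACC001    ACC002    ACC003    ACC004
#> "AHHHABH" "HHAHAHA" "AHHHHHA" "HHABHBA"
```

Seven SNPs suffice to give each of the 100 accessions a unique A/H/B
barcode.

The whole workflow — simulation (or an input VCF), variant summary,
filtering, tree, PCA, core, diversity evaluation, fingerprint — also
runs as one seeded, manifest-checksummed pipeline:

```r
run_pipeline(list(output_dir = "run1", seed = 42,
                  core = list(target_size = 22)))
```

See the vignette (`vignettes/core-collections-and-fingerprints.Rmd`)
for the underlying models and numerical conventions.

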