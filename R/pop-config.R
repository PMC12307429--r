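#' Configuration for the synthetic germplasm population generator
#'
#' Bundles the knobs of the two-level simulation model: loci receive an
#' ancestral allele frequency, each subpopulation drifts away from it under a
#' Balding--Nichols model with drift parameter `fst`, and diploid genotypes
#' are then drawn per accession with independent per-call missingness.
#'
#' @param n_accessions Number of accessions (samples) to simulate.
#' @param n_snps Number of SNP loci.
#' @param n_indels Number of InDel loci (alt/ref lengths differ by
#'   1..`indel_max_len` bases).
#' @param n_subpops Number of diverged subpopulations.
#' @param fst Balding--Nichols drift parameter in (0, 1); subpopulation
#'   frequencies are Beta-distributed around the ancestral frequency `p` with
#'   variance `fst * p * (1 - p)`, so the expected Hudson FST between
#'   subpopulations is approximately `fst`.
#' @param admixture_fraction Proportion of accessions given locus-wise mixed
#'   ancestry rather than a single source subpopulation.
#' @param maf_floor Lower bound of the ancestral allele-frequency draw; keeps
#'   simulated loci away from fixation so the MAF site filter is exercised
#'   near its threshold rather than trivially.
#' @param missing_rate Per-call probability of a missing genotype.
#' @param indel_max_len Maximum simulated InDel length in bases.
#' @param chrom_count Number of chromosomes loci are spread over.
#' @param seed Integer seed; all generator stages derive their streams from
#'   it, so a fixed seed reproduces the dataset bit for bit.
#'
#' @return An object of class `pop_config` (a validated list).
#' @examples
#' cfg <- pop_config(n_accessions = 20, n_snps = 100, n_indels = 10, seed = 1)
#' @export
pop_config <- function(n_accessions = 100, n_snps = 5000, n_indels = 500,
                       n_subpops = 2, fst = 0.1, admixture_fraction = 0.1,
                       maf_floor = 0.05, missing_rate = 0.05,
                       indel_max_len = 30, chrom_count = 8, seed = NULL) {
  stopifnot(n_accessions >= 1, n_snps >= 0, n_indels >= 0,
            n_snps + n_indels >= 1, chrom_count >= 1, indel_max_len >= 1)
  if (!(fst > 0 && fst < 1))
    stop("`fst` must lie strictly in (0, 1), got ", fst)
  if (!(missing_rate >= 0 && missing_rate < 0.2))
    stop("`missing_rate` must lie in [0, 0.2), got ", missing_rate)
  if (!(maf_floor >= 0 && maf_floor <= 0.5))
    stop("`maf_floor` must lie in [0, 0.5], got ", maf_floor)
  if (n_subpops < 1) stop("`n_subpops` must be >= 1")
  if (!(admixture_fraction >= 0 && admixture_fraction <= 1))
    stop("`admixture_fraction` must lie in [0, 1]")
  structure(list(
    n_accessions = as.integer(n_accessions),
    n_snps = as.integer(n_snps),
    n_indels = as.integer(n_indels),
    n_subpops = as.integer(n_subpops),
    fst = fst,
    admixture_fraction = admixture_fraction,
    maf_floor = maf_floor,
    missing_rate = missing_rate,
    indel_max_len = as.integer(indel_max_len),
    chrom_count = as.integer(chrom_count),
    seed = if (is.null(seed)) NULL else as.integer(seed)
  ), class = "pop_config")
}

#' @export
print.pop_config <- function(x, ...) {
  cat("Synthetic population configuration\n")
  cat(sprintf("  %d accessions in %d subpopulation(s), drift fst = %g\n",
              x$n_accessions, x$n_subpops, x$fst))
  cat(sprintf("  %d SNPs + %d InDels on %d chromosomes\n",
              x$n_snps, x$n_indels, x$chrom_count))
  cat(sprintf("  maf_floor = %g, missing_rate = %g, admixture = %g, seed = %s\n",
              x$maf_floor, x$missing_rate, x$admixture_fraction,
              if (is.null(x$seed)) "none" else x$seed))
  invisible(x)
}
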