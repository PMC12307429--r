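#' Simulate per-subpopulation allele frequencies
#'
#' First stage of the generator. Each locus gets an ancestral alternate-allele
#' frequency drawn uniformly on `[maf_floor, 1 - maf_floor]`; each
#' subpopulation then receives a drifted frequency from a Beta distribution
#' with mean `p` and variance `fst * p * (1 - p)` (Balding--Nichols shape
#' parameters `p(1-fst)/fst` and `(1-p)(1-fst)/fst`). Under this model the
#' expected Hudson FST between subpopulations is approximately `fst`.
#'
#' @param config A [pop_config()].
#' @return An object of class `allele_freqs`: list with `ancestral` (numeric
#'   vector, one entry per locus) and `subpop` (loci x subpopulations matrix).
#' @export
simulate_frequencies <- function(config) {
  stopifnot(inherits(config, "pop_config"))
  m <- config$n_snps + config$n_indels
  F <- config$fst
  with_seed(stage_seed(config$seed, 1L), {
    p <- runif(m, config$maf_floor, 1 - config$maf_floor)
    q <- vapply(seq_len(config$n_subpops), function(k)
      rbeta(m, p * (1 - F) / F, (1 - p) * (1 - F) / F),
      numeric(m))
    q <- matrix(q, nrow = m)
    colnames(q) <- paste0("pop", seq_len(config$n_subpops))
    structure(list(ancestral = p, subpop = q), class = "allele_freqs")
  })
}

# chrom/pos/ref/alt metadata for the simulated loci; SNP and InDel loci are
# interleaved along the genome in a deterministic order given the RNG state
simulate_locus_metadata <- function(config) {
  m <- config$n_snps + config$n_indels
  bases <- c("A", "C", "G", "T")
  type <- sample(c(rep("SNP", config$n_snps), rep("INDEL", config$n_indels)))
  chrom <- paste0("chr", sort(rep_len(seq_len(config$chrom_count), m)))
  pos <- integer(m)
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    pos[idx] <- sort(sample.int(10000000L, length(idx)))
  }
  ref <- character(m); alt <- character(m)
  snp <- type == "SNP"
  ref[snp] <- sample(bases, sum(snp), replace = TRUE)
  alt[snp] <- vapply(ref[snp], function(r)
    sample(setdiff(bases, r), 1L), character(1))
  ind <- which(!snp)
  if (length(ind)) {
    len <- sample.int(config$indel_max_len, length(ind), replace = TRUE)
    is_ins <- runif(length(ind)) < 0.5
    anchor <- sample(bases, length(ind), replace = TRUE)
    extra <- vapply(len, function(l)
      paste(sample(bases, l, replace = TRUE), collapse = ""), character(1))
    ref[ind] <- ifelse(is_ins, anchor, paste0(anchor, extra))
    alt[ind] <- ifelse(is_ins, paste0(anchor, extra), anchor)
  }
  data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt, type = type,
             stringsAsFactors = FALSE)
}

#' Simulate diploid genotypes for a structured population
#'
#' Accessions are split evenly across subpopulations; a fraction
#' `admixture_fraction` receives locus-wise mixed ancestry (each admixed
#' accession keeps a majority weight `w ~ U(0.5, 1)` on its home
#' subpopulation, each locus drawing its source subpopulation accordingly).
#' Dosages are binomial draws (2 trials at the source-subpopulation
#' frequency); missing calls are injected independently at `missing_rate`.
#' Duplicate genotype rows are re-drawn (bounded retries) so that all
#' accessions are pairwise distinguishable, a precondition of the
#' fingerprinting stage.
#'
#' @param freqs An `allele_freqs` object from [simulate_frequencies()].
#' @param config The same [pop_config()].
#' @param max_retries Re-draw attempts per duplicated accession row.
#' @return A `genotype_matrix` whose `samples` metadata records the true
#'   subpopulation (`subpop`) and admixture status of every accession, and
#'   whose locus metadata records chrom/pos/ref/alt/type.
#' @export
simulate_genotypes <- function(freqs, config, max_retries = 20L) {
  stopifnot(inherits(freqs, "allele_freqs"), inherits(config, "pop_config"))
  n <- config$n_accessions
  m <- length(freqs$ancestral)
  K <- config$n_subpops
  with_seed(stage_seed(config$seed, 2L), {
    loci <- simulate_locus_metadata(config)
    pop <- sort(rep_len(seq_len(K), n))
    n_adm <- round(config$admixture_fraction * n)
    admixed <- rep(FALSE, n)
    if (n_adm > 0 && K > 1) admixed[sample.int(n, n_adm)] <- TRUE

    draw_row <- function(i) {
      anc <- rep.int(pop[i], m)
      if (admixed[i]) {
        w <- runif(1, 0.5, 1)
        sw <- runif(m) > w
        if (any(sw))
          anc[sw] <- sample(seq_len(K)[-pop[i]], sum(sw), replace = TRUE)
      }
      g <- rbinom(m, 2L, freqs$subpop[cbind(seq_len(m), anc)])
      if (config$missing_rate > 0)
        g[runif(m) < config$missing_rate] <- NA_integer_
      as.integer(g)
    }

    X <- vapply(seq_len(n), draw_row, integer(m))
    X <- if (m == 1L) matrix(X, ncol = 1L) else t(X)
    keys <- apply(X, 1L, paste, collapse = ",")
    tries <- 0L
    while (anyDuplicated(keys)) {
      if (tries >= max_retries)
        stop("could not make all accession genotype rows pairwise distinct ",
             "after ", max_retries, " retries; the configuration is ",
             "degenerate (too few loci or no polymorphism)")
      for (i in which(duplicated(keys))) {
        X[i, ] <- draw_row(i)
        keys[i] <- paste(X[i, ], collapse = ",")
      }
      tries <- tries + 1L
    }

    rownames(X) <- sprintf("ACC%03d", seq_len(n))
    colnames(X) <- paste0(loci$chrom, "_", loci$pos)
    genotype_matrix(X, loci = loci,
                    samples = data.frame(id = rownames(X),
                                         subpop = pop, admixed = admixed,
                                         stringsAsFactors = FALSE))
  })
}

#' One-call generator for a synthetic population
#'
#' Convenience wrapper chaining [simulate_frequencies()] and
#' [simulate_genotypes()].
#'
#' @inheritParams simulate_frequencies
#' @return A `genotype_matrix`; the generating frequencies are attached as
#'   attribute `"freqs"`.
#' @export
simulate_population <- function(config) {
  freqs <- simulate_frequencies(config)
  gm <- simulate_genotypes(freqs, config)
  attr(gm, "freqs") <- freqs
  gm
}
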