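# Independent brute-force oracles, deliberately written as plain double
# loops over the definitions so they share no code with the implementation.

bf_distance <- function(X) {
  n <- nrow(X)
  D <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    s <- 0; cnt <- 0
    for (l in seq_len(ncol(X))) {
      gi <- X[i, l]; gj <- X[j, l]
      if (!is.na(gi) && !is.na(gj)) {
        s <- s + ((gi - gj) / 2)^2
        cnt <- cnt + 1
      }
    }
    D[i, j] <- s / cnt
  }
  D
}

bf_grm <- function(X) {
  n <- nrow(X); m <- ncol(X)
  p <- numeric(m)
  for (l in seq_len(m)) p[l] <- mean(X[, l], na.rm = TRUE) / 2
  G <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    s <- 0
    for (l in seq_len(m)) {
      gi <- X[i, l]; gj <- X[j, l]
      if (is.na(gi)) gi <- 2 * p[l]
      if (is.na(gj)) gj <- 2 * p[l]
      s <- s + (gi - 2 * p[l]) * (gj - 2 * p[l]) / (2 * p[l] * (1 - p[l]))
    }
    G[i, j] <- s / m
  }
  G
}

# per-locus diversity indices from first principles (allele counting)
bf_diversity <- function(X) {
  m <- ncol(X)
  out <- matrix(NA_real_, m, 6,
                dimnames = list(NULL, c("Na", "Ne", "Ho", "He", "I", "H")))
  for (l in seq_len(m)) {
    g <- X[, l]
    g <- g[!is.na(g)]
    n <- length(g)
    n_ref <- sum(2 - g)
    n_alt <- sum(g)
    p <- c(n_ref, n_alt) / (2 * n)
    pp <- p[p > 0]
    sumsq <- sum(p^2)
    out[l, "Na"] <- length(pp)
    out[l, "Ne"] <- 1 / sumsq
    out[l, "Ho"] <- mean(g == 1)
    out[l, "He"] <- 1 - sumsq
    out[l, "I"] <- -sum(pp * log(pp))
    out[l, "H"] <- (2 * n / (2 * n - 1)) * (1 - sumsq)
  }
  out
}

bf_coverage <- function(X, subset) {
  total <- 0; hit <- 0
  for (l in seq_len(ncol(X))) {
    full <- unique(X[, l]); full <- full[!is.na(full)]
    sub <- unique(X[subset, l]); sub <- sub[!is.na(sub)]
    total <- total + length(full)
    hit <- hit + sum(full %in% sub)
  }
  100 * hit / total
}

bf_resolved <- function(X, loci) {
  n <- nrow(X); cnt <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    diff <- FALSE
    for (l in loci) {
      gi <- X[i, l]; gj <- X[j, l]
      if (!is.na(gi) && !is.na(gj) && gi != gj) { diff <- TRUE; break }
    }
    if (diff) cnt <- cnt + 1
  }
  list(count = cnt, total = n * (n - 1) / 2)
}

# optimum coverage over all subsets of a given size (tiny instances only)
bf_best_coverage <- function(X, k) {
  subs <- combn(nrow(X), k)
  best <- 0
  for (s in seq_len(ncol(subs)))
    best <- max(best, bf_coverage(X, subs[, s]))
  best
}

# random dosage matrix with biallelic-SNP metadata; rows guaranteed distinct
rand_gm <- function(n, m, seed, missing_rate = 0) {
  set.seed(seed)
  repeat {
    X <- matrix(sample(0:2, n * m, replace = TRUE), n, m)
    if (missing_rate > 0) X[runif(n * m) < missing_rate] <- NA
    if (!anyDuplicated(apply(X, 1, paste, collapse = ","))) break
  }
  snp_gm(X)
}

# wrap a dosage matrix with minimal biallelic-SNP locus metadata
snp_gm <- function(X) {
  colnames(X) <- NULL
  m <- ncol(X)
  refalt <- matrix(c("A", "G"), m, 2, byrow = TRUE)
  genotype_matrix(X, loci = data.frame(
    chrom = "chr1", pos = seq_len(m) * 100L,
    ref = refalt[, 1], alt = refalt[, 2], stringsAsFactors = FALSE))
}

default_test_config <- function(seed, ...) {
  defaults <- list(n_accessions = 100, n_snps = 5000, n_indels = 500,
                   n_subpops = 2, fst = 0.1, maf_floor = 0.05,
                   missing_rate = 0.05, seed = seed)
  do.call(pop_config, utils::modifyList(defaults, list(...)))
}
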