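#' Candidate loci for fingerprinting
#'
#' The fingerprint stage uses a stricter filter than the population filter:
#' biallelic SNPs with MAF at least 0.05 (a locus at exactly 0.05 is kept)
#' and a genotype missing rate of exactly zero.
#'
#' @param x A `genotype_matrix` with locus metadata.
#' @param maf_min Minimum MAF (default 0.05).
#' @return Character vector of candidate locus ids.
#' @export
candidate_filter <- function(x, maf_min = 0.05) {
  stopifnot(inherits(x, "genotype_matrix"))
  if (is.null(x$loci)) stop("candidate_filter requires locus metadata")
  keep <- is_biallelic_snp(x$loci) &
    locus_missing_rate(x) == 0 &
    !is.na(maf(x)) & maf(x) >= maf_min
  if (!any(keep))
    stop("no candidate loci pass the fingerprint filter; ",
         "provide a larger or less missing-prone input")
  locus_ids(x)[keep]
}

# pair index table and pair-by-candidate difference matrix
pair_structure <- function(x, candidates) {
  n <- nrow(x$dosages)
  pr <- t(combn(n, 2L))
  d <- x$dosages[, candidates, drop = FALSE]
  D <- d[pr[, 1L], , drop = FALSE] != d[pr[, 2L], , drop = FALSE]
  D[is.na(D)] <- FALSE  # candidates are zero-missing by construction
  list(pairs = pr, D = D)
}

#' Pairs of accessions resolved by a locus subset
#'
#' A pair is resolved when its dosage vectors over the subset differ at at
#' least one locus.
#'
#' @param x A `genotype_matrix`.
#' @param locus_subset Locus ids (or indices) to genotype at.
#' @return List with `count` (resolved pairs) and `total`
#'   (`n * (n - 1) / 2`).
#' @export
resolved_pairs <- function(x, locus_subset) {
  stopifnot(inherits(x, "genotype_matrix"), length(locus_subset) > 0L)
  ps <- pair_structure(x, locus_subset)
  list(count = count_resolved_pairs_cpp(ps$D, seq_len(ncol(ps$D))),
       total = nrow(ps$pairs))
}

# remove loci one at a time while full resolution is preserved; scans
# ascending and restarts after each removal, so the result is deterministic
# and minimal with respect to single-locus removal
prune_panel <- function(D, sel) {
  total <- nrow(D)
  repeat {
    removed <- FALSE
    for (j in sel) {
      s2 <- setdiff(sel, j)
      if (length(s2) &&
          count_resolved_pairs_cpp(D, s2) == total) {
        sel <- s2
        removed <- TRUE
        break
      }
    }
    if (!removed) return(sel)
  }
}

closest_pair_report <- function(x, pairs, unresolved_rows) {
  i <- pairs[unresolved_rows[1L], ]
  paste0(sum(unresolved_rows > 0) , " unresolved pair(s); e.g. ",
         sample_ids(x)[i[1L]], " and ", sample_ids(x)[i[2L]],
         " are identical over all candidates")
}

new_fingerprint_panel <- function(x, candidates, sel, total,
                                  resolved, generations = NA_integer_,
                                  seed = NULL, method = "greedy") {
  loci <- candidates[sel]
  codes <- apply(x$dosages[, loci, drop = FALSE], 1L, function(g)
    paste(c("A", "H", "B")[g + 1L], collapse = ""))
  structure(list(loci = loci, codes = codes,
                 resolved_fraction = resolved / total,
                 ga_generations = generations, seed = seed,
                 method = method),
            class = "fingerprint_panel")
}

#' @export
print.fingerprint_panel <- function(x, ...) {
  cat(sprintf("Fingerprint panel (%s): %d loci, resolved fraction %.4f\n",
              x$method, length(x$loci), x$resolved_fraction))
  invisible(x)
}

#' Greedy discriminating-panel selection
#'
#' Deterministic baseline for [ga_select()]: iteratively adds the candidate
#' locus resolving the largest number of currently-unresolved accession
#' pairs (ties broken by the smallest candidate index) until all pairs are
#' resolved, then prunes redundant loci. By the classical set-cover
#' guarantee the panel is at most a `1 + ln(total pairs)` factor larger than
#' the optimum.
#'
#' @param x A `genotype_matrix`.
#' @param candidates Candidate locus ids from [candidate_filter()].
#' @return A `fingerprint_panel`.
#' @export
greedy_select <- function(x, candidates) {
  stopifnot(inherits(x, "genotype_matrix"), length(candidates) > 0L)
  ps <- pair_structure(x, candidates)
  D <- ps$D
  total <- nrow(D)
  unres <- rep(TRUE, total)
  sel <- integer(0)
  while (any(unres)) {
    g <- colSums(D[unres, , drop = FALSE])
    j <- which.max(g)  # ties -> smallest index
    if (g[j] == 0L)
      stop("no discriminating set exists: ",
           closest_pair_report(x, ps$pairs, which(unres)))
    sel <- c(sel, j)
    unres <- unres & !D[, j]
  }
  sel <- prune_panel(D, sel)
  new_fingerprint_panel(x, candidates, sel, total, total, method = "greedy")
}

#' Genetic-algorithm hyperparameters
#'
#' Settings of the bitmask GA used by [ga_select()]. `size_penalty` is the
#' weight of the panel size in the fitness
#' `f(S) = resolved_fraction(S) - size_penalty * |S|`; at its default
#' `1/n_candidates` a fully discriminating panel always outranks a
#' non-discriminating one.
#'
#' @param n_candidates Number of candidate loci (used for the per-bit
#'   defaults).
#' @param population_size Individuals per generation.
#' @param generations Maximum generations.
#' @param crossover_rate Probability a mating pair undergoes uniform
#'   crossover.
#' @param mutation_rate Per-bit flip probability.
#' @param tournament_size Tournament size for parent selection.
#' @param elitism Top individuals copied unchanged each generation.
#' @param size_penalty Fitness weight of panel size.
#' @param init_bits Expected number of loci switched on in each random
#'   initial individual.
#' @param stagnation Stop early after this many generations without
#'   best-fitness improvement.
#' @param seed Integer seed; fixing it makes [ga_select()] reproducible.
#' @return An object of class `ga_params` (a validated list).
#' @export
ga_params <- function(n_candidates, population_size = 200, generations = 300,
                      crossover_rate = 0.9,
                      mutation_rate = 1 / n_candidates,
                      tournament_size = 3, elitism = 2,
                      size_penalty = 1 / n_candidates,
                      init_bits = 16, stagnation = 60, seed = NULL) {
  stopifnot(population_size >= 2, generations >= 1,
            crossover_rate >= 0, crossover_rate <= 1,
            mutation_rate >= 0, mutation_rate <= 1,
            tournament_size >= 1, elitism >= 0,
            elitism < population_size, init_bits >= 1)
  structure(list(n_candidates = as.integer(n_candidates),
                 population_size = as.integer(population_size),
                 generations = as.integer(generations),
                 crossover_rate = crossover_rate,
                 mutation_rate = mutation_rate,
                 tournament_size = as.integer(tournament_size),
                 elitism = as.integer(elitism),
                 size_penalty = size_penalty,
                 init_bits = init_bits,
                 stagnation = as.integer(stagnation),
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "ga_params")
}

#' Genetic-algorithm selection of a minimal discriminating SNP panel
#'
#' Searches for a small locus subset at which every pair of accessions
#' differs, the basis of a DNA fingerprint. Individuals are bitmasks over
#' the candidates; the GA uses tournament selection, uniform crossover,
#' per-bit mutation and elitism, maximizing
#' `resolved_fraction(S) - size_penalty * |S|`. If the best individual does
#' not resolve every pair, a greedy repair adds the best-resolving loci;
#' a mandatory pruning pass then removes every locus whose removal keeps
#' all pairs resolved, so no returned locus is redundant.
#'
#' @param x A `genotype_matrix`.
#' @param candidates Candidate locus ids from [candidate_filter()].
#' @param params A [ga_params()] object; defaults to
#'   `ga_params(length(candidates))`.
#' @return A `fingerprint_panel` with `resolved_fraction = 1` whenever a
#'   discriminating set exists.
#' @export
ga_select <- function(x, candidates, params = NULL) {
  stopifnot(inherits(x, "genotype_matrix"), length(candidates) > 0L)
  m <- length(candidates)
  if (is.null(params)) params <- ga_params(m)
  stopifnot(inherits(params, "ga_params"))
  ps <- pair_structure(x, candidates)
  D <- ps$D
  total <- nrow(D)
  if (count_resolved_pairs_cpp(D, seq_len(m)) < total)
    stop("no discriminating set exists over the candidates: ",
         closest_pair_report(
           x, ps$pairs,
           which(rowSums(D) == 0L)))
  lam <- params$size_penalty
  fitness <- function(bits) {
    k <- sum(bits)
    if (k == 0L) return(-Inf)
    count_resolved_pairs_cpp(D, which(bits)) / total - lam * k
  }
  with_seed(params$seed, {
    P <- params$population_size
    pop <- matrix(runif(P * m) < params$init_bits / m, nrow = P)
    # every individual needs at least one locus
    empty <- rowSums(pop) == 0L
    if (any(empty)) pop[cbind(which(empty), sample.int(m, sum(empty),
                                                       replace = TRUE))] <- TRUE
    fit <- apply(pop, 1L, fitness)
    best_fit <- max(fit)
    stall <- 0L
    gen_used <- 0L
    for (gen in seq_len(params$generations)) {
      gen_used <- gen
      ord <- order(fit, decreasing = TRUE)
      elite <- pop[ord[seq_len(params$elitism)], , drop = FALSE]
      tourney <- function() {
        cand <- sample.int(P, params$tournament_size, replace = TRUE)
        cand[which.max(fit[cand])]
      }
      n_child <- P - params$elitism
      children <- matrix(FALSE, n_child, m)
      for (c_i in seq_len(n_child)) {
        p1 <- pop[tourney(), ]
        if (runif(1) < params$crossover_rate) {
          p2 <- pop[tourney(), ]
          mask <- runif(m) < 0.5
          child <- ifelse(mask, p1, p2)
        } else child <- p1
        flip <- runif(m) < params$mutation_rate
        child <- xor(child, flip)
        if (!any(child)) child[sample.int(m, 1L)] <- TRUE
        children[c_i, ] <- child
      }
      pop <- rbind(elite, children)
      fit <- apply(pop, 1L, fitness)
      new_best <- max(fit)
      if (new_best > best_fit + 1e-12) {
        best_fit <- new_best
        stall <- 0L
      } else stall <- stall + 1L
      if (stall >= params$stagnation) break
    }
    sel <- which(pop[which.max(fit), ])
    # repair: guarantee full resolution before pruning
    unres_rows <- which(!row_any_selected(D, sel))
    while (length(unres_rows)) {
      g <- colSums(D[unres_rows, , drop = FALSE])
      g[sel] <- 0L
      j <- which.max(g)
      sel <- c(sel, j)
      unres_rows <- unres_rows[!D[unres_rows, j]]
    }
    sel <- prune_panel(D, sort(sel))
    new_fingerprint_panel(x, candidates, sel, total, total,
                          generations = gen_used, seed = params$seed,
                          method = "ga")
  })
}

row_any_selected <- function(D, sel) {
  if (length(sel) == 0L) return(rep(FALSE, nrow(D)))
  rowSums(D[, sel, drop = FALSE]) > 0L
}

#' Exact minimal discriminating panel by enumeration
#'
#' Ground-truth oracle for small instances: enumerates candidate subsets in
#' increasing size (lexicographic within a size) and returns the first fully
#' discriminating one, which is therefore a minimum-cardinality panel with
#' the lexicographically smallest index tuple among ties.
#'
#' @param x A `genotype_matrix`.
#' @param candidates Candidate locus ids; at most 20 (guard against
#'   exponential blowup).
#' @return A `fingerprint_panel`, or `NULL` when no discriminating subset
#'   exists.
#' @export
exhaustive_min <- function(x, candidates) {
  stopifnot(inherits(x, "genotype_matrix"), length(candidates) > 0L)
  m <- length(candidates)
  if (m > 20L) stop("exhaustive_min is guarded to <= 20 candidates, got ", m)
  ps <- pair_structure(x, candidates)
  D <- ps$D
  total <- nrow(D)
  if (count_resolved_pairs_cpp(D, seq_len(m)) < total) return(NULL)
  for (k in seq_len(m)) {
    subsets <- combn(m, k)
    for (s in seq_len(ncol(subsets))) {
      sel <- subsets[, s]
      if (count_resolved_pairs_cpp(D, sel) == total)
        return(new_fingerprint_panel(x, candidates, sel, total, total,
                                     method = "exhaustive"))
    }
  }
  NULL
}

#' Fingerprint code table for a panel
#'
#' Per-accession genotype codes over the panel loci: `A` = homozygous
#' reference (dosage 0), `H` = heterozygous (1), `B` = homozygous alternate
#' (2).
#'
#' @param x A `genotype_matrix`.
#' @param panel A `fingerprint_panel` (or a character vector of locus ids).
#' @param tsv Optional path; writes the loci x accessions code table as TSV.
#' @return List with `table` (loci x accessions character matrix) and
#'   `codes` (named per-accession code strings).
#' @export
fingerprint_table <- function(x, panel, tsv = NULL) {
  loci <- if (inherits(panel, "fingerprint_panel")) panel$loci else panel
  if (!all(loci %in% locus_ids(x)))
    stop("panel loci absent from the matrix: ",
         paste(setdiff(loci, locus_ids(x)), collapse = ", "))
  d <- x$dosages[, loci, drop = FALSE]
  if (anyNA(d)) stop("panel loci contain missing calls")
  tab <- t(matrix(c("A", "H", "B")[d + 1L], nrow = nrow(d),
                  dimnames = dimnames(d)))
  codes <- apply(d, 1L, function(g)
    paste(c("A", "H", "B")[g + 1L], collapse = ""))
  if (!is.null(tsv))
    write.table(tab, tsv, sep = "\t", quote = FALSE, col.names = NA)
  list(table = tab, codes = codes)
}

#' Categorical fingerprint heatmap
#'
#' Simple image of the panel genotypes, one color per genotype class
#' (loci as rows, accessions as columns).
#'
#' @inheritParams fingerprint_table
#' @param col Three colors for dosages 0, 1, 2.
#' @return Invisibly, the dosage submatrix drawn.
#' @export
plot_fingerprint <- function(x, panel,
                             col = c("#4575b4", "#ffffbf", "#d73027")) {
  loci <- if (inherits(panel, "fingerprint_panel")) panel$loci else panel
  d <- x$dosages[, loci, drop = FALSE]
  graphics::image(seq_len(nrow(d)), seq_len(ncol(d)), d, col = col,
                  xlab = "accession", ylab = "locus", axes = FALSE,
                  main = "SNP fingerprint")
  graphics::box()
  invisible(t(d))
}
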