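#' Pairwise squared genetic distances
#'
#' For accessions i and j, the distance is the mean over loci non-missing in
#' both of `((g_i - g_j) / 2)^2`, i.e. the normalized mean squared dosage
#' difference. It is 0 for identical genotypes, 1 for opposite homozygotes at
#' every shared locus, and missing-aware (each pair is averaged over its own
#' shared loci). Computed with cross-products rather than a double loop.
#'
#' @param x A `genotype_matrix` (typically after [site_filter()]).
#' @return A symmetric numeric matrix with zero diagonal and entries in
#'   `[0, 1]`; the per-pair count of shared loci is attached as attribute
#'   `"n_loci"`.
#' @export
squared_distance <- function(x) {
  stopifnot(inherits(x, "genotype_matrix"))
  Y <- x$dosages / 2
  M <- !is.na(Y)
  Y0 <- Y
  Y0[!M] <- 0
  storage.mode(M) <- "double"
  N <- M %*% t(M)                      # shared-locus counts
  if (any(N[upper.tri(N)] == 0)) {
    ij <- which(N == 0 & upper.tri(N), arr.ind = TRUE)[1L, ]
    stop("accessions ", sample_ids(x)[ij[1]], " and ", sample_ids(x)[ij[2]],
         " share no non-missing locus")
  }
  S2 <- (Y0 * Y0) %*% t(M)             # sum of y_i^2 over shared loci
  D <- (S2 + t(S2) - 2 * (Y0 %*% t(Y0))) / N
  D[D < 0] <- 0                        # numerical noise
  diag(D) <- 0
  dimnames(D) <- list(sample_ids(x), sample_ids(x))
  attr(D, "n_loci") <- N
  D
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou--Nei neighbor joining (Studier--Keppler formulation, as implemented
#' in `ape::nj`). Negative branch lengths, which NJ can produce on
#' non-additive data, are clamped to zero; the total clamped length is kept
#' as an attribute.
#'
#' @param d Symmetric distance matrix (e.g. from [squared_distance()]).
#' @return An unrooted `ape::phylo` tree with attribute `"clamped"` giving
#'   the summed absolute value of clamped negative branch lengths.
#' @export
nj_tree <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) < 3L) stop("neighbor joining needs at least 3 samples")
  tr <- ape::nj(d)
  neg <- tr$edge.length < 0
  clamped <- sum(abs(tr$edge.length[neg]))
  tr$edge.length[neg] <- 0
  attr(tr, "clamped") <- clamped
  tr
}

#' Locus-bootstrap support for the neighbor-joining tree
#'
#' Resamples loci (columns) with replacement, rebuilds the distance matrix
#' and NJ tree for each replicate, and scores every internal edge of the main
#' tree by the percentage of replicates containing the same bipartition
#' (unrooted comparison).
#'
#' @param x A `genotype_matrix`.
#' @param n_reps Number of bootstrap replicates.
#' @param seed Integer seed for the resampling.
#' @return The main NJ tree with `node.label` set to the support percentages
#'   (root label empty); the numeric supports are attached as attribute
#'   `"support"`.
#' @export
bootstrap_support <- function(x, n_reps = 1000, seed = NULL) {
  stopifnot(inherits(x, "genotype_matrix"))
  if (n_reps < 1) stop("n_reps must be >= 1")
  main <- nj_tree(squared_distance(x))
  m <- ncol(x$dosages)
  boots <- with_seed(seed, lapply(seq_len(n_reps), function(b) {
    idx <- sample.int(m, m, replace = TRUE)
    Xb <- x$dosages[, idx, drop = FALSE]
    colnames(Xb) <- NULL  # resampling duplicates locus ids
    nj_tree(squared_distance(genotype_matrix(Xb)))
  }))
  counts <- ape::prop.clades(main, boots, rooted = FALSE)
  counts[is.na(counts)] <- 0
  support <- 100 * counts / n_reps
  main$node.label <- c("", format(support[-1L], trim = TRUE))
  attr(main, "support") <- support
  main
}

#' Genomic relationship matrix (VanRaden standardization)
#'
#' `G(i,j) = (1/m) * sum_l (g_il - 2 p_l)(g_jl - 2 p_l) / (2 p_l (1 - p_l))`
#' with `p_l` the alternate-allele frequency over non-missing calls; missing
#' dosages are mean-imputed to `2 p_l` (so they contribute 0 to the
#' standardized cross-product), matching GCTA's default handling.
#'
#' @param x A filtered `genotype_matrix`; monomorphic loci are rejected
#'   (their standardization divides by zero).
#' @return Symmetric samples x samples numeric matrix.
#' @export
grm <- function(x) {
  stopifnot(inherits(x, "genotype_matrix"))
  X <- x$dosages
  p <- colMeans(X, na.rm = TRUE) / 2
  if (any(is.na(p) | p <= 0 | p >= 1))
    stop("monomorphic or all-missing loci in input; run site_filter first")
  Z <- sweep(X, 2L, 2 * p)
  Z[is.na(Z)] <- 0
  Z <- sweep(Z, 2L, sqrt(2 * p * (1 - p)), "/")
  G <- tcrossprod(Z) / ncol(X)
  dimnames(G) <- list(sample_ids(x), sample_ids(x))
  G
}

#' Principal components of a relationship matrix
#'
#' Eigen-decomposition of the (symmetric) GRM; coordinates are the top-k
#' eigenvectors scaled by the square roots of their eigenvalues, and the
#' variance explained by each component is its eigenvalue divided by the
#' matrix trace.
#'
#' @param G Symmetric relationship matrix, e.g. from [grm()].
#' @param k Number of components to return.
#' @return An object of class `pca_result`: list with `coordinates`
#'   (samples x k), `variance_explained` (length-k fractions) and
#'   `eigenvalues`.
#' @export
pca_grm <- function(G, k = 10) {
  G <- as.matrix(G)
  if (k > nrow(G)) stop("k (", k, ") exceeds the number of samples")
  e <- eigen(G, symmetric = TRUE)
  vals <- e$values[seq_len(k)]
  coords <- e$vectors[, seq_len(k), drop = FALSE] %*%
    diag(sqrt(pmax(vals, 0)), k)
  rownames(coords) <- rownames(G)
  colnames(coords) <- paste0("PC", seq_len(k))
  structure(list(coordinates = coords,
                 variance_explained = vals / sum(diag(G)),
                 eigenvalues = vals),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  ve <- 100 * x$variance_explained
  cat(sprintf("PCA: %d samples, %d components\n", nrow(x$coordinates),
              ncol(x$coordinates)))
  cat("  variance explained (%):",
      paste(sprintf("%.1f", head(ve, 5)), collapse = ", "),
      if (length(ve) > 5) "..." else "", "\n")
  invisible(x)
}
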