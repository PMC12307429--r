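# incidence of genotype classes: samples x (locus,class) logical matrix
# restricted to the classes actually present in the full collection;
# missing calls never contribute a class
class_incidence <- function(x) {
  d <- x$dosages
  inc <- cbind(d == 0L, d == 1L, d == 2L)
  inc[is.na(inc)] <- FALSE
  inc[, colSums(inc) > 0L, drop = FALSE]
}

#' Genotype-class coverage of an accession subset
#'
#' For each locus, the full collection defines a set of observed genotype
#' classes (among 0, 1, 2; missing calls contribute nothing). The coverage
#' of a subset is the percentage of those (locus, class) combinations also
#' observed within the subset -- the criterion used by genotype-coverage
#' core-collection selectors.
#'
#' @param x A `genotype_matrix` defining the full collection.
#' @param subset Sample ids or indices of the candidate core.
#' @return Coverage percentage in `[0, 100]`.
#' @export
genotype_coverage <- function(x, subset) {
  stopifnot(inherits(x, "genotype_matrix"))
  if (length(subset) == 0L) stop("subset must be non-empty")
  inc <- class_incidence(x)
  rows <- if (is.character(subset)) match(subset, sample_ids(x)) else subset
  if (anyNA(rows)) stop("unknown sample ids in subset")
  100 * sum(colSums(inc[rows, , drop = FALSE]) > 0L) / ncol(inc)
}

#' Greedy genotype-coverage core-collection selection
#'
#' Starts from the empty set and repeatedly adds the accession that covers
#' the largest number of not-yet-covered (locus, genotype-class)
#' combinations, breaking ties by the smallest sample index. Stops when the
#' requested size is reached, the coverage target is met, or the best
#' remaining gain falls below `gain_floor` (in coverage percentage points).
#' The marginal gains of the greedy sequence are checked to be
#' non-increasing, the signature of the monotone submodular coverage
#' objective.
#'
#' @param x A `genotype_matrix`.
#' @param target_size Stop after selecting this many accessions
#'   (`NULL` = no size cap). When set, the full budget is always spent,
#'   even if later picks add no new coverage.
#' @param target_coverage Stop once coverage (percent) reaches this value;
#'   defaults to 99 when no `target_size` is given and is disabled
#'   otherwise.
#' @param gain_floor Stop when the best achievable gain (percentage points)
#'   drops below this; defaults to 0.01 when no `target_size` is given,
#'   otherwise 0.
#' @return An object of class `core_result`: list with `ids` (ordered
#'   selection), `coverage` (trajectory, percent after each addition),
#'   `final_coverage`, `final_size` and `stop_rule`.
#' @export
greedy_core <- function(x, target_size = NULL, target_coverage = NULL,
                        gain_floor = NULL) {
  stopifnot(inherits(x, "genotype_matrix"))
  # with a size budget the budget governs: zero-gain picks are still made
  # so that target_size = n returns the whole collection
  if (is.null(target_coverage))
    target_coverage <- if (is.null(target_size)) 99 else NA_real_
  if (is.null(gain_floor))
    gain_floor <- if (is.null(target_size)) 0.01 else 0
  if (!is.na(target_coverage) && target_coverage > 100)
    stop("target_coverage cannot exceed 100")
  n <- nrow(x$dosages)
  if (!is.null(target_size)) {
    target_size <- as.integer(target_size)
    stopifnot(target_size >= 1L, target_size <= n)
  }
  inc <- class_incidence(x)
  K <- ncol(inc)
  covered <- rep(FALSE, K)
  avail <- rep(TRUE, n)
  sel <- integer(0)
  traj <- numeric(0)
  gains <- numeric(0)
  rule <- "exhausted"
  repeat {
    g <- rowSums(inc[, !covered, drop = FALSE])
    g[!avail] <- -1
    j <- which.max(g)  # ties -> smallest index
    gain_pct <- 100 * g[j] / K
    if (length(sel) > 0L && gain_pct < gain_floor) { rule <- "gain_floor"; break }
    sel <- c(sel, j)
    avail[j] <- FALSE
    covered <- covered | inc[j, ]
    traj <- c(traj, 100 * sum(covered) / K)
    gains <- c(gains, gain_pct)
    if (!is.null(target_size) && length(sel) >= target_size) {
      rule <- "target_size"; break
    }
    if (!is.na(target_coverage) && traj[length(traj)] >= target_coverage) {
      rule <- "target_coverage"; break
    }
    if (all(!avail)) { rule <- "exhausted"; break }
  }
  # diminishing returns of the greedy sequence (submodularity)
  if (any(diff(gains) > 1e-9))
    stop("internal error: greedy marginal gains increased")
  structure(list(ids = sample_ids(x)[sel], coverage = traj,
                 final_coverage = traj[length(traj)],
                 final_size = length(sel), stop_rule = rule),
            class = "core_result")
}

#' @export
print.core_result <- function(x, ...) {
  cat(sprintf("Core collection: %d accessions, coverage %.2f%% (stop: %s)\n",
              x$final_size, x$final_coverage, x$stop_rule))
  invisible(x)
}

#' Write core-selection outputs
#'
#' @param x A `core_result`.
#' @param ids_path Optional path for the selected ids (one per line).
#' @param trajectory_path Optional path for the size/coverage trajectory TSV.
#' @return `x`, invisibly.
#' @export
write_core_result <- function(x, ids_path = NULL, trajectory_path = NULL) {
  stopifnot(inherits(x, "core_result"))
  if (!is.null(ids_path)) writeLines(x$ids, ids_path)
  if (!is.null(trajectory_path))
    write.table(data.frame(size = seq_along(x$coverage),
                           coverage = x$coverage),
                trajectory_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  invisible(x)
}
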