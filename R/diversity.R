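#' Per-locus genetic diversity indices
#'
#' For each locus, with allele frequencies `p_a` computed over the
#' non-missing calls of the chosen sample group:
#' * `Na` -- number of observed alleles (`p_a > 0`);
#' * `Ne` -- effective allele number `1 / sum(p_a^2)`;
#' * `Ho` -- observed heterozygote fraction among non-missing calls;
#' * `He` -- expected heterozygosity `1 - sum(p_a^2)`;
#' * `I`  -- Shannon's information index `-sum(p_a * ln p_a)`;
#' * `H`  -- unbiased gene diversity `(2n / (2n - 1)) * He` with `n` the
#'   non-missing sample count at the locus.
#'
#' `PLN` is the percentage of loci polymorphic (`Na >= 2`) within the group.
#' Dosage matrices encode two alleles, so `Na <= 2` here.
#'
#' @param x A `genotype_matrix`.
#' @param group Sample ids (or indices) defining the group; default all.
#' @param label Optional group label carried into the report.
#' @return An object of class `diversity_report`: list with `per_locus`
#'   (data.frame of the six indices), `means` (named vector of locus means),
#'   `pln` (percent), `n_samples`, and `group`.
#' @export
locus_diversity <- function(x, group = NULL, label = "all") {
  stopifnot(inherits(x, "genotype_matrix"))
  d <- x$dosages
  if (!is.null(group)) d <- d[group, , drop = FALSE]
  if (nrow(d) == 0L) stop("empty sample group")
  n_nm <- colSums(!is.na(d))
  if (any(n_nm == 0L)) {
    warning(sum(n_nm == 0L), " all-missing locus/loci skipped")
    d <- d[, n_nm > 0L, drop = FALSE]
    n_nm <- n_nm[n_nm > 0L]
  }
  q <- colMeans(d, na.rm = TRUE) / 2   # alternate-allele frequency
  p <- 1 - q
  sumsq <- p * p + q * q
  plnp <- function(f) ifelse(f > 0, -f * log(f), 0)
  per_locus <- data.frame(
    locus = colnames(d),
    Na = (p > 0) + (q > 0),
    Ne = 1 / sumsq,
    Ho = colMeans(d == 1L, na.rm = TRUE),
    He = 1 - sumsq,
    I = plnp(p) + plnp(q),
    H = (2 * n_nm / (2 * n_nm - 1)) * (1 - sumsq),
    row.names = NULL, stringsAsFactors = FALSE)
  idx <- c("Na", "Ne", "Ho", "He", "I", "H")
  structure(list(
    per_locus = per_locus,
    means = vapply(per_locus[idx], mean, numeric(1)),
    pln = 100 * mean(per_locus$Na >= 2L),
    n_samples = nrow(d),
    group = label
  ), class = "diversity_report")
}

#' @export
print.diversity_report <- function(x, ...) {
  cat(sprintf("Diversity report: group '%s', %d samples, %d loci\n",
              x$group, x$n_samples, nrow(x$per_locus)))
  cat(sprintf("  PLN = %.2f%%\n", x$pln))
  print(round(x$means, 4))
  invisible(x)
}

#' Compare diversity between two groups with Welch t-tests
#'
#' For each index, a two-sided two-sample Welch (unequal-variance) t-test on
#' the per-locus values of the two reports. Both reports must have been
#' computed on the same locus set.
#'
#' @param report_a,report_b `diversity_report` objects from
#'   [locus_diversity()].
#' @return data.frame with one row per index: `index`, `mean_a`, `mean_b`,
#'   `t`, `df`, `p_value`.
#' @export
compare_groups <- function(report_a, report_b) {
  stopifnot(inherits(report_a, "diversity_report"),
            inherits(report_b, "diversity_report"))
  if (!identical(report_a$per_locus$locus, report_b$per_locus$locus))
    stop("the two reports cover different locus sets")
  if (nrow(report_a$per_locus) < 2L)
    stop("need at least 2 loci for a t-test")
  idx <- c("Na", "Ne", "Ho", "He", "I", "H")
  rows <- lapply(idx, function(i) {
    a <- report_a$per_locus[[i]]
    b <- report_b$per_locus[[i]]
    tt <- tryCatch(t.test(a, b), error = function(e) NULL)
    data.frame(index = i, mean_a = mean(a), mean_b = mean(b),
               t = if (is.null(tt)) NA_real_ else unname(tt$statistic),
               df = if (is.null(tt)) NA_real_ else unname(tt$parameter),
               p_value = if (is.null(tt)) {
                 if (isTRUE(all.equal(mean(a), mean(b)))) 1 else NA_real_
               } else tt$p.value,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Core-versus-reserve diversity at graded sampling proportions
#'
#' Random sampling evaluation of a core collection: for each proportion `q`
#' (in percent), draws `floor(q% * group size)` accessions uniformly without
#' replacement from the core and from the non-core group (`q = 100` takes
#' every member) and computes the diversity indices of each draw, yielding a
#' two-rows-per-proportion table. Sample counts are truncated (floored)
#' towards zero; a proportion yielding zero samples is skipped with a
#' warning.
#'
#' @param x A `genotype_matrix`.
#' @param core_ids Sample ids of the core collection (subset of
#'   `sample_ids(x)`).
#' @param proportions Sampling proportions in percent.
#' @param seed Integer seed for the draws.
#' @return data.frame with columns `group`, `proportion`, `n_samples`,
#'   `PLN`, `Ho`, `He`, `Na`, `Ne`, `I`, `H`.
#' @export
sampling_evaluation <- function(x, core_ids,
                                proportions = c(10, 25, 50, 75, 100),
                                seed = NULL) {
  stopifnot(inherits(x, "genotype_matrix"))
  ids <- sample_ids(x)
  if (!all(core_ids %in% ids))
    stop("core_ids not found in the matrix: ",
         paste(setdiff(core_ids, ids), collapse = ", "))
  noncore_ids <- setdiff(ids, core_ids)
  groups <- list(core = core_ids, noncore = noncore_ids)
  with_seed(seed, {
    rows <- list()
    for (q in proportions) {
      for (g in names(groups)) {
        pool <- groups[[g]]
        size <- if (q >= 100) length(pool) else floor(q / 100 * length(pool))
        if (size == 0L) {
          warning("proportion ", q, "% yields 0 samples for group ", g,
                  "; skipped")
          next
        }
        draw <- if (size == length(pool)) pool else sample(pool, size)
        rep <- locus_diversity(x, group = draw, label = g)
        rows[[length(rows) + 1L]] <- data.frame(
          group = g, proportion = q, n_samples = size, PLN = rep$pln,
          Ho = rep$means[["Ho"]], He = rep$means[["He"]],
          Na = rep$means[["Na"]], Ne = rep$means[["Ne"]],
          I = rep$means[["I"]], H = rep$means[["H"]],
          stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, rows)
  })
}
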