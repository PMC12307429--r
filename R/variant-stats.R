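#' Classify variants as SNP, insertion, deletion or mixed
#'
#' A record is a SNP when the REF and every ALT allele are single bases; an
#' insertion when every ALT is longer than REF; a deletion when every ALT is
#' shorter; anything else (e.g. a SNP alt next to an InDel alt) is `mixed`.
#'
#' @param ref Character vector of REF alleles.
#' @param alt Character vector of ALT alleles (comma-separated when
#'   multiallelic).
#' @return Character vector in `c("SNP", "insertion", "deletion", "mixed")`.
#' @export
classify_variant <- function(ref, alt) {
  stopifnot(length(ref) == length(alt), all(nchar(ref) >= 1L))
  alts <- strsplit(alt, ",", fixed = TRUE)
  rl <- nchar(ref)
  vapply(seq_along(ref), function(i) {
    al <- nchar(alts[[i]])
    if (rl[i] == 1L && all(al == 1L)) "SNP"
    else if (all(al > rl[i])) "insertion"
    else if (all(al < rl[i])) "deletion"
    else "mixed"
  }, character(1))
}

#' Transition / transversion classification for biallelic SNPs
#'
#' A&harr;G and C&harr;T substitutions are transitions; the four other
#' unordered base pairs are transversions.
#'
#' @inheritParams classify_variant
#' @return Character vector in `c("transition", "transversion")`.
#' @export
ti_tv <- function(ref, alt) {
  if (any(grepl(",", alt, fixed = TRUE)))
    stop("ti_tv is defined for biallelic SNPs only (multiallelic input)")
  if (any(nchar(ref) != 1L | nchar(alt) != 1L))
    stop("ti_tv is defined for SNPs only (non-single-base allele)")
  pair <- paste0(pmin(ref, alt), pmax(ref, alt))
  if (any(!pair %in% c("AC", "AG", "AT", "CG", "CT", "GT")))
    stop("alleles must be A/C/G/T and distinct")
  ifelse(pair %in% c("AG", "CT"), "transition", "transversion")
}

#' Apply GATK-style hard filters
#'
#' Evaluates the kind-specific hard-filter expression used for plant
#' reduced-representation variant calls. For SNPs:
#' `QD < 2.0 || QUAL < 30.0 || SOR > 3.0 || FS > 60.0 || MQ < 40.0 ||
#' MQRankSum < -12.5 || ReadPosRankSum < -8.0`; for InDels:
#' `QD < 2.0 || QUAL < 30.0 || FS > 200.0 || MQ < 40.0 ||
#' ReadPosRankSum < -20.0`. A record fails when ANY clause is true; clauses
#' whose annotation is absent (`NA`) are skipped, i.e. treated as not
#' failing, matching GATK VariantFiltration behavior for missing rank-sum
#' annotations. All inequalities are strict, so boundary values (e.g.
#' `QD = 2.0`) pass.
#'
#' @param variants data.frame with columns `qual`, `QD`, `SOR`, `FS`, `MQ`,
#'   `MQRankSum`, `ReadPosRankSum` (e.g. the `variants` element of
#'   [read_vcf()]); missing columns are treated as all-absent.
#' @param kind `"SNP"` or `"InDel"`; the caller is responsible for matching
#'   it to [classify_variant()].
#' @return data.frame with logical `pass` and character `failed_clauses`
#'   (semicolon-separated clause names, `""` when passing).
#' @export
apply_hard_filters <- function(variants, kind = c("SNP", "InDel")) {
  kind <- match.arg(kind)
  rules <- .hard_filters[[kind]]
  n <- nrow(variants)
  failed <- matrix(FALSE, n, nrow(rules), dimnames = list(NULL, rules$field))
  for (r in seq_len(nrow(rules))) {
    f <- rules$field[r]
    x <- if (f == "QUAL") variants$qual else variants[[f]]
    if (is.null(x)) next
    hit <- if (rules$op[r] == "<") x < rules$value[r] else x > rules$value[r]
    hit[is.na(hit)] <- FALSE
    failed[, r] <- hit
  }
  data.frame(
    pass = rowSums(failed) == 0L,
    failed_clauses = apply(failed, 1L, function(h)
      paste(rules$field[h], collapse = ";")),
    stringsAsFactors = FALSE)
}

#' Variant summary statistics
#'
#' Counts and composition statistics of a variant set: SNP / insertion /
#' deletion counts, biallelic fraction, allele-count histogram, Ti/Tv counts
#' and ratio (biallelic SNPs only), the six unordered substitution-type
#' fractions, an InDel length histogram (bins 1..10 bp and ">10"), and
#' per-chromosome counts with per-kb densities when chromosome lengths are
#' supplied.
#'
#' @param variants data.frame with at least `chrom`, `ref`, `alt` (e.g. from
#'   [read_vcf()]).
#' @param chromosome_lengths Optional named numeric vector of chromosome
#'   lengths in bases; enables the density columns.
#' @return An object of class `variant_summary` (a list).
#' @export
summarize_variants <- function(variants, chromosome_lengths = NULL) {
  cls <- classify_variant(variants$ref, variants$alt)
  n_alt <- lengths(strsplit(variants$alt, ",", fixed = TRUE))
  n_alleles <- n_alt + 1L
  biallelic <- n_alleles == 2L
  bisnp <- biallelic & cls == "SNP"
  titv <- if (any(bisnp)) ti_tv(variants$ref[bisnp], variants$alt[bisnp])
          else character(0)
  ti <- sum(titv == "transition")
  tv <- sum(titv == "transversion")
  pairs <- c("AG", "CT", "AC", "AT", "CG", "GT")
  sub_counts <- setNames(integer(6), pairs)
  if (any(bisnp)) {
    pp <- paste0(pmin(variants$ref[bisnp], variants$alt[bisnp]),
                 pmax(variants$ref[bisnp], variants$alt[bisnp]))
    tab <- table(factor(pp, levels = pairs))
    sub_counts <- setNames(as.integer(tab), pairs)
  }
  is_indel <- cls %in% c("insertion", "deletion")
  indel_len <- integer(0)
  if (any(is_indel)) {
    alts <- strsplit(variants$alt[is_indel], ",", fixed = TRUE)
    rl <- nchar(variants$ref[is_indel])
    indel_len <- unlist(lapply(seq_along(alts), function(i)
      abs(nchar(alts[[i]]) - rl[i])))
  }
  len_bins <- c(as.character(1:10), ">10")
  len_hist <- setNames(integer(11), len_bins)
  if (length(indel_len)) {
    binned <- ifelse(indel_len > 10L, ">10", as.character(indel_len))
    tab <- table(factor(binned, levels = len_bins))
    len_hist <- setNames(as.integer(tab), len_bins)
  }
  per_chrom <- as.data.frame(table(chrom = variants$chrom, class = cls),
                             stringsAsFactors = FALSE)
  if (!is.null(chromosome_lengths)) {
    per_chrom$length_bp <- chromosome_lengths[per_chrom$chrom]
    per_chrom$density_per_kb <- per_chrom$Freq / (per_chrom$length_bp / 1000)
  }
  structure(list(
    snp_count = sum(cls == "SNP"),
    insertion_count = sum(cls == "insertion"),
    deletion_count = sum(cls == "deletion"),
    mixed_count = sum(cls == "mixed"),
    biallelic_fraction = if (length(cls)) mean(biallelic) else NA_real_,
    allele_count_histogram = table(n_alleles),
    ti_count = ti,
    tv_count = tv,
    ti_tv_ratio = if (tv > 0) ti / tv else NA_real_,
    substitution_type_counts = sub_counts,
    substitution_type_fractions = if (sum(sub_counts) > 0)
      sub_counts / sum(sub_counts) else sub_counts * NA_real_,
    indel_length_histogram = len_hist,
    per_chromosome = per_chrom
  ), class = "variant_summary")
}

#' @export
print.variant_summary <- function(x, ...) {
  cat("Variant summary\n")
  cat(sprintf("  SNPs: %d  insertions: %d  deletions: %d  mixed: %d\n",
              x$snp_count, x$insertion_count, x$deletion_count,
              x$mixed_count))
  cat(sprintf("  biallelic fraction: %.4f\n", x$biallelic_fraction))
  cat(sprintf("  Ti/Tv: %d/%d = %s\n", x$ti_count, x$tv_count,
              if (is.na(x$ti_tv_ratio)) "undefined" else
                sprintf("%.3f", x$ti_tv_ratio)))
  invisible(x)
}

#' Write a variant summary to TSV and JSON
#'
#' @param x A `variant_summary`.
#' @param tsv,json Optional output paths; omit either to skip it.
#' @return `x`, invisibly.
#' @export
write_variant_summary <- function(x, tsv = NULL, json = NULL) {
  stopifnot(inherits(x, "variant_summary"))
  if (!is.null(tsv)) {
    flat <- data.frame(
      statistic = c("snp_count", "insertion_count", "deletion_count",
                    "mixed_count", "biallelic_fraction", "ti_count",
                    "tv_count", "ti_tv_ratio"),
      value = c(x$snp_count, x$insertion_count, x$deletion_count,
                x$mixed_count, x$biallelic_fraction, x$ti_count, x$tv_count,
                x$ti_tv_ratio))
    write.table(flat, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(json)) {
    y <- unclass(x)
    y$allele_count_histogram <- as.list(y$allele_count_histogram)
    jsonlite::write_json(y, json, auto_unbox = TRUE, digits = NA,
                         na = "null")
  }
  invisible(x)
}
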