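#' Diploidized genotype dosage matrix
#'
#' The central container of the package: an accessions x loci matrix of
#' alternate-allele dosages in {0, 1, 2}, `NA` for missing calls, together
#' with per-locus metadata (chromosome, 1-based position, REF, ALT) and
#' optional per-sample metadata.
#'
#' @param dosages Integer matrix (samples x loci) with values in
#'   `c(0, 1, 2, NA)`. Row names are sample ids, column names locus ids; if
#'   absent they are generated.
#' @param loci `data.frame` with one row per locus and columns `chrom`,
#'   `pos`, `ref`, `alt` (ALT alleles comma-separated when multiallelic).
#'   May be `NULL` when only dosage-level operations are needed.
#' @param samples Optional `data.frame` of per-sample metadata (first column
#'   ignored for ids; row order must match `dosages`).
#'
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosages, loci = NULL, samples = NULL) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "integer"
  bad <- !(dosages %in% c(0L, 1L, 2L, NA))
  if (any(bad)) stop("dosages must be 0, 1, 2 or NA")
  if (is.null(rownames(dosages)))
    rownames(dosages) <- sprintf("ACC%03d", seq_len(nrow(dosages)))
  if (is.null(colnames(dosages)))
    colnames(dosages) <- sprintf("L%05d", seq_len(ncol(dosages)))
  if (anyDuplicated(rownames(dosages))) stop("duplicate sample ids")
  if (anyDuplicated(colnames(dosages))) stop("duplicate locus ids")
  if (!is.null(loci)) {
    stopifnot(nrow(loci) == ncol(dosages))
    rownames(loci) <- colnames(dosages)
  }
  if (!is.null(samples)) stopifnot(nrow(samples) == nrow(dosages))
  structure(list(dosages = dosages, loci = loci, samples = samples),
            class = "genotype_matrix")
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosages)

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d accessions x %d loci\n",
              nrow(x$dosages), ncol(x$dosages)))
  mr <- mean(is.na(x$dosages))
  cat(sprintf("  missing calls: %.2f%%", 100 * mr))
  if (!is.null(x$loci))
    cat(sprintf("; locus metadata: %s", paste(names(x$loci), collapse = ", ")))
  cat("\n")
  invisible(x)
}

#' Sample and locus identifiers
#' @param x A `genotype_matrix`.
#' @return Character vector of ids.
#' @export
sample_ids <- function(x) rownames(x$dosages)

#' @rdname sample_ids
#' @export
locus_ids <- function(x) colnames(x$dosages)

#' Minor allele frequency per locus
#'
#' Alternate-allele frequency computed over non-missing calls only
#' (denominator `2 * non-missing samples`), folded to `<= 0.5`. Loci with
#' no non-missing call get `NA`.
#'
#' @param x A `genotype_matrix`.
#' @param loci Optional locus ids or indices to restrict to.
#' @return Named numeric vector of MAFs in `[0, 0.5]`.
#' @export
maf <- function(x, loci = NULL) {
  d <- x$dosages
  if (!is.null(loci)) d <- d[, loci, drop = FALSE]
  af <- colMeans(d, na.rm = TRUE) / 2
  af[is.nan(af)] <- NA_real_
  pmin(af, 1 - af)
}

#' Fraction of missing calls per locus
#' @inheritParams maf
#' @return Named numeric vector in `[0, 1]`.
#' @export
locus_missing_rate <- function(x, loci = NULL) {
  d <- x$dosages
  if (!is.null(loci)) d <- d[, loci, drop = FALSE]
  colMeans(is.na(d))
}

is_biallelic_snp <- function(loci) {
  !grepl(",", loci$alt, fixed = TRUE) &
    nchar(loci$ref) == 1L & nchar(loci$alt) == 1L
}

#' Build a genotype matrix from parsed VCF genotypes
#'
#' Converts per-sample diploid GT calls to alternate-allele dosages: the
#' dosage is the number of non-reference alleles in the call, `./.` becomes
#' `NA`. Haploid or higher-ploidy GT strings are rejected.
#'
#' @param vcf A `vcf_data` object from [read_vcf()].
#' @return A `genotype_matrix` with locus metadata carried over.
#' @export
from_vcf <- function(vcf) {
  stopifnot(inherits(vcf, "vcf_data"))
  gt <- vcf$gt
  uniq <- unique(as.vector(gt))
  uniq <- uniq[!is.na(uniq)]
  # strip any trailing FORMAT subfields, keep the GT token
  tok <- sub(":.*$", "", uniq)
  alleles <- strsplit(tok, "[/|]")
  nall <- lengths(alleles)
  if (any(nall != 2L)) {
    bad <- uniq[nall != 2L][1L]
    stop("non-diploid GT call '", bad, "' (locus context: ",
         vcf$variants$chrom[1L], ")")
  }
  dosage_of <- vapply(alleles, function(a) {
    if (any(a == ".")) return(NA_integer_)
    sum(as.integer(a) > 0L)
  }, integer(1))
  names(dosage_of) <- uniq
  d <- matrix(dosage_of[sub(":.*$", "", gt)], nrow = nrow(gt),
              dimnames = dimnames(gt))
  loci <- vcf$variants[, c("chrom", "pos", "ref", "alt")]
  gmat <- t(d)  # samples x loci
  rownames(gmat) <- vcf$samples
  colnames(gmat) <- vcf$variants$id
  genotype_matrix(gmat, loci = loci)
}

#' Population-genetics site filter
#'
#' Applies the standard post-calling quality-control chain to loci: minimum
#' minor allele frequency, maximum genotype missing rate, and (optionally)
#' restriction to biallelic SNPs. Boundary handling follows common
#' VCFtools-style semantics: a locus with MAF exactly `maf_min` is retained
#' ("below" drops), and a locus with missing rate exactly `max_missing` is
#' retained ("exceeding" drops).
#'
#' @param x A `genotype_matrix`.
#' @param maf_min Minimum minor allele frequency (default 0.05). Loci with
#'   undefined MAF (all calls missing) are dropped under this rule.
#' @param max_missing Maximum tolerated fraction of missing calls
#'   (default 0.20).
#' @param biallelic_snps_only Keep only loci whose metadata marks them as
#'   biallelic single-nucleotide variants (default `TRUE`; requires locus
#'   metadata).
#' @return The filtered `genotype_matrix`, with the audit of dropped loci
#'   attached as attribute `"filter_audit"` (a `data.frame` with columns
#'   `locus` and `reason`; the reason recorded is the first failing rule in
#'   the order MAF, missingness, biallelic). Retrieve it with
#'   [filter_audit()].
#' @export
site_filter <- function(x, maf_min = 0.05, max_missing = 0.20,
                        biallelic_snps_only = TRUE) {
  stopifnot(inherits(x, "genotype_matrix"))
  m <- maf(x)
  mr <- locus_missing_rate(x)
  fail_maf <- is.na(m) | m < maf_min
  fail_mis <- mr > max_missing
  if (biallelic_snps_only) {
    if (is.null(x$loci))
      stop("biallelic_snps_only requires locus metadata (chrom/pos/ref/alt)")
    fail_bi <- !is_biallelic_snp(x$loci)
  } else fail_bi <- rep(FALSE, ncol(x$dosages))
  drop <- fail_maf | fail_mis | fail_bi
  reason <- ifelse(fail_maf, "maf",
                   ifelse(fail_mis, "missingness", "biallelic"))[drop]
  audit <- data.frame(locus = locus_ids(x)[drop], reason = reason,
                      stringsAsFactors = FALSE)
  keep <- which(!drop)
  if (length(keep) == 0L)
    warning("site_filter removed every locus; result is empty")
  out <- genotype_matrix(x$dosages[, keep, drop = FALSE],
                         loci = if (is.null(x$loci)) NULL else
                           x$loci[keep, , drop = FALSE],
                         samples = x$samples)
  attr(out, "filter_audit") <- audit
  out
}

#' @rdname site_filter
#' @export
filter_audit <- function(x) attr(x, "filter_audit")

#' Read and write dosage matrices as TSV
#'
#' Rows are accessions, columns locus ids, missing calls written as `"NA"`.
#'
#' @param x A `genotype_matrix`.
#' @param path File path.
#' @return `write_dosage_tsv` returns `path` invisibly; `read_dosage_tsv`
#'   returns a `genotype_matrix` without locus metadata.
#' @export
write_dosage_tsv <- function(x, path) {
  write.table(x$dosages, path, sep = "\t", quote = FALSE, na = "NA",
              col.names = NA)
  invisible(path)
}

#' @rdname write_dosage_tsv
#' @export
read_dosage_tsv <- function(path) {
  d <- as.matrix(read.table(path, sep = "\t", header = TRUE, row.names = 1,
                            check.names = FALSE))
  genotype_matrix(d)
}
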