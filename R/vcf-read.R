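#' Read a VCF file into a variant table and genotype matrix
#'
#' Thin wrapper around `vcfR::read.vcfR` that extracts the fields the
#' downstream stages need: site coordinates and alleles, QUAL, the numeric
#' INFO annotations consumed by the hard filters (absent keys stay `NA`,
#' never 0), and the raw per-sample GT strings.
#'
#' @param path Path to a VCF v4.x file (plain or bgzipped).
#' @return An object of class `vcf_data`: list with
#'   * `variants`: data.frame with `chrom`, `pos`, `id`, `ref`, `alt`,
#'     `qual`, `QD`, `SOR`, `FS`, `MQ`, `MQRankSum`, `ReadPosRankSum`;
#'   * `gt`: character matrix (loci x samples) of GT strings, `NA` = missing;
#'   * `samples`: sample names in column order.
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) stop("VCF file not found: ", path)
  v <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                error = function(e)
                  stop("failed to parse VCF '", path, "': ",
                       conditionMessage(e)))
  fix <- v@fix
  n_rec <- nrow(fix)
  ifields <- c("QD", "SOR", "FS", "MQ", "MQRankSum", "ReadPosRankSum")
  if (n_rec == 0L) {
    variants <- data.frame(chrom = character(0), pos = integer(0),
                           id = character(0), ref = character(0),
                           alt = character(0), qual = numeric(0))
    for (f in ifields) variants[[f]] <- numeric(0)
    gt <- matrix(NA_character_, 0L, 0L)
    samples <- character(0)
    if (ncol(v@gt) > 1L) {
      samples <- colnames(v@gt)[-1L]
      gt <- matrix(NA_character_, 0L, length(samples),
                   dimnames = list(NULL, samples))
    }
    return(structure(list(variants = variants, gt = gt, samples = samples),
                     class = "vcf_data"))
  }
  id <- fix[, "ID"]
  noid <- is.na(id) | id == "."
  id[noid] <- paste0(fix[noid, "CHROM"], "_", fix[noid, "POS"])
  variants <- data.frame(
    chrom = fix[, "CHROM"],
    pos = as.integer(fix[, "POS"]),
    id = id,
    ref = fix[, "REF"],
    alt = fix[, "ALT"],
    qual = suppressWarnings(as.numeric(fix[, "QUAL"])),
    stringsAsFactors = FALSE)
  for (f in ifields)
    variants[[f]] <- suppressWarnings(
      vcfR::extract.info(v, element = f, as.numeric = TRUE))
  gt <- NULL
  samples <- character(0)
  if (!is.null(v@gt) && ncol(v@gt) > 1L) {
    samples <- colnames(v@gt)[-1L]
    gt <- vcfR::extract.gt(v, element = "GT")
    rownames(gt) <- variants$id
  } else {
    gt <- matrix(NA_character_, n_rec, 0L)
  }
  structure(list(variants = variants, gt = gt, samples = samples),
            class = "vcf_data")
}

#' @export
print.vcf_data <- function(x, ...) {
  cat(sprintf("vcf_data: %d records, %d samples\n",
              nrow(x$variants), length(x$samples)))
  invisible(x)
}
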