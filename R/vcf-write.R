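# threshold tables for the GATK-style hard filters; clause fails when the
# annotation is on the wrong side of the bound
.hard_filters <- list(
  SNP = data.frame(
    field = c("QD", "QUAL", "SOR", "FS", "MQ", "MQRankSum", "ReadPosRankSum"),
    op    = c("<",  "<",    ">",   ">",  "<",  "<",          "<"),
    value = c(2.0,  30.0,   3.0,   60.0, 40.0, -12.5,        -8.0),
    stringsAsFactors = FALSE),
  InDel = data.frame(
    field = c("QD", "QUAL", "FS", "MQ", "ReadPosRankSum"),
    op    = c("<",  "<",    ">",  "<",  "<"),
    value = c(2.0,  30.0,   200.0, 40.0, -20.0),
    stringsAsFactors = FALSE)
)

# uniform draw ranges bracketing the thresholds: "pass" values are safely on
# the passing side for BOTH variant kinds, "fail" values just beyond the
# kind-specific threshold
.info_pass_ranges <- list(
  QD = c(5, 35), QUAL = c(50, 1000), SOR = c(0.3, 2.5), FS = c(0, 30),
  MQ = c(45, 60), MQRankSum = c(-3, 3), ReadPosRankSum = c(-3, 3)
)
.info_fail_ranges <- list(
  SNP = list(QD = c(0.1, 1.9), QUAL = c(1, 29), SOR = c(3.1, 6),
             FS = c(61, 150), MQ = c(10, 39), MQRankSum = c(-20, -12.6),
             ReadPosRankSum = c(-15, -8.1)),
  InDel = list(QD = c(0.1, 1.9), QUAL = c(1, 29), FS = c(201, 400),
               MQ = c(10, 39), ReadPosRankSum = c(-30, -20.1))
)

#' Simulate INFO annotations with known filter truth
#'
#' Draws the annotations consumed by [apply_hard_filters()] from two labeled
#' uniform mixtures: "pass-like" values inside ranges that satisfy every
#' clause, and -- for a chosen fraction of records -- one "fail-like" value
#' just beyond a kind-appropriate threshold. The returned truth table makes
#' filter behavior exactly checkable downstream.
#'
#' @param gm A `genotype_matrix` with locus metadata (used to decide whether
#'   each locus is a SNP or an InDel).
#' @param fail_fraction Fraction of records given one failing clause.
#' @param fail_field Optionally force the failing clause to a single
#'   annotation (e.g. `"QD"`); by default the clause is drawn at random among
#'   those defined for the record's kind.
#' @param fail_value Optional fixed value to assign to the failing field
#'   (e.g. `QD = 1.0`); by default drawn from the fail-side range.
#' @param seed Integer seed.
#' @return List with `info` (data.frame of annotation values, one row per
#'   locus) and `truth` (data.frame with `locus`, `kind`, `fail`, `clause`).
#' @export
simulate_info <- function(gm, fail_fraction = 0, fail_field = NULL,
                          fail_value = NULL, seed = NULL) {
  stopifnot(inherits(gm, "genotype_matrix"), !is.null(gm$loci))
  m <- nrow(gm$loci)
  # multiallelic SNPs (comma-separated single-base alts) count as SNP
  allsnp <- vapply(strsplit(gm$loci$alt, ",", fixed = TRUE), function(a)
    all(nchar(a) == 1L), logical(1)) & nchar(gm$loci$ref) == 1L
  kind <- ifelse(allsnp, "SNP", "InDel")
  with_seed(seed, {
    info <- as.data.frame(lapply(.info_pass_ranges, function(r)
      runif(m, r[1], r[2])))
    fail <- rep(FALSE, m)
    clause <- rep(NA_character_, m)
    n_fail <- round(fail_fraction * m)
    if (n_fail > 0) {
      idx <- sample.int(m, n_fail)
      fail[idx] <- TRUE
      for (i in idx) {
        flds <- names(.info_fail_ranges[[kind[i]]])
        f <- if (is.null(fail_field)) sample(flds, 1L) else fail_field
        if (!f %in% flds)
          stop("field '", f, "' has no failing clause for kind ", kind[i])
        r <- .info_fail_ranges[[kind[i]]][[f]]
        info[[f]][i] <- if (is.null(fail_value)) runif(1, r[1], r[2]) else
          fail_value
        clause[i] <- f
      }
    }
    list(info = info,
         truth = data.frame(locus = locus_ids(gm), kind = kind, fail = fail,
                            clause = clause, stringsAsFactors = FALSE))
  })
}

#' Write a genotype matrix as VCF v4.2
#'
#' Emits one record per locus with `GT` calls (`0/0`, `0/1`, `1/1`, `./.`)
#' and the INFO annotations needed by the hard-filter stage. With a fixed
#' seed and `timestamp = FALSE` the output is byte-identical across runs.
#'
#' @param gm A `genotype_matrix` with locus metadata.
#' @param path Output file path (plain text).
#' @param info Optional annotation set from [simulate_info()]; default is an
#'   all-passing draw (seeded from nothing, i.e. the session RNG).
#' @param timestamp Write a `##fileDate` header line (set `FALSE` for
#'   byte-reproducible output).
#' @return `path`, invisibly; the truth table of `info` (if one was
#'   supplied) is attached as attribute `"truth"`.
#' @export
write_vcf <- function(gm, path, info = NULL, timestamp = TRUE) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (is.null(gm$loci))
    stop("write_vcf requires locus metadata (chrom/pos/ref/alt)")
  if (is.null(info)) info <- simulate_info(gm)
  loci <- gm$loci
  n <- nrow(gm$dosages)
  gt_code <- c("0/0", "0/1", "1/1")
  gt <- matrix("./.", nrow = nrow(loci), ncol = n)
  ok <- !is.na(t(gm$dosages))
  gt[ok] <- gt_code[t(gm$dosages)[ok] + 1L]
  fmt <- function(x) sub("\\.?0+$", "", sprintf("%.4f", x))
  ifields <- c("QD", "SOR", "FS", "MQ", "MQRankSum", "ReadPosRankSum")
  info_str <- do.call(paste, c(lapply(ifields, function(f)
    paste0(f, "=", fmt(info$info[[f]]))), sep = ";"))
  body <- cbind(loci$chrom, loci$pos, locus_ids(gm), loci$ref, loci$alt,
                fmt(info$info$QUAL), ".", info_str, "GT", gt)
  hdr <- c("##fileformat=VCFv4.2",
           if (timestamp) paste0("##fileDate=", format(Sys.Date(), "%Y%m%d")),
           "##source=snpcore",
           paste0("##contig=<ID=", unique(loci$chrom), ">"),
           paste0("##INFO=<ID=", ifields,
                  ",Number=1,Type=Float,Description=\"", ifields, "\">"),
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", sample_ids(gm)), collapse = "\t"))
  con <- tryCatch(file(path, "w"),
                  error = function(e) stop("cannot open '", path, "': ",
                                           conditionMessage(e)))
  on.exit(close(con))
  writeLines(hdr, con)
  writeLines(do.call(paste, c(split(body, col(body)), sep = "\t")), con)
  invisible(structure(path, truth = info$truth))
}
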