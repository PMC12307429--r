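make_vcf_text <- function(records, samples = c("S1", "S2", "S3")) {
  c("##fileformat=VCFv4.2",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"),
    records)
}

test_that("VCF round-trip preserves record counts, dosages and truth labels", {
  cfg <- pop_config(n_accessions = 25, n_snps = 300, n_indels = 40, seed = 6)
  gm <- simulate_population(cfg)
  path <- file.path(tempdir(), "rt.vcf")
  write_vcf(gm, path, timestamp = FALSE)
  vcf <- read_vcf(path)
  expect_equal(nrow(vcf$variants), 340L)
  expect_equal(vcf$samples, sample_ids(gm))
  gm2 <- from_vcf(vcf)
  expect_identical(unname(gm2$dosages), unname(gm$dosages))
  # SNP/InDel labels survive the round trip
  cls <- classify_variant(vcf$variants$ref, vcf$variants$alt)
  expect_identical(cls %in% c("insertion", "deletion"),
                   gm$loci$type == "INDEL")
})

test_that("missing genotypes and empty bodies are handled explicitly", {
  p <- file.path(tempdir(), "mini.vcf")
  writeLines(make_vcf_text(
    "chr1\t100\t.\tA\tG\t50\t.\tQD=10\tGT\t./.\t0/1\t1/1"), p)
  vcf <- read_vcf(p)
  gm <- from_vcf(vcf)
  expect_identical(as.vector(gm$dosages), c(NA, 1L, 2L))

  pe <- file.path(tempdir(), "empty.vcf")
  writeLines(make_vcf_text(character(0)), pe)
  vcfe <- read_vcf(pe)
  expect_equal(nrow(vcfe$variants), 0L)

  expect_error(read_vcf(file.path(tempdir(), "nope.vcf")), "not found")

  ph <- file.path(tempdir(), "haploid.vcf")
  writeLines(make_vcf_text("chr1\t100\t.\tA\tG\t50\t.\tQD=10\tGT\t0\t1\t0"),
             ph)
  expect_error(from_vcf(read_vcf(ph)), "non-diploid")
})

test_that("variant classification follows the allele-length definition", {
  expect_equal(classify_variant("A", "G"), "SNP")
  expect_equal(classify_variant("A", "ATTG"), "insertion")
  expect_equal(classify_variant("ATTG", "A"), "deletion")
  expect_equal(classify_variant("A", "G,ATT"), "mixed")
  expect_equal(classify_variant("A", "G,T"), "SNP")  # multiallelic SNP
  expect_equal(classify_variant(c("A", "AC"), c("C", "A")),
               c("SNP", "deletion"))
})

test_that("transition/transversion assignment is exhaustive and guarded", {
  expect_equal(ti_tv("C", "T"), "transition")
  expect_equal(ti_tv("C", "G"), "transversion")
  pairs <- combn(c("A", "C", "G", "T"), 2)
  cls <- ti_tv(pairs[1, ], pairs[2, ])
  expect_equal(sum(cls == "transition"), 2L)
  expect_equal(sum(cls == "transversion"), 4L)
  expect_error(ti_tv("A", "G,T"), "biallelic")
  expect_error(ti_tv("AT", "A"), "SNP")
})

test_that("hard filters follow the printed expressions with strict bounds", {
  passing <- data.frame(qual = 100, QD = 10, SOR = 1, FS = 5, MQ = 55,
                        MQRankSum = 0, ReadPosRankSum = 0)
  expect_true(apply_hard_filters(passing, "SNP")$pass)

  low_qd <- transform(passing, QD = 1.5)
  r <- apply_hard_filters(low_qd, "SNP")
  expect_false(r$pass)
  expect_equal(r$failed_clauses, "QD")

  boundary <- transform(passing, QD = 2.0)
  expect_true(apply_hard_filters(boundary, "SNP")$pass)

  # FS = 100 fails the SNP expression but passes the InDel one
  fs100 <- transform(passing, FS = 100)
  expect_false(apply_hard_filters(fs100, "SNP")$pass)
  expect_true(apply_hard_filters(fs100, "InDel")$pass)

  # absent annotations never fail a clause
  sparse <- data.frame(qual = 100, QD = 10, SOR = NA, FS = NA, MQ = 55,
                       MQRankSum = NA, ReadPosRankSum = NA)
  expect_true(apply_hard_filters(sparse, "SNP")$pass)

  two_bad <- transform(passing, QD = 1, MQ = 30)
  expect_equal(apply_hard_filters(two_bad, "SNP")$failed_clauses, "QD;MQ")
})

test_that("variant summaries count composition correctly and are order-invariant", {
  v <- data.frame(
    chrom = "chr1", pos = 1:6, id = paste0("v", 1:6),
    ref = c("A", "C", "G", "A", "ATTTTTTTTTTTG", "A"),
    alt = c("G", "T", "T", "T", "A", "AT"),
    stringsAsFactors = FALSE)
  s <- summarize_variants(v)
  expect_equal(s$snp_count, 4L)
  expect_equal(s$deletion_count, 1L)
  expect_equal(s$insertion_count, 1L)
  expect_equal(s$ti_count, 2L)
  expect_equal(s$tv_count, 2L)
  expect_equal(s$ti_tv_ratio, 1.0)
  expect_equal(sum(s$substitution_type_fractions), 1, tolerance = 1e-9)
  # the 12-base deletion lands in the ">10" bin
  expect_equal(unname(s$indel_length_histogram[">10"]), 1L)
  expect_equal(unname(s$indel_length_histogram["1"]), 1L)
  s2 <- summarize_variants(v[sample(6), ])
  for (f in c("snp_count", "ti_tv_ratio", "biallelic_fraction",
              "indel_length_histogram"))
    expect_equal(s2[[f]], s[[f]])

  # 2 transitions + 1 transversion
  v3 <- data.frame(ref = c("A", "C", "A"), alt = c("G", "T", "C"),
                   chrom = "chr1", stringsAsFactors = FALSE)
  expect_equal(summarize_variants(v3)$ti_tv_ratio, 2.0)
  # no transversions -> undefined ratio, not infinity
  v4 <- data.frame(ref = "A", alt = "G", chrom = "chr1",
                   stringsAsFactors = FALSE)
  expect_true(is.na(summarize_variants(v4)$ti_tv_ratio))

  # densities per kb when lengths are given
  sl <- summarize_variants(v, chromosome_lengths = c(chr1 = 2000))
  expect_equal(sl$per_chromosome$density_per_kb,
               sl$per_chromosome$Freq / 2)
})

test_that("an InDel-free simulation yields no InDel records on re-read", {
  cfg <- pop_config(n_accessions = 10, n_snps = 80, n_indels = 0, seed = 11)
  gm <- simulate_population(cfg)
  path <- file.path(tempdir(), "snponly.vcf")
  write_vcf(gm, path, timestamp = FALSE)
  vcf <- read_vcf(path)
  cls <- classify_variant(vcf$variants$ref, vcf$variants$alt)
  expect_true(all(cls == "SNP"))
})
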