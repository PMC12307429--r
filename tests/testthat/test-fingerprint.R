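test_that("candidate filtering demands biallelic SNPs, MAF >= 0.05 and zero missingness", {
  # 10 samples; engineered columns
  X <- cbind(
    rep(c(0L, 1L), 5),                 # clean candidate
    c(rep(0L, 9), 1L),                 # MAF exactly 0.05 -> retained
    c(1L, rep(0L, 8), NA),             # one missing call -> excluded
    c(rep(0L, 10)),                    # monomorphic -> excluded
    rep(c(0L, 2L), 5))                 # clean candidate
  gm <- genotype_matrix(X, loci = data.frame(
    chrom = "chr1", pos = 1:5 * 7L, ref = "A",
    alt = c("G", "G", "G", "G", "C"), stringsAsFactors = FALSE))
  cand <- candidate_filter(gm)
  expect_setequal(cand, locus_ids(gm)[c(1, 2, 5)])

  allbad <- genotype_matrix(matrix(0L, 4, 2), loci = data.frame(
    chrom = "chr1", pos = c(1L, 2L), ref = "A", alt = "G"))
  expect_error(candidate_filter(allbad), "no candidate")
})

test_that("candidate counts equal a column-scan recount on generator output", {
  gm <- simulate_population(pop_config(n_accessions = 50, n_snps = 600,
                                       n_indels = 60, seed = 139))
  cand <- candidate_filter(gm)
  X <- gm$dosages
  oracle <- 0L
  for (l in seq_len(ncol(X))) {
    if (gm$loci$type[l] != "SNP") next
    if (anyNA(X[, l])) next
    f <- sum(X[, l]) / (2 * nrow(X))
    if (min(f, 1 - f) >= 0.05) oracle <- oracle + 1L
  }
  expect_equal(length(cand), oracle)
})

test_that("pair resolution counting matches a double-loop brute force", {
  gm <- rand_gm(10, 30, seed = 149)
  full <- resolved_pairs(gm, locus_ids(gm))
  expect_equal(full$count, full$total)  # rows are distinct by construction
  set.seed(151)
  for (i in 1:8) {
    sub <- sample(locus_ids(gm), sample(1:5, 1))
    got <- resolved_pairs(gm, sub)
    want <- bf_resolved(gm$dosages, match(sub, locus_ids(gm)))
    expect_equal(got, want)
  }
  # a locus where everyone is heterozygous resolves nothing
  het <- snp_gm(cbind(rep(1L, 6), rep(c(0L, 1L, 2L), 2)))
  expect_equal(resolved_pairs(het, locus_ids(het)[1])$count, 0L)
})

test_that("greedy panels discriminate whenever possible and respect the set-cover bound", {
  for (s in 1:5) {
    gm <- rand_gm(9, 14, seed = 160 + s)
    g <- greedy_select(gm, locus_ids(gm))
    expect_equal(g$resolved_fraction, 1)
    expect_equal(length(unique(g$codes)), 9L)
    opt <- exhaustive_min(gm, locus_ids(gm))
    expect_lte(length(opt$loci), length(g$loci))
    n_pairs <- 9 * 8 / 2
    expect_lte(length(g$loci), length(opt$loci) * (1 + log(n_pairs)))
  }
  # no discriminating set: two identical accessions
  X <- rbind(c(0L, 1L), c(0L, 1L), c(2L, 0L))
  gm_dup <- snp_gm(X)
  expect_error(greedy_select(gm_dup, locus_ids(gm_dup)), "no discriminating")
  expect_null(exhaustive_min(gm_dup, locus_ids(gm_dup)))
  expect_error(ga_select(gm_dup, locus_ids(gm_dup)), "no discriminating")
})

test_that("exhaustive enumeration finds singleton panels and honors its guard", {
  # one locus separates all three accessions
  X <- cbind(c(0L, 1L, 2L), c(0L, 0L, 1L), c(1L, 1L, 1L))
  gm <- snp_gm(X)
  opt <- exhaustive_min(gm, locus_ids(gm))
  expect_equal(opt$loci, locus_ids(gm)[1])
  expect_error(exhaustive_min(rand_gm(4, 21, seed = 167),
                              paste0("L", 1:21)), "guard")
})

test_that("the genetic algorithm returns pruned discriminating panels reproducibly", {
  gm <- rand_gm(12, 25, seed = 173)
  prm <- ga_params(25, seed = 7)
  p1 <- ga_select(gm, locus_ids(gm), prm)
  p2 <- ga_select(gm, locus_ids(gm), prm)
  expect_identical(p1$loci, p2$loci)
  expect_equal(p1$resolved_fraction, 1)
  # pruning: no single locus is redundant
  for (l in p1$loci) {
    rest <- setdiff(p1$loci, l)
    if (length(rest))
      expect_lt(resolved_pairs(gm, rest)$count, resolved_pairs(gm, rest)$total)
  }
  # two accessions: any differing locus suffices
  gm2 <- snp_gm(rbind(c(0L, 1L, 1L), c(0L, 1L, 2L)))
  p <- ga_select(gm2, locus_ids(gm2), ga_params(3, seed = 1))
  expect_equal(length(p$loci), 1L)
})

test_that("the GA matches the exhaustive optimum on instances with a known size-3 minimum", {
  # three ternary 'digit' loci separate 27 accessions; five noise loci are
  # nearly uninformative, so the unique minimum has size 3
  digits <- as.matrix(expand.grid(0:2, 0:2, 0:2))
  noise <- matrix(rep(c(0L, rep(1L, 26)), 5), 27, 5)
  X <- cbind(digits, noise)
  storage.mode(X) <- "integer"
  gm <- snp_gm(X)
  opt <- exhaustive_min(gm, locus_ids(gm))
  expect_equal(length(opt$loci), 3L)
  sizes <- vapply(1:10, function(s)
    length(ga_select(gm, locus_ids(gm), ga_params(8, seed = s))$loci),
    numeric(1))
  expect_true(all(sizes >= 3))
  expect_gte(mean(sizes == 3), 0.9)
})

test_that("fingerprint tables encode dosages as A/H/B and round-trip via TSV", {
  gm <- snp_gm(rbind(a = c(0L, 1L), b = c(2L, 1L)))
  ft <- fingerprint_table(gm, locus_ids(gm))
  expect_equal(unname(ft$codes), c("AH", "BH"))
  expect_equal(dim(ft$table), c(2L, 2L))  # loci x accessions
  expect_equal(unname(ft$table[1, ]), c("A", "B"))

  path <- file.path(tempdir(), "fp.tsv")
  gm3 <- rand_gm(6, 8, seed = 179)
  fingerprint_table(gm3, locus_ids(gm3)[1:4], tsv = path)
  back <- as.matrix(read.table(path, sep = "\t", header = TRUE,
                               row.names = 1, check.names = FALSE))
  code <- c(A = 0L, H = 1L, B = 2L)
  expect_equal(unname(t(matrix(code[back], nrow(back), ncol(back)))),
               unname(gm3$dosages[, 1:4]))

  expect_error(fingerprint_table(gm3, "nope"), "absent")
})
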