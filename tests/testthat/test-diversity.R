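test_that("diversity indices hit their closed forms on canonical loci", {
  # p = 0.5, all heterozygous, n = 10
  gm <- snp_gm(matrix(1L, 10, 1))
  r <- locus_diversity(gm)
  expect_equal(r$per_locus$Na, 2L)
  expect_equal(r$per_locus$Ne, 2, tolerance = 1e-12)
  expect_equal(r$per_locus$Ho, 1, tolerance = 1e-12)
  expect_equal(r$per_locus$He, 0.5, tolerance = 1e-12)
  expect_equal(r$per_locus$I, log(2), tolerance = 1e-12)
  expect_equal(r$per_locus$H, (20 / 19) * 0.5, tolerance = 1e-12)
  expect_equal(r$pln, 100)

  mono <- snp_gm(matrix(0L, 10, 1))
  rm_ <- locus_diversity(mono)
  expect_equal(unname(unlist(rm_$per_locus[c("Na", "Ne", "Ho", "He",
                                             "I", "H")])),
               c(1, 1, 0, 0, 0, 0))
  expect_equal(rm_$pln, 0)
})

test_that("all six indices match a brute-force per-locus recomputation", {
  gm <- rand_gm(20, 200, seed = 71, missing_rate = 0.05)
  r <- locus_diversity(gm)
  oracle <- bf_diversity(gm$dosages)
  for (i in colnames(oracle))
    expect_equal(r$per_locus[[i]], unname(oracle[, i]), tolerance = 1e-10)
  expect_equal(unname(r$means), unname(colMeans(oracle)), tolerance = 1e-10)
})

test_that("He stays below its unbiased correction and indices ignore ordering", {
  gm <- rand_gm(15, 100, seed = 73, missing_rate = 0.1)
  r <- locus_diversity(gm)
  expect_true(all(r$per_locus$H >= r$per_locus$He - 1e-12))
  poly <- r$per_locus$He > 0
  expect_true(all(r$per_locus$H[poly] > r$per_locus$He[poly]))
  perm <- sample(nrow(gm$dosages))
  r2 <- locus_diversity(genotype_matrix(gm$dosages[perm, ]))
  expect_equal(r2$means, r$means, tolerance = 1e-12)
})

test_that("polymorphism and allele counts are monotone under sample supersets", {
  gm <- rand_gm(30, 150, seed = 79, missing_rate = 0.05)
  ids <- sample_ids(gm)
  small <- locus_diversity(gm, group = ids[1:8])
  big <- locus_diversity(gm, group = ids[1:25])
  expect_lte(small$pln, big$pln)
  expect_lte(small$means[["Na"]], big$means[["Na"]])
})

test_that("Welch comparisons behave at the identity and match the textbook formula", {
  gm <- rand_gm(20, 50, seed = 83)
  r <- locus_diversity(gm)
  self <- compare_groups(r, r)
  expect_true(all(abs(self$p_value - 1) < 1e-12))

  # hand-made per-locus vectors checked against the Welch formulas
  a <- c(0.2, 0.4, 0.3, 0.5, 0.1)
  b <- c(0.6, 0.7, 0.4, 0.8, 0.5)
  ra <- r; rb <- r
  ra$per_locus <- data.frame(locus = paste0("l", 1:5), Na = a, Ne = a,
                             Ho = a, He = a, I = a, H = a)
  rb$per_locus <- data.frame(locus = paste0("l", 1:5), Na = b, Ne = b,
                             Ho = b, He = b, I = b, H = b)
  cmp <- compare_groups(ra, rb)
  se <- sqrt(var(a) / 5 + var(b) / 5)
  t_exp <- (mean(a) - mean(b)) / se
  df_exp <- se^4 / ((var(a) / 5)^2 / 4 + (var(b) / 5)^2 / 4)
  p_exp <- 2 * pt(abs(t_exp), df_exp, lower.tail = FALSE)
  expect_equal(cmp$t[1], t_exp, tolerance = 1e-12)
  expect_equal(cmp$df[1], df_exp, tolerance = 1e-12)
  expect_equal(cmp$p_value[1], p_exp, tolerance = 1e-12)
})

test_that("random halves of one population rarely differ significantly", {
  gm <- simulate_population(pop_config(n_accessions = 60, n_snps = 600,
                                       n_indels = 0, seed = 89))
  gf <- site_filter(gm)
  ids <- sample_ids(gf)
  set.seed(97)
  ok <- 0L
  n_trials <- 40L
  for (i in seq_len(n_trials)) {
    h <- sample(ids, 30)
    pa <- locus_diversity(gf, group = h)
    pb <- locus_diversity(gf, group = setdiff(ids, h))
    if (all(compare_groups(pa, pb)$p_value > 0.05)) ok <- ok + 1L
  }
  expect_gte(ok / n_trials, 0.9)
})

test_that("sampling evaluation is seeded, floors its sample counts and covers both groups", {
  gm <- simulate_population(pop_config(n_accessions = 50, n_snps = 500,
                                       n_indels = 0, seed = 101))
  gf <- site_filter(gm)
  core <- greedy_core(gf, target_size = 11)$ids
  t1 <- suppressWarnings(sampling_evaluation(gf, core, seed = 5))
  t2 <- suppressWarnings(sampling_evaluation(gf, core, seed = 5))
  expect_identical(t1, t2)
  expect_equal(nrow(t1), 10L)  # 5 proportions x 2 groups
  expect_equal(t1$n_samples[t1$group == "core"],
               floor(c(10, 25, 50, 75, 100) / 100 * 11))
  expect_equal(t1$n_samples[t1$group == "noncore"],
               floor(c(10, 25, 50, 75, 100) / 100 * 39))
  # q = 100 rows are the deterministic full-group reports
  full_core <- locus_diversity(gf, group = core)
  expect_equal(t1$He[t1$group == "core" & t1$proportion == 100],
               unname(full_core$means[["He"]]))

  # PLN grows with sampling proportion in expectation
  mean_pln <- function(q, n = 25) {
    # tiny subsamples legitimately warn about skipped all-missing loci
    v <- vapply(seq_len(n), function(s)
      suppressWarnings(sampling_evaluation(gf, core, proportions = q,
                                           seed = 1000 + s)$PLN[1]),
      numeric(1))
    mean(v)
  }
  expect_lte(mean_pln(25), mean_pln(75))
})
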