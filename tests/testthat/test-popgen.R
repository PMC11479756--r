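# Population-genomic statistics against brute-force oracles.

test_that("heterozygosity, G_ST, r2 and Tajima's D match brute-force oracles", {
  set.seed(30)
  for (rep in 1:5) {
    gt <- random_genotype_table(c(10, 10), n_loci = 50,
                                p = matrix(runif(100), 50, 2))
    expect_equal(observed_heterozygosity(gt), oracle_hobs(gt$geno),
                 tolerance = 1e-10)
    expect_equal(expected_heterozygosity(gt), oracle_hexp(gt$geno),
                 tolerance = 1e-10)
    expect_equal(gst_between_groups(gt),
                 oracle_gst(gt$geno, gt$samples$morph), tolerance = 1e-10)
    r2 <- ld_r2(gt)
    for (pair in list(c(1, 2), c(3, 40), c(17, 17))) {
      o <- oracle_r2(gt$geno, pair[1], pair[2])
      if (is.na(o)) expect_true(is.na(r2[pair[1], pair[2]]))
      else expect_equal(r2[pair[1], pair[2]], o, tolerance = 1e-10)
    }
    td <- tajimas_d(gt, window = 50)
    expect_equal(td$d[1], oracle_tajima(gt$geno), tolerance = 1e-10)
  }
})

test_that("multi-state loci are handled", {
  set.seed(31)
  gt <- random_genotype_table(c(8, 8), n_loci = 30, n_states = 3)
  expect_true(all(expected_heterozygosity(gt) <= 1 &
                    expected_heterozygosity(gt) >= 0))
  expect_equal(expected_heterozygosity(gt), oracle_hexp(gt$geno),
               tolerance = 1e-10)
  expect_equal(gst_between_groups(gt), oracle_gst(gt$geno, gt$samples$morph),
               tolerance = 1e-10)
  # triallelic closed form at p = (0.5, 0.25, 0.25)
  g1 <- matrix(c(rep(0L, 8), rep(1L, 4), rep(2L, 4)), nrow = 1)
  gt1 <- genotype_table(g1, tibble::tibble(id = as.character(1:8), sex = "M",
                                           morph = rep(c("CP", "NP"), 4)),
                        tibble::tibble(chrom = 1L, pos = 1L, qtl = FALSE,
                                       trait = NA_character_))
  expect_equal(expected_heterozygosity(gt1), 0.625)
})

test_that("G_ST closed-form example and bounds hold", {
  # two equal groups, biallelic p = 0.2 vs 0.8: H_S = 0.32, H_T = 0.5
  make_group <- function(p, n) {
    matrix(rep(c(rep(1L, round(2 * n * p)), rep(0L, 2 * n - round(2 * n * p)))),
           nrow = 1)
  }
  g <- cbind(make_group(0.2, 10), make_group(0.8, 10))
  gt <- genotype_table(g, tibble::tibble(id = as.character(1:20), sex = "M",
                                         morph = rep(c("CP", "NP"), each = 10)),
                       tibble::tibble(chrom = 1L, pos = 1L, qtl = FALSE,
                                      trait = NA_character_))
  expect_equal(gst_between_groups(gt), (0.5 - 0.32) / 0.5)
  # identical groups -> 0; fixed alternative alleles -> 1
  gfix <- cbind(matrix(0L, 1, 20), matrix(1L, 1, 20))
  gtfix <- genotype_table(gfix, tibble::tibble(id = as.character(1:20),
                                               sex = "M",
                                               morph = rep(c("CP", "NP"), each = 10)),
                          tibble::tibble(chrom = 1L, pos = 1L, qtl = FALSE,
                                         trait = NA_character_))
  expect_equal(gst_between_groups(gtfix), 1)
  expect_error(gst_between_groups(random_genotype_table(10, 5)),
               class = "morphsim_error")
})

test_that("Tajima's D behaves at the edges", {
  # no segregating sites -> missing
  g <- matrix(0L, 20, 20)
  gt <- genotype_table(g, tibble::tibble(id = as.character(1:10), sex = "M",
                                         morph = "CP"),
                       tibble::tibble(chrom = 1L, pos = 1:20, qtl = FALSE,
                                      trait = NA_character_))
  expect_true(is.na(tajimas_d(gt, 20)$d[1]))
  # all singletons -> negative D
  g2 <- matrix(0L, 16, 20)
  for (l in 1:16) g2[l, l] <- 1L
  gt2 <- genotype_table(g2, tibble::tibble(id = as.character(1:10), sex = "M",
                                           morph = "CP"),
                        tibble::tibble(chrom = 1L, pos = 1:16, qtl = FALSE,
                                       trait = NA_character_))
  expect_lt(tajimas_d(gt2, 16)$d[1], 0)
  expect_equal(tajimas_d(gt2, 16)$d[1], oracle_tajima(g2), tolerance = 1e-10)
})

test_that("LD r2 is 1 on self and duplicated loci, near 0 for independent ones", {
  set.seed(32)
  gt <- random_genotype_table(c(40, 40), n_loci = 30,
                              p = matrix(runif(60, 0.2, 0.8), 30, 2))
  gt$geno <- rbind(gt$geno, gt$geno[1, , drop = FALSE])
  gt$loci <- tibble::tibble(chrom = 1L, pos = 1:31, qtl = FALSE,
                            trait = NA_character_)
  r2 <- ld_r2(gt)
  expect_equal(unname(diag(r2)[1]), 1)
  expect_equal(r2[1, 31], 1)
  expect_lt(mean(r2[1, 2:30]), 6 / 80) # independent loci: E[r2] ~ 1/n
})

test_that("association scan calibrates under the null and detects fixed differences", {
  set.seed(33)
  # fixed difference between classes at n = 100 males
  g <- cbind(matrix(0L, 1, 100), matrix(1L, 1, 100))
  gt <- genotype_table(g, tibble::tibble(id = as.character(1:100), sex = "M",
                                         morph = rep(c("NN", "CP"), each = 50)),
                       tibble::tibble(chrom = 1L, pos = 1L, qtl = FALSE,
                                      trait = NA_character_))
  expect_lt(association_scan(gt, "courter")[1], 1e-6)
  # monomorphic locus -> exactly 1
  gmono <- matrix(1L, 1, 200)
  gtm <- genotype_table(gmono, gt$samples, gt$loci)
  expect_equal(association_scan(gtm, "courter")[1], 1)
  # permuted labels: p-values approximately uniform (KS test, alpha = 0.01)
  gt2 <- random_genotype_table(c(100, 100), n_loci = 400,
                               p = matrix(runif(800, 0.1, 0.9), 400, 2))
  gt2$samples$morph <- sample(rep(c("CP", "NN"), 100)) # permuted labels
  p <- association_scan(gt2, "courter")
  ks <- suppressWarnings(stats::ks.test(p, "punif"))
  expect_gt(ks$p.value, 0.01)
  # single class warns and returns 1
  gt3 <- random_genotype_table(20, 10)
  expect_warning(p3 <- association_scan(gt3, "courter"))
  expect_true(all(p3 == 1))
})

test_that("peak calling finds spikes, merges runs and ignores flat profiles", {
  n <- 300
  chrom <- rep(1L, n)
  pos <- 1:n
  flat <- rep(1, n)
  expect_equal(nrow(find_peaks(flat, chrom, pos)), 0)
  spike <- flat
  spike[150] <- 10
  pk <- find_peaks(spike, chrom, pos, threshold_quantile = 0.95)
  expect_equal(pk$pos, 150)
  two <- flat
  two[140] <- 8
  two[141:149] <- 7
  two[150] <- 9
  pk2 <- find_peaks(two, chrom, pos, threshold_quantile = 0.95)
  expect_equal(pk2$pos, 150) # contiguous qualifying run merges to its extremum
  # low direction works for p-values
  pv <- rep(0.5, n)
  pv[42] <- 1e-8
  pk3 <- find_peaks(pv, chrom, pos, direction = "low",
                    threshold_quantile = 0.99)
  expect_equal(pk3$pos, 42)
})

test_that("QTL detection respects the 50-position window", {
  qtl <- tibble::tibble(chrom = 1L, pos = 500L)
  hit <- tibble::tibble(chrom = 1L, pos = 500L)
  near <- tibble::tibble(chrom = 1L, pos = 550L)
  far <- tibble::tibble(chrom = 1L, pos = 551L)
  expect_equal(qtl_detection(hit, qtl)$prop_peaks_near_qtl, 1)
  expect_equal(qtl_detection(near, qtl)$prop_qtl_detected, 1)
  expect_equal(qtl_detection(far, qtl)$prop_peaks_near_qtl, 0)
  expect_equal(qtl_detection(far, qtl)$prop_qtl_detected, 0)
  none <- tibble::tibble(chrom = integer(0), pos = integer(0))
  d <- qtl_detection(none, qtl)
  expect_true(is.na(d$prop_peaks_near_qtl))
  expect_equal(d$prop_qtl_detected, 0)
})

test_that("non-QTL resampling null ranks the observed mean correctly", {
  set.seed(34)
  vals <- c(rep(10, 5), rnorm(200))
  is_qtl <- c(rep(TRUE, 5), rep(FALSE, 200))
  rs <- resample_nonqtl(vals, is_qtl, n_resamples = 999)
  expect_equal(rs$observed, 10)
  expect_equal(rs$quantile, 1) # observed far above every resample
  const <- resample_nonqtl(rep(2, 50), rep(c(TRUE, FALSE), 25), 99)
  expect_true(all(const$null == 2))
  expect_error(resample_nonqtl(vals, rep(TRUE, 205)),
               class = "morphsim_error")
  set.seed(1); a <- resample_nonqtl(vals, is_qtl, 99)
  set.seed(1); b <- resample_nonqtl(vals, is_qtl, 99)
  expect_identical(a, b)
})

test_that("QTL vs neutral comparison is a Welch t-test with power", {
  set.seed(35)
  stats_tbl <- tibble::tibble(qtl = c(rep(TRUE, 64), rep(FALSE, 1936)),
                              h_obs = c(rnorm(64, 0.8, 0.1),
                                        rnorm(1936, 0.5, 0.1)))
  res <- qtl_vs_neutral_test(stats_tbl)
  expect_lt(res$p, 0.01)
  ref <- t.test(stats_tbl$h_obs[stats_tbl$qtl],
                stats_tbl$h_obs[!stats_tbl$qtl])
  expect_equal(res$t, unname(ref$statistic))
  one <- tibble::tibble(qtl = rep(TRUE, 10), h_obs = runif(10))
  expect_error(qtl_vs_neutral_test(one), class = "morphsim_error")
})
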