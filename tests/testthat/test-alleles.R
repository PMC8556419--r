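test_that("archaic-allele probability evaluates its closed form", {
  expect_equal(archaic_allele_probability(0, 0, 0.9, 0.1, 0.02), 1)
  expect_equal(archaic_allele_probability(1, 0.5, 1, 0.1, 0.02), 0)
  expect_equal(archaic_allele_probability(0.02, 0.01, 0.9, 0.1, 0.02),
               (0.02 * 0.1 + 0.98) * (0.01 * 0.1 * 0.02 + 0.99))
  expect_error(archaic_allele_probability(1.2, 0, 1, 0, 0))
})

test_that("the probability is monotone decreasing in both frequencies", {
  grid <- seq(0, 1, by = 0.1)
  for (p in c(0.5, 0.9)) for (ma in c(0.001, 0.01)) {
    f1 <- archaic_allele_probability(grid, 0.3, p, ma, 1)
    expect_true(all(diff(f1) < 0))
    f2 <- archaic_allele_probability(0.3, grid, p, ma, 1)
    expect_true(all(diff(f2) < 0))
  }
})

test_that("allele calling applies a strict complement threshold", {
  # 5 test haplotypes; t1 carries an archaic segment over [0, 1000)
  geno <- matrix(0L, nrow = 3, ncol = 8)
  roles <- c(rep("test", 5), "african_ref", "african_ref", "outgroup")
  # site 1: derived only on the segment -> called
  geno[1, 1] <- 1L
  # site 2: derived on the segment and on 1 of the 4 off-segment test
  # haplotypes: with p = 0.5, p_d_Afr = 0, P(not archaic) = 0.125, an
  # exactly representable boundary for the strict-< rule
  geno[2, 1] <- 1L; geno[2, 2] <- 1L
  # site 3: derived on segment and fixed on modern sequence, p = 1
  geno[3, ] <- 1L; geno[3, 8] <- 0L
  p <- site_panel("1", c(100L, 200L, 300L), geno, roles,
                  hap = c(paste0("t", 1:5), "a1", "a2", "out"),
                  polarized = TRUE)
  seg <- data.frame(chrom = "1", start = 0L, end = 1000L, hap = "t1")
  calls <- call_archaic_alleles(p, seg, p = 0.5, m = 0, alpha = 0,
                                threshold = 0.125)
  expect_equal(calls$call, c(TRUE, FALSE, FALSE))
  expect_equal(calls$p_d_M, c(0, 0.25, 1))
  # the boundary case is exact: P(not A) == threshold is not called
  expect_identical(1 - calls$P_A[2], 0.125)
})

test_that("allele calling with full power rejects shared alleles", {
  calls <- archaic_allele_probability(1, 0, 1, 0.5, 0.5)
  expect_equal(calls, 0)
})

test_that("LD clustering joins tagged sites within the window", {
  set.seed(4)
  n <- 40
  tag <- rbinom(n, 1, 0.5)
  p <- site_panel("1", c(0L, 10000L, 20000L, 650000L), t(cbind(
    s1 = tag, s2 = tag, s3 = 1 - tag, s4 = rbinom(n, 1, 0.5))),
    roles = rep("test", n), polarized = TRUE)
  cl <- cluster_ld_loci(p, r2 = 0.8, window = 5e5)
  # perfect LD 10 kb apart joins; r^2 = 1 for the flipped site too
  expect_equal(cl$cluster[1], cl$cluster[2])
  expect_equal(cl$cluster[2], cl$cluster[3])
  # 630 kb away: outside the window, a new cluster regardless of LD
  expect_false(cl$cluster[4] == cl$cluster[1])
})

test_that("unlinked sites stay singleton clusters", {
  set.seed(11)
  g <- matrix(rbinom(60 * 40, 1, 0.4), nrow = 60)
  p <- site_panel("1", seq(0L, by = 1000L, length.out = 60), g,
                  roles = rep("test", 40), polarized = TRUE)
  cl <- cluster_ld_loci(p)
  expect_gte(mean(table(cl$cluster) == 1), 0.9)
  # every site belongs to exactly one cluster
  expect_equal(nrow(cl), 60L)
  expect_false(anyNA(cl$cluster))
})

test_that("enrichment scores match hand arithmetic on crafted loci", {
  n <- 120
  loci <- data.frame(site = 1:n, pos = (1:n) * 1e6, cluster = 1:n,
                     is_representative = TRUE)
  is_archaic <- c(rep(TRUE, 20), rep(FALSE, 100))
  freq <- rep(0.105, n)  # one frequency bin: matching is unconstrained
  # archaic loci all eQTL; exactly half of the non-archaic loci are
  ann <- data.frame(site = 1:n, tissue = "liver",
                    is_eqtl = c(rep(TRUE, 20), rep(c(TRUE, FALSE), 50)))
  res <- enrichment_test(loci, ann, is_archaic, freq, n_sets = 200,
                         seed = 2)
  expect_equal(res$score, 2, tolerance = 0.25)
  expect_lt(res$p_emp, 0.05)
  # identical GEA proportions: a null score near 1 and a large p
  ann0 <- data.frame(site = 1:n, tissue = "null",
                     is_eqtl = rep(c(TRUE, FALSE), 60))
  res0 <- enrichment_test(loci, ann0, is_archaic, freq, n_sets = 200,
                          seed = 2)
  expect_equal(res0$score, 1, tolerance = 0.3)
  expect_gt(res0$p_emp, 0.05)
})

test_that("the empirical test holds its size under a null annotation", {
  set.seed(31)
  n <- 150
  loci <- data.frame(site = 1:n, pos = (1:n) * 1e6, cluster = 1:n,
                     is_representative = TRUE)
  is_archaic <- rep(c(TRUE, FALSE), c(30, 120))
  freq <- runif(n, 0.05, 0.5)
  tissues <- paste0("t", 1:40)
  ann <- do.call(rbind, lapply(tissues, function(tt)
    data.frame(site = 1:n, tissue = tt,
               is_eqtl = rbinom(n, 1, 0.3) == 1)))
  res <- enrichment_test(loci, ann, is_archaic, freq, n_sets = 100,
                         seed = 7)
  expect_equal(nrow(res), 40L)
  expect_lte(mean(res$p_emp < 0.05), 0.125)
  expect_true(all(res$p_bh >= res$p_emp - 1e-12))
})
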