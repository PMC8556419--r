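test_that("observation states follow the derived-allele sharing rules", {
  p <- toy_panel()
  expect_equal(classify_observations(p, "t1"), c(1L, 2L, 3L, 4L, 4L))
  # t2 is ancestral at sites 1-3, derived at 4-5 (shared) -> all common
  expect_equal(classify_observations(p, "t2"), c(4L, 4L, 4L, 4L, 4L))
  expect_error(classify_observations(p, "nea"), "role 'test'")
  expect_error(classify_observations(p, "nope"), "unknown")
  # a missing archaic call never counts as carrying the derived allele
  p$geno[2, 5] <- NA
  expect_equal(classify_observations(p, "t1")[2], 1L)
})

test_that("transition matrix has the pulse-admixture form and limits", {
  par <- list(alpha = 0.02, T = 2000)
  expect_equal(transition_matrix(0, par), diag(2),
               ignore_attr = TRUE)
  m_inf <- transition_matrix(10, par)
  expect_equal(unname(m_inf[1, ]), c(0.98, 0.02), tolerance = 1e-8)
  expect_equal(unname(m_inf[2, ]), c(0.98, 0.02), tolerance = 1e-8)
  # direct evaluation at d = 1e-4 Morgans
  m <- transition_matrix(1e-4, par)
  expect_equal(m["AMH", "archaic"], 0.02 * (1 - exp(-0.2)))
  expect_equal(m["archaic", "AMH"], 0.98 * (1 - exp(-0.2)))
  expect_equal(unname(rowSums(m)), c(1, 1))
})

test_that("emission initialization is row-stochastic and epsilon-driven", {
  f <- c(0.01, 0.005, 0.09, 0.895)
  e <- emission_init(f, 0.99)
  expect_equal(unname(rowSums(e)), c(1, 1))
  expect_equal(sum(e[1, 3:4]), 0.99)          # AMH mass on states 3+4
  expect_equal(e[2, 3], 0.01)                 # archaic leak to state 3
  expect_lt(e[1, 2], 0.01)                    # frozen-entry seed is small
})

test_that("EM pools haplotypes, increases the likelihood and recovers alpha", {
  sim <- simulate_panel(scenario_config(chrom_len = 1e7, n_test = 20,
                                        n_african = 20, seed = 101))
  fit <- em_fit(panel = sim$panel)
  expect_true(all(diff(fit$loglik) > -1e-8 * abs(fit$loglik[1])))
  expect_gt(fit$alpha, 0.01)
  expect_lt(fit$alpha, 0.04)
  expect_equal(unname(rowSums(fit$emission)), c(1, 1), tolerance = 1e-9)
  # frozen entries retain their initial values
  expect_equal(fit$emission[1, 2], fit$frozen[1])
  expect_equal(fit$emission[2, 1], fit$frozen[2])
})

test_that("a panel without archaic or test-specific signal stays quiet", {
  sim <- small_sim(seed = 7, chrom_len = 2e6, n_test = 6)
  p <- sim$panel
  # erase all archaic sharing: make both archaic refs ancestral wherever
  # any test haplotype carries a derived allele, and strip states 1/2 by
  # giving one African every test-carried derived allele
  ti <- which(p$roles == "test")
  ai <- which(p$roles == "african_ref")
  carried <- rowSums(p$geno[, ti, drop = FALSE] == 1L) > 0L
  p$geno[carried, startsWith(p$roles, "archaic_ref")] <- 0L
  p$geno[carried, ai[1]] <- 1L
  obs <- observation_matrix(p)
  expect_true(all(obs %in% c(3L, 4L)))
  fit <- em_fit(obs, p)
  expect_lte(fit$alpha, 0.02)
  seg <- decode_segments(obs, p, fit)
  frac <- if (nrow(seg)) sum(seg$end - seg$start) / (2e6 * length(ti))
          else 0
  expect_lt(frac, 0.01)
})

test_that("an all-common panel is rejected as having no markers", {
  p <- toy_panel()
  p$geno[, 1:2] <- 0L
  expect_error(em_fit(panel = p), "no markers")
})

test_that("forward-backward posteriors are proper probabilities", {
  sim <- small_sim(seed = 9, chrom_len = 1e6, n_test = 4)
  p <- sim$panel
  obs <- observation_matrix(p)
  fit <- em_fit(obs, p, max_iter = 10L)
  d <- pmax(diff(p$gpos), 1e-9)
  post <- archseekr:::.hmm_posterior(obs[, 1], d, fit$emission,
                                     fit$alpha, fit$T)$gamma
  expect_true(all(abs(rowSums(post) - 1) < 1e-10))
  expect_true(all(post >= 0 & post <= 1))
})

test_that("decoding recovers simulated tracts with tight boundaries", {
  sim <- simulate_panel(scenario_config(chrom_len = 5e6, n_test = 6,
                                        n_african = 20, seed = 13,
                                        waves = list(list(lineage = "NEA",
                                                          t = 1000,
                                                          m = 0.01))))
  scan <- seek(sim$panel)
  validate_segments(scan$segments)
  tru <- sim$truth[sim$truth$end - sim$truth$start >= 5e4, ]
  expect_gt(nrow(tru), 0)
  hits <- 0; bnd_ok <- 0
  for (i in seq_len(nrow(tru))) {
    s <- scan$segments[scan$segments$hap == tru$hap[i], , drop = FALSE]
    ov <- s[pmin(s$end, tru$end[i]) > pmax(s$start, tru$start[i]), ,
            drop = FALSE]
    if (nrow(ov)) {
      hits <- hits + 1
      if (abs(min(ov$start) - tru$start[i]) < 25000 &&
          abs(max(ov$end) - tru$end[i]) < 25000)
        bnd_ok <- bnd_ok + 1
    }
  }
  expect_equal(hits, nrow(tru))        # every long tract is found
  expect_gte(bnd_ok / nrow(tru), 0.9)  # boundaries within 25 kb
  expect_true(all(scan$segments$mean_posterior >= 0 &
                    scan$segments$mean_posterior <= 1))
})

test_that("decoding an AMH-only observation sequence yields no segments", {
  p <- toy_panel()
  fit <- list(alpha = 0.02, T = 2000,
              emission = emission_init(c(.01, .005, .2, .785)))
  obs <- matrix(3L, nrow = 5, ncol = 1, dimnames = list(NULL, "t1"))
  p <- attach_genetic_map(p, NULL)
  expect_equal(nrow(decode_segments(obs, p, fit)), 0L)
})

test_that("pure archaic input decodes archaic; African input does not", {
  sim <- small_sim(seed = 21, chrom_len = 2e6, n_test = 4)
  p <- sim$panel
  nea <- which(p$roles == "archaic_ref:NEA")
  afr <- which(p$roles == "african_ref")
  ti <- which(p$roles == "test")
  # archaic references copied in as the test haplotypes
  p_arch <- p
  p_arch$geno[, ti] <- p$geno[, rep(nea, length.out = length(ti))]
  scan_a <- seek(p_arch)
  expect_gt(scan_a$called_fraction, 0.95)
  # Africans copied in as the test haplotypes
  p_afr <- p
  p_afr$geno[, ti] <- p$geno[, afr[seq_along(ti)]]
  scan_f <- seek(p_afr)
  expect_lt(scan_f$called_fraction, 0.01)
})

test_that("the scan object carries its methods", {
  sim <- small_sim(seed = 31, chrom_len = 1e6, n_test = 4)
  scan <- seek(sim$panel)
  expect_s3_class(scan, "archaic_scan")
  expect_named(coef(scan), c("alpha", "T"))
  expect_s3_class(logLik(scan), "logLik")
  expect_output(print(scan), "alpha")
  expect_output(print(summary(scan)), "emission")
})
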