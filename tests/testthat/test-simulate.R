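test_that("configs validate times, proportions and seeds", {
  expect_error(scenario_config(seed = NULL), "seed")
  expect_error(scenario_config(waves = list(list(lineage = "NEA",
                                                 t = 5000, m = 0.02)),
                               seed = 1), "wave time")
  expect_error(scenario_config(waves = list(list(lineage = "NEA",
                                                 t = 1000, m = 0.6),
                                            list(lineage = "DEN",
                                                 t = 1000, m = 0.5)),
                               seed = 1), ">= 1")
  expect_error(scenario_config(t_arc_split = 30000, seed = 1),
               "inconsistent split times")
  expect_error(scenario_config(waves = list(list(lineage = "XXX",
                                                 t = 100, m = 0.01)),
                               seed = 1), "lineage")
})

test_that("no introgression means no tracts and no archaic-marker excess", {
  sim <- simulate_panel(scenario_config(chrom_len = 2e6, n_test = 6,
                                        n_african = 20, waves = list(),
                                        seed = 5))
  expect_equal(nrow(sim$truth), 0L)
  obs <- observation_matrix(sim$panel)
  expect_lt(mean(obs == 2L), 0.005)
})

test_that("the simulated archaic fraction matches the pulse proportion", {
  sim <- simulate_panel(scenario_config(chrom_len = 1e7, n_test = 20,
                                        n_african = 10, seed = 8))
  frac <- sum(sim$truth$end - sim$truth$start) / (1e7 * 20)
  expect_gt(frac, 0.015)
  expect_lt(frac, 0.025)
  validate_segments(sim$truth)
})

test_that("identical seeds give bit-identical panels and truth", {
  cfg <- scenario_config(chrom_len = 1e6, n_test = 4, n_african = 6,
                         seed = 99)
  a <- simulate_panel(cfg); b <- simulate_panel(cfg)
  expect_identical(a$panel$geno, b$panel$geno)
  expect_identical(a$panel$pos, b$panel$pos)
  expect_identical(a$truth, b$truth)
})

test_that("pairwise divergences agree with the painted branch lengths", {
  cfg <- scenario_config(chrom_len = 5e6, n_test = 6, n_african = 10,
                         seed = 12)
  sim <- simulate_panel(cfg)
  p <- sim$panel
  span <- diff(range(p$pos)) + 1
  dens <- function(i, j) sum(p$geno[, i] != p$geno[, j]) / span
  afr <- which(p$roles == "african_ref")
  nea <- which(p$roles == "archaic_ref:NEA")[1]
  den <- which(p$roles == "archaic_ref:DEN")[1]
  mu <- cfg$mu
  nH <- cfg$n_test + cfg$n_african
  na <- cfg$n_african
  a_na <- sum(1 / seq_len(na - 1))
  p_old <- exp(-cfg$t_arch_split / (2 * cfg$ne_human))
  het <- 4 * cfg$ne_human * mu * (nH - 1) / nH  # per-haplotype load
  # African vs archaic: archaic-side branch depth + ancestral standing
  # variation, plus the African haplotype's own derived load
  d_obs <- mean(vapply(afr[1:5], dens, 0, j = nea))
  expected <- mu * cfg$t_arch_split + 2 * cfg$ne_anc * mu + het +
    mu * cfg$t_afr_test * (na - 1) / (na * a_na)
  expect_equal(d_obs, expected, tolerance = 0.1)
  # the two archaic references: branch mutations plus drift-sorted
  # ancestral-shared polymorphism
  d_arc <- dens(nea, den)
  expect_equal(d_arc, 2 * mu * cfg$t_arc_split + 0.5 * p_old * het,
               tolerance = 0.1)
})

test_that("tract-private derived alleles are absent from Africans", {
  sim <- simulate_panel(scenario_config(chrom_len = 5e6, n_test = 10,
                                        n_african = 20, seed = 14))
  p <- sim$panel
  afr <- p$geno[, p$roles == "african_ref", drop = FALSE]
  afr_mono <- rowSums(afr == 1L) == 0L
  ti <- which(p$roles == "test")
  # AIM density inside truth tracts dwarfs the outside density
  inside <- 0; in_len <- 0; outside <- 0; out_len <- 0
  for (k in seq_along(ti)) {
    h <- p$hap[ti[k]]
    tr <- sim$truth[sim$truth$hap == h, ]
    der <- p$geno[, ti[k]] == 1L & afr_mono
    pos <- p$pos[der]
    if (nrow(tr)) {
      iv <- findInterval(pos, tr$start)
      hit <- iv > 0 & pos < tr$end[pmax(iv, 1)]
      inside <- inside + sum(hit); outside <- outside + sum(!hit)
      in_len <- in_len + sum(tr$end - tr$start)
      out_len <- out_len + 5e6 - sum(tr$end - tr$start)
    }
  }
  expect_gt((inside / in_len) / (outside / out_len), 10)
})

test_that("preset families assemble the expected grids", {
  fam <- list(`one-wave` = 36L, `two-wave-one-lineage` = 48L,
              `two-wave-two-lineage` = 36L, `unknown-lineage` = 24L)
  total <- 0L
  for (f in names(fam)) {
    cfgs <- preset_scenarios(f, seed = 10)
    expect_length(cfgs, fam[[f]])
    total <- total + length(cfgs)
    if (f == "one-wave")
      expect_true(all(vapply(cfgs, function(cc) length(cc$waves), 0L)
                      == 1L))
    if (f == "unknown-lineage")
      expect_true(any(vapply(cfgs, function(cc) cc$t_unk_split, 0)
                      == round(610e3 / 30)))
  }
  expect_equal(total, 144L)
})
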