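#' Scenario configuration for the tract-level simulator
#'
#' Defines the demography and sampling design of one simulated dataset:
#' chromosome length, mutation/recombination rates, split times of the
#' population scaffold, the list of introgression waves, and sample counts
#' per role.  Times are in generations; helper arguments ending in `_kya`
#' accept thousands of years and convert with `gen_years`.
#'
#' The scaffold tree is
#' `((test, African), (archaic-1, archaic-2)), outgroup` with the
#' modern-human/archaic split at `t_arch_split`, the split of the two
#' archaic reference lineages at `t_arc_split`, and each sequenced archaic
#' reference diverging from its introgressing source `t_ref_div`
#' generations ago.  An `"UNK"` wave introgresses from an unsampled lineage
#' that split from the known archaic references `t_unk_split` generations
#' ago (above the archaic-1/archaic-2 split it attaches to their common
#' stem, below it to the archaic-1 branch).
#'
#' @param chrom_len chromosome length in bp.
#' @param mu mutation rate per bp per generation.
#' @param rec recombination rate per bp per generation (Morgans per bp).
#' @param n_test,n_african haplotype counts for the test and African
#'   panels.
#' @param n_archaic named integer vector of archaic reference haplotype
#'   counts, default `c(NEA = 2, DEN = 2)`.
#' @param waves list of waves, each `list(lineage, t, m)` with lineage in
#'   `names(n_archaic)` or `"UNK"`, time `t` in generations and proportion
#'   `m` in (0, 1).  `sum(m) < 1` required.
#' @param t_arch_split,t_arc_split,t_ref_div,t_unk_split,t_out,t_afr_test
#'   split times in generations (defaults: 700, 450, 100, 610 kya for the
#'   archaic scaffold; 6 Mya outgroup; 75 kya African/test).
#' @param ne_human,ne_anc,ne_arc effective sizes of the human panel, of
#'   the ancestral human-archaic population (drives diversity and the
#'   incomplete-lineage-sorting layer) and of the archaic populations
#'   (drives lineage sorting within the archaic clade).
#' @param ils_frac fraction of each human haplotype lying in deep-ancestry
#'   blocks that share ancestral standing variation with the archaic
#'   lineage (the incomplete-lineage-sorting layer).
#' @param gen_years years per generation (30).
#' @param seed mandatory integer seed.
#' @return a list of class `"scenario_config"`.
#' @export
scenario_config <- function(chrom_len = 1e7, mu = 1.25e-8, rec = 1e-8,
                            n_test = 20, n_african = 20,
                            n_archaic = c(NEA = 2, DEN = 2),
                            waves = list(list(lineage = "NEA", t = 2000,
                                              m = 0.02)),
                            t_arch_split = round(700e3 / 30),
                            t_arc_split = round(450e3 / 30),
                            t_ref_div = round(100e3 / 30),
                            t_unk_split = round(610e3 / 30),
                            t_out = round(6e6 / 30),
                            t_afr_test = round(75e3 / 30),
                            ne_human = 1e4, ne_anc = 1e4, ne_arc = 2500,
                            ils_frac = 0.01, gen_years = 30,
                            seed = NULL) {
  if (is.null(seed)) stop("a seed is mandatory for reproducibility")
  cfg <- list(chrom_len = as.integer(chrom_len), mu = mu, rec = rec,
              n_test = n_test, n_african = n_african,
              n_archaic = n_archaic, waves = waves,
              t_arch_split = t_arch_split, t_arc_split = t_arc_split,
              t_ref_div = t_ref_div, t_unk_split = t_unk_split,
              t_out = t_out, t_afr_test = t_afr_test,
              ne_human = ne_human, ne_anc = ne_anc, ne_arc = ne_arc,
              ils_frac = ils_frac,
              gen_years = gen_years, seed = as.integer(seed))
  class(cfg) <- "scenario_config"
  .validate_scenario(cfg)
  cfg
}

.validate_scenario <- function(cfg) {
  with(cfg, {
    if (!(t_out > t_arch_split && t_arch_split > t_arc_split &&
          t_arc_split > t_ref_div && t_ref_div > 0))
      stop("inconsistent split times: need t_out > t_arch_split > ",
           "t_arc_split > t_ref_div > 0")
    if (t_afr_test >= t_arch_split) stop("t_afr_test too old")
    if (length(n_archaic) != 2L || is.null(names(n_archaic)))
      stop("exactly two named archaic reference groups are required")
    ms <- vapply(waves, function(w) w$m, 0)
    if (length(waves) && sum(ms) >= 1) stop("sum of wave proportions >= 1")
    for (w in waves) {
      if (!w$lineage %in% c(names(n_archaic), "UNK"))
        stop("wave lineage must be a reference group or 'UNK'")
      lim <- if (w$lineage == "UNK") t_unk_split else t_ref_div
      if (w$t <= 0 || w$t >= lim)
        stop("wave time must lie in (0, ", lim, ") for lineage ",
             w$lineage)
    }
    if (any(vapply(waves, function(w) w$lineage, "") == "UNK") &&
        !(t_unk_split > t_ref_div && t_unk_split < t_arch_split))
      stop("t_unk_split must lie in (t_ref_div, t_arch_split)")
  })
  invisible(cfg)
}

#' @export
print.scenario_config <- function(x, ...) {
  cat("<scenario_config>", x$chrom_len / 1e6, "Mb;",
      x$n_test, "test /", x$n_african, "African /",
      paste(names(x$n_archaic), x$n_archaic, sep = "=", collapse = "+"),
      "archaic haplotypes\n")
  for (w in x$waves)
    cat(sprintf("  wave: %s  t = %d gens  m = %.3f\n", w$lineage, w$t, w$m))
  cat("  seed:", x$seed, "\n")
  invisible(x)
}

# poisson-process tracts for one haplotype; lengths Exp(rate t) in Morgans
.lay_tracts <- function(cfg) {
  L_bp <- cfg$chrom_len
  L_M <- L_bp * cfg$rec
  out <- list()
  for (wi in seq_along(cfg$waves)) {
    w <- cfg$waves[[wi]]
    n <- stats::rpois(1L, w$m * w$t * L_M)
    if (!n) next
    start <- sort(stats::runif(n, 0, L_bp))
    len <- stats::rexp(n, rate = w$t) / cfg$rec
    out[[length(out) + 1L]] <- data.frame(
      start = start, end = pmin(start + len, L_bp),
      lineage = w$lineage, wave = wi, t = w$t, stringsAsFactors = FALSE)
  }
  empty <- data.frame(start = integer(0), end = integer(0),
                      lineage = character(0), wave = integer(0),
                      t = numeric(0), stringsAsFactors = FALSE)
  if (!length(out)) return(empty)
  tr <- do.call(rbind, out)
  tr <- tr[order(tr$start), ]
  # resolve overlaps: earlier-starting tract wins, later one is truncated
  keep <- logical(nrow(tr)); cur_end <- -Inf
  for (i in seq_len(nrow(tr))) {
    if (tr$start[i] < cur_end) tr$start[i] <- cur_end
    if (tr$start[i] < tr$end[i]) {
      keep[i] <- TRUE
      cur_end <- tr$end[i]
    }
  }
  tr <- tr[keep, , drop = FALSE]
  tr$start <- as.integer(floor(tr$start))
  tr$end <- as.integer(ceiling(tr$end))
  tr <- tr[tr$end > tr$start, , drop = FALSE]
  tr
}

# site positions of one mutation category: Poisson(density * L) uniforms
.draw_sites <- function(density, L) {
  n <- stats::rpois(1L, density * L)
  if (!n) integer(0) else sort.int(sample.int(L, n)) - 1L
}

#' Simulate a phased panel with known archaic tracts
#'
#' Tract-level simulator with branch-painted mutations.  Archaic tracts are
#' laid per test haplotype as a Poisson process (density `m * t` per
#' Morgan, lengths exponential with rate `t` per Morgan), then mutations
#' are painted site by site with Poisson draws on every branch of the
#' scenario scaffold, so that test-specific, archaic-marker, AMH-marker and
#' common sites arise with the correct sharing structure: human
#' polymorphism (neutral frequency spectrum, absent from archaic tracts),
#' population-private drift variants, deep outgroup-stem mutations, archaic
#' stem/branch/reference-private mutations, source-branch and
#' post-introgression tract mutations, and ancestral standing variation
#' fixed on the archaic side that leaks into human haplotypes through
#' stylized incomplete-lineage-sorting blocks.
#'
#' Monomorphic rows (possible after tract overwriting) are dropped; the
#' returned panel is already polarized, with a haploid outgroup column
#' carrying the ancestral allele everywhere, and carries genetic positions
#' from the (uniform) recombination rate.
#'
#' @param cfg a [scenario_config()].
#' @return list with `panel` (a [site_panel()]), `truth` (tract table:
#'   `chrom`, `start`, `end`, `hap`, `lineage`, `wave`) and `config`.
#' @export
simulate_panel <- function(cfg) {
  stopifnot(inherits(cfg, "scenario_config"))
  set.seed(cfg$seed)
  L <- cfg$chrom_len
  arc_names <- names(cfg$n_archaic)
  has_unk <- any(vapply(cfg$waves, function(w) w$lineage, "") == "UNK")
  t_u <- if (has_unk) cfg$t_unk_split else NA_real_

  hap_roles <- c(rep("test", cfg$n_test),
                 rep("african_ref", cfg$n_african),
                 rep(paste0("archaic_ref:", arc_names), cfg$n_archaic),
                 "outgroup")
  hap_ids <- c(sprintf("tst%02d", seq_len(cfg$n_test)),
               sprintf("afr%02d", seq_len(cfg$n_african)),
               unlist(lapply(arc_names, function(g)
                 sprintf("%s%d", tolower(g), seq_len(cfg$n_archaic[[g]])))),
               "outgroup")
  nh <- length(hap_roles)
  i_test <- which(hap_roles == "test")
  i_afr <- which(hap_roles == "african_ref")
  i_arc <- lapply(arc_names, function(g)
    which(hap_roles == paste0("archaic_ref:", g)))
  names(i_arc) <- arc_names
  i_hum <- c(i_test, i_afr)

  # ground-truth tracts per test haplotype
  truth <- list()
  tracts_by_hap <- vector("list", cfg$n_test)
  for (j in seq_len(cfg$n_test)) {
    tr <- .lay_tracts(cfg)
    tracts_by_hap[[j]] <- tr
    if (!is.null(tr) && nrow(tr))
      truth[[length(truth) + 1L]] <- data.frame(
        chrom = "1", start = tr$start, end = tr$end,
        hap = hap_ids[i_test[j]], lineage = tr$lineage, wave = tr$wave,
        stringsAsFactors = FALSE)
  }
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(chrom = character(), start = integer(), end = integer(),
               hap = character(), lineage = character(), wave = integer(),
               stringsAsFactors = FALSE)

  # --- mutation categories -------------------------------------------------
  mu <- cfg$mu
  a_n <- sum(1 / seq_len(max(length(i_hum) - 1L, 1L)))
  sites <- list(); paint <- list()
  add <- function(pos, painter) {
    if (!length(pos)) return()
    sites[[length(sites) + 1L]] <<- pos
    paint[[length(paint) + 1L]] <<- painter
  }

  # (1) human neutral polymorphism.  A frequency-dependent share of it
  # predates the human-archaic split (P(old) ~ exp(-T/2Ne) * freq) and is
  # then sorted by drift on the archaic side: each archaic population
  # (each reference lineage and each introgressing source) independently
  # fixed or lost such a variant with probability 1/2.
  pos <- .draw_sites(4 * cfg$ne_human * mu * a_n, L)
  if (length(pos)) {
    nH <- length(i_hum)
    k <- sample.int(nH - 1L, length(pos), replace = TRUE,
                    prob = 1 / seq_len(nH - 1L))
    p <- k / nH
    carrier <- matrix(stats::runif(length(pos) * nH) < rep(p, nH),
                      nrow = length(pos))
    p_old <- exp(-cfg$t_arch_split / (2 * cfg$ne_human))
    shared <- stats::runif(length(pos)) < p_old * p
    coin_ref <- matrix(shared & stats::runif(length(pos) *
                                             length(arc_names)) < 0.5,
                       nrow = length(pos))
    coin_src <- matrix(shared & stats::runif(length(pos) *
                                             length(cfg$waves)) < 0.5,
                       nrow = length(pos))
    add(pos, list(kind = "hum_poly", carrier = carrier,
                  coin_ref = coin_ref, coin_src = coin_src))
  }
  # (2) population-private drift variants since the African/test split
  for (side in c("test", "afr")) {
    idx <- if (side == "test") i_test else i_afr
    pos <- .draw_sites(mu * cfg$t_afr_test, L)
    if (length(pos)) {
      k <- sample.int(max(length(idx) - 1L, 1L), length(pos),
                      replace = TRUE,
                      prob = 1 / seq_len(max(length(idx) - 1L, 1L)))
      p <- k / length(idx)
      carrier <- matrix(stats::runif(length(pos) * length(idx)) <
                          rep(p, length(idx)), nrow = length(pos))
      add(pos, list(kind = "pop_priv", idx = idx, carrier = carrier))
    }
  }
  # (3) deep stem: everything except the outgroup is derived
  add(.draw_sites(mu * (cfg$t_out - cfg$t_arch_split), L),
      list(kind = "stem"))
  # (4) archaic stem, split at the unknown-lineage divergence when needed
  t_hi <- cfg$t_arch_split
  t_mid <- if (has_unk && t_u > cfg$t_arc_split) t_u else cfg$t_arc_split
  add(.draw_sites(mu * (t_hi - t_mid), L),
      list(kind = "arc_stem", unk_shared = TRUE))
  if (t_mid > cfg$t_arc_split)
    add(.draw_sites(mu * (t_mid - cfg$t_arc_split), L),
        list(kind = "arc_stem", unk_shared = FALSE))
  # (5) per-lineage branch + reference-private mutations
  for (g in arc_names) {
    br_hi <- cfg$t_arc_split
    br_lo <- cfg$t_ref_div
    if (has_unk && t_u < cfg$t_arc_split && g == arc_names[1]) {
      # unknown lineage attaches to the first archaic branch
      add(.draw_sites(mu * (br_hi - t_u), L),
          list(kind = "branch", g = g, unk_shared = TRUE))
      add(.draw_sites(mu * (t_u - br_lo), L),
          list(kind = "branch", g = g, unk_shared = FALSE))
    } else {
      add(.draw_sites(mu * (br_hi - br_lo), L),
          list(kind = "branch", g = g, unk_shared = FALSE))
    }
    add(.draw_sites(mu * cfg$t_ref_div, L),
        list(kind = "ref_priv", g = g))
  }
  # (6) source-branch mutations per wave (carried by that wave's tracts),
  #     plus the source's own ancestral-standing fixations: every lineage
  #     resolves ~2 Ne_anc mu of the ancestral pool, and the portion not
  #     shared with the references (1 - carry probability) is private
  for (wi in seq_along(cfg$waves)) {
    w <- cfg$waves[[wi]]
    top <- if (w$lineage == "UNK") t_u else cfg$t_ref_div
    own_anc <- if (w$lineage == "UNK")
      2 * cfg$ne_anc * mu * exp(-(cfg$t_arch_split - top) /
                                  (2 * cfg$ne_anc))
    else 2 * cfg$ne_arc * mu
    add(.draw_sites(mu * (top - w$t) + own_anc, L),
        list(kind = "src_priv", wave = wi))
  }
  # (7) ancestral standing variation fixed on the archaic side; human
  #     haplotypes carry it only inside deep (ILS) blocks
  anc_pos <- .draw_sites(2 * cfg$ne_anc * mu, L)
  ils_blocks <- vector("list", length(i_hum))
  if (cfg$ils_frac > 0) {
    mean_block <- 1 / (2 * cfg$rec * cfg$t_arch_split)
    for (b in seq_along(i_hum)) {
      nb <- stats::rpois(1L, cfg$ils_frac * L / mean_block)
      if (!nb) next
      s <- sort(stats::runif(nb, 0, L))
      e <- pmin(s + stats::rexp(nb, 1 / mean_block), L)
      ils_blocks[[b]] <- cbind(s, e)
    }
  }
  add(anc_pos, list(kind = "anc_fix"))

  pos_all <- unlist(sites, use.names = FALSE)
  if (!length(pos_all)) stop("simulation produced no sites")
  ord <- order(pos_all)
  geno <- matrix(0L, nrow = length(pos_all), ncol = nh)
  offset <- 0L
  row_of <- vector("list", length(sites))
  for (ci in seq_along(sites)) {
    row_of[[ci]] <- offset + seq_along(sites[[ci]])
    offset <- offset + length(sites[[ci]])
  }

  in_tract <- function(j, p, wave_only = NULL, lineage_only = NULL) {
    tr <- tracts_by_hap[[j]]
    if (is.null(tr) || !nrow(tr)) return(rep(FALSE, length(p)))
    if (!is.null(wave_only)) tr <- tr[tr$wave == wave_only, , drop = FALSE]
    if (!is.null(lineage_only))
      tr <- tr[tr$lineage %in% lineage_only, , drop = FALSE]
    if (!nrow(tr)) return(rep(FALSE, length(p)))
    iv <- findInterval(p, tr$start)
    iv > 0L & p < tr$end[pmax(iv, 1L)]
  }

  for (ci in seq_along(sites)) {
    p <- sites[[ci]]; pa <- paint[[ci]]; rows <- row_of[[ci]]
    switch(pa$kind,
      hum_poly = {
        geno[rows, i_hum] <- pa$carrier * 1L
        # archaic tracts replace the human haplotype: no human-derived there
        for (j in seq_len(cfg$n_test))
          geno[rows[in_tract(j, p)], i_test[j]] <- 0L
        # ancestral-shared polymorphism sorted on the archaic side
        for (gi in seq_along(arc_names))
          geno[rows[pa$coin_ref[, gi]], i_arc[[arc_names[gi]]]] <- 1L
        for (wi in seq_along(cfg$waves))
          for (j in seq_len(cfg$n_test)) {
            hit <- pa$coin_src[, wi] & in_tract(j, p, wave_only = wi)
            geno[rows[hit], i_test[j]] <- 1L
          }
      },
      pop_priv = {
        geno[rows, pa$idx] <- pa$carrier * 1L
        if (identical(pa$idx, i_test))
          for (j in seq_len(cfg$n_test))
            geno[rows[in_tract(j, p)], i_test[j]] <- 0L
      },
      stem = geno[rows, -nh] <- 1L,
      arc_stem = {
        for (g in arc_names) geno[rows, i_arc[[g]]] <- 1L
        lin <- if (pa$unk_shared) c(arc_names, "UNK") else arc_names
        for (j in seq_len(cfg$n_test))
          geno[rows[in_tract(j, p, lineage_only = lin)], i_test[j]] <- 1L
      },
      branch = {
        geno[rows, i_arc[[pa$g]]] <- 1L
        lin <- if (pa$unk_shared) c(pa$g, "UNK") else pa$g
        for (j in seq_len(cfg$n_test))
          geno[rows[in_tract(j, p, lineage_only = lin)], i_test[j]] <- 1L
      },
      ref_priv = geno[rows, i_arc[[pa$g]]] <- 1L,
      src_priv = {
        for (j in seq_len(cfg$n_test))
          geno[rows[in_tract(j, p, wave_only = pa$wave)], i_test[j]] <- 1L
      },
      anc_fix = {
        for (g in arc_names) geno[rows, i_arc[[g]]] <- 1L
        # a source lineage carries a variant destined for fixation in the
        # sampled references only if it was already (near-)fixed when the
        # source diverged: carry probability decays with the stem time
        # remaining, 1 - exp(-(t_arch_split - t_div) / (2 Ne_anc))
        for (wi in seq_along(cfg$waves)) {
          w <- cfg$waves[[wi]]
          # fixation along the shared stem runs at the drift timescale of
          # the population the stem passes through: the deep ancestral
          # population for an unknown lineage, the (small) archaic
          # population for a source inside a sampled lineage
          pc <- if (w$lineage == "UNK")
            1 - exp(-(cfg$t_arch_split - t_u) / (2 * cfg$ne_anc))
          else
            1 - exp(-(cfg$t_arch_split - cfg$t_ref_div) /
                      (2 * cfg$ne_arc))
          carried <- stats::runif(length(p)) < pc
          for (j in seq_len(cfg$n_test)) {
            hit <- carried & in_tract(j, p, wave_only = wi)
            geno[rows[hit], i_test[j]] <- 1L
          }
        }
        for (b in seq_along(i_hum)) {
          bl <- ils_blocks[[b]]
          if (is.null(bl)) next
          iv <- findInterval(p, bl[, 1])
          inb <- iv > 0L & p < bl[pmax(iv, 1L), 2]
          hit <- inb & stats::runif(length(p)) < 0.5
          if (b <= cfg$n_test) {
            # an archaic tract overrides the block: it carries the allele
            hit <- hit & !in_tract(b, p)
            geno[rows[hit], i_hum[b]] <- 1L
          } else geno[rows[hit], i_hum[b]] <- 1L
        }
      })
  }
  # (8) post-introgression mutations private to each tract haplotype
  extra_pos <- list(); extra_hap <- list()
  for (j in seq_len(cfg$n_test)) {
    tr <- tracts_by_hap[[j]]
    if (is.null(tr) || !nrow(tr)) next
    for (r in seq_len(nrow(tr))) {
      nmut <- stats::rpois(1L, mu * tr$t[r] * (tr$end[r] - tr$start[r]))
      if (!nmut) next
      extra_pos[[length(extra_pos) + 1L]] <-
        tr$start[r] + sort.int(sample.int(tr$end[r] - tr$start[r],
                                          nmut)) - 1L
      extra_hap[[length(extra_hap) + 1L]] <- rep(i_test[j], nmut)
    }
  }
  if (length(extra_pos)) {
    ep <- unlist(extra_pos); eh <- unlist(extra_hap)
    g2 <- matrix(0L, nrow = length(ep), ncol = nh)
    g2[cbind(seq_along(ep), eh)] <- 1L
    pos_all <- c(pos_all, ep)
    geno <- rbind(geno, g2)
  }

  ord <- order(pos_all)
  pos_all <- pos_all[ord]
  geno <- geno[ord, , drop = FALSE]
  dup <- duplicated(pos_all)
  poly <- rowSums(geno) > 0L
  keep <- !dup & poly
  pos_all <- pos_all[keep]
  geno <- geno[keep, , drop = FALSE]

  panel <- site_panel("1", pos_all, geno, hap_roles, hap = hap_ids,
                      gpos = pos_all * cfg$rec, polarized = TRUE,
                      ref = rep("A", length(pos_all)),
                      alt = rep("G", length(pos_all)))
  list(panel = panel, truth = truth, config = cfg)
}

#' Preset scenario grids
#'
#' Emits the scenario families used by the benchmark suite.  The four
#' families assemble a 144-scenario grid: 36 single-wave configurations
#' (times 500-3000 generations, proportions 0.5-2%, two source-reference
#' divergence depths), 48 two-wave single-lineage configurations, 36
#' two-wave two-lineage configurations and 24 unknown-lineage
#' configurations (source split 310-610 kya from the known references,
#' including the deepest 610 kya setting).  The grids are approximate
#' reproductions: they cover the stated ranges, not a published table.
#'
#' @param family one of `"one-wave"`, `"two-wave-one-lineage"`,
#'   `"two-wave-two-lineage"`, `"unknown-lineage"`.
#' @param chrom_len,n_test,n_african panel size shared by every config in
#'   the family.
#' @param seed base seed; config i uses `seed + i`.
#' @return list of [scenario_config()] objects.
#' @export
preset_scenarios <- function(family = c("one-wave", "two-wave-one-lineage",
                                        "two-wave-two-lineage",
                                        "unknown-lineage"),
                             chrom_len = 1e7, n_test = 20, n_african = 20,
                             seed = 1000) {
  family <- match.arg(family)
  cfgs <- list()
  push <- function(waves, ...) {
    i <- length(cfgs) + 1L
    cfgs[[i]] <<- scenario_config(chrom_len = chrom_len, n_test = n_test,
                                  n_african = n_african, waves = waves,
                                  seed = seed + i, ...)
  }
  if (family == "one-wave") {
    for (tr in round(c(100e3, 300e3) / 30))
      for (t in c(500, 1000, 1500, 2000, 2500, 3000))
        for (m in c(0.005, 0.01, 0.02))
          push(list(list(lineage = "NEA", t = t, m = m)), t_ref_div = tr)
  } else if (family == "two-wave-one-lineage") {
    # mostly well-separated pulse pairs, plus one relatively close pair
    # (the documented hard corner for tract-length dating)
    tp <- list(c(500, 1500), c(500, 2000), c(500, 2500), c(500, 3000),
               c(800, 2400), c(1000, 2500), c(1000, 3000), c(1500, 2500))
    mp <- list(c(0.01, 0.01), c(0.02, 0.01), c(0.01, 0.02),
               c(0.015, 0.005), c(0.005, 0.015), c(0.015, 0.015))
    for (t2 in tp) for (m2 in mp)
      push(list(list(lineage = "NEA", t = t2[2], m = m2[1]),   # older
                list(lineage = "NEA", t = t2[1], m = m2[2])))  # recent
  } else if (family == "two-wave-two-lineage") {
    tp <- list(c(1000, 2000), c(1500, 2500), c(2000, 1000), c(2500, 1500),
               c(1500, 1500), c(2000, 3000))
    mp <- list(c(0.01, 0.01), c(0.02, 0.005), c(0.005, 0.02),
               c(0.015, 0.01), c(0.01, 0.015), c(0.02, 0.02))
    for (t2 in tp) for (m2 in mp)
      push(list(list(lineage = "NEA", t = t2[1], m = m2[1]),
                list(lineage = "DEN", t = t2[2], m = m2[2])))
  } else {
    for (ts in round(c(310e3, 410e3, 510e3, 610e3) / 30))
      for (t in c(1000, 1500, 2000))
        for (m in c(0.01, 0.02))
          push(list(list(lineage = "UNK", t = t, m = m)),
               t_unk_split = ts)
  }
  cfgs
}
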