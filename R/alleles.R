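#' Probability that a derived allele on an archaic segment is archaic
#'
#' For a derived allele observed on an inferred archaic segment, the
#' probability that it is genuinely of archaic origin combines two
#' independent leak paths: imperfect detection power may leave the allele
#' visible on inferred modern-human sequence, and back-flow admixture may
#' carry it into Africans.  With detection power `p`, back-flow proportion
#' `m` and archaic ancestry proportion `alpha`,
#' \deqn{P(A) = [p_d^M (1-p) + (1 - p_d^M)] [p_d^{Afr} m \alpha + (1 - p_d^{Afr})]}
#' where `p_d_M` and `p_d_Afr` are the allele's derived frequencies on
#' inferred modern-human segments and in Africans.  The probability is
#' monotone decreasing in both frequencies (for `p < 1`, `m alpha < 1`).
#'
#' @param p_d_M derived frequency on inferred modern-human sequence.
#' @param p_d_Afr derived frequency in the African panel.
#' @param p detection power of the segment scan.
#' @param m back-flow admixture proportion into Africans.
#' @param alpha archaic ancestry proportion in the admixed population.
#' @return `P(A)`; all arguments recycle.
#' @export
archaic_allele_probability <- function(p_d_M, p_d_Afr, p, m, alpha) {
  stopifnot(all(c(p_d_M, p_d_Afr, p, m, alpha) >= 0),
            all(c(p_d_M, p_d_Afr, p, m, alpha) <= 1))
  (p_d_M * (1 - p) + (1 - p_d_M)) * (p_d_Afr * m * alpha + (1 - p_d_Afr))
}

#' Call archaic alleles on decoded segments
#'
#' For every site at which some decoded archaic segment's haplotype
#' carries the derived allele, computes the derived frequency on inferred
#' modern-human sequence (test haplotypes outside their own archaic
#' segments), the derived frequency in Africans, and the probability that
#' the allele is not archaic; the allele is called archaic when that
#' complement is strictly below `threshold`.
#'
#' @param panel a polarized [site_panel()].
#' @param segments decoded segment table.
#' @param p,m,alpha see [archaic_allele_probability()]; `p` defaults to
#'   0.9, near the measured detection power; `m` and `alpha` must be set
#'   per dataset.
#' @param threshold call threshold on `P(not archaic)` (strict).
#' @return data frame: `pos`, `p_d_M`, `p_d_Afr`, `P_A`, `call`.
#' @export
call_archaic_alleles <- function(panel, segments, p = 0.9, m, alpha,
                                 threshold = 0.05) {
  test_i <- role_index(panel, "test")
  afr_i <- role_index(panel, "african_ref")
  n_site <- length(panel$pos)
  # haplotype-site archaic mask from the segments
  on_arch <- matrix(FALSE, n_site, length(test_i))
  colnames(on_arch) <- panel$hap[test_i]
  for (r in seq_len(nrow(segments))) {
    j <- match(segments$hap[r], colnames(on_arch))
    if (is.na(j)) next
    idx <- panel$pos >= segments$start[r] & panel$pos < segments$end[r]
    on_arch[idx, j] <- TRUE
  }
  gt <- panel$geno[, test_i, drop = FALSE]
  der_on_arch <- rowSums(gt == 1L & on_arch, na.rm = TRUE) > 0L
  cand <- which(der_on_arch)
  if (!length(cand))
    return(data.frame(pos = integer(0), p_d_M = numeric(0),
                      p_d_Afr = numeric(0), P_A = numeric(0),
                      call = logical(0)))
  mod <- gt == 1L & !on_arch
  mod_n <- rowSums(!is.na(gt) & !on_arch)
  p_d_M <- ifelse(mod_n > 0, rowSums(mod, na.rm = TRUE) / mod_n, 0)[cand]
  ga <- panel$geno[cand, afr_i, drop = FALSE]
  p_d_Afr <- rowMeans(ga == 1L, na.rm = TRUE)
  p_d_Afr[is.nan(p_d_Afr)] <- 0
  P_A <- archaic_allele_probability(p_d_M, p_d_Afr, p, m, alpha)
  data.frame(pos = panel$pos[cand], p_d_M = p_d_M, p_d_Afr = p_d_Afr,
             P_A = P_A, call = (1 - P_A) < threshold)
}

#' Cluster sites into LD loci
#'
#' Greedy left-to-right clustering: a site joins the nearest existing
#' cluster whose representative (founder) site tags it at `r^2 >`
#' `r2` and lies within `window` bp; otherwise it founds a new cluster.
#' Sites that no other site tags therefore remain singleton clusters.
#' `r^2` is the squared haplotype correlation within the chosen
#' population.
#'
#' @param panel a polarized [site_panel()].
#' @param population role whose haplotypes define LD (default `"test"`).
#' @param r2 tagging threshold (strict).
#' @param window maximum representative distance in bp.
#' @return data frame: `site` (panel site index), `pos`, `cluster`,
#'   `is_representative`.
#' @export
cluster_ld_loci <- function(panel, population = "test", r2 = 0.8,
                            window = 5e5) {
  idx <- role_index(panel, population)
  g <- panel$geno[, idx, drop = FALSE]
  n <- length(panel$pos)
  cluster <- integer(n)
  rep_site <- integer(0)   # representative site index per cluster
  for (i in seq_len(n)) {
    assigned <- FALSE
    if (length(rep_site)) {
      dist <- panel$pos[i] - panel$pos[rep_site]
      cand <- which(dist >= 0 & dist <= window)
      if (length(cand)) {
        for (k in cand[order(dist[cand])]) {
          gi <- g[i, ]; gr <- g[rep_site[k], ]
          ok <- !is.na(gi) & !is.na(gr)
          if (sum(ok) < 2L) next
          if (stats::sd(gi[ok]) == 0 || stats::sd(gr[ok]) == 0) next
          if (stats::cor(gi[ok], gr[ok])^2 > r2) {
            cluster[i] <- k; assigned <- TRUE; break
          }
        }
      }
    }
    if (!assigned) {
      rep_site <- c(rep_site, i)
      cluster[i] <- length(rep_site)
    }
  }
  data.frame(site = seq_len(n), pos = panel$pos, cluster = cluster,
             is_representative = seq_len(n) %in% rep_site)
}

#' eQTL enrichment of archaic loci
#'
#' A cluster is an archaic locus when it contains at least one called
#' archaic allele, and a gene-expression-associated (GEA) locus for a
#' tissue when at least one of its sites is an eQTL there.  For each
#' tissue the test draws `n_sets` random sets of non-archaic loci of
#' equal number and matched representative-allele frequency (1%-wide
#' bins) and computes the enrichment score
#' `(#archaic GEA / #archaic) / (#non-archaic GEA / #non-archaic)`;
#' scores above 1 indicate enrichment.  Draws whose denominator is zero
#' are redone (and counted).  One-sided empirical p-values are corrected
#' across tissues with Benjamini-Hochberg.
#'
#' Representative alleles follow the frequency-matching rules: for an
#' archaic GEA locus an archaic eQTL when available, else a random
#' archaic allele; for an archaic non-GEA locus a random archaic allele;
#' for a non-archaic locus a random eQTL (GEA) or random allele.
#'
#' @param loci output of [cluster_ld_loci()].
#' @param annotation data frame `site`, `tissue`, `is_eqtl` (site =
#'   panel site index).
#' @param is_archaic logical per panel site: called archaic allele.
#' @param freq derived-allele frequency per panel site (for matching).
#' @param n_sets number of matched resample sets.
#' @param seed integer seed.
#' @return data frame per tissue: `tissue`, `score` (median over sets),
#'   `p_emp`, `p_bh`, `n_archaic`, `n_gea_archaic`, `redraws`.
#' @export
enrichment_test <- function(loci, annotation, is_archaic, freq,
                            n_sets = 100L, seed = 1L) {
  old_seed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(seed)
  tissues <- unique(annotation$tissue)
  cl_sites <- split(loci$site, loci$cluster)
  arch_cl <- vapply(cl_sites, function(s) any(is_archaic[s]), TRUE)
  res <- list()
  for (tis in tissues) {
    eq <- rep(FALSE, max(loci$site))
    ann <- annotation[annotation$tissue == tis, ]
    eq[ann$site[ann$is_eqtl]] <- TRUE
    gea_cl <- vapply(cl_sites, function(s) any(eq[s]), TRUE)
    rep_freq <- vapply(seq_along(cl_sites), function(ci) {
      s <- cl_sites[[ci]]
      pool <- if (arch_cl[ci]) {
        pe <- s[is_archaic[s] & eq[s]]
        if (length(pe)) pe else s[is_archaic[s]]
      } else {
        pe <- s[eq[s]]
        if (gea_cl[ci] && length(pe)) pe else s
      }
      freq[if (length(pool) == 1L) pool else sample(pool, 1L)]
    }, 0)
    A <- which(arch_cl); N <- which(!arch_cl)
    if (!length(A) || !length(N)) next
    bin <- floor(pmin(rep_freq, 0.999999) / 0.01)
    propA <- mean(gea_cl[A])
    scores <- numeric(n_sets); props <- numeric(n_sets)
    redraws <- 0L
    N_by_bin <- split(N, bin[N])
    draw_set <- function() {
      vapply(A, function(a) {
        pool <- N_by_bin[[as.character(bin[a])]]
        while (is.null(pool)) {  # widen to nearest non-empty bin
          bins_av <- as.integer(names(N_by_bin))
          nb <- bins_av[which.min(abs(bins_av - bin[a]))]
          pool <- N_by_bin[[as.character(nb)]]
        }
        if (length(pool) == 1L) pool else sample(pool, 1L)
      }, 0L)
    }
    for (b in seq_len(n_sets)) {
      repeat {
        s <- draw_set()
        propN <- mean(gea_cl[s])
        if (propN > 0 || propA == 0) break
        redraws <- redraws + 1L
        if (redraws > 50L * n_sets) stop("degenerate annotation: no GEA ",
                                         "non-archaic loci drawable")
      }
      props[b] <- propN
      scores[b] <- if (propN == 0) NA else propA / propN
    }
    p_emp <- (1 + sum(props >= propA)) / (n_sets + 1)
    res[[length(res) + 1L]] <- data.frame(
      tissue = tis, score = stats::median(scores, na.rm = TRUE),
      p_emp = p_emp, n_archaic = length(A),
      n_gea_archaic = sum(gea_cl[A]), redraws = redraws,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  out$p_bh <- stats::p.adjust(out$p_emp, method = "BH")
  out[, c("tissue", "score", "p_emp", "p_bh", "n_archaic",
          "n_gea_archaic", "redraws")]
}
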