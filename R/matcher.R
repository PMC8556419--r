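#' Calibrate the reference ancestry tree from genome-wide distances
#'
#' The matcher works on a rooted tree over the role groups
#' `((test, African), (archaic-1, archaic-2)), outgroup`.  Calibration
#' replaces prior branch lengths with lengths fitted to genome-wide mean
#' pairwise difference densities between role groups — the same statistic
#' the per-segment profiles use, so that placement expectations and
#' observations stay on one scale.  Under a molecular clock the
#' least-squares height of each internal node is the mean of
#' `D / (2 mu)` over the group pairs whose most recent common ancestor is
#' that node, and the outgroup fixes the root depth.  Heights violating
#' the topology ordering are clamped (and reported via the `"clamped"`
#' attribute), mirroring the usual non-negativity clamp of least-squares
#' branch fitting.
#'
#' @param panel a polarized [site_panel()] containing test, African, two
#'   archaic reference groups and an outgroup.
#' @param mu mutation rate per bp per generation used to convert
#'   difference densities into time.
#' @param max_pairs cap on haplotype pairs sampled per group pair when
#'   averaging distances (keeps calibration O(sites)).
#' @return an object of class `"ancestry_tree"`: group names, node heights
#'   in generations (`h_ta`, `h_12`, `h_ha`, `h_root`), `mu`, and the
#'   group distance matrix (differences per bp).
#' @export
calibrate_tree <- function(panel, mu = 1.25e-8, max_pairs = 25L) {
  if (!panel$polarized) stop("panel must be polarized")
  og <- role_index(panel, "outgroup")
  if (!length(og)) stop("outgroup haplotype missing: cannot set the root")
  arcs <- archaic_groups(panel)
  if (length(arcs) != 2L)
    stop("matcher requires exactly two archaic reference groups")
  groups <- list(test = role_index(panel, "test"),
                 african = role_index(panel, "african_ref"))
  for (g in arcs) groups[[g]] <- role_index(panel, paste0("archaic_ref:", g))
  groups$outgroup <- og
  gn <- names(groups)
  span <- diff(range(panel$pos)) + 1L
  D <- matrix(0, length(groups), length(groups),
              dimnames = list(gn, gn))
  pair_dens <- function(i, j) {
    gi <- panel$geno[, i]; gj <- panel$geno[, j]
    ok <- !is.na(gi) & !is.na(gj)
    sum(gi[ok] != gj[ok]) / (span * mean(ok))
  }
  for (a in seq_along(groups)) for (b in seq_along(groups)) {
    if (b <= a) next
    ia <- groups[[a]]; ib <- groups[[b]]
    pairs <- expand.grid(ia, ib)
    if (nrow(pairs) > max_pairs)
      pairs <- pairs[sample.int(nrow(pairs), max_pairs), ]
    D[a, b] <- D[b, a] <- mean(mapply(pair_dens, pairs[[1]], pairs[[2]]))
  }
  h <- function(d) d / (2 * mu)
  h_ta <- h(D["test", "african"])
  h_12 <- h(D[arcs[1], arcs[2]])
  cross <- c(D["test", arcs[1]], D["test", arcs[2]],
             D["african", arcs[1]], D["african", arcs[2]])
  h_ha <- h(mean(cross))
  h_root <- h(mean(D["outgroup", c("test", "african", arcs)]))
  clamped <- character(0)
  if (h_ha < max(h_ta, h_12)) {
    clamped <- c(clamped, "h_ha")
    h_ha <- max(h_ta, h_12)
  }
  if (h_root < h_ha) { clamped <- c(clamped, "h_root"); h_root <- h_ha }
  out <- structure(list(arcs = arcs, h_ta = h_ta, h_12 = h_12,
                        h_ha = h_ha, h_root = h_root, mu = mu, D = D),
                   class = "ancestry_tree")
  attr(out, "clamped") <- clamped
  if (length(clamped))
    message("calibration clamped node height(s): ",
            paste(clamped, collapse = ", "))
  out
}

#' @export
print.ancestry_tree <- function(x, ...) {
  cat("<ancestry_tree> ((test,african),(", x$arcs[1], ",", x$arcs[2],
      ")),outgroup\n", sep = "")
  cat(sprintf("  node heights (generations): test/african %.0f; %s/%s %.0f;",
              x$h_ta, x$arcs[1], x$arcs[2], x$h_12),
      sprintf("human/archaic %.0f; root %.0f\n", x$h_ha, x$h_root))
  invisible(x)
}

#' Export / import the calibrated tree as Newick
#'
#' Branch lengths are written in generations; [ape::read.tree()] /
#' [ape::write.tree()] do the parsing.
#'
#' @param tree an `"ancestry_tree"`.
#' @param path file path.
#' @export
write_tree_newick <- function(tree, path) {
  nwk <- sprintf(
    "((( test:%f,african:%f):%f,(%s:%f,%s:%f):%f):%f,outgroup:%f);",
    tree$h_ta, tree$h_ta, tree$h_ha - tree$h_ta,
    tree$arcs[1], tree$h_12, tree$arcs[2], tree$h_12, tree$h_ha - tree$h_12,
    tree$h_root - tree$h_ha, tree$h_root)
  nwk <- gsub(" ", "", nwk)
  ph <- ape::read.tree(text = nwk)
  ape::write.tree(ph, file = path)
  invisible(path)
}

#' Per-reference-group difference profile of a segment
#'
#' For every reference group, the mean density of mismatching sites
#' between the segment's own haplotype and the group's haplotypes, over
#' the callable bp of the segment.  Group means keep the statistic on the
#' same scale as the calibrated tree at every segment length (a
#' per-segment minimum would be biased low over short windows).  Callable
#' bp is the segment length scaled by the fraction of its sites genotyped
#' in both haplotypes; missing reference calls are never imputed.
#'
#' @param segment one row of a segment table (`start`, `end`, `hap`).
#' @param panel a polarized [site_panel()].
#' @return list with `counts` and `callable` (named per group: `african`,
#'   each archaic group, `test` (other test haplotypes), `outgroup`) and
#'   the segment's haplotype and length.
#' @export
segment_difference_profile <- function(segment, panel) {
  idx <- which(panel$pos >= segment$start & panel$pos < segment$end)
  if (!length(idx)) stop("uninformative segment: no genotyped site")
  h <- match(segment$hap, panel$hap)
  if (is.na(h)) stop("unknown haplotype ", segment$hap)
  g0 <- panel$geno[idx, h]
  len <- segment$end - segment$start
  arcs <- archaic_groups(panel)
  groups <- list(african = role_index(panel, "african_ref"))
  for (g in arcs) groups[[g]] <- role_index(panel, paste0("archaic_ref:", g))
  groups$test <- setdiff(role_index(panel, "test"), h)
  groups$outgroup <- role_index(panel, "outgroup")
  counts <- callable <- stats::setNames(numeric(length(groups)),
                                        names(groups))
  for (gi in seq_along(groups)) {
    cols <- groups[[gi]]
    if (!length(cols)) { counts[gi] <- NA; callable[gi] <- NA; next }
    mis <- cal <- numeric(0)
    for (j in cols) {
      gj <- panel$geno[idx, j]
      ok <- !is.na(g0) & !is.na(gj)
      if (!any(ok)) next
      mis <- c(mis, sum(g0[ok] != gj[ok]))
      cal <- c(cal, len * mean(ok))
    }
    if (!length(mis)) stop("uninformative segment: no callable site")
    counts[gi] <- mean(mis); callable[gi] <- mean(cal)
  }
  list(counts = counts, callable = callable, hap = segment$hap, len = len)
}

# the seven candidate placements of a segment's source on the calibrated
# tree; each defines, per observed group, the MRCA time with the source as
# a function of the attachment time t on that edge.
.placements <- function(tree) {
  a1 <- tree$arcs[1]; a2 <- tree$arcs[2]
  list(
    list(label = a1, below = a1, lo = 0, hi = tree$h_12,
         fixed = c(african = tree$h_ha, test = tree$h_ha,
                   outgroup = tree$h_root),
         fixed_arc = stats::setNames(tree$h_12, a2)),
    list(label = a2, below = a2, lo = 0, hi = tree$h_12,
         fixed = c(african = tree$h_ha, test = tree$h_ha,
                   outgroup = tree$h_root),
         fixed_arc = stats::setNames(tree$h_12, a1)),
    list(label = "archaic_ancestor", below = c(a1, a2), lo = tree$h_12,
         hi = tree$h_ha,
         fixed = c(african = tree$h_ha, test = tree$h_ha,
                   outgroup = tree$h_root), fixed_arc = numeric(0)),
    list(label = "superarchaic", below = c(a1, a2, "african", "test"),
         lo = tree$h_ha, hi = tree$h_root,
         fixed = c(outgroup = tree$h_root), fixed_arc = numeric(0)),
    list(label = "AMH", below = "test", lo = 0, hi = tree$h_ta,
         fixed = c(african = tree$h_ta, outgroup = tree$h_root),
         fixed_arc = stats::setNames(c(tree$h_ha, tree$h_ha), c(a1, a2))),
    list(label = "ILS", below = c("test", "african"), lo = tree$h_ta,
         hi = tree$h_ha, fixed = c(outgroup = tree$h_root),
         fixed_arc = stats::setNames(c(tree$h_ha, tree$h_ha), c(a1, a2))),
    list(label = "outgroup", below = "outgroup", lo = 0, hi = tree$h_root,
         fixed = c(african = tree$h_root, test = tree$h_root),
         fixed_arc = stats::setNames(c(tree$h_root, tree$h_root),
                                     c(a1, a2)))
  )
}

#' Match a segment to one of the seven candidate origins
#'
#' Places the segment's source lineage on each of the seven candidate
#' edges of the calibrated tree — each archaic terminal edge, the archaic
#' common-ancestor edge, the superarchaic stem below the root, the
#' modern-human terminal edge (false positive), the human/archaic
#' ancestral edge (incomplete lineage sorting) and the outgroup side — and
#' scores each placement with an independent-Poisson log-likelihood of the
#' observed per-group difference counts given expected densities
#' `2 mu T_MRCA`.  The attachment time on the edge is profiled out by its
#' clamped maximum-likelihood value.  Exact ties are resolved toward the
#' edge closest to the root (the conservative call).
#'
#' @param profile output of [segment_difference_profile()].
#' @param tree a calibrated [calibrate_tree()] result.
#' @param gen_years years per generation for the reported split time.
#' @return list of class `"match_result"`: `loglik` (named length-7
#'   vector), `label`, `t_hat` (attachment time, generations),
#'   `split_kya`, and `lineage_class` (one of `archaic`, `ILS`,
#'   `false_positive`).
#' @export
match_segment <- function(profile, tree, gen_years = 30) {
  pls <- .placements(tree)
  mu <- tree$mu
  ll <- stats::setNames(numeric(length(pls)),
                        vapply(pls, `[[`, "", "label"))
  t_hat <- numeric(length(pls))
  mid <- numeric(length(pls))
  for (i in seq_along(pls)) {
    pl <- pls[[i]]
    nb <- profile$counts[pl$below]
    cb <- profile$callable[pl$below]
    t_mle <- sum(nb) / (2 * mu * sum(cb))
    t_mle <- min(max(t_mle, pl$lo), pl$hi)
    t_hat[i] <- t_mle
    mid[i] <- (pl$lo + pl$hi) / 2
    exp_t <- c(stats::setNames(rep(t_mle, length(pl$below)), pl$below),
               pl$fixed, pl$fixed_arc)
    lli <- 0
    for (g in names(exp_t)) {
      if (is.na(profile$counts[g])) next
      lam <- pmax(2 * mu * exp_t[g] * profile$callable[g], 1e-12)
      lli <- lli + stats::dpois(round(profile$counts[g]), lam, log = TRUE)
    }
    ll[i] <- lli
  }
  best <- which(ll == max(ll))
  if (length(best) > 1L) best <- best[which.max(mid[best])]
  structure(list(loglik = ll, label = names(ll)[best],
                 t_hat = t_hat[best],
                 split_kya = t_hat[best] * gen_years / 1000,
                 lineage_class = switch(names(ll)[best],
                   AMH = "false_positive", outgroup = "false_positive",
                   ILS = "ILS", "archaic")),
            class = "match_result")
}

#' Split-time estimate of a matched segment
#'
#' Converts the segment's difference density to its best-edge attachment
#' time, `t = density / (2 mu)` generations, clamped to the edge's time
#' interval, and reports it in thousands of years.
#'
#' @inheritParams match_segment
#' @param mu mutation rate (defaults to the tree's).
#' @return split time in kya.
#' @export
estimate_split_time <- function(profile, tree, mu = tree$mu,
                                gen_years = 30) {
  m <- match_segment(profile, tree, gen_years = gen_years)
  m$split_kya
}

#' Match every segment of a table
#'
#' Convenience wrapper: calibrates the tree (unless given), profiles and
#' matches each segment, and returns the segment table extended with the
#' seven log-likelihoods, the best label, the lineage class and the
#' per-segment split time.
#'
#' @param segments segment data frame ([decode_segments()]).
#' @param panel a polarized [site_panel()].
#' @param tree optional calibrated tree; computed from the panel if `NULL`.
#' @param gen_years years per generation.
#' @return the extended segment data frame; the calibrated tree is
#'   attached as attribute `"tree"`.
#' @export
match_segments <- function(segments, panel, tree = NULL, gen_years = 30) {
  if (is.null(tree)) tree <- calibrate_tree(panel)
  if (!nrow(segments)) {
    segments$label <- character(0)
    segments$lineage_class <- character(0)
    segments$split_kya <- numeric(0)
    attr(segments, "tree") <- tree
    return(segments)
  }
  res <- vector("list", nrow(segments))
  for (i in seq_len(nrow(segments))) {
    pr <- segment_difference_profile(segments[i, ], panel)
    res[[i]] <- match_segment(pr, tree, gen_years = gen_years)
  }
  lab <- vapply(res, `[[`, "", "label")
  lls <- t(vapply(res, `[[`, numeric(7), "loglik"))
  colnames(lls) <- paste0("ll_", names(res[[1]]$loglik))
  out <- cbind(segments, lls,
               data.frame(label = lab,
                          lineage_class = vapply(res, `[[`, "",
                                                 "lineage_class"),
                          split_kya = vapply(res, `[[`, 0, "split_kya"),
                          stringsAsFactors = FALSE))
  attr(out, "tree") <- tree
  out
}
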