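#' Local introgression frequency track of a population
#'
#' At every position, the fraction of the population's haplotypes covered
#' by an introgressed segment, stored as a piecewise-constant track over
#' `[0, genome_bp)`.
#'
#' @param segments segment table (rows restricted to the population's
#'   haplotypes are selected via `haps`).
#' @param haps character vector: the population's haplotype ids (defines
#'   the denominator, including haplotypes without any segment).
#' @param genome_bp genome length (bp).
#' @param chrom chromosome label for the track.
#' @return data frame of class `"freq_track"` with columns `start`, `end`,
#'   `p`; attributes `P` (genome-wide proportion), `L` (total length),
#'   `n_hap`.
#' @export
local_frequency <- function(segments, haps, genome_bp, chrom = "1") {
  seg <- segments[segments$hap %in% haps, , drop = FALSE]
  if (nrow(seg)) {
    ir <- IRanges::IRanges(start = seg$start + 1L, end = seg$end)
    cov <- IRanges::coverage(ir, width = genome_bp)
    rl <- S4Vectors::runLength(cov)
    rv <- S4Vectors::runValue(cov)
    end <- cumsum(rl)
    start <- end - rl
    track <- data.frame(start = start, end = end, p = rv / length(haps))
  } else {
    track <- data.frame(start = 0L, end = as.integer(genome_bp), p = 0)
  }
  structure(track, class = c("freq_track", "data.frame"),
            P = sum((track$end - track$start) * track$p) / genome_bp,
            L = genome_bp, n_hap = length(haps), chrom = chrom)
}

#' Total length of introgression-covered regions
#'
#' Regions with local introgression frequency strictly greater than the
#' threshold (default 0.02) count as introgression-covered.
#'
#' @param track a `"freq_track"`.
#' @param threshold strict lower bound on the local frequency.
#' @return covered length in bp.
#' @export
coverage_length <- function(track, threshold = 0.02) {
  sum((track$end - track$start)[track$p > threshold])
}

#' Ancestry-sharing ratio between two populations
#'
#' The ratio of observed co-localization of introgression to the sharing
#' expected at random given each population's genome-wide proportion:
#' \deqn{S_{ij} = \frac{\sum_k p_{ik} p_{jk} L_k}{P_i P_j L}}
#' where `p_ik` is the local introgression proportion of interval `k` in
#' population `i`, `L_k` its length, `P_i` the genome-wide proportion and
#' `L` the genome length.  Both tracks are refined to their common
#' breakpoints before the sum, so the statistic is exact.  `S = 1` for
#' identical uniform tracks; `S = 0` for disjoint introgression;
#' undefined (`NA`) when either genome-wide proportion is zero.
#'
#' @param track_i,track_j `"freq_track"` objects on the same genome.
#' @return the sharing ratio (scalar), or `NA` when undefined.
#' @export
sharing_ratio <- function(track_i, track_j) {
  L <- attr(track_i, "L")
  if (!identical(L, attr(track_j, "L")))
    stop("tracks cover different genome lengths")
  Pi <- attr(track_i, "P"); Pj <- attr(track_j, "P")
  if (Pi == 0 || Pj == 0) return(NA_real_)
  bp <- sort(unique(c(track_i$start, track_i$end,
                      track_j$start, track_j$end)))
  lk <- diff(bp)
  mid <- bp[-length(bp)]
  pi_k <- track_i$p[findInterval(mid, track_i$start)]
  pj_k <- track_j$p[findInterval(mid, track_j$start)]
  sum(pi_k * pj_k * lk) / (Pi * Pj * L)
}

#' Pairwise sharing matrix over populations
#' @param tracks named list of `"freq_track"` objects.
#' @return symmetric matrix of sharing ratios.
#' @export
sharing_matrix <- function(tracks) {
  n <- length(tracks)
  S <- matrix(NA_real_, n, n, dimnames = list(names(tracks),
                                              names(tracks)))
  for (i in seq_len(n)) for (j in i:n)
    S[i, j] <- S[j, i] <- sharing_ratio(tracks[[i]], tracks[[j]])
  S
}

#' Find introgression deserts
#'
#' Divides the genome into fixed bins (100 kb), computes each bin's
#' introgression-covered length (union over the supplied population
#' tracks, at the coverage threshold), and flags bins whose covered
#' length falls in the lower tail of the empirical bin distribution with
#' a two-tailed test at level `alpha`.  Adjacent significant-low bins are
#' merged into deserts and classified by length (`>5 Mb`, `>10 Mb`).
#'
#' @param tracks list of `"freq_track"` objects (one per population).
#' @param bin bin width in bp.
#' @param threshold coverage threshold passed to the per-bin covered
#'   length.
#' @param alpha two-tailed significance level.
#' @return data frame of deserts: `start`, `end`, `length`, `class`
#'   (`"desert"`, `">5Mb"`, `">10Mb"`), `p_emp` (the largest per-bin
#'   empirical lower-tail probability inside the desert).
#' @export
find_deserts <- function(tracks, bin = 1e5, threshold = 0.02,
                         alpha = 0.05) {
  if (!is.list(tracks) || inherits(tracks, "freq_track"))
    tracks <- list(tracks)
  L <- attr(tracks[[1]], "L")
  if (L < bin) stop("genome shorter than one bin")
  n_bins <- floor(L / bin)
  # per-bin covered length of the union over populations
  cov_union <- .bin_union_coverage(tracks, bin, n_bins, threshold)
  p_low <- vapply(cov_union, function(x) mean(cov_union <= x), 0)
  sig <- p_low <= alpha / 2
  if (!any(sig))
    return(data.frame(start = numeric(0), end = numeric(0),
                      length = numeric(0), class = character(0),
                      p_emp = numeric(0)))
  r <- rle(sig)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  idx <- which(r$values)
  out <- data.frame(start = (starts[idx] - 1) * bin,
                    end = ends[idx] * bin)
  out$length <- out$end - out$start
  out$class <- ifelse(out$length > 1e7, ">10Mb",
                      ifelse(out$length > 5e6, ">5Mb", "desert"))
  out$p_emp <- vapply(idx, function(k)
    max(p_low[starts[k]:ends[k]]), 0)
  out
}

.bin_union_coverage <- function(tracks, bin, n_bins, threshold) {
  irs <- lapply(tracks, function(tr) {
    hi <- tr[tr$p > threshold, , drop = FALSE]
    IRanges::IRanges(start = hi$start + 1L, end = hi$end)
  })
  u <- IRanges::reduce(do.call(c, irs))
  covered <- numeric(n_bins)
  if (!length(u)) return(covered)
  s <- IRanges::start(u) - 1L; e <- IRanges::end(u)
  for (r in seq_along(s)) {
    b1 <- floor(s[r] / bin) + 1L
    b2 <- min(floor((e[r] - 1) / bin) + 1L, n_bins)
    if (b1 > n_bins) next
    for (b in b1:b2) {
      lo <- (b - 1) * bin; up <- b * bin
      covered[b] <- covered[b] + min(e[r], up) - max(s[r], lo)
    }
  }
  covered
}

#' Introgression diversity curve
#'
#' Mean total (union) length of introgressed sequence carried by random
#' subsamples of haplotypes, as a function of subsample size; the mean is
#' taken over random permutations to suppress sampling error.  The curve
#' is non-decreasing in the subsample size.
#'
#' @param segments segment table.
#' @param haps the population's haplotype ids.
#' @param sizes subsample sizes (default `1:length(haps)`).
#' @param n_perm permutations per size (the full-sample point needs none).
#' @param seed integer seed.
#' @return data frame with `size` and `mean_union_bp`.
#' @export
diversity_curve <- function(segments, haps, sizes = seq_along(haps),
                            n_perm = 10000L, seed = 1L) {
  old_seed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(seed)
  seg <- segments[segments$hap %in% haps, , drop = FALSE]
  union_len <- function(hh) {
    s <- seg[seg$hap %in% hh, , drop = FALSE]
    if (!nrow(s)) return(0)
    sum(IRanges::width(IRanges::reduce(
      IRanges::IRanges(start = s$start + 1L, end = s$end))))
  }
  out <- vapply(sizes, function(s) {
    if (s >= length(haps)) return(union_len(haps))
    mean(vapply(seq_len(n_perm), function(i)
      union_len(sample(haps, s)), 0))
  }, 0)
  data.frame(size = sizes, mean_union_bp = out)
}
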