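#' Concordance of inferred segments against ground truth
#'
#' Scores inferred segments against simulator truth with three bases:
#' \describe{
#'   \item{length}{bp overlap: precision = |inferred n truth| / |inferred|,
#'     TPR = |inferred n truth| / |truth|, FPR = |inferred \\ truth| /
#'     |genome \\ truth|.}
#'   \item{snp}{same ratios counted in panel SNPs instead of bp.}
#'   \item{aim}{SNP ratios restricted to non-AMH ancestry-informative
#'     markers: sites where the focal haplotype carries the derived allele
#'     and the African panel is monomorphic ancestral.}
#' }
#' Metrics are reported per haplotype and pooled (summed numerators and
#' denominators over haplotypes).
#'
#' @param inferred,truth segment tables (`start`, `end`, `hap`).
#' @param panel the [site_panel()] (needed for `snp`/`aim` bases and for
#'   the genome length default).
#' @param basis `"length"`, `"snp"` or `"aim"`.
#' @param genome_bp genome length per haplotype; defaults to the panel
#'   span.
#' @param haps haplotypes to score (default: all test haplotypes of the
#'   panel), so haplotypes without inferred or true segments still count.
#' @return list with `pooled` (named vector `precision`, `tpr`, `fpr`)
#'   and `per_hap` (data frame).
#' @export
concordance <- function(inferred, truth, panel = NULL,
                        basis = c("length", "snp", "aim"),
                        genome_bp = NULL, haps = NULL) {
  basis <- match.arg(basis)
  if (is.null(haps)) {
    if (!is.null(panel)) haps <- panel$hap[role_index(panel, "test")]
    else haps <- sort(unique(c(inferred$hap, truth$hap)))
  }
  if (is.null(genome_bp)) {
    if (is.null(panel)) stop("genome_bp required without a panel")
    genome_bp <- max(panel$pos) + 1L
  }
  if (basis != "length" && is.null(panel))
    stop("snp/aim bases require the panel")
  afr_mono <- NULL
  if (basis == "aim") {
    afr <- panel$geno[, role_index(panel, "african_ref"), drop = FALSE]
    afr_mono <- rowSums(afr == 1L, na.rm = TRUE) == 0L
  }
  per <- lapply(haps, function(h) {
    ir_inf <- .seg_ir(inferred, h)
    ir_tru <- .seg_ir(truth, h)
    if (basis == "length") {
      ii <- sum(IRanges::width(IRanges::intersect(ir_inf, ir_tru)))
      ni <- sum(IRanges::width(ir_inf))
      nt <- sum(IRanges::width(ir_tru))
      fp <- ni - ii
      neg <- genome_bp - nt
    } else {
      hcol <- match(h, panel$hap)
      use <- rep(TRUE, length(panel$pos))
      if (basis == "aim")
        use <- afr_mono & !is.na(panel$geno[, hcol]) &
          panel$geno[, hcol] == 1L
      p <- panel$pos[use]
      in_inf <- .pos_in(p, inferred, h)
      in_tru <- .pos_in(p, truth, h)
      ii <- sum(in_inf & in_tru)
      ni <- sum(in_inf); nt <- sum(in_tru)
      fp <- ni - ii
      neg <- sum(use) - nt
    }
    c(ii = ii, ni = ni, nt = nt, fp = fp, neg = neg)
  })
  tab <- do.call(rbind, per)
  rate <- function(num, den) ifelse(den > 0, num / den, NA_real_)
  per_hap <- data.frame(hap = haps,
                        precision = rate(tab[, "ii"], tab[, "ni"]),
                        tpr = rate(tab[, "ii"], tab[, "nt"]),
                        fpr = rate(tab[, "fp"], tab[, "neg"]))
  tot <- colSums(tab)
  pooled <- c(precision = rate(tot[["ii"]], tot[["ni"]]),
              tpr = rate(tot[["ii"]], tot[["nt"]]),
              fpr = rate(tot[["fp"]], tot[["neg"]]))
  list(pooled = pooled, per_hap = per_hap, basis = basis)
}

.seg_ir <- function(seg, h) {
  s <- seg[seg$hap == h, , drop = FALSE]
  IRanges::reduce(IRanges::IRanges(start = s$start + 1L, end = s$end))
}

.pos_in <- function(p, seg, h) {
  s <- seg[seg$hap == h, , drop = FALSE]
  if (!nrow(s) || !length(p)) return(rep(FALSE, length(p)))
  s <- s[order(s$start), ]
  iv <- findInterval(p, s$start)
  iv > 0L & p < s$end[pmax(iv, 1L)]
}

#' Segment-based detection accuracy
#'
#' A segment counts as correctly identified when its overlap with the
#' ground-truth tracts of the same haplotype exceeds 80% of its own
#' length (strict).  Segments shorter than `min_len` are excluded first,
#' since stochastic boundary errors dominate them.
#'
#' @param inferred,truth segment tables.
#' @param min_overlap strict overlap fraction required.
#' @param min_len minimum segment length scored.
#' @return fraction of scored segments that are correct (`NaN` when no
#'   segment passes the length filter).
#' @export
segment_accuracy <- function(inferred, truth, min_overlap = 0.8,
                             min_len = 15000) {
  seg <- inferred[(inferred$end - inferred$start) >= min_len, ,
                  drop = FALSE]
  if (!nrow(seg)) return(NaN)
  ok <- vapply(seq_len(nrow(seg)), function(i) {
    tr <- truth[truth$hap == seg$hap[i], , drop = FALSE]
    if (!nrow(tr)) return(FALSE)
    ov <- sum(pmax(0, pmin(tr$end, seg$end[i]) -
                     pmax(tr$start, seg$start[i])))
    ov / (seg$end[i] - seg$start[i]) > min_overlap
  }, TRUE)
  mean(ok)
}

#' Lineage-matching accuracy
#'
#' Fraction of segments whose matched label equals the true source
#' lineage.
#'
#' @param labels matched labels.
#' @param truth_lineages true lineage per segment.
#' @return fraction correct.
#' @export
matching_accuracy <- function(labels, truth_lineages) {
  stopifnot(length(labels) == length(truth_lineages))
  mean(labels == truth_lineages)
}

#' Success of an inferred admixture model
#'
#' An inferred wave model is successful when it has the true number of
#' waves and, after matching waves oldest-to-oldest, every wave's time is
#' within `tol_time` relative error and every proportion within
#' `tol_prop` relative error.  The tolerances operationalize a
#' qualitative success notion and are deliberately exposed.
#'
#' @param model a `"wave_model"`.
#' @param truth_waves data frame with columns `t` (generations) and `m`
#'   (proportions), one row per true wave.
#' @param tol_time,tol_prop relative tolerances (0.3 and 0.5).
#' @return logical.
#' @export
model_success <- function(model, truth_waves, tol_time = 0.3,
                          tol_prop = 0.5) {
  if (model$K != nrow(truth_waves)) return(FALSE)
  o <- order(truth_waves$t, decreasing = TRUE)
  tt <- truth_waves$t[o]; tm <- truth_waves$m[o]
  ok_t <- abs(model$t - tt) / tt <= tol_time
  ok_m <- if (all(is.na(model$m))) rep(TRUE, model$K) else
    abs(model$m - tm) / tm <= tol_prop
  all(ok_t & ok_m)
}
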