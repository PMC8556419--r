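#' Construct a site panel
#'
#' A site panel holds phased biallelic alleles at ordered sites for a set of
#' haplotypes, together with physical (bp) and genetic (Morgan) coordinates
#' and the population role of every haplotype.  It is the shared in-memory
#' data model of the package: the detector, the matcher and all population
#' statistics operate on it.
#'
#' Coordinates are 0-based half-open throughout the package; positions read
#' from VCF (1-based) are converted on input.
#'
#' @param chrom chromosome identifier (single string).
#' @param pos integer vector of 0-based site positions, strictly increasing.
#' @param geno integer matrix, sites x haplotypes, values 0/1 (`NA` =
#'   missing).  Before polarization 0/1 mean REF/ALT; after polarization
#'   they mean ancestral/derived.
#' @param roles character vector, one per haplotype, each one of
#'   `"test"`, `"african_ref"`, `"archaic_ref:<name>"`, `"outgroup"`.
#' @param hap optional haplotype identifiers (defaults to `hap1..hapN`).
#' @param gpos optional numeric vector of genetic positions in Morgans,
#'   non-decreasing; filled later by [attach_genetic_map()] if absent.
#' @param polarized logical; `TRUE` once alleles are coded
#'   ancestral/derived.
#' @param ref,alt optional REF/ALT allele characters per site (kept so a
#'   panel can be written back to VCF).
#' @return an object of class `"site_panel"`.
#' @export
site_panel <- function(chrom, pos, geno, roles, hap = NULL, gpos = NULL,
                       polarized = FALSE, ref = NULL, alt = NULL) {
  pos <- as.integer(pos)
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  if (length(pos) != nrow(geno))
    stop("length(pos) must equal nrow(geno)")
  if (anyNA(pos)) stop("positions must not be NA")
  if (length(pos) > 1L && any(diff(pos) <= 0L))
    stop("site positions must be strictly increasing within a chromosome")
  if (length(roles) != ncol(geno))
    stop("one role per haplotype required")
  bad <- !grepl("^(test|african_ref|outgroup|archaic_ref:.+)$", roles)
  if (any(bad))
    stop("unknown role(s): ", paste(unique(roles[bad]), collapse = ", "))
  if (is.null(hap)) hap <- paste0("hap", seq_len(ncol(geno)))
  if (anyDuplicated(hap)) stop("haplotype ids must be unique")
  if (!is.null(gpos)) {
    gpos <- as.numeric(gpos)
    if (length(gpos) != length(pos)) stop("gpos length mismatch")
    if (length(gpos) > 1L && any(diff(gpos) < 0))
      stop("genetic positions must be non-decreasing")
  }
  colnames(geno) <- hap
  structure(list(chrom = as.character(chrom)[1], pos = pos, gpos = gpos,
                 geno = geno, roles = roles, hap = hap,
                 polarized = isTRUE(polarized), ref = ref, alt = alt),
            class = "site_panel")
}

#' @export
print.site_panel <- function(x, ...) {
  cat("<site_panel> chrom", x$chrom, "-", length(x$pos), "sites x",
      ncol(x$geno), "haplotypes\n")
  cat("  span:", if (length(x$pos)) paste0(min(x$pos), "-", max(x$pos) + 1L)
      else "(empty)", "bp;",
      if (is.null(x$gpos)) "no genetic map attached" else
        sprintf("%.4g Morgans", diff(range(x$gpos))), "\n")
  cat("  roles:", paste(sprintf("%s=%d", names(table(x$roles)),
                                table(x$roles)), collapse = ", "), "\n")
  cat("  alleles coded:", if (x$polarized) "ancestral/derived" else
      "REF/ALT (not polarized)", "\n")
  invisible(x)
}

#' Haplotype indices with a given role
#'
#' @param panel a [site_panel()].
#' @param role exact role string, or `"archaic_ref"` to match every archaic
#'   reference group.
#' @return integer vector of haplotype (column) indices.
#' @export
role_index <- function(panel, role) {
  if (identical(role, "archaic_ref"))
    which(startsWith(panel$roles, "archaic_ref"))
  else which(panel$roles == role)
}

#' Names of the archaic reference groups in a panel
#' @param panel a [site_panel()].
#' @return character vector, e.g. `c("NEA", "DEN")`.
#' @export
archaic_groups <- function(panel)
  unique(sub("^archaic_ref:", "", grep("^archaic_ref:", panel$roles,
                                       value = TRUE)))

#' Subset a panel by sites and/or haplotypes
#' @param panel a [site_panel()].
#' @param sites integer/logical site index.
#' @param haps integer/logical haplotype index.
#' @return a [site_panel()].
#' @export
subset_panel <- function(panel, sites = NULL, haps = NULL) {
  if (is.null(sites)) sites <- seq_along(panel$pos)
  if (is.null(haps)) haps <- seq_len(ncol(panel$geno))
  site_panel(panel$chrom, panel$pos[sites],
             panel$geno[sites, haps, drop = FALSE], panel$roles[haps],
             hap = panel$hap[haps],
             gpos = if (!is.null(panel$gpos)) panel$gpos[sites],
             polarized = panel$polarized,
             ref = if (!is.null(panel$ref)) panel$ref[sites],
             alt = if (!is.null(panel$alt)) panel$alt[sites])
}

#' Construct a genetic map
#'
#' Piecewise-linear map from physical position (bp) to cumulative genetic
#' position (cM).  Interpolation is linear between anchors; outside the
#' anchored range the rate of the nearest flanking interval is extended.
#'
#' @param pos_bp integer anchor positions (bp), strictly increasing.
#' @param cm cumulative genetic position (cM) at each anchor, non-decreasing.
#' @return an object of class `"genetic_map"`.
#' @export
genetic_map <- function(pos_bp, cm) {
  pos_bp <- as.numeric(pos_bp); cm <- as.numeric(cm)
  if (length(pos_bp) != length(cm) || length(pos_bp) < 1L)
    stop("need matching, non-empty anchor vectors")
  if (is.unsorted(pos_bp, strictly = TRUE))
    stop("map anchor positions must be strictly increasing")
  if (is.unsorted(cm)) stop("genetic positions must be non-decreasing")
  structure(list(pos = pos_bp, cm = cm), class = "genetic_map")
}

#' @export
print.genetic_map <- function(x, ...) {
  cat("<genetic_map>", length(x$pos), "anchors,",
      sprintf("%.6g-%.6g bp, %.4g-%.4g cM\n",
              min(x$pos), max(x$pos), min(x$cm), max(x$cm)))
  invisible(x)
}

#' Interpolate genetic position (cM) at physical positions
#'
#' @param map a [genetic_map()], or `NULL` for the constant 1 cM/Mb
#'   fallback (the genome-wide human average).
#' @param pos_bp positions to interpolate at.
#' @return numeric vector of genetic positions in cM.
#' @export
interpolate_cm <- function(map, pos_bp) {
  if (is.null(map)) return(as.numeric(pos_bp) * 1e-6)
  p <- map$pos; g <- map$cm
  if (length(p) == 1L) return(rep(g, length(pos_bp)))
  # local rates for extrapolation beyond the anchored range
  r_lo <- (g[2] - g[1]) / (p[2] - p[1])
  n <- length(p)
  r_hi <- (g[n] - g[n - 1]) / (p[n] - p[n - 1])
  out <- stats::approx(p, g, xout = pos_bp, rule = 2)$y
  lo <- pos_bp < p[1]; hi <- pos_bp > p[n]
  out[lo] <- g[1] + (pos_bp[lo] - p[1]) * r_lo
  out[hi] <- g[n] + (pos_bp[hi] - p[n]) * r_hi
  out
}

#' Attach genetic coordinates to a panel
#'
#' Fills the `gpos` slot (Morgans) by interpolating a [genetic_map()] at the
#' panel's site positions.  With `map = NULL` a constant 1 cM/Mb is applied,
#' which keeps the HMM runnable when no map is available.
#'
#' @param panel a [site_panel()].
#' @param map a [genetic_map()] or `NULL`.
#' @return the panel with `gpos` filled (in Morgans).
#' @export
attach_genetic_map <- function(panel, map = NULL) {
  cm <- interpolate_cm(map, panel$pos)
  panel$gpos <- cm / 100  # Morgans
  panel
}

#' Polarize a panel to ancestral/derived coding
#'
#' Re-expresses every site's alleles as ancestral (0) / derived (1) using an
#' ancestral-allele source: either the panel's own outgroup haplotype
#' (`ancestral = "outgroup"`) or an explicit character vector of ancestral
#' bases aligned to the sites.  Sites whose ancestral state cannot be
#' resolved (missing outgroup call, or an ancestral base matching neither
#' allele) are dropped and counted.
#'
#' @param panel a [site_panel()].
#' @param ancestral `"outgroup"` (default) or a character vector of
#'   ancestral alleles per site (e.g. extracted from a FASTA).
#' @return the polarized panel; the number of dropped sites is available as
#'   `attr(, "dropped")`.
#' @export
polarize <- function(panel, ancestral = "outgroup") {
  if (panel$polarized) return(panel)
  n <- length(panel$pos)
  if (identical(ancestral, "outgroup")) {
    og <- role_index(panel, "outgroup")
    if (!length(og)) stop("panel has no outgroup haplotype")
    anc01 <- panel$geno[, og[1]]
  } else {
    if (length(ancestral) != n) stop("ancestral vector length mismatch")
    anc <- toupper(as.character(ancestral))
    anc01 <- rep(NA_integer_, n)
    if (is.null(panel$ref) || is.null(panel$alt))
      stop("panel lacks REF/ALT alleles needed to interpret ancestral bases")
    anc01[anc == toupper(panel$ref)] <- 0L
    anc01[anc == toupper(panel$alt)] <- 1L
  }
  keep <- !is.na(anc01)
  flip <- which(keep & anc01 == 1L)
  geno <- panel$geno
  geno[flip, ] <- 1L - geno[flip, ]
  out <- site_panel(panel$chrom, panel$pos[keep],
                    geno[keep, , drop = FALSE], panel$roles,
                    hap = panel$hap,
                    gpos = if (!is.null(panel$gpos)) panel$gpos[keep],
                    polarized = TRUE,
                    ref = if (!is.null(panel$ref)) panel$ref[keep],
                    alt = if (!is.null(panel$alt)) panel$alt[keep])
  # after flipping, record swapped ref/alt so allele letters stay truthful
  if (!is.null(out$ref)) {
    fk <- anc01[keep] == 1L
    tmp <- out$ref[fk]; out$ref[fk] <- out$alt[fk]; out$alt[fk] <- tmp
  }
  attr(out, "dropped") <- sum(!keep)
  if (sum(!keep))
    message(sum(!keep), " site(s) dropped: ancestral state unresolved")
  out
}
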