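#' Read a phased VCF plus role manifest into a site panel
#'
#' Parses a phased, biallelic SNV VCF with \pkg{vcfR} and attaches
#' population roles from a manifest.  Multi-allelic sites, indels and sites
#' with unphased diploid genotypes are dropped with a logged count.  Each
#' diploid sample contributes two haplotypes named `<sample>_1`,
#' `<sample>_2`; haploid genotypes contribute one.
#'
#' @param vcf_path path to a VCF (optionally bgzipped).
#' @param manifest data frame with columns `sample`, `role`, or the path of
#'   a tab-separated file with those columns.  Roles are `test`,
#'   `african_ref`, `archaic_ref:<name>`, `outgroup`.
#' @return an unpolarized [site_panel()].
#' @export
read_phased_panel <- function(vcf_path, manifest) {
  man <- if (is.character(manifest))
    utils::read.table(manifest, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE)
  else as.data.frame(manifest, stringsAsFactors = FALSE)
  if (!all(c("sample", "role") %in% names(man)))
    stop("manifest needs columns 'sample' and 'role'")
  v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (nrow(fix) == 0L) stop("VCF contains no variants")
  chrom <- fix[, "CHROM"]
  if (length(unique(chrom)) > 1L)
    stop("panel must be single-chromosome; split the VCF first")
  pos1 <- as.integer(fix[, "POS"])
  if (is.unsorted(pos1)) stop("VCF is not coordinate-sorted")
  vcf_samples <- colnames(v@gt)[-1]
  missing <- setdiff(man$sample, vcf_samples)
  if (length(missing))
    stop("manifest sample(s) absent from VCF: ",
         paste(missing, collapse = ", "))
  ref <- fix[, "REF"]; alt <- fix[, "ALT"]
  gt <- v@gt[, man$sample, drop = FALSE]
  gt <- sub(":.*$", "", gt)
  biallelic <- !grepl(",", alt) & nchar(ref) == 1L & nchar(alt) == 1L &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  phased <- !apply(gt, 1L, function(r) any(grepl("/", r)))
  keep <- biallelic & phased
  n_drop <- sum(!keep)
  if (n_drop)
    message(n_drop, " site(s) dropped (multi-allelic, indel or unphased)")
  gt <- gt[keep, , drop = FALSE]
  pos1 <- pos1[keep]; ref <- ref[keep]; alt <- alt[keep]
  if (anyDuplicated(pos1)) stop("duplicated site positions in VCF")
  # expand samples to haplotypes
  cols <- list(); roles <- character(); hap <- character()
  for (i in seq_len(nrow(man))) {
    g <- gt[, i]
    ploidy <- length(strsplit(g[1], "|", fixed = TRUE)[[1]])
    parts <- strsplit(g, "|", fixed = TRUE)
    for (k in seq_len(ploidy)) {
      a <- vapply(parts, `[`, "", k)
      ai <- suppressWarnings(as.integer(a))
      cols[[length(cols) + 1L]] <- ai
      roles <- c(roles, man$role[i])
      hap <- c(hap, if (ploidy == 1L) man$sample[i] else
        paste0(man$sample[i], "_", k))
    }
  }
  geno <- do.call(cbind, cols)
  site_panel(unique(chrom), pos1 - 1L, geno, roles, hap = hap,
             ref = ref, alt = alt)
}

#' Write a site panel to VCF (+ manifest)
#'
#' Emits a minimal phased VCF with one diploid sample per haplotype pair
#' where roles allow, or haploid columns otherwise.  Haplotypes are written
#' as haploid sample columns so that role bookkeeping is exact.
#'
#' @param panel a [site_panel()].
#' @param vcf_path output VCF path.
#' @param manifest_path optional path for the matching role manifest TSV.
#' @return invisibly, the VCF path.
#' @export
write_panel_vcf <- function(panel, vcf_path, manifest_path = NULL) {
  ref <- if (!is.null(panel$ref)) panel$ref else rep("A", length(panel$pos))
  alt <- if (!is.null(panel$alt)) panel$alt else rep("G", length(panel$pos))
  g <- panel$geno
  gch <- matrix(as.character(g), nrow = nrow(g))
  gch[is.na(g)] <- "."
  con <- file(vcf_path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               paste0("##contig=<ID=", panel$chrom, ">"),
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", panel$hap), collapse = "\t")), con)
  body <- cbind(panel$chrom, panel$pos + 1L, ".", ref, alt, ".", "PASS",
                ".", "GT", gch)
  writeLines(apply(body, 1L, paste, collapse = "\t"), con)
  if (!is.null(manifest_path))
    utils::write.table(data.frame(sample = panel$hap, role = panel$roles),
                       manifest_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(vcf_path)
}

#' Read / write a plain-text genetic map ("pos cM")
#'
#' @param path file with two whitespace-separated columns: position (bp)
#'   and cumulative genetic position (cM); a header line is allowed.
#' @return a [genetic_map()].
#' @export
read_genetic_map <- function(path) {
  first <- readLines(path, n = 1L)
  header <- !grepl("^\\s*[0-9]", first)
  d <- utils::read.table(path, header = header)
  genetic_map(d[[1]], d[[2]])
}

#' @rdname read_genetic_map
#' @param map a [genetic_map()].
#' @export
write_genetic_map <- function(map, path) {
  utils::write.table(data.frame(pos = map$pos, cM = map$cm), path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Validate a segment table
#'
#' Segments are half-open `[start, end)` intervals on one test haplotype.
#' Within a haplotype they must be sorted and non-overlapping and every
#' segment must satisfy `start < end`.
#'
#' @param seg data frame with at least `chrom`, `start`, `end`, `hap`.
#' @return the segment table, invisibly, or an error.
#' @export
validate_segments <- function(seg) {
  stopifnot(all(c("chrom", "start", "end", "hap") %in% names(seg)))
  if (any(seg$start >= seg$end)) stop("segment with start >= end")
  for (h in unique(seg$hap)) {
    s <- seg[seg$hap == h, ]
    s <- s[order(s$start), ]
    if (nrow(s) > 1L && any(s$start[-1L] < s$end[-nrow(s)]))
      stop("overlapping segments on haplotype ", h)
  }
  invisible(seg)
}

#' Write / read decoded segments (BED + TSV sidecar)
#'
#' `write_segments()` writes `<prefix>.bed` (0-based half-open, name =
#' haplotype) and `<prefix>.seg.tsv` carrying every column of the segment
#' table (haplotype, state, posterior, lineage, ...).  `read_segments()`
#' restores the table from the TSV; the round trip is the identity.
#'
#' @param seg segment data frame (see [validate_segments()]).
#' @param prefix output path prefix.
#' @return invisibly, the prefix (write) or the segment table (read).
#' @export
write_segments <- function(seg, prefix) {
  validate_segments(seg)
  bed <- data.frame(seg$chrom, seg$start, seg$end, seg$hap)
  utils::write.table(bed, paste0(prefix, ".bed"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(seg, paste0(prefix, ".seg.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(prefix)
}

#' @rdname write_segments
#' @export
read_segments <- function(prefix) {
  path <- paste0(prefix, ".seg.tsv")
  d <- tryCatch(
    utils::read.table(path, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE, colClasses = NA),
    error = function(e) stop("malformed segment table ", path, ": ",
                             conditionMessage(e)))
  n_expect <- length(readLines(path)) - 1L
  if (nrow(d) != n_expect)
    stop("malformed row in ", path, " near line ", nrow(d) + 1L)
  d$chrom <- as.character(d$chrom)
  d$hap <- as.character(d$hap)
  validate_segments(d)
  d
}

#' Write / read simulator ground-truth tracts
#'
#' BED-like text table: `chrom start end hap lineage wave`.  Truth tracts
#' must be non-overlapping per haplotype; overlapping input is refused.
#'
#' @param truth data frame with columns `chrom`, `start`, `end`, `hap`,
#'   `lineage`, `wave`.
#' @param path output file.
#' @export
write_truth <- function(truth, path) {
  stopifnot(all(c("chrom", "start", "end", "hap", "lineage", "wave")
                %in% names(truth)))
  validate_segments(truth)
  utils::write.table(truth[, c("chrom", "start", "end", "hap", "lineage",
                               "wave")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  d$chrom <- as.character(d$chrom); d$hap <- as.character(d$hap)
  validate_segments(d)
  d
}
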