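# Hand-built fixtures shared across test files.  Everything is generated in
# code; no binary data.

# A tiny polarized panel with 2 test, 2 African, 1 NEA, 1 DEN and an
# outgroup haplotype.  Genotypes are chosen so every observation state
# occurs for test haplotype 1:
#   site 1: test1 derived, all refs ancestral          -> state 1
#   site 2: test1 + NEA derived, Africans ancestral    -> state 2
#   site 3: test1 + African derived, archaic ancestral -> state 3
#   site 4: everyone (but outgroup) derived            -> state 4
#   site 5: test1 ancestral                            -> state 4
toy_panel <- function() {
  geno <- rbind(
    c(1, 0, 0, 0, 0, 0, 0),
    c(1, 0, 0, 0, 1, 0, 0),
    c(1, 0, 1, 0, 0, 0, 0),
    c(1, 1, 1, 1, 1, 1, 0),
    c(0, 1, 0, 1, 0, 1, 0))
  site_panel("1", c(100L, 200L, 300L, 400L, 500L), geno,
             roles = c("test", "test", "african_ref", "african_ref",
                       "archaic_ref:NEA", "archaic_ref:DEN", "outgroup"),
             hap = c("t1", "t2", "a1", "a2", "nea", "den", "out"),
             polarized = TRUE)
}

# Write a small diploid phased VCF by hand (returns path + manifest df).
toy_vcf <- function(dir = tempdir()) {
  path <- file.path(dir, "toy.vcf")
  lines <- c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=1>",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "S1", "S2", "S3", sep = "\t"),
    paste("1", "101", ".", "A", "G", ".", "PASS", ".", "GT",
          "0|1", "0|0", "1|1", sep = "\t"),
    paste("1", "201", ".", "C", "T", ".", "PASS", ".", "GT",
          "1|1", "0|1", "0|0", sep = "\t"),
    paste("1", "301", ".", "G", "A", ".", "PASS", ".", "GT",
          "0|0", "0|0", "0|1", sep = "\t"),
    paste("1", "401", ".", "T", "C", ".", "PASS", ".", "GT",
          "1|0", "1|0", "0|0", sep = "\t"),
    paste("1", "501", ".", "A", "C", ".", "PASS", ".", "GT",
          "0|1", "1|1", "0|0", sep = "\t"))
  writeLines(lines, path)
  list(path = path,
       manifest = data.frame(sample = c("S1", "S2", "S3"),
                             role = c("test", "african_ref", "outgroup"),
                             stringsAsFactors = FALSE))
}

# Paint a clean clock panel from known node heights (one haplotype per
# group, no within-group diversity): an independent oracle for the tree
# calibration.  Densities are 2 mu h per pair.
clock_panel <- function(h_ta = 2500, h_12 = 15000, h_ha = 23000,
                        h_root = 2e5, mu = 1.25e-8, L = 5e6, seed = 1) {
  set.seed(seed)
  draw <- function(rate) {
    n <- rpois(1, rate * L)
    sort(sample.int(L, n)) - 1L
  }
  # mutations per branch of ((test,african),(NEA,DEN)),outgroup
  cat_list <- list(
    test  = draw(mu * h_ta),
    afr   = draw(mu * h_ta),
    nea   = draw(mu * h_12),
    den   = draw(mu * h_12),
    hum   = draw(mu * (h_ha - h_ta)),   # shared test+african
    arc   = draw(mu * (h_ha - h_12)),   # shared NEA+DEN
    stem  = draw(mu * (h_root - h_ha))) # shared by all four
  carriers <- list(test = "t", afr = "a", nea = "n", den = "d",
                   hum = c("t", "a"), arc = c("n", "d"),
                   stem = c("t", "a", "n", "d"))
  pos <- unlist(cat_list, use.names = FALSE)
  hapn <- c("t", "a", "n", "d", "o")
  geno <- matrix(0L, length(pos), 5, dimnames = list(NULL, hapn))
  at <- 0L
  for (nm in names(cat_list)) {
    idx <- at + seq_along(cat_list[[nm]])
    geno[idx, carriers[[nm]]] <- 1L
    at <- at + length(cat_list[[nm]])
  }
  o <- order(pos)
  keep <- !duplicated(pos[o])
  site_panel("1", pos[o][keep], geno[o, ][keep, , drop = FALSE],
             roles = c("test", "african_ref", "archaic_ref:NEA",
                       "archaic_ref:DEN", "outgroup"),
             hap = hapn, polarized = TRUE)
}

# Small standard simulated scenario reused by several test files.
small_sim <- function(seed = 3, chrom_len = 5e6, n_test = 10, ...) {
  simulate_panel(scenario_config(chrom_len = chrom_len, n_test = n_test,
                                 n_african = 20, seed = seed, ...))
}

# Tract-length sample straight from synthetic lengths in Morgans.
lengths_sample <- function(morgans, trunc = 0) {
  structure(list(morgans = morgans, bp = morgans / 1e-8,
                 hap = rep("h", length(morgans)), trunc_morgans = trunc,
                 n = length(morgans)),
            class = "tract_sample")
}
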