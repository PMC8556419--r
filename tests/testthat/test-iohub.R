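test_that("phased VCF parses into haplotype columns with roles", {
  v <- toy_vcf()
  p <- read_phased_panel(v$path, v$manifest)
  expect_s3_class(p, "site_panel")
  expect_equal(length(p$pos), 5L)
  expect_equal(ncol(p$geno), 6L)  # 3 diploid samples
  expect_equal(p$pos, c(100L, 200L, 300L, 400L, 500L))  # 0-based
  expect_equal(unname(p$geno[1, ]), c(0L, 1L, 0L, 0L, 1L, 1L))
  expect_equal(p$roles, rep(c("test", "african_ref", "outgroup"),
                            each = 2))
})

test_that("non-biallelic and unphased sites are dropped with a count", {
  v <- toy_vcf()
  lines <- readLines(v$path)
  lines <- append(lines, paste("1", "351", ".", "A", "G,T", ".", "PASS",
                               ".", "GT", "0|1", "0|2", "0|0",
                               sep = "\t"),
                  after = 7L)
  lines <- append(lines, paste("1", "451", ".", "A", "G", ".", "PASS",
                               ".", "GT", "0/1", "0|0", "0|0",
                               sep = "\t"),
                  after = 9L)
  path2 <- file.path(tempdir(), "toy2.vcf")
  writeLines(lines, path2)
  expect_message(p <- read_phased_panel(path2, v$manifest),
                 "2 site\\(s\\) dropped")
  expect_equal(length(p$pos), 5L)
})

test_that("missing manifest sample and unsorted VCF are hard errors", {
  v <- toy_vcf()
  bad <- rbind(v$manifest,
               data.frame(sample = "S9", role = "test"))
  expect_error(read_phased_panel(v$path, bad), "S9")
  lines <- readLines(v$path)
  lines <- c(lines[1:4], lines[6], lines[5], lines[7:9])
  path3 <- file.path(tempdir(), "toy3.vcf")
  writeLines(lines, path3)
  expect_error(read_phased_panel(path3, v$manifest), "sorted")
})

test_that("panel VCF writing round-trips through the reader", {
  p0 <- toy_panel()
  vp <- file.path(tempdir(), "rt.vcf")
  mp <- file.path(tempdir(), "rt.manifest.tsv")
  write_panel_vcf(p0, vp, mp)
  p1 <- read_phased_panel(vp, mp)
  expect_equal(p1$pos, p0$pos)
  expect_equal(unname(p1$geno), unname(p0$geno))
  expect_equal(p1$roles, p0$roles)
})

test_that("polarization recodes against the ancestral allele", {
  # REF=A ALT=G with ancestral=G: G carriers become ancestral
  p <- site_panel("1", c(10L, 20L), rbind(c(0L, 1L), c(1L, 0L)),
                  roles = c("test", "outgroup"), ref = c("A", "A"),
                  alt = c("G", "G"))
  pol <- polarize(p, ancestral = c("G", "A"))
  expect_true(pol$polarized)
  # site 1: hap1 carried A (=REF, now derived) -> 1; outgroup G -> 0
  expect_equal(unname(pol$geno[1, ]), c(1L, 0L))
  # site 2 ancestral=REF: coding unchanged
  expect_equal(unname(pol$geno[2, ]), c(1L, 0L))
})

test_that("unresolvable ancestral states drop the site; counts conserved", {
  p <- site_panel("1", c(10L, 20L, 30L),
                  rbind(c(0L, 1L), c(1L, 0L), c(0L, 0L)),
                  roles = c("test", "outgroup"),
                  ref = rep("A", 3), alt = rep("G", 3))
  expect_message(pol <- polarize(p, ancestral = c("N", "A", "T")),
                 "2 site\\(s\\) dropped")
  expect_equal(length(pol$pos), 1L)
  # polarizing an already ancestral=REF panel is the identity
  p2 <- polarize(p, ancestral = c("A", "A", "A"))
  expect_equal(unname(p2$geno), unname(p$geno))
  # relabeling conserves per-site allele counts
  pol3 <- polarize(p, ancestral = c("G", "G", "G"))
  expect_equal(rowSums(pol3$geno == 1L) + rowSums(pol3$geno == 0L),
               rep(2, 3))
})

test_that("outgroup column supplies the ancestral allele by default", {
  sim <- small_sim(seed = 11, chrom_len = 5e5, n_test = 2)
  p <- sim$panel
  expect_equal(unname(polarize(p)$geno), unname(p$geno))  # already coded
})

test_that("genetic map interpolates, extrapolates and falls back", {
  gm <- genetic_map(c(0, 1e6), c(0, 1))
  expect_equal(interpolate_cm(gm, 5e5), 0.5)
  expect_equal(interpolate_cm(gm, 2e6), 2)  # flanking-rate extrapolation
  expect_equal(interpolate_cm(NULL, 2e6), 2)  # 1 cM/Mb fallback
  p <- toy_panel()
  p2 <- attach_genetic_map(p, gm)
  expect_equal(p2$gpos, p$pos / 1e6 / 100)
  expect_error(genetic_map(c(100, 100), c(0, 1)), "strictly increasing")
  expect_error(site_panel("1", c(5L, 5L), matrix(0L, 2, 1), "test"),
               "strictly increasing")
})

test_that("genetic map file round-trips", {
  gm <- genetic_map(c(0, 5e5, 1e6), c(0, 0.4, 1.2))
  f <- file.path(tempdir(), "map.txt")
  write_genetic_map(gm, f)
  gm2 <- read_genetic_map(f)
  expect_equal(gm2$pos, gm$pos)
  expect_equal(gm2$cm, gm$cm)
})

test_that("segment tables round-trip through BED + TSV", {
  seg <- data.frame(chrom = "1", start = c(100L, 5000L, 100L),
                    end = c(900L, 9000L, 800L),
                    hap = c("h1", "h1", "h2"), state = "archaic",
                    mean_posterior = c(0.99, 0.8, 0.7),
                    n_snps = c(5L, 9L, 3L), stringsAsFactors = FALSE)
  pre <- file.path(tempdir(), "segrt")
  write_segments(seg, pre)
  expect_true(file.exists(paste0(pre, ".bed")))
  seg2 <- read_segments(pre)
  expect_equal(seg2, seg)
  # empty table round-trips too
  pre0 <- file.path(tempdir(), "segrt0")
  write_segments(seg[0, ], pre0)
  expect_equal(nrow(read_segments(pre0)), 0L)
})

test_that("overlapping segments on one haplotype are refused", {
  seg <- data.frame(chrom = "1", start = c(100L, 500L),
                    end = c(900L, 1200L), hap = "h1")
  expect_error(write_segments(seg, file.path(tempdir(), "bad")),
               "overlapping")
  tru <- cbind(seg, lineage = "NEA", wave = 1L)
  expect_error(write_truth(tru, file.path(tempdir(), "bad.tsv")),
               "overlapping")
})

test_that("truth tracts round-trip and empty truth writes a valid file", {
  tru <- data.frame(chrom = "1", start = c(0L, 2000L), end = c(1000L, 2500L),
                    hap = "h1", lineage = c("NEA", "DEN"), wave = c(1L, 2L),
                    stringsAsFactors = FALSE)
  f <- file.path(tempdir(), "truth.tsv")
  write_truth(tru, f)
  expect_equal(read_truth(f), tru)
  write_truth(tru[0, ], f)
  expect_equal(nrow(read_truth(f)), 0L)
})
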