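# archseekr

Archaic hominins — Neanderthals and Denisovans — interbred with the
ancestors of present-day non-Africans, leaving a mosaic of short archaic
tracts in modern genomes.  `archseekr` detects those tracts in phased
genomes, assigns each one to an ancestral lineage, and reconstructs the
number, ages and proportions of the introgression pulses that produced
them.  It is written for population geneticists who have phased VCFs for
a test population, an African reference panel, archaic reference genomes
and an outgroup, and want segment calls, lineage labels and a dated
multi-wave admixture model from one coherent toolchain.

## The method

**Detection.** Every site of a polarized panel is classified per test
haplotype into four observation states by derived-allele sharing:
test-specific, archaic marker (derived in an archaic reference, absent
from Africans), AMH marker (derived in Africans, absent from archaic
references), or common.  A two-state hidden Markov model (hidden
ancestry: modern vs archaic) runs along the genetic map with
pulse-admixture transitions — P(modern→archaic) = α(1−e^(−T·d)) over d
Morgans — and is fitted by a constrained EM: α, T and six of the eight
emission entries are re-estimated each iteration, while
P(archaic marker | modern) and P(test-specific marker | archaic) stay at
their ε-derived initial values (ε = 0.99) to control false detection.
Segments are decoded by Viterbi with midpoint boundaries and per-segment
posterior confidence.

**Matching.** A rooted reference tree `((test, African), (NEA, DEN)),
outgroup` is calibrated from genome-wide pairwise difference densities;
each segment's per-group difference profile is scored under seven
Poisson placements of its source — either archaic terminal edge, the
archaic common ancestor (including unknown archaic lineages), a
superarchaic stem, the modern-human edge (false positive), the
human–archaic ancestral edge (incomplete lineage sorting), or the
outgroup side — and labelled by the maximum-likelihood edge, with a
per-segment split-time estimate.

**History.** Tract lengths of one lineage (≥ 15 kb, in Morgans) follow a
K-component exponential mixture under a K-pulse history; the package
fits it by EM with an analytic correction for the 15-kb truncation,
selects K by sequential likelihood-ratio tests (χ², df = 2), converts
rates to times in generations (30-year generations → kya) and
proportions of the archaic fraction, and attaches bootstrap confidence
intervals and per-K support ratios.

The package also includes population statistics (local introgression
frequency, the ancestry-sharing ratio S_ij, introgression deserts,
diversity curves), per-allele archaic-origin probability calls with an
eQTL-enrichment test on LD-clustered loci, a tract-level simulator with
exact ground truth, and the concordance metrics used to benchmark
detection.  See the methods vignette
(`vignettes/archaic-introgression-methods.Rmd`) for models, assumptions
and design decisions.

## Worked example

Simulate a 5 Mb panel with a single 2% Neanderthal pulse 2000
generations ago, scan it, match the segments and date the pulse:

```r
library(archseekr)

cfg <- scenario_config(chrom_len = 5e6, n_test = 10, n_african = 20,
                       waves = list(list(lineage = "NEA", t = 2000, m = 0.02)),
                       seed = 42)
sim  <- simulate_panel(cfg)
scan <- seek(sim$panel)
scan
#> Archaic introgression scan
#>   10 test haplotypes, 5 Mb scanned
#>   fitted alpha = 0.02899, T = 1648 generations
#>   21 segments decoded (2.80% of haplotype-bp archaic)
```

The fitted `alpha` is the genome-wide archaic proportion and `T` the
transition-scale introgression age; `scan$segments` holds the calls with
their posterior confidence:

```r
head(scan$segments[, c("start", "end", "hap", "mean_posterior", "n_snps")], 3)
#>     start     end   hap mean_posterior n_snps
#> 1 3214297 3232185 tst01      0.9939722     87
#> 2 4153164 4227626 tst01      0.9804012    354
#> 3 4683750 4702068 tst01      0.9278841     97

m <- match_segments(scan$segments, sim$panel)
table(m$label)
#> archaic_ancestor              NEA
#>                2               19

concordance(scan$segments, sim$truth, sim$panel, basis = "length",
            genome_bp = cfg$chrom_len)$pooled
#> precision       tpr       fpr
#>    0.9823    0.9334    0.0005

reconstruct_history(m, "archaic", genome_bp = cfg$chrom_len,
                    n_hap = cfg$n_test, seed = 1)
#> Introgression wave model: K = 1 wave(s), 19 tracts
#>   wave 1: t = 1791 generations (53.7 kya at 30 y), m = 2.797%
#>   log-likelihood: 122.7816
```

Against the simulator's exact truth, 98.2% of called base pairs are truly
archaic (precision), 93.3% of archaic base pairs are recovered (TPR), and
0.05% of non-archaic sequence is miscalled (FPR); the single dated wave
(1791 generations ≈ 54 kya, 2.8%) recovers the simulated pulse within
the sampling noise of a 5 Mb panel.

A thin command-line front end (`inst/scripts/archseek`) exposes the same
pipeline as `archseek seek|match|history|simulate|evaluate` for shell
use on VCF + manifest + genetic-map files.

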