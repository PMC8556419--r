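---
title: "Detecting archaic introgression and dating admixture waves with archseekr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting archaic introgression and dating admixture waves with archseekr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(archseekr)
```

# The problem

A few percent of every non-African human genome descends from archaic
hominins — Neanderthals and Denisovans — through ancient interbreeding.
That ancestry survives as a mosaic of short tracts whose length
distribution shrinks with the age of the admixture pulse, so phased
modern genomes carry two complementary signals: *where* archaic sequence
lies (marker sharing with sequenced archaic genomes, depletion of common
modern variation) and *when* it arrived (tract lengths in genetic map
units).  `archseekr` implements a three-stage pipeline over these
signals — segment detection, lineage assignment, history reconstruction —
together with the population statistics, allele-level calls, simulator
and benchmark metrics needed to validate it end to end.

# The detection model

## Observation states

Each site of a polarized panel is classified, per test haplotype, by
derived-allele sharing with the reference panels: test-specific (state 1,
the derived allele is absent from both African and archaic references),
archaic marker (state 2, present in an archaic reference but in no
African), modern-human marker (state 3, present in Africans but in no
archaic reference), and common (state 4, everything else, including all
sites where the test haplotype is ancestral).  Missing reference
genotypes never count as carrying the derived allele; nothing is imputed.

## The hidden Markov model

A two-state HMM runs along the site grid of each test haplotype: hidden
state 0 is modern-human ancestry, hidden state 1 archaic.  Transitions
over a genetic distance $d$ Morgans follow the pulse-admixture Markov
model with introgression proportion $\alpha$ and time $T$ generations:

$$P(0 \to 1) = \alpha\,(1 - e^{-T d}), \qquad
  P(1 \to 0) = (1-\alpha)\,(1 - e^{-T d}),$$

the identity at $d = 0$ and the stationary distribution
$(1-\alpha, \alpha)$ as $d \to \infty$.  The initial distribution is the
stationary one.

## Constrained EM

Initial values are $\alpha_0 = 0.02$ and $T_0 = 2000$ generations;
results are insensitive to reasonable alternatives because both are
re-estimated.  The emission matrix is initialized from the genome-wide
observation-state frequencies through a single concentration parameter
$\varepsilon = 0.99$: the modern-human row puts mass $\varepsilon$ on
states 3 and 4 (split by frequency) and $1-\varepsilon$ on states 1 and
2; the archaic row puts mass $\varepsilon$ on states 1, 2 and 4 and
$1-\varepsilon$ on state 3.

Each EM iteration re-estimates $\alpha$ from the pooled marginal archaic
posterior, $T$ by a one-dimensional search maximizing the expected
transition log-likelihood (on $\log T$, clamped to $[1, 10^5]$;
$\alpha$ is clamped to $[10^{-6}, 0.5]$), and six of the eight emission
entries from expected counts.  Two entries stay frozen at their
$\varepsilon$-derived initial values:

* $P(\text{state 2} \mid \text{modern})$ — kept small so that genuine
  archaic markers cannot be absorbed into the modern-human state, which
  would destroy sensitivity;
* $P(\text{state 1} \mid \text{archaic})$ — kept small so that bursts of
  population-private variation (rare variants the African panel happens
  to miss) are not swallowed by the archaic state.  This is the
  false-detection guard: with this entry free, any unusual run of
  test-specific variants is called archaic, and sensitivity to an
  *unknown* archaic source would be driven almost entirely by its private
  alleles rather than by sharing with the sequenced references.  Freezing
  it also reproduces the characteristic drop in sensitivity when the
  introgressing lineage is deeply diverged from all references, which is
  the method's documented behaviour.  Which two entries to freeze is not
  derivable from first principles; this choice is the package's own.

Convergence is declared when the relative log-likelihood change falls
below $10^{-5}$ (at most 200 iterations); the trace is non-decreasing up
to numerical noise and is exposed in the fit object.

## Decoding

Segments are decoded by the Viterbi path (deterministic and
reproducible; posterior-threshold decoding would need an arbitrary
threshold and can produce fragmented calls).  A maximal run of the
archaic state becomes a segment; each boundary is placed at the midpoint
between the two SNPs flanking the state switch, with integer rounding
toward the shorter archaic segment, and runs touching the panel edge end
at the edge site.  The mean forward-backward posterior over the run is
reported per segment, so downstream users can filter on confidence.

# Lineage assignment

Candidate segments are matched to a rooted reference tree
`((test, African), (archaic-1, archaic-2)), outgroup`.  Calibration
replaces prior branch lengths by heights fitted to genome-wide mean
pairwise difference densities (per bp) between role groups; under a
clock, the least-squares height of an internal node is the mean of
$D/(2\mu)$ over pairs spanning it, the outgroup sets the root, and
ordering violations are clamped to zero-length branches.  Because the
outgroup is also the polarization ancestor, only the ingroup side
accumulates derived differences and the fitted root depth is half the
chronological one; placements use the same scale, so this cancels.

Each segment's per-group difference densities are then scored under
seven placements of its source lineage: the two archaic terminal edges,
the archaic common-ancestor edge (which also hosts unknown archaic
lineages splitting inside the archaic clade), a superarchaic stem edge
below the root, the modern-human terminal edge (a false positive), the
human–archaic ancestral edge (incomplete lineage sorting), and the
outgroup side.  Site differences are modeled as independent Poisson
counts with mean $2\mu\,T_{\mathrm{MRCA}}\,L$; the attachment time on the
edge is profiled out by its clamped maximum-likelihood value
$\hat t = \sum n_g / (2\mu \sum L_g)$ over the groups below the edge.
Exact ties go to the edge closest to the root — the conservative call.
Profiles use group means rather than the nearest haplotype: a per-segment
minimum over haplotypes is biased low over short windows (it selects on
noise), which would systematically favour the incomplete-lineage-sorting
placement; the group mean stays on the calibration scale at every
segment length.  The per-segment split time is
$\hat t$ converted at 30 years per generation; $\mu = 1.25\times10^{-8}$
per bp per generation by default, both configurable.

Segments labelled as false positives or incomplete lineage sorting are
excluded from history fitting.

# History reconstruction

Tract lengths from one matched lineage, converted to Morgans, follow a
$K$-component exponential mixture under a $K$-pulse history: component
$k$ has rate $u_k \approx (1-\alpha_{\mathrm{tot}})\,t_k$ per Morgan.
Segments shorter than 15 kb are removed first — below that scale
boundary noise dominates and the empirical length distribution is
unreliable.  The truncation is corrected analytically: a left-truncated
exponential mixture is again an exponential mixture in the shifted
lengths with weights damped by $e^{-u_k c}$, so the EM runs on shifted
lengths and the weights are un-damped afterwards.  $K=1$ uses the
closed-form MLE; $K \ge 2$ uses EM with ten fixed-seed restarts,
tolerance $10^{-6}$, 500 iterations.  Wave times apply the
$(1-\alpha_{\mathrm{tot}})$ small-proportion correction, and wave
proportions split the genome-wide introgressed fraction in proportion to
each component's length mass $w_k/u_k$.

The number of waves is selected by a sequential likelihood-ratio test of
$K$ against $K+1$, $2\Delta\ell$ against $\chi^2_2$ (one extra time, one
extra proportion) at level 0.05, with a guard requiring at least $10K$
tracts; the modern-human side is fixed at a single wave by construction
of the two-state detection model.  Bootstrap resampling of tracts (100
resamples by default, refitting including the selection step) yields
percentile intervals and the support ratio per $K$.  A selected wave with
proportion under 0.5% whose $K$ is supported by fewer than half the
resamples is deemed unstable and dropped, mirroring the observation that
spurious extra pulses carry small, unstable proportions.

# The simulator

`simulate_panel()` is a tract-level painter, not a coalescent engine: it
lays ground-truth tracts as a Poisson process (density $m\,t$ per Morgan,
lengths $\mathrm{Exp}(t)$ per Morgan) and then paints mutations site by
site with Poisson draws on each branch of the scaffold
`((test, African), (NEA source/ref, DEN source/ref)), outgroup`.  The
painted layers and their default calibration:

* human neutral polymorphism at Watterson density
  $4 N_e \mu\, a_n$ ($N_e = 10^4$), with a $1/k$ frequency spectrum; a
  frequency-dependent share $e^{-T_{\mathrm{split}}/2N_e} \cdot p$ of it
  predates the human–archaic split and is drift-sorted (probability 1/2)
  in each archaic population, so introgressed tracts are not perfectly
  depleted of shared variation;
* population-private drift variants since the African/test split (75
  kya);
* deep stem mutations shared by everything except the outgroup (6 Mya);
* archaic stem, branch and reference-private mutations for a 700 kya
  human–archaic split, 450 kya split of the two reference lineages, and
  sources diverging 100 kya from their sequenced reference;
* ancestral standing variation destined for fixation in the references
  ($2 N_{\mathrm{anc}} \mu$ per bp), carried by a source lineage with
  probability $1 - e^{-\Delta t / 2N}$ where $\Delta t$ is the shared
  stem time and $N$ the population the stem runs through (the deep
  ancestral $N_{\mathrm{anc}} = 10^4$ for unknown lineages, the small
  archaic $N_{\mathrm{arc}} = 2500$ within a sampled lineage) — this
  lineage-sorting decay is what makes deeply diverged unknown sources
  genuinely harder to detect;
* each source's own privately fixed ancestral variants (the complement
  of the shared ones), plus source-branch and post-introgression
  mutations private to tracts;
* a stylized incomplete-lineage-sorting layer: 1% of each human
  haplotype lies in deep-ancestry blocks of mean length
  $1/(2 r T_{\mathrm{split}})$ bp that carry archaic-fixed ancestral
  alleles with probability 1/2.

Unknown (`"UNK"`) sources attach to the archaic stem above the
reference split or to the first reference branch below it, with all
sharing densities adjusted accordingly.  Defaults
$\mu = 1.25\times10^{-8}$, $r = 10^{-8}$ per bp per generation, 30-year
generations.

What the painter does *not* emulate: local genealogy fluctuation around
tract boundaries (adjacent stretches of elevated archaic sharing, which
in coalescent data blur boundaries outward), ragged fine-scale truth
tracts, within-archaic reference heterozygosity, genotype or phasing
error, and linkage between painted sites beyond the block layers.
Passing benchmarks therefore demonstrate correctness of the estimators
under the pulse-admixture model with realistic marker densities; they do
not bound performance on real data, where boundary blur raises the
false-positive base-pair rate and lowers precision relative to this
testbed.  The same gap explains why the testbed's length-based precision
tends to sit a few points above, and its false-positive rate below,
values reported from full coalescent simulations.

# Benchmark design

The evaluation module scores detections by base-pair overlap, by SNP
counts, or restricted to non-AMH ancestry-informative markers (derived
in the focal haplotype, monomorphic-ancestral in the African panel);
segment-level accuracy uses the strict >80% overlap rule with a 15-kb
length filter.  Admixture-model success means the selected $K$ is true
and every wave time is within 30% and every proportion within 50%
relative error after oldest-first matching; the tolerances are an
explicit operationalization of a qualitative criterion and are exposed
as arguments.  The preset grids (36 one-wave, 48 two-wave one-lineage,
36 two-wave two-lineage, 24 unknown-lineage configurations, 144 in all)
cover pulse times of 500–3000 generations, proportions of 0.5–2%, and
unknown-source splits of 310–610 kya; they are approximate
reproductions of a benchmark design whose exact tables are not public.
The two-wave time pairs are predominantly well-separated pulses, with
one relatively close pair retained as the hard corner where
tract-length dating is known to break down.
The benchmark suite runs the concordance scenarios at 10 Mb with 20
test haplotypes, the unknown-lineage history grid at 16 Mb with 32 test
haplotypes, and the two-wave history grid at 24 Mb with 40 test
haplotypes — the largest sizes at which a full grid run stays at desk
scale.  Even so, two-wave scenarios yield only a few hundred tracts
each, whereas the likelihood-ratio selection of a second wave at rate
ratios below about three only approaches full power with thousands of
tracts; at this scale a substantial minority of two-wave scenarios are
expected to fall back to a single fitted wave, and the grid's success
rate understates what the estimator achieves on full-size tract
samples (its operating characteristics at large n are established
directly by the mixture-recovery and selection tests on synthetic
tract samples).

# Numerical notes and degenerate inputs

Forward–backward uses per-site scaling; posteriors sum to one to within
$10^{-10}$.  Zero genetic distances are floored at $10^{-9}$ Morgans so
transitions stay well-defined.  Panels with no informative markers are
rejected ("no markers") rather than fitted.  Exponential-mixture EM
guards degenerate components by flooring responsibilities and declares
non-convergence after all restarts with diagnostics.  Empty segment
lists, all-zero frequency tracks, populations without introgression
(sharing ratio undefined, reported `NA`) and genomes shorter than one
desert bin are handled explicitly.  The desert test includes the tested
bin in its empirical null — with thousands of bins the difference from
leave-one-out is negligible.

# Limitations

Diploid unphased input, within-segment recombination in the matcher,
continuous-migration histories, joint multi-population fitting, and
lift-over/phasing/imputation are out of scope.  The matcher assumes
exactly two archaic reference groups; more would enlarge the placement
set combinatorially.  Real-data allele calling requires dataset-specific
detection power, back-flow and ancestry proportions; the defaults are
deliberately conservative and must be set by the user.
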