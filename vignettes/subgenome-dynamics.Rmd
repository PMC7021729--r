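---
title: "Dissecting subgenome dynamics in allotetraploid genomes with polysub"
author: "polysub authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dissecting subgenome dynamics in allotetraploid genomes with polysub}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

An allotetraploid genome carries two complete chromosome sets (subgenomes A
and B) inherited from two diploid progenitor species that hybridised and
doubled.  When the progenitors are unknown or extinct, everything about the
polyploid's history has to be read out of the genome itself: which
chromosome belongs to which subgenome, when the progenitors diverged, when
the merger happened, how much duplicated gene content has been lost since
(fractionation), whether chromosome arms have traded segments
(homoeologous exchange), and whether one subgenome dominates expression.

`polysub` implements this battery of analyses as composable functions plus
a bundled synthetic-genome generator with complete ground truth, so every
stage can be validated end to end without external data.

## The synthetic allopolyploid generator

`simConfig()` describes a scenario; `simulatePolyploid()` realises it.  The
default scenario is a small allotetraploid grass genome: two progenitors
that split `t_divergence = 5e6` years ago and merged `t_merger = 1.1e6`
years ago, a synonymous substitution rate of `1.5e-8` per site per year and
an LTR rate of `1.3e-8`, 159-bp centromeric satellite monomers in two
lineages split by 10% of sites, per-gene post-merger loss probabilities of
2% per subgenome (two thirds of losses leaving pseudogene remnants), 5%
tandem duplication with arrays of up to 15 copies, three segmental
inversions, and a 10-tissue, 3-replicate expression atlas.

Coding sequences evolve under an exact continuous-time codon process:
every single-nucleotide change that preserves the amino acid occurs at rate
`mu_neutral / 3` (which makes the substitution rate per NG86 synonymous
site exactly `mu_neutral`), every amino-acid-changing step at
`mu_neutral * ka_ks_true / 3` (default `ka_ks_true = 0.2`), and changes
creating stop codons never.  The process is simulated by uniformised
thinning, so multiple hits per codon are handled exactly.  The expected
synonymous divergence of a homoeolog pair is therefore
`2 * mu_neutral * t_divergence` (0.15 under the defaults), which the NG86
estimator downstream must recover — an internal consistency check, and the
basis of the package's divergence-recovery tests at 1,000 pairs of 300
codons.

LTR retrotransposons are simulated per family with activity windows in
years.  Each element's two terminal repeats start identical and accumulate
substitutions independently at `mu_ltr`, giving expected pairwise
divergence `2 * mu_ltr * age` (before multiple-hit saturation, which the
simulation also reproduces since repeats evolve under Jukes–Cantor
dynamics).  The default landscape is teff-like at reduced scale: five
A-specific families and one B-specific family whose activity
ends at or before the merger (260 elements in total), four shared families
spanning or postdating the merger, and one deliberately undersized family
that the five-intact-copy filter must discard.  Insertion ages are drawn
uniformly within the family window; the uniform choice is a configuration
default, not an inference assumption.

The expression atlas draws per-pair baselines log-normally
(`meanlog = log(100)`, `sdlog = 1`), gives a fraction `frac_biased = 0.658`
of pairs a true log2 shift of 1 toward one homoeolog (B with probability
`prob_bias_toward_B = 0.56`), keeps that direction in every tissue for
`frac_consistent_across_tissues = 0.869` of biased pairs and flips it in a
uniform 1..(n_tissues-1) tissues for the rest, shares tissue effects
between the two homoeologs of a pair, and draws replicate counts from a
negative binomial with constant dispersion 0.05 and log-normal library-size
factors.  The three bias parameters describe a teff-like pattern of mild,
mostly stable B-subgenome expression dominance.

What the generator deliberately does *not* emulate: read-level noise and
mapping ambiguity (counts are direct draws, not alignments), indels in
coding sequence, gene-wise dispersion trends, GC or codon-usage bias,
nested or truncated transposon insertions, and satellite higher-order
repeat structure.  Passing tests therefore demonstrate correctness of the
estimators under the stated generative model, not robustness to every
artifact of real sequencing data.

## Satellite phasing

`detectTandemRepeats()` scores each candidate period p by the fraction of
positions matching their p-shifted neighbour, maximised over 4p-bp sliding
windows; the reported period is the smallest candidate within 95% of the
best score, which suppresses period multiples, and the array extent is the
run where the 2p-smoothed match profile stays above the midpoint between
the random-sequence baseline (0.25) and the array score.  The detection
threshold of 0.7 sits far above the baseline yet tolerates >10% per-copy
divergence.

`consensusMonomer()` phase-aligns copies by circular rotation against the
first copy (minimal Hamming distance, ties resolved toward the smallest
offset) and takes per-column majorities, breaking ties in the fixed order
A < C < G < T so consensus building is fully deterministic.

`phaseSubgenomes()` computes exact circular p-distances between the
per-chromosome consensuses, builds a neighbor-joining tree, and roots it at
the internal edge whose bipartition maximises the ratio of between- to
within-clade mean distance — a midpoint-like best-split rooting, used
because no outgroup is available.  If that ratio does not exceed 1 the
phasing is declared unresolvable (this is what happens when the two
monomer lineages are identical).  Support is the fraction of monomer-column
bootstrap replicates recovering each clade.  A neighbor-joining tree is
used rather than maximum likelihood: for a two-clade split over short
monomers the topology is method-robust, and NJ keeps the column bootstrap
inexpensive.  Labels are deterministic (the clade containing the
lexicographically smallest chromosome id is "A") and phasing is invariant
to input order and monomer rotation.

## LTR insertion-time dating and the polyploidy bracket

`ltrDivergence()` globally aligns the two terminal repeats (match 1,
mismatch −1, gap open 4, gap extend 1) and reports the raw proportion of
mismatched columns among aligned non-gap columns.  The raw p-distance is
the default because insertion dating conventionally approximates K by
percent identity; `jc_correct = TRUE` applies the Jukes–Cantor correction
for sensitivity analysis.  Elements whose repeats align over less than
half the shorter repeat are flagged non-intact and excluded.
`insertionTime()` is the textbook `T = K / (2 mu)`; both rate constants
(1.5e-8 for genes, 1.3e-8 for LTRs) are arguments everywhere, never
hard-coded.

`classifyFamilySpecificity()` drops families with fewer than five intact
copies and calls a family subgenome-specific when every intact member lies
on one subgenome.  `bracketPolyploidy()` turns the specific families into a
date for the merger: such families were only active while the progenitors
evolved separately, so their youngest insertion bounds the merger from
above.

The naive bound — the minimum insertion time over all specific elements —
is available as `method = "minimum"`, but on realistic repeat lengths it is
dominated by measurement error: K is a binomial proportion over L aligned
sites, so a 500-bp repeat at K ≈ 0.029 carries a standard error of about
0.0075, i.e. roughly 0.29 Myr per element, and the minimum over hundreds of
elements lands far below the true floor.  The default
(`method = "deconvolution"`) therefore estimates the truncation point of
the pooled insertion-age distribution under the exact binomial observation
model `K·L ~ Binomial(L, 3/4 (1 − exp(−8 mu a/3)))`.  Because the age
density just above the floor is unknown, two limiting edge shapes are
fitted — ages uniform above the floor (a flat edge, which biases the floor
down when the density actually rises) and exponential decay from the floor
with the decay rate estimated from the upper tail (maximal edge
concentration, which biases it up) — and the midpoint is reported, with
both fits returned as an explicit bracket and the raw minimum kept as a
diagnostic.  In the package's recovery tests this estimator locates a
1.1-Myr merger within 15% from 260 specific elements with 500-bp repeats.

## Synteny, homoeolog pairing and fractionation

`findHomologyPairs()` seeds candidate pairs with shared frame-aligned
12-mers (sampled every 3 bp) and scores candidates by local alignment.
The C-score of a pair is its score divided by the best score either member
achieves, so the default cutoff of 0.99 keeps reciprocal-best pairs — the
recent homoeologs — and discards paralogs from older whole-genome
duplications, which at ~70% identity score far below the ~94%-identity
homoeologs.  The k-mer seeding assumes homoeologs share enough exact
12-mers; at 94% identity roughly half of frame-aligned 12-mers survive, so
the 5-shared-k-mer threshold is conservative.

`chainBlocks()` is a gap-penalised dynamic program over the anchor dot-plot
of each chromosome pair: the longest strictly monotone chain (ascending or
descending, rank gaps at most `max_gap = 25` on both axes) is extracted,
removed, and the search repeated while chains of at least `min_block = 5`
anchors remain.  `max_gap` follows common collinearity-tool defaults and is
exposed as configuration.  `resolveHomoeologPairs()` reduces anchors to 1:1
pairs greedily by descending alignment score with ties to the smaller
rank, so tandem copies cannot claim two partners.  `syntenicDepth()`
counts, for every reference gene, the blocks in which it is anchored — a
diploid reference against an intact tetraploid sits at depth 2, and
fractionation of one copy drops a gene to depth 1, so under a loss rate r
per subgenome the depth-2 fraction is approximately (1−r)².
`tandemGeneArrays()` single-links within-chromosome hits at rank distance
≤ 10.  `classifyRetention()` labels genes as pair / gene+pseudogene /
single, and `testBiasedFractionation()` is the exact two-sided binomial
test of equal losses.

## Ka/Ks and the exchange scan

`alignCodons()` aligns the translated proteins (BLOSUM62, affine gaps) and
threads the alignment back onto codons; gapped columns are excluded.
`ng86()` implements Nei–Gojobori (1986) counting: per-codon synonymous
site fractions averaged over the two sequences (mutations to stop codons
count as nonsynonymous), pathway-averaged difference counts that skip
routes through stop codons (falling back to all routes when every one is
blocked), and the Jukes–Cantor correction on both proportions.  Pairs with
ps or pn at or beyond 0.75 are flagged saturated; omega is reported as
missing when Ks is 0.  Transitions and transversions are weighted equally
(pure NG86, no kappa).  NG86 was chosen over maximum-likelihood codon
models for transparency and zero dependencies; at the divergence this
package targets (Ks ≈ 0.15) the two agree closely, and the package's
tolerance statements for Ks-based quantities are set accordingly.

`ksDistribution()` reports the median and the number of kernel-density
peaks (Silverman bandwidth; a peak is a local maximum above 10% of the
density maximum, which ignores baseline ripple), and
`scanHomoeologousExchange()` slides windows of 50 gene pairs at step 25
along each chromosome and flags windows whose median Ks falls below half
the genome-wide median — a recent exchange replaces one homoeolog with a
copy of the other, collapsing local divergence toward zero.  Window, step
and threshold are unstandardised in the literature; the defaults are
deliberately coarse (an exchanged segment must span roughly half a window
to be caught) and all three are arguments.

## Homoeolog expression bias

Counts are normalised by median-of-ratios size factors over the full
matrix.  For each pair and tissue, `hebTest()` compares the two homoeologs
on the log scale: HEB is `log2((mean_A + 1)/(mean_B + 1))` (positive =
A-dominant; the pseudocount is configurable), the dispersion is a
method-of-moments estimate pooled across the pair and floored at the
tissue-wide mean of pair dispersions (the ensemble version of
common-dispersion estimation — with three replicates a per-pair moment
estimate alone is too noisy), and the Wald statistic uses the delta-method
standard error from the NB variance function with a normal reference.
Under a null simulation this combination keeps the BH false-discovery rate
within its level across dispersions from 0.01 to 1.  The standalone
`testPairTissue()`, which has no ensemble to borrow from, instead uses a
deliberately conservative t reference with `n_a + n_b − 3` degrees of
freedom, calibrated so its raw type-I error stays at or below nominal over
the same dispersion sweep.

`classifyBias()` adjusts p-values by Benjamini–Hochberg within each tissue
(a `per_tissue = FALSE` switch performs a single global adjustment;
designs differ on this and both are defensible) and classes records as A-
or B-biased at FDR < 0.05, balanced otherwise, or not expressed when both
normalized means fall below 1 — the floor that operationalises "negligible
expression".  `dominanceConsistency()` labels pairs consistent, reversing
or never-biased; note that detected consistency slightly exceeds the
generating consistency because a reversing pair whose flipped tissues all
fail the significance cutoff reads as consistent — a censoring effect any
finite-power analysis shares.  `kaksByHeb()` stratifies pairs by the
number of biased tissues (none / intermediate / all) and compares the
extreme strata by two-sided Mann–Whitney tests on Ka/Ks and on Ks.

## Pipeline, sizes and reproducibility

`runPipeline()` chains all stages on a simulated genome and emits a
summary block (divergence time from the median Ks, polyploidy bracket,
retention fraction, fractionation p, bias shares, consistency share,
repeat-content excess between subgenomes).  Every stage draws its random
numbers from a stream derived from the single configuration seed, so a
given `SimConfig` reproduces byte-identical simulated data and identical
downstream numbers.

The package's own test and validation runs use desk-scale problem sizes
chosen to keep Monte-Carlo error well inside the stated tolerances: 1,000
homoeolog pairs of 300 codons for Ks recovery (binomial error on the
median ≈ 0.001), 260 specific LTR elements with 500-bp repeats for the
polyploidy bracket, 20 chromosomes with 150–824 monomer copies for
phasing, and 5,000 pairs × 10 tissues × 3 replicates for the expression
atlas (50,000 comparisons, so a 3-percentage-point tolerance on a bias
share is ~13 binomial standard errors).

## Known limitations

The homology search is k-mer seeded and will miss homoeologs more diverged
than ~85% identity or shorter than ~100 codons.  The exchange scan detects
only exchanges long enough to dominate a window and assumes exchanges are
recent (near-zero Ks).  The NB test does not shrink effect sizes, so very
low counts produce noisy HEB magnitudes even when direction calls are
controlled.  The polyploidy bracket assumes specific-family activity
genuinely ceased at the merger; ongoing activity in an unrecognised
contaminating family would bias the floor young.  None of the estimators
model indels in coding sequence; `alignCodons()` handles them, but the
generator never produces them, so that path is validated only on
constructed cases.
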