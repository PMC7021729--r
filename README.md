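# polysub

Subgenome dynamics in allopolyploid genomes: phasing, dating,
fractionation, divergence and expression bias — with a fully synthetic,
truth-tracked test bed.

## What it is for

Allotetraploids carry two subgenomes (A and B) from two diploid progenitor
species.  When those progenitors are unknown, the polyploid's history must
be reconstructed from the genome alone.  `polysub` provides that
reconstruction toolkit for R users working on polyploid genomics:

- **Subgenome phasing** from centromeric satellite monomers: tandem-repeat
  detection by periodicity scoring, circular-alignment consensus building,
  and a neighbor-joining monomer phylogeny whose best two-clade split
  assigns chromosomes to subgenomes (`detectTandemRepeats`,
  `consensusMonomer`, `phaseSubgenomes`).
- **Polyploidy dating** from LTR retrotransposons: the two terminal
  repeats of an element are identical at insertion, so their divergence K
  dates it via *T = K/2μ* (μ = 1.3×10⁻⁸ per site per year for LTRs).
  Families with ≥5 intact copies that are restricted to one subgenome were
  active only before the genome merger, so their youngest insertions
  bracket the polyploidy event (`ltrDivergence`, `insertionTime`,
  `classifyFamilySpecificity`, `bracketPolyploidy`).
- **Syntenic homoeolog pairing and fractionation**: k-mer seeded homology
  search with a C-score filter (cutoff 0.99) that removes older
  whole-genome-duplication paralogs, monotone-chain block detection
  (minimum block 5 genes), 1:1 pair resolution, tandem arrays (gene
  distance ≤ 10), retention classes and an exact binomial test for biased
  gene loss (`findHomologyPairs`, `chainBlocks`, `resolveHomoeologPairs`,
  `syntenicDepth`, `tandemGeneArrays`, `classifyRetention`,
  `testBiasedFractionation`).
- **Molecular evolution**: Nei–Gojobori (1986) Ka/Ks with pathway
  averaging and Jukes–Cantor correction, Ks→time conversion
  (*T = Ks/2μ*, μ = 1.5×10⁻⁸ for synonymous sites), Ks distribution
  summaries, and a windowed-Ks scan for homoeologous exchange
  (`ng86`, `kaKs`, `ksToTime`, `ksDistribution`,
  `scanHomoeologousExchange`).
- **Homoeolog expression bias**: median-of-ratios normalization,
  negative-binomial Wald tests per pair and tissue, BH-controlled bias
  classes, cross-tissue dominance consistency, and Ka/Ks stratified by
  bias strength (`hebTest`, `classifyBias`, `dominanceConsistency`,
  `kaksByHeb`).
- **A synthetic allopolyploid generator** (`simConfig`,
  `simulatePolyploid`, `writeSimulatedPolyploid`) that emulates two
  progenitors diverging 5 Myr ago and merging 1.1 Myr ago, LTR families
  with pre- and post-merger activity, two 159-bp satellite monomer
  lineages, configurable gene loss / tandem duplication / inversions, and
  a 10-tissue × 3-replicate negative-binomial expression atlas — all with
  complete truth tables, so every stage above is testable offline.

## Worked example

A desk-scale end-to-end run (two chromosome pairs, 30 genes each):

```r
library(polysub)
cfg <- simConfig(seed = 9, n_chromosome_pairs = 2, genes_per_chromosome = 30,
                 codons_per_gene = 100, satellite_copy_range = c(30, 80))
rep <- runPipeline(cfg, verbose = FALSE)
str(rep$summary)
```

```
List of 16
 $ subgenome_divergence_myr  : num 5.07
 $ polyploidy_myr            : num 1.06
 $ polyploidy_raw_min_myr    : num 0.615
 $ median_ks                 : num 0.152
 $ ks_peaks                  : int 1
 $ phasing_accuracy          : num 1
 $ n_homoeolog_pairs         : int 58
 $ retention_fraction        : num 0.983
 $ fractionation_p           : num 1
 $ n_exchange_windows_flagged: int 0
 $ bias_share_B_significant  : num 0.615
 $ bias_share_B_point        : num 0.58
 $ consistency_share         : num 0.844
 $ repeat_mb_A               : num 0.368
 $ repeat_mb_B               : num 0.146
 $ repeat_excess_percent     : num 151
```

Reading it: the median homoeolog Ks of 0.152 converts to a progenitor
divergence of 5.07 Myr (the generating scenario used 5 Myr); the
subgenome-specific LTR families bracket the merger at 1.06 Myr (truth
1.1 Myr; the raw minimum insertion time of 0.61 Myr illustrates why the
measurement-error-aware floor is the default); satellite phasing assigned
all chromosomes to the correct subgenome; 98.3% of genes survive as pairs
or gene+pseudogene pairs with no loss bias (binomial p = 1); the exchange
scan flags nothing, as simulated; 61.5% of significantly biased
comparisons favor the B subgenome in this small run; and 84.4% of
ever-biased pairs keep one dominant homoeolog across all tissues.  At this
tiny scale the shares carry binomial noise of several points; the
full-scale recovery runs below use 1,000–5,000 pairs.

`runPipeline(cfg, outdir = "out")` additionally writes the simulated
bundle (FASTA / GFF3 / BED / TSV with `truth_*` attributes) and a JSON
report.  `inst/scripts/polysub.R` wraps `simulate`, `run-all` and
`validate` for shell use.

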