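# Shared small simulations, cached per test run.

.sim_cache <- new.env(parent = emptyenv())

smallConfig <- function(seed = 101L, ...) {
  simConfig(seed = seed, n_chromosome_pairs = 2L,
            genes_per_chromosome = 30L, codons_per_gene = 100L,
            satellite_copy_range = c(30L, 80L), ...)
}

# a cached default-rate small genome shared by synteny / kaks tests
cachedSmallSim <- function() {
  if (is.null(.sim_cache$sp)) {
    cfg <- smallConfig(seed = 77L)
    sp <- simulateProgenitors(cfg)
    sp <- simulateSatellites(cfg, sp)
    .sim_cache$sp <- simulateAtlas(cfg, sp)
  }
  .sim_cache$sp
}

geneOrders <- function(sp) {
  g <- truthGenes(sp)
  g <- g[g$status == "retained", ]
  data.frame(gene_id = g$gene_id, chromosome = g$chromosome, rank = g$rank)
}

# partition equality up to label swap (adjusted Rand index 1 for two
# two-group partitions)
samePartition <- function(labels, truth) {
  truth <- truth[names(labels)]
  mean(labels == truth) %in% c(0, 1) ||
    all((labels == labels[1]) == (truth == truth[1]))
}

randomCdsString <- function(n_codons, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sense <- setdiff(names(Biostrings::GENETIC_CODE),
                   names(Biostrings::GENETIC_CODE)[
                     Biostrings::GENETIC_CODE == "*"])
  paste0(c("ATG", sample(sense, n_codons - 1, replace = TRUE)),
         collapse = "")
}
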