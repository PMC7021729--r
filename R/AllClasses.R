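#' Configuration for the synthetic allopolyploid generator
#'
#' A \code{SimConfig} captures the full scenario an allotetraploid simulation
#' is run under: the age of the progenitor split (\code{t_divergence}), the
#' age of the genome merger (\code{t_merger}), per-year substitution rates for
#' synonymous sites (\code{mu_neutral}) and LTR sequences (\code{mu_ltr}),
#' gene complement sizes, post-merger gene loss (fractionation) and tandem
#' duplication rates, inversion counts, LTR retrotransposon family activity
#' windows, centromeric satellite parameters, and the expression-atlas model.
#'
#' @slot seed integer; master seed from which all stage seeds derive.
#' @slot n_chromosome_pairs integer; homoeologous chromosome pairs.
#' @slot genes_per_chromosome integer; genes on each ancestral chromosome.
#' @slot codons_per_gene integer (>= 100).
#' @slot t_divergence years since the two progenitors split.
#' @slot t_merger years since the allopolyploidy event (< t_divergence).
#' @slot mu_neutral substitutions per synonymous site per year.
#' @slot mu_ltr substitutions per site per year used for LTR sequences.
#' @slot ka_ks_true true nonsynonymous/synonymous rate ratio of simulated CDS.
#' @slot ltr_families data.frame with columns \code{name},
#'   \code{subgenome} (\code{"A"}, \code{"B"} or \code{"shared"}),
#'   \code{start_age}, \code{end_age} (years, start >= end) and \code{copies}.
#' @slot ltr_length bp of each terminal repeat.
#' @slot satellite_monomer_length bp (default 159).
#' @slot satellite_clade_divergence proportion of monomer sites separating the
#'   two subgenome satellite lineages.
#' @slot satellite_copy_range integer range of monomer copies per array.
#' @slot satellite_copy_noise per-copy, per-site substitution probability.
#' @slot fractionation_rate_A,fractionation_rate_B per-gene loss probability.
#' @slot pseudogene_fraction fraction of lost genes leaving a recognizable
#'   pseudogene remnant.
#' @slot tandem_rate per-gene probability of a tandem duplication.
#' @slot tandem_max_copies maximum array size (<= 15).
#' @slot inversion_count number of segmental inversions applied to the B
#'   subgenome gene order.
#' @slot atlas list with \code{n_tissues}, \code{n_reps}, \code{dispersion},
#'   \code{frac_biased}, \code{prob_bias_toward_B},
#'   \code{frac_consistent_across_tissues}, \code{effect_log2},
#'   \code{baseline_meanlog}, \code{baseline_sdlog}, \code{tissue_sdlog},
#'   \code{libsize_sdlog}.
#' @seealso [simConfig()], [simulatePolyploid()]
#' @export
setClass("SimConfig", representation(
  seed = "integer",
  n_chromosome_pairs = "integer",
  genes_per_chromosome = "integer",
  codons_per_gene = "integer",
  t_divergence = "numeric",
  t_merger = "numeric",
  mu_neutral = "numeric",
  mu_ltr = "numeric",
  ka_ks_true = "numeric",
  ltr_families = "data.frame",
  ltr_length = "integer",
  satellite_monomer_length = "integer",
  satellite_clade_divergence = "numeric",
  satellite_copy_range = "integer",
  satellite_copy_noise = "numeric",
  fractionation_rate_A = "numeric",
  fractionation_rate_B = "numeric",
  pseudogene_fraction = "numeric",
  tandem_rate = "numeric",
  tandem_max_copies = "integer",
  inversion_count = "integer",
  atlas = "list"
))

setValidity("SimConfig", function(object) {
  msg <- character()
  if (object@t_merger >= object@t_divergence)
    msg <- c(msg, "t_merger must be younger than t_divergence")
  if (object@codons_per_gene < 100L)
    msg <- c(msg, "codons_per_gene must be >= 100")
  if (object@satellite_monomer_length < 20L)
    msg <- c(msg, "satellite monomer length must be >= 20 bp")
  rates <- c(object@mu_neutral, object@mu_ltr, object@ka_ks_true,
             object@fractionation_rate_A, object@fractionation_rate_B,
             object@tandem_rate, object@satellite_clade_divergence,
             object@satellite_copy_noise)
  if (any(rates < 0)) msg <- c(msg, "all rates must be >= 0")
  if (object@tandem_max_copies > 15L)
    msg <- c(msg, "tandem_max_copies must be <= 15")
  if (object@atlas$n_reps < 2L) msg <- c(msg, "atlas n_reps must be >= 2")
  if (object@atlas$dispersion <= 0) msg <- c(msg, "atlas dispersion must be > 0")
  fam <- object@ltr_families
  if (nrow(fam)) {
    need <- c("name", "subgenome", "start_age", "end_age", "copies")
    if (!all(need %in% names(fam)))
      msg <- c(msg, "ltr_families must have columns name, subgenome, start_age, end_age, copies")
    else {
      if (!all(fam$subgenome %in% c("A", "B", "shared")))
        msg <- c(msg, "ltr_families$subgenome must be A, B or shared")
      if (any(fam$start_age < fam$end_age) || any(fam$end_age < 0))
        msg <- c(msg, "family activity windows need start_age >= end_age >= 0")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Simulated allotetraploid genome with full ground truth
#'
#' Container for everything one simulation run produced: per-gene truth table
#' (subgenome, homoeolog partner, retention status, tandem arrays, gene
#' order), coding sequences, the ancestral diploid gene set (a stand-in
#' diploid reference for syntenic-depth analyses), LTR element records with
#' true insertion ages, centromeric satellite arrays with true clade labels,
#' and the expression atlas with its truth bias table.
#'
#' @slot config the [SimConfig-class] the object was generated under.
#' @slot genes data.frame truth table, one row per gene copy.
#' @slot cds [Biostrings::DNAStringSet] of retained gene coding sequences.
#' @slot ancestral_cds [Biostrings::DNAStringSet] of the ancestral diploid genes.
#' @slot ltr_elements data.frame of LTR elements (may be empty until
#'   [simulateLtrLandscape()] is run).
#' @slot ltr_seqs [Biostrings::DNAStringSet] of paired terminal repeats, ids
#'   \code{<element>_5p} / \code{<element>_3p}.
#' @slot satellites list: \code{arrays} data.frame, \code{monomers} (list of
#'   [Biostrings::DNAStringSet] per chromosome), \code{clade_monomers}.
#' @slot atlas list: \code{counts} integer matrix, \code{samples} data.frame,
#'   \code{truth} data.frame.
#' @export
setClass("SimulatedPolyploid", representation(
  config = "SimConfig",
  genes = "data.frame",
  cds = "DNAStringSet",
  ancestral_cds = "DNAStringSet",
  ltr_elements = "data.frame",
  ltr_seqs = "DNAStringSet",
  satellites = "list",
  atlas = "list"
))

setValidity("SimulatedPolyploid", function(object) {
  g <- object@genes
  if (!nrow(g)) return("empty gene truth table")
  need <- c("gene_id", "chromosome", "subgenome", "pair_id", "rank", "status")
  if (!all(need %in% names(g)))
    return(paste("gene table must contain:", paste(need, collapse = ", ")))
  if (!all(g$status %in% c("retained", "lost", "pseudogene")))
    return("gene status must be retained/lost/pseudogene")
  if (length(object@atlas) && !is.null(object@atlas$counts) &&
      any(object@atlas$counts < 0))
    return("atlas counts must be non-negative")
  TRUE
})

#' Result of satellite-based subgenome phasing
#'
#' @slot tree an [ape::phylo] neighbor-joining tree over per-chromosome
#'   satellite consensus monomers (rooted at the best two-clade split).
#' @slot assignments named character vector, chromosome -> "A"/"B".
#' @slot support numeric bootstrap proportion for each of the two clades.
#' @slot diagnostics list with within/between-clade mean distances and, when
#'   homoeolog pairing was supplied, a consistency flag.
#' @export
setClass("PhasingResult", representation(
  tree = "ANY",
  assignments = "character",
  support = "numeric",
  diagnostics = "list"
))

setValidity("PhasingResult", function(object) {
  if (!all(object@assignments %in% c("A", "B")))
    return("assignments must be A or B")
  if (length(unique(object@assignments)) != 2L)
    return("phasing must yield exactly two clades")
  TRUE
})
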