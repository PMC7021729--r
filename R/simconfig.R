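#' Default LTR retrotransposon family scenario
#'
#' A scaled-down teff-like landscape: six subgenome-specific
#' families (five restricted to the A subgenome, one to the B subgenome)
#' whose activity windows all predate the genome merger, four shared families
#' spanning or postdating the merger, and one undersized family that the
#' five-intact-copy filter must drop.
#'
#' @return data.frame with columns \code{name}, \code{subgenome},
#'   \code{start_age}, \code{end_age}, \code{copies}.
#' @export
defaultLtrFamilies <- function() {
  data.frame(
    name = c("RLG_A1", "RLG_A2", "RLG_A3", "RLC_A4", "RLG_A5", "RLG_B1",
             "RLC_S1", "RLG_S2", "RLG_S3", "RLX_S4", "RLX_small"),
    subgenome = c("A", "A", "A", "A", "A", "B",
                  "shared", "shared", "shared", "shared", "shared"),
    start_age = c(1.6e6, 2.0e6, 2.5e6, 3.0e6, 2.2e6, 1.8e6,
                  1.0e6, 2.5e6, 0.5e6, 3.5e6, 0.8e6),
    end_age = c(1.1e6, 1.2e6, 1.4e6, 1.8e6, 1.3e6, 1.1e6,
                0, 2.0e5, 0, 1.0e6, 0),
    copies = c(60L, 50L, 40L, 30L, 40L, 40L, 40L, 40L, 30L, 30L, 4L),
    stringsAsFactors = FALSE
  )
}

#' Default expression-atlas model
#'
#' Ten tissues with three biological replicates, negative-binomial counts
#' with a constant gene-wise dispersion.  The default bias structure is
#' teff-like: about two thirds of homoeolog pairs carry true expression
#' bias, 56\% of biased comparisons favor the B subgenome, and 86.9\% of
#' biased pairs keep the same dominant homoeolog in every tissue.
#'
#' @param n_tissues,n_reps atlas dimensions.
#' @param dispersion NB dispersion (variance = mu + dispersion * mu^2).
#' @param frac_biased fraction of pairs with true expression bias.
#' @param prob_bias_toward_B probability a biased pair's dominant homoeolog
#'   is on the B subgenome.
#' @param frac_consistent_across_tissues fraction of biased pairs whose
#'   dominant homoeolog is the same in every tissue.
#' @param effect_log2 log2 fold change applied to the dominant homoeolog.
#' @param baseline_meanlog,baseline_sdlog log-normal baseline expression.
#' @param tissue_sdlog log-normal spread of shared pair-by-tissue effects.
#' @param libsize_sdlog log-normal spread of library-size factors.
#' @return list suitable for the \code{atlas} slot of [SimConfig-class].
#' @export
atlasSpec <- function(n_tissues = 10L, n_reps = 3L, dispersion = 0.05,
                      frac_biased = 0.658, prob_bias_toward_B = 0.56,
                      frac_consistent_across_tissues = 0.869,
                      effect_log2 = 1, baseline_meanlog = log(100),
                      baseline_sdlog = 1, tissue_sdlog = 0.4,
                      libsize_sdlog = 0.1) {
  list(n_tissues = as.integer(n_tissues), n_reps = as.integer(n_reps),
       dispersion = dispersion, frac_biased = frac_biased,
       prob_bias_toward_B = prob_bias_toward_B,
       frac_consistent_across_tissues = frac_consistent_across_tissues,
       effect_log2 = effect_log2, baseline_meanlog = baseline_meanlog,
       baseline_sdlog = baseline_sdlog, tissue_sdlog = tissue_sdlog,
       libsize_sdlog = libsize_sdlog)
}

#' Build a simulation configuration
#'
#' Defaults describe a teff-like allotetraploid scenario: two diploid
#' progenitors that
#' diverged 5 Myr ago and merged into an allotetraploid 1.1 Myr ago, a
#' synonymous substitution rate of 1.5e-8 per site per year, an LTR rate of
#' 1.3e-8, 159-bp centromeric satellite monomers in two subgenome lineages,
#' and a ten-tissue, three-replicate expression atlas.
#'
#' @param seed master seed; every stage derives its own stream from it.
#' @param n_chromosome_pairs,genes_per_chromosome,codons_per_gene genome size.
#' @param t_divergence,t_merger years before present.
#' @param mu_neutral,mu_ltr substitution rates per site per year.
#' @param ka_ks_true true omega under which coding sequences evolve.
#' @param ltr_families see [defaultLtrFamilies()].
#' @param ltr_length terminal repeat length in bp.
#' @param satellite_monomer_length,satellite_clade_divergence,
#'   satellite_copy_range,satellite_copy_noise satellite model.
#' @param fractionation_rate_A,fractionation_rate_B per-gene loss
#'   probabilities after the merger.
#' @param pseudogene_fraction fraction of losses leaving pseudogene remnants.
#' @param tandem_rate,tandem_max_copies tandem duplication model.
#' @param inversion_count segmental inversions applied to the B gene order.
#' @param atlas see [atlasSpec()].
#' @return a validated [SimConfig-class] object.
#' @examples
#' cfg <- simConfig(seed = 1, n_chromosome_pairs = 2,
#'                  genes_per_chromosome = 20, codons_per_gene = 120)
#' cfg
#' @export
simConfig <- function(seed = 42L,
                      n_chromosome_pairs = 10L,
                      genes_per_chromosome = 100L,
                      codons_per_gene = 300L,
                      t_divergence = 5.0e6,
                      t_merger = 1.1e6,
                      mu_neutral = 1.5e-8,
                      mu_ltr = 1.3e-8,
                      ka_ks_true = 0.2,
                      ltr_families = defaultLtrFamilies(),
                      ltr_length = 500L,
                      satellite_monomer_length = 159L,
                      satellite_clade_divergence = 0.10,
                      satellite_copy_range = c(22L, 824L),
                      satellite_copy_noise = 0.02,
                      fractionation_rate_A = 0.02,
                      fractionation_rate_B = 0.02,
                      pseudogene_fraction = 0.67,
                      tandem_rate = 0.05,
                      tandem_max_copies = 15L,
                      inversion_count = 3L,
                      atlas = atlasSpec()) {
  if (n_chromosome_pairs < 1L || genes_per_chromosome < 1L)
    stop("degenerate configuration: need at least 1 chromosome pair and 1 gene")
  new("SimConfig",
      seed = as.integer(seed),
      n_chromosome_pairs = as.integer(n_chromosome_pairs),
      genes_per_chromosome = as.integer(genes_per_chromosome),
      codons_per_gene = as.integer(codons_per_gene),
      t_divergence = t_divergence,
      t_merger = t_merger,
      mu_neutral = mu_neutral,
      mu_ltr = mu_ltr,
      ka_ks_true = ka_ks_true,
      ltr_families = ltr_families,
      ltr_length = as.integer(ltr_length),
      satellite_monomer_length = as.integer(satellite_monomer_length),
      satellite_clade_divergence = satellite_clade_divergence,
      satellite_copy_range = as.integer(satellite_copy_range),
      satellite_copy_noise = satellite_copy_noise,
      fractionation_rate_A = fractionation_rate_A,
      fractionation_rate_B = fractionation_rate_B,
      pseudogene_fraction = pseudogene_fraction,
      tandem_rate = tandem_rate,
      tandem_max_copies = as.integer(tandem_max_copies),
      inversion_count = as.integer(inversion_count),
      atlas = atlas)
}

# stage-specific RNG streams derived from the master seed
stageSeed <- function(config, stage) {
  offsets <- c(progenitors = 1L, ltr = 2L, satellites = 3L, atlas = 4L,
               layout = 5L)
  s <- (as.integer(config@seed) %% 1000000L) * 2011L + offsets[[stage]]
  set.seed(s)
  invisible(s)
}

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig\n")
  cat(sprintf("  %d chromosome pairs x %d genes x %d codons\n",
              object@n_chromosome_pairs, object@genes_per_chromosome,
              object@codons_per_gene))
  cat(sprintf("  divergence %.2f Myr, merger %.2f Myr\n",
              object@t_divergence / 1e6, object@t_merger / 1e6))
  cat(sprintf("  mu (synonymous) %.3g, mu (LTR) %.3g per site per year\n",
              object@mu_neutral, object@mu_ltr))
  cat(sprintf("  %d LTR families; satellite monomer %d bp\n",
              nrow(object@ltr_families), object@satellite_monomer_length))
  cat(sprintf("  atlas: %d tissues x %d reps\n",
              object@atlas$n_tissues, object@atlas$n_reps))
  invisible(NULL)
})
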