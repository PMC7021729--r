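# Accessors and show methods for SimulatedPolyploid.

#' @describeIn SimulatedPolyploid-accessors per-gene truth table
#' @export
setGeneric("truthGenes", function(x) standardGeneric("truthGenes"))

#' @describeIn SimulatedPolyploid-accessors surviving homoeolog pairs
#' @export
setGeneric("truthPairs", function(x) standardGeneric("truthPairs"))

#' @describeIn SimulatedPolyploid-accessors coding sequences
#' @export
setGeneric("cdsSet", function(x) standardGeneric("cdsSet"))

#' @describeIn SimulatedPolyploid-accessors ancestral diploid gene set
#' @export
setGeneric("ancestralCds", function(x) standardGeneric("ancestralCds"))

#' @describeIn SimulatedPolyploid-accessors LTR element truth records
#' @export
setGeneric("ltrElements", function(x) standardGeneric("ltrElements"))

#' @describeIn SimulatedPolyploid-accessors paired terminal repeat sequences
#' @export
setGeneric("ltrSequences", function(x) standardGeneric("ltrSequences"))

#' @describeIn SimulatedPolyploid-accessors satellite array truth table
#' @export
setGeneric("satelliteArrays", function(x) standardGeneric("satelliteArrays"))

#' @describeIn SimulatedPolyploid-accessors per-chromosome monomer copies
#' @export
setGeneric("satelliteMonomers", function(x)
  standardGeneric("satelliteMonomers"))

#' @describeIn SimulatedPolyploid-accessors atlas count matrix
#' @export
setGeneric("atlasCounts", function(x) standardGeneric("atlasCounts"))

#' @describeIn SimulatedPolyploid-accessors atlas sample sheet
#' @export
setGeneric("atlasSamples", function(x) standardGeneric("atlasSamples"))

#' @describeIn SimulatedPolyploid-accessors per-pair atlas truth
#' @export
setGeneric("atlasTruth", function(x) standardGeneric("atlasTruth"))

#' @describeIn SimulatedPolyploid-accessors the generating configuration
#' @export
setGeneric("simulationConfig", function(x)
  standardGeneric("simulationConfig"))

#' Accessors for SimulatedPolyploid objects
#'
#' @param x a [SimulatedPolyploid-class].
#' @name SimulatedPolyploid-accessors
#' @aliases truthGenes truthPairs cdsSet ancestralCds ltrElements
#'   ltrSequences satelliteArrays satelliteMonomers atlasCounts atlasSamples
#'   atlasTruth simulationConfig
NULL

setMethod("truthGenes", "SimulatedPolyploid", function(x) x@genes)

setMethod("truthPairs", "SimulatedPolyploid", function(x) {
  g <- x@genes[!x@genes$is_tandem_copy & !is.na(x@genes$pair_id), ]
  a <- g[g$subgenome == "A" & g$status == "retained", ]
  b <- g[g$subgenome == "B" & g$status == "retained", ]
  common <- intersect(a$pair_id, b$pair_id)
  a <- a[match(common, a$pair_id), ]
  b <- b[match(common, b$pair_id), ]
  data.frame(pair_id = common,
             gene_a = a$gene_id, gene_b = b$gene_id,
             chromosome_a = a$chromosome, chromosome_b = b$chromosome,
             rank_a = a$rank, rank_b = b$rank,
             stringsAsFactors = FALSE)
})

setMethod("cdsSet", "SimulatedPolyploid", function(x) x@cds)
setMethod("ancestralCds", "SimulatedPolyploid", function(x) x@ancestral_cds)
setMethod("ltrElements", "SimulatedPolyploid", function(x) x@ltr_elements)
setMethod("ltrSequences", "SimulatedPolyploid", function(x) x@ltr_seqs)
setMethod("satelliteArrays", "SimulatedPolyploid",
          function(x) x@satellites$arrays)
setMethod("satelliteMonomers", "SimulatedPolyploid",
          function(x) x@satellites$monomers)
setMethod("atlasCounts", "SimulatedPolyploid", function(x) x@atlas$counts)
setMethod("atlasSamples", "SimulatedPolyploid", function(x) x@atlas$samples)
setMethod("atlasTruth", "SimulatedPolyploid", function(x) x@atlas$truth)
setMethod("simulationConfig", "SimulatedPolyploid", function(x) x@config)

setMethod("show", "SimulatedPolyploid", function(object) {
  g <- object@genes
  cat("SimulatedPolyploid\n")
  cat(sprintf("  %d chromosomes, %d gene records (%d retained, %d pseudogene, %d lost)\n",
              length(unique(g$chromosome)), nrow(g),
              sum(g$status == "retained"), sum(g$status == "pseudogene"),
              sum(g$status == "lost")))
  cat(sprintf("  %d surviving homoeolog pairs\n", nrow(truthPairs(object))))
  if (nrow(object@ltr_elements))
    cat(sprintf("  %d LTR elements in %d families\n",
                nrow(object@ltr_elements),
                length(unique(object@ltr_elements$family))))
  if (length(object@satellites))
    cat(sprintf("  satellite arrays on %d chromosomes (monomer %d bp)\n",
                nrow(object@satellites$arrays),
                object@satellites$arrays$monomer_length[1]))
  if (length(object@atlas))
    cat(sprintf("  atlas: %d genes x %d samples\n",
                nrow(object@atlas$counts), ncol(object@atlas$counts)))
  invisible(NULL)
})

setMethod("show", "PhasingResult", function(object) {
  cat("PhasingResult\n")
  tab <- table(object@assignments)
  cat(sprintf("  %d chromosomes -> clades A (n=%d) / B (n=%d)\n",
              length(object@assignments), tab[["A"]], tab[["B"]]))
  cat(sprintf("  bootstrap support: %s\n",
              paste(sprintf("%.2f", object@support), collapse = " / ")))
  d <- object@diagnostics
  if (!is.null(d$within_mean))
    cat(sprintf("  mean distance within %.4f, between %.4f\n",
                d$within_mean, d$between_mean))
  invisible(NULL)
})
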