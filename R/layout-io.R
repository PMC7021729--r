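# Deterministic genome layout and plain-text exports.
#
# Chromosome coordinates are assigned in one pass: a 500-bp leading spacer,
# genes in rank order separated by 300-bp spacers, the satellite array
# inserted after the middle gene, and LTR elements (5' LTR + 200-bp internal
# + 3' LTR) inserted after randomly chosen genes (layout RNG stream).
# GFF3 output is 1-based inclusive; BED output is 0-based half-open.

.SPACER_LEAD <- 500L
.SPACER_GENE <- 300L
.LTR_INTERNAL <- 200L

# per-chromosome ordered segment table with widths; sequences filled lazily
layoutGenome <- function(sp) {
  config <- sp@config
  stageSeed(config, "layout")
  genes <- sp@genes[sp@genes$status != "lost", ]
  chroms <- sort(unique(sp@genes$chromosome))
  has_ltr <- nrow(sp@ltr_elements) > 0L
  has_sat <- length(sp@satellites) > 0L

  gene_rows <- list()
  ltr_rows <- list()
  sat_rows <- list()
  seqs <- setNames(vector("list", length(chroms)), chroms)

  for (chr in chroms) {
    g <- genes[genes$chromosome == chr, ]
    g <- g[order(g$rank), ]
    n <- nrow(g)
    ltr_here <- if (has_ltr) {
      e <- sp@ltr_elements[sp@ltr_elements$chromosome == chr, ]
      if (nrow(e)) e$after_gene <- sample.int(max(n, 1L), nrow(e),
                                             replace = TRUE)
      e
    } else NULL
    sat_after <- max(n %/% 2L, 1L)

    pos <- .SPACER_LEAD + 1L          # 1-based start of next feature
    parts <- list(strrep("N", .SPACER_LEAD))
    for (i in seq_len(n)) {
      w <- if (g$status[i] == "retained")
        nchar(as.character(sp@cds[[g$gene_id[i]]]))
      else 3L * config@codons_per_gene
      gene_rows[[length(gene_rows) + 1L]] <- data.frame(
        gene_id = g$gene_id[i], chromosome = chr, start = pos,
        end = pos + w - 1L, strand = g$strand[i], status = g$status[i],
        stringsAsFactors = FALSE)
      parts[[length(parts) + 1L]] <-
        if (g$status[i] == "retained") as.character(sp@cds[[g$gene_id[i]]])
        else strrep("N", w)
      pos <- pos + w
      parts[[length(parts) + 1L]] <- strrep("N", .SPACER_GENE)
      pos <- pos + .SPACER_GENE

      if (has_sat && i == sat_after) {
        copies <- as.character(sp@satellites$monomers[[chr]])
        w_s <- sum(nchar(copies))
        sat_rows[[length(sat_rows) + 1L]] <- data.frame(
          chromosome = chr, start0 = pos - 1L, end0 = pos - 1L + w_s,
          clade = sp@satellites$arrays$clade[
            sp@satellites$arrays$chromosome == chr],
          copy_number = length(copies), stringsAsFactors = FALSE)
        parts[[length(parts) + 1L]] <- paste0(copies, collapse = "")
        pos <- pos + w_s
        parts[[length(parts) + 1L]] <- strrep("N", .SPACER_GENE)
        pos <- pos + .SPACER_GENE
      }
      if (!is.null(ltr_here) && nrow(ltr_here)) {
        for (k in which(ltr_here$after_gene == i)) {
          id <- ltr_here$element_id[k]
          l5 <- as.character(sp@ltr_seqs[[paste0(id, "_5p")]])
          l3 <- as.character(sp@ltr_seqs[[paste0(id, "_3p")]])
          internal <- strrep("N", .LTR_INTERNAL)
          w_e <- nchar(l5) + .LTR_INTERNAL + nchar(l3)
          ltr_rows[[length(ltr_rows) + 1L]] <- data.frame(
            element_id = id, family = ltr_here$family[k], chromosome = chr,
            start = pos, end = pos + w_e - 1L,
            subgenome = ltr_here$subgenome[k], age = ltr_here$age[k],
            stringsAsFactors = FALSE)
          parts[[length(parts) + 1L]] <- paste0(l5, internal, l3)
          pos <- pos + w_e
          parts[[length(parts) + 1L]] <- strrep("N", .SPACER_GENE)
          pos <- pos + .SPACER_GENE
        }
      }
    }
    seqs[[chr]] <- paste0(unlist(parts), collapse = "")
  }
  list(genes = do.call(rbind, gene_rows),
       ltr = if (length(ltr_rows)) do.call(rbind, ltr_rows) else NULL,
       satellites = if (length(sat_rows)) do.call(rbind, sat_rows) else NULL,
       sequences = seqs)
}

#' Assemble chromosome sequences of a simulated polyploid
#'
#' @param sp a [SimulatedPolyploid-class].
#' @return named [Biostrings::DNAStringSet] (intergenic space is N-padded).
#' @export
chromosomeSequences <- function(sp) {
  lay <- layoutGenome(sp)
  Biostrings::DNAStringSet(unlist(lay$sequences))
}

#' Write a simulated polyploid to plain-text files
#'
#' Emits genome FASTA, gene and TE GFF3 (truth labels in \code{truth_*}
#' attributes), satellite BED, CDS FASTA, paired-LTR FASTA, expression
#' counts and sample sheet TSV, truth tables TSV, and a JSON configuration
#' snapshot.
#'
#' @param sp a [SimulatedPolyploid-class].
#' @param outdir output directory (created if missing).
#' @return invisibly, the named vector of written paths.
#' @export
writeSimulatedPolyploid <- function(sp, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  lay <- layoutGenome(sp)
  paths <- c()
  wp <- function(name) {
    p <- file.path(outdir, name)
    paths[[name]] <<- p
    p
  }

  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(unlist(lay$sequences)), wp("genome.fa"))
  Biostrings::writeXStringSet(sp@cds, wp("cds.fa"))
  if (length(sp@ltr_seqs))
    Biostrings::writeXStringSet(sp@ltr_seqs, wp("ltr_pairs.fa"))

  g <- lay$genes
  truth <- sp@genes[match(g$gene_id, sp@genes$gene_id), ]
  gr <- GenomicRanges::GRanges(g$chromosome,
                               IRanges::IRanges(g$start, g$end),
                               strand = g$strand)
  mcols(gr) <- S4Vectors::DataFrame(
    source = "polysub_sim",
    type = ifelse(g$status == "pseudogene", "pseudogene", "gene"),
    ID = g$gene_id, truth_subgenome = truth$subgenome,
    truth_pair = truth$pair_id, truth_status = truth$status)
  rtracklayer::export(gr, wp("genes.gff3"), format = "gff3")

  if (!is.null(lay$ltr)) {
    e <- lay$ltr
    gr_e <- GenomicRanges::GRanges(e$chromosome,
                                   IRanges::IRanges(e$start, e$end))
    mcols(gr_e) <- S4Vectors::DataFrame(
      source = "polysub_sim", type = "LTR_retrotransposon",
      ID = e$element_id, family = e$family,
      truth_subgenome = e$subgenome, truth_age = e$age)
    rtracklayer::export(gr_e, wp("ltr.gff3"), format = "gff3")
  }

  if (!is.null(lay$satellites)) {
    s <- lay$satellites
    write.table(
      data.frame(s$chromosome, s$start0, s$end0,
                 paste0("SatT_", s$clade), s$copy_number, "+"),
      wp("satellites.bed"), sep = "\t", quote = FALSE,
      row.names = FALSE, col.names = FALSE)
  }

  if (length(sp@atlas)) {
    cm <- data.frame(gene_id = rownames(sp@atlas$counts), sp@atlas$counts,
                     check.names = FALSE)
    write.table(cm, wp("counts.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    write.table(sp@atlas$samples, wp("samples.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(sp@atlas$truth, wp("truth_atlas.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  write.table(sp@genes, wp("truth_genes.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  if (nrow(sp@ltr_elements))
    write.table(sp@ltr_elements, wp("truth_ltr.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)

  cfg <- sp@config
  snap <- list(seed = cfg@seed, n_chromosome_pairs = cfg@n_chromosome_pairs,
               genes_per_chromosome = cfg@genes_per_chromosome,
               codons_per_gene = cfg@codons_per_gene,
               t_divergence = cfg@t_divergence, t_merger = cfg@t_merger,
               mu_neutral = cfg@mu_neutral, mu_ltr = cfg@mu_ltr,
               ka_ks_true = cfg@ka_ks_true,
               satellite_monomer_length = cfg@satellite_monomer_length,
               atlas = cfg@atlas)
  jsonlite::write_json(snap, wp("config.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(unlist(paths))
}
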