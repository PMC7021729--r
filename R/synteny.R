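# Homology search, collinear chaining, tandem arrays, retention and
# fractionation.

#' K-mer seeded homology search with C-score filtering
#'
#' Candidate gene pairs share at least \code{min_shared} frame-aligned
#' k-mers; candidates are scored by local alignment (match 1, mismatch -1,
#' gap open 4, gap extend 1).  The C-score of a pair is its score divided by
#' the best score either gene attains against the other gene set, so a
#' cutoff near 1 retains reciprocal-best (recent homoeolog) pairs and
#' discards older whole-genome-duplication paralogs.
#'
#' @param cds_a,cds_b named [Biostrings::DNAStringSet] gene sets.
#' @param cscore retain pairs with C-score >= this value (0 keeps all hits).
#' @param k,min_shared k-mer length and minimum shared k-mer count for a
#'   candidate (k-mers are taken every 3 bp to stay frame-aligned).
#' @param self set \code{TRUE} for a within-genome search (tandem arrays):
#'   self hits are dropped and each unordered pair is reported once.
#' @return data.frame: \code{gene_a}, \code{gene_b}, \code{shared_kmers},
#'   \code{score}, \code{cscore}.
#' @export
findHomologyPairs <- function(cds_a, cds_b, cscore = 0.99, k = 12L,
                              min_shared = 5L, self = FALSE) {
  if (!length(cds_a) || !length(cds_b)) stop("empty input gene set")
  if (is.null(names(cds_a)) || is.null(names(cds_b)))
    stop("gene sets must be named")

  kmerTable <- function(x) {
    ch <- as.character(x)
    rows <- lapply(seq_along(ch), function(i) {
      s <- ch[i]
      starts <- seq(1L, nchar(s) - k + 1L, by = 3L)
      unique(substring(s, starts, starts + k - 1L))
    })
    data.frame(kmer = unlist(rows),
               gene = rep(names(x), lengths(rows)),
               stringsAsFactors = FALSE)
  }
  ta <- kmerTable(cds_a)
  tb <- kmerTable(cds_b)
  m <- merge(ta, tb, by = "kmer")
  if (!nrow(m))
    return(data.frame(gene_a = character(), gene_b = character(),
                      shared_kmers = integer(), score = numeric(),
                      cscore = numeric()))
  key <- paste(m$gene.x, m$gene.y, sep = "\r")
  cnt <- table(key)
  cand <- do.call(rbind, strsplit(names(cnt[cnt >= min_shared]), "\r",
                                  fixed = TRUE))
  shared <- as.integer(cnt[cnt >= min_shared])
  keep <- rep(TRUE, nrow(cand))
  if (self) keep <- cand[, 1] < cand[, 2]   # drop self hits + mirror dups
  cand <- cand[keep, , drop = FALSE]
  shared <- shared[keep]
  if (!nrow(cand))
    return(data.frame(gene_a = character(), gene_b = character(),
                      shared_kmers = integer(), score = numeric(),
                      cscore = numeric()))

  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1)
  score <- vapply(seq_len(nrow(cand)), function(i)
    Biostrings::pairwiseAlignment(cds_a[[cand[i, 1]]], cds_b[[cand[i, 2]]],
                                  substitutionMatrix = mat, gapOpening = 4,
                                  gapExtension = 1, type = "local",
                                  scoreOnly = TRUE),
    numeric(1))
  best_a <- tapply(score, cand[, 1], max)
  best_b <- tapply(score, cand[, 2], max)
  if (self) {
    # within one genome, "best score of gene g" spans both hit columns
    genes <- unique(c(cand[, 1], cand[, 2]))
    best <- setNames(numeric(length(genes)), genes)
    for (g in genes)
      best[g] <- max(score[cand[, 1] == g | cand[, 2] == g])
    best_a <- best
    best_b <- best
  }
  cs <- score / pmax(best_a[cand[, 1]], best_b[cand[, 2]])
  out <- data.frame(gene_a = cand[, 1], gene_b = cand[, 2],
                    shared_kmers = shared, score = score, cscore = cs,
                    stringsAsFactors = FALSE)
  out <- out[out$cscore >= cscore, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Chain homology anchors into collinear blocks
#'
#' Dynamic programming over the anchor dot-plot of every chromosome pair:
#' the highest-scoring strictly monotone chain (ascending or descending on
#' the second genome, rank gaps at most \code{max_gap} on both axes) is
#' extracted, its anchors removed, and the process repeats until no chain of
#' at least \code{min_block} anchors remains.
#'
#' @param pairs data.frame with \code{gene_a}, \code{gene_b} (candidate
#'   homology pairs).
#' @param gene_orders data.frame with \code{gene_id}, \code{chromosome},
#'   \code{rank}.
#' @param min_block minimum anchors per reported block (default 5).
#' @param max_gap maximum rank gap between consecutive anchors (default 25).
#' @return list with \code{blocks} (one row per block: \code{block_id},
#'   \code{chr_a}, \code{chr_b}, \code{orientation}, \code{n_anchors}) and
#'   \code{anchors} (per anchor: genes, ranks, \code{block_id}).
#' @export
chainBlocks <- function(pairs, gene_orders, min_block = 5L, max_gap = 25L) {
  ix_a <- match(pairs$gene_a, gene_orders$gene_id)
  ix_b <- match(pairs$gene_b, gene_orders$gene_id)
  ok <- !is.na(ix_a) & !is.na(ix_b)
  anc <- data.frame(
    gene_a = pairs$gene_a[ok], gene_b = pairs$gene_b[ok],
    chr_a = gene_orders$chromosome[ix_a[ok]],
    chr_b = gene_orders$chromosome[ix_b[ok]],
    ra = gene_orders$rank[ix_a[ok]], rb = gene_orders$rank[ix_b[ok]],
    stringsAsFactors = FALSE)
  if ("score" %in% names(pairs)) anc$score <- pairs$score[ok]

  blocks <- list()
  anchors_out <- list()
  bid <- 0L
  for (grp in split(anc, paste(anc$chr_a, anc$chr_b, sep = "\r"))) {
    grp <- grp[order(grp$ra, grp$rb), ]
    repeat {
      n <- nrow(grp)
      if (n < min_block) break
      ch <- .bestChain(grp$ra, grp$rb, max_gap)
      if (length(ch$idx) < min_block) break
      bid <- bid + 1L
      sel <- grp[ch$idx, ]
      sel$block_id <- bid
      anchors_out[[bid]] <- sel
      blocks[[bid]] <- data.frame(
        block_id = bid, chr_a = sel$chr_a[1], chr_b = sel$chr_b[1],
        orientation = if (ch$dir > 0) "same" else "inverted",
        n_anchors = nrow(sel), stringsAsFactors = FALSE)
      grp <- grp[-ch$idx, , drop = FALSE]
    }
  }
  if (!length(blocks))
    return(list(blocks = data.frame(block_id = integer(), chr_a = character(),
                                    chr_b = character(),
                                    orientation = character(),
                                    n_anchors = integer()),
                anchors = data.frame()))
  list(blocks = do.call(rbind, blocks),
       anchors = do.call(rbind, anchors_out))
}

# longest strictly monotone chain (both directions) with gap limit;
# O(n^2) DP, returns anchor indices and direction
.bestChain <- function(ra, rb, max_gap) {
  n <- length(ra)
  run <- function(dir) {
    len <- rep(1L, n)
    prev <- rep(0L, n)
    for (i in seq_len(n)) {
      for (j in seq_len(i - 1L)) {
        if (ra[i] <= ra[j]) next
        if (ra[i] - ra[j] > max_gap) next
        db <- dir * (rb[i] - rb[j])
        if (db <= 0 || db > max_gap) next
        if (len[j] + 1L > len[i]) {
          len[i] <- len[j] + 1L
          prev[i] <- j
        }
      }
    }
    i <- which.max(len)
    idx <- integer(0)
    while (i > 0L) {
      idx <- c(i, idx)
      i <- prev[i]
    }
    idx
  }
  up <- run(1L)
  dn <- run(-1L)
  if (length(up) >= length(dn)) list(idx = up, dir = 1L)
  else list(idx = dn, dir = -1L)
}

#' Resolve anchors to 1:1 homoeolog pairs
#'
#' Within chained blocks every gene may still take part in several anchors
#' (tandem copies); anchors are accepted greedily by descending alignment
#' score (ties to the smaller rank) with each gene used once.
#'
#' @param chain result of [chainBlocks()].
#' @return data.frame of pairs: \code{gene_a}, \code{gene_b},
#'   \code{chr_a}, \code{chr_b}, \code{rank_a}, \code{rank_b},
#'   \code{block_id}.
#' @export
resolveHomoeologPairs <- function(chain) {
  a <- chain$anchors
  if (!nrow(a))
    return(data.frame(gene_a = character(), gene_b = character(),
                      chr_a = character(), chr_b = character(),
                      rank_a = integer(), rank_b = integer(),
                      block_id = integer()))
  ord <- if ("score" %in% names(a))
    order(-a$score, a$ra, a$rb) else order(a$ra, a$rb)
  a <- a[ord, ]
  used_a <- character(0)
  used_b <- character(0)
  keep <- logical(nrow(a))
  for (i in seq_len(nrow(a))) {
    if (a$gene_a[i] %in% used_a || a$gene_b[i] %in% used_b) next
    keep[i] <- TRUE
    used_a <- c(used_a, a$gene_a[i])
    used_b <- c(used_b, a$gene_b[i])
  }
  out <- a[keep, c("gene_a", "gene_b", "chr_a", "chr_b", "ra", "rb",
                   "block_id")]
  names(out)[5:6] <- c("rank_a", "rank_b")
  out <- out[order(out$chr_a, out$rank_a), ]
  rownames(out) <- NULL
  out
}

#' Syntenic depth of a reference gene set
#'
#' For every reference gene, counts the number of distinct blocks in which
#' it is anchored; a diploid reference seen from an intact tetraploid sits
#' at depth 2, and a gene whose ortholog was fractionated from one
#' subgenome drops to depth 1.
#'
#' @param chain result of [chainBlocks()] computed with the reference genome
#'   on the \code{gene_a} side.
#' @param ref_orders data.frame with \code{gene_id}, \code{chromosome},
#'   \code{rank} for the reference gene set.
#' @return list: \code{depth} (per gene), \code{histogram} (depth counts,
#'   summing to the reference gene count), \code{modal_depth}.
#' @export
syntenicDepth <- function(chain, ref_orders) {
  depth <- setNames(integer(nrow(ref_orders)), ref_orders$gene_id)
  a <- chain$anchors
  if (nrow(a)) {
    tab <- table(a$gene_a[!duplicated(paste(a$gene_a, a$block_id))])
    hit <- intersect(names(tab), names(depth))
    depth[hit] <- as.integer(tab[hit])
  }
  hist <- table(factor(depth, levels = 0:max(c(depth, 2L))))
  list(depth = depth, histogram = hist,
       modal_depth = as.integer(names(hist)[which.max(hist)]))
}

#' Tandem gene arrays from within-genome hits
#'
#' Single-linkage clustering of within-chromosome homology hits whose gene
#' rank distance is at most \code{max_gene_distance}.
#'
#' @param hits data.frame with \code{gene_a}, \code{gene_b} (within-genome
#'   hits, e.g. [findHomologyPairs()] with \code{self = TRUE} and
#'   \code{cscore = 0}).
#' @param gene_orders data.frame with \code{gene_id}, \code{chromosome},
#'   \code{rank}.
#' @param max_gene_distance maximum rank distance clustered (default 10).
#' @return data.frame: \code{array_id}, \code{chromosome}, \code{size},
#'   \code{genes} (comma-joined ids).
#' @export
tandemGeneArrays <- function(hits, gene_orders, max_gene_distance = 10L) {
  ix_a <- match(hits$gene_a, gene_orders$gene_id)
  ix_b <- match(hits$gene_b, gene_orders$gene_id)
  ok <- !is.na(ix_a) & !is.na(ix_b) &
    gene_orders$chromosome[ix_a] == gene_orders$chromosome[ix_b] &
    abs(gene_orders$rank[ix_a] - gene_orders$rank[ix_b]) > 0 &
    abs(gene_orders$rank[ix_a] - gene_orders$rank[ix_b]) <= max_gene_distance
  if (!any(ok))
    return(data.frame(array_id = integer(), chromosome = character(),
                      size = integer(), genes = character()))
  g <- igraph::graph_from_data_frame(
    data.frame(from = hits$gene_a[ok], to = hits$gene_b[ok]),
    directed = FALSE)
  comp <- igraph::components(g)
  rows <- lapply(seq_len(comp$no), function(i) {
    genes <- sort(names(comp$membership)[comp$membership == i])
    data.frame(
      array_id = i,
      chromosome = gene_orders$chromosome[match(genes[1],
                                                gene_orders$gene_id)],
      size = length(genes), genes = paste(genes, collapse = ","),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Classify gene retention after polyploidy
#'
#' Each gene is labeled \code{"pair"} (in a resolved homoeolog pair),
#' \code{"gene+pseudogene"} (its partner survives only as a pseudogene), or
#' \code{"single"}.
#'
#' @param pairs resolved pairs ([resolveHomoeologPairs()] or any data.frame
#'   with \code{gene_a}, \code{gene_b}).
#' @param genes character vector of all gene ids to classify.
#' @param pseudogene_partnered character vector of gene ids whose homoeolog
#'   partner is annotated as a pseudogene.
#' @return list: \code{classes} (named character), \code{summary} with
#'   counts and \code{fraction_retained} = (paired + pseudogene-partnered) /
#'   total.
#' @export
classifyRetention <- function(pairs, genes, pseudogene_partnered = character()) {
  paired <- unique(c(pairs$gene_a, pairs$gene_b))
  paired <- intersect(paired, genes)
  pseudo <- intersect(pseudogene_partnered, genes)
  clash <- intersect(paired, pseudo)
  if (length(clash))
    stop("genes both paired and pseudogene-partnered: ",
         paste(head(clash, 5), collapse = ", "))
  cls <- setNames(rep("single", length(genes)), genes)
  cls[paired] <- "pair"
  cls[pseudo] <- "gene+pseudogene"
  n <- length(genes)
  list(classes = cls,
       summary = list(
         n_genes = n, n_pair = sum(cls == "pair"),
         n_gene_pseudogene = sum(cls == "gene+pseudogene"),
         n_single = sum(cls == "single"),
         fraction_retained = (sum(cls == "pair") +
                                sum(cls == "gene+pseudogene")) / n))
}

#' Exact binomial test for biased fractionation
#'
#' Tests whether post-polyploidy gene losses are split evenly between the
#' two subgenomes (two-sided, null probability 0.5).
#'
#' @param losses_a,losses_b gene-loss counts for the A and B subgenomes.
#' @return list: the counts, \code{p} (two-sided exact binomial),
#'   \code{biased} at the 0.05 level, \code{defined}.
#' @examples
#' testBiasedFractionation(647, 678)$p   # ~0.41, no bias
#' @export
testBiasedFractionation <- function(losses_a, losses_b) {
  if (losses_a < 0 || losses_b < 0) stop("counts must be >= 0")
  if (losses_a + losses_b == 0)
    return(list(losses_a = 0L, losses_b = 0L, p = NA_real_,
                biased = NA, defined = FALSE))
  p <- binom.test(losses_a, losses_a + losses_b, 0.5)$p.value
  list(losses_a = losses_a, losses_b = losses_b, p = p,
       biased = p < 0.05, defined = TRUE)
}
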