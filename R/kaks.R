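#' Codon-aware alignment of two coding sequences
#'
#' Globally aligns the two translated proteins (BLOSUM62, affine gaps) and
#' threads the alignment back onto codons.  Columns containing a gap are
#' excluded from downstream substitution counting.
#'
#' @param cds_a,cds_b coding sequences (character or
#'   [Biostrings::DNAString]), lengths multiples of 3, no internal stops.
#' @return list with integer codon-index vectors \code{codons_a},
#'   \code{codons_b} (gap-free columns only) and \code{n_gap_columns}.
#' @export
alignCodons <- function(cds_a, cds_b) {
  a <- as.character(cds_a)
  b <- as.character(cds_b)
  ca <- stringToCodons(a)
  cb <- stringToCodons(b)
  tab <- codonTables()
  if (any(tab$is_stop[ca[-length(ca)]]) || any(tab$is_stop[cb[-length(cb)]]))
    stop("internal stop codon in coding sequence")
  ca <- ca[!tab$is_stop[ca]]
  cb <- cb[!tab$is_stop[cb]]

  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(paste0(tab$aa[ca], collapse = "")),
    Biostrings::AAString(paste0(tab$aa[cb], collapse = "")),
    substitutionMatrix = "BLOSUM62", gapOpening = 10, gapExtension = 0.5,
    type = "global")
  pat <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  sub <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  gap <- pat == "-" | sub == "-"
  if (mean(gap) > 0.5) stop("alignment is more than 50% gaps; pair skipped")
  ia <- cumsum(pat != "-")
  ib <- cumsum(sub != "-")
  keep <- !gap
  list(codons_a = ca[ia[keep]], codons_b = cb[ib[keep]],
       n_gap_columns = sum(gap))
}

#' Nei-Gojobori (1986) Ka/Ks for one aligned codon pair
#'
#' Synonymous site counts are the per-codon fraction of single-nucleotide
#' changes that preserve the amino acid (averaged over the two sequences);
#' differences between codons are averaged over all substitution pathways
#' that avoid stop codons.  The proportions are Jukes-Cantor corrected,
#' \code{d = -3/4 log(1 - 4p/3)}.
#'
#' @param x either the result of [alignCodons()] or a coding sequence
#'   (then \code{y} must be the second sequence and the two are paired
#'   positionally).
#' @param y optional second coding sequence.
#' @param min_codons minimum ungapped codon columns (default 30).
#' @return one-row data.frame: \code{S}, \code{N}, \code{Sd}, \code{Nd},
#'   \code{ps}, \code{pn}, \code{Ks}, \code{Ka}, \code{omega},
#'   \code{saturated}.  \code{omega} is \code{NA} when \code{Ks} is 0 or the
#'   pair is saturated (\code{ps} or \code{pn} >= 0.75).
#' @examples
#' ng86("ATGAAACCCGGG", "ATGAAACCAGGG")
#' @export
ng86 <- function(x, y = NULL, min_codons = 30L) {
  if (!is.null(y)) {
    ca <- stringToCodons(as.character(x))
    cb <- stringToCodons(as.character(y))
    if (length(ca) != length(cb))
      stop("positional pairing requires equal lengths; use alignCodons()")
    tab0 <- codonTables()
    keep <- !tab0$is_stop[ca] & !tab0$is_stop[cb]
    ca <- ca[keep]; cb <- cb[keep]
  } else {
    ca <- x$codons_a
    cb <- x$codons_b
  }
  if (length(ca) < min_codons)
    stop("fewer than ", min_codons, " ungapped codon columns")
  tab <- codonTables()
  S <- (sum(tab$syn_sites[ca]) + sum(tab$syn_sites[cb])) / 2
  N <- 3 * length(ca) - S
  Sd <- sum(tab$sd_tab[cbind(ca, cb)])
  Nd <- sum(tab$nd_tab[cbind(ca, cb)])
  ps <- Sd / S
  pn <- Nd / N
  saturated <- ps >= 0.75 || pn >= 0.75
  jc <- function(p) if (p >= 0.75) NA_real_ else -0.75 * log(1 - 4 * p / 3)
  Ks <- jc(ps)
  Ka <- jc(pn)
  omega <- if (saturated || is.na(Ks) || Ks == 0) NA_real_ else Ka / Ks
  data.frame(S = S, N = N, Sd = Sd, Nd = Nd, ps = ps, pn = pn,
             Ks = Ks, Ka = Ka, omega = omega, saturated = saturated)
}

#' Ka/Ks for a table of gene pairs
#'
#' @param pairs data.frame with columns \code{gene_a}, \code{gene_b} (and
#'   optionally \code{pair_id}).
#' @param cds named [Biostrings::DNAStringSet] holding both gene sets.
#' @param align align proteins first ([alignCodons()]); with \code{FALSE},
#'   equal-length pairs are compared positionally (our simulator introduces
#'   no indels, and this is several-fold faster).
#' @return \code{pairs} with the [ng86()] columns appended; pairs that fail
#'   alignment or length checks get NA values and a \code{note}.
#' @export
kaKs <- function(pairs, cds, align = TRUE) {
  stopifnot(all(c("gene_a", "gene_b") %in% names(pairs)))
  res <- vector("list", nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    res[[i]] <- tryCatch({
      a <- cds[[pairs$gene_a[i]]]
      b <- cds[[pairs$gene_b[i]]]
      st <- if (align) ng86(alignCodons(a, b))
            else ng86(as.character(a), as.character(b))
      st$note <- NA_character_
      st
    }, error = function(e) {
      data.frame(S = NA_real_, N = NA_real_, Sd = NA_real_, Nd = NA_real_,
                 ps = NA_real_, pn = NA_real_, Ks = NA_real_, Ka = NA_real_,
                 omega = NA_real_, saturated = NA, note = conditionMessage(e))
    })
  }
  cbind(pairs, do.call(rbind, res))
}

#' Convert synonymous divergence to time
#'
#' \code{T = Ks / (2 * mu)}: divergence accumulates along both lineages.
#' With the grass synonymous rate 1.5e-8 per site per year, the observed
#' homoeolog Ks median of 0.15 converts to a progenitor divergence of 5 Myr.
#'
#' @param ks synonymous substitutions per synonymous site (>= 0).
#' @param mu substitutions per site per year (> 0).
#' @return years.
#' @examples
#' ksToTime(0.15)            # 5e6
#' @export
ksToTime <- function(ks, mu = 1.5e-8) {
  if (any(mu <= 0)) stop("mu must be > 0")
  if (any(ks < 0, na.rm = TRUE)) stop("ks must be >= 0")
  ks / (2 * mu)
}

#' Summarise a Ks distribution
#'
#' @param ks numeric vector of per-pair Ks values (NAs dropped).
#' @param breaks histogram breaks (passed to [graphics::hist] semantics via
#'   [base::cut]); default 40 equal bins.
#' @param min_pairs minimum number of valid pairs (default 30).
#' @return list: \code{median}, \code{n_peaks}, \code{peaks} (locations),
#'   \code{density}, \code{histogram} data.frame.
#' @export
ksDistribution <- function(ks, breaks = 40L, min_pairs = 30L) {
  ks <- ks[is.finite(ks)]
  if (length(ks) < min_pairs)
    stop("need at least ", min_pairs, " valid pairs")
  if (sd(ks) == 0) {
    return(list(median = ks[1], n_peaks = 1L, peaks = ks[1], density = NULL,
                histogram = data.frame(mid = ks[1], count = length(ks))))
  }
  d <- density(ks, bw = "nrd0")  # Silverman's rule
  y <- d$y
  loc <- which(y > c(-Inf, y[-length(y)]) & y >= c(y[-1], -Inf) &
                 y > 0.1 * max(y))
  h <- hist(ks, breaks = breaks, plot = FALSE)
  list(median = median(ks), n_peaks = length(loc), peaks = d$x[loc],
       density = d,
       histogram = data.frame(mid = h$mids, count = h$counts))
}

#' Windowed-Ks scan for homoeologous exchange
#'
#' Recent replacement of one homoeologous segment by the other erases
#' divergence locally, so windows whose median Ks falls below
#' \code{threshold_fraction} of the genome-wide median are flagged as
#' candidate exchanges.
#'
#' @param pairs data.frame with \code{chromosome} (the A-side chromosome or
#'   any per-chromosome grouping), \code{rank} (gene order) and \code{Ks}.
#' @param window,step window size and step in genes.
#' @param threshold_fraction flag windows below this fraction of the genome
#'   median.
#' @return data.frame of windows: \code{chromosome}, \code{start_rank},
#'   \code{end_rank}, \code{n}, \code{median_ks}, \code{genome_median},
#'   \code{flagged}.
#' @export
scanHomoeologousExchange <- function(pairs, window = 50L, step = 25L,
                                     threshold_fraction = 0.5) {
  stopifnot(all(c("chromosome", "rank", "Ks") %in% names(pairs)))
  pairs <- pairs[is.finite(pairs$Ks), ]
  gm <- median(pairs$Ks)
  out <- list()
  for (chr in unique(pairs$chromosome)) {
    p <- pairs[pairs$chromosome == chr, ]
    p <- p[order(p$rank), ]
    n <- nrow(p)
    if (n < window) {
      warning("chromosome ", chr, " has fewer pairs (", n,
              ") than one window; using a single window")
      starts <- 1L
      win <- n
    } else {
      starts <- seq(1L, n - window + 1L, by = step)
      win <- window
    }
    md <- vapply(starts, function(s) median(p$Ks[s:(s + win - 1L)]),
                 numeric(1))
    out[[chr]] <- data.frame(
      chromosome = chr,
      start_rank = p$rank[starts],
      end_rank = p$rank[pmin(starts + win - 1L, n)],
      n = win, median_ks = md, genome_median = gm,
      flagged = md < threshold_fraction * gm,
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
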