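# Homoeolog expression bias: normalization, NB Wald testing, bias
# classification, dominance consistency, and the Ka/Ks-by-bias comparison.

#' Median-of-ratios library size factors
#'
#' @param counts genes x samples integer matrix.
#' @return numeric vector of size factors (geometric-mean reference,
#'   per-sample median ratio), normalised to geometric mean 1.
#' @export
sizeFactorsMOR <- function(counts) {
  lg <- log(counts)
  ref <- rowMeans(lg)
  use <- is.finite(ref)
  if (!any(use)) stop("no gene has positive counts in every sample")
  sf <- apply(counts[use, , drop = FALSE], 2L,
              function(x) exp(median(log(x) - ref[use], na.rm = TRUE)))
  sf / exp(mean(log(sf)))
}

#' Homoeolog expression bias (signed log ratio)
#'
#' \code{log2((mean_a + pseudocount) / (mean_b + pseudocount))}: positive
#' values mean the A homoeolog is dominant, negative the B homoeolog.
#'
#' @param mean_a,mean_b normalized mean expression (>= 0).
#' @param pseudocount added to both means (default 1).
#' @return log2 ratio (antisymmetric in its arguments).
#' @examples
#' heb(30, 10)    # ~ +1.5, A-dominant
#' @export
heb <- function(mean_a, mean_b, pseudocount = 1) {
  if (any(mean_a < 0) || any(mean_b < 0)) stop("means must be >= 0")
  log2((mean_a + pseudocount) / (mean_b + pseudocount))
}

#' Negative-binomial Wald test for one homoeolog pair in one tissue
#'
#' Replicate counts of the two homoeologs are compared on the log scale:
#' the dispersion is a method-of-moments estimate pooled across the pair,
#' the standard error comes from the NB variance function
#' \code{Var = mu + alpha mu^2} by the delta method, and the two-sided
#' p-value uses a deliberately conservative t reference with
#' \code{n_a + n_b - 3} degrees of freedom: with no ensemble of genes to
#' borrow dispersion information from, the moment estimate is noisy at
#' typical replicate numbers and a normal reference is anticonservative
#' (the matrix-wide [hebTest()] pools dispersion across pairs instead).
#'
#' @param counts_a,counts_b replicate count vectors (>= 2 each), already
#'   normalized for library size (or raw with \code{size_factors} given).
#' @param size_factors optional per-replicate size factors, recycled to
#'   \code{c(counts_a, counts_b)}.
#' @param pseudocount added to group means for the log ratio.
#' @return list: \code{mean_a}, \code{mean_b}, \code{log2fc}, \code{wald},
#'   \code{p}, \code{dispersion}, \code{expressed}.
#' @export
testPairTissue <- function(counts_a, counts_b, size_factors = NULL,
                           pseudocount = 1) {
  na <- length(counts_a)
  nb <- length(counts_b)
  if (na < 2L || nb < 2L) stop("need >= 2 replicates per homoeolog")
  if (!is.null(size_factors)) {
    sf <- rep_len(size_factors, na + nb)
    counts_a <- counts_a / sf[seq_len(na)]
    counts_b <- counts_b / sf[na + seq_len(nb)]
  }
  ma <- mean(counts_a)
  mb <- mean(counts_b)
  if (ma == 0 && mb == 0)
    return(list(mean_a = 0, mean_b = 0, log2fc = NA_real_, wald = NA_real_,
                p = NA_real_, dispersion = NA_real_, expressed = FALSE))
  alphaOf <- function(x) {
    m <- mean(x)
    if (m <= 0) return(0)
    max((var(x) - m) / m^2, 0)
  }
  alpha <- mean(c(alphaOf(counts_a), alphaOf(counts_b)))
  delta <- log(ma + pseudocount) - log(mb + pseudocount)
  se2 <- (1 / (ma + pseudocount) + alpha) / na +
    (1 / (mb + pseudocount) + alpha) / nb
  w <- delta / sqrt(se2)
  p <- 2 * pt(-abs(w), df = max(na + nb - 3L, 1L))
  list(mean_a = ma, mean_b = mb, log2fc = delta / log(2), wald = w, p = p,
       dispersion = alpha, expressed = TRUE)
}

#' Expression-bias tests for all pairs in all tissues
#'
#' NB Wald tests across a counts matrix: median-of-ratios normalization
#' over the full matrix, then per pair and tissue a moment dispersion
#' floored at the tissue-wide mean of pair dispersions (information sharing
#' across the ensemble, in the spirit of common-dispersion estimation),
#' Wald statistic and two-sided normal p-value.
#'
#' @param counts genes x samples matrix.
#' @param samples data.frame with \code{sample}, \code{tissue}, \code{rep}
#'   (\code{sample} matching \code{colnames(counts)}).
#' @param pairs data.frame with \code{pair_id}, \code{gene_a},
#'   \code{gene_b}.
#' @param pseudocount for the log ratio (default 1).
#' @param expression_floor pairs with both normalized means below it are
#'   labeled not expressed and excluded from testing (default 1).
#' @return data.frame, one row per pair x tissue: means, \code{heb},
#'   \code{wald}, \code{p}, \code{expressed}.
#' @export
hebTest <- function(counts, samples, pairs, pseudocount = 1,
                    expression_floor = 1) {
  stopifnot(all(samples$sample %in% colnames(counts)))
  sf <- sizeFactorsMOR(counts)
  norm <- sweep(counts, 2L, sf, "/")
  ia <- match(pairs$gene_a, rownames(counts))
  ib <- match(pairs$gene_b, rownames(counts))
  if (anyNA(ia) || anyNA(ib)) stop("pair genes missing from counts matrix")
  out <- list()
  for (tis in unique(samples$tissue)) {
    cols <- samples$sample[samples$tissue == tis]
    nr <- length(cols)
    A <- norm[ia, cols, drop = FALSE]
    B <- norm[ib, cols, drop = FALSE]
    ma <- rowMeans(A)
    mb <- rowMeans(B)
    va <- apply(A, 1L, var)
    vb <- apply(B, 1L, var)
    aA <- (va - ma) / ma^2
    aB <- (vb - mb) / mb^2
    aA[!is.finite(aA)] <- 0
    aB[!is.finite(aB)] <- 0
    alpha <- (pmax(aA, 0) + pmax(aB, 0)) / 2
    alpha <- pmax(alpha, mean(alpha))   # common-dispersion floor
    delta <- log(ma + pseudocount) - log(mb + pseudocount)
    se2 <- (1 / (ma + pseudocount) + alpha) / nr +
      (1 / (mb + pseudocount) + alpha) / nr
    w <- delta / sqrt(se2)
    p <- 2 * pnorm(-abs(w))
    expressed <- !(ma < expression_floor & mb < expression_floor)
    p[!expressed] <- NA_real_
    out[[tis]] <- data.frame(
      pair_id = pairs$pair_id, tissue = tis, mean_a = ma, mean_b = mb,
      heb = delta / log(2), wald = w, p = p, expressed = expressed,
      stringsAsFactors = FALSE, row.names = NULL)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Classify per-tissue bias with FDR control
#'
#' Benjamini-Hochberg adjustment within each tissue (a global flag is
#' provided because analysis designs differ on this); significant records are
#' A- or B-biased by the sign of the log ratio, the rest balanced, and
#' pairs below the expression floor in a tissue stay \code{not_expressed}.
#'
#' @param records output of [hebTest()].
#' @param alpha FDR level (default 0.05).
#' @param per_tissue adjust within tissue (default) or globally.
#' @return \code{records} with \code{padj} and \code{bias_class} columns.
#' @export
classifyBias <- function(records, alpha = 0.05, per_tissue = TRUE) {
  records$padj <- NA_real_
  if (per_tissue) {
    for (tis in unique(records$tissue)) {
      sel <- records$tissue == tis & !is.na(records$p)
      records$padj[sel] <- p.adjust(records$p[sel], "BH")
    }
  } else {
    sel <- !is.na(records$p)
    records$padj[sel] <- p.adjust(records$p[sel], "BH")
  }
  records$bias_class <- ifelse(
    !records$expressed, "not_expressed",
    ifelse(!is.na(records$padj) & records$padj < alpha,
           ifelse(records$heb > 0, "A", "B"), "balanced"))
  records
}

#' Cross-tissue dominance consistency
#'
#' Pairs biased in at least one tissue are \code{consistent_A} /
#' \code{consistent_B} when every biased tissue agrees in sign, otherwise
#' \code{reversing}; pairs with no significant tissue are
#' \code{never_biased}.
#'
#' @param records classified records ([classifyBias()]).
#' @param pair_chromosomes optional named vector mapping \code{pair_id} to a
#'   chromosome-pair label, enabling per-chromosome summaries with a
#'   signed-rank test of median HEB against 0.
#' @return list: \code{pair_labels} (named), \code{shares} (consistent /
#'   reversing fractions among ever-biased pairs), \code{per_tissue} counts,
#'   optional \code{per_chromosome} table.
#' @export
dominanceConsistency <- function(records, pair_chromosomes = NULL) {
  if (length(unique(records$tissue)) < 2L)
    stop("need at least 2 tissues")
  spl <- split(records$bias_class, records$pair_id)
  lab <- vapply(spl, function(cl) {
    nA <- sum(cl == "A")
    nB <- sum(cl == "B")
    if (nA == 0 && nB == 0) "never_biased"
    else if (nA > 0 && nB > 0) "reversing"
    else if (nA > 0) "consistent_A" else "consistent_B"
  }, character(1))
  ever <- lab != "never_biased"
  shares <- list(
    consistent = if (any(ever)) mean(lab[ever] %in%
                                       c("consistent_A", "consistent_B"))
                 else NA_real_,
    reversing = if (any(ever)) mean(lab[ever] == "reversing") else NA_real_,
    ever_biased = mean(ever))
  per_tissue <- as.data.frame.matrix(
    table(records$tissue, factor(records$bias_class,
                                 levels = c("A", "B", "balanced",
                                            "not_expressed"))))
  out <- list(pair_labels = lab, shares = shares, per_tissue = per_tissue)
  if (!is.null(pair_chromosomes)) {
    chr <- pair_chromosomes[records$pair_id]
    grps <- split(records, chr)
    rows <- lapply(names(grps), function(nm) {
      r <- grps[[nm]]
      sig <- r$bias_class %in% c("A", "B")
      data.frame(
        chromosome = nm,
        n_biased = sum(sig),
        frac_B = if (any(sig)) mean(r$bias_class[sig] == "B") else NA_real_,
        wilcox_p = tryCatch(wilcox.test(r$heb[r$expressed])$p.value,
                            error = function(e) NA_real_),
        stringsAsFactors = FALSE)
    })
    out$per_chromosome <- do.call(rbind, rows)
    rownames(out$per_chromosome) <- NULL
  }
  out
}

#' Ka/Ks stratified by expression-bias strength
#'
#' Pairs are stratified by the number of tissues with significant bias:
#' none, all tissues, or intermediate; the extreme strata are compared by a
#' two-sided Mann-Whitney test on Ka/Ks (and on Ks, where no difference is
#' the expectation under uniform divergence).
#'
#' @param records classified records ([classifyBias()]).
#' @param omega named vector of Ka/Ks per \code{pair_id}.
#' @param ks optional named vector of Ks per \code{pair_id}.
#' @param min_n strata smaller than this are not compared (default 10).
#' @return list: \code{strata} (named), per-stratum medians, Mann-Whitney
#'   p-values \code{p_omega} (and \code{p_ks}).
#' @export
kaksByHeb <- function(records, omega, ks = NULL, min_n = 10L) {
  nt <- length(unique(records$tissue))
  spl <- split(records$bias_class %in% c("A", "B"), records$pair_id)
  nbias <- vapply(spl, sum, integer(1))
  stratum <- ifelse(nbias == 0L, "none",
                    ifelse(nbias == nt, "all", "intermediate"))
  om <- omega[names(stratum)]
  med <- tapply(om, stratum, median, na.rm = TRUE)
  res <- list(strata = stratum, median_omega = med)
  n_none <- sum(stratum == "none" & !is.na(om))
  n_all <- sum(stratum == "all" & !is.na(om))
  if (n_none >= min_n && n_all >= min_n) {
    res$p_omega <- wilcox.test(om[stratum == "none"],
                               om[stratum == "all"])$p.value
  } else {
    warning("stratum below ", min_n, " pairs; omega comparison skipped")
    res$p_omega <- NA_real_
  }
  if (!is.null(ks)) {
    kk <- ks[names(stratum)]
    res$median_ks <- tapply(kk, stratum, median, na.rm = TRUE)
    res$p_ks <- if (n_none >= min_n && n_all >= min_n)
      wilcox.test(kk[stratum == "none"], kk[stratum == "all"])$p.value
    else NA_real_
  }
  res
}
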