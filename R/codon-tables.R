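# Codon bookkeeping shared by the simulator and the NG86 estimator.
#
# Codons are indexed 1..64 as 16*(b1-1) + 4*(b2-1) + b3 with bases ordered
# A,C,G,T.  All tables are built once per session from the standard genetic
# code and cached in .codon_cache.

.codon_cache <- new.env(parent = emptyenv())

.BASES <- c("A", "C", "G", "T")

codonIndex <- function(b1, b2, b3) 16L * (b1 - 1L) + 4L * (b2 - 1L) + b3

#' @noRd
codonTables <- function() {
  if (!is.null(.codon_cache$tab)) return(.codon_cache$tab)

  grid <- expand.grid(b3 = 1:4, b2 = 1:4, b1 = 1:4)[, 3:1]
  codons <- apply(grid, 1L, function(b) paste0(.BASES[b], collapse = ""))
  ord <- codonIndex(grid$b1, grid$b2, grid$b3)
  codons[ord] <- codons            # identity by construction, kept explicit
  code <- Biostrings::GENETIC_CODE
  aa <- unname(code[codons])
  stopifnot(!anyNA(aa))
  base_mat <- as.matrix(grid)[order(ord), , drop = FALSE]

  # 9 single-nucleotide neighbours per codon: 3 positions x 3 alternative bases
  nbr <- matrix(0L, 64L, 9L)
  for (ci in 1:64) {
    b <- base_mat[ci, ]
    j <- 0L
    for (pos in 1:3) {
      for (alt in setdiff(1:4, b[pos])) {
        j <- j + 1L
        nb <- b
        nb[pos] <- alt
        nbr[ci, j] <- codonIndex(nb[1], nb[2], nb[3])
      }
    }
  }
  nbr_aa <- matrix(aa[nbr], 64L, 9L)
  is_stop <- aa == "*"
  nbr_syn <- nbr_aa == matrix(aa, 64L, 9L) & !matrix(is_stop, 64L, 9L)
  nbr_stop <- matrix(is_stop[nbr], 64L, 9L)

  # NG86 synonymous site count per codon: fraction of the three possible
  # changes at each position that preserve the amino acid (changes creating
  # a stop count as nonsynonymous).
  syn_sites <- rowSums(nbr_syn & !nbr_stop) / 3
  syn_sites[is_stop] <- NA_real_

  paths <- ng86PathwayTables(base_mat, aa)

  .codon_cache$tab <- list(
    codons = codons, aa = aa, base_mat = base_mat, is_stop = is_stop,
    nbr = nbr, nbr_syn = nbr_syn & !nbr_stop, nbr_stop = nbr_stop,
    syn_sites = syn_sites, sd_tab = paths$sd, nd_tab = paths$nd
  )
  .codon_cache$tab
}

# Pathway-averaged synonymous/nonsynonymous difference counts between every
# ordered codon pair (NG86): enumerate all orderings of the differing
# positions, drop pathways passing through a stop codon (fall back to all
# pathways, counting stop steps as nonsynonymous, when every route is
# blocked), and average.
ng86PathwayTables <- function(base_mat, aa) {
  sd <- matrix(0, 64L, 64L)
  nd <- matrix(0, 64L, 64L)
  perms2 <- list(c(1L, 2L), c(2L, 1L))
  perms3 <- list(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
                 c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L))
  for (i in 1:64) {
    if (aa[i] == "*") next
    for (j in 1:64) {
      if (aa[j] == "*" || i == j) next
      diffpos <- which(base_mat[i, ] != base_mat[j, ])
      k <- length(diffpos)
      perms <- switch(k, list(diffpos),
                      lapply(perms2, function(p) diffpos[p]),
                      lapply(perms3, function(p) diffpos[p]))
      res <- lapply(perms, function(ord) {
        cur <- base_mat[i, ]
        s <- 0; n <- 0; blocked <- FALSE
        for (pos in ord) {
          prev_aa <- aa[codonIndex(cur[1], cur[2], cur[3])]
          cur[pos] <- base_mat[j, pos]
          new_aa <- aa[codonIndex(cur[1], cur[2], cur[3])]
          if (new_aa == "*") blocked <- TRUE
          if (!identical(new_aa, prev_aa)) n <- n + 1 else s <- s + 1
        }
        c(s = s, n = n, blocked = as.numeric(blocked))
      })
      res <- do.call(rbind, res)
      ok <- res[, "blocked"] == 0
      if (!any(ok)) ok <- rep(TRUE, nrow(res))
      sd[i, j] <- mean(res[ok, "s"])
      nd[i, j] <- mean(res[ok, "n"])
    }
  }
  list(sd = sd, nd = nd)
}

# --- conversions ------------------------------------------------------------

# integer codon indices <-> DNA character strings
codonsToString <- function(idx) {
  tab <- codonTables()
  paste0(tab$codons[idx], collapse = "")
}

stringToCodons <- function(x) {
  x <- toupper(as.character(x))
  n <- nchar(x)
  if (n %% 3L != 0L) stop("sequence length is not a multiple of 3")
  v <- match(strsplit(x, "")[[1]], .BASES)
  if (anyNA(v)) stop("non-ACGT character in coding sequence")
  dim(v) <- c(3L, n %/% 3L)
  codonIndex(v[1, ], v[2, ], v[3, ])
}

# integer base vectors (1..4) <-> character strings
intToDna <- function(v) paste0(.BASES[v], collapse = "")
dnaToInt <- function(x) {
  v <- match(strsplit(toupper(as.character(x)), "")[[1]], .BASES)
  if (anyNA(v)) stop("non-ACGT character in sequence")
  v
}
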