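# Independent oracles used by unit and acceptance tests.  These re-derive
# expected values from first principles without touching the package's
# internal tables.

# --- NG86 oracle: exhaustive pathway enumeration from the genetic code ----

.oracle_code <- Biostrings::GENETIC_CODE

oracleSynSites <- function(codon) {
  b <- strsplit(codon, "")[[1]]
  aa <- .oracle_code[[codon]]
  syn <- 0
  for (pos in 1:3) {
    for (alt in setdiff(c("A", "C", "G", "T"), b[pos])) {
      nb <- b
      nb[pos] <- alt
      nb_aa <- .oracle_code[[paste0(nb, collapse = "")]]
      if (nb_aa == aa && nb_aa != "*") syn <- syn + 1
    }
  }
  syn / 3
}

# all permutations of a short vector (n <= 3)
.perms <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (rest in .perms(v[-i]))
      out <- c(out, list(c(v[i], rest)))
  out
}

oracleCodonDiffs <- function(c1, c2) {
  b1 <- strsplit(c1, "")[[1]]
  b2 <- strsplit(c2, "")[[1]]
  dp <- which(b1 != b2)
  if (!length(dp)) return(c(sd = 0, nd = 0))
  paths <- .perms(dp)
  res <- list()
  for (ord in paths) {
    cur <- b1
    s <- 0
    n <- 0
    blocked <- FALSE
    for (pos in ord) {
      aa_prev <- .oracle_code[[paste0(cur, collapse = "")]]
      cur[pos] <- b2[pos]
      aa_new <- .oracle_code[[paste0(cur, collapse = "")]]
      if (aa_new == "*") blocked <- TRUE
      if (aa_new != aa_prev) n <- n + 1 else s <- s + 1
    }
    res[[length(res) + 1]] <- c(s = s, n = n, blocked = blocked)
  }
  m <- do.call(rbind, res)
  ok <- m[, "blocked"] == 0
  if (!any(ok)) ok <- rep(TRUE, nrow(m))
  c(sd = mean(m[ok, "s"]), nd = mean(m[ok, "n"]))
}

oracleNg86 <- function(cds1, cds2) {
  sp1 <- substring(cds1, seq(1, nchar(cds1), 3), seq(3, nchar(cds1), 3))
  sp2 <- substring(cds2, seq(1, nchar(cds2), 3), seq(3, nchar(cds2), 3))
  keep <- .oracle_code[sp1] != "*" & .oracle_code[sp2] != "*"
  sp1 <- sp1[keep]
  sp2 <- sp2[keep]
  S <- (sum(vapply(sp1, oracleSynSites, numeric(1))) +
          sum(vapply(sp2, oracleSynSites, numeric(1)))) / 2
  N <- 3 * length(sp1) - S
  d <- vapply(seq_along(sp1),
              function(i) oracleCodonDiffs(sp1[i], sp2[i]), numeric(2))
  Sd <- sum(d["sd", ])
  Nd <- sum(d["nd", ])
  jc <- function(p) if (p >= 0.75) NA_real_ else -0.75 * log(1 - 4 * p / 3)
  list(S = S, N = N, Sd = Sd, Nd = Nd,
       Ks = jc(Sd / S), Ka = jc(Nd / N))
}

# --- longest strictly monotone chain oracle (O(n^2), direct) -------------

oracleBestChainLength <- function(ra, rb, max_gap) {
  n <- length(ra)
  best <- 0L
  for (dir in c(1L, -1L)) {
    len <- rep(1L, n)
    ord <- order(ra, rb)
    ra_o <- ra[ord]
    rb_o <- rb[ord]
    for (i in seq_len(n)) {
      for (j in seq_len(i - 1L)) {
        if (ra_o[i] <= ra_o[j] || ra_o[i] - ra_o[j] > max_gap) next
        db <- dir * (rb_o[i] - rb_o[j])
        if (db <= 0 || db > max_gap) next
        len[i] <- max(len[i], len[j] + 1L)
      }
    }
    best <- max(best, max(len))
  }
  best
}

# --- column-majority consensus oracle (no rotation) ----------------------

oracleMajorityConsensus <- function(copies) {
  M <- do.call(rbind, strsplit(copies, ""))
  paste0(apply(M, 2, function(col) {
    tab <- table(factor(col, levels = c("A", "C", "G", "T")))
    names(tab)[which.max(tab)]
  }), collapse = "")
}
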