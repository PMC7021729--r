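# Sequence evolution primitives: Jukes-Cantor-like per-site substitution for
# neutral DNA and an exact codon-level process in which every synonymous
# single-nucleotide change occurs at rate mu/3 (so the substitution rate per
# NG86 synonymous site is exactly mu) and every nonsynonymous change at rate
# mu*omega/3.  Changes creating stop codons are forbidden.

# Evolve integer base vector(s) under JC: each site substitutes at rate mu
# to one of the three alternative bases uniformly.
evolveDnaJC <- function(v, mu, time) {
  n <- length(v)
  nev <- rpois(n, mu * time)
  rounds <- if (length(nev)) max(nev) else 0L
  r <- 0L
  while (r < rounds) {
    r <- r + 1L
    act <- which(nev >= r)
    if (!length(act)) break
    shift <- sample.int(3L, length(act), replace = TRUE)
    v[act] <- ((v[act] - 1L + shift) %% 4L) + 1L
  }
  v
}

# Substitute exactly k randomly chosen distinct sites (used to plant a fixed
# divergence between satellite monomer lineages).
mutateFixedSites <- function(v, k) {
  k <- min(k, length(v))
  if (k <= 0L) return(v)
  sites <- sample.int(length(v), k)
  shift <- sample.int(3L, k, replace = TRUE)
  v[sites] <- ((v[sites] - 1L + shift) %% 4L) + 1L
  v
}

# Exact stochastic simulation of the codon substitution process by uniform
# thinning: propose events at the dominating rate 3*mu per codon, pick one of
# the nine single-nucleotide neighbours uniformly, and accept synonymous
# changes with probability 1, nonsynonymous with probability omega, stop-
# creating changes never.
evolveCodons <- function(idx, mu, omega, time) {
  tab <- codonTables()
  n <- length(idx)
  nev <- rpois(n, 3 * mu * time)
  rounds <- if (n) max(nev) else 0L
  r <- 0L
  while (r < rounds) {
    r <- r + 1L
    act <- which(nev >= r)
    if (!length(act)) break
    j <- sample.int(9L, length(act), replace = TRUE)
    cur <- idx[act]
    sel <- cbind(cur, j)
    p <- ifelse(tab$nbr_stop[sel], 0,
                ifelse(tab$nbr_syn[sel], 1, omega))
    ok <- runif(length(act)) < p
    idx[act[ok]] <- tab$nbr[sel][ok]
  }
  idx
}

# Random open reading frame: ATG followed by sense (non-stop) codons.
randomCds <- function(n_codons) {
  tab <- codonTables()
  sense <- which(!tab$is_stop)
  atg <- which(tab$codons == "ATG")
  c(atg, sample(sense, n_codons - 1L, replace = TRUE))
}

randomDnaInt <- function(n) sample.int(4L, n, replace = TRUE)
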