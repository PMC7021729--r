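#' Simulate the progenitor split and genome merger
#'
#' Evolves one ancestral diploid gene set along two independent lineages for
#' \code{t_divergence} years (synonymous sites substitute at
#' \code{mu_neutral}, nonsynonymous sites at \code{mu_neutral * ka_ks_true}),
#' merges the lineages into A and B subgenome chromosomes, then applies
#' post-merger fractionation (with a configurable fraction of losses leaving
#' pseudogene remnants), tandem duplication, and segmental inversions.  The
#' expected synonymous divergence of a homoeolog pair is
#' \code{2 * mu_neutral * t_divergence}.
#'
#' @param config a [SimConfig-class].
#' @return a [SimulatedPolyploid-class] carrying the gene truth table, the
#'   retained coding sequences and the ancestral diploid gene set (LTR,
#'   satellite and atlas slots are filled by the later stages).
#' @seealso [simulatePolyploid()] runs all four stages.
#' @examples
#' sp <- simulateProgenitors(simConfig(seed = 1, n_chromosome_pairs = 2,
#'   genes_per_chromosome = 10, codons_per_gene = 100))
#' head(truthGenes(sp))
#' @export
simulateProgenitors <- function(config) {
  stopifnot(is(config, "SimConfig"))
  validObject(config)
  stageSeed(config, "progenitors")

  nchr <- config@n_chromosome_pairs
  gpc <- config@genes_per_chromosome
  L <- config@codons_per_gene
  n_genes <- nchr * gpc

  anc <- unlist(lapply(seq_len(n_genes), function(i) randomCds(L)))
  seqA <- evolveCodons(anc, config@mu_neutral, config@ka_ks_true,
                       config@t_divergence)
  seqB <- evolveCodons(anc, config@mu_neutral, config@ka_ks_true,
                       config@t_divergence)
  gene_of <- rep(seq_len(n_genes), each = L)

  chr_num <- rep(seq_len(nchr), each = gpc)
  pos <- rep(seq_len(gpc), times = nchr)
  pair_id <- sprintf("p%02d.%04d", chr_num, pos)

  makeSide <- function(sub, rate) {
    lost <- runif(n_genes) < rate
    pseudo <- lost & runif(n_genes) < config@pseudogene_fraction
    status <- ifelse(pseudo, "pseudogene", ifelse(lost, "lost", "retained"))
    data.frame(
      gene_id = sprintf("g%02d%s.%04d", chr_num, sub, pos),
      chromosome = sprintf("%d%s", chr_num, sub),
      subgenome = sub,
      pair_id = pair_id,
      anc_pos = pos,
      status = status,
      is_tandem_copy = FALSE,
      tandem_parent = NA_character_,
      strand = "+",
      stringsAsFactors = FALSE
    )
  }
  gA <- makeSide("A", config@fractionation_rate_A)
  gB <- makeSide("B", config@fractionation_rate_B)

  seq_env <- new.env(parent = emptyenv())
  storeSeq <- function(df, evolved) {
    keep <- df$status == "retained"
    for (i in which(keep)) {
      g <- which(chr_num == as.integer(substr(df$chromosome[i], 1,
                   nchar(df$chromosome[i]) - 1)) & pos == df$anc_pos[i])
      assign(df$gene_id[i], evolved[gene_of == g], envir = seq_env)
    }
  }
  storeSeq(gA, seqA)
  storeSeq(gB, seqB)

  # tandem duplication: extra copies inserted adjacent to the parent, each
  # diverging from it for a uniform fraction of the post-merger interval
  addTandems <- function(df) {
    cand <- which(df$status == "retained")
    dup <- cand[runif(length(cand)) < config@tandem_rate]
    rows <- list(df)
    for (i in dup) {
      extra <- sample.int(max(config@tandem_max_copies - 1L, 1L), 1L)
      parent_seq <- get(df$gene_id[i], envir = seq_env)
      for (k in seq_len(extra)) {
        cid <- sprintf("%s.t%d", df$gene_id[i], k)
        cseq <- evolveCodons(parent_seq, config@mu_neutral,
                             config@ka_ks_true, runif(1) * config@t_merger)
        assign(cid, cseq, envir = seq_env)
        row <- df[i, ]
        row$gene_id <- cid
        row$pair_id <- NA_character_
        row$is_tandem_copy <- TRUE
        row$tandem_parent <- df$gene_id[i]
        rows <- c(rows, list(row))
      }
    }
    do.call(rbind, rows)
  }
  gA <- addTandems(gA)
  gB <- addTandems(gB)
  genes <- rbind(gA, gB)

  # gene order: ancestral position, tandem copies right after their parent
  genes$ord_key <- genes$anc_pos
  tc <- genes$is_tandem_copy
  genes$ord_key[tc] <- genes$anc_pos[tc] +
    as.integer(sub(".*\\.t", "", genes$gene_id[tc])) / 100
  genes <- genes[order(genes$chromosome, genes$ord_key), ]
  genes$rank <- NA_integer_
  for (chr in unique(genes$chromosome)) {
    sel <- genes$chromosome == chr & genes$status != "lost"
    genes$rank[sel] <- seq_len(sum(sel))
  }

  # segmental inversions on the B subgenome gene order
  if (config@inversion_count > 0L) {
    b_chrs <- unique(genes$chromosome[genes$subgenome == "B"])
    for (k in seq_len(config@inversion_count)) {
      chr <- sample(b_chrs, 1L)
      sel <- which(genes$chromosome == chr & !is.na(genes$rank))
      n <- length(sel)
      if (n < 8L) next
      len <- sample(5:min(30L, n - 2L), 1L)
      start <- sample.int(n - len, 1L)
      seg <- sel[order(genes$rank[sel])][start:(start + len - 1L)]
      genes$rank[seg] <- rev(genes$rank[seg])
      genes$strand[seg] <- ifelse(genes$strand[seg] == "+", "-", "+")
    }
  }
  genes <- genes[order(genes$chromosome, ifelse(is.na(genes$rank), 1e9,
                                                genes$rank)), ]
  genes$ord_key <- NULL
  rownames(genes) <- NULL

  keep <- genes$gene_id[genes$status == "retained"]
  cds <- Biostrings::DNAStringSet(vapply(keep, function(id)
    codonsToString(get(id, envir = seq_env)), character(1)))
  names(cds) <- keep

  anc_ids <- sprintf("anc%02d.%04d", chr_num, pos)
  anc_cds <- Biostrings::DNAStringSet(vapply(seq_len(n_genes), function(g)
    codonsToString(anc[gene_of == g]), character(1)))
  names(anc_cds) <- anc_ids

  new("SimulatedPolyploid", config = config, genes = genes, cds = cds,
      ancestral_cds = anc_cds,
      ltr_elements = data.frame(), ltr_seqs = Biostrings::DNAStringSet(),
      satellites = list(), atlas = list())
}

#' Simulate the LTR retrotransposon landscape
#'
#' Places each configured family's elements on its allowed subgenome(s) with
#' insertion ages drawn uniformly within the family activity window.  Both
#' terminal repeats start identical at insertion and then accumulate
#' substitutions independently at \code{mu_ltr}, so the expected pairwise
#' divergence of an element aged T is \code{2 * mu_ltr * T} (before
#' multiple-hit saturation).
#'
#' @param config a [SimConfig-class].
#' @param sp a [SimulatedPolyploid-class] from [simulateProgenitors()].
#' @param allow_recent_specific suppress the warning issued when a
#'   subgenome-restricted family has activity younger than the merger (such a
#'   family contradicts independent progenitor evolution).
#' @return \code{sp} with the \code{ltr_elements} table and paired LTR
#'   sequences filled in.
#' @export
simulateLtrLandscape <- function(config, sp, allow_recent_specific = FALSE) {
  stopifnot(is(sp, "SimulatedPolyploid"))
  stageSeed(config, "ltr")
  fam <- config@ltr_families
  if (!nrow(fam)) stop("no LTR families configured")

  bad <- fam$subgenome %in% c("A", "B") & fam$end_age < config@t_merger
  if (any(bad) && !allow_recent_specific)
    warning("subgenome-restricted families active after the merger: ",
            paste(fam$name[bad], collapse = ", "))

  chromsA <- unique(sp@genes$chromosome[sp@genes$subgenome == "A"])
  chromsB <- unique(sp@genes$chromosome[sp@genes$subgenome == "B"])

  recs <- list()
  seqs <- list()
  for (f in seq_len(nrow(fam))) {
    n <- fam$copies[f]
    sub <- if (fam$subgenome[f] == "shared")
      sample(c("A", "B"), n, replace = TRUE) else rep(fam$subgenome[f], n)
    chrom <- vapply(sub, function(s)
      sample(if (s == "A") chromsA else chromsB, 1L), character(1))
    age <- runif(n, fam$end_age[f], fam$start_age[f])
    ids <- sprintf("%s_e%03d", fam$name[f], seq_len(n))
    for (i in seq_len(n)) {
      anc <- randomDnaInt(config@ltr_length)
      l5 <- evolveDnaJC(anc, config@mu_ltr, age[i])
      l3 <- evolveDnaJC(anc, config@mu_ltr, age[i])
      seqs[[paste0(ids[i], "_5p")]] <- intToDna(l5)
      seqs[[paste0(ids[i], "_3p")]] <- intToDna(l3)
    }
    recs[[f]] <- data.frame(
      element_id = ids, family = fam$name[f], chromosome = chrom,
      subgenome = sub, age = age, intact = TRUE, stringsAsFactors = FALSE)
  }
  elements <- do.call(rbind, recs)
  rownames(elements) <- NULL
  sp@ltr_elements <- elements
  sp@ltr_seqs <- Biostrings::DNAStringSet(unlist(seqs))
  sp
}

#' Simulate centromeric satellite arrays
#'
#' One random ancestral monomer is mutated along two lineages, each by half
#' the configured clade divergence, yielding one satellite monomer lineage
#' per subgenome.  Every chromosome receives one tandem array whose copy
#' number is drawn from \code{satellite_copy_range}; each copy carries
#' independent per-site noise at \code{satellite_copy_noise}.
#'
#' @inheritParams simulateLtrLandscape
#' @return \code{sp} with the \code{satellites} slot filled: \code{arrays}
#'   truth table, per-chromosome monomer copies, and the two clade monomers.
#' @export
simulateSatellites <- function(config, sp) {
  stopifnot(is(sp, "SimulatedPolyploid"))
  stageSeed(config, "satellites")
  L <- config@satellite_monomer_length
  anc <- randomDnaInt(L)
  half <- round(config@satellite_clade_divergence / 2 * L)
  cladeA <- mutateFixedSites(anc, half)
  cladeB <- mutateFixedSites(anc, half)

  chroms <- unique(sp@genes$chromosome)
  monomers <- vector("list", length(chroms))
  names(monomers) <- chroms
  arrays <- data.frame(
    chromosome = chroms,
    clade = substr(chroms, nchar(chroms), nchar(chroms)),
    copy_number = {
      vals <- seq(config@satellite_copy_range[1],
                  config@satellite_copy_range[2])
      vals[sample.int(length(vals), length(chroms), replace = TRUE)]
    },
    monomer_length = L,
    stringsAsFactors = FALSE
  )
  for (i in seq_along(chroms)) {
    src <- if (arrays$clade[i] == "A") cladeA else cladeB
    n <- arrays$copy_number[i]
    m <- matrix(rep(src, each = n), nrow = n)
    mask <- matrix(runif(n * L) < config@satellite_copy_noise, nrow = n)
    shift <- matrix(sample.int(3L, n * L, replace = TRUE), nrow = n)
    m[mask] <- ((m[mask] - 1L + shift[mask]) %% 4L) + 1L
    copies <- Biostrings::DNAStringSet(apply(m, 1L, intToDna))
    names(copies) <- sprintf("%s_sat%04d", chroms[i], seq_len(n))
    monomers[[i]] <- copies
  }
  clade_mono <- Biostrings::DNAStringSet(c(A = intToDna(cladeA),
                                           B = intToDna(cladeB)))
  sp@satellites <- list(arrays = arrays, monomers = monomers,
                        clade_monomers = clade_mono)
  sp
}

#' Simulate the homoeolog expression atlas
#'
#' Per-pair baseline means are log-normal; a fraction \code{frac_biased} of
#' homoeolog pairs receive a log2 fold shift of \code{effect_log2} toward one
#' homoeolog (B with probability \code{prob_bias_toward_B}).  A fraction
#' \code{frac_consistent_across_tissues} of biased pairs keep that direction
#' in all tissues; the rest flip direction in at least one tissue.  Tissue
#' effects are shared by the two homoeologs of a pair, and replicate counts
#' are negative-binomial with the configured dispersion and log-normal
#' library-size factors.
#'
#' @inheritParams simulateLtrLandscape
#' @return \code{sp} with the \code{atlas} slot filled: \code{counts}
#'   (genes x tissue_rep), \code{samples}, per-pair \code{truth} and the long
#'   per-pair-per-tissue \code{truth_tissues} table.
#' @export
simulateAtlas <- function(config, sp) {
  stopifnot(is(sp, "SimulatedPolyploid"))
  if (config@atlas$dispersion <= 0) stop("dispersion must be > 0")
  stageSeed(config, "atlas")
  a <- config@atlas
  prs <- truthPairs(sp)
  if (!nrow(prs)) stop("no surviving homoeolog pairs to build an atlas on")
  nt <- a$n_tissues
  nr <- a$n_reps
  tissues <- sprintf("tissue%02d", seq_len(nt))

  np <- nrow(prs)
  biased <- runif(np) < a$frac_biased
  direction <- ifelse(biased,
                      ifelse(runif(np) < a$prob_bias_toward_B, "B", "A"),
                      NA_character_)
  consistent <- ifelse(biased,
                       runif(np) < a$frac_consistent_across_tissues, NA)

  # per-pair per-tissue true dominant homoeolog
  dir_mat <- matrix("none", np, nt, dimnames = list(prs$pair_id, tissues))
  for (i in which(biased)) {
    d <- rep(direction[i], nt)
    if (!consistent[i]) {
      k <- sample.int(nt - 1L, 1L)
      flip <- sample.int(nt, k)
      d[flip] <- ifelse(direction[i] == "A", "B", "A")
    }
    dir_mat[i, ] <- d
  }

  base <- rlnorm(np, a$baseline_meanlog, a$baseline_sdlog)
  tiss_eff <- matrix(rlnorm(np * nt, 0, a$tissue_sdlog), np, nt)
  half <- 2^(a$effect_log2 / 2)

  samples <- data.frame(
    sample = as.vector(t(outer(tissues, sprintf("rep%d", seq_len(nr)),
                               paste, sep = "_"))),
    tissue = rep(tissues, each = nr),
    rep = rep(seq_len(nr), times = nt),
    stringsAsFactors = FALSE
  )
  sf_true <- rlnorm(nrow(samples), 0, a$libsize_sdlog)

  gene_ids <- c(prs$gene_a, prs$gene_b)
  counts <- matrix(0L, length(gene_ids), nrow(samples),
                   dimnames = list(gene_ids, samples$sample))
  size <- 1 / a$dispersion
  for (t in seq_len(nt)) {
    muA <- base * tiss_eff[, t] *
      ifelse(dir_mat[, t] == "A", half, ifelse(dir_mat[, t] == "B", 1 / half, 1))
    muB <- base * tiss_eff[, t] *
      ifelse(dir_mat[, t] == "B", half, ifelse(dir_mat[, t] == "A", 1 / half, 1))
    cols <- which(samples$tissue == tissues[t])
    for (j in cols) {
      counts[, j] <- c(rnbinom(np, mu = muA * sf_true[j], size = size),
                       rnbinom(np, mu = muB * sf_true[j], size = size))
    }
  }

  truth <- data.frame(pair_id = prs$pair_id, biased = biased,
                      direction = direction, consistent = consistent,
                      stringsAsFactors = FALSE)
  truth_tissues <- data.frame(
    pair_id = rep(prs$pair_id, times = nt),
    tissue = rep(tissues, each = np),
    true_dir = as.vector(dir_mat),
    stringsAsFactors = FALSE
  )
  sp@atlas <- list(counts = counts, samples = samples, truth = truth,
                   truth_tissues = truth_tissues, size_factors_true = sf_true)
  sp
}

#' Run all four simulation stages
#'
#' @param config a [SimConfig-class].
#' @param ... passed to [simulateLtrLandscape()].
#' @return a fully populated [SimulatedPolyploid-class].
#' @examples
#' sp <- simulatePolyploid(simConfig(seed = 7, n_chromosome_pairs = 2,
#'   genes_per_chromosome = 15, codons_per_gene = 100,
#'   satellite_copy_range = c(20, 40),
#'   atlas = atlasSpec(n_tissues = 3)))
#' sp
#' @export
simulatePolyploid <- function(config, ...) {
  sp <- simulateProgenitors(config)
  sp <- simulateLtrLandscape(config, sp, ...)
  sp <- simulateSatellites(config, sp)
  simulateAtlas(config, sp)
}
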