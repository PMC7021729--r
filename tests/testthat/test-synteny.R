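# Homology search with C-score filtering, block chaining, syntenic depth,
# tandem arrays, retention and biased fractionation.

test_that("identical gene sets give reciprocal-best pairs at C-score 1", {
  set.seed(51)
  cds <- Biostrings::DNAStringSet(vapply(1:6, function(i)
    randomCdsString(80), character(1)))
  names(cds) <- sprintf("g%d", 1:6)
  hp <- findHomologyPairs(cds, cds, cscore = 0.99)
  twin <- hp[hp$gene_a == hp$gene_b, ]
  expect_equal(sort(twin$gene_a), sort(names(cds)))
  expect_true(all(twin$cscore == 1))
})

test_that("C-score 0.99 keeps the recent homoeolog and drops the ancient paralog", {
  set.seed(52)
  mutate_frac <- function(cds, frac) {
    v <- stringToCodons(cds)
    n <- max(1L, round(length(v) * frac * 3))
    # substitute whole codons with random sense codons to control identity
    tab <- polysub:::codonTables()
    pos <- sample(2:length(v), min(n, length(v) - 1L))
    v[pos] <- sample(which(!tab$is_stop), length(pos), replace = TRUE)
    polysub:::codonsToString(v)
  }
  anc <- randomCdsString(150)
  genomeA <- Biostrings::DNAStringSet(c(query = anc))
  genomeB <- Biostrings::DNAStringSet(c(
    homoeolog = mutate_frac(anc, 0.05),
    paralog = mutate_frac(anc, 0.45)))
  hp <- findHomologyPairs(genomeA, genomeB, cscore = 0.99)
  expect_equal(hp$gene_b, "homoeolog")
  # exhaustive scoring oracle: score all pairs directly and apply the
  # C-score definition without the k-mer seeding path
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1)
  sc <- vapply(names(genomeB), function(b)
    Biostrings::pairwiseAlignment(genomeA[[1]], genomeB[[b]],
                                  substitutionMatrix = mat, gapOpening = 4,
                                  gapExtension = 1, type = "local",
                                  scoreOnly = TRUE), numeric(1))
  oracle_keep <- names(sc)[sc / max(sc) >= 0.99]
  expect_equal(sort(hp$gene_b), sort(oracle_keep))
})

test_that("perfect collinearity chains into a single full-length block", {
  pairs <- data.frame(gene_a = sprintf("a%03d", 1:100),
                      gene_b = sprintf("b%03d", 1:100))
  orders <- data.frame(
    gene_id = c(pairs$gene_a, pairs$gene_b),
    chromosome = rep(c("cA", "cB"), each = 100),
    rank = c(1:100, 1:100))
  ch <- chainBlocks(pairs, orders)
  expect_equal(nrow(ch$blocks), 1L)
  expect_equal(ch$blocks$n_anchors, 100L)
  expect_equal(ch$blocks$orientation, "same")
})

test_that("an internal inversion splits into blocks matching the monotone oracle", {
  rb <- c(1:40, 60:41, 61:100)   # 20-gene inversion
  pairs <- data.frame(gene_a = sprintf("a%03d", 1:100),
                      gene_b = sprintf("b%03d", rb))
  orders <- data.frame(
    gene_id = c(sprintf("a%03d", 1:100), sprintf("b%03d", 1:100)),
    chromosome = rep(c("cA", "cB"), each = 100),
    rank = c(1:100, 1:100))
  ch <- chainBlocks(pairs, orders)
  expect_true(nrow(ch$blocks) %in% 2:3)
  expect_true("inverted" %in% ch$blocks$orientation)
  expect_equal(sum(ch$blocks$n_anchors), 100L)
  expect_equal(max(ch$blocks$n_anchors),
               oracleBestChainLength(1:100, rb, max_gap = 25L))
})

test_that("chaining matches the longest-monotone-subsequence oracle on random dot plots", {
  set.seed(53)
  for (rep in 1:5) {
    n <- 40L
    ra <- sample.int(60L, n)
    rb <- sample.int(60L, n)
    pairs <- data.frame(gene_a = sprintf("a%02d", seq_len(n)),
                        gene_b = sprintf("b%02d", seq_len(n)))
    orders <- data.frame(
      gene_id = c(pairs$gene_a, pairs$gene_b),
      chromosome = rep(c("cA", "cB"), each = n),
      rank = c(ra, rb))
    ch <- chainBlocks(pairs, orders, min_block = 2L, max_gap = 60L)
    expect_equal(max(ch$blocks$n_anchors),
                 oracleBestChainLength(ra, rb, max_gap = 60L))
  }
})

test_that("chaining is invariant under coordinate reflection", {
  sp <- cachedSmallSim()
  g <- truthGenes(sp)
  ret <- g[g$status == "retained", ]
  orders <- geneOrders(sp)
  tp <- truthPairs(sp)
  pairs <- tp[, c("gene_a", "gene_b")]
  ch1 <- chainBlocks(pairs, orders)
  refl <- orders
  for (chr in unique(refl$chromosome)) {
    sel <- refl$chromosome == chr & grepl("B", chr)
    if (chr %in% refl$chromosome[grepl("B$", refl$chromosome)]) {
      s2 <- refl$chromosome == chr
      refl$rank[s2] <- max(refl$rank[s2]) + 1L - refl$rank[s2]
    }
  }
  ch2 <- chainBlocks(pairs, refl)
  expect_equal(sum(ch1$blocks$n_anchors), sum(ch2$blocks$n_anchors))
  m1 <- sort(paste(ch1$anchors$gene_a, ch1$anchors$gene_b))
  m2 <- sort(paste(ch2$anchors$gene_a, ch2$anchors$gene_b))
  expect_equal(m1, m2)
})

test_that("simulated tetraploid pairing reaches 95% recall against truth", {
  # chromosomes long enough that inversion segments exceed min_block
  cfg <- simConfig(seed = 78L, n_chromosome_pairs = 2L,
                   genes_per_chromosome = 80L, codons_per_gene = 100L,
                   inversion_count = 1L)
  sp <- simulateProgenitors(cfg)
  g <- truthGenes(sp)
  ret <- g[g$status == "retained", ]
  cdsA <- cdsSet(sp)[ret$gene_id[ret$subgenome == "A"]]
  cdsB <- cdsSet(sp)[ret$gene_id[ret$subgenome == "B"]]
  hp <- findHomologyPairs(cdsA, cdsB)
  ch <- chainBlocks(hp, geneOrders(sp))
  pairs <- resolveHomoeologPairs(ch)
  tp <- truthPairs(sp)
  recall <- mean(paste(tp$gene_a, tp$gene_b) %in%
                   paste(pairs$gene_a, pairs$gene_b))
  expect_gte(recall, 0.95)
  # 1:1 after resolution
  expect_false(anyDuplicated(pairs$gene_a) > 0)
  expect_false(anyDuplicated(pairs$gene_b) > 0)
})

test_that("syntenic depth is 2 without losses and the histogram is conserved", {
  cfg <- smallConfig(seed = 54L, fractionation_rate_A = 0,
                     fractionation_rate_B = 0, tandem_rate = 0,
                     inversion_count = 0L)
  sp <- simulateProgenitors(cfg)
  g <- truthGenes(sp)
  # anchors from truth: ancestral gene vs its two descendants
  anc_ids <- names(ancestralCds(sp))
  anc_pos <- as.integer(sub(".*\\.", "", anc_ids))
  anc_chr <- sub("anc", "", sub("\\..*", "", anc_ids))
  ref_orders <- data.frame(gene_id = anc_ids,
                           chromosome = paste0("ref", anc_chr),
                           rank = anc_pos)
  desc <- g[g$status == "retained" & !g$is_tandem_copy, ]
  pairs <- data.frame(
    gene_a = sprintf("anc%s.%04d",
                     sub("[AB]$", "", desc$chromosome),
                     desc$anc_pos),
    gene_b = desc$gene_id)
  orders <- rbind(ref_orders,
                  data.frame(gene_id = desc$gene_id,
                             chromosome = desc$chromosome,
                             rank = desc$rank))
  pairs$gene_a <- sprintf("anc%02d.%04d",
                          as.integer(sub("[AB]$", "", desc$chromosome)),
                          desc$anc_pos)
  ch <- chainBlocks(pairs, orders)
  dep <- syntenicDepth(ch, ref_orders)
  expect_equal(sum(dep$histogram), nrow(ref_orders))
  expect_equal(dep$modal_depth, 2L)
  expect_gte(mean(dep$depth == 2), 0.95)
})

test_that("fractionation shifts the depth distribution by the closed form", {
  cfg <- simConfig(seed = 55L, n_chromosome_pairs = 2L,
                   genes_per_chromosome = 200L, codons_per_gene = 100L,
                   fractionation_rate_A = 0.05, fractionation_rate_B = 0.05,
                   pseudogene_fraction = 0, tandem_rate = 0,
                   inversion_count = 0L)
  sp <- simulateProgenitors(cfg)
  g <- truthGenes(sp)
  desc <- g[g$status == "retained" & !g$is_tandem_copy, ]
  anc_ids <- names(ancestralCds(sp))
  ref_orders <- data.frame(
    gene_id = anc_ids,
    chromosome = paste0("ref", sub("anc", "", sub("\\..*", "", anc_ids))),
    rank = as.integer(sub(".*\\.", "", anc_ids)))
  pairs <- data.frame(
    gene_a = sprintf("anc%02d.%04d",
                     as.integer(sub("[AB]$", "", desc$chromosome)),
                     desc$anc_pos),
    gene_b = desc$gene_id)
  orders <- rbind(ref_orders,
                  data.frame(gene_id = desc$gene_id,
                             chromosome = desc$chromosome,
                             rank = desc$rank))
  dep <- syntenicDepth(chainBlocks(pairs, orders), ref_orders)
  frac2 <- mean(dep$depth == 2)
  # closed form: both descendants retained with prob (1 - r)^2
  expect_lt(abs(frac2 - 0.95^2), 0.04)
})

test_that("tandem arrays respect the rank-distance threshold", {
  orders <- data.frame(gene_id = sprintf("g%02d", 1:40),
                       chromosome = "c1", rank = 1:40)
  hits3 <- data.frame(gene_a = c("g01", "g02"), gene_b = c("g02", "g03"))
  ta <- tandemGeneArrays(hits3, orders)
  expect_equal(nrow(ta), 1L)
  expect_equal(ta$size, 3L)
  # distance 11 exceeds the threshold, distance 10 does not
  far <- data.frame(gene_a = "g01", gene_b = "g12")
  expect_equal(nrow(tandemGeneArrays(far, orders)), 0L)
  edge <- data.frame(gene_a = "g01", gene_b = "g11")
  expect_equal(tandemGeneArrays(edge, orders)$size, 2L)
})

test_that("simulated tandem arrays are recovered exactly", {
  sp <- cachedSmallSim()
  g <- truthGenes(sp)
  ret <- g[g$status == "retained" & g$subgenome == "A", ]
  cdsA <- cdsSet(sp)[ret$gene_id]
  hits <- findHomologyPairs(cdsA, cdsA, cscore = 0, self = TRUE)
  ta <- tandemGeneArrays(hits, geneOrders(sp))
  truth <- table(g$tandem_parent[g$subgenome == "A" & g$is_tandem_copy])
  expect_equal(nrow(ta), length(truth))
  for (parent in names(truth)) {
    row <- ta[grepl(parent, ta$genes, fixed = TRUE), ]
    expect_equal(row$size, unname(truth[parent]) + 1L)
  }
})

test_that("retention classification reproduces the pair/pseudogene accounting", {
  n_pairs <- 27423L
  pairs <- data.frame(gene_a = sprintf("A%05d", seq_len(n_pairs)),
                      gene_b = sprintf("B%05d", seq_len(n_pairs)))
  genes <- c(pairs$gene_a, pairs$gene_b,
             sprintf("P%04d", 1:9036), sprintf("S%04d", 1:4373))
  ret <- classifyRetention(pairs, genes,
                           pseudogene_partnered = sprintf("P%04d", 1:9036))
  expect_equal(ret$summary$n_genes, 68255L)
  expect_equal(ret$summary$n_pair, 54846L)
  expect_equal(ret$summary$n_gene_pseudogene, 9036L)
  expect_lt(abs(ret$summary$fraction_retained - 0.935), 0.002)
  expect_error(
    classifyRetention(pairs, genes,
                      pseudogene_partnered = pairs$gene_a[1]),
    "both paired")
  all_paired <- classifyRetention(pairs, c(pairs$gene_a, pairs$gene_b))
  expect_equal(all_paired$summary$fraction_retained, 1.0)
})

test_that("biased fractionation test reproduces the exact binomial", {
  expect_equal(testBiasedFractionation(50, 50)$p, 1.0)
  near <- testBiasedFractionation(647, 678)
  expect_equal(near$p, binom.test(647, 1325, 0.5)$p.value)
  expect_lt(abs(near$p - 0.41), 0.01)
  expect_false(near$biased)
  skew <- testBiasedFractionation(100, 200)
  expect_lt(skew$p, 1e-8)
  expect_true(skew$biased)
  undef <- testBiasedFractionation(0, 0)
  expect_false(undef$defined)
  expect_error(testBiasedFractionation(-1, 5))
})
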