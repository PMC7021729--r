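# HEB quantification, NB Wald testing, bias classification, dominance
# consistency and the Ka/Ks-by-bias comparison.

test_that("heb is the signed log ratio with the documented conventions", {
  expect_equal(heb(100, 100), 0)
  expect_lt(abs(heb(300, 100) - log2(3)), 0.02)
  set.seed(61)
  a <- runif(50, 0, 500)
  b <- runif(50, 0, 500)
  expect_equal(heb(a, b), -heb(b, a))          # antisymmetry
  expect_true(all((heb(a, b) > 0) == (a > b)))
  expect_error(heb(-1, 5), ">= 0")
})

test_that("testPairTissue handles balanced, shifted and empty pairs", {
  same <- testPairTissue(c(100, 110, 90), c(100, 110, 90))
  expect_equal(same$log2fc, 0)
  expect_gt(same$p, 0.95)
  shift <- testPairTissue(c(200, 220, 180), c(100, 110, 90))
  expect_lt(abs(shift$log2fc - 1), 0.1)
  expect_lt(shift$p, 0.05)
  zero <- testPairTissue(c(0, 0, 0), c(0, 0, 0))
  expect_false(zero$expressed)
  expect_error(testPairTissue(c(1, 2), 3), "replicates")
})

test_that("testPairTissue agrees with a likelihood-ratio oracle on the same NB model", {
  # LR oracle: NB likelihood with the same pooled moment dispersion,
  # common-mean vs two-mean fit, chi-square with 1 df
  lrOracle <- function(a, b) {
    alphaOf <- function(x) max((var(x) - mean(x)) / mean(x)^2, 0)
    alpha <- mean(c(alphaOf(a), alphaOf(b)))
    size <- if (alpha > 0) 1 / alpha else 1e8
    ll <- function(x, mu) sum(dnbinom(x, size = size, mu = mu, log = TRUE))
    stat <- 2 * (ll(a, mean(a)) + ll(b, mean(b)) -
                   ll(c(a, b), mean(c(a, b))))
    pchisq(stat, df = 1, lower.tail = FALSE)
  }
  set.seed(62)
  agree <- 0L
  for (i in 1:30) {
    mu <- rlnorm(1, log(150), 0.5)
    fc <- sample(c(1, 1, 2, 3), 1)
    a <- rnbinom(3, mu = mu * fc, size = 20)
    b <- rnbinom(3, mu = mu, size = 20)
    if (sum(a) == 0 || sum(b) == 0) next
    mine <- testPairTissue(a, b)$p
    orc <- lrOracle(a, b)
    agree <- agree + ((mine < 0.05) == (orc < 0.05))
  }
  expect_gte(agree, 24L)   # decisions coincide for the large majority
})

test_that("hebTest matches DESeq2 per-tissue results on simulated counts", {
  cfg <- smallConfig(seed = 63L)
  sp <- simulateProgenitors(cfg)
  sp <- simulateAtlas(cfg, sp)
  prs <- truthPairs(sp)
  rec <- hebTest(atlasCounts(sp), atlasSamples(sp), prs)
  one <- rec[rec$tissue == "tissue01", ]

  suppressPackageStartupMessages(library(DESeq2))
  samples <- atlasSamples(sp)
  cols <- samples$sample[samples$tissue == "tissue01"]
  cnt <- atlasCounts(sp)[, cols]
  # one row per pair: the A homoeolog's replicates as condition A columns,
  # the B homoeolog's as condition B -- DESeq2 then tests A vs B per pair
  dds <- DESeq2::DESeqDataSetFromMatrix(
    countData = cbind(cnt[prs$gene_a, ], cnt[prs$gene_b, ]),
    colData = data.frame(homoeolog = factor(rep(c("A", "B"),
                                                each = length(cols)))),
    design = ~homoeolog)
  invisible(capture.output(suppressMessages(dds <- DESeq2::DESeq(dds,
                                                                 quiet = TRUE))))
  res <- DESeq2::results(dds, contrast = c("homoeolog", "A", "B"))
  # sign agreement for clearly biased pairs under both methods
  strong <- which(!is.na(res$padj) & res$padj < 0.01 & one$p < 0.01)
  expect_gt(length(strong), 5)
  expect_true(all(sign(res$log2FoldChange[strong]) ==
                    sign(one$heb[strong])))
  # effect sizes track each other
  ok <- is.finite(res$log2FoldChange)
  expect_gt(cor(res$log2FoldChange[ok], one$heb[ok]), 0.9)
})

test_that("false positives after BH stay below the FDR level under the null", {
  cfg <- simConfig(seed = 64L, n_chromosome_pairs = 2L,
                   genes_per_chromosome = 500L, codons_per_gene = 100L,
                   fractionation_rate_A = 0, fractionation_rate_B = 0,
                   tandem_rate = 0, inversion_count = 0L,
                   atlas = atlasSpec(frac_biased = 0))
  sp <- simulateProgenitors(cfg)
  sp <- simulateAtlas(cfg, sp)
  rec <- classifyBias(hebTest(atlasCounts(sp), atlasSamples(sp),
                              truthPairs(sp)))
  expect_lte(mean(rec$bias_class %in% c("A", "B")), 0.05)
})

test_that("single-pair type-I error stays at or below nominal across dispersions", {
  set.seed(65)
  for (disp in c(0.01, 0.2, 1)) {
    n_sim <- 1500L
    mu <- rlnorm(n_sim, log(100), 1)
    fp <- 0L
    for (i in seq_len(n_sim)) {
      a <- rnbinom(3, mu = mu[i], size = 1 / disp)
      b <- rnbinom(3, mu = mu[i], size = 1 / disp)
      r <- testPairTissue(a, b)
      if (r$expressed && !is.na(r$p) && r$p < 0.05) fp <- fp + 1L
    }
    # nominal 0.05 plus ~3 Monte-Carlo standard errors
    expect_lte(fp / n_sim, 0.05 + 3 * sqrt(0.05 * 0.95 / n_sim))
  }
})

test_that("classifyBias applies the FDR cutoff and sign convention", {
  rec <- data.frame(
    pair_id = sprintf("p%02d", 1:40), tissue = "t1",
    mean_a = 100, mean_b = 100,
    heb = c(rep(0.8, 10), rep(-0.8, 10), rep(0.1, 20)),
    wald = 0,
    p = c(rep(1e-8, 10), rep(1e-8, 10), runif(20, 0.2, 1)),
    expressed = TRUE, stringsAsFactors = FALSE)
  cl <- classifyBias(rec, alpha = 0.05)
  expect_true(all(cl$bias_class[1:10] == "A"))
  expect_true(all(cl$bias_class[11:20] == "B"))
  expect_true(all(cl$bias_class[21:40] == "balanced"))
  expect_true(all(cl$padj >= cl$p))
  # per-tissue class counts partition the tested pairs
  expect_equal(sum(table(cl$bias_class)), nrow(rec))
})

test_that("relabeling subgenomes negates heb and swaps the classes", {
  sp <- cachedSmallSim()
  prs <- truthPairs(sp)
  fwd <- classifyBias(hebTest(atlasCounts(sp), atlasSamples(sp), prs))
  swapped <- prs
  swapped$gene_a <- prs$gene_b
  swapped$gene_b <- prs$gene_a
  rev <- classifyBias(hebTest(atlasCounts(sp), atlasSamples(sp), swapped))
  expect_equal(rev$heb, -fwd$heb)
  expect_equal(rev$bias_class == "A", fwd$bias_class == "B")
  expect_equal(rev$bias_class == "balanced", fwd$bias_class == "balanced")
})

test_that("dominance labels follow the biased-tissue pattern", {
  mk <- function(pair, classes) data.frame(
    pair_id = pair, tissue = sprintf("t%02d", seq_along(classes)),
    heb = ifelse(classes == "A", 1, ifelse(classes == "B", -1, 0)),
    expressed = TRUE, bias_class = classes, stringsAsFactors = FALSE)
  rec <- rbind(
    mk("p1", c("A", "A", "A", rep("balanced", 7))),
    mk("p2", c("A", "B", rep("balanced", 8))),
    mk("p3", rep("balanced", 10)),
    mk("p4", c(rep("B", 10))))
  dom <- dominanceConsistency(rec)
  expect_equal(unname(dom$pair_labels[c("p1", "p2", "p3", "p4")]),
               c("consistent_A", "reversing", "never_biased",
                 "consistent_B"))
  expect_equal(dom$shares$consistent, 2 / 3)
  expect_equal(dom$shares$reversing, 1 / 3)
})

test_that("default atlas recovers the bias-direction and consistency structure", {
  cfg <- simConfig(seed = 66L, n_chromosome_pairs = 4L,
                   genes_per_chromosome = 375L, codons_per_gene = 100L,
                   fractionation_rate_A = 0, fractionation_rate_B = 0,
                   tandem_rate = 0, inversion_count = 0L)
  sp <- simulateProgenitors(cfg)
  sp <- simulateAtlas(cfg, sp)
  prs <- truthPairs(sp)
  rec <- classifyBias(hebTest(atlasCounts(sp), atlasSamples(sp), prs))
  sig <- rec$bias_class %in% c("A", "B")
  expect_lt(abs(mean(rec$bias_class[sig] == "B") - 0.56), 0.03)
  dom <- dominanceConsistency(
    rec, pair_chromosomes = setNames(sub("A$", "", prs$chromosome_a),
                                     prs$pair_id))
  # detected consistency exceeds the generator parameter slightly because
  # reversing pairs with undetected flipped tissues read as consistent
  expect_lt(abs(dom$shares$consistent - 0.869), 0.06)
  expect_equal(sum(dom$per_tissue[1, ]), nrow(prs))
  expect_equal(nrow(dom$per_chromosome), 4L)
})

test_that("kaksByHeb recovers planted omega strata and ignores flat ones", {
  set.seed(67)
  nt <- 10L
  n_per <- 300L
  mk_rec <- function(pair, n_biased) {
    cl <- c(rep("B", n_biased), rep("balanced", nt - n_biased))
    data.frame(pair_id = pair, tissue = sprintf("t%02d", 1:nt),
               heb = -1, expressed = TRUE, bias_class = cl,
               stringsAsFactors = FALSE)
  }
  pairs_all <- sprintf("a%03d", 1:n_per)
  pairs_none <- sprintf("n%03d", 1:n_per)
  rec <- rbind(
    do.call(rbind, lapply(pairs_all, mk_rec, n_biased = nt)),
    do.call(rbind, lapply(pairs_none, mk_rec, n_biased = 0L)))
  omega <- setNames(c(rlnorm(n_per, log(0.28), 0.3),
                      rlnorm(n_per, log(0.17), 0.3)),
                    c(pairs_all, pairs_none))
  res <- kaksByHeb(rec, omega)
  expect_lt(abs(res$median_omega[["all"]] - 0.28), 0.03)
  expect_lt(abs(res$median_omega[["none"]] - 0.17), 0.02)
  expect_lt(res$p_omega, 0.01)
  # shared omega across strata stays non-significant at alpha 0.01
  flat <- setNames(rlnorm(2 * n_per, log(0.2), 0.3),
                   c(pairs_all, pairs_none))
  expect_gt(kaksByHeb(rec, flat)$p_omega, 0.01)
  # identical omega everywhere: medians equal
  const <- setNames(rep(0.2, 2 * n_per), c(pairs_all, pairs_none))
  cres <- suppressWarnings(kaksByHeb(rec, const))
  expect_equal(unname(cres$median_omega[["all"]]),
               unname(cres$median_omega[["none"]]))
  # undersized strata are skipped with a warning
  expect_warning(kaksByHeb(rec[rec$pair_id %in% pairs_all[1:5] |
                                 rec$pair_id %in% pairs_none, ], omega),
                 "skipped")
})

test_that("size factors recover planted library depths", {
  set.seed(68)
  mu <- rlnorm(400, log(200), 0.8)
  sf_true <- c(0.6, 1, 1.4, 0.9, 1.1, 1.3)
  counts <- sapply(sf_true, function(s) rnbinom(400, mu = mu * s, size = 20))
  rownames(counts) <- sprintf("g%03d", 1:400)
  colnames(counts) <- sprintf("s%d", 1:6)
  sf <- sizeFactorsMOR(counts)
  sf_ref <- sf_true / exp(mean(log(sf_true)))
  expect_lt(max(abs(sf - sf_ref) / sf_ref), 0.1)
})
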