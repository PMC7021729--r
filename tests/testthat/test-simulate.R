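# Synthetic allopolyploid generator: divergence scaling, truth-table
# consistency, LTR ages, satellite lineages, atlas bias structure,
# determinism and degenerate configurations.

test_that("near-zero divergence time yields identical homoeolog pairs", {
  cfg <- smallConfig(seed = 21L, t_divergence = 2, t_merger = 1)
  sp <- simulateProgenitors(cfg)
  prs <- truthPairs(sp)
  ks <- vapply(seq_len(nrow(prs)), function(i)
    ng86(as.character(cdsSet(sp)[[prs$gene_a[i]]]),
         as.character(cdsSet(sp)[[prs$gene_b[i]]]))$Ks, numeric(1))
  expect_true(all(ks == 0))
})

test_that("default divergence scenario has median NG86 Ks near 2*mu*T = 0.15", {
  cfg <- simConfig(seed = 22L, n_chromosome_pairs = 2L,
                   genes_per_chromosome = 60L, codons_per_gene = 300L,
                   fractionation_rate_A = 0, fractionation_rate_B = 0,
                   tandem_rate = 0, inversion_count = 0L)
  sp <- simulateProgenitors(cfg)
  kk <- kaKs(truthPairs(sp), cdsSet(sp), align = FALSE)
  expect_lt(abs(median(kk$Ks) - 0.15) / 0.15, 0.1)
  expect_lt(abs(median(kk$omega, na.rm = TRUE) - 0.2), 0.07)
})

test_that("fractionation losses recount from the truth table and match the rate", {
  cfg <- simConfig(seed = 23L, n_chromosome_pairs = 4L,
                   genes_per_chromosome = 500L, codons_per_gene = 100L,
                   fractionation_rate_A = 0.02, fractionation_rate_B = 0.02,
                   tandem_rate = 0, inversion_count = 0L)
  sp <- simulateProgenitors(cfg)
  g <- truthGenes(sp)
  # Bernoulli-count oracle: direct recount per subgenome
  for (s in c("A", "B")) {
    lost <- sum(g$subgenome == s & g$status != "retained")
    n <- sum(g$subgenome == s & !g$is_tandem_copy)
    expect_equal(n, 2000L)
    expect_lt(abs(lost - n * 0.02), 3 * sqrt(n * 0.02 * 0.98) + 1)
    # cds holds exactly the retained genes
    expect_setequal(names(cdsSet(sp))[grepl(paste0("^g..", s), names(cdsSet(sp)))],
                    g$gene_id[g$subgenome == s & g$status == "retained"])
  }
  # pseudogene share of losses follows pseudogene_fraction
  lost_all <- g$status != "retained" & !g$is_tandem_copy
  expect_lt(abs(mean(g$status[lost_all] == "pseudogene") - 0.67), 0.2)
})

test_that("LTR paired divergence follows K = 2*mu*age including age zero", {
  fams <- data.frame(name = c("old", "young"),
                     subgenome = c("A", "shared"),
                     start_age = c(1.1e6, 0), end_age = c(1.1e6, 0),
                     copies = c(200L, 10L))
  cfg <- smallConfig(seed = 24L, ltr_families = fams)
  sp <- simulateProgenitors(cfg)
  sp <- suppressWarnings(simulateLtrLandscape(cfg, sp))
  el <- dateLtrElements(ltrElements(sp), ltrSequences(sp), mu = cfg@mu_ltr)
  young <- el[el$family == "young", ]
  expect_true(all(young$K == 0))
  old <- el[el$family == "old", ]
  # JC expectation of p-distance at 2*mu*T = 0.0286 is ~0.02833
  expect_lt(abs(mean(old$K) - 0.0286) / 0.0286, 0.1)
})

test_that("subgenome-restricted families active after the merger warn", {
  fams <- data.frame(name = "bad", subgenome = "A",
                     start_age = 9e5, end_age = 0, copies = 6L)
  cfg <- smallConfig(seed = 25L, ltr_families = fams)
  sp <- simulateProgenitors(cfg)
  expect_warning(simulateLtrLandscape(cfg, sp), "active after the merger")
  expect_silent(simulateLtrLandscape(cfg, sp, allow_recent_specific = TRUE))
})

test_that("satellite lineages share the monomer length but differ in composition", {
  sp <- cachedSmallSim()
  cm <- sp@satellites$clade_monomers
  expect_equal(unname(nchar(as.character(cm))), c(159L, 159L))
  d <- mean(strsplit(as.character(cm[["A"]]), "")[[1]] !=
              strsplit(as.character(cm[["B"]]), "")[[1]])
  expect_gt(d, 0.05)  # configured 10% split across two lineages
  arr <- satelliteArrays(sp)
  expect_true(all(arr$copy_number >= 30 & arr$copy_number <= 80))
  # truth recount: emitted copy numbers match the stored copies
  for (chr in arr$chromosome)
    expect_equal(length(satelliteMonomers(sp)[[chr]]),
                 arr$copy_number[arr$chromosome == chr])
})

test_that("atlas truth tables follow the configured bias structure", {
  cfg <- simConfig(seed = 26L, n_chromosome_pairs = 4L,
                   genes_per_chromosome = 500L, codons_per_gene = 100L,
                   fractionation_rate_A = 0, fractionation_rate_B = 0,
                   tandem_rate = 0, inversion_count = 0L)
  sp <- simulateProgenitors(cfg)
  sp <- simulateAtlas(cfg, sp)
  tr <- atlasTruth(sp)
  n <- nrow(tr)
  expect_equal(n, 2000L)
  expect_lt(abs(mean(tr$biased) - 0.658), 3 * sqrt(0.658 * 0.342 / n))
  bi <- tr[tr$biased, ]
  expect_lt(abs(mean(bi$direction == "B") - 0.56),
            3 * sqrt(0.56 * 0.44 / nrow(bi)))
  expect_lt(abs(mean(bi$consistent) - 0.869),
            3 * sqrt(0.869 * 0.131 / nrow(bi)))
  # per-tissue truth is internally consistent with the per-pair table
  tt <- sp@atlas$truth_tissues
  per_pair <- tapply(tt$true_dir != "none", tt$pair_id, any)
  expect_equal(as.vector(per_pair[tr$pair_id]), tr$biased)
  cons_rec <- tapply(tt$true_dir, tt$pair_id, function(d)
    length(unique(d[d != "none"])) <= 1L)
  expect_true(all(cons_rec[tr$pair_id[tr$biased & tr$consistent]]))
  expect_true(all(!cons_rec[tr$pair_id[tr$biased & !tr$consistent]]))
  # counts are non-negative integers
  expect_true(all(atlasCounts(sp) >= 0))
  expect_true(all(atlasCounts(sp) == round(atlasCounts(sp))))
})

test_that("frac_biased = 0 yields a bias-free truth table", {
  cfg <- smallConfig(seed = 27L, atlas = atlasSpec(frac_biased = 0))
  sp <- simulateProgenitors(cfg)
  sp <- simulateAtlas(cfg, sp)
  expect_equal(sum(atlasTruth(sp)$biased), 0L)
  expect_error(simulateAtlas(smallConfig(seed = 27L,
                                         atlas = atlasSpec(dispersion = 0)),
                             sp))
})

test_that("identical seeds reproduce identical outputs", {
  cfg <- smallConfig(seed = 28L)
  a <- simulatePolyploid(cfg)
  b <- simulatePolyploid(cfg)
  expect_identical(as.character(cdsSet(a)), as.character(cdsSet(b)))
  expect_identical(truthGenes(a), truthGenes(b))
  expect_identical(ltrElements(a)$age, ltrElements(b)$age)
  expect_identical(as.character(ltrSequences(a)),
                   as.character(ltrSequences(b)))
  expect_identical(atlasCounts(a), atlasCounts(b))
  expect_identical(as.character(sp_mono_a <- satelliteMonomers(a)[["1A"]]),
                   as.character(satelliteMonomers(b)[["1A"]]))
})

test_that("degenerate configurations are rejected", {
  expect_error(simConfig(n_chromosome_pairs = 0), "degenerate")
  expect_error(simConfig(genes_per_chromosome = 0), "degenerate")
  expect_error(simConfig(codons_per_gene = 50), "codons_per_gene")
  expect_error(simConfig(t_divergence = 1e6, t_merger = 2e6), "younger")
  expect_error(simConfig(satellite_monomer_length = 10), "monomer")
  expect_error(simConfig(tandem_max_copies = 20), "tandem_max_copies")
  bad_fam <- data.frame(name = "x", subgenome = "A",
                        start_age = 1e5, end_age = 2e5, copies = 5L)
  expect_error(simConfig(ltr_families = bad_fam), "start_age")
})
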