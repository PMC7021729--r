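#' Percent repeat-content excess of one subgenome over the other
#'
#' @param mb_a,mb_b repetitive-sequence totals (Mb) for the two subgenomes.
#' @return percentage by which A exceeds B: \code{(mb_a - mb_b)/mb_b * 100}.
#' @examples
#' repeatExcessPercent(87.5, 64.9)   # ~35
#' @export
repeatExcessPercent <- function(mb_a, mb_b) {
  if (mb_b <= 0) stop("reference total must be > 0")
  (mb_a - mb_b) / mb_b * 100
}

#' Run the full subgenome-dynamics pipeline on a simulated genome
#'
#' Chains every stage on a freshly simulated allotetraploid: simulation,
#' satellite consensus and subgenome phasing, LTR dating with the
#' polyploidy bracket, homology search, block chaining and 1:1 homoeolog
#' pairing, tandem arrays, retention and fractionation, NG86 Ka/Ks with the
#' Ks distribution and divergence time, the windowed-Ks exchange scan, and
#' homoeolog expression bias with dominance consistency, then consolidates
#' a summary block (divergence time, polyploidy bracket, retention
#' fraction, fractionation p, bias shares, consistency share, repeat
#' excess).
#'
#' @param config a [SimConfig-class].
#' @param outdir optional directory; when given, the simulated bundle and a
#'   JSON report are written there.
#' @param align_kaks protein-align pairs before NG86 (slower; positional
#'   pairing is exact for the indel-free simulator output).
#' @param verbose print stage progress to stderr.
#' @return list with \code{stages} (per-stage results) and \code{summary}.
#' @export
runPipeline <- function(config, outdir = NULL, align_kaks = FALSE,
                        verbose = TRUE) {
  say <- function(...) if (verbose) message("[polysub] ", ...)

  say("stage 1/7: simulate")
  sp <- simulatePolyploid(config)
  genes <- truthGenes(sp)
  tp <- truthPairs(sp)

  say("stage 2/7: satellite phasing")
  cons <- vapply(satelliteMonomers(sp), consensusMonomer, character(1))
  chrom_pairs <- data.frame(
    a = sort(unique(genes$chromosome[genes$subgenome == "A"])),
    b = sort(unique(genes$chromosome[genes$subgenome == "B"])))
  phasing <- phaseSubgenomes(cons, homoeolog_pairs = chrom_pairs)
  truth_sub <- setNames(
    substr(names(cons), nchar(names(cons)), nchar(names(cons))),
    names(cons))
  phase_acc <- max(mean(phasing@assignments == truth_sub),
                   mean(phasing@assignments != truth_sub))

  say("stage 3/7: LTR dating")
  el <- ltrElements(sp)
  el$subgenome <- unname(phasing@assignments[el$chromosome])
  el <- dateLtrElements(el, ltrSequences(sp), mu = config@mu_ltr)
  fams <- classifyFamilySpecificity(el)
  bracket <- bracketPolyploidy(el, fams, mu = config@mu_ltr)

  say("stage 4/7: synteny and homoeolog pairing")
  ret_genes <- genes[genes$status == "retained", ]
  idsA <- ret_genes$gene_id[ret_genes$subgenome == "A"]
  idsB <- ret_genes$gene_id[ret_genes$subgenome == "B"]
  orders <- data.frame(gene_id = ret_genes$gene_id,
                       chromosome = ret_genes$chromosome,
                       rank = ret_genes$rank)
  hits <- findHomologyPairs(cdsSet(sp)[idsA], cdsSet(sp)[idsB])
  chain <- chainBlocks(hits, orders)
  pairs <- resolveHomoeologPairs(chain)
  primaryA <- ret_genes$gene_id[ret_genes$subgenome == "A" &
                                  !ret_genes$is_tandem_copy]
  pseudo_partner <- vapply(primaryA, function(id) {
    pid <- genes$pair_id[genes$gene_id == id]
    any(genes$pair_id == pid & genes$subgenome == "B" &
          genes$status == "pseudogene", na.rm = TRUE)
  }, logical(1))
  retention <- classifyRetention(pairs, primaryA,
                                 primaryA[pseudo_partner])
  lossA <- sum(genes$subgenome == "A" & genes$status != "retained")
  lossB <- sum(genes$subgenome == "B" & genes$status != "retained")
  fract <- testBiasedFractionation(lossA, lossB)

  say("stage 5/7: Ka/Ks")
  kk <- kaKs(pairs, cdsSet(sp), align = align_kaks)
  ksd <- ksDistribution(kk$Ks)
  div_time <- ksToTime(ksd$median, mu = config@mu_neutral)

  say("stage 6/7: homoeologous-exchange scan")
  scan_in <- data.frame(chromosome = kk$chr_a, rank = kk$rank_a, Ks = kk$Ks)
  scan <- suppressWarnings(scanHomoeologousExchange(scan_in))

  say("stage 7/7: expression bias")
  heb_pairs <- tp[tp$gene_a %in% rownames(atlasCounts(sp)) &
                    tp$gene_b %in% rownames(atlasCounts(sp)), ]
  rec <- classifyBias(hebTest(atlasCounts(sp), atlasSamples(sp), heb_pairs))
  pair_chr <- setNames(sub("A$", "", heb_pairs$chromosome_a),
                       heb_pairs$pair_id)
  dom <- dominanceConsistency(rec, pair_chromosomes = pair_chr)
  omega <- setNames(kk$omega, kk$gene_a)
  pair_omega <- setNames(
    omega[heb_pairs$gene_a], heb_pairs$pair_id)
  kbh <- tryCatch(
    suppressWarnings(kaksByHeb(rec, pair_omega,
                               ks = setNames(kk$Ks[match(heb_pairs$gene_a,
                                                         kk$gene_a)],
                                             heb_pairs$pair_id))),
    error = function(e) NULL)

  sig <- rec$bias_class %in% c("A", "B")
  # repeat content per subgenome (LTR elements + satellite arrays), Mb
  el_len <- 2 * config@ltr_length + .LTR_INTERNAL
  rep_mb <- vapply(c("A", "B"), function(s) {
    ltr_bp <- sum(el$subgenome == s, na.rm = TRUE) * el_len
    arr <- satelliteArrays(sp)
    sat_bp <- sum(arr$copy_number[arr$clade == s] * arr$monomer_length[1])
    (ltr_bp + sat_bp) / 1e6
  }, numeric(1))

  summary <- list(
    subgenome_divergence_myr = div_time / 1e6,
    polyploidy_myr = bracket$estimate / 1e6,
    polyploidy_raw_min_myr = bracket$raw_min / 1e6,
    median_ks = ksd$median,
    ks_peaks = ksd$n_peaks,
    phasing_accuracy = phase_acc,
    n_homoeolog_pairs = nrow(pairs),
    retention_fraction = retention$summary$fraction_retained,
    fractionation_p = fract$p,
    n_exchange_windows_flagged = sum(scan$flagged),
    bias_share_B_significant = mean(rec$bias_class[sig] == "B"),
    bias_share_B_point = mean(rec$heb[rec$expressed] < 0),
    consistency_share = dom$shares$consistent,
    repeat_mb_A = rep_mb[["A"]], repeat_mb_B = rep_mb[["B"]],
    repeat_excess_percent = repeatExcessPercent(rep_mb[["A"]],
                                                rep_mb[["B"]]))

  report <- list(
    stages = list(
      simulate = list(config_seed = config@seed,
                      n_genes = nrow(genes), n_truth_pairs = nrow(tp)),
      satellites = list(phasing = phasing, consensuses = cons),
      ltr = list(elements = el, families = fams, bracket = bracket),
      synteny = list(blocks = chain$blocks, pairs = pairs,
                     retention = retention$summary,
                     fractionation = fract),
      kaks = list(pairs = kk, distribution = ksd[c("median", "n_peaks",
                                                   "peaks")]),
      he_scan = list(windows = scan),
      heb = list(records = rec, dominance = dom[c("shares", "per_tissue",
                                                  "per_chromosome")],
                 kaks_by_heb = kbh)),
    summary = summary)

  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    writeSimulatedPolyploid(sp, file.path(outdir, "sim"))
    jsonlite::write_json(summary, file.path(outdir, "report.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  say("done; divergence ", sprintf("%.2f", summary$subgenome_divergence_myr),
      " Myr, polyploidy ", sprintf("%.2f", summary$polyploidy_myr), " Myr")
  report
}

#' Validate input files for format well-formedness
#'
#' Diagnoses (never mutates): FASTA readability and unique ids, GFF3
#' 9-column structure with 1-based coordinates and end >= start, BED
#' 0-based half-open intervals, counts/sample-sheet cross references.
#'
#' @param paths named list with any of \code{fasta}, \code{gff3},
#'   \code{bed}, \code{counts}, \code{samples} (file paths).
#' @return data.frame of issues: \code{file}, \code{check}, \code{message};
#'   zero rows means a clean bundle.
#' @export
validateInputs <- function(paths) {
  issues <- list()
  add <- function(file, check, message)
    issues[[length(issues) + 1L]] <<- data.frame(
      file = file, check = check, message = message,
      stringsAsFactors = FALSE)

  for (f in paths$fasta) {
    x <- tryCatch(Biostrings::readDNAStringSet(f), error = function(e) e)
    if (inherits(x, "error")) add(f, "fasta", conditionMessage(x))
    else if (anyDuplicated(names(x))) add(f, "fasta", "duplicate sequence ids")
  }
  for (f in paths$gff3) {
    g <- tryCatch(read.table(f, sep = "\t", comment.char = "#",
                             quote = "", stringsAsFactors = FALSE),
                  error = function(e) e)
    if (inherits(g, "error")) { add(f, "gff3", conditionMessage(g)); next }
    if (ncol(g) != 9L) add(f, "gff3", "expected 9 tab-separated columns")
    else {
      if (any(g[[5]] < g[[4]])) add(f, "gff3", "feature end < start")
      if (any(g[[4]] < 1L)) add(f, "gff3", "start < 1 (GFF3 is 1-based)")
    }
  }
  for (f in paths$bed) {
    b <- tryCatch(read.table(f, sep = "\t", stringsAsFactors = FALSE),
                  error = function(e) e)
    if (inherits(b, "error")) { add(f, "bed", conditionMessage(b)); next }
    if (ncol(b) < 3L) add(f, "bed", "fewer than 3 columns")
    else {
      if (any(b[[3]] <= b[[2]])) add(f, "bed", "end <= start (half-open)")
      if (any(b[[2]] < 0L)) add(f, "bed", "start < 0")
    }
  }
  cts <- NULL
  if (!is.null(paths$counts)) {
    f <- paths$counts
    cts <- tryCatch(read.table(f, sep = "\t", header = TRUE,
                               check.names = FALSE,
                               stringsAsFactors = FALSE),
                    error = function(e) e)
    if (inherits(cts, "error")) { add(f, "counts", conditionMessage(cts))
      cts <- NULL
    } else {
      num <- cts[, -1, drop = FALSE]
      if (!all(vapply(num, is.numeric, logical(1))))
        add(f, "counts", "non-numeric count columns")
      else if (any(num < 0)) add(f, "counts", "negative counts")
    }
  }
  if (!is.null(paths$samples)) {
    f <- paths$samples
    ss <- tryCatch(read.table(f, sep = "\t", header = TRUE,
                              stringsAsFactors = FALSE),
                   error = function(e) e)
    if (inherits(ss, "error")) add(f, "samples", conditionMessage(ss))
    else {
      need <- c("sample", "tissue", "rep")
      if (!all(need %in% names(ss)))
        add(f, "samples", paste("missing columns:",
                                paste(setdiff(need, names(ss)),
                                      collapse = ", ")))
      else if (!is.null(cts) && !inherits(cts, "error")) {
        missing_cols <- setdiff(ss$sample, colnames(cts)[-1])
        if (length(missing_cols))
          add(f, "cross", paste("sample sheet entries missing from counts:",
                                paste(head(missing_cols, 5),
                                      collapse = ", ")))
      }
    }
  }
  if (!length(issues))
    return(data.frame(file = character(), check = character(),
                      message = character()))
  do.call(rbind, issues)
}
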