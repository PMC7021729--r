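#' Divergence between the two terminal repeats of an LTR element
#'
#' The two LTRs are identical at insertion, so their divergence K dates the
#' element.  The repeats are globally aligned (match 1, mismatch -1, gap
#' open 4, gap extend 1) and K is the raw proportion of mismatched columns
#' among aligned non-gap columns ("percent identity" distance); an optional
#' Jukes-Cantor correction is available for sensitivity analysis.
#'
#' @param ltr5,ltr3 the two terminal repeat sequences (character or
#'   [Biostrings::DNAString]).
#' @param jc_correct apply \code{-3/4 log(1 - 4K/3)}.
#' @param min_coverage minimum fraction of the shorter repeat that must be
#'   aligned; below it the element is flagged non-intact.
#' @return list: \code{K}, \code{aligned_columns}, \code{coverage},
#'   \code{intact}.
#' @examples
#' ltrDivergence(strrep("ACGT", 100), strrep("ACGT", 100))$K  # 0
#' @export
ltrDivergence <- function(ltr5, ltr3, jc_correct = FALSE,
                          min_coverage = 0.5) {
  a <- as.character(ltr5)
  b <- as.character(ltr3)
  if (!nchar(a) || !nchar(b)) stop("empty LTR sequence")
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1)
  pa <- Biostrings::pairwiseAlignment(Biostrings::DNAString(a),
                                      Biostrings::DNAString(b),
                                      substitutionMatrix = mat,
                                      gapOpening = 4, gapExtension = 1,
                                      type = "global")
  pat <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  sub <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  keep <- pat != "-" & sub != "-"
  ncol_aln <- sum(keep)
  coverage <- ncol_aln / min(nchar(a), nchar(b))
  K <- if (ncol_aln) mean(pat[keep] != sub[keep]) else NA_real_
  if (jc_correct && !is.na(K) && K < 0.75) K <- -0.75 * log(1 - 4 * K / 3)
  list(K = K, aligned_columns = ncol_aln, coverage = coverage,
       intact = is.finite(K) && coverage >= min_coverage)
}

#' Insertion time from paired-LTR divergence
#'
#' \code{T = K / (2 * mu)}.
#'
#' @param K divergence proportion (>= 0).
#' @param mu substitutions per site per year (> 0); the conventional grass value for LTR
#'   sequences is 1.3e-8.
#' @return years.
#' @examples
#' insertionTime(0.0286, 1.3e-8)  # 1.1e6
#' @export
insertionTime <- function(K, mu = 1.3e-8) {
  if (any(mu <= 0)) stop("mu must be > 0")
  if (any(K < 0, na.rm = TRUE)) stop("K must be >= 0")
  K / (2 * mu)
}

#' Date all elements of an LTR table
#'
#' Convenience wrapper: computes K and insertion time for every element from
#' a paired-LTR sequence set with ids \code{<element>_5p} / \code{<element>_3p}.
#'
#' @param elements data.frame with at least \code{element_id}; columns
#'   \code{family}, \code{chromosome}, \code{subgenome} are carried through.
#' @param ltr_seqs named [Biostrings::DNAStringSet].
#' @param mu substitution rate per site per year.
#' @param jc_correct see [ltrDivergence()].
#' @return \code{elements} with \code{K}, \code{insertion_time},
#'   \code{intact} columns filled.
#' @export
dateLtrElements <- function(elements, ltr_seqs, mu = 1.3e-8,
                            jc_correct = FALSE) {
  stopifnot("element_id" %in% names(elements))
  n <- nrow(elements)
  K <- numeric(n)
  intact <- logical(n)
  for (i in seq_len(n)) {
    id <- elements$element_id[i]
    d <- ltrDivergence(ltr_seqs[[paste0(id, "_5p")]],
                       ltr_seqs[[paste0(id, "_3p")]],
                       jc_correct = jc_correct)
    K[i] <- d$K
    intact[i] <- d$intact
  }
  elements$K <- K
  elements$insertion_time <- insertionTime(K, mu)
  elements$intact <- intact
  attr(elements, "ltr_length") <- round(median(vapply(
    seq_len(n), function(i)
      nchar(as.character(ltr_seqs[[paste0(elements$element_id[i], "_5p")]])),
    numeric(1))))
  elements
}

#' Classify LTR families as subgenome-specific or shared
#'
#' Families with fewer than \code{min_copies} intact elements are dropped.
#' A family is subgenome-specific when every intact element lies on the same
#' subgenome.
#'
#' @param elements data.frame with \code{family}, \code{subgenome},
#'   \code{intact} and \code{insertion_time} columns (see
#'   [dateLtrElements()]).
#' @param min_copies minimum intact copies per family (default 5).
#' @return data.frame, one row per retained family: \code{family},
#'   \code{n_intact}, \code{specificity} (\code{"A-specific"},
#'   \code{"B-specific"}, \code{"shared"}), insertion-time quartiles,
#'   \code{min_insertion_time}.
#' @export
classifyFamilySpecificity <- function(elements, min_copies = 5L) {
  need <- c("family", "subgenome", "intact", "insertion_time")
  if (!all(need %in% names(elements)))
    stop("elements must carry columns: ", paste(need, collapse = ", "))
  if (anyNA(elements$subgenome))
    stop("elements lacking subgenome labels; run phasing first")
  el <- elements[elements$intact, ]
  fams <- split(el, el$family)
  rows <- lapply(fams, function(f) {
    if (nrow(f) < min_copies) return(NULL)
    subs <- unique(f$subgenome)
    spec <- if (length(subs) == 1L) paste0(subs, "-specific") else "shared"
    q <- quantile(f$insertion_time, c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(family = f$family[1], n_intact = nrow(f), specificity = spec,
               q25 = q[1], median = q[2], q75 = q[3],
               min_insertion_time = min(f$insertion_time),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(family = character(), n_intact = integer(),
                      specificity = character(), q25 = numeric(),
                      median = numeric(), q75 = numeric(),
                      min_insertion_time = numeric())
  rownames(out) <- NULL
  out
}

#' Bracket the polyploidy event from subgenome-specific families
#'
#' Subgenome-specific families were only active while the progenitors
#' evolved independently, so their youngest insertions bound the merger from
#' above.  The raw per-element minimum insertion time is dominated by
#' measurement noise on K (the binomial sampling error
#' \code{sqrt(K(1-K)/L)} on an L-bp repeat translates to hundreds of kyr),
#' so by default the truncation point of the pooled insertion-age
#' distribution is estimated by deconvolution under the exact binomial
#' observation model \code{K*L ~ Binomial(L, 3/4(1 - exp(-8 mu a / 3)))}.
#' Because the age density just above the truncation point is unknown, two
#' limiting edge shapes are fitted -- ages uniform above the floor (flat
#' edge; biases the floor down when the density rises) and exponentially
#' decaying from the floor with the decay rate estimated from the upper tail
#' (maximal edge concentration; biases it up) -- and the midpoint is
#' reported as the estimate with the two fits as an explicit bracket.
#'
#' @param elements dated element table ([dateLtrElements()]).
#' @param reports family table ([classifyFamilySpecificity()]).
#' @param mu substitution rate used for dating (per site per year).
#' @param method \code{"deconvolution"} (default) or \code{"minimum"} (the
#'   naive youngest-element rule; appropriate when K values are effectively
#'   noise-free).
#' @param ltr_length repeat length L in bp used for the binomial model;
#'   defaults to the \code{ltr_length} attribute set by [dateLtrElements()].
#' @return list: \code{estimate} (years; \code{NA} when undetermined),
#'   \code{independence_floor} (= estimate), \code{floor_lower},
#'   \code{floor_upper} (the two limiting fits), \code{raw_min},
#'   \code{determined}, \code{evidence} (specific-family table), and
#'   \code{youngest_shared_activity} for context.
#' @export
bracketPolyploidy <- function(elements, reports, mu = 1.3e-8,
                              method = c("deconvolution", "minimum"),
                              ltr_length = NULL) {
  method <- match.arg(method)
  spec <- reports[reports$specificity != "shared", , drop = FALSE]
  shared <- reports[reports$specificity == "shared", , drop = FALSE]
  youngest_shared <- if (nrow(shared)) min(shared$min_insertion_time) else NA_real_
  if (!nrow(spec))
    return(list(estimate = NA_real_, independence_floor = NA_real_,
                floor_lower = NA_real_, floor_upper = NA_real_,
                raw_min = NA_real_, determined = FALSE,
                evidence = spec, youngest_shared_activity = youngest_shared))
  el <- elements[elements$intact & elements$family %in% spec$family, ]
  raw_min <- min(el$insertion_time)
  if (is.null(ltr_length)) ltr_length <- attr(elements, "ltr_length")

  if (method == "minimum" || nrow(el) < 30L || is.null(ltr_length)) {
    return(list(estimate = raw_min, independence_floor = raw_min,
                floor_lower = raw_min, floor_upper = raw_min,
                raw_min = raw_min, determined = TRUE, evidence = spec,
                youngest_shared_activity = youngest_shared))
  }

  fl <- ageFloorDeconvolution(round(el$K * ltr_length), ltr_length, mu)
  list(estimate = fl[["mid"]], independence_floor = fl[["mid"]],
       floor_lower = fl[["lo"]], floor_upper = fl[["hi"]],
       raw_min = raw_min, determined = TRUE, evidence = spec,
       youngest_shared_activity = youngest_shared)
}

# Truncation-point deconvolution for insertion ages observed through
# binomial divergence sampling: k mismatches over L sites, expected
# proportion p(a) = 3/4 (1 - exp(-8 mu a / 3)) for an element of age a.
# Returns the flat-edge fit (lo), the exponential-edge fit (hi) and their
# midpoint (mid).
ageFloorDeconvolution <- function(k, L, mu) {
  p_of_a <- function(a) 0.75 * (1 - exp(-8 * mu * a / 3))
  tt <- (k / L) / (2 * mu)
  dmean <- function(agrid) {
    dm <- vapply(p_of_a(agrid), function(p) dbinom(k, L, p),
                 numeric(length(k)))
    rowMeans(dm)
  }
  # flat edge: ages ~ Uniform(F, F + w)
  nllU <- function(par) {
    F <- max(par[1], 0)
    w <- exp(pmin(par[2], 16))
    -sum(log(pmax(dmean(seq(F, F + w, length.out = 150)), 1e-300)))
  }
  q <- quantile(tt, c(0.05, 0.95), names = FALSE)
  lo <- max(optim(c(q[1], log(max(q[2] - q[1], 2e5))), nllU,
                  method = "Nelder-Mead",
                  control = list(maxit = 2000))$par[1], 0)
  # exponential edge: decay rate from the upper tail where blur is small,
  # then a one-dimensional profile over the floor
  q2 <- quantile(tt, c(0.3, 0.95), names = FALSE)
  r <- 1 / max(mean(tt[tt >= q2[1] & tt <= q2[2]]) - q2[1], 1e5)
  nllE <- function(F) {
    agrid <- F + qexp(seq(0.0025, 0.9975, length.out = 200), r)
    -sum(log(pmax(dmean(agrid), 1e-300)))
  }
  hi <- optimize(nllE, interval = c(max(min(tt) - 5e5, 0),
                                    quantile(tt, 0.5, names = FALSE)))$minimum
  c(lo = lo, hi = hi, mid = (lo + hi) / 2)
}
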