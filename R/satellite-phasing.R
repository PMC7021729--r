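# Satellite detection, consensus building and subgenome phasing.
#
# Monomers are handled as integer base vectors internally; rotation
# (register) alignment is circular Hamming minimisation.

# all circular rotations of 1..L as an index matrix (rotation k in row k+1)
.rotationIndex <- function(L) {
  outer(0:(L - 1), 0:(L - 1), function(k, j) ((j + k) %% L) + 1L)
}

# best rotation of v against ref: minimal Hamming distance, ties broken by
# the smallest rotation offset
.bestRotation <- function(v, ref, rot_idx = .rotationIndex(length(v))) {
  mism <- rowSums(matrix(v[t(rot_idx)], nrow = nrow(rot_idx),
                         byrow = TRUE) != rep(ref, each = nrow(rot_idx)))
  # matrix above: row k = v rotated by k-1
  which.min(mism) - 1L
}

.rotate <- function(v, k) {
  L <- length(v)
  if (k == 0L) return(v)
  v[((seq_len(L) - 1L + k) %% L) + 1L]
}

#' Detect tandem repeat arrays by periodicity scoring
#'
#' For every candidate period p, the fraction of positions matching their
#' p-shifted neighbour is computed and maximised over sliding windows of
#' 4p bp (k-mer-free offset autocorrelation).  The reported period is the
#' smallest candidate scoring within 95\% of the best, which suppresses
#' period multiples; array extent is the maximal run where the local match
#' fraction stays above the detection threshold.
#'
#' @param sequence a [Biostrings::DNAString], character string, or named
#'   [Biostrings::DNAStringSet] (then all entries are scanned and a
#'   \code{chromosome} column is added).
#' @param min_period,max_period period search range in bp.
#' @param min_copies minimum copies for a reported array.
#' @param min_score windowed match fraction required to call an array
#'   (random sequence scores ~0.25).
#' @return data.frame with \code{start0}, \code{end0} (0-based half-open),
#'   \code{period}, \code{copy_number}, \code{score}; zero rows when
#'   nothing periodic is found.
#' @export
detectTandemRepeats <- function(sequence, min_period = 20L,
                                max_period = 400L, min_copies = 5L,
                                min_score = 0.7) {
  if (is(sequence, "DNAStringSet") ||
      (is.character(sequence) && length(sequence) > 1L)) {
    nm <- names(sequence)
    if (is.null(nm)) nm <- as.character(seq_along(sequence))
    out <- lapply(seq_along(sequence), function(i) {
      r <- detectTandemRepeats(sequence[[i]], min_period, max_period,
                               min_copies, min_score)
      if (nrow(r)) cbind(chromosome = nm[i], r) else r
    })
    out <- out[vapply(out, nrow, integer(1)) > 0L]
    if (!length(out))
      return(data.frame(chromosome = character(), start0 = integer(),
                        end0 = integer(), period = integer(),
                        copy_number = integer(), score = numeric()))
    return(do.call(rbind, out))
  }

  s <- dnaToInt(sequence)
  n <- length(s)
  if (n <= 2L * min_period) stop("sequence shorter than 2 x min_period")
  empty <- data.frame(start0 = integer(), end0 = integer(),
                      period = integer(), copy_number = integer(),
                      score = numeric())
  max_period <- min(max_period, floor((n - 1) / 2))

  periods <- min_period:max_period
  best_win <- numeric(length(periods))
  for (ii in seq_along(periods)) {
    p <- periods[ii]
    d <- s[seq_len(n - p)] == s[(p + 1L):n]
    W <- min(4L * p, length(d))
    cs <- c(0, cumsum(d))
    best_win[ii] <- max((cs[(W + 1L):length(cs)] -
                           cs[seq_len(length(cs) - W)]) / W)
  }
  if (max(best_win) < min_score) return(empty)
  cand <- periods[best_win >= 0.95 * max(best_win) & best_win >= min_score]
  p <- min(cand)
  score <- best_win[periods == p]

  # array extent: runs where the 2p-smoothed match profile stays high
  d <- s[seq_len(n - p)] == s[(p + 1L):n]
  W <- min(2L * p, length(d))
  cs <- c(0, cumsum(d))
  sm <- (cs[(W + 1L):length(cs)] - cs[seq_len(length(cs) - W)]) / W
  thr <- (0.25 + score) / 2
  hi <- sm >= thr
  if (!any(hi)) return(empty)
  r <- rle(hi)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  rows <- lapply(runs, function(k) {
    a0 <- starts[k] - 1L               # 0-based window start
    b0 <- min(ends[k] + W + p, n)      # matched offset reaches p further
    width <- b0 - a0
    if (width < min_copies * p) return(NULL)
    data.frame(start0 = a0, end0 = b0, period = p,
               copy_number = as.integer(floor(width / p)), score = score)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Majority-rule consensus of satellite monomer copies
#'
#' Copies are phase-aligned by circular rotation against the first copy
#' (minimal Hamming distance, ties to the smallest offset), then each
#' column's majority base is taken; ties are broken in the fixed base order
#' A < C < G < T.
#'
#' @param copies [Biostrings::DNAStringSet] or character vector of monomer
#'   copies (at least 2).
#' @param max_copies cap on copies used (evenly subsampled above it).
#' @return consensus as a character string.
#' @export
consensusMonomer <- function(copies, max_copies = 200L) {
  copies <- as.character(copies)
  if (length(copies) < 2L) stop("need at least 2 copies")
  lens <- nchar(copies)
  if (max(lens) > 1.2 * min(lens))
    stop("copy lengths differ by more than 20%")
  Lmode <- as.integer(names(sort(table(lens), decreasing = TRUE))[1])
  copies <- copies[lens == Lmode]
  if (length(copies) > max_copies)
    copies <- copies[round(seq(1, length(copies), length.out = max_copies))]
  M <- do.call(rbind, lapply(copies, dnaToInt))
  L <- ncol(M)
  rot_idx <- .rotationIndex(L)
  ref <- M[1, ]
  for (i in seq_len(nrow(M))[-1]) {
    k <- .bestRotation(M[i, ], ref, rot_idx)
    M[i, ] <- .rotate(M[i, ], k)
  }
  cnt <- vapply(1:4, function(b) colSums(M == b), numeric(L))
  maj <- apply(cnt, 1L, which.max)   # which.max ties -> first = A<C<G<T
  intToDna(maj)
}

#' Phase chromosomes into subgenomes from satellite consensus monomers
#'
#' Pairwise circular p-distances between per-chromosome consensus monomers
#' feed a neighbor-joining tree; the internal edge whose bipartition
#' maximises the between/within mean-distance ratio defines the two clades
#' (a midpoint-like best-split rooting -- the true outgroup is unknown).
#' Clade labels are deterministic: the clade holding the lexicographically
#' smallest chromosome id is called A.  Support is the proportion of
#' monomer-column bootstrap replicates whose best split recovers each clade.
#'
#' @param consensuses named character vector or [Biostrings::DNAStringSet]
#'   of equal-length consensus monomers, one per chromosome (>= 4).
#' @param homoeolog_pairs optional two-column data.frame of candidate
#'   homoeologous chromosome pairs; phasing is checked to place one member
#'   of each pair in each clade.
#' @param n_boot bootstrap replicates (default 100).
#' @return a [PhasingResult-class].
#' @export
phaseSubgenomes <- function(consensuses, homoeolog_pairs = NULL,
                            n_boot = 100L) {
  cons <- if (is.character(consensuses)) consensuses
          else as.character(consensuses)
  if (length(cons) < 4L) stop("need at least 4 consensus monomers")
  if (is.null(names(cons)) || anyDuplicated(names(cons)))
    stop("consensuses must carry unique chromosome names")
  lens <- nchar(cons)
  if (max(lens) > 1.2 * min(lens))
    stop("consensus lengths differ by more than 20%")
  if (length(unique(lens)) > 1L)
    stop("consensus monomers must have equal length for column bootstrap")
  n <- length(cons)
  L <- lens[1]
  M <- do.call(rbind, lapply(cons, dnaToInt))
  rot_idx <- .rotationIndex(L)

  # register all monomers against the first, then exact circular p-distance
  for (i in seq_len(n)[-1])
    M[i, ] <- .rotate(M[i, ], .bestRotation(M[i, ], M[1, ], rot_idx))
  D <- matrix(0, n, n, dimnames = list(names(cons), names(cons)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      mism <- rowSums(matrix(M[j, ][t(rot_idx)], nrow = L, byrow = TRUE) !=
                        rep(M[i, ], each = L))
      D[i, j] <- D[j, i] <- min(mism) / L
    }
  }

  split_of <- function(Dm) {
    tr <- ape::nj(stats::as.dist(Dm))
    ntip <- length(tr$tip.label)
    internal <- which(tr$edge[, 2] > ntip)
    best <- NULL
    best_ratio <- -Inf
    for (e in internal) {
      tips <- .tipsBelow(tr, tr$edge[e, 2])
      if (length(tips) < 2L || length(tips) > ntip - 2L) next
      a <- tr$tip.label[tips]
      b <- setdiff(tr$tip.label, a)
      wb <- c(Dm[a, a][upper.tri(diag(length(a)))],
              Dm[b, b][upper.tri(diag(length(b)))])
      bt <- as.vector(Dm[a, b])
      ratio <- mean(bt) / max(mean(wb), .Machine$double.eps)
      if (ratio > best_ratio) {
        best_ratio <- ratio
        best <- list(a = sort(a), b = sort(b), ratio = ratio,
                     within = mean(wb), between = mean(bt), tree = tr)
      }
    }
    best
  }

  best <- split_of(D)
  if (is.null(best) || !is.finite(best$ratio) || best$ratio <= 1)
    stop("unresolvable phasing: between-clade distance does not exceed ",
         "within-clade distance")

  first <- sort(names(cons))[1]
  cladeA <- if (first %in% best$a) best$a else best$b
  cladeB <- setdiff(names(cons), cladeA)
  assignments <- setNames(ifelse(names(cons) %in% cladeA, "A", "B"),
                          names(cons))

  # column bootstrap on the registered monomer matrix
  hitsA <- 0L
  hitsB <- 0L
  for (b in seq_len(n_boot)) {
    cols <- sample.int(L, L, replace = TRUE)
    Mb <- M[, cols, drop = FALSE]
    Db <- matrix(0, n, n, dimnames = dimnames(D))
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        Db[i, j] <- Db[j, i] <- mean(Mb[i, ] != Mb[j, ])
      }
    }
    sb <- tryCatch(split_of(Db), error = function(e) NULL)
    if (is.null(sb)) next
    if (identical(sb$a, sort(cladeA)) || identical(sb$b, sort(cladeA)))
      hitsA <- hitsA + 1L
    if (identical(sb$a, sort(cladeB)) || identical(sb$b, sort(cladeB)))
      hitsB <- hitsB + 1L
  }

  diagnostics <- list(within_mean = best$within, between_mean = best$between,
                      ratio = best$ratio, distances = D)
  if (!is.null(homoeolog_pairs)) {
    hp <- as.data.frame(homoeolog_pairs)
    ok <- assignments[hp[[1]]] != assignments[hp[[2]]]
    diagnostics$pairs_consistent <- all(ok)
    diagnostics$inconsistent_pairs <- hp[!ok, , drop = FALSE]
    if (!all(ok))
      warning(sum(!ok), " homoeologous pair(s) fall in the same clade")
  }

  tree <- tryCatch(ape::root(best$tree, outgroup = cladeB,
                             resolve.root = TRUE),
                   error = function(e) best$tree)
  new("PhasingResult", tree = tree, assignments = assignments,
      support = c(A = hitsA / n_boot, B = hitsB / n_boot),
      diagnostics = diagnostics)
}

#' Rank satellite arrays as centromere candidates
#'
#' Centromeric satellites are typically the highest-copy-number tandem
#' repeats in a genome and sit near centromere-enriched gypsy
#' retrotransposons.  Arrays are ranked by copy number; when gypsy element
#' intervals are supplied, each array is additionally flagged when a gypsy
#' element lies within \code{window} bp.
#'
#' @param arrays data.frame from [detectTandemRepeats()] with a
#'   \code{chromosome} column.
#' @param gypsy optional data.frame of gypsy element intervals with columns
#'   \code{chromosome}, \code{start}, \code{end} (1-based).
#' @param window proximity window in bp (default 1e5).
#' @return \code{arrays} ordered by decreasing copy number, with
#'   \code{rank} and (when \code{gypsy} is given) \code{near_gypsy}.
#' @export
rankSatelliteCandidates <- function(arrays, gypsy = NULL, window = 1e5) {
  if (!nrow(arrays)) return(arrays)
  out <- arrays[order(-arrays$copy_number), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  if (!is.null(gypsy)) {
    out$near_gypsy <- vapply(seq_len(nrow(out)), function(i) {
      g <- gypsy[gypsy$chromosome == out$chromosome[i], , drop = FALSE]
      if (!nrow(g)) return(FALSE)
      any(g$end >= out$start0[i] + 1 - window &
            g$start <= out$end0[i] + window)
    }, logical(1))
  }
  rownames(out) <- NULL
  out
}

# tip indices below an internal node of an ape tree
.tipsBelow <- function(tr, node) {
  ntip <- length(tr$tip.label)
  if (node <= ntip) return(node)
  out <- integer()
  stack <- node
  while (length(stack)) {
    nd <- stack[1]
    stack <- stack[-1]
    kids <- tr$edge[tr$edge[, 1] == nd, 2]
    out <- c(out, kids[kids <= ntip])
    stack <- c(stack, kids[kids > ntip])
  }
  out
}
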