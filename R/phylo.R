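## LTR phylogeny: Kimura two-parameter distances, neighbor-joining with
## negative-branch clamping, and column-resampling bootstrap support.
## NJ on K2P distances stands in for a likelihood search: it is
## deterministic, fast, and sufficient for the question the tree answers
## here — whether each element's 5' and 3' LTRs pair as sisters.

#' K2P distance from transition/transversion proportions
#'
#' d = -1/2 ln(1 - 2P - Q) - 1/4 ln(1 - 2Q) with P the transition and Q
#' the transversion proportion over shared gap-free columns. NA on
#' saturation (log argument <= 0).
#'
#' @param P,Q proportions.
#' @return distance (substitutions/site) or NA.
#' @export
k2p_from_counts <- function(P, Q) {
  a1 <- 1 - 2 * P - Q
  a2 <- 1 - 2 * Q
  if (a1 <= 0 || a2 <= 0) return(NA_real_)
  -0.5 * log(a1) - 0.25 * log(a2)
}

## pairwise K2P from two aligned character vectors (may contain "-")
k2p_pair <- function(a, b) {
  keep <- a %in% BASES & b %in% BASES
  a <- a[keep]; b <- b[keep]
  n <- length(a)
  if (n == 0L) return(list(d = NA_real_, n = 0L, P = NA_real_, Q = NA_real_))
  diff <- a != b
  purine_a <- a %in% c("A", "G")
  purine_b <- b %in% c("A", "G")
  ts <- diff & (purine_a == purine_b)
  P <- sum(ts) / n
  Q <- sum(diff & !ts) / n
  list(d = k2p_from_counts(P, Q), n = n, P = P, Q = Q)
}

## coerce aligned input (named character vector of equal-length strings,
## DNAStringSet, or character matrix) to a character matrix taxa x columns
as_aln_matrix <- function(aln) {
  if (is.matrix(aln)) return(aln)
  if (inherits(aln, "DNAStringSet"))
    aln <- stats::setNames(as.character(aln), names(aln))
  lens <- nchar(aln)
  if (length(unique(lens)) != 1L)
    stop("alignment rows must have equal length")
  m <- do.call(rbind, strsplit(toupper(aln), ""))
  rownames(m) <- names(aln)
  m
}

#' K2P distance matrix over an alignment
#'
#' @param aln named character vector of equal-length aligned sequences
#'   (gaps as "-"), a DNAStringSet, or a character matrix.
#' @param min_pair_sites minimum shared gap-free columns per pair; pairs
#'   below it (or saturated pairs) get NA and are listed in the
#'   `"undefined_pairs"` attribute.
#' @return symmetric numeric matrix with zero diagonal.
#' @export
k2p_distance_matrix <- function(aln, min_pair_sites = 50L) {
  m <- as_aln_matrix(aln)
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  bad <- character(0)
  if (n >= 2L) for (i in 1:(n - 1L)) for (j in (i + 1L):n) {
    k <- k2p_pair(m[i, ], m[j, ])
    if (k$n < min_pair_sites || is.na(k$d)) {
      d[i, j] <- d[j, i] <- NA_real_
      bad <- c(bad, paste(rownames(m)[i], rownames(m)[j], sep = ":"))
    } else d[i, j] <- d[j, i] <- k$d
  }
  attr(d, "undefined_pairs") <- bad
  d
}

#' Neighbor-joining tree with clamped branch lengths
#'
#' Standard NJ agglomeration (via ape) on a complete finite distance
#' matrix; negative branch lengths are clamped to zero with the deficit
#' moved to the sister branch, preserving path lengths through the
#' parent.
#'
#' @param d symmetric distance matrix, n >= 3, no NA.
#' @return an ape `phylo` tree (unrooted).
#' @export
neighbor_joining <- function(d) {
  if (any(is.na(d))) {
    bad <- attr(d, "undefined_pairs")
    if (is.null(bad)) {
      idx <- which(is.na(d) & upper.tri(d), arr.ind = TRUE)
      bad <- paste(rownames(d)[idx[, 1]], colnames(d)[idx[, 2]], sep = ":")
    }
    stop("undefined distances for pairs: ", paste(bad, collapse = ", "))
  }
  if (nrow(d) < 3L) stop("need at least 3 taxa")
  tr <- ape::nj(stats::as.dist(d))
  for (pass in 1:10) {
    neg <- which(tr$edge.length < 0)
    if (!length(neg)) break
    for (e in neg) {
      parent <- tr$edge[e, 1]
      sib <- setdiff(which(tr$edge[, 1] == parent), e)
      if (length(sib)) tr$edge.length[sib[1]] <-
          tr$edge.length[sib[1]] + tr$edge.length[e]
      tr$edge.length[e] <- 0
    }
  }
  tr
}

#' Bootstrap support by column resampling
#'
#' Resamples alignment columns with replacement `n_reps` times, rebuilds
#' the NJ tree per replicate, and reports for each internal node of the
#' full-alignment tree the percentage of replicates containing that
#' split. Splits below `report_threshold` are suppressed in the rendered
#' node labels but retained in the returned data.
#'
#' @param aln alignment as in [k2p_distance_matrix()].
#' @param n_reps replicates.
#' @param seed integer seed (deterministic supports).
#' @param report_threshold percent below which node labels are blanked.
#' @return list(tree, support, labelled_tree) where `support` is percent
#'   per internal node of `tree`.
#' @export
bootstrap_support <- function(aln, n_reps = 1000L, seed = 42L,
                              report_threshold = 50) {
  m <- as_aln_matrix(aln)
  main <- neighbor_joining(k2p_distance_matrix(m))
  reps <- with_seed(seed, {
    lapply(seq_len(n_reps), function(r) {
      cols <- sample.int(ncol(m), ncol(m), replace = TRUE)
      neighbor_joining(k2p_distance_matrix(m[, cols, drop = FALSE]))
    })
  })
  counts <- ape::prop.clades(main, reps, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  support <- 100 * counts / n_reps
  lab <- main
  lab$node.label <- ifelse(support >= report_threshold,
                           sprintf("%.0f", support), "")
  list(tree = main, support = support, labelled_tree = lab)
}

#' Are two taxa a cherry on a tree?
#'
#' @param tree an ape `phylo`.
#' @param a,b tip labels.
#' @return TRUE iff `a` and `b` are adjacent to the same internal node.
#' @export
is_cherry <- function(tree, a, b) {
  ia <- match(a, tree$tip.label); ib <- match(b, tree$tip.label)
  if (is.na(ia) || is.na(ib)) return(FALSE)
  pa <- tree$edge[tree$edge[, 2] == ia, 1]
  pb <- tree$edge[tree$edge[, 2] == ib, 1]
  length(pa) == 1L && length(pb) == 1L && pa == pb
}

#' Simple reference-anchored multiple alignment of LTR sequences
#'
#' Intended for the synthetic fixtures (substitution-dominated
#' divergence): sequences at least `min_len` bp are globally aligned to
#' the longest sequence and merged column-wise (center-star); shorter
#' sequences are excluded with a reason, mirroring the exclusion of
#' too-short LTRs from the published tree.
#'
#' @param seqs named character vector.
#' @param min_len minimum LTR length for inclusion.
#' @return list(alignment = named character vector of equal-length rows,
#'   excluded = data.frame(taxon, length, reason)).
#' @export
align_ltrs <- function(seqs, min_len = 300L) {
  lens <- nchar(seqs)
  short <- which(lens < min_len)
  excl <- data.frame(taxon = names(seqs)[short],
                     length = unname(lens[short]),
                     reason = rep("below minimum LTR length",
                                  length(short)),
                     stringsAsFactors = FALSE)
  seqs <- seqs[lens >= min_len]
  if (length(seqs) < 2L)
    return(list(alignment = seqs, excluded = excl))
  if (length(unique(nchar(seqs))) == 1L &&
      all(nchar(seqs) == nchar(seqs[1])))
    return(list(alignment = seqs, excluded = excl))

  ref_i <- which.max(nchar(seqs))
  ref <- seqs[[ref_i]]
  nref <- nchar(ref)
  # per sequence: chars per ref column + insertions before each ref pos
  per <- lapply(seqs, function(s) {
    aln <- Biostrings::pairwiseAlignment(
      pattern = Biostrings::DNAString(s),
      subject = Biostrings::DNAString(ref), type = "global",
      substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
        match = 2, mismatch = -3, baseOnly = TRUE),
      gapOpening = 8, gapExtension = 0.2)
    pa <- strsplit(as.character(Biostrings::pattern(aln)), "")[[1]]
    sa <- strsplit(as.character(Biostrings::subject(aln)), "")[[1]]
    cols <- rep("-", nref)
    ins <- integer(nref + 1L)  # insertions before ref position i (1-based)
    sp <- 0L
    for (i in seq_along(pa)) {
      if (sa[i] == "-") ins[sp + 1L] <- ins[sp + 1L] + 1L
      else { sp <- sp + 1L; cols[sp] <- pa[i] }
    }
    list(cols = cols, ins = ins)
  })
  max_ins <- Reduce(pmax, lapply(per, `[[`, "ins"))
  rows <- vapply(per, function(p) {
    out <- character(0)
    for (i in seq_len(nref + 1L)) {
      if (max_ins[i] > 0L)
        out <- c(out, rep("-", max_ins[i]))  # insertions collapsed to gaps
      if (i <= nref) out <- c(out, p$cols[i])
    }
    paste(out, collapse = "")
  }, "")
  names(rows) <- names(seqs)
  list(alignment = rows, excluded = excl)
}
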