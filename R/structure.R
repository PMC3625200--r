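## Structure typing: full-length vs. truncated, subtype I/II via the
## 292 bp pol-env boundary segment, gag/pro/pol/env stop-codon and frame
## annotation against the consensus gene map, nested-insertion detection,
## and 5'/3' LTR divergence.

STOP_CODONS <- c("TAG", "TGA", "TAA")

#' Align a (possibly truncated) element to a consensus and project
#' coordinates
#'
#' Single global-in-pattern pairwise alignment (Biostrings) of the query
#' into the consensus; returns, for every consensus position, the 1-based
#' query position aligned there (NA at gaps / outside the aligned range).
#'
#' @param query element sequence.
#' @param ref consensus sequence.
#' @return integer vector of length `nchar(ref)`.
#' @keywords internal
align_to_consensus <- function(query, ref) {
  aln <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAString(query),
    subject = Biostrings::DNAString(ref),
    type = "global-local",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = 2, mismatch = -3, baseOnly = TRUE),
    gapOpening = 8, gapExtension = 0.2)
  pa <- strsplit(as.character(Biostrings::pattern(aln)), "")[[1]]
  sa <- strsplit(as.character(Biostrings::subject(aln)), "")[[1]]
  map <- rep(NA_integer_, nchar(ref))
  qp <- BiocGenerics::start(Biostrings::pattern(aln)) - 1L
  sp <- BiocGenerics::start(Biostrings::subject(aln)) - 1L
  for (i in seq_along(pa)) {
    qg <- pa[i] == "-"; sg <- sa[i] == "-"
    if (!qg) qp <- qp + 1L
    if (!sg) sp <- sp + 1L
    if (!qg && !sg) map[sp] <- qp
  }
  map
}

#' Is an element full-length?
#'
#' An element is full-length iff its (largest contiguous) internal region
#' exceeds 7 kb — strict inequality.
#'
#' @param element one row of an element data.frame (uses
#'   `max_internal_len`), or a bare internal length.
#' @return logical.
#' @export
call_full_length <- function(element) {
  len <- if (is.numeric(element)) element else element$max_internal_len
  len > 7000
}

#' Subtype an element internal region (type I vs. II)
#'
#' Type II elements carry the 292 bp pol-env boundary segment; type I
#' elements lack it. II iff at least `min_cov` of the segment's consensus
#' columns align to element bases; I iff the segment is absent (coverage
#' < `min_cov`) while at least 200 bp align on each side of the boundary;
#' NA otherwise (e.g. an element truncated before pol).
#'
#' @param internal_seq the element's internal sequence.
#' @param consensus consensus list from [toy_provirus()] (type II
#'   internal + boundary span).
#' @param min_cov minimum aligned fraction of the boundary segment.
#' @return "I", "II" or NA.
#' @export
call_type <- function(internal_seq, consensus = toy_provirus(),
                      min_cov = 0.5) {
  ref <- consensus$internal
  b <- consensus$boundary_span - (consensus$internal_span[1])  # internal 1-based
  map <- align_to_consensus(internal_seq, ref)
  cov <- mean(!is.na(map[b[1]:b[2]]))
  left <- sum(!is.na(map[seq_len(b[1] - 1L)]))
  right <- sum(!is.na(map[seq(b[2] + 1L, nchar(ref))]))
  if (cov >= min_cov) return("II")
  if (left >= 200L && right >= 200L) return("I")
  NA_character_
}

## first codon-boundary consensus position >= cpos for a gene
codon_anchor <- function(cpos, gene_start, frame) {
  ph <- (cpos - gene_start - frame) %% 3L
  cpos + ((3L - ph) %% 3L)
}

translate_find_stop <- function(seq) {
  n <- nchar(seq) - nchar(seq) %% 3L
  if (n < 3L) return(NULL)
  codons <- substring(seq, seq(1L, n - 2L, by = 3L), seq(3L, n, by = 3L))
  hit <- which(codons %in% STOP_CODONS)
  if (!length(hit)) return(NULL)
  list(codon = codons[hit[1]], codon_index = hit[1],
       pos = (hit[1] - 1L) * 3L + 1L)
}

#' Annotate gene ORF status of an element against the consensus
#'
#' Projects each gene span of the consensus gene map through a single
#' global pairwise alignment. Per gene: MISSING when under half the span
#' projects; BROKEN_FRAME when the net projected indel length is not a
#' codon multiple; otherwise the gene is translated in the projected
#' frame and the first in-frame stop (TAG/TGA/TAA) reported, or INTACT.
#' For type I elements whose pol and env project into one frame with no
#' intervening stop, an in-frame pol-env fusion is additionally reported.
#'
#' @param element_seq element sequence, element-forward orientation; pass
#'   `strand = "-"` to annotate a minus-strand genomic sequence.
#' @param consensus consensus list from [toy_provirus()].
#' @param gene_map data.frame (gene, start, end, frame) on the consensus.
#' @param element_type "I", "II" or NA; FUSED is only reportable for
#'   type I.
#' @param strand "+" or "-".
#' @return list(genes = data.frame(gene, status, stop_codon, stop_pos,
#'   coverage), fused = logical).
#' @export
annotate_orfs <- function(element_seq, consensus = toy_provirus(),
                          gene_map = consensus$gene_map,
                          element_type = NA_character_, strand = "+") {
  if (identical(strand, "-")) element_seq <- revcomp(element_seq)
  map <- align_to_consensus(element_seq, consensus$seq)
  genes <- gene_map
  res <- data.frame(gene = genes$gene, status = "MISSING",
                    stop_codon = NA_character_, stop_pos = NA_integer_,
                    coverage = 0, stringsAsFactors = FALSE)
  anchors <- rep(NA_integer_, nrow(genes))
  for (gi in seq_len(nrow(genes))) {
    g <- genes[gi, ]
    span <- g$start:g$end
    proj <- map[span]
    cov <- mean(!is.na(proj))
    res$coverage[gi] <- cov
    if (cov < 0.5) next
    cs <- span[which(!is.na(proj))[1]]
    ce <- span[rev(which(!is.na(proj)))[1]]
    qs <- map[cs]; qe <- map[ce]
    net_indel <- (qe - qs) - (ce - cs)
    if (net_indel %% 3L != 0L) { res$status[gi] <- "BROKEN_FRAME"; next }
    ca <- codon_anchor(cs, g$start, g$frame)
    while (ca <= ce && is.na(map[ca])) ca <- ca + 3L
    if (ca > ce) { res$status[gi] <- "BROKEN_FRAME"; next }
    qa <- map[ca]
    anchors[gi] <- qa
    stop_hit <- translate_find_stop(substr(element_seq, qa, qe))
    if (is.null(stop_hit)) {
      res$status[gi] <- "INTACT"
    } else {
      res$status[gi] <- "STOP"
      res$stop_codon[gi] <- stop_hit$codon
      res$stop_pos[gi] <- qa + stop_hit$pos - 1L
    }
  }
  fused <- FALSE
  if (identical(element_type, "I")) {
    ip <- match("pol", res$gene); ie <- match("env", res$gene)
    if (!is.na(anchors[ip]) && !is.na(anchors[ie]) &&
        (anchors[ie] - anchors[ip]) %% 3L == 0L) {
      env_end <- map[genes$end[ie]:genes$start[ie]]
      env_end <- env_end[!is.na(env_end)][1]
      if (!is.na(env_end)) {
        span_seq <- substr(element_seq, anchors[ip], env_end)
        fused <- is.null(translate_find_stop(span_seq))
      }
    }
  }
  list(genes = res, fused = fused)
}

#' Detect nested repeat insertions within an element
#'
#' Reports repeat hits of other families lying fully inside the element
#' span, together with the consensus gene each interrupts (via the host
#' part's consensus coordinates).
#'
#' @param element one row of an element data.frame.
#' @param parts the element's parts (rows of the assembly `parts` for
#'   this locus).
#' @param hits full hit table.
#' @param consensus consensus list (for the gene map).
#' @param pairing family pairing, to know which families are "self".
#' @return data.frame(family, start, end, gene).
#' @export
detect_nested_insertions <- function(element, parts, hits,
                                     consensus = toy_provirus(),
                                     pairing = default_family_pairing()) {
  self_fams <- unique(c(pairing$ltr_family, pairing$internal_family))
  inside <- hits[hits$contig == element$contig &
                 hits$start >= element$start & hits$end <= element$end &
                 !(hits$family %in% self_fams), , drop = FALSE]
  if (!nrow(inside))
    return(data.frame(family = character(), start = integer(),
                      end = integer(), gene = character(),
                      stringsAsFactors = FALSE))
  gm <- consensus$gene_map
  ioff <- consensus$internal_span[1]  # internal coords + ioff = element coords
  gene_at <- function(mid) {
    host <- parts[parts$start <= mid & parts$end > mid, , drop = FALSE]
    if (!nrow(host) || host$kind[1] != "INTERNAL") return(NA_character_)
    cpos <- host$cons_start[1] + (mid - host$start[1]) + ioff
    hit <- gm$gene[gm$start <= cpos & gm$end >= cpos]
    if (length(hit)) hit[1] else NA_character_
  }
  inside$gene <- vapply((inside$start + inside$end) %/% 2L, gene_at, "")
  inside[, c("family", "start", "end", "gene")]
}

#' Kimura two-parameter divergence between an element's two LTRs
#'
#' Globally aligns the LTR pair and computes the K2P distance over
#' gap-free columns. Undefined (NA, flagged) when either LTR is shorter
#' than 100 bp after alignment or the distance saturates.
#'
#' @param ltr5_seq,ltr3_seq LTR sequences in element orientation.
#' @return list(d, n_sites, P, Q, flag).
#' @export
ltr_divergence <- function(ltr5_seq, ltr3_seq) {
  if (is.na(ltr5_seq) || is.na(ltr3_seq) ||
      min(nchar(ltr5_seq), nchar(ltr3_seq)) < 100L)
    return(list(d = NA_real_, n_sites = 0L, P = NA_real_, Q = NA_real_,
                flag = "LTR shorter than 100 bp"))
  # stiff gap penalties: substitutions must be scored as substitutions,
  # not gapped around, or the distance is deflated
  aln <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAString(ltr5_seq),
    subject = Biostrings::DNAString(ltr3_seq),
    type = "global",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = 2, mismatch = -3, baseOnly = TRUE),
    gapOpening = 25, gapExtension = 2)
  a <- strsplit(as.character(Biostrings::pattern(aln)), "")[[1]]
  b <- strsplit(as.character(Biostrings::subject(aln)), "")[[1]]
  keep <- a != "-" & b != "-"
  a <- a[keep]; b <- b[keep]
  n <- length(a)
  if (n < 100L)
    return(list(d = NA_real_, n_sites = n, P = NA_real_, Q = NA_real_,
                flag = "fewer than 100 aligned columns"))
  k2 <- k2p_pair(a, b)
  list(d = k2$d, n_sites = k2$n, P = k2$P, Q = k2$Q,
       flag = if (is.na(k2$d)) "saturated" else "")
}
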