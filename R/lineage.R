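## Lineage specificity: decide presence/absence of each element at the
## orthologous position in outgroup genomes via anchored flank mapping,
## detect target site duplications, classify classical vs. non-classical
## (target-deleting) insertion mechanisms, and detect junction
## microhomology — the NHEJ signature.

#' Extract raw flanks of an element
#'
#' Returns the `flank_len` bases on each side of the element span,
#' excluding the element itself. Detected TSD copies remain included
#' (raw flanks). Flanks are clipped at contig ends with a flag.
#'
#' @param genome character scalar.
#' @param start,end element span, 0-based half-open.
#' @param flank_len bp per side.
#' @return list(upstream, downstream, clipped_up, clipped_down).
#' @export
extract_flanks <- function(genome, start, end, flank_len = 2000L) {
  L <- nchar(genome)
  if (start < 0L || end > L || start >= end)
    stop("element span outside contig")
  us <- max(0L, start - flank_len)
  de <- min(L, end + flank_len)
  list(upstream = seq_slice(genome, us, start),
       downstream = seq_slice(genome, end, de),
       clipped_up = us == 0L && start < flank_len,
       clipped_down = de == L && L - end < flank_len)
}

## candidate anchor offsets by exact seed matching (seed-and-verify;
## substitution-style divergence keeps flank/outgroup coordinates in
## register, so fixed-offset verification is exact)
seed_candidates <- function(flank, subject_ds, seed_len = 32L,
                            step = 64L) {
  L <- nchar(flank)
  if (L < seed_len) return(integer(0))
  offs <- seq(1L, L - seed_len + 1L, by = step)
  seeds <- substring(flank, offs, offs + seed_len - 1L)
  keep <- !grepl("[^ACGT]", seeds)
  if (!any(keep)) return(integer(0))
  offs <- offs[keep]; seeds <- seeds[keep]
  pd <- Biostrings::PDict(Biostrings::DNAStringSet(seeds))
  m <- Biostrings::matchPDict(pd, subject_ds)
  cand <- integer(0)
  for (k in seq_along(m)) {
    st <- BiocGenerics::start(m[[k]])
    if (length(st)) cand <- c(cand, st - offs[k] + 1L)
  }
  unique(cand)
}

#' Map a flank onto an outgroup genome
#'
#' Seed-and-verify anchored mapping: exact 32-mer seeds locate candidate
#' offsets, full-length mismatch counting scores them. Returns UNRESOLVED
#' (NULL hit) when the flank is too short, unmapped, or ambiguous — a
#' second candidate scoring within 5% of the best, as arises in segmental
#' duplications.
#'
#' @param flank character scalar.
#' @param outgroup character scalar (or DNAString).
#' @param min_identity minimum full-flank identity.
#' @param min_hit_len minimum flank length considered mappable.
#' @return list(state = "RESOLVED"/"UNRESOLVED", start, end (0-based
#'   half-open on outgroup), strand, identity, reason).
#' @export
map_flanks <- function(flank, outgroup, min_identity = 0.9,
                       min_hit_len = 200L) {
  unres <- function(reason)
    list(state = "UNRESOLVED", start = NA_integer_, end = NA_integer_,
         strand = NA_character_, identity = NA_real_, reason = reason)
  L <- nchar(flank)
  if (L < min_hit_len) return(unres("flank too short"))
  subj <- if (methods::is(outgroup, "DNAString")) outgroup
          else Biostrings::DNAString(outgroup)
  score_at <- function(pos, query) {  # 1-based start on outgroup
    if (pos < 1L || pos + L - 1L > length(subj)) return(NA_real_)
    mm <- Biostrings::neditStartingAt(query, subj, starting.at = pos,
                                      with.indels = FALSE)
    1 - mm / L
  }
  scan <- function(query_chr, strand) {
    cand <- seed_candidates(query_chr, subj)
    if (!length(cand))
      return(data.frame(pos = integer(), strand = character(),
                        id = numeric()))
    q <- Biostrings::DNAString(query_chr)
    id <- vapply(cand, score_at, 0, query = q)
    data.frame(pos = cand, strand = strand, id = id)
  }
  hits <- scan(flank, "+")
  # search the reverse strand only if the forward strand is inconclusive
  if (!nrow(hits) || max(hits$id, na.rm = TRUE) < min_identity)
    hits <- rbind(hits, scan(revcomp(flank), "-"))
  hits <- hits[!is.na(hits$id) & hits$id >= min_identity, , drop = FALSE]
  if (!nrow(hits)) return(unres("no acceptable hit"))
  hits <- hits[order(-hits$id), , drop = FALSE]
  if (nrow(hits) > 1L && hits$id[2] >= 0.95 * hits$id[1])
    return(unres("ambiguous: near-best secondary hit"))
  best <- hits[1, ]
  list(state = "RESOLVED", start = best$pos - 1L,
       end = best$pos - 1L + L, strand = best$strand,
       identity = best$id, reason = "")
}

#' Build an ortholog anchor from two mapped flanks
#'
#' @param up,down results of [map_flanks()] for the upstream and
#'   downstream flank.
#' @return list(resolved, gap, up_end, down_start, strand) where `gap` is
#'   the signed bp between the flank images (negative = overlap, e.g. the
#'   single target-site copy shared by both flanks at a TSD locus).
#' @export
ortholog_anchor <- function(up, down) {
  if (up$state != "RESOLVED" || down$state != "RESOLVED" ||
      !identical(up$strand, down$strand))
    return(list(resolved = FALSE, gap = NA_integer_))
  if (up$strand == "+") {
    gap <- down$start - up$end
    list(resolved = TRUE, gap = as.integer(gap), up_end = up$end,
         down_start = down$start, strand = "+")
  } else {
    gap <- up$start - down$end
    list(resolved = TRUE, gap = as.integer(gap), up_end = down$end,
         down_start = up$start, strand = "-")
  }
}

#' Call the ortholog state from an anchor gap
#'
#' PRESENT when the inter-anchor gap fits the element length within
#' `tol`; ABSENT when the gap is small relative to the element
#' (< 0.1 x element length — classical pre-insertion sites overlap by the
#' TSD length, non-classical sites gap by the deleted length); gaps
#' outside both bands are ABSENT only when sequence evidence shows the
#' inter-anchor outgroup sequence lacks element-derived content (large
#' target deletions can exceed 10% of, or even exceed, the element
#' length), otherwise UNRESOLVED.
#'
#' @param anchor from [ortholog_anchor()].
#' @param element_len bp.
#' @param tol relative tolerance for PRESENT.
#' @param absence_evidence optional logical from
#'   [gap_lacks_element()]; consulted only for gaps outside both bands.
#' @return list(state, gap).
#' @export
call_ortholog_state <- function(anchor, element_len, tol = 0.2,
                                absence_evidence = NULL) {
  if (!isTRUE(anchor$resolved))
    return(list(state = "UNRESOLVED", gap = NA_integer_))
  gap <- anchor$gap
  if (abs(gap - element_len) <= tol * element_len) {
    # a target deletion of about the element's size mimics presence;
    # sequence evidence that the inter-anchor region lacks element
    # content overrides the size-based call
    if (isTRUE(absence_evidence))
      return(list(state = "ABSENT", gap = gap))
    return(list(state = "PRESENT", gap = gap))
  }
  if (gap < 0.1 * element_len)
    return(list(state = "ABSENT", gap = gap))
  if (isTRUE(absence_evidence))
    return(list(state = "ABSENT", gap = gap))
  list(state = "UNRESOLVED", gap = gap)
}

#' Does the outgroup inter-anchor sequence lack element-derived content?
#'
#' Samples up to 60 20-mers evenly along the element and checks whether
#' any occur (either strand) in the outgroup sequence between the two
#' flank images. Used as absence evidence when a target deletion is large
#' relative to the element.
#'
#' @param outgroup character scalar.
#' @param up_end,down_start 0-based anchor bounds on the outgroup.
#' @param element_seq character scalar.
#' @return TRUE when fewer than 5% of sampled k-mers are found.
#' @export
gap_lacks_element <- function(outgroup, up_end, down_start, element_seq) {
  gap_seq <- seq_slice(outgroup, up_end, down_start)
  if (nchar(gap_seq) < 20L) return(TRUE)
  L <- nchar(element_seq)
  if (L < 20L) return(TRUE)
  n <- min(60L, L - 19L)
  offs <- unique(as.integer(round(seq(1L, L - 19L, length.out = n))))
  kmers <- substring(element_seq, offs, offs + 19L)
  kmers <- kmers[!grepl("[^ACGT]", kmers)]
  if (!length(kmers)) return(TRUE)
  subj <- Biostrings::DNAString(gap_seq)
  found <- vapply(kmers, function(k) {
    length(Biostrings::matchPattern(k, subj)) > 0L ||
      length(Biostrings::matchPattern(revcomp(k), subj)) > 0L
  }, TRUE)
  mean(found) < 0.05
}

#' Detect a target site duplication around an element
#'
#' Longest k <= `max_tsd` such that the k bases immediately 5' of the
#' element equal the k bases immediately 3' of it; exact match required
#' below `allow_mismatch_at`, one mismatch tolerated at or above it.
#' Returns length 0 (blunt junction) when the best k < `min_tsd`.
#'
#' @param genome character scalar.
#' @param start,end element span, 0-based half-open.
#' @param max_tsd,min_tsd,allow_mismatch_at bp thresholds.
#' @return list(len, seq, mismatches, at_edge).
#' @export
detect_tsd <- function(genome, start, end, max_tsd = 25L, min_tsd = 4L,
                       allow_mismatch_at = 8L) {
  L <- nchar(genome)
  if (start <= 0L || end >= L)
    return(list(len = 0L, seq = "", mismatches = 0L, at_edge = TRUE))
  left <- seq_slice(genome, max(0L, start - max_tsd), start)
  right <- seq_slice(genome, end, min(L, end + max_tsd))
  k <- tsd_longest_k(left, right, max_tsd, min_tsd, allow_mismatch_at)
  list(len = k$len,
       seq = if (k$len > 0L) substr(right, 1L, k$len) else "",
       mismatches = k$mismatches, at_edge = FALSE)
}

## median with even-count ties resolved toward the earlier outgroup
median_gap <- function(gaps) {
  n <- length(gaps)
  if (!n) return(NA_integer_)
  s <- sort(gaps)
  if (n %% 2L == 1L) return(as.integer(s[(n + 1L) %/% 2L]))
  mid <- s[c(n %/% 2L, n %/% 2L + 1L)]
  first_hit <- which(gaps %in% mid)[1]
  as.integer(gaps[first_hit])
}

#' Classify the insertion mechanism of a human-specific locus
#'
#' CLASSICAL: a TSD of at least `min_tsd` bp and no positive absent-state
#' gap (the pre-insertion flank images overlap by the TSD). NON_CLASSICAL:
#' a blunt junction (TSD length 0) and a consensus absent-state gap of at
#' least 1 bp — the target deletion, sized as the median gap across
#' informative outgroups. Anything else is UNDETERMINED.
#'
#' @param tsd_len detected TSD length, bp.
#' @param gaps integer vector of gaps from outgroups called ABSENT, in
#'   outgroup input order (closest first).
#' @param min_tsd bp.
#' @return list(mechanism, deleted_target_len).
#' @export
classify_mechanism <- function(tsd_len, gaps, min_tsd = 4L) {
  gaps <- gaps[!is.na(gaps)]
  if (tsd_len >= min_tsd && length(gaps) && all(gaps <= 0L))
    return(list(mechanism = "CLASSICAL", deleted_target_len = 0L))
  if (tsd_len == 0L && length(gaps)) {
    med <- median_gap(gaps)
    if (!is.na(med) && med >= 1L)
      return(list(mechanism = "NON_CLASSICAL", deleted_target_len = med))
  }
  list(mechanism = "UNDETERMINED", deleted_target_len = 0L)
}

#' Detect junction microhomology at a non-classical insertion
#'
#' mh5 is the longest exact overlap between the element's 5' terminal
#' window and the outgroup sequence immediately inside the deleted
#' region's 5' edge; mh3 symmetric at the 3' edge. Length 0 when below
#' `min_len`.
#'
#' @param element_seq element sequence (carrier orientation).
#' @param outgroup_context pre-insertion sequence spanning both
#'   breakpoints (the deleted region), or NA when unavailable.
#' @param window bp searched at each terminus.
#' @param min_len minimum reportable length.
#' @return list(mh5 = list(len, seq), mh3 = list(len, seq), defined).
#' @export
detect_microhomology <- function(element_seq, outgroup_context,
                                 window = 15L, min_len = 1L) {
  if (is.na(outgroup_context) || !nzchar(outgroup_context))
    return(list(mh5 = list(len = NA_integer_, seq = NA_character_),
                mh3 = list(len = NA_integer_, seq = NA_character_),
                defined = FALSE))
  m5 <- longest_prefix_match(element_seq, outgroup_context, window)
  m3 <- longest_suffix_match(element_seq, outgroup_context, window)
  if (m5 < min_len) m5 <- 0L
  if (m3 < min_len) m3 <- 0L
  list(mh5 = list(len = m5, seq = substr(element_seq, 1L, m5)),
       mh3 = list(len = m3,
                  seq = if (m3 > 0L)
                    substr(element_seq, nchar(element_seq) - m3 + 1L,
                           nchar(element_seq)) else ""),
       defined = TRUE)
}

#' Screen an element catalog for lineage-specific insertions
#'
#' For every element: extract 2 kb flanks, anchor them in each outgroup,
#' call PRESENT/ABSENT/UNRESOLVED, and for human-specific loci (absent in
#' at least one outgroup, present in none; unresolved outgroups are
#' non-informative) detect the TSD, classify the mechanism, size the
#' target deletion (median across informative outgroups) and detect
#' junction microhomology against the closest informative outgroup's
#' pre-insertion sequence.
#'
#' @param elements element data.frame from [assemble_elements()].
#' @param carrier carrier genome, character scalar.
#' @param outgroups named list/vector of outgroup genomes, closest first.
#' @param flank_len,min_identity,tol,min_tsd see the per-step functions.
#' @param include_solo include solo-LTR elements in the screen (the
#'   published survey excluded solitary LTRs from its candidate set; set
#'   FALSE for that convention).
#' @return data.frame of lineage calls, one row per screened element.
#' @export
lineage_screen <- function(elements, carrier, outgroups,
                           flank_len = 2000L, min_identity = 0.9,
                           tol = 0.2, min_tsd = 4L, include_solo = TRUE) {
  if (is.null(names(outgroups)))
    names(outgroups) <- paste0("outgroup", seq_along(outgroups))
  outgroup_ds <- lapply(outgroups, Biostrings::DNAString)
  if (!include_solo)
    elements <- elements[elements$structure_class != "SOLO_LTR", ,
                         drop = FALSE]
  rows <- vector("list", nrow(elements))
  for (i in seq_len(nrow(elements))) {
    el <- elements[i, ]
    elen <- el$end - el$start
    eseq <- seq_slice(carrier, el$start, el$end)
    fl <- extract_flanks(carrier, el$start, el$end, flank_len)
    states <- character(length(outgroups))
    gaps <- rep(NA_integer_, length(outgroups))
    contexts <- rep(NA_character_, length(outgroups))
    for (k in seq_along(outgroups)) {
      og <- outgroups[[k]]
      up <- map_flanks(fl$upstream, outgroup_ds[[k]], min_identity)
      down <- map_flanks(fl$downstream, outgroup_ds[[k]], min_identity)
      anc <- ortholog_anchor(up, down)
      ev <- NULL
      if (isTRUE(anc$resolved) && anc$strand == "+" &&
          anc$gap >= 0.1 * elen)
        ev <- gap_lacks_element(og, anc$up_end, anc$down_start, eseq)
      st <- call_ortholog_state(anc, elen, tol, absence_evidence = ev)
      states[k] <- st$state
      gaps[k] <- st$gap
      if (isTRUE(anc$resolved) && anc$strand == "+")
        contexts[k] <- seq_slice(og, anc$up_end, anc$down_start)
    }
    human_specific <- !any(states == "PRESENT") && any(states == "ABSENT")
    tsd <- detect_tsd(carrier, el$start, el$end, min_tsd = min_tsd)
    mech <- list(mechanism = "UNDETERMINED", deleted_target_len = 0L)
    mh <- list(mh5 = list(len = 0L, seq = ""), mh3 = list(len = 0L, seq = ""))
    if (human_specific) {
      inf <- which(states == "ABSENT")
      mech <- classify_mechanism(tsd$len, gaps[inf], min_tsd)
      if (mech$mechanism == "NON_CLASSICAL") {
        ctx <- contexts[inf][!is.na(contexts[inf])]
        mh <- detect_microhomology(eseq,
                                   if (length(ctx)) ctx[1] else NA_character_)
      }
    }
    row <- data.frame(locus_id = el$locus_id, element_len = elen,
                      human_specific = human_specific,
                      mechanism = if (human_specific) mech$mechanism
                                  else "UNDETERMINED",
                      tsd_len = tsd$len, tsd_seq = tsd$seq,
                      tsd_mismatches = tsd$mismatches,
                      deleted_target_len = mech$deleted_target_len,
                      mh5 = mh$mh5$len, mh3 = mh$mh3$len,
                      stringsAsFactors = FALSE)
    for (k in seq_along(outgroups)) {
      row[[paste0("state_", names(outgroups)[k])]] <- states[k]
      row[[paste0("gap_", names(outgroups)[k])]] <- gaps[k]
    }
    rows[[i]] <- row
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
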