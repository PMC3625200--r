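## RepeatMasker-style hit tables: parsing, writing, defragmentation of
## split hits, and assembly of LTR/internal parts into ERV loci.
##
## The on-disk format is a 15-column whitespace-separated table
## (score, div, del, ins, query, q_begin, q_end, q_left, strand,
## repeat_name, repeat_class, r_begin, r_end, r_left, hit_id) following
## RepeatMasker conventions: 1-based inclusive coordinates, strand "+" or
## "C", and for "C" hits the consensus begin/left fields swapped, with the
## "left" count parenthesized. In memory all genomic intervals are 0-based
## half-open and consensus coordinates are normalized to begin <= end.

OUT_COLS <- c("score", "div", "del", "ins", "query", "q_begin", "q_end",
              "q_left", "strand", "repeat_name", "repeat_class",
              "r_begin", "r_end", "r_left", "hit_id")

#' Parse a RepeatMasker-style .out table
#'
#' Header lines are tolerated (any leading lines whose first field is not
#' numeric are skipped). Minus-strand ("C" or "-") consensus coordinates
#' are normalized to begin <= end with the parenthesized "left" field
#' resolved.
#'
#' @param path file path (or connection) to the table.
#' @return data.frame with columns contig, start, end (0-based half-open),
#'   strand ("+"/"-"), family, repeat_class, cons_start, cons_end (1-based
#'   inclusive), hit_id, score, div; hits in file order.
#' @export
parse_repeat_hits <- function(path) {
  lines <- readLines(path)
  empty <- data.frame(contig = character(), start = integer(),
                      end = integer(), strand = character(),
                      family = character(), repeat_class = character(),
                      cons_start = integer(), cons_end = integer(),
                      hit_id = integer(), score = numeric(),
                      div = numeric(), stringsAsFactors = FALSE)
  if (!length(lines)) return(empty)
  toks <- strsplit(trimws(lines), "\\s+")
  is_data <- vapply(toks, function(t)
    length(t) >= 14L && !is.na(suppressWarnings(as.numeric(t[1]))), TRUE)
  # header lines may only precede data lines
  first_data <- which(is_data)[1]
  if (is.na(first_data)) return(empty)
  rows <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    if (i < first_data || !nzchar(trimws(lines[i]))) next
    t <- toks[[i]]
    if (length(t) < 14L || is.na(suppressWarnings(as.numeric(t[1]))))
      stop("malformed repeat-hit row at line ", i)
    strand <- if (t[9] %in% c("C", "-")) "-" else "+"
    unparen <- function(x) as.integer(gsub("[()]", "", x))
    if (strand == "+") {
      cb <- as.integer(t[12]); ce <- as.integer(t[13])
    } else {
      # C rows: r_begin column holds (left), r_left column holds begin
      cb <- unparen(t[14]); ce <- as.integer(t[13])
    }
    if (is.na(cb) || is.na(ce) || cb > ce)
      stop("malformed consensus coordinates at line ", i)
    rows[[i]] <- data.frame(
      contig = t[5],
      start = as.integer(t[6]) - 1L, end = as.integer(t[7]),
      strand = strand, family = t[10], repeat_class = t[11],
      cons_start = cb, cons_end = ce,
      hit_id = if (length(t) >= 15L) as.integer(t[15]) else NA_integer_,
      score = as.numeric(t[1]), div = as.numeric(t[2]),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(out)) empty else { rownames(out) <- NULL; out }
}

#' Write hits in the .out-style format read by [parse_repeat_hits()]
#'
#' @param hits data.frame in the in-memory layout of [parse_repeat_hits()].
#' @param path output path.
#' @param contig_lens optional named vector of contig lengths (for the
#'   q_left field; 0 used when unknown).
#' @param family_lens optional named vector of consensus lengths (for the
#'   r_left field).
#' @export
write_repeat_hits <- function(hits, path, contig_lens = NULL,
                              family_lens = NULL) {
  if (!nrow(hits)) { writeLines(character(0), path); return(invisible(path)) }
  qlen <- if (is.null(contig_lens)) rep(0L, nrow(hits))
          else as.integer(contig_lens[hits$contig])
  flen <- if (is.null(family_lens)) rep(NA_integer_, nrow(hits))
          else as.integer(family_lens[hits$family])
  flen[is.na(flen)] <- hits$cons_end[is.na(flen)]
  lines <- character(nrow(hits))
  for (i in seq_len(nrow(hits))) {
    h <- hits[i, ]
    qleft <- sprintf("(%d)", max(0L, qlen[i] - h$end))
    rleft <- max(0L, flen[i] - h$cons_end)
    if (h$strand == "+") {
      strand <- "+"
      r1 <- h$cons_start; r2 <- h$cons_end; r3 <- sprintf("(%d)", rleft)
    } else {
      strand <- "C"
      r1 <- sprintf("(%d)", rleft); r2 <- h$cons_end; r3 <- h$cons_start
    }
    lines[i] <- paste(h$score, format(h$div, nsmall = 1), "0.0", "0.0",
                      h$contig, h$start + 1L, h$end, qleft, strand,
                      h$family, h$repeat_class, r1, r2, r3,
                      if (is.na(h$hit_id)) i else h$hit_id,
                      sep = "\t")
  }
  header <- paste(OUT_COLS, collapse = "\t")
  writeLines(c(header, lines), path)
  invisible(path)
}

## total bp of [gs, ge) covered by intervals in starts/ends (0-based half-open)
interval_coverage <- function(gs, ge, starts, ends) {
  if (ge <= gs || !length(starts)) return(0L)
  s <- pmax(starts, gs); e <- pmin(ends, ge)
  keep <- s < e
  if (!any(keep)) return(0L)
  r <- IRanges::IRanges(start = s[keep] + 1L, end = e[keep])
  sum(IRanges::width(IRanges::reduce(r)))
}

#' Merge fragmented same-family hits into element parts
#'
#' Two same-family, same-strand hits merge iff their consensus spans are
#' collinear in strand order (consensus overlap <= `max_consensus_overlap`)
#' and either the genomic gap is <= `max_genomic_gap` or (with
#' `nested_repeat_bridge`) the gap is >= 80% covered by hits of other
#' repeat families. Merging is transitive along the genomic order.
#'
#' Hits are never merged across a gap occupied (>= 50%) by their partner
#' LTR/internal family: an intervening LTR annotation marks an
#' element-internal boundary (a tandem junction or recombination scar),
#' not a nested repeat.
#'
#' @param hits data.frame from [parse_repeat_hits()] /
#'   [emit_repeat_annotations()].
#' @param max_genomic_gap bp.
#' @param max_consensus_overlap bp.
#' @param nested_repeat_bridge logical.
#' @param pairing LTR/internal family pairing
#'   ([default_family_pairing()]).
#' @return data.frame of merged groups: contig, start, end, strand, family,
#'   repeat_class, cons_start, cons_end, n_hits, hit_ids (comma-joined),
#'   cons_coverage (bp of consensus covered by the group's hits).
#' @export
defragment_hits <- function(hits, max_genomic_gap = 5000L,
                            max_consensus_overlap = 50L,
                            nested_repeat_bridge = TRUE,
                            pairing = default_family_pairing()) {
  if (!nrow(hits)) {
    return(data.frame(contig = character(), start = integer(),
                      end = integer(), strand = character(),
                      family = character(), repeat_class = character(),
                      cons_start = integer(), cons_end = integer(),
                      n_hits = integer(), hit_ids = character(),
                      cons_coverage = integer(), stringsAsFactors = FALSE))
  }
  hits <- hits[order(hits$contig, hits$start), , drop = FALSE]
  groups <- list()
  partner_of <- function(fam) {
    p <- c(pairing$internal_family[pairing$ltr_family == fam],
           pairing$ltr_family[pairing$internal_family == fam])
    if (length(p)) p else character(0)
  }
  for (key in unique(paste(hits$contig, hits$family, hits$strand))) {
    sel <- paste(hits$contig, hits$family, hits$strand) == key
    h <- hits[sel, , drop = FALSE]
    others <- hits[hits$contig == h$contig[1] & hits$family != h$family[1], ,
                   drop = FALSE]
    partners <- hits[hits$contig == h$contig[1] &
                     hits$family %in% partner_of(h$family[1]), ,
                     drop = FALSE]
    cur <- h[1, , drop = FALSE]
    members <- list(h[1, ])
    flush <- function() {
      m <- do.call(rbind, members)
      cov <- interval_coverage(min(m$cons_start) - 1L, max(m$cons_end),
                               m$cons_start - 1L, m$cons_end)
      data.frame(contig = m$contig[1], start = min(m$start),
                 end = max(m$end), strand = m$strand[1],
                 family = m$family[1], repeat_class = m$repeat_class[1],
                 cons_start = min(m$cons_start), cons_end = max(m$cons_end),
                 n_hits = nrow(m),
                 hit_ids = paste(m$hit_id, collapse = ","),
                 cons_coverage = cov, stringsAsFactors = FALSE)
    }
    if (nrow(h) > 1L) for (i in 2:nrow(h)) {
      prev <- members[[length(members)]]
      nxt <- h[i, ]
      if (nxt$strand == "+") {
        overlap <- prev$cons_end - nxt$cons_start + 1L
        collinear <- overlap <= max_consensus_overlap &&
          nxt$cons_end >= prev$cons_end
      } else {
        overlap <- nxt$cons_end - prev$cons_start + 1L
        collinear <- overlap <= max_consensus_overlap &&
          nxt$cons_start <= prev$cons_start
      }
      gap <- nxt$start - prev$end
      blocked <- gap > 0L && nrow(partners) &&
        interval_coverage(prev$end, nxt$start, partners$start,
                          partners$end) >= 0.5 * gap
      near <- gap <= max_genomic_gap
      bridged <- FALSE
      if (collinear && !blocked && !near && nested_repeat_bridge &&
          gap > 0L) {
        cov <- interval_coverage(prev$end, nxt$start, others$start,
                                 others$end)
        bridged <- cov >= 0.8 * gap
      }
      if (collinear && !blocked && (near || bridged)) {
        members[[length(members) + 1L]] <- nxt
      } else {
        groups[[length(groups) + 1L]] <- flush()
        members <- list(nxt)
      }
    }
    groups[[length(groups) + 1L]] <- flush()
  }
  out <- do.call(rbind, groups)
  out <- out[order(out$contig, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Default LTR/internal family pairing
#' @return data.frame mapping LTR family names to internal family names.
#' @export
default_family_pairing <- function() {
  data.frame(ltr_family = LTR_FAMILY, internal_family = INT_FAMILY,
             stringsAsFactors = FALSE)
}

#' Assemble merged hit groups into structured ERV elements
#'
#' Adjacent LTR/internal groups of a paired family set within
#' `max_part_gap` bp chain into one element; inverted parts (opposite
#' strand) are chained too, with orientation recorded — the K124-like
#' layout requires it. Structure classes: >= 2 internals and >= 3 LTRs =
#' MULTI_LTR_TANDEM; a lone LTR = SOLO_LTR; otherwise FULL_PROVIRUS when
#' the largest contiguous internal exceeds 7 kb, else TRUNCATED_PROVIRUS;
#' anything else NON_CANONICAL.
#'
#' @param groups output of [defragment_hits()] (or the `parts` of a
#'   previous assembly: assembly is idempotent).
#' @param max_part_gap bp between consecutive parts of one element.
#' @param pairing data.frame like [default_family_pairing()].
#' @return list with `elements` (one row per locus) and `parts` (ordered
#'   parts per locus, with `orientation` relative to the element).
#' @export
assemble_elements <- function(groups, max_part_gap = 100L,
                              pairing = default_family_pairing()) {
  erv_fams <- unique(c(pairing$ltr_family, pairing$internal_family))
  g <- groups[groups$family %in% erv_fams, , drop = FALSE]
  g <- g[order(g$contig, g$start), , drop = FALSE]
  kind_of <- function(fam)
    ifelse(fam %in% pairing$ltr_family, "LTR", "INTERNAL")

  elements <- list(); parts <- list(); eid <- 0L
  i <- 1L
  while (i <= nrow(g)) {
    chain <- g[i, , drop = FALSE]
    j <- i + 1L
    while (j <= nrow(g) && g$contig[j] == chain$contig[1] &&
           g$start[j] - chain$end[nrow(chain)] <= max_part_gap) {
      chain <- rbind(chain, g[j, ])
      j <- j + 1L
    }
    i <- j
    eid <- eid + 1L
    id <- sprintf("E%03d", eid)
    kinds <- kind_of(chain$family)
    lens <- chain$end - chain$start
    # element strand: strand of the largest part
    strand <- chain$strand[which.max(lens)]
    n_ltr <- sum(kinds == "LTR"); n_int <- sum(kinds == "INTERNAL")
    max_int <- if (n_int) max(lens[kinds == "INTERNAL"]) else 0L
    cls <- if (n_int >= 2L && n_ltr >= 3L) "MULTI_LTR_TANDEM"
      else if (n_ltr == 1L && n_int == 0L) "SOLO_LTR"
      else if (n_int >= 1L) {
        if (max_int > 7000L) "FULL_PROVIRUS" else "TRUNCATED_PROVIRUS"
      } else "NON_CANONICAL"
    ltr_lens <- lens[kinds == "LTR"]
    elements[[eid]] <- data.frame(
      locus_id = id, contig = chain$contig[1],
      start = min(chain$start), end = max(chain$end), strand = strand,
      structure_class = cls,
      n_parts = nrow(chain), n_ltr = n_ltr, n_internal = n_int,
      internal_length = sum(lens[kinds == "INTERNAL"]),
      max_internal_len = max_int,
      ltr5_len = if (kinds[1] == "LTR") lens[1] else NA_integer_,
      ltr3_len = if (n_ltr >= 1L && kinds[length(kinds)] == "LTR")
        lens[length(kinds)] else NA_integer_,
      stringsAsFactors = FALSE)
    parts[[eid]] <- data.frame(
      locus_id = id, contig = chain$contig, kind = kinds,
      strand = chain$strand,
      orientation = ifelse(chain$strand == strand, "same", "inverted"),
      start = chain$start, end = chain$end,
      cons_start = chain$cons_start, cons_end = chain$cons_end,
      family = chain$family, stringsAsFactors = FALSE)
  }
  elements <- do.call(rbind, elements)
  parts <- do.call(rbind, parts)
  if (is.null(elements)) {
    elements <- data.frame(); parts <- data.frame()
  } else rownames(elements) <- rownames(parts) <- NULL
  list(elements = elements, parts = parts)
}
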