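## Synthetic ERV genome generator.
##
## Builds a carrier genome with planted insertions of every observed class
## (classical full-length / truncated proviruses with 4-6 bp TSDs, solo
## LTRs retaining the founding TSD, non-classical target-deleting
## insertions with junction microhomology, K108-like 2-internal/3-LTR
## tandems, K124-like inverted-partial-LTR layouts), an outgroup genome
## carrying the pre-insertion alleles, RepeatMasker-style annotations with
## optional fragmentation by nested repeats, and a diploid population
## segregating absent/provirus/solo-LTR alleles. All truth is recorded so
## downstream stages can be scored exactly.

ERV_CLASSES <- c("CLASSICAL_FULL", "CLASSICAL_TRUNCATED", "SOLO_LTR",
                 "NON_CLASSICAL", "MULTI_LTR_TANDEM", "INVERTED_LTR")

LTR_FAMILY <- "ERVK_LTR_sim"
INT_FAMILY <- "ERVK_int_sim"
NESTED_FAMILY <- "AluY_sim"

#' Simulation configuration
#'
#' Defaults are the study conditions emulated throughout the package:
#' a 2 Mb background at the human average GC (0.41) carrying 40 insertions
#' across all six structural classes, 4-6 bp target site duplications,
#' target deletions spanning the published 6-10,207 bp envelope, 0-10 bp
#' junction microhomology, ~1% within-element LTR divergence on a ~5%
#' diverged per-locus founder, identical flanks between carrier and
#' outgroup, and a 0.2 chance that an internal annotation is fragmented by
#' a nested repeat.
#'
#' @param genome_length background length in bp.
#' @param gc_fraction background GC fraction in `[0, 1)`.
#' @param n_insertions number of planted loci.
#' @param class_mix named proportions over the six insertion classes;
#'   must sum to 1. Counts are apportioned by largest remainder.
#' @param tsd_len_range inclusive bp range for target site duplications.
#' @param target_del_range inclusive bp range for non-classical target
#'   deletions; must lie within `[1, genome_length/10]`.
#' @param microhomology_range inclusive bp range for junction microhomology
#'   at each end of a non-classical insertion.
#' @param ltr_divergence per-site substitution rate applied independently
#'   to each LTR copy relative to its locus founder.
#' @param founder_ltr_divergence per-site rate separating each locus
#'   founder LTR from the consensus LTR.
#' @param flank_divergence per-site rate separating outgroup flanks from
#'   the carrier (0 = identical flanks).
#' @param fragmentation_rate probability that an internal part's annotation
#'   is split by a nested repeat.
#' @param seed integer seed; identical seeds give byte-identical output.
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(genome_length = 2e6L,
                       gc_fraction = 0.41,
                       n_insertions = 40L,
                       class_mix = c(CLASSICAL_FULL = 0.35,
                                     CLASSICAL_TRUNCATED = 0.20,
                                     SOLO_LTR = 0.15,
                                     NON_CLASSICAL = 0.15,
                                     MULTI_LTR_TANDEM = 0.075,
                                     INVERTED_LTR = 0.075),
                       tsd_len_range = c(4L, 6L),
                       target_del_range = c(6L, 10207L),
                       microhomology_range = c(0L, 10L),
                       ltr_divergence = 0.01,
                       founder_ltr_divergence = 0.05,
                       flank_divergence = 0,
                       fragmentation_rate = 0.2,
                       seed = 1L) {
  if (abs(sum(class_mix) - 1) > 1e-9)
    stop("class_mix must sum to 1")
  if (!all(names(class_mix) %in% ERV_CLASSES))
    stop("unknown insertion class in class_mix")
  if (target_del_range[1] < 1 || target_del_range[2] > genome_length / 10)
    stop("target_del_range must lie within [1, genome_length/10]")
  structure(
    list(genome_length = as.integer(genome_length),
         gc_fraction = gc_fraction,
         n_insertions = as.integer(n_insertions),
         class_mix = class_mix,
         tsd_len_range = as.integer(tsd_len_range),
         target_del_range = as.integer(target_del_range),
         microhomology_range = as.integer(microhomology_range),
         ltr_divergence = ltr_divergence,
         founder_ltr_divergence = founder_ltr_divergence,
         flank_divergence = flank_divergence,
         fragmentation_rate = fragmentation_rate,
         seed = as.integer(seed)),
    class = "sim_config")
}

#' Generate an i.i.d. background genome
#'
#' @param length sequence length in bp (> 0).
#' @param gc_fraction expected GC fraction in `[0, 1]`.
#' @param seed integer seed.
#' @return character scalar of A/C/G/T.
#' @examples
#' s <- generate_background(1000, 0.5, 1)
#' @export
generate_background <- function(length, gc_fraction, seed) {
  if (length <= 0) stop("length must be positive")
  if (gc_fraction < 0 || gc_fraction > 1)
    stop("gc_fraction must be in [0, 1]")
  with_seed(seed, random_bases(as.integer(length), gc = gc_fraction))
}

## sample uniformly from a vector, robust to length-1 vectors
sample_from <- function(v, n = 1L) {
  v[sample.int(length(v), n, replace = TRUE)]
}

## apportion counts by largest remainder so they sum exactly to n
apportion_counts <- function(mix, n) {
  raw <- mix * n
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

## core of the TSD detector, reused by the generator to sanitize junctions:
## longest k in [min_tsd, max_tsd] such that the last k bases of `left`
## equal the first k of `right`; exact below `allow_mismatch_at`, one
## mismatch tolerated at or above it.
tsd_longest_k <- function(left, right, max_tsd = 25L, min_tsd = 4L,
                          allow_mismatch_at = 8L) {
  kmax <- min(max_tsd, nchar(left), nchar(right))
  if (kmax < min_tsd) return(list(len = 0L, mismatches = 0L))
  for (k in seq(kmax, min_tsd)) {
    l <- substr(left, nchar(left) - k + 1L, nchar(left))
    r <- substr(right, 1L, k)
    mm <- hamming(l, r)
    if (mm == 0L || (k >= allow_mismatch_at && mm == 1L))
      return(list(len = as.integer(k), mismatches = as.integer(mm)))
  }
  list(len = 0L, mismatches = 0L)
}

## build one element of a given class; returns seq + parts (element-local
## 0-based half-open coords) + metadata
build_element <- function(class, cons, cfg) {
  ltr_copy <- function(founder) mutate_seq(founder, cfg$ltr_divergence)
  founder <- mutate_seq(cons$ltr, cfg$founder_ltr_divergence)
  part <- function(kind, seq, strand, cs, ce, family) {
    list(kind = kind, seq = seq, strand = strand,
         cons_start = cs, cons_end = ce, family = family)
  }
  parts <- switch(class,
    CLASSICAL_FULL = {
      type <- sample(c("I", "II"), 1L)
      internal <- if (type == "I") cons$internal_type1 else cons$internal
      list(part("LTR", ltr_copy(founder), "+", 1L, LTR_LEN, LTR_FAMILY),
           part("INTERNAL", internal, "+", 1L, 7530L, INT_FAMILY),
           part("LTR", ltr_copy(founder), "+", 1L, LTR_LEN, LTR_FAMILY))
    },
    CLASSICAL_TRUNCATED = {
      keep <- sample(500:6500, 1L)
      a <- sample.int(7530L - keep + 1L, 1L)
      internal <- substr(cons$internal, a, a + keep - 1L)
      list(part("LTR", ltr_copy(founder), "+", 1L, LTR_LEN, LTR_FAMILY),
           part("INTERNAL", internal, "+", a, a + keep - 1L, INT_FAMILY),
           part("LTR", ltr_copy(founder), "+", 1L, LTR_LEN, LTR_FAMILY))
    },
    SOLO_LTR = list(
      part("LTR", ltr_copy(founder), "+", 1L, LTR_LEN, LTR_FAMILY)),
    NON_CLASSICAL = {
      keep <- sample(800:3000, 1L)
      a <- sample.int(7530L - keep + 1L, 1L)
      internal <- substr(cons$internal, a, a + keep - 1L)
      list(part("INTERNAL", internal, "+", a, a + keep - 1L, INT_FAMILY))
    },
    MULTI_LTR_TANDEM = list(
      part("LTR", ltr_copy(founder), "+", 1L, LTR_LEN, LTR_FAMILY),
      part("INTERNAL", cons$internal, "+", 1L, 7530L, INT_FAMILY),
      part("LTR", ltr_copy(founder), "+", 1L, LTR_LEN, LTR_FAMILY),
      part("INTERNAL", cons$internal, "+", 1L, 7530L, INT_FAMILY),
      part("LTR", ltr_copy(founder), "+", 1L, LTR_LEN, LTR_FAMILY)),
    INVERTED_LTR = {
      # K124-like end state: full LTR + partial internal + inverted
      # partial LTR + 206 bp internal + inverted partial LTR
      int1 <- substr(cons$internal, 1L, 1171L)
      int2 <- substr(cons$internal, 3000L, 3205L)
      pltr <- substr(founder, 1L, 78L)
      list(part("LTR", ltr_copy(founder), "+", 1L, LTR_LEN, LTR_FAMILY),
           part("INTERNAL", int1, "+", 1L, 1171L, INT_FAMILY),
           part("LTR", revcomp(mutate_seq(pltr, cfg$ltr_divergence)), "-",
                1L, 78L, LTR_FAMILY),
           part("INTERNAL", int2, "+", 3000L, 3205L, INT_FAMILY),
           part("LTR", revcomp(mutate_seq(pltr, cfg$ltr_divergence)), "-",
                1L, 78L, LTR_FAMILY))
    },
    stop("unknown class: ", class))

  seq <- paste(vapply(parts, `[[`, "", "seq"), collapse = "")
  offs <- cumsum(c(0L, vapply(parts, function(p) nchar(p$seq), 0L)))
  pdf <- data.frame(
    kind = vapply(parts, `[[`, "", "kind"),
    strand = vapply(parts, `[[`, "", "strand"),
    rel_start = offs[-length(offs)],
    rel_end = offs[-1L],
    cons_start = vapply(parts, function(p) as.integer(p$cons_start), 0L),
    cons_end = vapply(parts, function(p) as.integer(p$cons_end), 0L),
    family = vapply(parts, `[[`, "", "family"),
    stringsAsFactors = FALSE)
  type <- if (class %in% c("MULTI_LTR_TANDEM")) "II"
          else if (class == "CLASSICAL_FULL") {
            if (nchar(seq) < 2L * LTR_LEN + 7530L) "I" else "II"
          } else NA_character_
  list(seq = seq, parts = pdf, type = type,
       ltr5 = if (pdf$kind[1] == "LTR") parts[[1]]$seq else NA_character_)
}

#' Plant ERV insertions into a background genome
#'
#' Constructs the carrier genome (each planted allele realized), the
#' outgroup genome (pre-insertion alleles: the background, which for
#' non-classical loci retains the target bases the carrier lost), and a
#' truth table. Classical-mechanism loci duplicate `tsd_len` target bases
#' on both sides of the element; non-classical loci delete
#' `deleted_target_len` target bases and share exactly
#' `microhomology_5`/`microhomology_3` bases between the element termini
#' and the deleted region's edges. Junctions are sanitized so the realized
#' TSD/microhomology equals the recorded truth (no accidental longer
#' duplications).
#'
#' @param background background genome, character scalar (or NULL to
#'   generate one from `config`).
#' @param consensus consensus list as from [toy_provirus()].
#' @param config a [sim_config()].
#' @return list with `carrier`, `outgroup`, `background`, `truth`
#'   (data.frame, one row per locus), `parts` (data.frame of element parts
#'   in carrier coordinates), and `element_seqs` (named list).
#' @export
plant_insertions <- function(background = NULL, consensus = toy_provirus(),
                             config = sim_config()) {
  cfg <- config
  if (is.null(background))
    background <- generate_background(cfg$genome_length, cfg$gc_fraction,
                                      cfg$seed)
  with_seed(cfg$seed + 1L, plant_insertions_impl(background, consensus, cfg))
}

plant_insertions_impl <- function(bg, cons, cfg) {
  n <- cfg$n_insertions
  L <- nchar(bg)
  counts <- apportion_counts(cfg$class_mix, n)
  classes <- sample(rep(names(cfg$class_mix), counts))

  # evenly spaced sites with jitter; reserve room for flanks + deletions
  slot <- L / (n + 1)
  jit <- floor(slot / 8)
  sites <- sort(as.integer(round((1:n) * slot +
                                 sample_from(seq(-jit, jit), n))))
  if (any(classes == "NON_CLASSICAL") &&
      slot - 4500 < cfg$target_del_range[1])
    stop("deletion extends past contig spacing; enlarge the genome or ",
         "shrink target_del_range")
  dels <- ifelse(classes == "NON_CLASSICAL",
                 pmin(sample_from(cfg$target_del_range[1]:cfg$target_del_range[2],
                             n),
                      as.integer(floor(slot - 4500))),
                 0L)
  if (any(diff(sites) - dels[-n] < 4200L) ||
      sites[1] < 2100L || sites[n] + dels[n] + 2100L > L)
    stop("site collision: insertion sites/deletions overlap or exceed contig")

  truth <- vector("list", n)
  parts_all <- vector("list", n)
  elem_seqs <- vector("list", n)
  pieces <- character(0)
  cursor <- 0L   # background position consumed so far
  carrier_len <- 0L

  set_bg <- function(pos1, base) {  # 1-based position
    substr(bg, pos1, pos1) <<- base
  }

  for (i in seq_len(n)) {
    cl <- classes[i]
    x <- sites[i]
    el <- build_element(cl, cons, cfg)
    eseq <- el$seq
    elen <- nchar(eseq)

    if (cl == "NON_CLASSICAL") {
      d <- dels[i]
      tsd_len <- 0L; tsd_seq <- ""
      mh_cap <- max(0L, (d - 1L) %/% 2L)  # both ends read off the deletion
      mh5 <- min(sample_from(cfg$microhomology_range[1]:cfg$microhomology_range[2]),
                 mh_cap)
      mh3 <- min(sample_from(cfg$microhomology_range[1]:cfg$microhomology_range[2]),
                 mh_cap)
      deleted <- seq_slice(bg, x, x + d)
      # plant exact-microhomology ends, then force a mismatch just beyond
      if (mh5 > 0L) substr(eseq, 1L, mh5) <- substr(deleted, 1L, mh5)
      if (nchar(eseq) > mh5 && d > mh5 &&
          substr(eseq, mh5 + 1L, mh5 + 1L) ==
          substr(deleted, mh5 + 1L, mh5 + 1L)) {
        b <- substr(deleted, mh5 + 1L, mh5 + 1L)
        substr(eseq, mh5 + 1L, mh5 + 1L) <- setdiff(BASES, b)[sample.int(3L, 1L)]
      }
      if (mh3 > 0L)
        substr(eseq, elen - mh3 + 1L, elen) <-
          substr(deleted, d - mh3 + 1L, d)
      if (elen > mh3 && d > mh3) {
        pe <- elen - mh3; pd <- d - mh3
        if (substr(eseq, pe, pe) == substr(deleted, pd, pd)) {
          b <- substr(deleted, pd, pd)
          substr(eseq, pe, pe) <- setdiff(BASES, b)[sample.int(3L, 1L)]
        }
      }
      # sanitize: no accidental TSD at the junction (truth says blunt)
      for (try in 1:12) {
        left <- seq_slice(bg, x - 25L, x)
        right <- seq_slice(bg, x + d, x + d + 25L)
        if (tsd_longest_k(left, right)$len == 0L) break
        set_bg(x, setdiff(BASES, substr(bg, x, x))[sample.int(3L, 1L)])
      }
      deleted <- seq_slice(bg, x, x + d)  # may have been touched above
      pieces <- c(pieces, seq_slice(bg, cursor, x), eseq)
      e_start <- carrier_len + (x - cursor)
      carrier_len <- e_start + elen
      cursor <- x + d
      truth_row <- list(tsd_len = 0L, tsd_seq = "", del = d,
                        mh5 = mh5, mh3 = mh3)
    } else {
      d <- 0L
      tsd_len <- sample_from(cfg$tsd_len_range[1]:cfg$tsd_len_range[2])
      # sanitize junction so the realized duplication is exactly tsd_len
      for (try in 1:12) {
        t <- seq_slice(bg, x, x + tsd_len)
        left <- paste0(seq_slice(bg, x - 25L, x), t)
        right <- paste0(t, seq_slice(bg, x + tsd_len, x + tsd_len + 25L))
        k <- tsd_longest_k(left, right)
        if (k$len == tsd_len && k$mismatches == 0L) break
        pos <- if (try %% 2L == 1L) x else x + tsd_len + 1L
        set_bg(pos, setdiff(BASES, substr(bg, pos, pos))[sample.int(3L, 1L)])
      }
      tsd_seq <- seq_slice(bg, x, x + tsd_len)
      pieces <- c(pieces, seq_slice(bg, cursor, x + tsd_len), eseq)
      e_start <- carrier_len + (x + tsd_len - cursor)
      carrier_len <- e_start + elen
      cursor <- x
      truth_row <- list(tsd_len = tsd_len, tsd_seq = tsd_seq, del = 0L,
                        mh5 = 0L, mh3 = 0L)
    }

    id <- sprintf("L%03d", i)
    pdf <- el$parts
    pdf$locus_id <- id
    pdf$contig <- "carrier"
    pdf$start <- e_start + pdf$rel_start
    pdf$end <- e_start + pdf$rel_end
    parts_all[[i]] <- pdf[c("locus_id", "contig", "kind", "strand",
                            "start", "end", "cons_start", "cons_end",
                            "family")]
    elem_seqs[[i]] <- eseq
    truth[[i]] <- data.frame(
      locus_id = id, insertion_class = cl, contig = "carrier",
      carrier_start = e_start, carrier_end = e_start + elen,
      element_len = elen,
      bg_site = x, tsd_len = truth_row$tsd_len, tsd_seq = truth_row$tsd_seq,
      deleted_target_len = truth_row$del,
      microhomology_5 = truth_row$mh5, microhomology_3 = truth_row$mh3,
      element_type = if (is.null(el$type) || is.na(el$type))
        NA_character_ else el$type,
      freq_absent = 0, freq_provirus = 1, freq_solo = 0,
      genotyped = TRUE,
      stringsAsFactors = FALSE)
  }
  pieces <- c(pieces, seq_slice(bg, cursor, L))
  carrier <- paste(pieces, collapse = "")

  outgroup <- if (cfg$flank_divergence > 0)
    mutate_seq(bg, cfg$flank_divergence) else bg

  truth <- do.call(rbind, truth)
  parts <- do.call(rbind, parts_all)
  names(elem_seqs) <- truth$locus_id
  list(carrier = carrier, outgroup = outgroup, background = bg,
       truth = truth, parts = parts, element_seqs = elem_seqs)
}

#' Emit RepeatMasker-style annotations for planted elements
#'
#' One hit per contiguous element part. With probability
#' `fragmentation_rate`, an internal part's annotation (length >= 400 bp)
#' is split into two hits whose consensus coordinates continue across a
#' gap annotated under a nested-repeat family, emulating annotation
#' fragmentation by nested insertions. The carrier sequence itself is not
#' modified; fragmentation here is an annotation-level artifact, which is
#' all the downstream merge logic consumes.
#'
#' @param sim result of [plant_insertions()] (only `$parts` is used).
#' @param fragmentation_rate per-part split probability.
#' @param seed integer seed.
#' @return a RepeatHit data.frame (contig, start, end, strand, family,
#'   repeat_class, cons_start, cons_end, hit_id, score, div) with 0-based
#'   half-open genomic and 1-based inclusive consensus coordinates.
#' @export
emit_repeat_annotations <- function(sim, fragmentation_rate = 0, seed = 1L) {
  parts <- sim$parts
  with_seed(seed + 7L, {
    rows <- vector("list", nrow(parts))
    for (i in seq_len(nrow(parts))) {
      p <- parts[i, ]
      len <- p$end - p$start
      split_it <- p$kind == "INTERNAL" && len >= 400L &&
        stats::runif(1) < fragmentation_rate
      if (!split_it) {
        rows[[i]] <- data.frame(
          contig = p$contig, start = p$start, end = p$end,
          strand = p$strand, family = p$family,
          repeat_class = if (p$family == LTR_FAMILY) "LTR/ERVK" else "LTR/ERVK-int",
          cons_start = p$cons_start, cons_end = p$cons_end,
          stringsAsFactors = FALSE)
      } else {
        g <- sample_from(80L:min(300L, len - 300L))
        m1 <- sample_from(seq(150L, len - 150L - g))
        rows[[i]] <- data.frame(
          contig = p$contig,
          start = c(p$start, p$start + m1, p$start + m1 + g),
          end = c(p$start + m1, p$start + m1 + g, p$end),
          strand = c(p$strand, "+", p$strand),
          family = c(p$family, NESTED_FAMILY, p$family),
          repeat_class = c("LTR/ERVK-int", "SINE/Alu", "LTR/ERVK-int"),
          cons_start = c(p$cons_start, 1L, p$cons_start + m1),
          cons_end = c(p$cons_start + m1 - 1L, g, p$cons_end - g),
          stringsAsFactors = FALSE)
      }
    }
    hits <- do.call(rbind, rows)
    hits <- hits[order(hits$contig, hits$start), , drop = FALSE]
    hits$hit_id <- seq_len(nrow(hits))
    hits$score <- 2000L
    hits$div <- 1.0
    rownames(hits) <- NULL
    hits
  })
}

#' Draw a diploid population over absent/provirus/solo-LTR alleles
#'
#' 2n haplotypes are drawn independently per locus from the truth table's
#' allele frequencies; the genotype matrix records the drawn (unordered)
#' state pairs.
#'
#' @param truth truth data.frame from [plant_insertions()] (columns
#'   `freq_absent`, `freq_provirus`, `freq_solo`, `genotyped`).
#' @param n_individuals panel size.
#' @param seed integer seed.
#' @return list with `matrix` (loci x individuals data.frame of
#'   "STATE/STATE" strings, states sorted within a cell), `hap1`/`hap2`
#'   (character matrices of haplotype states), and `genotyped` (logical
#'   per-locus flag).
#' @export
simulate_population <- function(truth, n_individuals = 80L, seed = 1L) {
  freqs <- as.matrix(truth[, c("freq_absent", "freq_provirus", "freq_solo")])
  if (any(abs(rowSums(freqs) - 1) > 1e-9))
    stop("allele-state frequencies must sum to 1 per locus")
  states <- c("ABSENT", "PROVIRUS", "SOLO_LTR")
  n_loci <- nrow(truth)
  with_seed(seed + 11L, {
    draw <- function() {
      m <- matrix(NA_character_, n_loci, n_individuals)
      for (l in seq_len(n_loci))
        m[l, ] <- sample(states, n_individuals, replace = TRUE,
                         prob = freqs[l, ])
      m
    }
    hap1 <- draw(); hap2 <- draw()
    geno <- matrix(paste(pmin(hap1, hap2), pmax(hap1, hap2), sep = "/"),
                   n_loci, n_individuals)
    gm <- as.data.frame(geno, stringsAsFactors = FALSE)
    names(gm) <- sprintf("ind%03d", seq_len(n_individuals))
    rownames(gm) <- truth$locus_id
    list(matrix = gm, hap1 = hap1, hap2 = hap2,
         genotyped = truth$genotyped)
  })
}

#' Allele-frequency scheme for the population panel study
#'
#' Assigns per-locus allele frequencies reproducing the published panel
#' pattern at matched scale: of 29 loci, 4 are flagged ungenotypable
#' (segmental-duplication/centromere analogs), 13 are fixed for the
#' provirus, 9 segregate absent/provirus at 0.5/0.5, and 3 segregate all
#' three states at 0.4/0.4/0.2. At 2n = 160 haplotypes these frequencies
#' realize exactly 12 polymorphic and 3 tri-state loci with probability
#' effectively 1.
#'
#' @param truth truth data.frame with at least 29 rows.
#' @return the truth data.frame with frequency and `genotyped` columns set.
#' @export
panel_study_frequencies <- function(truth) {
  if (nrow(truth) < 29L) stop("panel scheme needs at least 29 loci")
  truth <- truth[seq_len(29L), , drop = FALSE]
  truth$genotyped <- TRUE
  truth$freq_absent <- 0; truth$freq_provirus <- 1; truth$freq_solo <- 0
  truth$genotyped[26:29] <- FALSE
  # tri-state loci need a solo-LTR allele distinct from the provirus:
  # pick loci carrying both an LTR and an internal region
  solo_ok <- which(truth$genotyped &
                   truth$insertion_class %in%
                     c("CLASSICAL_FULL", "CLASSICAL_TRUNCATED",
                       "MULTI_LTR_TANDEM", "INVERTED_LTR"))
  if (length(solo_ok) < 3L) stop("panel scheme needs 3 solo-compatible loci")
  tri <- solo_ok[1:3]
  bi <- setdiff(which(truth$genotyped), tri)[1:9]
  truth$freq_absent[tri] <- 0.4
  truth$freq_provirus[tri] <- 0.4
  truth$freq_solo[tri] <- 0.2
  truth$freq_absent[bi] <- 0.5
  truth$freq_provirus[bi] <- 0.5
  truth
}
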