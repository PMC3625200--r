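## Population genotyping by in-silico PCR: per-allele band prediction
## from flank/internal primer sets, three-state diploid genotype calling,
## and the polymorphism-rate summary.
##
## The assay mirrors the wet-lab design: one primer in each conserved
## flank and one inside the element. The flank-flank product size
## separates ABSENT (pre-insertion size), SOLO_LTR (+ LTR + one TSD) and
## PROVIRUS (+ element + one TSD) alleles; the flank-internal product
## appears only when the internal region is present.

#' Build per-locus allele sequences (absent / provirus / solo LTR)
#'
#' Local region around the insertion site: `window` bp of background on
#' each side. The provirus allele realizes the planted element with its
#' TSD; the solo-LTR allele keeps a single LTR between the TSD copies
#' (NA for loci without an LTR part); non-classical loci realize their
#' target deletion in the provirus allele.
#'
#' @param sim result of [plant_insertions()].
#' @param locus_id locus to build.
#' @param window bp of flank per side.
#' @return named list of sequences (SOLO_LTR may be NA).
#' @export
locus_alleles <- function(sim, locus_id, window = 600L) {
  tr <- sim$truth[sim$truth$locus_id == locus_id, ]
  stopifnot(nrow(tr) == 1L)
  bg <- sim$background
  x <- tr$bg_site
  d <- tr$deleted_target_len
  eseq <- sim$element_seqs[[locus_id]]
  pp <- sim$parts[sim$parts$locus_id == locus_id, , drop = FALSE]
  ltr_rows <- which(pp$kind == "LTR")
  ltr_seq <- if (length(ltr_rows)) {
    r <- pp[ltr_rows[1], ]
    substr(eseq, r$start - tr$carrier_start + 1L, r$end - tr$carrier_start)
  } else NA_character_
  left <- seq_slice(bg, x - window, x)
  tsd <- tr$tsd_seq
  if (tr$insertion_class == "NON_CLASSICAL") {
    # absent allele retains the target region the carrier deleted
    right_pre <- seq_slice(bg, x, x + d + window)
    right_post <- seq_slice(bg, x + d, x + d + window)
    list(ABSENT = paste0(left, right_pre),
         PROVIRUS = paste0(left, eseq, right_post),
         SOLO_LTR = NA_character_)
  } else if (tr$insertion_class == "SOLO_LTR") {
    # the planted allele is itself a solitary LTR; there is no distinct
    # third state at such a locus
    right <- seq_slice(bg, x, x + window)
    list(ABSENT = paste0(left, right),
         PROVIRUS = paste0(left, tsd, eseq, right),
         SOLO_LTR = NA_character_)
  } else {
    right <- seq_slice(bg, x, x + window)  # starts with the target site
    list(ABSENT = paste0(left, right),
         PROVIRUS = paste0(left, tsd, eseq, right),
         SOLO_LTR = if (is.na(ltr_seq)) NA_character_
                    else paste0(left, tsd, ltr_seq, right))
  }
}

#' Design a primer set for a locus
#'
#' Forward and reverse primers in the conserved flanks, plus a
#' reverse-oriented primer inside the internal region (when present).
#'
#' @param sim result of [plant_insertions()].
#' @param locus_id locus.
#' @param flank_offset bp from the insertion site to the primer's outer
#'   end.
#' @param primer_len bp (15-35).
#' @param internal_offset bp into the first internal part.
#' @param max_amplicon bp; larger products give no band.
#' @return list(locus_id, flank_forward, flank_reverse, internal_primer,
#'   max_amplicon).
#' @export
design_primers <- function(sim, locus_id, flank_offset = 450L,
                           primer_len = 20L, internal_offset = 300L,
                           max_amplicon = 12000L) {
  stopifnot(primer_len >= 15L, primer_len <= 35L)
  tr <- sim$truth[sim$truth$locus_id == locus_id, ]
  bg <- sim$background
  x <- tr$bg_site
  d <- tr$deleted_target_len
  fwd <- seq_slice(bg, x - flank_offset, x - flank_offset + primer_len)
  rev_site <- seq_slice(bg, x + d + flank_offset - primer_len,
                        x + d + flank_offset)
  eseq <- sim$element_seqs[[locus_id]]
  pp <- sim$parts[sim$parts$locus_id == locus_id, , drop = FALSE]
  int_rows <- which(pp$kind == "INTERNAL")
  internal <- if (length(int_rows)) {
    r <- pp[int_rows[1], ]
    s <- r$start - tr$carrier_start + internal_offset
    revcomp(substr(eseq, s + 1L, s + primer_len))
  } else NA_character_
  list(locus_id = locus_id, flank_forward = fwd,
       flank_reverse = revcomp(rev_site), internal_primer = internal,
       max_amplicon = as.integer(max_amplicon))
}

## primer sites with <= max_mismatch mismatches and an exact 3'-terminal
## base, in the given orientation ("F": primer as written anneals to the
## minus strand, extends rightward; "R": anneals to the plus strand,
## extends leftward)
primer_sites <- function(primer, subject_ds, orientation,
                         max_mismatch = 2L) {
  query <- if (orientation == "F") primer else revcomp(primer)
  m <- Biostrings::matchPattern(query, subject_ds,
                                max.mismatch = max_mismatch)
  if (!length(m)) return(data.frame(start = integer(), end = integer()))
  st <- BiocGenerics::start(m); en <- BiocGenerics::end(m)
  # 3' anchor: terminal primer base must match the template exactly
  subj <- as.character(subject_ds)
  keep <- vapply(seq_along(st), function(i) {
    if (orientation == "F")
      substr(subj, en[i], en[i]) == substr(primer, nchar(primer),
                                           nchar(primer))
    else
      substr(subj, st[i], st[i]) ==
        substr(revcomp(primer), 1L, 1L)
  }, TRUE)
  data.frame(start = st[keep] - 1L, end = en[keep])  # 0-based half-open
}

#' Predict PCR products on an allele sequence
#'
#' All products between validly oriented primer hits (forward-oriented
#' hit upstream of a reverse-oriented hit) with at most `max_mismatch`
#' mismatches and an exact 3'-terminal base; products larger than
#' `max_amplicon` are reported as NO_BAND.
#'
#' @param allele_seq character scalar.
#' @param primers list from [design_primers()].
#' @param max_mismatch per-primer mismatch allowance.
#' @return data.frame(fwd, rev, size, band); attribute `unamplifiable` is
#'   TRUE when either flank primer found no site.
#' @export
predict_amplicons <- function(allele_seq, primers, max_mismatch = 2L) {
  subj <- Biostrings::DNAString(allele_seq)
  fsites <- primer_sites(primers$flank_forward, subj, "F", max_mismatch)
  rsites <- primer_sites(primers$flank_reverse, subj, "R", max_mismatch)
  isites <- if (!is.na(primers$internal_primer))
    primer_sites(primers$internal_primer, subj, "R", max_mismatch)
  else data.frame(start = integer(), end = integer())
  out <- list()
  add <- function(fname, f, rname, r) {
    for (i in seq_len(nrow(f))) for (j in seq_len(nrow(r))) {
      if (r$end[j] > f$start[i]) {
        size <- r$end[j] - f$start[i]
        out[[length(out) + 1L]] <<- data.frame(
          fwd = fname, rev = rname, size = size,
          band = size <= primers$max_amplicon,
          stringsAsFactors = FALSE)
      }
    }
  }
  add("flank_forward", fsites, "flank_reverse", rsites)
  add("flank_forward", fsites, "internal", isites)
  res <- if (length(out)) do.call(rbind, out)
         else data.frame(fwd = character(), rev = character(),
                         size = integer(), band = logical(),
                         stringsAsFactors = FALSE)
  attr(res, "unamplifiable") <- nrow(fsites) == 0L || nrow(rsites) == 0L
  res
}

#' Expected band signatures per allele state
#'
#' @param sim result of [plant_insertions()].
#' @param locus_id locus.
#' @param primers list from [design_primers()].
#' @return named list of sorted band-size vectors per available state.
#' @export
state_signatures <- function(sim, locus_id, primers) {
  alleles <- locus_alleles(sim, locus_id)
  sigs <- list()
  for (s in names(alleles)) {
    if (is.na(alleles[[s]])) next
    amp <- predict_amplicons(alleles[[s]], primers)
    sigs[[s]] <- sort(amp$size[amp$band])
  }
  sigs
}

sizes_match <- function(obs, expct, tol) {
  if (length(obs) != length(expct)) return(FALSE)
  all(abs(sort(obs) - sort(expct)) <= tol * sort(expct))
}

#' Call a diploid genotype from observed band sizes
#'
#' Matches the observed band-size set against the union signature of
#' every unordered state pair within a relative size tolerance;
#' ambiguous (zero or multiple consistent pairs) cells are UNRESOLVED.
#'
#' @param observed_sizes numeric vector of band sizes for one individual
#'   at one locus.
#' @param signatures named list of per-state band sizes
#'   ([state_signatures()]).
#' @param size_tolerance relative tolerance.
#' @return "STATE/STATE" string (states sorted) or "UNRESOLVED".
#' @export
call_genotype <- function(observed_sizes, signatures,
                          size_tolerance = 0.05) {
  states <- names(signatures)
  obs <- sort(unique(round(observed_sizes)))
  consistent <- character(0)
  for (i in seq_along(states)) for (j in i:length(states)) {
    expct <- sort(unique(c(signatures[[i]], signatures[[j]])))
    # merge expected sizes indistinguishable at tolerance
    if (sizes_match(obs, expct, size_tolerance) ||
        sizes_match(obs, unique_within_tol(expct, size_tolerance),
                    size_tolerance))
      consistent <- c(consistent,
                      paste(sort(c(states[i], states[j])), collapse = "/"))
  }
  consistent <- unique(consistent)
  if (length(consistent) == 1L) consistent else "UNRESOLVED"
}

unique_within_tol <- function(sizes, tol) {
  sizes <- sort(sizes)
  keep <- c(TRUE, diff(sizes) > tol * sizes[-length(sizes)])
  sizes[keep]
}

#' Genotype a simulated population panel by in-silico PCR
#'
#' For each genotyped locus and individual, pools the predicted bands of
#' the two haplotype alleles and calls the state pair.
#'
#' @param sim result of [plant_insertions()].
#' @param pop result of [simulate_population()].
#' @param size_tolerance relative band-size tolerance.
#' @return list(matrix = called genotype data.frame (loci x individuals),
#'   genotyped = logical per-locus flag).
#' @export
genotype_panel <- function(sim, pop, size_tolerance = 0.05) {
  truth <- sim$truth
  loci <- truth$locus_id
  n_ind <- ncol(pop$matrix)
  called <- matrix(NA_character_, length(loci), n_ind,
                   dimnames = list(loci, names(pop$matrix)))
  for (l in seq_along(loci)) {
    if (!pop$genotyped[l]) next
    primers <- design_primers(sim, loci[l])
    sigs <- state_signatures(sim, loci[l], primers)
    alleles <- locus_alleles(sim, loci[l])
    amps <- lapply(sigs, identity)  # per-state band sizes
    for (ind in seq_len(n_ind)) {
      h <- c(pop$hap1[l, ind], pop$hap2[l, ind])
      obs <- sort(unique(unlist(amps[h])))
      called[l, ind] <- call_genotype(obs, sigs, size_tolerance)
    }
  }
  list(matrix = as.data.frame(called, stringsAsFactors = FALSE),
       genotyped = pop$genotyped)
}

#' Summarize polymorphism over a genotype matrix
#'
#' A locus is polymorphic iff at least two distinct haplotype states are
#' observed across all genotyped individuals; the rate is polymorphic /
#' genotyped loci. Loci exhibiting all three states are flagged.
#'
#' @param geno_matrix loci x individuals data.frame of "STATE/STATE"
#'   strings (UNRESOLVED cells ignored).
#' @param genotyped logical per-locus flag; ungenotypable loci are
#'   excluded from the denominator.
#' @return list(per_locus, n_polymorphic, n_genotyped,
#'   polymorphism_percent, tri_state_loci).
#' @export
polymorphism_summary <- function(geno_matrix,
                                 genotyped = rep(TRUE, nrow(geno_matrix))) {
  loci <- rownames(geno_matrix)
  states_of <- function(row) {
    cells <- unlist(row, use.names = FALSE)
    cells <- cells[!is.na(cells) & cells != "UNRESOLVED"]
    unique(unlist(strsplit(cells, "/", fixed = TRUE)))
  }
  per <- lapply(seq_len(nrow(geno_matrix)), function(l)
    states_of(geno_matrix[l, ]))
  n_states <- vapply(per, length, 0L)
  polymorphic <- n_states >= 2L & genotyped
  tri <- n_states == 3L & genotyped
  n_gt <- sum(genotyped)
  if (n_gt == 0L) stop("no genotyped loci")
  list(per_locus = data.frame(locus_id = loci,
                              genotyped = genotyped,
                              n_states = n_states,
                              polymorphic = polymorphic,
                              tri_state = tri,
                              stringsAsFactors = FALSE),
       n_polymorphic = sum(polymorphic),
       n_genotyped = n_gt,
       polymorphism_percent = 100 * sum(polymorphic) / n_gt,
       tri_state_loci = loci[tri])
}
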