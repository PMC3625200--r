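## End-to-end orchestration and summary reporting, plus re-derivation of
## the published aggregate counts from the bundled machine-readable
## transcriptions of the survey's structure and locus tables.

#' Path to a bundled fixture file
#' @param file file name under `extdata`.
#' @export
ervscribe_fixture <- function(file) {
  system.file("extdata", file, package = "ervscribe", mustWork = TRUE)
}

#' Construct and validate a catalog summary
#'
#' @param n_events,n_full_length,n_truncated,n_non_classical event counts
#'   (non-classical loci are counted apart from full/truncated).
#' @param n_type_I,n_type_II subtype counts among full-length events.
#' @param n_polymorphic,n_genotyped panel counts.
#' @param mean_rec_rate cM/Mb.
#' @param n_intact_no_stop_typeI type I full-length elements without stop
#'   codons.
#' @param n_intact_typeII type II full-length elements without stop codons
#'   or structural breaks.
#' @return list of class `catalog_summary`; errors if the event counts do
#'   not add up.
#' @export
catalog_summary <- function(n_events, n_full_length, n_truncated,
                            n_non_classical, n_type_I = NA_integer_,
                            n_type_II = NA_integer_,
                            n_polymorphic = NA_integer_,
                            n_genotyped = NA_integer_,
                            mean_rec_rate = NA_real_,
                            n_intact_no_stop_typeI = NA_integer_,
                            n_intact_typeII = NA_integer_) {
  if (n_events != n_full_length + n_truncated + n_non_classical)
    stop("event counts do not sum: ", n_events, " != ",
         n_full_length, " + ", n_truncated, " + ", n_non_classical)
  pct <- if (!is.na(n_genotyped) && n_genotyped > 0)
    100 * n_polymorphic / n_genotyped else NA_real_
  structure(list(
    n_events = n_events, n_full_length = n_full_length,
    n_truncated = n_truncated, n_non_classical = n_non_classical,
    n_type_I = n_type_I, n_type_II = n_type_II,
    n_polymorphic = n_polymorphic, n_genotyped = n_genotyped,
    polymorphism_percent = pct, mean_rec_rate = mean_rec_rate,
    n_intact_no_stop_typeI = n_intact_no_stop_typeI,
    n_intact_typeII = n_intact_typeII), class = "catalog_summary")
}

#' @export
print.catalog_summary <- function(x, ...) {
  cat("ERV insertion catalog summary\n")
  cat(sprintf("  events: %d (%d full-length, %d truncated, %d non-classical)\n",
              x$n_events, x$n_full_length, x$n_truncated,
              x$n_non_classical))
  if (!is.na(x$n_type_I))
    cat(sprintf("  full-length subtypes: %d type I / %d type II\n",
                x$n_type_I, x$n_type_II))
  if (!is.na(x$polymorphism_percent))
    cat(sprintf("  polymorphic: %d/%d (%.1f%%)\n", x$n_polymorphic,
                x$n_genotyped, x$polymorphism_percent))
  if (!is.na(x$mean_rec_rate))
    cat(sprintf("  mean recombination rate: %.1f cM/Mb\n",
                x$mean_rec_rate))
  invisible(x)
}

#' Recompute the published aggregates from the bundled locus tables
#'
#' Applies the package's own rules to the transcribed tables: the
#' full-length call (largest internal > 7 kb, multi-internal loci counted
#' once), the non-classical and polymorphic feature flags, the
#' genotyped-locus denominator (segmental-duplication/centromere loci
#' never observed polymorphic are the unamplifiable set), the
#' recombination-rate mean, subtype counts, and stop-free tallies.
#'
#' @param loci_tsv path to the locus-characteristics TSV (defaults to
#'   the bundled fixture).
#' @param structure_tsv path to the full-length structure TSV.
#' @return a [catalog_summary()].
#' @export
summarize_fixture <- function(loci_tsv = ervscribe_fixture("locus_catalog.tsv"),
                              structure_tsv = ervscribe_fixture("fulllength_structure.tsv")) {
  t3 <- utils::read.delim(loci_tsv, stringsAsFactors = FALSE)
  t2 <- utils::read.delim(structure_tsv, stringsAsFactors = FALSE)
  need3 <- c("locus", "features", "rec_rate", "internal", "internal2")
  need2 <- c("type", "locus", "comment", "stop_region")
  if (!all(need3 %in% names(t3)) || !all(need2 %in% names(t2)))
    stop("fixture schema mismatch")

  n_events <- nrow(t3)
  max_internal <- pmax(t3$internal, t3$internal2, na.rm = TRUE)
  non_classical <- grepl("Non-classical", t3$features)
  full <- call_full_length(max_internal) & !non_classical
  polymorphic <- grepl("polymorphic", t3$features, ignore.case = TRUE)
  excluded <- grepl("SD region|centromere", t3$features) & !polymorphic
  n_genotyped <- n_events - sum(excluded)

  # one event per locus: collapse sub-lettered rows (e.g. tandem halves)
  t2$event <- sub("[a-z]$", "", t2$locus)
  ev <- t2[!duplicated(t2$event), , drop = FALSE]
  no_stop <- !nzchar(trimws(t2$stop_region)) | t2$stop_region == "-"
  no_stop_ev <- tapply(no_stop, t2$event, all)[ev$event]
  clean_comment <- !nzchar(trimws(t2$comment)) | t2$comment == "-"
  clean_ev <- tapply(clean_comment, t2$event, all)[ev$event]

  catalog_summary(
    n_events = n_events,
    n_full_length = sum(full),
    n_truncated = n_events - sum(full) - sum(non_classical),
    n_non_classical = sum(non_classical),
    n_type_I = sum(ev$type == "I"),
    n_type_II = sum(ev$type == "II"),
    n_polymorphic = sum(polymorphic),
    n_genotyped = n_genotyped,
    mean_rec_rate = round(mean(t3$rec_rate), 1),
    n_intact_no_stop_typeI = sum(ev$type == "I" & no_stop_ev),
    n_intact_typeII = sum(ev$type == "II" & no_stop_ev & clean_ev))
}

#' Synthetic context tracks for a simulated genome
#'
#' Gene intervals, recombination-rate tiles and a two-arm cytoband
#' layout, generated deterministically so context statistics can run on
#' simulated carriers.
#'
#' @param genome_length bp.
#' @param seed integer.
#' @param genes_per_mb expected gene density.
#' @param tile bp per recombination-rate window.
#' @param mean_rate cM/Mb (rates drawn from a gamma with this mean).
#' @return list(genes, rate_windows, cytobands).
#' @export
simulate_context_tracks <- function(genome_length, seed = 1L,
                                    genes_per_mb = 10, tile = 100000L,
                                    mean_rate = 1.2) {
  with_seed(seed + 23L, {
    n_genes <- stats::rpois(1, genes_per_mb * genome_length / 1e6)
    gs <- sort(sample.int(genome_length - 10000L, n_genes))
    genes <- data.frame(gene_id = sprintf("G%04d", seq_len(n_genes)),
                        start = gs,
                        end = gs + sample(2000:10000, n_genes, TRUE),
                        stringsAsFactors = FALSE)
    starts <- seq(0L, genome_length - 1L, by = tile)
    rate_windows <- data.frame(
      contig = "carrier", start = starts,
      end = pmin(starts + tile, genome_length),
      rate = round(stats::rgamma(length(starts), shape = 2,
                                 scale = mean_rate / 2), 1),
      stringsAsFactors = FALSE)
    p_end <- as.integer(genome_length * 0.4)
    cytobands <- data.frame(
      contig = "carrier", start = c(0L, p_end),
      end = c(p_end, genome_length), arm = c("p", "q"),
      stringsAsFactors = FALSE)
    list(genes = genes, rate_windows = rate_windows, cytobands = cytobands)
  })
}

#' Structure report over an assembled catalog
#'
#' Per element: full-length flag, subtype and ORF annotation per internal
#' copy (tandem loci are annotated per copy but counted as one event),
#' and 5'/3' LTR divergence.
#'
#' @param assembly list from [assemble_elements()].
#' @param carrier carrier genome.
#' @param consensus consensus list.
#' @return data.frame, one row per internal copy (solo LTRs: one row with
#'   NA type), with `copy` indexing copies within a locus.
#' @export
structure_report <- function(assembly, carrier,
                             consensus = toy_provirus()) {
  els <- assembly$elements
  rows <- list()
  for (i in seq_len(nrow(els))) {
    el <- els[i, ]
    pp <- assembly$parts[assembly$parts$locus_id == el$locus_id, ,
                         drop = FALSE]
    ints <- pp[pp$kind == "INTERNAL", , drop = FALSE]
    ltrs <- pp[pp$kind == "LTR", , drop = FALSE]
    ltr5 <- if (nrow(ltrs)) seq_slice(carrier, ltrs$start[1], ltrs$end[1])
            else NA_character_
    ltr3 <- if (nrow(ltrs) > 1L)
      seq_slice(carrier, ltrs$start[nrow(ltrs)], ltrs$end[nrow(ltrs)])
    else NA_character_
    div <- ltr_divergence(ltr5, ltr3)
    if (!nrow(ints)) {
      rows[[length(rows) + 1L]] <- data.frame(
        locus_id = el$locus_id, copy = 1L,
        structure_class = el$structure_class,
        full_length = FALSE, element_type = NA_character_,
        n_stop_genes = NA_integer_, fused_pol_env = NA,
        ltr_k2p = div$d, stringsAsFactors = FALSE)
      next
    }
    for (ci in seq_len(nrow(ints))) {
      iseq <- seq_slice(carrier, ints$start[ci], ints$end[ci])
      if (ints$strand[ci] == "-") iseq <- revcomp(iseq)
      ty <- call_type(iseq, consensus)
      orfs <- annotate_orfs(iseq, consensus, element_type = ty)
      rows[[length(rows) + 1L]] <- data.frame(
        locus_id = el$locus_id, copy = ci,
        structure_class = el$structure_class,
        full_length = call_full_length(el),
        element_type = if (is.na(ty)) NA_character_ else ty,
        n_stop_genes = sum(orfs$genes$status == "STOP"),
        fused_pol_env = orfs$fused,
        ltr_k2p = div$d, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  path
}

#' Write an element catalog as BED12 (blocks = parts)
#' @param assembly list from [assemble_elements()].
#' @param path output path.
#' @export
write_catalog_bed <- function(assembly, path) {
  els <- assembly$elements
  lines <- character(nrow(els))
  for (i in seq_len(nrow(els))) {
    el <- els[i, ]
    pp <- assembly$parts[assembly$parts$locus_id == el$locus_id, ,
                         drop = FALSE]
    pp <- pp[order(pp$start), ]
    lines[i] <- paste(el$contig, el$start, el$end, el$locus_id, 0,
                      el$strand, el$start, el$end, "0,0,0", nrow(pp),
                      paste0(paste(pp$end - pp$start, collapse = ","), ","),
                      paste0(paste(pp$start - el$start, collapse = ","), ","),
                      sep = "\t")
  }
  writeLines(lines, path)
  invisible(path)
}

#' Run the full pipeline on a simulated genome
#'
#' Stages in dependency order: simulate, annotate, defragment + assemble,
#' lineage screen, structure typing, LTR phylogeny, genomic context, and
#' (given at least 29 loci) the population panel. Every output file is
#' logged with its md5 hash; reruns with the same config give identical
#' hashes.
#'
#' @param config a [sim_config()].
#' @param out_dir output directory (created).
#' @param outgroups logical: run the lineage stage (FALSE skips it with a
#'   warning and leaves the summary fields NA).
#' @param n_individuals panel size.
#' @param boot_reps bootstrap replicates for the LTR tree.
#' @return list(summary, files (named md5 vector), stages).
#' @export
run_pipeline <- function(config = sim_config(), out_dir = tempfile("erv"),
                         outgroups = TRUE, n_individuals = 80L,
                         boot_reps = 1000L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cons <- toy_provirus()
  stages <- list()
  step <- function(name, expr) {
    res <- tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    stages[[name]] <<- TRUE
    res
  }

  sim <- step("simulate", plant_insertions(config = config))
  write_fasta_chr(c(carrier = sim$carrier), file.path(out_dir, "carrier.fa"))
  write_fasta_chr(c(outgroup = sim$outgroup),
                  file.path(out_dir, "outgroup.fa"))
  write_tsv(sim$truth, file.path(out_dir, "truth.tsv"))

  hits <- step("annotate",
               emit_repeat_annotations(sim, config$fragmentation_rate,
                                       config$seed))
  write_repeat_hits(hits, file.path(out_dir, "hits.out"),
                    contig_lens = c(carrier = nchar(sim$carrier)),
                    family_lens = c(ERVK_LTR_sim = LTR_LEN,
                                    ERVK_int_sim = 7530L))

  assembly <- step("catalog", {
    groups <- defragment_hits(hits)
    assemble_elements(groups)
  })
  write_tsv(assembly$elements, file.path(out_dir, "catalog.tsv"))
  write_catalog_bed(assembly, file.path(out_dir, "catalog.bed"))

  lineage <- NULL
  if (isTRUE(outgroups)) {
    lineage <- step("lineage",
                    lineage_screen(assembly$elements, sim$carrier,
                                   list(outgroup = sim$outgroup)))
    write_tsv(lineage, file.path(out_dir, "lineage.tsv"))
  } else {
    warning("no outgroups configured; lineage stage skipped")
  }

  structure <- step("structure", structure_report(assembly, sim$carrier,
                                                  cons))
  write_tsv(structure, file.path(out_dir, "structure.tsv"))

  phylo <- step("phylo", {
    ltr_seqs <- catalog_ltr_sequences(assembly, sim$carrier)
    if (length(ltr_seqs$alignment) >= 4L) {
      bs <- bootstrap_support(ltr_seqs$alignment, n_reps = boot_reps,
                              seed = config$seed)
      ape::write.tree(bs$labelled_tree, file.path(out_dir, "ltr_tree.nwk"))
      bs
    } else NULL
  })

  tracks <- simulate_context_tracks(nchar(sim$carrier), config$seed)
  context <- step("context", {
    rec <- recombination_context(tracks$rate_windows, tracks$cytobands,
                                 data.frame(locus_id = assembly$elements$locus_id,
                                            contig = assembly$elements$contig,
                                            start = assembly$elements$start,
                                            end = assembly$elements$end))
    gc <- vapply(seq_len(nrow(assembly$elements)), function(i)
      gc_content_flanks(sim$carrier, assembly$elements$start[i],
                        assembly$elements$end[i])$gc_percent, 0)
    gd <- vapply(seq_len(nrow(assembly$elements)), function(i)
      gene_density(tracks$genes, assembly$elements$start[i],
                   assembly$elements$end[i],
                   contig_len = nchar(sim$carrier)), 0)
    cbind(rec$per_locus, gc_percent = gc, genes_per_mb = gd)
  })
  write_tsv(context, file.path(out_dir, "context.tsv"))

  panel <- NULL
  if (nrow(sim$truth) >= 29L) {
    panel <- step("genotype", {
      ptruth <- panel_study_frequencies(sim$truth)
      psim <- sim; psim$truth <- ptruth
      pop <- simulate_population(ptruth, n_individuals, config$seed)
      called <- genotype_panel(psim, pop)
      polymorphism_summary(called$matrix, called$genotyped)
    })
    write_tsv(panel$per_locus, file.path(out_dir, "panel.tsv"))
  }

  non_classical <- if (!is.null(lineage))
    sum(lineage$mechanism == "NON_CLASSICAL") else NA_integer_
  nc_ids <- if (!is.null(lineage))
    lineage$locus_id[lineage$mechanism == "NON_CLASSICAL"] else character(0)
  full <- sum(call_full_length(assembly$elements) &
              !(assembly$elements$locus_id %in% nc_ids))
  n_events <- nrow(assembly$elements)
  summary <- catalog_summary(
    n_events = n_events,
    n_full_length = full,
    n_truncated = n_events - full -
      ifelse(is.na(non_classical), 0L, non_classical),
    n_non_classical = ifelse(is.na(non_classical), 0L, non_classical),
    n_polymorphic = if (!is.null(panel)) panel$n_polymorphic else NA_integer_,
    n_genotyped = if (!is.null(panel)) panel$n_genotyped else NA_integer_,
    mean_rec_rate = context$rate |> mean(na.rm = TRUE) |> round(1))

  files <- list.files(out_dir, full.names = TRUE)
  hashes <- tools::md5sum(files)
  names(hashes) <- basename(files)
  list(summary = summary, files = hashes,
       stages = names(stages), sim = sim, assembly = assembly,
       lineage = lineage, structure = structure, phylo = phylo,
       context = context, panel = panel, out_dir = out_dir)
}

#' Collect labelled LTR sequences from an assembled catalog
#'
#' Elements contribute their LTR copies labelled `<locus>_5p`, `_3p`
#' (and `_m<i>` for additional copies); sequences below the minimum
#' length are excluded (see [align_ltrs()]).
#'
#' @param assembly list from [assemble_elements()].
#' @param carrier carrier genome.
#' @param min_len minimum LTR length.
#' @return list(alignment, excluded) from [align_ltrs()].
#' @export
catalog_ltr_sequences <- function(assembly, carrier, min_len = 300L) {
  seqs <- character(0)
  for (i in seq_len(nrow(assembly$elements))) {
    el <- assembly$elements[i, ]
    pp <- assembly$parts[assembly$parts$locus_id == el$locus_id, ,
                         drop = FALSE]
    ltrs <- pp[pp$kind == "LTR", , drop = FALSE]
    if (nrow(ltrs) < 2L) next
    for (k in seq_len(nrow(ltrs))) {
      tag <- if (k == 1L) "5p" else if (k == nrow(ltrs)) "3p"
             else paste0("m", k - 1L)
      s <- seq_slice(carrier, ltrs$start[k], ltrs$end[k])
      if (ltrs$strand[k] == "-") s <- revcomp(s)
      seqs[paste0(el$locus_id, "_", tag)] <- s
    }
  }
  align_ltrs(seqs, min_len = min_len)
}
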