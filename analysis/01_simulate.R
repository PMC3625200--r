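#!/usr/bin/env Rscript
# Stage 1 — simulate the study genome.
#
# Builds the synthetic carrier/outgroup pair the rest of the analysis
# runs on: a 2 Mb background at 41% GC carrying 40 ERV insertions drawn
# from all six structural classes (full-length and truncated proviruses
# with 4-6 bp TSDs, solo LTRs, non-classical target-deleting insertions
# with 0-10 bp junction microhomology, 2-internal/3-LTR tandems, and the
# inverted-partial-LTR layout), plus RepeatMasker-style annotations with
# a 0.2 per-part chance of fragmentation by a nested repeat.

suppressMessages(library(ervscribe))

out <- "results/analysis"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

cfg <- sim_config(seed = 42L)
sim <- plant_insertions(config = cfg)
hits <- emit_repeat_annotations(sim, cfg$fragmentation_rate, cfg$seed)

Biostrings::writeXStringSet(
  Biostrings::DNAStringSet(c(carrier = sim$carrier)),
  file.path(out, "carrier.fa"))
Biostrings::writeXStringSet(
  Biostrings::DNAStringSet(c(outgroup = sim$outgroup)),
  file.path(out, "outgroup.fa"))
write.table(sim$truth, file.path(out, "truth.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(sim$parts, file.path(out, "truth_parts.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write_repeat_hits(hits, file.path(out, "hits.out"),
                  contig_lens = c(carrier = nchar(sim$carrier)),
                  family_lens = c(ERVK_LTR_sim = 968L,
                                  ERVK_int_sim = 7530L))

cat(sprintf("planted %d loci on a %d bp carrier (%d annotation rows; %d parts)\n",
            nrow(sim$truth), nchar(sim$carrier), nrow(hits),
            nrow(sim$parts)))
print(table(sim$truth$insertion_class))
cat(sprintf("target deletions: %s bp; microhomology: %s bp per end\n",
            paste(range(sim$truth$deleted_target_len[
              sim$truth$insertion_class == "NON_CLASSICAL"]),
              collapse = "-"),
            paste(range(c(sim$truth$microhomology_5,
                          sim$truth$microhomology_3)), collapse = "-")))
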