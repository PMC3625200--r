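#!/usr/bin/env Rscript
# Stage 6 — genomic context of the insertion loci.
#
# Flanking GC content (20 kb each side, element excluded), gene density
# in a 2 Mb window centered on each locus, and the recombination rate of
# the window holding each midpoint, summarized per chromosome arm.
# Gene and recombination tracks are simulated deterministically (10
# genes/Mb, gamma-distributed rates with mean 1.2 cM/Mb) since the
# carrier is synthetic.

suppressMessages(library(ervscribe))

out <- "results/analysis"
carrier <- as.character(Biostrings::readDNAStringSet(
  file.path(out, "carrier.fa"))[[1]])
elements <- read.delim(file.path(out, "catalog.tsv"))

tracks <- simulate_context_tracks(nchar(carrier), seed = 42L)
rec <- recombination_context(tracks$rate_windows, tracks$cytobands,
                             data.frame(locus_id = elements$locus_id,
                                        contig = elements$contig,
                                        start = elements$start,
                                        end = elements$end))
gc <- vapply(seq_len(nrow(elements)), function(i)
  gc_content_flanks(carrier, elements$start[i],
                    elements$end[i])$gc_percent, 0)
gd <- vapply(seq_len(nrow(elements)), function(i)
  gene_density(tracks$genes, elements$start[i], elements$end[i],
               contig_len = nchar(carrier)), 0)

ctx <- cbind(rec$per_locus, gc_percent = round(gc, 1),
             genes_per_mb = round(gd, 1))
write.table(ctx, file.path(out, "context.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

cat(sprintf("flanking GC: mean %.1f%% (background GC 41%%)\n", mean(gc)))
cat(sprintf("gene density: mean %.1f genes/Mb\n", mean(gd)))
print(rec$summary)
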