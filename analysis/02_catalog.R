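#!/usr/bin/env Rscript
# Stage 2 — defragment annotations and assemble the element catalog.
#
# Annotation tools report one row per fragment, so nested repeats split
# a single element across several hits; defragmentation merges collinear
# same-family fragments (bridging gaps covered by nested-repeat hits)
# and assembly chains adjacent LTR/internal parts into structured loci.
# The hit-vs-locus count gap below is the fragmentary-annotation
# phenomenon in miniature.

suppressMessages(library(ervscribe))

out <- "results/analysis"
hits <- parse_repeat_hits(file.path(out, "hits.out"))
groups <- defragment_hits(hits)
asm <- assemble_elements(groups)

write.table(asm$elements, file.path(out, "catalog.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(asm$parts, file.path(out, "catalog_parts.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write_catalog_bed(asm, file.path(out, "catalog.bed"))

truth <- read.delim(file.path(out, "truth.tsv"))
recovered <- sum(paste(asm$elements$start, asm$elements$end) %in%
                 paste(truth$carrier_start, truth$carrier_end))
cat(sprintf("%d raw hits -> %d merged groups -> %d elements (%d/%d planted spans recovered)\n",
            nrow(hits), nrow(groups), nrow(asm$elements), recovered,
            nrow(truth)))
print(table(asm$elements$structure_class))
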