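Package: ervscribe
Title: Identification and Characterization of Lineage-Specific Endogenous
    Retrovirus Insertions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An analysis pipeline for cataloguing lineage-specific endogenous
    retrovirus (ERV) insertions from repeat-annotation tables and genome
    sequences. Merges fragmented RepeatMasker-style hits into structured
    LTR/internal elements, decides presence or absence at orthologous
    positions in outgroup genomes, detects target site duplications,
    classifies classical versus non-classical (target-deleting) insertion
    mechanisms with junction microhomology, annotates gag/pro/pol/env open
    reading frames against a consensus, builds bootstrap-supported
    neighbor-joining phylogenies of LTRs under the Kimura two-parameter
    model, computes flanking GC content, gene density and recombination-rate
    context, and genotypes absent/provirus/solo-LTR allele states in a
    diploid population panel by in-silico PCR. A synthetic-genome generator
    with known planted truth makes every stage testable without reference
    genomes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    IRanges,
    ape,
    jsonlite,
    methods,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
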