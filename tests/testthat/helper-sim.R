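# Shared simulated fixtures, built once per test run and memoized.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

# compact all-class genome: 600 kb, 10 loci
small_cfg <- function(...) {
  sim_config(genome_length = 600000L, n_insertions = 10L, seed = 3L, ...)
}

small_sim <- function() {
  fixture("small_sim", function() plant_insertions(config = small_cfg()))
}

small_assembly <- function() {
  fixture("small_assembly", function() {
    hits <- emit_repeat_annotations(small_sim(), fragmentation_rate = 0,
                                    seed = 3L)
    assemble_elements(defragment_hits(hits))
  })
}

# 29-locus genome for the population panel
panel_sim <- function() {
  fixture("panel_sim", function()
    plant_insertions(config = sim_config(genome_length = 1600000L,
                                         n_insertions = 29L, seed = 13L)))
}

# full-provirus-only genome for LTR phylogeny (within-element divergence
# 0.01, between-element 0.10)
phylo_sim <- function() {
  fixture("phylo_sim", function()
    plant_insertions(config = sim_config(
      genome_length = 800000L, n_insertions = 12L,
      class_mix = c(CLASSICAL_FULL = 1, CLASSICAL_TRUNCATED = 0,
                    SOLO_LTR = 0, NON_CLASSICAL = 0,
                    MULTI_LTR_TANDEM = 0, INVERTED_LTR = 0),
      ltr_divergence = 0.01, founder_ltr_divergence = 0.10, seed = 9L)))
}

phylo_ltrs <- function() {
  fixture("phylo_ltrs", function() {
    sim <- phylo_sim()
    hits <- emit_repeat_annotations(sim, 0, 9L)
    asm <- assemble_elements(defragment_hits(hits))
    catalog_ltr_sequences(asm, sim$carrier)
  })
}

# match assembled elements back to planted truth rows by exact span
truth_match <- function(elements, truth) {
  match(paste(elements$start, elements$end),
        paste(truth$carrier_start, truth$carrier_end))
}

rand_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
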