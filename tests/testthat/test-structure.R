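# Structure typing: full-length rule, subtype calls, ORF annotation,
# nested insertions, LTR divergence.

test_that("the full-length call applies the 7 kb rule with strict inequality", {
  expect_true(call_full_length(7530))
  expect_false(call_full_length(515))
  expect_false(call_full_length(7000))
  expect_true(call_full_length(7001))
})

test_that("subtype calls hinge on the pol-env boundary segment", {
  cons <- toy_provirus()
  expect_equal(call_type(cons$internal, cons), "II")
  expect_equal(call_type(cons$internal_type1, cons), "I")
  # truncated before pol: boundary region not covered on either side
  expect_true(is.na(call_type(substr(cons$internal, 1, 2000), cons)))
})

test_that("the intact consensus annotates as four intact genes", {
  cons <- toy_provirus()
  rep <- annotate_orfs(cons$seq, cons, element_type = "II")
  expect_equal(rep$genes$status, rep("INTACT", 4))
  expect_false(rep$fused)
})

test_that("a planted in-frame TGA in pro is found; other genes stay intact", {
  cons <- toy_provirus()
  gm <- cons$gene_map
  pro <- gm[gm$gene == "pro", ]
  # overwrite the second codon of pro with TGA
  seq <- cons$seq
  substr(seq, pro$start + 3L, pro$start + 5L) <- "TGA"
  rep <- annotate_orfs(seq, cons)
  expect_equal(rep$genes$status[rep$genes$gene == "pro"], "STOP")
  expect_equal(rep$genes$stop_codon[rep$genes$gene == "pro"], "TGA")
  expect_equal(rep$genes$status[rep$genes$gene != "pro"], rep("INTACT", 3))
})

test_that("the boundary-deleted internal shows the in-frame pol-env fusion", {
  cons <- toy_provirus()
  type1 <- paste0(cons$ltr, cons$internal_type1, cons$ltr)
  ty <- call_type(cons$internal_type1, cons)
  expect_equal(ty, "I")
  rep <- annotate_orfs(type1, cons, element_type = ty)
  expect_true(rep$fused)
  # the fusion is only reportable for type I
  rep2 <- annotate_orfs(cons$seq, cons, element_type = "II")
  expect_false(rep2$fused)
})

test_that("ORF reports are strand-consistent", {
  cons <- toy_provirus()
  fwd <- annotate_orfs(cons$seq, cons)
  rev <- annotate_orfs(revcomp(cons$seq), cons, strand = "-")
  expect_identical(fwd$genes, rev$genes)
})

test_that("nested insertions are reported with their host gene", {
  cfg <- sim_config(genome_length = 200000L, n_insertions = 1L,
                    class_mix = c(CLASSICAL_FULL = 1, CLASSICAL_TRUNCATED = 0,
                                  SOLO_LTR = 0, NON_CLASSICAL = 0,
                                  MULTI_LTR_TANDEM = 0, INVERTED_LTR = 0),
                    seed = 53L)
  sim <- plant_insertions(config = cfg)
  hits <- emit_repeat_annotations(sim, fragmentation_rate = 1, seed = 53L)
  asm <- assemble_elements(defragment_hits(hits))
  el <- asm$elements[1, ]
  pp <- asm$parts[asm$parts$locus_id == el$locus_id, ]
  nested <- detect_nested_insertions(el, pp, hits)
  expect_gte(nrow(nested), 1L)
  expect_true(all(nested$family == "AluY_sim"))
  expect_true(all(nested$gene %in% c("gag", "pro", "pol", "env",
                                     NA_character_)))

  # clean element: no nested hits reported
  clean_hits <- emit_repeat_annotations(sim, 0, 53L)
  expect_equal(nrow(detect_nested_insertions(el, pp, clean_hits)), 0L)

  # a foreign hit in the flank (outside the span) is not reported
  flank_hit <- clean_hits[1, ]
  flank_hit$family <- "AluY_sim"
  flank_hit$start <- el$end + 500L
  flank_hit$end <- el$end + 800L
  expect_equal(nrow(detect_nested_insertions(el, pp,
                                             rbind(clean_hits, flank_hit))),
               0L)
})

test_that("LTR divergence matches the closed form and ape's K80", {
  set.seed(61)
  a <- rand_dna(200)
  # 20 transitions + 10 transversions at scattered sites: P=0.1, Q=0.05
  ch <- strsplit(a, "")[[1]]
  transition <- c(A = "G", G = "A", C = "T", T = "C")
  transversion <- c(A = "C", G = "T", C = "G", T = "A")
  b <- ch
  ts_sites <- seq(1, by = 6, length.out = 20)
  tv_sites <- seq(123, by = 6, length.out = 10)
  b[ts_sites] <- transition[ch[ts_sites]]
  b[tv_sites] <- transversion[ch[tv_sites]]
  b <- paste(b, collapse = "")

  expect_equal(ltr_divergence(a, a)$d, 0)
  div <- ltr_divergence(a, b)
  expect_equal(div$d, 0.1701812, tolerance = 1e-6)
  expect_equal(div$d, ltr_divergence(b, a)$d)

  # independent oracle
  m <- rbind(a = tolower(strsplit(a, "")[[1]]),
             b = tolower(strsplit(b, "")[[1]]))
  expect_equal(div$d,
               as.numeric(ape::dist.dna(ape::as.DNAbin(m), model = "K80")),
               tolerance = 1e-9)

  short <- ltr_divergence(substr(a, 1, 80), substr(b, 1, 80))
  expect_true(is.na(short$d))
})

test_that("planted subtypes are recovered wherever the boundary is covered", {
  sim <- small_sim()
  asm <- small_assembly()
  rep <- structure_report(asm, sim$carrier)
  m <- truth_match(asm$elements, sim$truth)
  first_copy <- rep[rep$copy == 1L, ]
  planted <- sim$truth$element_type[m]
  comparable <- !is.na(planted)
  expect_true(all(first_copy$element_type[comparable] ==
                  planted[comparable]))
  # full-length flags follow the internal length of the planted class
  expect_equal(first_copy$full_length,
               sim$truth$insertion_class[m] %in%
                 c("CLASSICAL_FULL", "MULTI_LTR_TANDEM"))
})
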