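# Lineage specificity: flank extraction/mapping, ortholog states, TSD
# and microhomology detection, mechanism classification, full recovery.

test_that("flank extraction is exact slicing, clipped at contig ends", {
  g <- rand_dna(100000, seed = 1)
  fl <- extract_flanks(g, 5000L, 14000L)
  expect_identical(fl$upstream, substr(g, 3001, 5000))
  expect_identical(fl$downstream, substr(g, 14001, 16000))
  expect_false(fl$clipped_up)

  near <- extract_flanks(g, 500L, 1500L)
  expect_equal(nchar(near$upstream), 500L)
  expect_true(near$clipped_up)
  expect_error(extract_flanks(g, -5L, 100L), "outside contig")
})

test_that("flank mapping recovers planted coordinates and flags ambiguity", {
  sim <- small_sim()
  tr <- sim$truth[sim$truth$insertion_class == "CLASSICAL_FULL", ][1, ]
  fl <- extract_flanks(sim$carrier, tr$carrier_start, tr$carrier_end)
  up <- map_flanks(fl$upstream, sim$outgroup)
  expect_equal(up$state, "RESOLVED")
  # upstream flank ends at the TSD copy: bg site + tsd length
  expect_equal(up$end, tr$bg_site + tr$tsd_len)
  expect_equal(up$identity, 1)

  expect_equal(map_flanks(strrep("N", 2000), sim$outgroup)$state,
               "UNRESOLVED")
  expect_equal(map_flanks(substr(sim$carrier, 1, 100), sim$outgroup)$state,
               "UNRESOLVED")  # below the mappable length floor

  # a flank planted twice in the outgroup is ambiguous
  dup <- paste0(sim$outgroup, substr(sim$outgroup, 10001, 12000))
  res <- map_flanks(substr(sim$outgroup, 10001, 12000), dup)
  expect_equal(res$state, "UNRESOLVED")
  expect_match(res$reason, "ambiguous")
})

test_that("ortholog states follow the gap rules", {
  anchor <- function(gap) list(resolved = TRUE, gap = as.integer(gap))
  expect_equal(call_ortholog_state(anchor(9466), 9466)$state, "PRESENT")
  expect_equal(call_ortholog_state(anchor(-5), 9466)$state, "ABSENT")
  st <- call_ortholog_state(anchor(37), 142, absence_evidence = TRUE)
  expect_equal(st$state, "ABSENT")
  expect_equal(st$gap, 37L)
  # large gap without sequence evidence stays unresolved
  expect_equal(call_ortholog_state(anchor(5000), 2000)$state, "UNRESOLVED")
  expect_equal(call_ortholog_state(list(resolved = FALSE), 100)$state,
               "UNRESOLVED")
})

test_that("TSD detection finds planted duplications and respects the mismatch rule", {
  set.seed(7)
  left <- rand_dna(50)
  right <- rand_dna(50)
  elem <- rand_dna(200)
  mk <- function(tsd_l, tsd_r) paste0(left, tsd_l, elem, tsd_r, right)
  g <- mk("ACGTT", "ACGTT")
  res <- detect_tsd(g, 55L, 255L)
  expect_equal(res$len, 5L)
  expect_equal(res$seq, "ACGTT")
  expect_equal(res$mismatches, 0L)

  # 9-mer duplication with one substitution: tolerated at length >= 8
  t9 <- "ACGTACGTA"
  t9mm <- "ACGTACCTA"
  res9 <- detect_tsd(mk(t9, t9mm), 59L, 259L)
  expect_equal(res9$len, 9L)
  expect_equal(res9$mismatches, 1L)

  edge <- detect_tsd(paste0(elem, right), 0L, 200L)
  expect_equal(edge$len, 0L)
  expect_true(edge$at_edge)
})

test_that("random junctions rarely show a spurious TSD", {
  # brute-force simulation oracle: P(>= 4 bp duplication) is small
  set.seed(11)
  n_trials <- 1000L
  found <- vapply(seq_len(n_trials), function(i) {
    g <- paste0(rand_dna(40), rand_dna(100), rand_dna(40))
    detect_tsd(g, 40L, 140L)$len > 0L
  }, TRUE)
  expect_gte(mean(!found), 0.99)
})

test_that("mechanism classification separates classical from target-deleting", {
  cl <- classify_mechanism(5L, c(-5L))
  expect_equal(cl$mechanism, "CLASSICAL")
  expect_equal(cl$deleted_target_len, 0L)

  nc <- classify_mechanism(0L, c(37L, 37L))
  expect_equal(nc$mechanism, "NON_CLASSICAL")
  expect_equal(nc$deleted_target_len, 37L)

  expect_equal(classify_mechanism(0L, c(0L))$mechanism, "UNDETERMINED")
  # conflicting sizes resolve by median, ties toward the first outgroup
  expect_equal(classify_mechanism(0L, c(30L, 40L))$deleted_target_len, 30L)
  expect_equal(classify_mechanism(0L, c(20L, 30L, 40L))$deleted_target_len,
               30L)
})

test_that("microhomology detection returns planted lengths exactly", {
  set.seed(23)
  ctx <- rand_dna(60)
  core <- rand_dna(150)
  # force mismatches just beyond the planted overlaps on both ends
  if (substr(core, 1, 1) == substr(ctx, 5, 5))
    substr(ctx, 5, 5) <- "N"
  if (substr(core, 150, 150) == substr(ctx, 57, 57))
    substr(ctx, 57, 57) <- "N"
  elem <- paste0(substr(ctx, 1, 4), core, substr(ctx, 58, 60))
  mh <- detect_microhomology(elem, ctx)
  expect_equal(mh$mh5$len, 4L)
  expect_equal(mh$mh5$seq, substr(ctx, 1, 4))
  expect_equal(mh$mh3$len, 3L)

  none <- detect_microhomology(paste0("G", core, "G"),
                               paste0("C", rand_dna(40), "A"))
  expect_equal(none$mh5$len, 0L)
  expect_equal(none$mh3$len, 0L)

  undef <- detect_microhomology(elem, NA_character_)
  expect_false(undef$defined)
})

test_that("a batch with three of four microhomology-bearing junctions reports three", {
  set.seed(29)
  cases <- lapply(1:4, function(i) {
    ctx <- rand_dna(80)
    core <- rand_dna(200)
    if (i < 4) {
      elem <- paste0(substr(ctx, 1, 2 + i), core,
                     substr(ctx, 80 - i, 80))
      list(elem = elem, ctx = ctx)
    } else {
      # blunt case: force terminal mismatches
      elem <- paste0(if (substr(ctx, 1, 1) == "A") "C" else "A", core,
                     if (substr(ctx, 80, 80) == "G") "T" else "G")
      list(elem = elem, ctx = ctx)
    }
  })
  both <- vapply(cases, function(cs) {
    mh <- detect_microhomology(cs$elem, cs$ctx)
    mh$mh5$len >= 1L && mh$mh3$len >= 1L
  }, TRUE)
  expect_equal(sum(both), 3L)
})

test_that("the screen recovers every planted truth field on clean data", {
  sim <- small_sim()
  asm <- small_assembly()
  lin <- lineage_screen(asm$elements, sim$carrier,
                        list(chimp = sim$outgroup))
  m <- truth_match(asm$elements, sim$truth)
  tr <- sim$truth[m, ]
  expect_true(all(lin$human_specific))
  mech_expect <- ifelse(tr$insertion_class == "NON_CLASSICAL",
                        "NON_CLASSICAL", "CLASSICAL")
  expect_equal(lin$mechanism, mech_expect)
  expect_equal(lin$tsd_len, tr$tsd_len)
  expect_equal(lin$tsd_seq, tr$tsd_seq)
  expect_equal(lin$deleted_target_len, tr$deleted_target_len)
  expect_equal(lin$mh5, tr$microhomology_5)
  expect_equal(lin$mh3, tr$microhomology_3)
  # gap/TSD duality: classical overlap magnitude equals the TSD length
  classical <- lin$mechanism == "CLASSICAL"
  expect_equal(-lin$gap_chimp[classical], lin$tsd_len[classical])
})

test_that("calls are stable under 2% flank divergence", {
  for (seed in c(31L, 37L)) {
    cfg <- sim_config(genome_length = 500000L, n_insertions = 8L,
                      flank_divergence = 0.02, seed = seed)
    sim <- plant_insertions(config = cfg)
    hits <- emit_repeat_annotations(sim, 0, seed)
    asm <- assemble_elements(defragment_hits(hits))
    lin <- lineage_screen(asm$elements, sim$carrier,
                          list(chimp = sim$outgroup))
    m <- truth_match(asm$elements, sim$truth)
    tr <- sim$truth[m, ]
    expect_true(all(lin$human_specific))
    expect_equal(lin$mechanism,
                 ifelse(tr$insertion_class == "NON_CLASSICAL",
                        "NON_CLASSICAL", "CLASSICAL"))
    expect_equal(lin$deleted_target_len, tr$deleted_target_len)
  }
})

test_that("the solo-LTR exclusion convention is available", {
  asm <- small_assembly()
  lin <- lineage_screen(asm$elements, small_sim()$carrier,
                        list(chimp = small_sim()$outgroup),
                        include_solo = FALSE)
  expect_false(any(lin$locus_id %in%
                   asm$elements$locus_id[asm$elements$structure_class ==
                                         "SOLO_LTR"]))
})
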