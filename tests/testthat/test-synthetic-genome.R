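# Synthetic genome generator: background composition, planted-allele
# construction, truth/emission consistency, population draws.

test_that("background generation honours length, GC and seed", {
  s <- generate_background(100000, 0.41, 7)
  expect_equal(nchar(s), 100000L)
  ch <- strsplit(s, "")[[1]]
  gc <- mean(ch %in% c("G", "C"))
  expect_lt(abs(gc - 0.41), 0.02)

  at_only <- generate_background(1000, 0.0, 1)
  expect_true(grepl("^[AT]+$", at_only))

  expect_identical(generate_background(5000, 0.5, 7),
                   generate_background(5000, 0.5, 7))
  expect_error(generate_background(0, 0.5, 1), "positive")
})

test_that("classical insertions duplicate the target site on both sides", {
  cfg <- sim_config(genome_length = 200000L, n_insertions = 1L,
                    class_mix = c(CLASSICAL_FULL = 1, CLASSICAL_TRUNCATED = 0,
                                  SOLO_LTR = 0, NON_CLASSICAL = 0,
                                  MULTI_LTR_TANDEM = 0, INVERTED_LTR = 0),
                    seed = 41L)
  sim <- plant_insertions(config = cfg)
  tr <- sim$truth[1, ]
  L <- tr$tsd_len
  left <- substr(sim$carrier, tr$carrier_start - L + 1L, tr$carrier_start)
  right <- substr(sim$carrier, tr$carrier_end + 1L, tr$carrier_end + L)
  expect_identical(left, tr$tsd_seq)
  expect_identical(right, tr$tsd_seq)
  # outgroup holds a single copy: pre-insertion allele is the background
  expect_identical(sim$outgroup, sim$background)
})

test_that("non-classical insertions delete target bases and plant exact microhomology", {
  cfg <- sim_config(genome_length = 200000L, n_insertions = 1L,
                    class_mix = c(CLASSICAL_FULL = 0, CLASSICAL_TRUNCATED = 0,
                                  SOLO_LTR = 0, NON_CLASSICAL = 1,
                                  MULTI_LTR_TANDEM = 0, INVERTED_LTR = 0),
                    target_del_range = c(37L, 37L), seed = 43L)
  sim <- plant_insertions(config = cfg)
  tr <- sim$truth[1, ]
  expect_identical(tr$deleted_target_len, 37L)
  expect_identical(tr$tsd_len, 0L)
  # carrier lost exactly 37 target bases and gained the element
  expect_identical(nchar(sim$carrier),
                   nchar(sim$background) - 37L + tr$element_len)
  # the outgroup inter-flank distance at the locus is the deletion size
  deleted <- substr(sim$outgroup, tr$bg_site + 1L, tr$bg_site + 37L)
  eseq <- sim$element_seqs[[tr$locus_id]]
  if (tr$microhomology_5 > 0)
    expect_identical(substr(eseq, 1, tr$microhomology_5),
                     substr(deleted, 1, tr$microhomology_5))
  if (tr$microhomology_3 > 0)
    expect_identical(substr(eseq, nchar(eseq) - tr$microhomology_3 + 1,
                            nchar(eseq)),
                     substr(deleted, 37L - tr$microhomology_3 + 1L, 37L))
})

test_that("a solo LTR allele adds one LTR plus one TSD copy over the outgroup", {
  cfg <- sim_config(genome_length = 200000L, n_insertions = 1L,
                    class_mix = c(CLASSICAL_FULL = 0, CLASSICAL_TRUNCATED = 0,
                                  SOLO_LTR = 1, NON_CLASSICAL = 0,
                                  MULTI_LTR_TANDEM = 0, INVERTED_LTR = 0),
                    seed = 47L)
  sim <- plant_insertions(config = cfg)
  tr <- sim$truth[1, ]
  expect_identical(nchar(sim$carrier) - nchar(sim$outgroup),
                   tr$element_len + tr$tsd_len)
  expect_identical(tr$element_len, 968L)
})

test_that("planted elements re-extract exactly and pre-insertion alleles reconstruct", {
  sim <- small_sim()
  for (i in seq_len(nrow(sim$truth))) {
    tr <- sim$truth[i, ]
    expect_identical(substr(sim$carrier, tr$carrier_start + 1L,
                            tr$carrier_end),
                     sim$element_seqs[[tr$locus_id]])
    x <- tr$bg_site
    if (tr$insertion_class == "NON_CLASSICAL") {
      # carrier = outgroup with the deleted bases replaced by the element
      reconstructed <- paste0(
        substr(sim$carrier, tr$carrier_start - 99L, tr$carrier_start),
        substr(sim$carrier, tr$carrier_end + 1L, tr$carrier_end + 100L))
      expect_identical(reconstructed,
                       paste0(substr(sim$background, x - 99L, x),
                              substr(sim$background,
                                     x + tr$deleted_target_len + 1L,
                                     x + tr$deleted_target_len + 100L)))
    } else {
      # outgroup = carrier with element plus one TSD copy excised
      L <- tr$tsd_len
      excised <- paste0(
        substr(sim$carrier, tr$carrier_start - L - 99L, tr$carrier_start),
        substr(sim$carrier, tr$carrier_end + L + 1L,
               tr$carrier_end + L + 100L))
      expect_identical(excised,
                       substr(sim$background, x - 99L, x + L + 100L))
    }
  }
})

test_that("the generator is byte-deterministic under a fixed seed", {
  a <- plant_insertions(config = small_cfg())
  b <- plant_insertions(config = small_cfg())
  expect_identical(a$carrier, b$carrier)
  expect_identical(a$truth, b$truth)
  expect_identical(emit_repeat_annotations(a, 0.5, 3L),
                   emit_repeat_annotations(b, 0.5, 3L))
})

test_that("population draws follow the planted allele frequencies", {
  truth <- small_sim()$truth
  truth$freq_absent <- 0.4
  truth$freq_provirus <- 0.4
  truth$freq_solo <- 0.2
  pop <- simulate_population(truth, n_individuals = 80L, seed = 5L)
  haps <- c(pop$hap1[1, ], pop$hap2[1, ])
  expect_length(haps, 160L)
  # exact binomial 99% bounds on each state count (2n = 160 draws)
  for (st in c("ABSENT", "PROVIRUS", "SOLO_LTR")) {
    f <- c(ABSENT = 0.4, PROVIRUS = 0.4, SOLO_LTR = 0.2)[[st]]
    n_obs <- sum(haps == st)
    expect_gte(n_obs, qbinom(0.005, 160, f))
    expect_lte(n_obs, qbinom(0.995, 160, f))
  }
  # all three states observed when every frequency exceeds 0.2
  for (l in seq_len(nrow(truth)))
    expect_length(unique(c(pop$hap1[l, ], pop$hap2[l, ])), 3L)

  truth$freq_solo <- 0.5  # frequencies no longer sum to 1
  expect_error(simulate_population(truth, 10L, 1L), "sum to 1")
})

test_that("a fixed-provirus locus is monomorphic across the panel", {
  truth <- small_sim()$truth  # defaults: provirus frequency 1
  pop <- simulate_population(truth, n_individuals = 20L, seed = 2L)
  expect_true(all(unlist(pop$matrix) == "PROVIRUS/PROVIRUS"))
})
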