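# Repeat-hit parsing, defragmentation and element assembly.

toy_out_file <- function() {
  path <- tempfile(fileext = ".out")
  writeLines(c(
    "score div del ins query q_begin q_end q_left strand repeat_name repeat_class r_begin r_end r_left hit_id",
    "2000 1.0 0.0 0.0 chr1 101 1068 (8932) + ERVK_LTR_sim LTR/ERVK 1 968 (0) 1",
    "1800 2.0 0.0 0.0 chr1 1069 8598 (1402) + ERVK_int_sim LTR/ERVK-int 1 7530 (0) 2",
    "1500 1.5 0.0 0.0 chr2 501 1000 (9000) C ERVK_LTR_sim LTR/ERVK (468) 968 469 3"),
    path)
  path
}

test_that("the .out parser reads strands and normalizes minus-strand consensus coords", {
  hits <- parse_repeat_hits(toy_out_file())
  expect_equal(nrow(hits), 3L)
  expect_equal(hits$strand, c("+", "+", "-"))
  expect_equal(hits$start, c(100L, 1068L, 500L))  # 0-based half-open
  expect_equal(hits$end, c(1068L, 8598L, 1000L))
  # C row: begin/left swapped on disk, normalized in memory
  expect_equal(hits$cons_start[3], 469L)
  expect_equal(hits$cons_end[3], 968L)
})

test_that("an empty hit file parses to an empty table", {
  path <- tempfile()
  writeLines(character(0), path)
  hits <- parse_repeat_hits(path)
  expect_equal(nrow(hits), 0L)
})

test_that("a malformed row errors with its line number", {
  path <- tempfile()
  writeLines(c("2000 1.0 0.0 0.0 chr1 101 1068 (8932) + F C 1 968 (0) 1",
               "garbage row"), path)
  expect_error(parse_repeat_hits(path), "line 2")
})

test_that("writer followed by parser is the identity on a randomized table", {
  set.seed(17)
  n <- 25L
  starts <- sort(sample.int(100000L, n))
  lens <- sample(100:2000, n, replace = TRUE)
  cs <- sample.int(5000L, n)
  hits <- data.frame(
    contig = sample(c("c1", "c2"), n, replace = TRUE),
    start = starts, end = starts + lens,
    strand = sample(c("+", "-"), n, replace = TRUE),
    family = sample(c("ERVK_LTR_sim", "ERVK_int_sim", "AluY_sim"), n,
                    replace = TRUE),
    repeat_class = "LTR/ERVK",
    cons_start = cs, cons_end = cs + sample(50:1000, n, replace = TRUE),
    hit_id = seq_len(n), score = 1000, div = 1.0,
    stringsAsFactors = FALSE)
  path <- tempfile(fileext = ".out")
  write_repeat_hits(hits, path)
  back <- parse_repeat_hits(path)
  expect_equal(back[, names(hits)], hits, ignore_attr = TRUE)
})

test_that("fragments split by a nested repeat merge via the bridge rule", {
  # 6 kb gap (beyond max_genomic_gap) covered by a nested-repeat hit
  hits <- data.frame(
    contig = "c1",
    start = c(0L, 9000L, 3050L),
    end = c(3000L, 12000L, 8950L),
    strand = "+",
    family = c("ERVK_int_sim", "ERVK_int_sim", "L1_sim"),
    repeat_class = c("LTR/ERVK-int", "LTR/ERVK-int", "LINE/L1"),
    cons_start = c(1L, 3001L, 1L),
    cons_end = c(3000L, 6000L, 5900L),
    hit_id = 1:3, score = 1000, div = 1,
    stringsAsFactors = FALSE)
  merged <- defragment_hits(hits)
  erv <- merged[merged$family == "ERVK_int_sim", ]
  expect_equal(nrow(erv), 1L)
  expect_equal(erv$n_hits, 2L)
  # with the bridge off, the 6 kb gap keeps the fragments apart
  apart <- defragment_hits(hits, nested_repeat_bridge = FALSE)
  expect_equal(sum(apart$family == "ERVK_int_sim"), 2L)
})

test_that("same-family hits on opposite strands never merge", {
  hits <- data.frame(
    contig = "c1", start = c(0L, 1100L), end = c(1000L, 2100L),
    strand = c("+", "-"), family = "ERVK_int_sim",
    repeat_class = "LTR/ERVK-int",
    cons_start = c(1L, 1001L), cons_end = c(1000L, 2000L),
    hit_id = 1:2, score = 1000, div = 1, stringsAsFactors = FALSE)
  expect_equal(nrow(defragment_hits(hits)), 2L)
})

test_that("without fragmentation, group count equals planted part count", {
  sim <- small_sim()
  hits <- emit_repeat_annotations(sim, fragmentation_rate = 0, seed = 3L)
  expect_equal(nrow(hits), nrow(sim$parts))
  groups <- defragment_hits(hits)
  expect_equal(nrow(groups), nrow(sim$parts))
})

test_that("forced fragmentation of one full provirus yields four or more hits", {
  cfg <- sim_config(genome_length = 200000L, n_insertions = 1L,
                    class_mix = c(CLASSICAL_FULL = 1, CLASSICAL_TRUNCATED = 0,
                                  SOLO_LTR = 0, NON_CLASSICAL = 0,
                                  MULTI_LTR_TANDEM = 0, INVERTED_LTR = 0),
                    seed = 5L)
  sim <- plant_insertions(config = cfg)
  hits <- emit_repeat_annotations(sim, fragmentation_rate = 1, seed = 5L)
  expect_gte(nrow(hits[hits$family != "AluY_sim", ]), 4L)
  # the raw-vs-reassembled phenomenon in miniature
  asm <- assemble_elements(defragment_hits(hits))
  expect_gt(nrow(hits), nrow(asm$elements))
  expect_equal(nrow(asm$elements), 1L)
})

test_that("assembly recovers every planted locus with its structure class", {
  sim <- small_sim()
  asm <- small_assembly()
  expect_equal(nrow(asm$elements), nrow(sim$truth))
  m <- truth_match(asm$elements, sim$truth)
  expect_false(anyNA(m))
  expected <- c(CLASSICAL_FULL = "FULL_PROVIRUS",
                CLASSICAL_TRUNCATED = "TRUNCATED_PROVIRUS",
                SOLO_LTR = "SOLO_LTR",
                NON_CLASSICAL = "TRUNCATED_PROVIRUS",
                MULTI_LTR_TANDEM = "MULTI_LTR_TANDEM",
                INVERTED_LTR = "MULTI_LTR_TANDEM")
  expect_equal(asm$elements$structure_class,
               unname(expected[sim$truth$insertion_class[m]]))
  # tandem layout: three LTRs around two internals
  tandem <- asm$elements[asm$elements$structure_class == "MULTI_LTR_TANDEM", ]
  expect_true(all(tandem$n_ltr >= 3L & tandem$n_internal >= 2L))
})

test_that("assembly is idempotent and element spans do not overlap", {
  asm <- small_assembly()
  again <- assemble_elements(asm$parts)
  expect_equal(again$elements$start, asm$elements$start)
  expect_equal(again$elements$end, asm$elements$end)
  expect_equal(again$elements$structure_class,
               asm$elements$structure_class)
  els <- asm$elements[order(asm$elements$start), ]
  expect_true(all(els$start[-1] >= els$end[-nrow(els)]))
})

test_that("an isolated LTR far from any internal is a solo LTR", {
  groups <- data.frame(
    contig = "c1", start = c(0L, 60000L), end = c(968L, 67530L),
    strand = "+", family = c("ERVK_LTR_sim", "ERVK_int_sim"),
    repeat_class = "x", cons_start = 1L, cons_end = c(968L, 7530L),
    n_hits = 1L, hit_ids = "1", cons_coverage = c(968L, 7530L),
    stringsAsFactors = FALSE)
  asm <- assemble_elements(groups)
  expect_equal(asm$elements$structure_class[1], "SOLO_LTR")
})
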