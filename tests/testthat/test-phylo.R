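# K2P distances, neighbor joining, bootstrap support, sister-pairing.

test_that("K2P matrix matches brute-force per-pair recomputation and ape", {
  set.seed(71)
  base <- rand_dna(400)
  seqs <- c(t1 = base,
            t2 = ervscribe:::with_seed(1, ervscribe:::mutate_seq(base, 0.05)),
            t3 = ervscribe:::with_seed(2, ervscribe:::mutate_seq(base, 0.10)),
            t4 = ervscribe:::with_seed(3, ervscribe:::mutate_seq(base, 0.15)))
  d <- k2p_distance_matrix(seqs)
  expect_equal(diag(d), rep(0, 4), ignore_attr = TRUE)
  expect_equal(d, t(d), ignore_attr = TRUE)

  # independent per-pair oracle: direct formula over site loops
  oracle <- function(a, b) {
    av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
    pur <- function(x) x %in% c("A", "G")
    n <- length(av); ts <- 0; tv <- 0
    for (i in seq_len(n)) {
      if (av[i] != bv[i]) {
        if (pur(av[i]) == pur(bv[i])) ts <- ts + 1 else tv <- tv + 1
      }
    }
    P <- ts / n; Q <- tv / n
    -0.5 * log(1 - 2 * P - Q) - 0.25 * log(1 - 2 * Q)
  }
  for (i in 1:3) for (j in (i + 1):4)
    expect_equal(d[i, j], oracle(seqs[[i]], seqs[[j]]), tolerance = 1e-12)

  m <- do.call(rbind, strsplit(tolower(seqs), ""))
  rownames(m) <- names(seqs)
  da <- as.matrix(ape::dist.dna(ape::as.DNAbin(m), model = "K80"))
  expect_equal(unname(d[names(seqs), names(seqs)]), unname(da),
               tolerance = 1e-9)
})

test_that("identical rows give zero distance; saturation is flagged", {
  seqs <- c(a = strrep("ACGT", 50), b = strrep("ACGT", 50))
  expect_true(all(k2p_distance_matrix(seqs) == 0))

  sat <- c(a = strrep("A", 100), b = strrep("G", 100),
           c = strrep("A", 100))
  d <- k2p_distance_matrix(sat)
  expect_true(is.na(d["a", "b"]))
  expect_true("a:b" %in% attr(d, "undefined_pairs"))
  expect_error(neighbor_joining(d), "a:b")
})

test_that("NJ recovers an additive four-taxon tree exactly", {
  # tree ((A:1,B:2):1,(C:3,D:1)) -> pairwise path lengths
  d <- matrix(c(0, 3, 5, 3,
                3, 0, 6, 4,
                5, 6, 0, 4,
                3, 4, 4, 0), 4, 4,
              dimnames = list(c("A", "B", "C", "D"),
                              c("A", "B", "C", "D")))
  tr <- neighbor_joining(d)
  co <- ape::cophenetic.phylo(tr)[rownames(d), colnames(d)]
  expect_equal(co, d, tolerance = 1e-12, ignore_attr = TRUE)
  expect_true(is_cherry(tr, "A", "B"))
  expect_true(is_cherry(tr, "C", "D"))
})

test_that("three taxa give the unique unrooted topology", {
  d <- matrix(c(0, 2, 3, 2, 0, 4, 3, 4, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- neighbor_joining(d)
  expect_equal(ape::Ntip(tr), 3L)
  expect_equal(tr$Nnode, 1L)
})

test_that("permuting taxon order gives an isomorphic tree", {
  seqs <- phylo_ltrs()$alignment
  t1 <- neighbor_joining(k2p_distance_matrix(seqs))
  t2 <- neighbor_joining(k2p_distance_matrix(rev(seqs)))
  expect_equal(ape::dist.topo(ape::unroot(t1), ape::unroot(t2))[1], 0,
               ignore_attr = TRUE)
})

test_that("each element's two LTRs pair as a cherry; a swap breaks it", {
  seqs <- phylo_ltrs()$alignment
  tree <- neighbor_joining(k2p_distance_matrix(seqs))
  ids <- unique(sub("_(5p|3p)$", "", names(seqs)))
  for (id in ids)
    expect_true(is_cherry(tree, paste0(id, "_5p"), paste0(id, "_3p")))

  # gene-conversion-like swap: one element's 3' LTR replaced by a copy of
  # another element's LTR breaks exactly that cherry
  swapped <- seqs
  swapped[[paste0(ids[1], "_3p")]] <- seqs[[paste0(ids[2], "_5p")]]
  tr2 <- neighbor_joining(k2p_distance_matrix(swapped))
  expect_false(is_cherry(tr2, paste0(ids[1], "_5p"),
                         paste0(ids[1], "_3p")))
  for (id in ids[-(1:2)])
    expect_true(is_cherry(tr2, paste0(id, "_5p"), paste0(id, "_3p")))
})

test_that("bootstrap gives full support to a clean deep split, deterministically", {
  set.seed(73)
  clade1 <- rand_dna(600)
  clade2 <- ervscribe:::with_seed(4, ervscribe:::mutate_seq(clade1, 0.2))
  seqs <- c(a1 = clade1, a2 = clade1, a3 = clade1, a4 = clade1,
            b1 = clade2, b2 = clade2, b3 = clade2, b4 = clade2)
  bs <- bootstrap_support(seqs, n_reps = 1000L, seed = 7L)
  # locate the internal node whose tip set is exactly one clade
  pp <- ape::prop.part(bs$tree)
  tips <- bs$tree$tip.label
  b_set <- sort(match(c("b1", "b2", "b3", "b4"), tips))
  a_set <- sort(match(c("a1", "a2", "a3", "a4"), tips))
  node_sets <- lapply(pp, sort)
  deep <- which(vapply(node_sets, function(s)
    identical(s, b_set) || identical(s, a_set), TRUE))
  expect_gte(length(deep), 1L)
  expect_true(all(bs$support[deep] == 100))

  bs2 <- bootstrap_support(seqs, n_reps = 1000L, seed = 7L)
  expect_identical(bs$support, bs2$support)

  one <- bootstrap_support(seqs, n_reps = 1L, seed = 7L)
  expect_true(all(one$support %in% c(0, 100)))
})

test_that("short LTRs are excluded from alignment with a reason", {
  seqs <- c(long1 = rand_dna(500, seed = 79), long2 = rand_dna(500),
            short = rand_dna(120))
  al <- align_ltrs(seqs)
  expect_equal(al$excluded$taxon, "short")
  expect_match(al$excluded$reason, "minimum LTR length")
  expect_equal(sort(names(al$alignment)), c("long1", "long2"))
})
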