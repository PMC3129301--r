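aln_of <- function(...) {
  seqs <- c(...)
  retroclock:::new_alignment(tibble::tibble(id = names(seqs), seq = unname(seqs)))
}

test_that("k2p_matrix computes hand-checked entries and respects deletion mode", {
  aln <- aln_of(a = "AAAA", b = "GAAA", c = "AAAA")
  m <- k2p_matrix(aln)
  expect_equal(m["a", "b"], 0.346574, tolerance = 1e-5)
  expect_equal(m["b", "c"], 0.346574, tolerance = 1e-5)
  expect_equal(m["a", "c"], 0)
  expect_true(isSymmetric(m))
  expect_equal(diag(m), c(a = 0, b = 0, c = 0))

  # identical rows -> all-zero matrix
  m0 <- k2p_matrix(aln_of(a = "ACGT", b = "ACGT", c = "ACGT"))
  expect_true(all(m0 == 0))

  # pairwise vs complete deletion agree exactly on gap-free alignments
  set.seed(417)
  anc <- rand_seq(60)
  rows <- vapply(1:4, function(i) evolve_copy(anc, 3e6), character(1))
  aln2 <- aln_of(a = rows[1], b = rows[2], c = rows[3], d = rows[4])
  expect_equal(k2p_matrix(aln2, "pairwise"), k2p_matrix(aln2, "complete"))

  # a pairwise-deleted gap column changes only the pairs it touches
  aln3 <- aln_of(a = "A-GT", b = "ACGT", c = "ACGT")
  m3 <- k2p_matrix(aln3, "pairwise")
  expect_equal(m3["a", "b"], 0)
  m3c <- k2p_matrix(aln3, "complete")
  expect_equal(m3c["b", "c"], 0)
})

test_that("k2p_matrix reports the offending saturated pair", {
  aln <- aln_of(a = "ACGTACGT", b = "ACGTACGT", c = "CAGTCAGT")
  # a vs c has Q = 0.5: saturated
  expect_error(k2p_matrix(aln), "a/c")
})

test_that("NJ reconstructs a four-taxon additive matrix exactly", {
  d <- matrix(c(0, 2, 3, 3,
                2, 0, 3, 3,
                3, 3, 0, 2,
                3, 3, 2, 0), 4, 4,
              dimnames = list(c("A", "B", "C", "D"), c("A", "B", "C", "D")))
  tr <- neighbor_joining(d)
  expect_equal(phangorn::RF.dist(ape::unroot(tr),
                                 ape::read.tree(text = "((A:1,B:1):1,C:1,D:1);")), 0)
  pl <- ape::cophenetic.phylo(tr)[rownames(d), colnames(d)]
  expect_equal(pl, d, tolerance = 1e-12)
  # internal branch of the AB|CD split has length 1
  el <- tr$edge.length
  expect_true(any(abs(el - 1) < 1e-12))
})

test_that("NJ resolves an all-zero matrix as a zero-length star", {
  d <- matrix(0, 3, 3, dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  tr <- neighbor_joining(d)
  expect_equal(sort(tr$tip.label), c("x", "y", "z"))
  expect_true(all(tr$edge.length == 0))
  expect_error(neighbor_joining(d[1:2, 1:2]), ">= 3")
})

test_that("NJ recovers the generating topology from random additive matrices", {
  set.seed(418)
  for (trial in 1:20) {
    k <- sample(4:8, 1)
    gen <- ape::rtree(k, tip.label = paste0("t", 1:k))
    gen$edge.length <- stats::runif(nrow(gen$edge), 0.1, 2)
    d <- ape::cophenetic.phylo(gen)
    tr <- neighbor_joining(d)
    expect_equal(phangorn::RF.dist(ape::unroot(gen), ape::unroot(tr)), 0)
    pl <- ape::cophenetic.phylo(tr)[rownames(d), colnames(d)]
    expect_equal(pl, d, tolerance = 1e-8)
    # independent implementation agrees on the topology
    expect_equal(phangorn::RF.dist(ape::unroot(ape::nj(d)), ape::unroot(tr)), 0)
  }
})

test_that("NJ is invariant to label permutations of the input matrix", {
  set.seed(419)
  gen <- ape::rtree(6, tip.label = paste0("s", 1:6))
  d <- ape::cophenetic.phylo(gen)
  t1 <- neighbor_joining(d)
  perm <- sample(6)
  t2 <- neighbor_joining(d[perm, perm])
  expect_identical(write_newick(t1), write_newick(t2))
})

test_that("bootstrap supports are reproducible, bounded, and sharp with one replicate", {
  groups <- tibble::tibble(group_id = c("g1", "g2"), genome = c("B", "D"),
                           n_members = c(2, 2), stem_time = 3e6, crown_time = 4e5)
  fam <- simulate_family(groups, domain_len = 200, seed = 420)
  t1 <- bootstrap_support(fam$aln, n_reps = 30, seed = 7)
  t2 <- bootstrap_support(fam$aln, n_reps = 30, seed = 7)
  expect_identical(write_newick(t1), write_newick(t2))
  sup <- suppressWarnings(as.numeric(t1$node.label))
  sup <- sup[!is.na(sup)]
  expect_true(all(sup >= 0 & sup <= 100))

  tr1 <- bootstrap_support(fam$aln, n_reps = 1, seed = 8)
  s1 <- suppressWarnings(as.numeric(tr1$node.label))
  expect_true(all(s1[!is.na(s1)] %in% c(0, 100)))

  # strong signal: the true split between the two groups is near-certain
  s <- suppressWarnings(as.numeric(t1$node.label))
  expect_gte(max(s, na.rm = TRUE), 95)
})

test_that("pure clades are classified genome-specific; impure ones are not", {
  tips_b <- paste0("B", 1:6); tips_d <- paste0("D", 1:6)
  nwk <- sprintf("((%s),(%s));",
                 paste(tips_b, collapse = ","), paste(tips_d, collapse = ","))
  tr <- ape::read.tree(text = nwk)
  lab <- tibble::tibble(id = c(tips_b, tips_d),
                        genome = rep(c("B", "D"), each = 6))
  g <- classify_genome_groups(tr, lab, purity_threshold = 0.9, min_size = 5)
  expect_setequal(g$group_label, c("B-specific", "D-specific"))
  expect_equal(sort(g$size), c(6L, 6L))

  # one D tip inside the B clade: purity 6/7 < 0.9, so no B-specific group of 7
  lab2 <- lab
  lab2$genome[lab2$id == "B6"] <- "D"
  g2 <- classify_genome_groups(tr, lab2, purity_threshold = 0.9, min_size = 5)
  expect_false(any(g2$group_label == "B-specific" & g2$size == 7))

  # no clade reaches min_size: everything lands in one mixed group
  g3 <- classify_genome_groups(tr, lab, purity_threshold = 0.9, min_size = 10)
  expect_equal(g3$group_label, "mixed")
  expect_equal(g3$size, 12L)
})

test_that("planted genome groups are recovered from simulated families", {
  groups <- tibble::tibble(
    group_id = c("B", "D", "mix"),
    genome = list("B", "D", c("A", "B", "D")),
    n_members = c(8, 7, 6),
    stem_time = c(3e6, 3e6, 3e6),
    crown_time = c(5e5, 5e5, 5e5)
  )
  fam <- simulate_family(groups, domain_len = 500, seed = 421)
  tr <- neighbor_joining(k2p_matrix(fam$aln))
  g <- classify_genome_groups(tr, fam$labels, purity_threshold = 0.9, min_size = 5)
  memb <- tidy(g)
  expect_equal(sort(memb$id[memb$group_label == "B-specific"]),
               sort(fam$truth$id[fam$truth$group_id == "B"]))
  expect_equal(sort(memb$id[memb$group_label == "D-specific"]),
               sort(fam$truth$id[fam$truth$group_id == "D"]))
  expect_equal(sort(memb$id[memb$group_label == "mixed"]),
               sort(fam$truth$id[fam$truth$group_id == "mix"]))
})
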