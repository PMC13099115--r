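test_that("projection reproduces rows, deletions and usable distances", {
  ref <- synthetic_provirus(2)
  cfg <- single_tip_config(2)
  a <- evolve_copy(ref, make_truth(age = 5e5), cfg)$element
  msa <- reference_projected_msa(c(x = a, y = a), ref)
  expect_identical(msa$matrix["x", ], msa$matrix["y", ])
  expect_equal(ncol(msa$matrix), ref$length)
  # 1 kb deletion appears as a gap block at the deleted interval
  del <- evolve_copy(ref, make_truth(
    age = 5e5, events = list(list(type = "deletion", start = 2001,
                                  size = 1000))), cfg)$element
  msa2 <- reference_projected_msa(c(d = del), ref)
  gaps <- which(msa2$matrix["d", ] == "-")
  expect_equal(length(gaps), 1000)
  expect_lt(abs(min(gaps) - 2001), 30)
  # projection distances close to direct pairwise distances
  set.seed(23)
  b <- ervmine:::diverge_seq(ref$seq, 0.08)
  c_ <- ervmine:::diverge_seq(ref$seq, 0.08)
  m3 <- reference_projected_msa(c(b = b, c = c_), ref)
  d_proj <- k2p_distance(list(a = m3$matrix["b", ], b = m3$matrix["c", ]))$K
  d_direct <- k2p_distance(b, c_)$K  # equal length, already aligned
  expect_lt(abs(d_proj - d_direct) / d_direct, 0.05)
})

test_that("k2p_matrix is symmetric, zero-diagonal, and consistent", {
  set.seed(24)
  anc <- random_seq(1000)
  seqs <- vapply(1:4, function(i) ervmine:::diverge_seq(anc, 0.04), "")
  names(seqs) <- paste0("s", 1:4)
  D <- k2p_matrix(seqs)
  expect_true(isSymmetric(D))
  expect_equal(diag(D), setNames(rep(0, 4), names(seqs)))
  expect_equal(D["s1", "s2"], k2p_distance(seqs[1], seqs[2])$K)
  expect_identical(k2p_matrix(rbind(s1 = strsplit(seqs[[1]], "")[[1]],
                                    s2 = strsplit(seqs[[1]], "")[[1]]))[1, 2],
                   0)
})

test_that("NJ recovers additive four-taxon trees exactly", {
  tr <- ape::read.tree(text = "((A:1,B:2):1,(C:3,D:4):0);")
  D <- cophenetic(tr)[LETTERS[1:4], LETTERS[1:4]]
  nj <- neighbor_joining(D)
  expect_equal(cophenetic(nj)[LETTERS[1:4], LETTERS[1:4]], D,
               tolerance = 1e-9)
  split_ab <- ape::is.monophyletic(ape::root(nj, "D"), c("A", "B"))
  expect_true(split_ab)
  # three taxa resolve as the unique star
  D3 <- D[1:3, 1:3]
  nj3 <- neighbor_joining(D3)
  expect_equal(ape::Ntip(nj3), 3)
  expect_error(neighbor_joining(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
})

test_that("midpoint rooting preserves path lengths and centers the root", {
  # chain A-B-C with lengths 1 and 3: root on the B-C branch
  tr <- ape::read.tree(text = "(A:1,B:0,C:3);")
  rooted <- midpoint_root(tr)
  d <- cophenetic(rooted)
  expect_equal(d["A", "C"], 4)
  root_node <- ape::Ntip(rooted) + 1
  depths <- ape::dist.nodes(rooted)[root_node,
                                    match(c("A", "C"), rooted$tip.label)]
  expect_equal(max(abs(depths - 2)), 0, tolerance = 1e-9)
  expect_equal(unname(cophenetic(tr)["A", "C"]),
               unname(cophenetic(rooted)["A", "C"]))
})

test_that("bootstrap supports are percentages, deterministic by seed", {
  set.seed(25)
  anc <- random_seq(800)
  anc1 <- ervmine:::diverge_seq(anc, 0.1)
  anc2 <- ervmine:::diverge_seq(anc, 0.1)
  seqs <- c(a1 = ervmine:::diverge_seq(anc1, 0.02),
            a2 = ervmine:::diverge_seq(anc1, 0.02),
            b1 = ervmine:::diverge_seq(anc2, 0.02),
            b2 = ervmine:::diverge_seq(anc2, 0.02))
  bs1 <- bootstrap_support(seqs, B = 30, seed = 5)
  bs2 <- bootstrap_support(seqs, B = 30, seed = 5)
  expect_identical(bs1$support, bs2$support)
  expect_true(all(bs1$support >= 0 & bs1$support <= 100))
  # a deep clean split gets full support
  expect_true(100 %in% bs1$support)
  # B = 1 gives supports in {0, 100}
  bs3 <- bootstrap_support(seqs, B = 1, seed = 6)
  expect_true(all(bs3$support %in% c(0, 100)))
})

test_that("monophyly testing covers trivial and structured cases", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  expect_true(is_monophyletic(tr, c("A", "B", "C", "D")))
  expect_true(is_monophyletic(tr, "A"))
  expect_true(is_monophyletic(tr, c("A", "B"), outgroup = "D"))
  expect_false(is_monophyletic(tr, c("A", "C"), outgroup = "D"))
})

test_that("introgressed copies nest inside the donor lineage clade", {
  seqs <- simulate_introgression_copies(seed = 31)
  tree <- neighbor_joining(k2p_matrix(seqs))
  recip <- grep("recipient", names(seqs), value = TRUE)
  donor <- grep("donor", names(seqs), value = TRUE)
  expect_true(is_monophyletic(tree, recip, outgroup = "exogenous_ref"))
  expect_true(is_monophyletic(tree, c(recip, donor),
                              outgroup = "exogenous_ref"))
  expect_false(is_monophyletic(tree, donor, outgroup = "exogenous_ref"))
})

test_that("gene trees slice at reference intervals and compare bipartitions", {
  ref <- synthetic_provirus(7)
  set.seed(26)
  anc1 <- ervmine:::diverge_seq(ref$seq, 0.02)
  anc2 <- ervmine:::diverge_seq(ref$seq, 0.02)
  seqs <- c(a1 = ervmine:::diverge_seq(anc1, 0.01),
            a2 = ervmine:::diverge_seq(anc1, 0.01),
            b1 = ervmine:::diverge_seq(anc2, 0.01),
            b2 = ervmine:::diverge_seq(anc2, 0.01))
  msa <- reference_projected_msa(seqs, ref)
  gt <- gene_trees(msa, ref)
  expect_setequal(names(gt), c("gag", "pol", "env"))
  full <- neighbor_joining(k2p_matrix(msa))
  cmp <- compare_bipartitions(full, gt$gag)
  expect_gte(cmp$shared, 1)
})
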