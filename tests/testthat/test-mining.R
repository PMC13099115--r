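test_that("k-mer index counts match a direct window-count oracle", {
  set.seed(1)
  g <- c(s1 = random_seq(5000), s2 = random_seq(3000))
  # plant some Ns
  substr(g[["s1"]], 100, 130) <- paste(rep("N", 31), collapse = "")
  k <- 11
  idx <- index_genome(g, k)
  oracle <- sum(vapply(g, function(s) {
    ch <- strsplit(s, "")[[1]]
    wins <- vapply(seq_len(nchar(s) - k + 1), function(i) {
      all(ch[i:(i + k - 1)] %in% c("A", "C", "G", "T"))
    }, TRUE)
    sum(wins)
  }, 1))
  expect_equal(n_indexed_positions(idx), oracle)
  expect_error(index_genome(character(0)), "empty")
})

test_that("verbatim implants are found with full identity and coverage", {
  set.seed(2)
  q <- random_seq(600)
  bg <- random_seq(50000)
  g <- c(s1 = paste0(substr(bg, 1, 20000), q, substr(bg, 20001, 50000)))
  idx <- index_genome(g)
  h <- search_genome(q, idx, query_id = "q")
  h <- filter_hits(h, "locus_mining")
  expect_equal(nrow(h), 1)
  expect_equal(h$identity, 100)
  expect_equal(h$query_coverage, 100)
  expect_equal(h$s_start, 20000)
  expect_equal(h$s_end, 20600)
  expect_equal(h$strand, "+")
})

test_that("absent queries yield no filtered hits on random background", {
  set.seed(3)
  q <- random_seq(600)
  g <- c(s1 = random_seq(1000000))
  idx <- index_genome(g)
  h <- filter_hits(search_genome(q, idx, query_id = "q"), "locus_mining")
  expect_equal(nrow(h), 0)
  loci <- merge_to_loci(h)
  expect_equal(nrow(loci), 0)
})

test_that("diverged implants are recovered with commensurate identity", {
  set.seed(4)
  ids <- replicate(30, {
    q <- random_seq(2000)
    qd <- ervmine:::diverge_seq(q, 0.10)
    g <- c(s1 = paste0(random_seq(20000), qd, random_seq(20000)))
    h <- filter_hits(search_genome(q, index_genome(g), query_id = "q"),
                     "locus_mining")
    expect_gte(nrow(h), 1)
    h$identity[which.max(h$score)]
  })
  expect_true(all(ids >= 85 & ids <= 95))
})

test_that("filter thresholds act exactly at the printed 50 percent cutoffs", {
  h <- data.frame(subject_scaffold = "s", strand = "+", q_start = 0,
                  q_end = 50, s_start = 0, s_end = 50, score = 10,
                  matches = 25, identity = c(49.9, 50.0),
                  query_coverage = c(40, 60), query_id = "q")
  expect_equal(nrow(filter_hits(h, "host_range")), 1)
  expect_equal(filter_hits(h, "host_range")$identity, 50.0)
  expect_equal(nrow(filter_hits(h[1, ], "locus_mining")), 0)
  expect_equal(nrow(filter_hits(h[2, ], "locus_mining")), 1)
  expect_error(filter_hits(h, "nonsense"))
})

test_that("hits merge into loci across queries but not across copies", {
  # LTR-query hit nested in a full-genome hit -> one locus
  h <- data.frame(
    subject_scaffold = "s", strand = "+",
    q_start = c(0, 0), q_end = c(600, 7000),
    s_start = c(10000, 9400), s_end = c(10600, 16400),
    score = c(600, 7000), matches = c(600, 7000),
    identity = 100, query_coverage = 100, query_id = c("LTR", "full"))
  loci <- merge_to_loci(h)
  expect_equal(nrow(loci), 1)
  expect_equal(loci$start, 9400)
  expect_equal(loci$end, 16400)
  expect_setequal(strsplit(loci$queries, ",")[[1]], c("full", "LTR"))
  # two copies 50 kb apart at max_gap 2000 -> two loci
  h2 <- h
  h2$s_start <- c(10000, 60000); h2$s_end <- c(16000, 66000)
  h2$query_id <- "full"
  expect_equal(nrow(merge_to_loci(h2, max_gap = 2000)), 2)
})

test_that("a solo LTR is mined through the LTR query alone", {
  set.seed(6)
  ref <- synthetic_provirus(6)
  ltr <- reference_feature_seq(ref, "LTR")
  g <- c(s1 = paste0(random_seq(30000), ltr, random_seq(30000)))
  mined <- mine_genome(g, ref, genome_id = "g")
  expect_equal(nrow(mined$loci), 1)
  expect_identical(mined$loci$queries, "LTR")
  expect_lt(abs(mined$loci$start - 30000), 5)
  expect_lt(abs(mined$loci$end - 30600), 5)
})

test_that("flank extraction clips at scaffold ends and flags truncation", {
  g <- c(s1 = strrep("A", 100000))
  locus <- data.frame(locus_id = "l1", genome_id = "g", scaffold = "s1",
                      start = 50000, end = 58000, strand = "+")
  fl <- extract_with_flanks(locus, g, 16000)
  expect_equal(fl$ext_start, 34000)
  expect_equal(fl$ext_end, 74000)
  expect_false(fl$truncated_up || fl$truncated_down)
  locus$start <- 5000; locus$end <- 13000
  fl <- extract_with_flanks(locus, g, 16000)
  expect_equal(fl$flank_up_len, 5000)
  expect_true(fl$truncated_up)
  expect_false(fl$truncated_down)
  locus$start <- -5
  expect_error(extract_with_flanks(locus, g), "outside")
})

test_that("search is strand-symmetric under genome reverse complement", {
  set.seed(7)
  q <- random_seq(1500)
  qd <- ervmine:::diverge_seq(q, 0.05)
  bg_l <- random_seq(10000); bg_r <- random_seq(12000)
  g_fwd <- c(s1 = paste0(bg_l, qd, bg_r))
  g_rev <- c(s1 = ervmine:::revcomp(g_fwd[["s1"]]))
  len <- nchar(g_fwd[["s1"]])
  hf <- filter_hits(search_genome(q, index_genome(g_fwd), query_id = "q"),
                    "locus_mining")
  hr <- filter_hits(search_genome(q, index_genome(g_rev), query_id = "q"),
                    "locus_mining")
  expect_equal(nrow(hf), 1)
  expect_equal(nrow(hr), 1)
  expect_equal(hr$s_start, len - hf$s_end)
  expect_equal(hr$s_end, len - hf$s_start)
  expect_equal(hr$score, hf$score)
  expect_true(hf$strand != hr$strand)
})

test_that("mined loci never extend beyond their scaffold", {
  sim <- simulate_mining_benchmark(seed = 13, background_length = 150000,
                                   endogenization_rate = 3)
  for (ind in names(sim$genomes)) {
    mined <- mine_genome(sim$genomes[[ind]], sim$provirus_ref,
                         genome_id = ind)
    if (!nrow(mined$loci)) next
    lens <- nchar(sim$genomes[[ind]])[mined$loci$scaffold]
    expect_true(all(mined$loci$start >= 0))
    expect_true(all(mined$loci$end <= lens))
    expect_true(all(mined$loci$start < mined$loci$end))
    # non-overlapping after merging
    ord <- order(mined$loci$scaffold, mined$loci$start)
    l <- mined$loci[ord, ]
    same <- duplicated(l$scaffold)
    expect_true(all(l$start[-1][same[-1]] >= l$end[-nrow(l)][same[-1]]))
  }
})
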