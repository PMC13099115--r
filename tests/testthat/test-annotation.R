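ref <- synthetic_provirus(1)
ref_ltr <- reference_feature_seq(ref, "LTR")
cfg <- single_tip_config(1)

test_that("find_ltrs locates terminal, solo and internal LTR copies", {
  # undiverged provirus: exactly the two terminal LTRs
  iv <- find_ltrs(ref$seq, ref_ltr)
  expect_equal(nrow(iv), 2)
  expect_equal(iv$start, c(1, ref$length - 599))
  expect_equal(iv$end, c(600, ref$length))
  expect_true(all(iv$identity > 99))
  # solo LTR element
  solo <- evolve_copy(ref, make_truth(
    age = 2e5, events = list(list(type = "solo_collapse", kept = "3p"))),
    cfg)
  expect_equal(nrow(find_ltrs(solo$element, ref_ltr)), 1)
  # atypical element with an internal LTR-like spacer
  atyp <- evolve_copy(ref, make_truth(
    age = 2e5, events = list(list(type = "duplication"))), cfg)
  expect_equal(nrow(find_ltrs(atyp$element, ref_ltr)), 3)
})

test_that("pair_ltrs picks the outermost compatible pair", {
  iv <- data.frame(start = c(1, 7000), end = c(600, 7600), identity = 99)
  p <- pair_ltrs(iv, 7600)
  expect_equal(p$internal_length, 6399)
  expect_equal(nrow(p$internal_intervals), 0)
  expect_null(pair_ltrs(iv[1, , drop = FALSE], 600))
  # three intervals: outermost pair, middle flagged internal
  iv3 <- rbind(iv, data.frame(start = 3500, end = 4100, identity = 99))
  p3 <- pair_ltrs(iv3[order(iv3$start), ], 7600)
  expect_equal(p3$ltr5$start, 1)
  expect_equal(p3$ltr3$end, 7600)
  expect_equal(p3$internal_intervals$start, 3500)
  # contiguous LTRs (paired solo) have no compatible pair
  iv_ps <- data.frame(start = c(1, 651), end = c(600, 1250), identity = 99)
  expect_null(pair_ltrs(iv_ps, 1250))
})

test_that("signatures are read from the innermost 4 nt of each flank", {
  s <- extract_signature("TTTTGGAG", "GGAGTTTT")
  expect_identical(s$upstream_4mer, "GGAG")
  expect_identical(s$downstream_4mer, "GGAG")
  expect_true(s$is_matching)
  s2 <- extract_signature("TTTTGGAG", "GGAATTTT")
  expect_false(s2$is_matching)
  # truncated flank: N-padded, never matching
  s3 <- extract_signature("AG", "AGNNTTTT")
  expect_identical(s3$upstream_4mer, "NNAG")
  expect_false(s3$is_matching)
})

test_that("genes and peptides annotate at high identity on a clean copy", {
  ann <- annotate_genes(ref$seq, ref)
  genes <- ann[ann$type == "gene", ]
  expect_setequal(genes$name, c("gag", "pol", "env"))
  expect_true(all(genes$identity > 99))
  expect_true(all(!genes$rescued))
  expect_equal(sum(ann$type == "peptide"), 9)
})

test_that("a fully deleted gene is not annotated; neighbours survive", {
  pol <- ref$features[ref$features$name == "pol", ]
  elem <- paste0(substr(ref$seq, 1, pol$start - 1),
                 substr(ref$seq, pol$end + 1, ref$length))
  ann <- annotate_genes(elem, ref)
  genes <- ann[ann$type == "gene", ]
  expect_setequal(genes$name, c("gag", "env"))
})

test_that("peptide rescue re-admits a gene that fails the overall cutoff", {
  # destroy pol except the reverse transcriptase segment
  pol <- ref$features[ref$features$name == "pol", ]
  rt <- ref$features[ref$features$name == "reverse transcriptase", ]
  set.seed(8)
  scrambled <- ref$seq
  left <- pol$start:(rt$start - 1)
  right <- (rt$end + 1):pol$end
  for (block in list(left, right)) {
    substr(scrambled, min(block), max(block)) <-
      random_seq(length(block))
  }
  ann <- annotate_genes(scrambled, ref, gene_cutoff = 80)
  genes <- ann[ann$type == "gene", ]
  expect_true("pol" %in% genes$name)
  expect_true(genes$rescued[genes$name == "pol"])
  expect_true("reverse transcriptase" %in% ann$name)
})

test_that("ORF scanning flags nonsense substitutions and large deletions", {
  ann <- annotate_genes(ref$seq, ref)
  orf <- scan_orfs(ref$seq, ann, ref)
  expect_true(orf$fully_open_orf)
  # single nonsense substitution in env
  env <- ref$features[ref$features$name == "env", ]
  mut <- ref$seq
  substr(mut, env$start + 30, env$start + 32) <- "TAA"
  orf2 <- scan_orfs(mut, annotate_genes(mut, ref), ref)
  genes2 <- orf2$annotations[orf2$annotations$type == "gene", ]
  expect_false(genes2$intact_orf[genes2$name == "env"])
  expect_true(genes2$intact_orf[genes2$name == "gag"])
  expect_false(orf2$fully_open_orf)
  # in-frame 1200 nt deletion in gag: frame open, deletion flagged
  gag <- ref$features[ref$features$name == "gag", ]
  del <- paste0(substr(ref$seq, 1, gag$start + 89),
                substr(ref$seq, gag$start + 90 + 1200, ref$length))
  orf3 <- scan_orfs(del, annotate_genes(del, ref), ref)
  genes3 <- orf3$annotations[orf3$annotations$type == "gene", ]
  g <- genes3[genes3$name == "gag", ]
  expect_true(g$intact_orf)
  expect_equal(g$largest_deletion, 1200)
  expect_true(g$truncation_flag)
})

test_that("open-ORF status is monotone under added stop codons", {
  ann <- annotate_genes(ref$seq, ref)
  base_open <- scan_orfs(ref$seq, ann, ref)$fully_open_orf
  expect_true(base_open)
  set.seed(9)
  for (i in 1:5) {
    gene <- ref$features[ref$features$type == "gene", ][sample(3, 1), ]
    pos <- gene$start + 3 * sample.int((gene$end - gene$start) %/% 3 - 2, 1)
    mut <- ref$seq
    substr(mut, pos, pos + 2) <- "TGA"
    expect_false(scan_orfs(mut, annotate_genes(mut, ref),
                           ref)$fully_open_orf)
  }
})

test_that("classification follows the five-class decision order", {
  mk <- function(events, age = 2e5) {
    evolve_copy(ref, make_truth(age = age, events = events), cfg)
  }
  classify_elem <- function(elem, clipped = FALSE) {
    locus <- list(element_seq = elem, flank_up = strrep("A", 100),
                  flank_down = strrep("A", 100), start = 1000, end = 2000,
                  strand = "+", locus_id = "x", genome_id = "g")
    annotate_copy(locus, ref, scaffold_len = if (clipped) 2000 else NA)$class
  }
  expect_identical(classify_elem(mk(list())$element), "typical")
  expect_identical(
    classify_elem(mk(list(list(type = "solo_collapse", kept = "5p")))$element),
    "solo_ltr")
  expect_identical(
    classify_elem(mk(list(list(type = "paired_solo", remnant = 40)))$element),
    "paired_solo_ltr")
  expect_identical(
    classify_elem(mk(list(list(type = "duplication")))$element), "atypical")
  expect_identical(classify_elem(mk(list())$element, clipped = TRUE),
                   "incomplete_segment")
  # a clean provirus with a 1.5 kb internal deletion stays typical
  del <- mk(list(list(type = "deletion", start = 3000, size = 1500)))
  expect_identical(classify_elem(del$element), "typical")
})
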