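test_that("fisher_exact handles canonical tables", {
  expect_equal(fisher_exact(matrix(1, 2, 2)), 1.0)
  expect_equal(fisher_exact(matrix(c(5, 0, 0, 5), 2, 2)), 2 / 252,
               tolerance = 1e-12)
  expect_lt(fisher_exact(matrix(c(65, 50, 0, 15), 2, 2)), 0.001)
  expect_error(fisher_exact(matrix(c(-1, 1, 1, 1), 2, 2)))
  expect_error(fisher_exact(matrix(c(0.5, 1, 1, 1), 2, 2)))
})

test_that("fisher_exact equals brute-force enumeration and fisher.test", {
  set.seed(20)
  for (i in 1:200) {
    t22 <- matrix(sample(0:12, 4, replace = TRUE), 2, 2)
    expect_equal(fisher_exact(t22), fisher_bruteforce(t22),
                 tolerance = 1e-12)
    if (sum(t22) > 0) {
      expect_equal(fisher_exact(t22), fisher.test(t22)$p.value,
                   tolerance = 1e-6)
    }
  }
})

test_that("bonferroni multiplies and caps", {
  expect_equal(bonferroni(c(0.01, 0.2, 0.03), 3), c(0.03, 0.6, 0.09))
  expect_equal(bonferroni(0.5, 3), 1.0)
  expect_equal(bonferroni(c(0.2, 0.4)), c(0.4, 0.8))
  expect_equal(bonferroni(0.07, 1), 0.07)
  expect_error(bonferroni(c(0.1, 0.2), 1), "family_size")
})

test_that("shared loci group by flank identity; signatures never merge", {
  set.seed(21)
  anc_up <- random_seq(800); anc_down <- random_seq(800)
  div <- function(s) ervmine:::diverge_seq(s, 0.0025)
  copies <- data.frame(
    copy_uid = c("g1_c1", "g2_c1", "g1_c2", "g2_c2"),
    genome_id = c("g1", "g2", "g1", "g2"),
    flank_up = c(div(anc_up), div(anc_up), random_seq(800), random_seq(800)),
    flank_down = c(div(anc_down), div(anc_down), random_seq(800),
                   random_seq(800)),
    signature = c("GGAG", "GGAG", "CTGT", "CTGT"))
  og <- match_orthologous_loci(copies)
  g <- og$groups
  # the shared locus forms one flank_match group of two
  expect_equal(g$group_id[g$copy_uid == "g1_c1"],
               g$group_id[g$copy_uid == "g2_c1"])
  expect_identical(unique(g$evidence[g$copy_uid %in% c("g1_c1", "g2_c1")]),
                   "flank_match")
  # same signature at different loci: separate groups, reported coincidence
  expect_false(g$group_id[g$copy_uid == "g1_c2"] ==
                 g$group_id[g$copy_uid == "g2_c2"])
  expect_true("CTGT" %in% og$signature_coincidences$signature)
  # single genome: every copy its own group
  og1 <- match_orthologous_loci(copies[copies$genome_id == "g1", ])
  expect_equal(length(unique(og1$groups$group_id)), 2)
})

test_that("grouping is order-independent (single linkage)", {
  set.seed(22)
  up <- random_seq(700); down <- random_seq(700)
  d <- function(s) ervmine:::diverge_seq(s, 0.003)
  copies <- data.frame(
    copy_uid = paste0("c", 1:3), genome_id = paste0("g", 1:3),
    flank_up = c(d(up), d(up), d(up)),
    flank_down = c(d(down), d(down), d(down)),
    signature = "AAAA")
  g1 <- match_orthologous_loci(copies)$groups
  g2 <- match_orthologous_loci(copies[3:1, ])$groups
  expect_equal(length(unique(g1$group_id)), 1)
  expect_equal(length(unique(g2$group_id)), 1)
})

test_that("count tables sum to copy totals and honor removals", {
  ct <- data.frame(
    locus_id = paste0("l", 1:5), genome_id = c("g1", "g1", "g1", "g2", "g2"),
    class = c("typical", "solo_ltr", "typical", "typical", "atypical"),
    gag = c(TRUE, FALSE, TRUE, TRUE, TRUE),
    pol = c(TRUE, FALSE, FALSE, TRUE, TRUE),
    env = c(TRUE, FALSE, TRUE, TRUE, TRUE),
    scaffold = "s1")
  tabs <- build_count_tables(ct)
  expect_equal(sum(tabs$classes), 5)
  expect_equal(unname(colSums(tabs$classes)), c(3, 2))
  expect_equal(unname(tabs$genes["pol", ]), c(1, 1))
  # recombinant-removed copies leave the gene counts
  tabs2 <- build_count_tables(ct, nonrecombinant_ids = c("l1", "l4"))
  expect_equal(unname(rowSums(tabs2$genes)), c(2, 2, 2))
})

test_that("count comparisons reproduce the printed significance bounds", {
  # gene family: 65 gag, 50 pol, 65 env over 65 typical copies
  tabs <- list(
    classes = matrix(c(65, 0), 2, 1,
                     dimnames = list(c("typical", "solo_ltr"), "g")),
    genes = matrix(c(65, 50, 65), 3, 1,
                   dimnames = list(c("gag", "pol", "env"), "g")),
    peptides = NULL)
  res <- run_count_comparisons(tabs)
  gene <- res[res$family == "gene_presence", ]
  expect_lt(gene$p_bonferroni[gene$label == "gag vs pol"], 0.001)
  expect_lt(gene$p_bonferroni[gene$label == "pol vs env"], 0.001)
  expect_equal(gene$p_bonferroni[gene$label == "gag vs env"], 1)
  # two identical genomes: all corrected p = 1
  tabs2 <- list(classes = matrix(c(10, 5, 10, 5), 2, 2,
                                 dimnames = list(c("typical", "solo_ltr"),
                                                 c("a", "b"))),
                genes = NULL, peptides = NULL)
  res2 <- run_count_comparisons(tabs2)
  expect_true(all(res2$p_bonferroni == 1))
})
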