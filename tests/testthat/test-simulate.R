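test_that("default pedigree has 5 tips with the oldest split at 2 My", {
  tree <- build_host_pedigree(sim_config(seed = 1))
  expect_length(tree$tips, 5)
  expect_setequal(tree$tips,
                  c("chaus", "nigripes", "catus_1", "catus_2", "catus_3"))
  expect_equal(max(tree$branches$t_old), 2.0)
  expect_equal(tree$branches$t_old[tree$branches$child == "chaus"], 2.0)
})

test_that("degenerate and invalid pedigrees are handled", {
  cfg <- sim_config(seed = 1,
                    tree = list(topology = "single", duration = 0))
  tree <- build_host_pedigree(cfg)
  expect_length(tree$tips, 1)
  # no branch length, no insertions possible
  truth <- simulate_endogenization(tree, synthetic_provirus(1),
                                   single_tip_config(1))
  cfg_bad <- sim_config(seed = 1)
  cfg_bad$tree$introgression <- list(donor = "chaus", recipient = "nigripes",
                                     time_mya = 1.8)
  expect_error(build_host_pedigree(cfg_bad), "outside")
  cfg_bad$tree$introgression$time_mya <- 1.2
  expect_s3_class(build_host_pedigree(cfg_bad), "host_tree")
})

test_that("copies are inherited by exactly the descendant tip set", {
  cfg <- sim_config(seed = 5, background_length = 100000,
                    endogenization_rate = 5, min_copy_spacing = 2000)
  tree <- build_host_pedigree(cfg)
  truth <- simulate_endogenization(tree, synthetic_provirus(5), cfg)
  for (i in seq_len(nrow(truth))) {
    expect_setequal(strsplit(truth$carriers[i], ",")[[1]],
                    descendant_tips(tree, truth$branch[i]))
  }
  # a copy on the nigripes+catus ancestral branch is absent from chaus
  anc <- truth[truth$branch == "anc_nigripes_catus", ]
  if (nrow(anc)) {
    expect_false(any(grepl("chaus", anc$carriers)))
  }
})

test_that("introgression transfers pre-existing donor copies to recipient", {
  cfg <- sim_config(seed = 11, background_length = 200000,
                    endogenization_rate = 4, min_copy_spacing = 2000,
                    tree = list(topology = "felis", chaus_split = 2,
                                nigripes_split = 1.5, catus_split = 0.1,
                                n_catus = 1,
                                introgression = list(donor = "catus_1",
                                                     recipient = "chaus",
                                                     time_mya = 0.05)))
  tree <- build_host_pedigree(cfg)
  truth <- simulate_endogenization(tree, synthetic_provirus(11), cfg)
  donor_line <- ancestor_branches(tree, "catus_1")
  for (i in seq_len(nrow(truth))) {
    carried <- strsplit(truth$carriers[i], ",")[[1]]
    transferred <- truth$branch[i] %in% donor_line &&
      truth$age_years[i] > 0.05e6
    if (transferred) {
      expect_true("chaus" %in% carried)
    }
    if (!truth$branch[i] %in% c(donor_line, "chaus", "root")) {
      expect_false("chaus" %in% carried)
    }
  }
})

test_that("endogenization event counts follow the Poisson expectation", {
  lambda <- 2
  counts <- vapply(1:100, function(s) {
    cfg <- sim_config(seed = s, background_length = 100000,
                      endogenization_rate = lambda, min_copy_spacing = 500,
                      tree = list(topology = "felis", chaus_split = 2,
                                  nigripes_split = 1.5, catus_split = 0.1,
                                  n_catus = 1))
    tree <- build_host_pedigree(cfg)
    nrow(simulate_endogenization(tree, synthetic_provirus(1), cfg))
  }, 1)
  br <- build_host_pedigree(sim_config(
    seed = 1, tree = list(topology = "felis", chaus_split = 2,
                          nigripes_split = 1.5, catus_split = 0.1,
                          n_catus = 1)))$branches
  total_len <- sum(br$t_old - br$t_young)
  expected <- lambda * total_len
  se <- sqrt(expected / 100)
  expect_lt(abs(mean(counts) - expected), 3 * se)
  # rate zero gives an empty truth list
  cfg0 <- sim_config(seed = 1, endogenization_rate = 0)
  tree0 <- build_host_pedigree(cfg0)
  expect_equal(nrow(simulate_endogenization(tree0, synthetic_provirus(1),
                                            cfg0)), 0)
})

test_that("age-0 copies are identical to the reference with equal LTRs", {
  ref <- synthetic_provirus(3)
  cfg <- single_tip_config(3)
  tr <- make_truth(age = 0, tsd = "GGAG")
  inst <- evolve_copy(ref, tr, cfg)
  expect_identical(inst$element, ref$seq)
  L <- 600
  expect_identical(substr(inst$element, 1, L),
                   substr(inst$element, nchar(inst$element) - L + 1,
                          nchar(inst$element)))
  expect_identical(inst$tsd_up, "GGAG")
  expect_identical(inst$tsd_down, "GGAG")
})

test_that("solo collapse leaves exactly one LTR between the TSD copies", {
  ref <- synthetic_provirus(3)
  cfg <- single_tip_config(3)
  tr <- make_truth(age = 0, tsd = "ACGT",
                   events = list(list(type = "solo_collapse", kept = "5p")),
                   class_truth = "solo_ltr")
  inst <- evolve_copy(ref, tr, cfg)
  expect_equal(nchar(inst$element), 600)
  expect_identical(inst$element, substr(ref$seq, 1, 600))
  expect_identical(inst$tsd_up, inst$tsd_down)
  expect_identical(inst$tsd_up, "ACGT")
})

test_that("LTR-pair differences match the neutral-clock Poisson mean", {
  ref <- synthetic_provirus(4)
  cfg <- single_tip_config(4)
  set.seed(99)
  age <- 1e6
  L <- 600
  diffs <- vapply(1:500, function(i) {
    inst <- evolve_copy(ref, make_truth(age = age), cfg)
    l5 <- strsplit(substr(inst$element, 1, L), "")[[1]]
    l3 <- strsplit(substr(inst$element, nchar(inst$element) - L + 1,
                          nchar(inst$element)), "")[[1]]
    sum(l5 != l3)
  }, 1)
  expected <- 2 * cfg$r * age * L
  se <- sqrt(expected / 500)
  expect_lt(abs(mean(diffs) - expected), 3 * se)
})

test_that("emitted genome length equals background + element + TSD", {
  ref <- synthetic_provirus(6)
  cfg <- single_tip_config(6, background_length = 50000)
  tr <- make_truth(pos = 20000, age = 0)
  em <- emit_genomes(tr, ref, cfg, individuals = "tip_1")
  g <- em$genomes$tip_1[["scaffold_1"]]
  expect_equal(nchar(g), 50000 + nchar(ref$seq) + 4)
  # the 4-mers flanking the element are both the truth TSD
  row <- em$truth_table[1, ]
  expect_identical(substr(g, row$genome_start - 3, row$genome_start),
                   row$tsd)
  expect_identical(substr(g, row$genome_end + 1, row$genome_end + 4),
                   row$tsd)
  # element sits where the truth table says
  expect_identical(substr(g, row$genome_start + 1, row$genome_end), ref$seq)
})

test_that("end-truncated implants are emitted as incomplete segments", {
  ref <- synthetic_provirus(6)
  cfg <- single_tip_config(6, background_length = 50000)
  tr <- make_truth(pos = 2000, age = 0, trunc_cut = 3000L)
  em <- emit_genomes(tr, ref, cfg, individuals = "tip_1")
  row <- em$truth_table[1, ]
  expect_identical(row$class_truth, "incomplete_segment")
  expect_equal(row$genome_start, 0)
  expect_equal(row$genome_end, nchar(ref$seq) - 3000)
})

test_that("identical config and seed give byte-identical outputs", {
  cfg <- sim_config(seed = 21, background_length = 60000,
                    endogenization_rate = 2, min_copy_spacing = 2000,
                    tree = list(topology = "felis", chaus_split = 2,
                                nigripes_split = 1.5, catus_split = 0.1,
                                n_catus = 1))
  s1 <- simulate_genomes(cfg)
  s2 <- simulate_genomes(cfg)
  expect_identical(s1$genomes, s2$genomes)
  expect_identical(s1$truth_table, s2$truth_table)
})

test_that("config validation rejects bad rates and TSD lengths", {
  expect_error(sim_config(solo_collapse_hazard = -0.1), "probability")
  expect_error(sim_config(tsd_length = 5), "fixed at 4")
  expect_error(sim_config(deletion_size_range = c(10, 500)), "1000")
})
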