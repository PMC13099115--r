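#' Benchmark scenario: one exemplar of each copy class per genome
#'
#' Implants, in each of `n_individuals` genomes, one copy of each of the
#' five structural classes (typical, solo LTR, paired solo LTR, atypical,
#' incomplete segment) at modest age, yielding a clean classification
#' benchmark with known truth.
#'
#' @param seed integer seed
#' @param n_individuals number of genomes (default 6, 30 copies total)
#' @param age_years age of every implanted copy
#' @return list with `genomes`, `truth_table`, `provirus_ref`, `config`
#' @export
simulate_class_benchmark <- function(seed = 1, n_individuals = 6,
                                     age_years = 3e5) {
  config <- sim_config(seed = seed, background_length = 200000,
                       n_scaffolds = 1, host_background_divergence = 0.002,
                       endogenization_rate = 0)
  ref <- synthetic_provirus(seed)
  inds <- sprintf("ind_%d", seq_len(n_individuals))
  rows <- list()
  classes <- c("incomplete_segment", "typical", "solo_ltr",
               "paired_solo_ltr", "atypical")
  positions <- c(2000, 40000, 80000, 120000, 160000)
  k <- 0
  set.seed(substream_seed(seed, "misc"))
  anc <- ancestral_scaffolds(config)
  for (ind in inds) {
    for (j in seq_along(classes)) {
      k <- k + 1
      pos <- positions[j]
      tsd <- substr(anc[[1]], pos + 1, pos + 4)
      ev <- switch(classes[j],
        typical = list(),
        incomplete_segment = list(),
        solo_ltr = list(list(type = "solo_collapse", kept = "5p")),
        paired_solo_ltr = list(list(type = "paired_solo", remnant = 50L)),
        atypical = list(list(type = "duplication")))
      rows[[k]] <- data.frame(
        copy_id = sprintf("copy_%03d", k), branch = ind,
        scaffold = "scaffold_1", insertion_position = pos,
        age_years = age_years, tsd = tsd, strand = "+",
        class_truth = if (classes[j] == "incomplete_segment") "typical"
                      else classes[j],
        carriers = ind, parent_copy_ids = "",
        trunc_cut = if (classes[j] == "incomplete_segment") 3000L else 0L)
    }
  }
  truth <- do.call(rbind, rows)
  truth$events <- lapply(seq_len(nrow(truth)), function(i) {
    j <- (i - 1) %% length(classes) + 1
    switch(classes[j],
      typical = list(), incomplete_segment = list(),
      solo_ltr = list(list(type = "solo_collapse", kept = "5p")),
      paired_solo_ltr = list(list(type = "paired_solo", remnant = 50L)),
      atypical = list(list(type = "duplication")))
  })
  em <- emit_genomes(truth, ref, config, individuals = inds)
  list(genomes = em$genomes, truth_table = em$truth_table,
       provirus_ref = ref, config = config)
}

#' Benchmark scenario: locus mining on a small host pedigree
#'
#' Simulates three individuals (a jungle-cat-like, a black-footed-cat-like
#' and one domestic-cat-like tip) with 1 Mb scaffolds and insertions drawn
#' on the pedigree, the default mining benchmark.
#'
#' @param seed integer seed
#' @param background_length scaffold length (default 1 Mb)
#' @param endogenization_rate events per branch per My
#' @return as [simulate_genomes()]
#' @export
simulate_mining_benchmark <- function(seed = 1, background_length = 1e6,
                                      endogenization_rate = 2.5) {
  config <- sim_config(
    seed = seed, background_length = background_length,
    endogenization_rate = endogenization_rate,
    tree = list(topology = "felis", chaus_split = 2, nigripes_split = 1.5,
                catus_split = 0.1, n_catus = 1))
  simulate_genomes(config)
}

#' Simulate independently diverging LTR pairs for dating benchmarks
#'
#' Each pair starts as one ancestral LTR (identical repeats at integration)
#' and both members then accumulate K80 substitutions independently for
#' `age_years` at rate `r` — the generating process the `T = K/2r` clock
#' estimator assumes.
#'
#' @param n number of pairs
#' @param age_years true insertion age
#' @param ltr_len LTR length in bp
#' @param r substitutions/site/year
#' @param kappa transition/transversion rate ratio
#' @param seed integer seed
#' @return character matrix `n x 2` of LTR sequences
#' @export
simulate_ltr_pairs <- function(n, age_years, ltr_len = 600, r = 2.3e-9,
                               kappa = 2, seed = 1) {
  set.seed(seed)
  out <- matrix("", n, 2)
  for (i in seq_len(n)) {
    anc <- seq_chars(random_dna(ltr_len))
    out[i, 1] <- chars_seq(evolve_chars(anc, age_years, r, kappa))
    out[i, 2] <- chars_seq(evolve_chars(anc, age_years, r, kappa))
  }
  out
}

#' Simulate a clonal (recombination-free) aligned triplet
#'
#' Three sequences diverged independently from one ancestor; pairwise
#' divergence is about `divergence`. The null scenario for recombination
#' screens.
#'
#' @param len alignment length
#' @param divergence expected pairwise substitutions/site
#' @param kappa transition/transversion rate ratio
#' @return character vector of 3 equal-length sequences
#'   (candidate, parent A, parent B roles are interchangeable)
#' @export
simulate_clonal_triplet <- function(len = 2000, divergence = 0.05, kappa = 2) {
  anc <- random_dna(len)
  vapply(1:3, function(i) diverge_seq(anc, divergence / 2, kappa), "")
}

#' Simulate a recombinant (mosaic) aligned triplet
#'
#' Two parents diverge to about `parent_divergence` from each other; the
#' candidate is a 50/50 mosaic spliced at the midpoint, with slight
#' post-recombination divergence.
#'
#' @param len alignment length
#' @param parent_divergence expected parent-parent substitutions/site
#' @param extra post-recombination divergence of the mosaic
#' @param kappa transition/transversion rate ratio
#' @return list with `seqs` (candidate, parent A, parent B) and `breakpoint`
#' @export
simulate_mosaic_triplet <- function(len = 2000, parent_divergence = 0.05,
                                    extra = 0.002, kappa = 2) {
  anc <- random_dna(len)
  pa <- diverge_seq(anc, parent_divergence / 2, kappa)
  pb <- diverge_seq(anc, parent_divergence / 2, kappa)
  bp <- len %/% 2
  cand <- diverge_seq(paste0(substr(pa, 1, bp),
                             substr(pb, bp + 1, len)), extra, kappa)
  list(seqs = c(cand, pa, pb), breakpoint = bp)
}

#' Simulate a single-origin ERV copy set with an exogenous reference
#'
#' All endogenous copies descend from one endogenization of the ancestral
#' provirus (ages uniform up to `max_age_years`); the exogenous reference
#' diverged much earlier (`exo_divergence` substitutions/site). Used for
#' monophyly benchmarks.
#'
#' @param n_copies endogenous copies
#' @param max_age_years oldest insertion age
#' @param exo_divergence provirus-to-exogenous divergence, subs/site
#' @param r,kappa substitution model parameters
#' @param seed integer seed
#' @param provirus_ref optional `provirus_reference`
#' @return named character vector: copies `endo_*` plus `exogenous_ref`
#' @export
simulate_single_origin <- function(n_copies = 6, max_age_years = 3.5e6,
                                   exo_divergence = 0.05, r = 2.3e-9,
                                   kappa = 2, seed = 1, provirus_ref = NULL) {
  set.seed(seed)
  if (is.null(provirus_ref)) provirus_ref <- synthetic_provirus(seed)
  ages <- stats::runif(n_copies, 1e5, max_age_years)
  seqs <- vapply(ages, function(a) evolve_seq(provirus_ref$seq, a, r, kappa), "")
  names(seqs) <- sprintf("endo_%d", seq_len(n_copies))
  c(seqs, exogenous_ref = diverge_seq(provirus_ref$seq, exo_divergence, kappa))
}

#' Simulate copy sets under an introgression hypothesis
#'
#' A donor host lineage radiates its own ERV copies; a recent subvariant of
#' that lineage seeds copies in a recipient species (introgression), so
#' recipient copies nest inside the donor clade. An independent second
#' lineage and an exogenous reference complete the set.
#'
#' @param seed integer seed
#' @param provirus_ref optional `provirus_reference`
#' @param kappa transition/transversion rate ratio
#' @return named character vector of aligned sequences (`donor_*`,
#'   `recipient_*`, `other_*`, `exogenous_ref`)
#' @export
simulate_introgression_copies <- function(seed = 1, provirus_ref = NULL,
                                          kappa = 2) {
  set.seed(seed)
  if (is.null(provirus_ref)) provirus_ref <- synthetic_provirus(seed)
  a0 <- provirus_ref$seq
  donor_anc <- diverge_seq(a0, 0.004, kappa)
  recip_anc <- diverge_seq(donor_anc, 0.0015, kappa)
  other_anc <- diverge_seq(a0, 0.004, kappa)
  out <- c(
    stats::setNames(vapply(1:4, function(i) diverge_seq(donor_anc, 0.002, kappa), ""),
                    sprintf("donor_%d", 1:4)),
    stats::setNames(vapply(1:3, function(i) diverge_seq(recip_anc, 0.0005, kappa), ""),
                    sprintf("recipient_%d", 1:3)),
    stats::setNames(vapply(1:3, function(i) diverge_seq(other_anc, 0.002, kappa), ""),
                    sprintf("other_%d", 1:3)),
    exogenous_ref = diverge_seq(a0, 0.05, kappa))
  out
}
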