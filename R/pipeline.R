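#' Build a pipeline configuration
#'
#' @param seed master seed
#' @param sim a [sim_config()] to simulate input genomes, or `NULL` when
#'   `genome_fastas` are given
#' @param genome_fastas named character vector of FASTA paths (ignored when
#'   `sim` is given)
#' @param provirus_ref a `provirus_reference`, or `NULL` for the synthetic
#'   default
#' @param out_dir artifact directory (`NULL`: no files written)
#' @param mining parameter overrides for [mining_params()]
#' @param r,r_interval dating rate and interval
#' @param min_methods recombination consensus threshold
#' @param bootstrap_B bootstrap replicates for the tree
#' @param stages named logical toggles: `recomb`, `compare`, `phylo`
#' @return list of class `pipeline_config`
#' @export
pipeline_config <- function(seed = 1, sim = sim_config(seed = seed),
                            genome_fastas = NULL, provirus_ref = NULL,
                            out_dir = NULL, mining = list(), r = 2.3e-9,
                            r_interval = c(2.0e-9, 2.5e-9), min_methods = 2,
                            bootstrap_B = 50,
                            stages = list(recomb = TRUE, compare = TRUE,
                                          phylo = TRUE)) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#' @param path YAML file
#' @return a `pipeline_config`
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim <- if (!is.null(y$sim)) do.call(sim_config, y$sim) else NULL
  do.call(pipeline_config,
          c(list(seed = y$seed %||% 1, sim = sim,
                 genome_fastas = unlist(y$genome_fastas)),
            y[setdiff(names(y), c("seed", "sim", "genome_fastas"))]))
}

#' Run the full ERV characterization pipeline
#'
#' simulate/load -> mine -> annotate -> date -> recombination-screen ->
#' compare -> tree, returning a machine-readable report and (optionally)
#' writing per-stage TSV artifacts.
#'
#' @param config a [pipeline_config()]
#' @return a `run_report` list: per-genome class counts, dating summary,
#'   recombination removals, ortholog groups, Fisher results, trees, plus
#'   all intermediate tables
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  ref <- config$provirus_ref %||% synthetic_provirus(config$seed)
  truth_table <- NULL
  if (!is.null(config$sim)) {
    sim <- simulate_genomes(config$sim, provirus_ref = ref,
                            out_dir = if (!is.null(config$out_dir)) {
                              file.path(config$out_dir, "sim")
                            } else NULL)
    genomes <- sim$genomes
    truth_table <- sim$truth_table
  } else {
    if (is.null(config$genome_fastas) || !length(config$genome_fastas)) {
      stop("no input genomes: provide `sim` or `genome_fastas`")
    }
    genomes <- lapply(config$genome_fastas, function(p) {
      ss <- Biostrings::readDNAStringSet(p)
      stats::setNames(as.character(ss), sub("\\s.*", "", names(ss)))
    })
    if (is.null(names(genomes))) {
      names(genomes) <- sub("\\.[^.]*$", "", basename(config$genome_fastas))
    }
  }
  params <- do.call(mining_params, config$mining)

  mined <- lapply(names(genomes), function(g) {
    mine_genome(genomes[[g]], ref, params, genome_id = g)
  })
  names(mined) <- names(genomes)

  annotated <- lapply(names(genomes), function(g) {
    annotate_genome(mined[[g]], ref,
                    scaffold_lengths = nchar(genomes[[g]]))
  })
  names(annotated) <- names(genomes)
  copy_table <- do.call(rbind, lapply(names(genomes), function(g) {
    ct <- annotated[[g]]$copy_table
    if (is.null(ct)) return(NULL)
    loci <- mined[[g]]$loci
    cbind(ct, loci[match(ct$locus_id, loci$locus_id),
                   c("scaffold", "start", "end", "strand")])
  }))
  records <- unlist(lapply(annotated, `[[`, "records"), recursive = FALSE)

  dating <- date_copies(records, config$r, config$r_interval)

  # recombination screen per genome over typical copies
  removed_ids <- character(0)
  recomb <- NULL
  if (isTRUE(config$stages$recomb)) {
    calls <- list()
    for (g in names(genomes)) {
      recs <- annotated[[g]]$records
      typ <- Filter(function(r) r$class == "typical", recs)
      if (length(typ) < 3) next
      seqs <- vapply(typ, function(r) r$locus_id, "")
      msa <- reference_projected_msa(
        stats::setNames(vapply(typ, function(r) {
          mined[[g]]$loci$element_seq[mined[[g]]$loci$locus_id == r$locus_id]
        }, ""), seqs), ref)
      rows <- apply(msa$matrix, 1, paste, collapse = "")
      scr <- screen_recombination(rows, min_methods = config$min_methods,
                                  seed = substream_seed(config$seed, "recomb"))
      calls[[g]] <- scr
      removed_ids <- c(removed_ids,
                       scr$decisions$copy_id[scr$decisions$removed])
    }
    recomb <- calls
  }

  nonrecomb_ids <- setdiff(copy_table$locus_id[copy_table$class == "typical"],
                           removed_ids)

  # comparative stage
  comparative <- NULL
  if (isTRUE(config$stages$compare)) {
    flank_cols <- do.call(rbind, lapply(names(genomes), function(g) {
      loci <- mined[[g]]$loci
      if (!nrow(loci)) return(NULL)
      ct <- annotated[[g]]$copy_table
      data.frame(copy_uid = loci$locus_id, genome_id = g,
                 flank_up = loci$flank_up, flank_down = loci$flank_down,
                 signature = ifelse(ct$signature_matching,
                                    ct$signature_up, NA))
    }))
    orthologs <- match_orthologous_loci(flank_cols)
    tables <- build_count_tables(copy_table, records,
                                 nonrecombinant_ids = nonrecomb_ids)
    fisher <- run_count_comparisons(tables)
    comparative <- list(orthologs = orthologs, tables = tables,
                       fisher = fisher)
  }

  # phylogeny of nonrecombinant typical copies + reference outgroup tip
  phylo <- NULL
  if (isTRUE(config$stages$phylo)) {
    elems <- do.call(c, lapply(names(genomes), function(g) {
      loci <- mined[[g]]$loci
      keep <- loci$locus_id %in% nonrecomb_ids
      stats::setNames(loci$element_seq[keep], loci$locus_id[keep])
    }))
    if (length(elems) >= 3) {
      msa <- reference_projected_msa(
        c(elems, reference = ref$seq), ref)
      D <- k2p_matrix(msa)
      if (!any(is.na(D))) {
        bs <- bootstrap_support(msa, B = config$bootstrap_B,
                                seed = substream_seed(config$seed, "phylo"))
        phylo <- list(msa = msa, tree = bs$tree, support = bs$support)
      }
    }
  }

  report <- list(
    seed = config$seed,
    n_genomes = length(genomes),
    class_counts = if (!is.null(copy_table)) {
      as.data.frame.matrix(table(copy_table$class, copy_table$genome_id))
    } else NULL,
    dating_summary = if (!is.null(dating)) {
      list(n_dated = nrow(dating),
           median_T = stats::median(dating$T_years, na.rm = TRUE),
           pct_identical_ltrs = 100 * mean(dating$identical_ltrs))
    } else NULL,
    recomb_removed = removed_ids,
    n_ortholog_groups = if (!is.null(comparative)) {
      length(unique(comparative$orthologs$groups$group_id))
    } else NULL)

  out <- structure(list(report = report, copy_table = copy_table,
                        records = records, mined = mined, dating = dating,
                        recomb = recomb, comparative = comparative,
                        phylo = phylo, truth_table = truth_table,
                        provirus_ref = ref, genomes = genomes),
                   class = "run_report")
  if (!is.null(config$out_dir)) write_report(out, config$out_dir)
  out
}

write_report <- function(out, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(out$copy_table)) {
    write_copy_table(out$copy_table, file.path(out_dir, "copies.tsv"))
  }
  if (!is.null(out$dating)) {
    utils::write.table(out$dating, file.path(out_dir, "dating.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(out$comparative$fisher)) {
    utils::write.table(out$comparative$fisher,
                       file.path(out_dir, "fisher.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  if (!is.null(out$comparative$orthologs$groups)) {
    utils::write.table(out$comparative$orthologs$groups,
                       file.path(out_dir, "ortholog_groups.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(out$phylo$tree)) {
    write_tree_newick(out$phylo$tree, file.path(out_dir, "tree.nwk"))
  }
  jsonlite::write_json(out$report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(out_dir)
}

#' Evaluate pipeline results against simulator ground truth
#'
#' Matches mined loci to implanted copies by coordinate overlap and
#' computes locus-level sensitivity and precision, boundary error,
#' the classification confusion matrix, signature accuracy, dating bias
#' and RMSE, and recombination screen power/type-I error.
#'
#' @param result a `run_report` from [run_pipeline()] (run on simulated
#'   input), or a list with `copy_table` and `dating`
#' @param truth_table the simulator truth (defaults to the one recorded in
#'   `result`)
#' @param boundary_tol bp tolerance for the boundary-accuracy count
#' @return list of evaluation blocks
#' @export
evaluate_against_truth <- function(result, truth_table = NULL,
                                   boundary_tol = 50) {
  truth <- truth_table %||% result$truth_table
  if (is.null(truth)) stop("no truth table available")
  ct <- result$copy_table
  matches <- list()
  for (i in seq_len(nrow(truth))) {
    tr <- truth[i, ]
    cand <- which(ct$genome_id == tr$carrier & ct$scaffold == tr$scaffold &
                    ct$start < tr$genome_end & ct$end > tr$genome_start)
    j <- if (length(cand)) cand[1] else NA_integer_
    matches[[i]] <- data.frame(
      truth_idx = i, copy_idx = j,
      found = !is.na(j),
      boundary_ok = if (!is.na(j)) {
        abs(ct$start[j] - tr$genome_start) <= boundary_tol &&
          abs(ct$end[j] - tr$genome_end) <= boundary_tol
      } else FALSE,
      class_truth = tr$class_truth,
      class_called = if (!is.na(j)) ct$class[j] else NA,
      sig_ok = if (!is.na(j)) {
        isTRUE(ct$signature_matching[j]) && ct$signature_up[j] == tr$tsd
      } else NA,
      age_years = tr$age_years,
      locus_id = if (!is.na(j)) ct$locus_id[j] else NA,
      is_recombinant = nzchar(tr$parent_copy_ids))
  }
  mm <- do.call(rbind, matches)
  non_trunc <- mm$class_truth != "incomplete_segment"
  sensitivity <- mean(mm$found[non_trunc])
  boundary_acc <- mean(mm$boundary_ok[non_trunc & mm$found])
  precision <- mean(ct$locus_id %in% mm$locus_id)
  confusion <- table(truth = mm$class_truth[mm$found],
                     called = mm$class_called[mm$found])
  dating_eval <- NULL
  if (!is.null(result$dating)) {
    dd <- merge(mm[mm$found & !mm$is_recombinant, ],
                result$dating, by = "locus_id")
    dd <- dd[!is.na(dd$T_years), ]
    if (nrow(dd)) {
      dating_eval <- list(
        n = nrow(dd),
        bias = mean(dd$T_years - dd$age_years),
        rmse = sqrt(mean((dd$T_years - dd$age_years)^2)))
    }
  }
  recomb_eval <- NULL
  if (!is.null(result$report$recomb_removed)) {
    rem <- result$report$recomb_removed
    rec_rows <- mm$found & mm$is_recombinant
    non_rows <- mm$found & !mm$is_recombinant &
      mm$class_truth == "typical"
    recomb_eval <- list(
      power = if (any(rec_rows)) mean(mm$locus_id[rec_rows] %in% rem)
              else NA,
      type1 = if (any(non_rows)) mean(mm$locus_id[non_rows] %in% rem)
              else NA)
  }
  list(sensitivity = sensitivity, precision = precision,
       boundary_accuracy = boundary_acc, confusion = confusion,
       signature_accuracy = mean(mm$sig_ok[mm$found & non_trunc],
                                 na.rm = TRUE),
       dating = dating_eval, recombination = recomb_eval,
       matches = mm)
}
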