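#' Ancestral background scaffolds
#'
#' Generates the ancestral (pre-divergence) background sequence shared by
#' all simulated individuals: iid nucleotides at the configured GC content,
#' one string per scaffold. Deterministic given the config seed.
#'
#' @param config a [sim_config()]
#' @return named character vector of scaffold sequences
#' @export
ancestral_scaffolds <- function(config) {
  set.seed(substream_seed(config$seed, "emit"))
  out <- vapply(seq_len(config$n_scaffolds),
                function(i) random_dna(config$background_length, config$gc), "")
  names(out) <- paste0("scaffold_", seq_len(config$n_scaffolds))
  out
}

#' Simulate endogenization events on a host pedigree
#'
#' Draws a Poisson number of germline insertion events on every branch of
#' the host tree (rate = `endogenization_rate` events/branch/My), assigns
#' each event a uniform time on its branch, a uniform position on a
#' uniformly chosen scaffold, a strand, and the 4-nt target-site duplication
#' read from the ancestral background at the integration point. Each copy is
#' inherited by all tip descendants of its branch (plus introgression
#' recipients, for copies already present in the donor lineage at the
#' introgression time). Structural events (solo-LTR collapse, paired-solo
#' collapse, internal deletion, internal duplication, inter-copy
#' recombination) are drawn here and recorded in the truth; [evolve_copy()]
#' applies them.
#'
#' @param host_tree from [build_host_pedigree()]
#' @param provirus_ref a `provirus_reference`
#' @param config a [sim_config()]
#' @return truth data.frame, one row per copy, with list-column `events`
#' @export
simulate_endogenization <- function(host_tree, provirus_ref, config) {
  if (config$background_length < 1) stop("zero-length background")
  anc <- ancestral_scaffolds(config)
  set.seed(substream_seed(config$seed, "endogenization"))
  br <- host_tree$branches
  rows <- list()
  used <- replicate(config$n_scaffolds, numeric(0), simplify = FALSE)
  copy_n <- 0
  for (i in seq_len(nrow(br))) {
    dur <- br$t_old[i] - br$t_young[i]
    n_ev <- stats::rpois(1, config$endogenization_rate * dur)
    if (n_ev == 0) next
    times <- stats::runif(n_ev, br$t_young[i], br$t_old[i])
    for (t_my in times) {
      age <- t_my * 1e6
      if (age > config$max_insertion_age_years) next
      copy_n <- copy_n + 1
      sc <- sample.int(config$n_scaffolds, 1)
      pos <- draw_position(used[[sc]], config)
      if (is.na(pos)) { copy_n <- copy_n - 1; next }
      used[[sc]] <- c(used[[sc]], pos)
      tsd <- substr(anc[[sc]], pos + 1, pos + config$tsd_length)
      carriers <- descendant_tips(host_tree, br$child[i])
      rows[[length(rows) + 1]] <- list(
        copy_id = sprintf("copy_%03d", copy_n), branch = br$child[i],
        scaffold = names(anc)[sc], insertion_position = pos,
        age_years = age, tsd = tsd,
        strand = sample(c("+", "-"), 1), carriers = carriers
      )
    }
  }
  # introgression: copies in the donor lineage at the transfer time also
  # appear in the recipient subtree
  ie <- host_tree$introgression
  if (!is.null(ie) && length(rows)) {
    donor_line <- ancestor_branches(host_tree, ie$donor)
    extra <- descendant_tips(host_tree, ie$recipient)
    for (j in seq_along(rows)) {
      if (rows[[j]]$branch %in% donor_line &&
          rows[[j]]$age_years > ie$time_mya * 1e6) {
        rows[[j]]$carriers <- unique(c(rows[[j]]$carriers, extra))
      }
    }
  }
  truth <- truth_from_rows(rows, config)
  draw_structural_events(truth, provirus_ref, config)
}

draw_position <- function(used, config) {
  lo <- config$end_margin
  hi <- config$background_length - config$end_margin
  if (hi <= lo) return(NA_integer_)
  for (try in 1:100) {
    pos <- floor(stats::runif(1, lo, hi))
    if (!length(used) || min(abs(used - pos)) >= config$min_copy_spacing) {
      return(pos)
    }
  }
  NA_integer_
}

truth_from_rows <- function(rows, config) {
  if (!length(rows)) {
    return(data.frame(copy_id = character(0), branch = character(0),
                      scaffold = character(0), insertion_position = integer(0),
                      age_years = numeric(0), tsd = character(0),
                      strand = character(0), class_truth = character(0),
                      carriers = character(0), parent_copy_ids = character(0),
                      trunc_cut = integer(0)))
  }
  df <- do.call(rbind, lapply(rows, function(r) {
    data.frame(copy_id = r$copy_id, branch = r$branch, scaffold = r$scaffold,
               insertion_position = r$insertion_position,
               age_years = r$age_years, tsd = r$tsd, strand = r$strand,
               class_truth = "typical",
               carriers = paste(r$carriers, collapse = ","),
               parent_copy_ids = "", trunc_cut = 0L)
  }))
  df$events <- replicate(nrow(df), list(), simplify = FALSE)
  df
}

# Draw per-copy structural events; sets class_truth accordingly.
draw_structural_events <- function(truth, provirus_ref, config) {
  n <- nrow(truth)
  if (n == 0) return(truth)
  L <- ltr_length(provirus_ref)
  total <- provirus_ref$length
  for (i in seq_len(n)) {
    age_my <- truth$age_years[i] / 1e6
    p_collapse <- 1 - exp(-config$solo_collapse_hazard * age_my)
    if (stats::runif(1) < p_collapse) {
      if (stats::runif(1) < config$paired_solo_frac) {
        truth$events[[i]] <- list(list(type = "paired_solo",
                                       remnant = sample(0:100, 1)))
        truth$class_truth[i] <- "paired_solo_ltr"
      } else {
        truth$events[[i]] <- list(list(type = "solo_collapse",
                                       kept = sample(c("5p", "3p"), 1)))
        truth$class_truth[i] <- "solo_ltr"
      }
      next
    }
    if (stats::runif(1) < config$duplication_prob) {
      truth$events[[i]] <- list(list(type = "duplication"))
      truth$class_truth[i] <- "atypical"
      next
    }
    if (stats::runif(1) < config$deletion_prob) {
      rng <- config$deletion_size_range
      size <- round(exp(stats::runif(1, log(rng[1]), log(rng[2]))))
      int_lo <- L + 1
      int_hi <- total - L
      size <- min(size, int_hi - int_lo - 100)
      if (size >= rng[1]) {
        start <- sample(int_lo:(int_hi - size), 1)
        truth$events[[i]] <- list(list(type = "deletion", start = start,
                                       size = size))
      }
    }
  }
  # recombination among structurally intact copies
  intact <- which(vapply(truth$events, length, 0L) == 0 &
                    truth$class_truth == "typical")
  if (length(intact) >= 3 && config$recombination_prob > 0) {
    for (i in intact) {
      if (stats::runif(1) >= config$recombination_prob) next
      pool <- setdiff(intact, i)
      if (length(pool) < 2) next
      parents <- sample(pool, 2)
      bp <- sample(round(0.2 * total):round(0.8 * total), 1)
      truth$events[[i]] <- list(list(
        type = "recombination", breakpoint = bp,
        parents = truth$copy_id[parents]))
      truth$parent_copy_ids[i] <- paste(truth$copy_id[parents], collapse = ",")
    }
  }
  truth
}

#' Evolve one ERV copy from the reference provirus
#'
#' Applies neutral K80 substitutions independently to every site (both LTRs
#' therefore diverge independently) for the copy's age at rate `config$r`,
#' evolves both target-site-duplication copies the same way, then applies
#' the copy's recorded structural events: internal deletion, solo-LTR
#' collapse (one LTR left between the original TSD copies), paired-solo
#' collapse (both LTRs retained, internal region lost), or internal
#' duplication (repeated internal region around an LTR-like spacer —
#' the atypical architecture). Recombination mosaics are assembled by the
#' caller from the parents' evolved instances.
#'
#' @param provirus_ref a `provirus_reference`
#' @param truth_row one row of the truth table (data.frame or list) with
#'   `age_years`, `tsd` and `events`
#' @param config a [sim_config()]
#' @return list with `element` (character), `tsd_up`, `tsd_down`, `ltrs`
#'   (data.frame of LTR intervals in element coordinates, 1-based) and
#'   `class`
#' @export
evolve_copy <- function(provirus_ref, truth_row, config) {
  age <- truth_row$age_years
  if (age < 0) stop("age_years must be >= 0")
  events <- truth_row$events
  if (is.data.frame(truth_row)) events <- truth_row$events[[1]]
  chars <- evolve_chars(seq_chars(provirus_ref$seq), age, config$r, config$kappa)
  tsd_up <- chars_seq(evolve_chars(seq_chars(truth_row$tsd), age, config$r,
                                   config$kappa))
  tsd_down <- chars_seq(evolve_chars(seq_chars(truth_row$tsd), age, config$r,
                                     config$kappa))
  L <- ltr_length(provirus_ref)
  total <- provirus_ref$length
  element <- chars
  ltrs <- data.frame(start = c(1, total - L + 1), end = c(L, total),
                     label = c("LTR5", "LTR3"))
  cls <- "typical"
  for (ev in events) {
    if (ev$type == "deletion") {
      keep <- setdiff(seq_along(element), ev$start:(ev$start + ev$size - 1))
      element <- element[keep]
      ltrs$start[2] <- ltrs$start[2] - ev$size
      ltrs$end[2] <- ltrs$end[2] - ev$size
    } else if (ev$type == "solo_collapse") {
      idx <- if (ev$kept == "5p") 1:L else (length(element) - L + 1):length(element)
      element <- element[idx]
      ltrs <- data.frame(start = 1, end = L, label = "LTR")
      cls <- "solo_ltr"
    } else if (ev$type == "paired_solo") {
      rem <- ev$remnant
      idx <- c(1:(L + rem), (length(element) - L + 1):length(element))
      element <- element[idx]
      ltrs <- data.frame(start = c(1, L + rem + 1),
                         end = c(L, 2 * L + rem), label = c("LTR5", "LTR3"))
      cls <- "paired_solo_ltr"
    } else if (ev$type == "duplication") {
      internal <- element[(L + 1):(length(element) - L)]
      ltr_mid <- evolve_chars(seq_chars(substr(provirus_ref$seq, 1, L)),
                              age, config$r, config$kappa)
      internal2 <- evolve_chars(
        seq_chars(substr(provirus_ref$seq, L + 1, total - L)),
        age, config$r, config$kappa)
      element <- c(element[1:L], internal, ltr_mid, internal2,
                   element[(length(element) - L + 1):length(element)])
      n_int <- length(internal)
      ltrs <- data.frame(
        start = c(1, L + n_int + 1, length(element) - L + 1),
        end = c(L, 2 * L + n_int, length(element)),
        label = c("LTR5", "LTRmid", "LTR3"))
      cls <- "atypical"
    }
  }
  list(element = chars_seq(element), tsd_up = tsd_up, tsd_down = tsd_down,
       ltrs = ltrs, class = cls)
}

#' Emit per-individual genomes with implanted copies and ground truth
#'
#' Builds each individual's genome: the ancestral background diverged by
#' half the configured pairwise background divergence (star approximation),
#' with every carried copy implanted at its locus flanked by the two
#' evolved target-site-duplication copies. Each carrier's element instance
#' is evolved independently for the copy's age, so shared loci carry
#' per-individual divergence (and may date slightly differently per
#' carrier), while locus structure (collapse, deletions) is inherited.
#' Recombinant copies are spliced from their parents' instances at the
#' recorded breakpoint. Copies flagged for end-truncation lose their
#' upstream flank and the clipped part of the element (class
#' `incomplete_segment`).
#'
#' @param truths truth table from [simulate_endogenization()]
#' @param provirus_ref a `provirus_reference`
#' @param config a [sim_config()]
#' @param out_dir if non-NULL, write per-individual FASTA (width 80), truth
#'   TSV (0-based half-open coordinates), truth GFF3 and a JSON run log here
#' @param individuals individuals to emit; default: pedigree tips
#' @return list with `genomes` (per individual: named character vector of
#'   scaffolds), `truth_table` (one row per copy per carrier) and `files`
#' @export
emit_genomes <- function(truths, provirus_ref, config, out_dir = NULL,
                         individuals = NULL) {
  if (is.null(individuals)) {
    individuals <- build_host_pedigree(config)$tips
  }
  anc <- ancestral_scaffolds(config)
  d_half <- config$host_background_divergence / 2
  genomes <- list()
  rows <- list()
  base_seed <- substream_seed(config$seed, "evolve")

  # evolve every (copy, carrier) instance deterministically
  instances <- list()
  carriers_of <- strsplit(truths$carriers, ",", fixed = TRUE)
  get_instance <- function(i, ind) {
    key <- paste0(truths$copy_id[i], "|", ind)
    if (!is.null(instances[[key]])) return(instances[[key]])
    set.seed((base_seed + 7919L * i + 131L * match(ind, individuals)) %%
               .Machine$integer.max)
    evs <- truths$events[[i]]
    is_recomb <- length(evs) && evs[[1]]$type == "recombination"
    row <- list(age_years = truths$age_years[i], tsd = truths$tsd[i],
                events = if (is_recomb) list() else evs)
    inst <- evolve_copy(provirus_ref, row, config)
    if (is_recomb) {
      ev <- evs[[1]]
      pa <- get_instance(match(ev$parents[1], truths$copy_id), ind)
      pb <- get_instance(match(ev$parents[2], truths$copy_id), ind)
      mosaic <- paste0(substr(pa$element, 1, ev$breakpoint),
                       substr(pb$element, ev$breakpoint + 1,
                              nchar(pb$element)))
      # modest post-recombination divergence of the mosaic lineage
      inst$element <- evolve_seq(mosaic, 2e5, config$r, config$kappa)
    }
    instances[[key]] <<- inst
    inst
  }

  for (ind in individuals) {
    set.seed((base_seed + 104729L * match(ind, individuals)) %%
               .Machine$integer.max)
    bg <- lapply(anc, function(s) diverge_seq(s, d_half, config$kappa))
    carried <- which(vapply(carriers_of, function(cc) ind %in% cc, TRUE))
    scafs <- character(length(anc))
    names(scafs) <- names(anc)
    for (sc in names(anc)) {
      idx <- carried[truths$scaffold[carried] == sc]
      idx <- idx[order(truths$insertion_position[idx])]
      pieces <- character(0)
      prev_end <- 0L
      cur_len <- 0L
      for (i in idx) {
        inst <- get_instance(i, ind)
        elem <- inst$element
        if (truths$strand[i] == "-") elem <- revcomp(elem)
        pos <- truths$insertion_position[i]
        cut <- truths$trunc_cut[i]
        if (cut > 0) {
          # scaffold boundary falls inside the element: no upstream flank;
          # only valid for the leftmost copy on a scaffold
          elem_keep <- substr(elem, cut + 1, nchar(elem))
          pieces <- c(pieces, elem_keep, inst$tsd_down)
          g_start <- cur_len
          cur_len <- cur_len + nchar(elem_keep)
          g_end <- cur_len
          cur_len <- cur_len + 4L
          prev_end <- pos + 4L
          cls <- "incomplete_segment"
        } else {
          up_bg <- substr(bg[[sc]], prev_end + 1, pos)
          pieces <- c(pieces, up_bg, inst$tsd_up)
          cur_len <- cur_len + nchar(up_bg) + 4L
          g_start <- cur_len
          pieces <- c(pieces, elem, inst$tsd_down)
          cur_len <- cur_len + nchar(elem)
          g_end <- cur_len
          cur_len <- cur_len + 4L
          prev_end <- pos + 4L
          cls <- truths$class_truth[i]
        }
        rows[[length(rows) + 1]] <- data.frame(
          copy_id = truths$copy_id[i], carrier = ind, scaffold = sc,
          insertion_position = truths$insertion_position[i],
          genome_start = g_start, genome_end = g_end,
          strand = truths$strand[i], age_years = truths$age_years[i],
          tsd = truths$tsd[i], class_truth = cls,
          parent_copy_ids = truths$parent_copy_ids[i],
          events = serialize_events(truths$events[[i]]))
      }
      if (prev_end < nchar(bg[[sc]])) {
        pieces <- c(pieces, substr(bg[[sc]], prev_end + 1, nchar(bg[[sc]])))
      }
      scafs[[sc]] <- paste(pieces, collapse = "")
    }
    genomes[[ind]] <- scafs
  }
  truth_table <- if (length(rows)) do.call(rbind, rows) else NULL
  files <- list()
  if (!is.null(out_dir)) {
    files <- write_simulation(genomes, truth_table, config, out_dir)
  }
  list(genomes = genomes, truth_table = truth_table, files = files)
}

serialize_events <- function(events) {
  if (!length(events)) return("")
  paste(vapply(events, function(e) {
    paste0(e$type, "(", paste(
      vapply(setdiff(names(e), "type"),
             function(k) paste0(k, "=", paste(e[[k]], collapse = "|")), ""),
      collapse = ";"), ")")
  }, ""), collapse = ",")
}

write_simulation <- function(genomes, truth_table, config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- list(fasta = character(0))
  for (ind in names(genomes)) {
    path <- file.path(out_dir, paste0(ind, ".fasta"))
    ss <- Biostrings::DNAStringSet(genomes[[ind]])
    Biostrings::writeXStringSet(ss, path, width = 80)
    files$fasta <- c(files$fasta, path)
  }
  if (!is.null(truth_table)) {
    files$truth_tsv <- file.path(out_dir, "truth.tsv")
    utils::write.table(truth_table, files$truth_tsv, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    files$truth_gff <- file.path(out_dir, "truth.gff3")
    write_truth_gff3(truth_table, files$truth_gff)
  }
  files$run_log <- file.path(out_dir, "run_log.json")
  jsonlite::write_json(list(seed = config$seed, tool = "ervmine",
                            n_individuals = length(genomes)),
                       files$run_log, auto_unbox = TRUE)
  files$config <- file.path(out_dir, "scenario.yaml")
  cfg <- unclass(config)
  cfg$tree$introgression <- NULL
  yaml::write_yaml(cfg, files$config)
  files
}

write_truth_gff3 <- function(truth_table, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (i in seq_len(nrow(truth_table))) {
    r <- truth_table[i, ]
    # GFF3 is 1-based inclusive
    writeLines(sprintf(
      "%s\tervmine_sim\tERV_copy\t%d\t%d\t.\t%s\t.\tID=%s;carrier=%s;class=%s;tsd=%s",
      r$scaffold, r$genome_start + 1, r$genome_end, r$strand,
      paste0(r$copy_id, "_", r$carrier), r$carrier, r$class_truth, r$tsd), con)
    writeLines(sprintf(
      "%s\tervmine_sim\tTSD\t%d\t%d\t.\t+\t.\tParent=%s_%s",
      r$scaffold, r$genome_start - 3, r$genome_start, r$copy_id, r$carrier), con)
    writeLines(sprintf(
      "%s\tervmine_sim\tTSD\t%d\t%d\t.\t+\t.\tParent=%s_%s",
      r$scaffold, r$genome_end + 1, r$genome_end + 4, r$copy_id, r$carrier), con)
  }
}

#' Run the full simulation: pedigree, endogenization, emission
#'
#' @param config a [sim_config()]
#' @param provirus_ref reference provirus; default [synthetic_provirus()]
#'   built from the same seed
#' @param out_dir optional output directory (see [emit_genomes()])
#' @return list with `tree`, `truth`, `genomes`, `truth_table`, `files`,
#'   `provirus_ref`
#' @export
simulate_genomes <- function(config, provirus_ref = NULL, out_dir = NULL) {
  if (is.null(provirus_ref)) provirus_ref <- synthetic_provirus(config$seed)
  tree <- build_host_pedigree(config)
  truth <- simulate_endogenization(tree, provirus_ref, config)
  em <- emit_genomes(truth, provirus_ref, config, out_dir = out_dir)
  list(tree = tree, truth = truth, genomes = em$genomes,
       truth_table = em$truth_table, files = em$files,
       provirus_ref = provirus_ref)
}
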