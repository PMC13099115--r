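#' Exact two-sided Fisher test for a 2x2 table
#'
#' Computed by direct hypergeometric enumeration with fixed margins: the
#' two-sided p-value is the sum of the probabilities of all tables whose
#' probability does not exceed that of the observed table (probability-mass
#' criterion, ties included with a small relative tolerance).
#'
#' @param table_2x2 2x2 matrix of non-negative integer counts
#' @return two-sided p-value
#' @export
fisher_exact <- function(table_2x2) {
  t <- as.matrix(table_2x2)
  if (!all(dim(t) == c(2, 2))) stop("need a 2x2 table")
  if (any(t < 0) || any(t != round(t))) {
    stop("counts must be non-negative integers")
  }
  m <- sum(t[1, ])      # row 1 total
  n <- sum(t[2, ])      # row 2 total
  k <- sum(t[, 1])      # column 1 total
  if (m + n == 0 || k == 0 || k == m + n) return(1)
  x_obs <- t[1, 1]
  lo <- max(0, k - n)
  hi <- min(k, m)
  xs <- lo:hi
  probs <- stats::dhyper(xs, m, n, k)
  p_obs <- stats::dhyper(x_obs, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

#' Bonferroni correction
#'
#' @param p_values numeric vector of p-values
#' @param family_size number of tests in the family (defaults to
#'   `length(p_values)`; must be at least that)
#' @return corrected p-values, capped at 1
#' @export
bonferroni <- function(p_values, family_size = length(p_values)) {
  if (family_size < length(p_values)) {
    stop("family_size must be >= number of tests")
  }
  pmin(1, p_values * family_size)
}

#' Match orthologous insertion loci across genomes
#'
#' Copies occupying the same locus in different genomes are identified by
#' global alignment of their flanking sequence (element excised): pairs at
#' `min_flank_identity` percent or better on both sides, over at least
#' `min_flank_len` bp per side, are joined by single-linkage into
#' `flank_match` groups. Copies sharing only their 4-mer signature are
#' reported as `signature_only` coincidences — convergent integration-site
#' 4-mers, never merged into locus groups.
#'
#' @param copies data.frame with `copy_uid`, `genome_id`, `flank_up`,
#'   `flank_down`, `signature` columns
#' @param flank_eval_len bp of flank (adjacent to the element) compared
#' @param min_flank_identity percent identity threshold (default 90)
#' @param min_flank_len minimum compared length per side (default 500)
#' @return list: `groups` (copy_uid, group_id, evidence),
#'   `signature_coincidences` (pairs in different groups sharing a 4-mer)
#' @export
match_orthologous_loci <- function(copies, flank_eval_len = 600,
                                   min_flank_identity = 90,
                                   min_flank_len = 500) {
  n <- nrow(copies)
  usable <- which(nchar(copies$flank_up) >= min_flank_len &
                    nchar(copies$flank_down) >= min_flank_len)
  up <- substr(copies$flank_up,
               pmax(1, nchar(copies$flank_up) - flank_eval_len + 1),
               nchar(copies$flank_up))
  down <- substr(copies$flank_down, 1, flank_eval_len)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  union_ <- function(i, j) parent[find(i)] <<- find(j)
  flank_pid <- function(a, b) {
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(a), Biostrings::DNAString(b), type = "global",
      substitutionMatrix = dna_submat(1, -2), gapOpening = 5,
      gapExtension = 2)
    100 * Biostrings::nmatch(pa) /
      nchar(as.character(Biostrings::alignedPattern(pa)))
  }
  if (length(usable) >= 2) {
    cmb <- utils::combn(usable, 2)
    for (c_i in seq_len(ncol(cmb))) {
      i <- cmb[1, c_i]; j <- cmb[2, c_i]
      if (copies$genome_id[i] == copies$genome_id[j]) next
      if (flank_pid(up[i], up[j]) >= min_flank_identity &&
          flank_pid(down[i], down[j]) >= min_flank_identity) {
        union_(i, j)
      }
    }
  }
  roots <- vapply(seq_len(n), find, 1L)
  group_id <- match(roots, unique(roots))
  groups <- data.frame(
    copy_uid = copies$copy_uid, genome_id = copies$genome_id,
    group_id = sprintf("og_%03d", group_id),
    evidence = ifelse(duplicated(roots) | duplicated(roots, fromLast = TRUE),
                      "flank_match", "singleton"))
  # signature-only coincidences: same 4-mer, different locus groups
  coinc <- list()
  sig <- copies$signature
  for (s in unique(sig[!is.na(sig) & sig != ""])) {
    idx <- which(sig == s)
    if (length(idx) < 2) next
    prs <- utils::combn(idx, 2)
    for (c_i in seq_len(ncol(prs))) {
      i <- prs[1, c_i]; j <- prs[2, c_i]
      if (group_id[i] != group_id[j]) {
        coinc[[length(coinc) + 1]] <- data.frame(
          signature = s, copy_a = copies$copy_uid[i],
          copy_b = copies$copy_uid[j])
      }
    }
  }
  list(groups = groups,
       signature_coincidences = if (length(coinc)) do.call(rbind, coinc)
                                else NULL)
}

#' Build class, gene, peptide and placement count tables
#'
#' @param copy_table per-copy annotation table (rows from
#'   [annotate_genome()], column `genome_id`, `class`, gene presence flags)
#' @param records copy records (for peptide presence)
#' @param nonrecombinant_ids copy ids (locus_id) retained after the
#'   recombination screen; `NULL` keeps all typical copies
#' @return list of matrices/data.frames: `classes` (class x genome),
#'   `genes` (gene x genome, nonrecombinant typical copies),
#'   `peptides` (peptide x genome), `placements` (per-scaffold counts)
#' @export
build_count_tables <- function(copy_table, records = NULL,
                               nonrecombinant_ids = NULL) {
  classes <- c("typical", "solo_ltr", "atypical", "paired_solo_ltr",
               "incomplete_segment")
  genomes <- sort(unique(copy_table$genome_id))
  class_tab <- t(vapply(classes, function(cl) {
    vapply(genomes, function(g) {
      sum(copy_table$class == cl & copy_table$genome_id == g)
    }, 1L)
  }, integer(length(genomes))))
  colnames(class_tab) <- genomes
  tt <- copy_table[copy_table$class == "typical", , drop = FALSE]
  if (!is.null(nonrecombinant_ids)) {
    tt <- tt[tt$locus_id %in% nonrecombinant_ids, , drop = FALSE]
  }
  gene_tab <- t(vapply(c("gag", "pol", "env"), function(g) {
    vapply(genomes, function(gn) {
      sum(tt[[g]] & tt$genome_id == gn)
    }, 1L)
  }, integer(length(genomes))))
  colnames(gene_tab) <- genomes
  pep_tab <- NULL
  if (!is.null(records)) {
    keep <- vapply(records, function(r) {
      r$class == "typical" &&
        (is.null(nonrecombinant_ids) || r$locus_id %in% nonrecombinant_ids)
    }, TRUE)
    recs <- records[keep]
    pep_names <- unique(unlist(lapply(recs, function(r) {
      r$annotations$name[r$annotations$type == "peptide"]
    })))
    if (length(pep_names)) {
      pep_tab <- t(vapply(pep_names, function(p) {
        vapply(genomes, function(gn) {
          sum(vapply(recs, function(r) {
            r$genome_id == gn && p %in% r$annotations$name
          }, TRUE))
        }, 1L)
      }, integer(length(genomes))))
      colnames(pep_tab) <- genomes
    }
  }
  placements <- stats::aggregate(
    list(n_copies = copy_table$locus_id),
    by = list(genome_id = copy_table$genome_id,
              scaffold = copy_table$scaffold %||%
                rep("scaffold_1", nrow(copy_table))),
    FUN = length)
  list(classes = class_tab, genes = gene_tab, peptides = pep_tab,
       placements = placements)
}

#' Fisher count comparisons across the three comparison families
#'
#' (a) per-genome-pair 2x2 tables of typical vs solo-LTR counts; (b)
#' per-gene-pair 2x2 tables of presence/absence over nonrecombinant typical
#' copies; (c) per-peptide-vs-rest tables within each polypeptide. Each
#' family is Bonferroni-corrected by the number of tests it actually runs.
#'
#' @param tables from [build_count_tables()]
#' @param n_typical named per-genome totals of (nonrecombinant) typical
#'   copies for the gene family denominators; defaults to the class table's
#'   typical row
#' @param peptide_parents named list mapping polypeptide name to its
#'   peptide row names in `tables$peptides`
#' @return data.frame of `FisherResult` rows: family, label, counts,
#'   `p_two_sided`, `p_bonferroni`, `family_size`
#' @export
run_count_comparisons <- function(tables, n_typical = NULL,
                                  peptide_parents = NULL) {
  res <- list()
  cls <- tables$classes
  genomes <- colnames(cls)
  if (length(genomes) >= 2) {
    prs <- utils::combn(genomes, 2)
    for (i in seq_len(ncol(prs))) {
      a <- prs[1, i]; b <- prs[2, i]
      t22 <- matrix(c(cls["typical", a], cls["solo_ltr", a],
                      cls["typical", b], cls["solo_ltr", b]), 2, 2)
      res[[length(res) + 1]] <- data.frame(
        family = "copy_load", label = paste(a, "vs", b),
        a = t22[1, 1], b = t22[2, 1], c = t22[1, 2], d = t22[2, 2],
        p_two_sided = fisher_exact(t22))
    }
  }
  gn <- tables$genes
  if (!is.null(gn) && ncol(gn) >= 1) {
    tot <- rowSums(gn)
    if (is.null(n_typical)) {
      n_all <- sum(tables$classes["typical", ])
    } else n_all <- sum(n_typical)
    gene_names <- rownames(gn)
    prs <- utils::combn(gene_names, 2)
    for (i in seq_len(ncol(prs))) {
      g1 <- prs[1, i]; g2 <- prs[2, i]
      t22 <- matrix(c(tot[g1], n_all - tot[g1],
                      tot[g2], n_all - tot[g2]), 2, 2)
      res[[length(res) + 1]] <- data.frame(
        family = "gene_presence", label = paste(g1, "vs", g2),
        a = t22[1, 1], b = t22[2, 1], c = t22[1, 2], d = t22[2, 2],
        p_two_sided = fisher_exact(t22))
    }
  }
  pep <- tables$peptides
  if (!is.null(pep)) {
    if (is.null(peptide_parents)) {
      peptide_parents <- list(
        gag = intersect(rownames(pep), c("matrix p15", "p12", "capsid",
                                         "nucleocapsid")),
        pol = intersect(rownames(pep), c("protease", "reverse transcriptase",
                                         "integrase")),
        env = intersect(rownames(pep), c("SU", "TM")))
    }
    for (poly in names(peptide_parents)) {
      peps <- peptide_parents[[poly]]
      if (length(peps) < 2) next
      tot <- rowSums(pep[peps, , drop = FALSE])
      for (p in peps) {
        rest <- round(mean(tot[setdiff(peps, p)]))
        n_max <- max(tot)
        t22 <- matrix(c(tot[p], max(0, n_max - tot[p]),
                        rest, max(0, n_max - rest)), 2, 2)
        res[[length(res) + 1]] <- data.frame(
          family = "peptide_presence", label = paste0(poly, ":", p),
          a = t22[1, 1], b = t22[2, 1], c = t22[1, 2], d = t22[2, 2],
          p_two_sided = fisher_exact(t22))
      }
    }
  }
  if (!length(res)) return(NULL)
  out <- do.call(rbind, res)
  out$family_size <- stats::ave(out$p_two_sided, out$family, FUN = length)
  out$p_bonferroni <- pmin(1, out$p_two_sided * out$family_size)
  rownames(out) <- NULL
  out
}
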