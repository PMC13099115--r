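dna_submat <- function(match = 2, mismatch = -3) {
  Biostrings::nucleotideSubstitutionMatrix(match = match, mismatch = mismatch,
                                           baseOnly = FALSE, type = "DNA")
}

# Global alignment of an element to the full reference provirus, projected
# onto reference coordinates. Insertions relative to the reference are
# dropped (and counted); deletions appear as "-" in the row. Long gaps are
# cheap (small gap-extension cost) so multi-kb internal deletions are
# bridged rather than truncated.
project_to_reference <- function(element_seq, ref_seq,
                                 gap_open = 10, gap_ext = 0.5) {
  pa <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAString(element_seq),
    subject = Biostrings::DNAString(ref_seq),
    type = "global", substitutionMatrix = dna_submat(1, -2),
    gapOpening = gap_open, gapExtension = gap_ext)
  pat <- seq_chars(as.character(Biostrings::alignedPattern(pa)))
  sub <- seq_chars(as.character(Biostrings::alignedSubject(pa)))
  keep <- sub != "-"
  row <- pat[keep]
  # element coordinate of each reference column (0 where gapped)
  elem_pos <- cumsum(pat != "-")[keep]
  elem_pos[row == "-"] <- 0L
  list(row = row, elem_pos = elem_pos, n_insertions = sum(!keep),
       ref_chars = seq_chars(ref_seq))
}

#' Locate reference-LTR matches within an element
#'
#' Finds all non-overlapping local alignments of the reference LTR in the
#' element at `min_identity` percent or better, by greedy best-score-first
#' selection (the best local hit is accepted, then the flanking segments
#' are searched recursively).
#'
#' @param element_seq element sequence, element orientation
#' @param reference_ltr reference LTR sequence
#' @param min_identity percent identity cutoff (default 70)
#' @param min_frac minimum aligned length as a fraction of the LTR
#' @return data.frame of intervals: `start`, `end` (1-based, inclusive),
#'   `identity`, sorted by `start`
#' @export
find_ltrs <- function(element_seq, reference_ltr, min_identity = 70,
                      min_frac = 0.5) {
  min_len <- ceiling(min_frac * nchar(reference_ltr))
  res <- find_ltrs_rec(element_seq, reference_ltr, min_identity, min_len,
                       offset = 0L, depth = 0L)
  if (!length(res)) {
    return(data.frame(start = integer(0), end = integer(0),
                      identity = numeric(0)))
  }
  df <- do.call(rbind, res)
  df[order(df$start), , drop = FALSE]
}

find_ltrs_rec <- function(seg, ltr, min_identity, min_len, offset, depth) {
  if (depth > 6 || nchar(seg) < min_len) return(list())
  pa <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAString(ltr), subject = Biostrings::DNAString(seg),
    type = "local", substitutionMatrix = dna_submat(2, -3),
    gapOpening = 5, gapExtension = 2)
  s <- Biostrings::subject(pa)
  s_start <- Biostrings::start(s)
  s_end <- Biostrings::end(s)
  aln_len <- nchar(as.character(Biostrings::alignedSubject(pa)))
  matches <- Biostrings::nmatch(pa)
  identity <- 100 * matches / aln_len
  if (aln_len < min_len || identity < min_identity) return(list())
  hit <- data.frame(start = offset + s_start, end = offset + s_end,
                    identity = identity)
  left <- if (s_start > 1) {
    find_ltrs_rec(substr(seg, 1, s_start - 1), ltr, min_identity, min_len,
                  offset, depth + 1)
  } else list()
  right <- if (s_end < nchar(seg)) {
    find_ltrs_rec(substr(seg, s_end + 1, nchar(seg)), ltr, min_identity,
                  min_len, offset + s_end, depth + 1)
  } else list()
  c(list(hit), left, right)
}

#' Pair the outermost compatible LTR intervals
#'
#' Selects the outermost pair of LTR intervals whose internal span lies
#' within the configured bounds; intervals between the pair are flagged as
#' internal (LTR-like) segments.
#'
#' @param intervals data.frame from [find_ltrs()]
#' @param element_len element length
#' @param internal_bounds allowed bp between the paired LTRs
#' @return list with `ltr5`, `ltr3` (start/end vectors),
#'   `internal_length`, `internal_intervals` — or `NULL` if no compatible
#'   pair exists
#' @export
pair_ltrs <- function(intervals, element_len,
                      internal_bounds = c(2000, 12000)) {
  n <- nrow(intervals)
  if (n < 2) return(NULL)
  best <- NULL
  for (i in seq_len(n - 1)) {
    for (j in seq((i + 1), n)) {
      internal <- intervals$start[j] - intervals$end[i] - 1
      if (internal >= internal_bounds[1] && internal <= internal_bounds[2]) {
        span <- intervals$end[j] - intervals$start[i]
        if (is.null(best) || span > best$span) {
          best <- list(i = i, j = j, span = span, internal = internal)
        }
      }
    }
  }
  if (is.null(best)) return(NULL)
  list(ltr5 = intervals[best$i, ], ltr3 = intervals[best$j, ],
       internal_length = best$internal,
       internal_intervals = intervals[setdiff(seq_len(n),
                                              c(best$i, best$j)), ,
                                      drop = FALSE])
}

#' Extract the 4-nt target-site signature from locus flanks
#'
#' The genomic signature of retroviral integration: the 4 nt immediately
#' upstream and downstream of the element. Flanks shorter than 4 nt are
#' N-padded and never match.
#'
#' @param flank_up upstream flank (sequence ending at the element start)
#' @param flank_down downstream flank (sequence starting at the element end)
#' @return list: `upstream_4mer`, `downstream_4mer`, `is_matching`
#' @export
extract_signature <- function(flank_up, flank_down) {
  pad <- function(x, side) {
    if (nchar(x) >= 4) return(x)
    miss <- strrep("N", 4 - nchar(x))
    if (side == "up") paste0(miss, x) else paste0(x, miss)
  }
  up <- pad(substr(flank_up, max(1, nchar(flank_up) - 3), nchar(flank_up)),
            "up")
  down <- pad(substr(flank_down, 1, min(4, nchar(flank_down))), "down")
  matching <- !grepl("N", up) && !grepl("N", down) && up == down
  list(upstream_4mer = up, downstream_4mer = down, is_matching = matching)
}

#' Annotate genes and peptides on an element
#'
#' Projects the element onto the reference provirus by global alignment and
#' scores every reference feature: identity is identical columns divided by
#' the reference feature length, so whole-gene deletions score near zero.
#' Features at `gene_cutoff` percent or better are emitted; a gene whose
#' own identity falls below the cutoff is still emitted (flagged
#' `rescued`) when any of its peptides passes. Annotations are trimmed to
#' the aligned high-identity segment (terminal columns dropped until a
#' 20-column window reaches 50 percent identity).
#'
#' @param element_seq element sequence, element orientation
#' @param provirus_ref a `provirus_reference` with a feature table
#' @param gene_cutoff percent identity cutoff (default 25)
#' @param peptide_rescue enable gene rescue through passing peptides
#' @return data.frame of annotations (attribute `"projection"` carries the
#'   element-to-reference projection for reuse)
#' @export
annotate_genes <- function(element_seq, provirus_ref, gene_cutoff = 25,
                           peptide_rescue = TRUE) {
  feats <- provirus_ref$features[provirus_ref$features$type %in%
                                   c("gene", "peptide"), , drop = FALSE]
  if (nrow(feats) == 0) stop("reference carries no gene/peptide features")
  proj <- project_to_reference(element_seq, provirus_ref$seq)
  rows <- list()
  for (i in seq_len(nrow(feats))) {
    f <- feats[i, ]
    cols <- f$start:f$end
    seg <- proj$row[cols]
    match_vec <- seg == proj$ref_chars[cols] & seg != "-"
    flen <- length(cols)
    identity <- 100 * sum(match_vec) / flen
    trim <- trim_to_identity(match_vec, seg)
    largest_del <- max_gap_run(seg)
    el_start <- el_end <- NA_integer_
    if (!is.na(trim[1])) {
      nz <- proj$elem_pos[cols][trim[1]:trim[2]]
      nz <- nz[nz > 0]
      if (length(nz)) { el_start <- min(nz); el_end <- max(nz) }
    }
    rows[[i]] <- data.frame(
      name = f$name, type = f$type, parent = f$parent,
      identity = identity, start = el_start, end = el_end,
      ref_start = f$start, ref_end = f$end,
      largest_deletion = largest_del, rescued = FALSE)
  }
  ann <- do.call(rbind, rows)
  pass <- ann$identity >= gene_cutoff & !is.na(ann$start)
  if (peptide_rescue) {
    for (g in ann$name[ann$type == "gene"]) {
      gi <- which(ann$name == g)
      if (!pass[gi]) {
        peps <- which(ann$type == "peptide" & ann$parent == g)
        if (any(pass[peps])) {
          pass[gi] <- TRUE
          ann$rescued[gi] <- TRUE
        }
      }
    }
  }
  out <- ann[pass, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "projection") <- proj
  out
}

# Trim rule: drop terminal columns until a 20-column sliding window reaches
# >= 50% identity; returns c(first, last) indices within the feature, or NA.
trim_to_identity <- function(match_vec, seg, win = 20, min_id = 0.5) {
  n <- length(match_vec)
  nongap <- which(seg != "-")
  if (!length(nongap)) return(c(NA_integer_, NA_integer_))
  if (n < win) {
    return(c(nongap[1], nongap[length(nongap)]))
  }
  cs <- cumsum(c(0, match_vec))
  wmean <- (cs[(win + 1):(n + 1)] - cs[1:(n - win + 1)]) / win
  ok <- which(wmean >= min_id)
  if (!length(ok)) return(c(NA_integer_, NA_integer_))
  first <- max(ok[1], nongap[1])
  last <- min(ok[length(ok)] + win - 1, nongap[length(nongap)])
  if (first > last) return(c(NA_integer_, NA_integer_))
  c(first, last)
}

max_gap_run <- function(seg) {
  r <- rle(seg == "-")
  if (!any(r$values)) return(0L)
  max(r$lengths[r$values])
}

#' Scan reading frames of annotated genes
#'
#' Translates each annotated gene from the projected element sequence in
#' the reference frame; `intact_orf` is true iff no in-frame stop occurs
#' before the feature's end. The copy-level `fully_open_orf` is true iff
#' every annotated gene is intact. Deletions larger than 1000 nt are
#' flagged (`truncation_flag`) even when the residual frame stays open.
#'
#' @param element_seq element sequence
#' @param annotations from [annotate_genes()] (its projection attribute is
#'   reused when present)
#' @param provirus_ref the reference used for annotation
#' @return list: `annotations` (with `intact_orf` and `truncation_flag`
#'   columns on gene rows) and `fully_open_orf`
#' @export
scan_orfs <- function(element_seq, annotations, provirus_ref) {
  proj <- attr(annotations, "projection")
  if (is.null(proj)) {
    proj <- project_to_reference(element_seq, provirus_ref$seq)
  }
  ann <- annotations
  if (nrow(ann) == 0) {
    ann$intact_orf <- logical(0)
    ann$truncation_flag <- logical(0)
    return(list(annotations = ann, fully_open_orf = FALSE))
  }
  ann$intact_orf <- NA
  ann$truncation_flag <- ann$largest_deletion > 1000
  genes <- which(ann$type == "gene")
  for (i in genes) {
    cols <- ann$ref_start[i]:ann$ref_end[i]
    seg <- proj$row[cols]
    nt <- seg[seg != "-"]
    n_cod <- length(nt) %/% 3
    if (n_cod < 2) { ann$intact_orf[i] <- FALSE; next }
    codons <- apply(matrix(nt[1:(n_cod * 3)], nrow = 3), 2, paste,
                    collapse = "")
    internal_stops <- codons[-n_cod] %in% c("TAA", "TAG", "TGA")
    ann$intact_orf[i] <- !any(internal_stops)
  }
  fully_open <- length(genes) > 0 && all(ann$intact_orf[genes])
  list(annotations = ann, fully_open_orf = fully_open)
}

#' Classify a copy into the five-class structural taxonomy
#'
#' Decision order: (1) element clipped at a scaffold end →
#' `incomplete_segment`; (2) a single LTR and no gene annotation →
#' `solo_ltr`; (3) two or more LTR intervals separated by less than
#' `paired_gap` bp with no gene annotation → `paired_solo_ltr`; (4) an LTR
#' pair with internal gene annotations in reference order (deletions
#' allowed) → `typical`; (5) anything else (duplicated genes, internal
#' LTR-like segments, disordered architecture) → `atypical`.
#'
#' @param ltr_intervals data.frame from [find_ltrs()]
#' @param ltr_pair from [pair_ltrs()] (may be `NULL`)
#' @param gene_annotations gene rows of [annotate_genes()] output
#' @param element_clipped is the element clipped at a scaffold end?
#' @param paired_gap gap threshold for paired solo LTRs (default 200)
#' @return one of `"typical"`, `"solo_ltr"`, `"atypical"`,
#'   `"paired_solo_ltr"`, `"incomplete_segment"`
#' @export
classify <- function(ltr_intervals, ltr_pair, gene_annotations,
                     element_clipped = FALSE, paired_gap = 200) {
  n_ltr <- nrow(ltr_intervals)
  n_gene <- if (is.null(gene_annotations)) 0 else nrow(gene_annotations)
  if (element_clipped) return("incomplete_segment")
  if (n_ltr == 1 && n_gene == 0) return("solo_ltr")
  if (n_ltr >= 2 && n_gene == 0) {
    gaps <- ltr_intervals$start[-1] - ltr_intervals$end[-n_ltr] - 1
    if (all(gaps < paired_gap)) return("paired_solo_ltr")
  }
  if (!is.null(ltr_pair) && n_ltr == 2 && n_gene > 0) {
    ord <- gene_annotations$name[order(gene_annotations$start)]
    expected <- c("gag", "pol", "env")
    if (identical(ord, expected[expected %in% ord])) return("typical")
  }
  "atypical"
}

#' Annotate and classify one mined locus
#'
#' Runs LTR detection, LTR pairing, signature extraction, gene/peptide
#' annotation, ORF scanning and classification on one row of a mined locus
#' table (with flanks attached, as produced by [mine_genome()]).
#'
#' @param locus one locus row (list or 1-row data.frame) with
#'   `element_seq`, `flank_up`, `flank_down`, `start`, `end`, `strand`,
#'   `scaffold`
#' @param provirus_ref a `provirus_reference`
#' @param scaffold_len length of the locus's scaffold (for end-clipping
#'   detection); `NA` disables the check on the downstream side
#' @param opts list of thresholds: `ltr_min_identity` (70), `gene_cutoff`
#'   (25), `paired_gap` (200), `internal_bounds` (c(2000, 12000)),
#'   `boundary_tol` (50)
#' @return a list (`copy_record`): class, signature, LTR pair sequences,
#'   annotations, ORF flags
#' @export
annotate_copy <- function(locus, provirus_ref, scaffold_len = NA,
                          opts = list()) {
  o <- utils::modifyList(list(ltr_min_identity = 70, gene_cutoff = 25,
                              paired_gap = 200,
                              internal_bounds = c(2000, 12000),
                              boundary_tol = 50), opts)
  elem <- locus$element_seq
  ref_ltr <- reference_feature_seq(provirus_ref, "LTR")
  ltrs <- find_ltrs(elem, ref_ltr, o$ltr_min_identity)
  pair <- pair_ltrs(ltrs, nchar(elem), o$internal_bounds)
  sig <- extract_signature(locus$flank_up, locus$flank_down)
  ann <- annotate_genes(elem, provirus_ref, o$gene_cutoff)
  orf <- scan_orfs(elem, ann, provirus_ref)
  genes <- orf$annotations[orf$annotations$type == "gene", , drop = FALSE]
  clipped <- isTRUE(locus$start <= o$boundary_tol) ||
    (!is.na(scaffold_len) && locus$end >= scaffold_len - o$boundary_tol)
  cls <- classify(ltrs, pair, genes, element_clipped = clipped,
                  paired_gap = o$paired_gap)
  ltr5_seq <- ltr3_seq <- NA_character_
  if (!is.null(pair)) {
    ltr5_seq <- substr(elem, pair$ltr5$start, pair$ltr5$end)
    ltr3_seq <- substr(elem, pair$ltr3$start, pair$ltr3$end)
  }
  list(locus_id = locus$locus_id %||% NA_character_,
       genome_id = locus$genome_id %||% NA_character_,
       class = cls, signature = sig, ltr_intervals = ltrs, ltr_pair = pair,
       ltr5_seq = ltr5_seq, ltr3_seq = ltr3_seq,
       annotations = orf$annotations, fully_open_orf = orf$fully_open_orf)
}

#' Annotate every locus mined from a genome
#'
#' @param mined output of [mine_genome()]
#' @param provirus_ref a `provirus_reference`
#' @param scaffold_lengths named lengths of the genome's scaffolds
#' @param opts see [annotate_copy()]
#' @return list with `records` (list of copy records) and `copy_table`
#'   (one summary row per copy)
#' @export
annotate_genome <- function(mined, provirus_ref, scaffold_lengths = NULL,
                            opts = list()) {
  loci <- mined$loci
  records <- lapply(seq_len(nrow(loci)), function(i) {
    sl <- if (!is.null(scaffold_lengths)) {
      scaffold_lengths[[loci$scaffold[i]]]
    } else NA
    annotate_copy(loci[i, ], provirus_ref, scaffold_len = sl, opts = opts)
  })
  copy_table <- do.call(rbind, lapply(records, function(r) {
    genes <- r$annotations[r$annotations$type == "gene", , drop = FALSE]
    data.frame(
      locus_id = r$locus_id, genome_id = r$genome_id, class = r$class,
      signature_up = r$signature$upstream_4mer,
      signature_down = r$signature$downstream_4mer,
      signature_matching = r$signature$is_matching,
      n_ltr = nrow(r$ltr_intervals),
      has_ltr_pair = !is.null(r$ltr_pair),
      gag = "gag" %in% genes$name, pol = "pol" %in% genes$name,
      env = "env" %in% genes$name,
      fully_open_orf = r$fully_open_orf,
      largest_deletion = if (nrow(genes)) max(genes$largest_deletion) else 0L)
  }))
  list(records = records, copy_table = copy_table)
}

#' Write the per-copy annotation table as TSV
#' @param copy_table from [annotate_genome()]
#' @param path output path
#' @return the path, invisibly
#' @export
write_copy_table <- function(copy_table, path) {
  utils::write.table(copy_table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
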