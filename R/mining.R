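#' Default mining parameters
#'
#' BLASTn-like scoring for the native seed-and-extend search: match +1,
#' mismatch -2, gap open -5, gap extend -2, X-drop 20, diagonal band 50,
#' k = 11. Identity/coverage thresholds default to 50/50 as in the two
#' screening modes (host-range: identity; locus mining: query coverage).
#'
#' @param k seed k-mer length
#' @param match,mismatch,gap_open,gap_extend alignment scores
#' @param xdrop ungapped extension drop-off
#' @param band maximum diagonal drift bridged when chaining HSPs
#' @param chain_gap maximum gap (bp) bridged when chaining HSPs
#' @param min_score minimum HSP score reported
#' @param identity_threshold percent identity cutoff (host-range mode)
#' @param coverage_threshold percent query-coverage cutoff (locus mode)
#' @param max_gap merge distance for combining hits into loci
#' @param flank_len flanking bp extracted around each locus
#' @return list of parameters
#' @export
mining_params <- function(k = 11, match = 1, mismatch = -2, gap_open = -5,
                          gap_extend = -2, xdrop = 20, band = 50,
                          chain_gap = 200, min_score = 25,
                          identity_threshold = 50, coverage_threshold = 50,
                          max_gap = 2000, flank_len = 16000) {
  as.list(environment())
}

#' Build an exact-match k-mer index of a genome
#'
#' Indexes every k-mer on the forward strand of every scaffold
#' (N-containing windows skipped). Queries are later searched as given and
#' reverse-complemented, so forward-only indexing covers both strands.
#'
#' @param genome named character vector of scaffold sequences, or a
#'   `DNAStringSet`
#' @param k k-mer length (8--15)
#' @return a `kmer_index` (external pointer plus metadata)
#' @export
index_genome <- function(genome, k = 11) {
  if (methods::is(genome, "DNAStringSet")) {
    genome <- stats::setNames(as.character(genome), names(genome))
  }
  if (length(genome) == 0 || all(nchar(genome) == 0)) stop("empty genome")
  if (is.null(names(genome))) {
    names(genome) <- paste0("scaffold_", seq_along(genome))
  }
  ptr <- cpp_index_genome(unname(genome), names(genome), as.integer(k))
  structure(list(ptr = ptr, k = k, scaffold_names = names(genome),
                 scaffold_lengths = stats::setNames(nchar(genome),
                                                    names(genome)),
                 genome = genome),
            class = "kmer_index")
}

#' @export
print.kmer_index <- function(x, ...) {
  cat(sprintf("kmer_index: k=%d, %d scaffolds, %.0f indexed positions\n",
              x$k, length(x$scaffold_names), cpp_index_size(x$ptr)))
  invisible(x)
}

#' Number of indexed k-mer positions
#' @param index a `kmer_index`
#' @return count of indexed (non-N) k-mer start positions
#' @export
n_indexed_positions <- function(index) cpp_index_size(index$ptr)

#' Seed-and-extend search of a query against an indexed genome
#'
#' Exact k-mer seeds are extended ungapped with an X-drop rule, then
#' colinear HSPs with bounded diagonal drift are chained. Both strands are
#' searched; coordinates are 0-based half-open on the forward subject
#' strand, query coordinates on the forward query.
#'
#' @param query character scalar (the query sequence)
#' @param genome_index a `kmer_index`
#' @param params from [mining_params()]
#' @param query_id label recorded in the hit table
#' @return data.frame of HSPs with `identity` (percent matching columns)
#'   and `query_coverage` (percent of query aligned)
#' @export
search_genome <- function(query, genome_index, params = mining_params(),
                   query_id = "query") {
  stopifnot(inherits(genome_index, "kmer_index"))
  if (nchar(query) < genome_index$k) stop("query shorter than k")
  df <- cpp_search(genome_index$ptr, query, params$match, params$mismatch,
                   params$xdrop, params$band, params$chain_gap,
                   abs(params$gap_open), abs(params$gap_extend),
                   params$min_score)
  if (nrow(df) == 0) {
    df$identity <- numeric(0); df$query_coverage <- numeric(0)
    df$query_id <- character(0)
    return(df)
  }
  aln_len <- pmax(df$q_end - df$q_start, df$s_end - df$s_start)
  df$identity <- 100 * df$matches / aln_len
  df$query_coverage <- 100 * (df$q_end - df$q_start) / nchar(query)
  df$query_id <- query_id
  df[order(-df$score), ]
}

#' Filter HSPs by screening mode
#'
#' `host_range` retains hits at `identity >= threshold` (default 50
#' percent); `locus_mining` retains hits at `query_coverage >= threshold`
#' (default 50 percent).
#'
#' @param hsps data.frame from [search()]
#' @param mode `"host_range"` or `"locus_mining"`
#' @param threshold percent cutoff; defaults to the mode's 50
#' @return filtered data.frame
#' @export
filter_hits <- function(hsps, mode = c("locus_mining", "host_range"),
                        threshold = 50) {
  mode <- match.arg(mode)
  if (nrow(hsps) == 0) return(hsps)
  keep <- if (mode == "host_range") hsps$identity >= threshold
          else hsps$query_coverage >= threshold
  hsps[keep, , drop = FALSE]
}

#' Merge HSPs from all queries into non-overlapping loci
#'
#' HSPs whose subject intervals overlap or lie within `max_gap` bp of each
#' other on the same scaffold are merged into one locus; locus strand is
#' decided by the score-weighted majority of supporting HSPs.
#'
#' @param hsps data.frame of (filtered) HSPs from one genome, any queries
#' @param max_gap merge distance in bp
#' @param genome_id label
#' @return data.frame of loci: `locus_id`, `scaffold`, `start`, `end`
#'   (0-based half-open), `strand`, `n_hsps`, `queries`
#' @export
merge_to_loci <- function(hsps, max_gap = 2000, genome_id = "genome") {
  if (nrow(hsps) == 0) {
    return(data.frame(locus_id = character(0), genome_id = character(0),
                      scaffold = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      n_hsps = integer(0), queries = character(0)))
  }
  out <- list()
  for (sc in unique(hsps$subject_scaffold)) {
    h <- hsps[hsps$subject_scaffold == sc, , drop = FALSE]
    ir <- IRanges::IRanges(start = h$s_start + 1, end = h$s_end)
    red <- IRanges::reduce(ir, min.gapwidth = max_gap + 1)
    ov <- IRanges::findOverlaps(ir, red)
    for (j in seq_along(red)) {
      members <- S4Vectors::queryHits(ov)[S4Vectors::subjectHits(ov) == j]
      hm <- h[members, , drop = FALSE]
      strand_score <- tapply(hm$score, hm$strand, sum)
      out[[length(out) + 1]] <- data.frame(
        genome_id = genome_id, scaffold = sc,
        start = IRanges::start(red)[j] - 1L, end = IRanges::end(red)[j],
        strand = names(strand_score)[which.max(strand_score)],
        n_hsps = nrow(hm),
        queries = paste(sort(unique(hm$query_id)), collapse = ","))
    }
  }
  loci <- do.call(rbind, out)
  loci <- loci[order(loci$scaffold, loci$start), , drop = FALSE]
  loci$locus_id <- sprintf("%s_locus_%03d", genome_id, seq_len(nrow(loci)))
  rownames(loci) <- NULL
  loci[, c("locus_id", "genome_id", "scaffold", "start", "end", "strand",
           "n_hsps", "queries")]
}

#' Extract a locus with flanking sequence
#'
#' Returns the locus sequence together with up to `flank_len` bp of
#' flanking sequence per side, clipped at scaffold boundaries
#' (`truncated_*` flags mark clipping). The element sequence is
#' reverse-complemented to element orientation for minus-strand loci;
#' flanks are reported in forward genomic orientation.
#'
#' @param locus one row of the locus table from [merge_to_loci()]
#' @param genome named character vector of scaffolds
#' @param flank_len requested flank length (bp)
#' @return list: `element_seq` (element orientation), `flank_up`,
#'   `flank_down` (genomic orientation), `flank_up_len`, `flank_down_len`,
#'   `truncated_up`, `truncated_down`, `ext_start`, `ext_end`
#' @export
extract_with_flanks <- function(locus, genome, flank_len = 16000) {
  if (flank_len < 0) stop("flank_len must be >= 0")
  sc <- genome[[locus$scaffold]]
  if (is.null(sc) || locus$start < 0 || locus$end > nchar(sc)) {
    stop("locus outside scaffold")
  }
  up_start <- max(0, locus$start - flank_len)
  down_end <- min(nchar(sc), locus$end + flank_len)
  flank_up <- substr(sc, up_start + 1, locus$start)
  flank_down <- substr(sc, locus$end + 1, down_end)
  elem <- substr(sc, locus$start + 1, locus$end)
  if (locus$strand == "-") elem <- revcomp(elem)
  list(element_seq = elem, flank_up = flank_up, flank_down = flank_down,
       flank_up_len = nchar(flank_up), flank_down_len = nchar(flank_down),
       truncated_up = up_start == 0 && locus$start < flank_len,
       truncated_down = down_end == nchar(sc) &&
         nchar(sc) - locus$end < flank_len,
       ext_start = up_start, ext_end = down_end)
}

#' Mine all ERV loci in one genome with multiple queries
#'
#' Runs [search()] with every query (typically LTR, *gag*, *pol*, *env* and
#' the complete provirus), filters HSPs on per-query coverage
#' (locus-mining mode), merges them into loci and extracts flanks.
#'
#' @param genome named character vector of scaffolds (or `DNAStringSet`)
#' @param provirus_ref a `provirus_reference`; queries are derived from its
#'   feature table
#' @param params from [mining_params()]
#' @param genome_id label
#' @return list with `loci` (data.frame, one row per locus, flank columns
#'   included) and `hits` (the filtered HSP table)
#' @export
mine_genome <- function(genome, provirus_ref, params = mining_params(),
                        genome_id = "genome") {
  if (methods::is(genome, "DNAStringSet")) {
    genome <- stats::setNames(as.character(genome), names(genome))
  }
  index <- index_genome(genome, params$k)
  queries <- c(
    LTR = reference_feature_seq(provirus_ref, "LTR"),
    gag = reference_feature_seq(provirus_ref, "gag"),
    pol = reference_feature_seq(provirus_ref, "pol"),
    env = reference_feature_seq(provirus_ref, "env"),
    full = provirus_ref$seq)
  hits <- do.call(rbind, lapply(names(queries), function(qn) {
    h <- search_genome(queries[[qn]], index, params, query_id = qn)
    filter_hits(h, "locus_mining", params$coverage_threshold)
  }))
  loci <- merge_to_loci(hits, params$max_gap, genome_id)
  if (nrow(loci) > 0) {
    fl <- lapply(seq_len(nrow(loci)), function(i) {
      extract_with_flanks(loci[i, ], genome, params$flank_len)
    })
    for (col in c("element_seq", "flank_up", "flank_down")) {
      loci[[col]] <- vapply(fl, function(x) x[[col]], "")
    }
    for (col in c("flank_up_len", "flank_down_len")) {
      loci[[col]] <- vapply(fl, function(x) as.integer(x[[col]]), 1L)
    }
    for (col in c("truncated_up", "truncated_down")) {
      loci[[col]] <- vapply(fl, function(x) x[[col]], TRUE)
    }
  }
  list(loci = loci, hits = hits)
}

#' Write a tabular hit table (BLAST outfmt-6-like plus coverage)
#' @param hits HSP data.frame from [search()]
#' @param path output TSV path
#' @return the path, invisibly
#' @export
write_hit_table <- function(hits, path) {
  cols <- c("query_id", "subject_scaffold", "identity", "matches",
            "q_start", "q_end", "s_start", "s_end", "strand", "score",
            "query_coverage")
  utils::write.table(hits[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write loci as BED (0-based half-open)
#' @param loci locus table from [merge_to_loci()]
#' @param path output BED path
#' @return the path, invisibly
#' @export
write_locus_bed <- function(loci, path) {
  bed <- data.frame(loci$scaffold, loci$start, loci$end, loci$locus_id,
                    0L, loci$strand)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
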