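#' Global alignment of an LTR pair
#'
#' Needleman-Wunsch global alignment with affine gap penalties,
#' deterministic given the inputs.
#'
#' @param ltr5_seq,ltr3_seq the two LTR sequences
#' @param match,mismatch,gap_open,gap_ext alignment scores (penalties
#'   positive)
#' @return list of aligned character vectors `a`, `b` (equal length)
#' @export
align_ltr_pair <- function(ltr5_seq, ltr3_seq, match = 1, mismatch = -2,
                           gap_open = 5, gap_ext = 2) {
  if (!nchar(ltr5_seq) || !nchar(ltr3_seq)) stop("empty LTR sequence")
  pa <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAString(ltr5_seq),
    subject = Biostrings::DNAString(ltr3_seq),
    type = "global", substitutionMatrix = dna_submat(match, mismatch),
    gapOpening = gap_open, gapExtension = gap_ext)
  list(a = seq_chars(as.character(Biostrings::alignedPattern(pa))),
       b = seq_chars(as.character(Biostrings::alignedSubject(pa))))
}

is_transition <- function(x, y) {
  (x == "A" & y == "G") | (x == "G" & y == "A") |
    (x == "C" & y == "T") | (x == "T" & y == "C")
}

#' Kimura two-parameter distance from a pairwise alignment
#'
#' P and Q are the transition and transversion proportions over comparable
#' (non-gap, non-N) columns;
#' K = 0.5 ln(1 / (1 - 2P - Q)) + 0.25 ln(1 / (1 - 2Q)).
#' When `1 - 2P - Q <= 0` or `1 - 2Q <= 0` the estimator is undefined and
#' the result is flagged `saturated`.
#'
#' @param alignment list with aligned character vectors `a` and `b` (as
#'   from [align_ltr_pair()]), or two aligned strings via `b`
#' @param b optional second aligned string when `alignment` is a string
#' @return list: `K`, `P`, `Q`, `n_sites`, `saturated`
#' @export
k2p_distance <- function(alignment, b = NULL) {
  if (is.character(alignment)) {
    alignment <- list(a = seq_chars(alignment), b = seq_chars(b))
  }
  x <- alignment$a
  y <- alignment$b
  ok <- x %in% BASES & y %in% BASES
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n == 0) stop("no comparable (non-gap, non-N) columns")
  diff <- x != y
  P <- sum(diff & is_transition(x, y)) / n
  Q <- sum(diff & !is_transition(x, y)) / n
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0) {
    return(list(K = NA_real_, P = P, Q = Q, n_sites = n, saturated = TRUE))
  }
  K <- 0.5 * log(1 / w1) + 0.25 * log(1 / w2)
  list(K = K, P = P, Q = Q, n_sites = n, saturated = FALSE)
}

#' Date an insertion from LTR-pair divergence
#'
#' Applies the LTR molecular clock `T = K / (2 r)`: each LTR of a pair,
#' identical at integration, accumulates substitutions independently, so
#' their distance K corresponds to twice the insertion age times the rate.
#' The rate interval gives age bounds (a larger rate implies a younger
#' bound). `K = 0` is reported as `identical_ltrs` — an age lower bound of
#' zero, not a precise date.
#'
#' @param K nucleotide distance between the LTRs (substitutions/site)
#' @param r substitution rate, substitutions/site/year (default 2.3e-9)
#' @param r_interval plausible rate range (default 2.0e-9 to 2.5e-9)
#' @param saturated was the distance estimator saturated?
#' @return list: `K`, `T_years`, `T_low`, `T_high`, `identical_ltrs`,
#'   `saturated`
#' @export
date_insertion <- function(K, r = 2.3e-9, r_interval = c(2.0e-9, 2.5e-9),
                           saturated = FALSE) {
  if (isTRUE(saturated) || is.na(K)) {
    return(list(K = NA_real_, T_years = NA_real_, T_low = NA_real_,
                T_high = NA_real_, identical_ltrs = FALSE, saturated = TRUE))
  }
  if (K < 0) stop("K must be >= 0")
  if (r <= 0) stop("r must be > 0")
  list(K = K, T_years = K / (2 * r),
       T_low = K / (2 * max(r_interval)),
       T_high = K / (2 * min(r_interval)),
       identical_ltrs = K == 0, saturated = FALSE)
}

#' Date all typical copies of an annotated genome
#'
#' @param records copy records from [annotate_genome()]
#' @param r,r_interval see [date_insertion()]
#' @return data.frame: one row per copy with an LTR pair (`K`, `P`, `Q`,
#'   `n_sites`, `T_years`, `T_low`, `T_high`, flags)
#' @export
date_copies <- function(records, r = 2.3e-9,
                        r_interval = c(2.0e-9, 2.5e-9)) {
  rows <- lapply(records, function(rec) {
    if (is.na(rec$ltr5_seq) || is.na(rec$ltr3_seq)) return(NULL)
    aln <- align_ltr_pair(rec$ltr5_seq, rec$ltr3_seq)
    kk <- k2p_distance(aln)
    dt <- date_insertion(kk$K, r, r_interval, kk$saturated)
    data.frame(locus_id = rec$locus_id, genome_id = rec$genome_id,
               class = rec$class, K = kk$K, P = kk$P, Q = kk$Q,
               n_sites = kk$n_sites, T_years = dt$T_years,
               T_low = dt$T_low, T_high = dt$T_high,
               identical_ltrs = isTRUE(dt$identical_ltrs),
               saturated = kk$saturated)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows)) return(NULL)
  do.call(rbind, rows)
}
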