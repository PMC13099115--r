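as_aln_matrix <- function(seqs) {
  if (is.matrix(seqs)) return(seqs)
  if (length(unique(nchar(seqs))) != 1) {
    stop("sequences must be aligned (equal length)")
  }
  do.call(rbind, strsplit(toupper(seqs), "", fixed = TRUE))
}

#' Variable alignment columns among a set of sequences
#'
#' Columns where the considered sequences differ; columns containing a gap
#' or N in any sequence are excluded.
#'
#' @param seqs character vector of aligned sequences (or char matrix)
#' @return integer vector of column indices
#' @export
variable_sites <- function(seqs) {
  m <- as_aln_matrix(seqs)
  ok <- apply(m, 2, function(col) all(col %in% BASES))
  varying <- apply(m, 2, function(col) length(unique(col)) > 1)
  which(ok & varying)
}

# max chi-square over breakpoints for a binary match vector, windows of w
# variable sites each side; returns c(stat, index_of_breakpoint)
maxchi_stat <- function(eq, w) {
  m <- length(eq)
  if (m < 2 * w) return(c(NA_real_, NA_real_))
  cs <- cumsum(eq)
  b <- w:(m - w)
  a <- cs[b] - c(0, cs)[b - w + 1]
  cc <- cs[b + w] - cs[b]
  N <- 2 * w
  num <- N * (a * (w - cc) - (w - a) * cc)^2
  den <- w * w * (a + cc) * (N - a - cc)
  chi <- ifelse(den > 0, num / den, 0)
  i <- which.max(chi)
  c(chi[i], b[i])
}

#' MaxChi recombination scan of an aligned triplet
#'
#' For each sequence pair, slides a putative breakpoint along the
#' triplet's variable sites; at each, a 2x2 table of matches/mismatches in
#' the `w` variable sites left vs right of the breakpoint is scored by
#' chi-square. The maximum over pairs and breakpoints is the statistic; its
#' p-value comes from permuting variable-site order.
#'
#' @param seqs 3 aligned sequences (candidate, parent A, parent B)
#' @param window_halfwidth `w`, variable sites per window side
#' @param n_permutations permutation-null draws
#' @param seed integer seed for the permutations
#' @param alpha significance level for the `significant` flag
#' @return list: `method`, `stat`, `breakpoint` (alignment column),
#'   `p_value`, `significant`, `no_call`
#' @export
maxchi_scan <- function(seqs, window_halfwidth = 30, n_permutations = 200,
                        seed = 1, alpha = 0.05) {
  m <- as_aln_matrix(seqs)
  stopifnot(nrow(m) == 3)
  vs <- variable_sites(m)
  w <- window_halfwidth
  if (length(vs) < 2 * w) {
    return(list(method = "maxchi", stat = NA_real_, breakpoint = NA_real_,
                p_value = NA_real_, significant = FALSE, no_call = TRUE))
  }
  pairs <- list(c(1, 2), c(1, 3), c(2, 3))
  eqs <- lapply(pairs, function(p) m[p[1], vs] == m[p[2], vs])
  obs <- vapply(eqs, maxchi_stat, numeric(2), w = w)
  best_pair <- which.max(obs[1, ])
  stat <- obs[1, best_pair]
  breakpoint <- vs[obs[2, best_pair]]
  set.seed(seed)
  perm <- vapply(seq_len(n_permutations), function(i) {
    p <- sample.int(length(vs))
    max(vapply(eqs, function(e) maxchi_stat(e[p], w)[1], 0))
  }, 0)
  p_value <- (1 + sum(perm >= stat)) / (n_permutations + 1)
  list(method = "maxchi", stat = stat, breakpoint = breakpoint,
       p_value = p_value, significant = p_value < alpha, no_call = FALSE)
}

#' Chimaera-style recombination scan of an aligned triplet
#'
#' As [maxchi_scan()], but the scanned vector is the candidate's match
#' pattern restricted to sites where the two parents differ and the
#' candidate matches exactly one of them.
#'
#' @inheritParams maxchi_scan
#' @return as [maxchi_scan()] with `method = "chimaera"`
#' @export
chimaera_scan <- function(seqs, window_halfwidth = 30, n_permutations = 200,
                          seed = 1, alpha = 0.05) {
  m <- as_aln_matrix(seqs)
  stopifnot(nrow(m) == 3)
  vs <- variable_sites(m)
  inf <- vs[m[2, vs] != m[3, vs] &
              (m[1, vs] == m[2, vs] | m[1, vs] == m[3, vs])]
  w <- window_halfwidth
  if (length(inf) < 2 * w) {
    return(list(method = "chimaera", stat = NA_real_, breakpoint = NA_real_,
                p_value = NA_real_, significant = FALSE, no_call = TRUE))
  }
  z <- m[1, inf] == m[2, inf]
  obs <- maxchi_stat(z, w)
  set.seed(seed)
  perm <- vapply(seq_len(n_permutations), function(i) {
    maxchi_stat(z[sample.int(length(z))], w)[1]
  }, 0)
  p_value <- (1 + sum(perm >= obs[1])) / (n_permutations + 1)
  list(method = "chimaera", stat = obs[1], breakpoint = inf[obs[2]],
       p_value = p_value, significant = p_value < alpha, no_call = FALSE)
}

# longest run (in windows) where the locally closest parent differs from
# the globally closest; returns c(run_length, start_column)
rdp_run_stat <- function(m, starts, window_len, global_closest) {
  local_closest <- vapply(starts, function(s) {
    cols <- s:(s + window_len - 1)
    ia <- sum(m[1, cols] == m[2, cols])
    ib <- sum(m[1, cols] == m[3, cols])
    if (ia == ib) global_closest else if (ia > ib) 2L else 3L
  }, 1L)
  disc <- local_closest != global_closest
  r <- rle(disc)
  if (!any(r$values)) return(c(0, NA_real_))
  len <- max(r$lengths[r$values])
  idx <- which(r$values & r$lengths == len)[1]
  first <- if (idx == 1) 1 else sum(r$lengths[1:(idx - 1)]) + 1
  c(len, starts[first])
}

#' RDP-style sliding-window identity scan of an aligned triplet
#'
#' Flags regions where the candidate's locally closest parent differs from
#' its globally closest parent; the statistic is the longest run of such
#' discordant windows, with a permutation p-value over column order.
#'
#' @inheritParams maxchi_scan
#' @param window_len window length in alignment columns (>= 30)
#' @param step window step in columns
#' @return as [maxchi_scan()] with `method = "rdp_window"`
#' @export
rdp_window_scan <- function(seqs, window_len = 100, step = 25,
                            n_permutations = 200, seed = 1, alpha = 0.05) {
  m <- as_aln_matrix(seqs)
  stopifnot(nrow(m) == 3)
  L <- ncol(m)
  if (window_len < 30) stop("window_len must be >= 30")
  if (window_len >= L) {
    return(list(method = "rdp_window", stat = NA_real_,
                breakpoint = NA_real_, p_value = NA_real_,
                significant = FALSE, no_call = TRUE))
  }
  starts <- seq(1, L - window_len + 1, by = step)
  ia <- sum(m[1, ] == m[2, ]); ib <- sum(m[1, ] == m[3, ])
  global_closest <- if (ia >= ib) 2L else 3L
  obs <- rdp_run_stat(m, starts, window_len, global_closest)
  set.seed(seed)
  perm <- vapply(seq_len(n_permutations), function(i) {
    mp <- m[, sample.int(L), drop = FALSE]
    rdp_run_stat(mp, starts, window_len, global_closest)[1]
  }, 0)
  p_value <- (1 + sum(perm >= obs[1])) / (n_permutations + 1)
  list(method = "rdp_window", stat = obs[1], breakpoint = obs[2],
       p_value = p_value, significant = p_value < alpha, no_call = FALSE)
}

#' Run all recombination scans on one triplet
#'
#' @param seqs 3 aligned sequences (candidate, parent A, parent B)
#' @param seed integer seed
#' @param methods subset of `c("maxchi", "chimaera", "rdp_window")`
#' @param window_halfwidth variable-site half-window for MaxChi/Chimaera
#' @param window_len,step column window for the RDP-style scan
#' @param n_permutations permutation-null draws per scan
#' @param alpha significance level
#' @return data.frame, one row per method
#' @export
scan_triplet <- function(seqs, seed = 1,
                         methods = c("maxchi", "chimaera", "rdp_window"),
                         window_halfwidth = 30, window_len = 100, step = 25,
                         n_permutations = 200, alpha = 0.05) {
  res <- list()
  if ("maxchi" %in% methods) {
    res$maxchi <- maxchi_scan(seqs, window_halfwidth, n_permutations,
                              seed = seed, alpha = alpha)
  }
  if ("chimaera" %in% methods) {
    res$chimaera <- chimaera_scan(seqs, window_halfwidth, n_permutations,
                                  seed = seed + 1, alpha = alpha)
  }
  if ("rdp_window" %in% methods) {
    res$rdp_window <- rdp_window_scan(seqs, window_len, step,
                                      n_permutations, seed = seed + 2,
                                      alpha = alpha)
  }
  do.call(rbind, lapply(res, function(r) {
    data.frame(method = r$method, stat = r$stat, breakpoint = r$breakpoint,
               p_value = r$p_value, significant = r$significant,
               no_call = r$no_call)
  }))
}

#' Screen a set of aligned copies for recombination
#'
#' Enumerates triplets of the aligned copies (every member takes the
#' candidate role once per unordered triple), runs the configured scans,
#' and applies the consensus rule via [consensus_calls()].
#'
#' @param seqs named character vector of aligned copies
#' @param min_methods methods required to flag a copy for removal
#' @param max_triplets cap on scanned unordered triples
#' @param seed integer seed
#' @param alpha significance level
#' @param ... passed to the scans
#' @return list: `calls` (per-triplet-method table) and `decisions`
#'   (per-copy consensus; `removed` flags)
#' @export
screen_recombination <- function(seqs, min_methods = 2, max_triplets = 200,
                                 seed = 1, alpha = 0.05, ...) {
  n <- length(seqs)
  ids <- names(seqs) %||% as.character(seq_len(n))
  names(seqs) <- ids
  if (n < 3) {
    return(list(calls = NULL,
                decisions = data.frame(copy_id = ids,
                                       methods_supporting = 0L,
                                       removed = FALSE)))
  }
  triples <- utils::combn(n, 3)
  if (ncol(triples) > max_triplets) {
    set.seed(seed)
    triples <- triples[, sample.int(ncol(triples), max_triplets),
                       drop = FALSE]
  }
  calls <- list()
  for (j in seq_len(ncol(triples))) {
    tri <- triples[, j]
    for (cand_pos in 1:3) {
      roles <- c(tri[cand_pos], tri[-cand_pos])
      df <- scan_triplet(seqs[roles], seed = seed + 31L * j + cand_pos, ...)
      df$candidate <- ids[roles[1]]
      df$parent_a <- ids[roles[2]]
      df$parent_b <- ids[roles[3]]
      calls[[length(calls) + 1]] <- df
    }
  }
  calls <- do.call(rbind, calls)
  rownames(calls) <- NULL
  decisions <- consensus_calls(calls, min_methods = min_methods,
                               alpha = alpha, all_ids = ids)
  list(calls = calls, decisions = decisions)
}

#' Consensus removal rule over recombination calls
#'
#' Per candidate copy, counts the methods with at least one significant
#' call after Bonferroni correction over the scans performed by that
#' method; copies supported by `min_methods` or more methods are flagged
#' `removed` (excluded from phylogeny input downstream).
#'
#' @param calls data.frame from [screen_recombination()] /
#'   [scan_triplet()] with `candidate`, `method`, `p_value`, `no_call`
#' @param min_methods removal threshold (methods supporting)
#' @param alpha significance level applied to corrected p-values
#' @param all_ids optional full copy id set (so never-scanned copies get a
#'   row)
#' @return data.frame: `copy_id`, `methods_supporting`, `removed`
#' @export
consensus_calls <- function(calls, min_methods = 2, alpha = 0.05,
                            all_ids = NULL) {
  ids <- all_ids %||% unique(calls$candidate)
  support <- stats::setNames(integer(length(ids)), ids)
  for (meth in unique(calls$method)) {
    cm <- calls[calls$method == meth & !calls$no_call, , drop = FALSE]
    if (!nrow(cm)) next
    p_adj <- pmin(1, cm$p_value * nrow(cm))
    sig_ids <- unique(cm$candidate[p_adj < alpha])
    support[sig_ids] <- support[sig_ids] + 1L
  }
  data.frame(copy_id = ids, methods_supporting = unname(support),
             removed = unname(support) >= min_methods)
}
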