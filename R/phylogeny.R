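#' Reference-projected multiple alignment of copies
#'
#' Each copy is globally aligned to the reference provirus and written into
#' a row indexed by reference coordinates; copy insertions relative to the
#' reference are dropped (and counted), deletions appear as gaps. The
#' result is a deterministic, desk-scale stand-in for a progressive
#' multiple alignment, adequate at the low divergences typical of a single
#' ERV lineage.
#'
#' @param copies named character vector of copy sequences (element
#'   orientation)
#' @param provirus_ref a `provirus_reference`
#' @param min_alignable minimum fraction of reference columns a copy must
#'   cover to be included (default 0.3)
#' @return object of class `projected_msa`: list with `matrix` (rows =
#'   copies, char matrix over reference columns), `dropped_insertions`,
#'   `excluded`
#' @export
reference_projected_msa <- function(copies, provirus_ref,
                                    min_alignable = 0.3) {
  stopifnot(length(copies) >= 1)
  ids <- names(copies) %||% paste0("copy_", seq_along(copies))
  rows <- list()
  dropped <- integer(0)
  excluded <- character(0)
  for (i in seq_along(copies)) {
    pr <- project_to_reference(copies[[i]], provirus_ref$seq)
    frac <- sum(pr$row != "-") / length(pr$row)
    if (frac < min_alignable) {
      excluded <- c(excluded, ids[i])
      next
    }
    rows[[ids[i]]] <- pr$row
    dropped[ids[i]] <- pr$n_insertions
  }
  if (!length(rows)) stop("no copy passed the alignable-fraction filter")
  structure(list(matrix = do.call(rbind, rows),
                 dropped_insertions = dropped, excluded = excluded),
            class = "projected_msa")
}

#' @export
print.projected_msa <- function(x, ...) {
  cat(sprintf("projected_msa: %d rows x %d reference columns (%d excluded)\n",
              nrow(x$matrix), ncol(x$matrix), length(x$excluded)))
  invisible(x)
}

msa_matrix <- function(msa) {
  if (inherits(msa, "projected_msa")) return(msa$matrix)
  as_aln_matrix(msa)
}

#' Pairwise K2P distance matrix over an alignment
#'
#' Pairwise distances over shared non-gap, non-N columns, using the same
#' estimator as the dating module. Saturated or incomparable pairs are NA
#' (reported, not repaired).
#'
#' @param msa a `projected_msa`, char matrix, or named character vector of
#'   aligned sequences
#' @return symmetric distance matrix with zero diagonal
#' @export
k2p_matrix <- function(msa) {
  m <- msa_matrix(msa)
  n <- nrow(m)
  if (n < 2) stop("need at least 2 sequences")
  D <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      kk <- tryCatch(
        k2p_distance(list(a = m[i, ], b = m[j, ])),
        error = function(e) list(K = NA_real_))
      D[i, j] <- D[j, i] <- kk$K
    }
  }
  D
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard NJ agglomeration (via ape); negative branch lengths are
#' clamped to zero and recorded in the `clamped` attribute.
#'
#' @param D symmetric distance matrix, n >= 3
#' @return a `phylo` tree
#' @export
neighbor_joining <- function(D) {
  D <- as.matrix(D)
  if (!isSymmetric(unname(D), tol = 1e-8)) stop("distance matrix not symmetric")
  if (any(is.na(D))) stop("distance matrix contains NA (saturated pairs)")
  tr <- ape::nj(stats::as.dist(D))
  n_clamped <- sum(tr$edge.length < 0)
  tr$edge.length[tr$edge.length < 0] <- 0
  attr(tr, "clamped") <- n_clamped
  tr
}

#' Midpoint-root a tree
#'
#' Roots at the midpoint of the longest tip-to-tip path.
#'
#' @param tree a `phylo` with branch lengths
#' @return rooted `phylo`
#' @export
midpoint_root <- function(tree) {
  phangorn::midpoint(tree)
}

#' Nonparametric bootstrap support for NJ splits
#'
#' Resamples alignment columns with replacement, rebuilds the K2P + NJ
#' tree, and reports for each internal edge of the reference tree the
#' percentage of replicates containing the same bipartition.
#'
#' @param msa alignment (as for [k2p_matrix()])
#' @param B bootstrap replicates
#' @param seed integer seed
#' @param tree optional reference tree (built from the full alignment if
#'   omitted)
#' @return list: `tree` (with `node.label` support values in 0..100),
#'   `support` (numeric per internal node)
#' @export
bootstrap_support <- function(msa, B = 100, seed = 1, tree = NULL) {
  m <- msa_matrix(msa)
  if (is.null(tree)) tree <- neighbor_joining(k2p_matrix(m))
  set.seed(seed)
  boots <- vector("list", B)
  for (b in seq_len(B)) {
    cols <- sample.int(ncol(m), replace = TRUE)
    Db <- k2p_matrix(m[, cols, drop = FALSE])
    if (any(is.na(Db))) {
      cap <- max(Db, na.rm = TRUE) * 2
      Db[is.na(Db)] <- cap
    }
    boots[[b]] <- neighbor_joining(Db)
  }
  counts <- ape::prop.clades(tree, boots, rooted = FALSE)
  counts[is.na(counts)] <- 0
  support <- round(100 * counts / B)
  tree$node.label <- as.character(support)
  list(tree = tree, support = support)
}

#' Is a tip subset monophyletic?
#'
#' True iff the smallest clade containing the subset contains no other
#' tips; an outgroup can be supplied to root an unrooted tree first.
#'
#' @param tree a `phylo`
#' @param tip_subset character tips
#' @param outgroup optional tip(s) to root by
#' @return logical
#' @export
is_monophyletic <- function(tree, tip_subset, outgroup = NULL) {
  if (!is.null(outgroup)) {
    tree <- ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
  }
  if (length(tip_subset) <= 1) return(TRUE)
  ape::is.monophyletic(tree, tip_subset)
}

#' Per-gene trees from a projected alignment
#'
#' Slices the reference-projected alignment at annotated reference gene
#' intervals and builds one NJ tree per slice, enabling descriptive
#' gene-vs-genome topology comparison (shared/different bipartitions).
#'
#' @param msa a `projected_msa`
#' @param provirus_ref the reference carrying gene features
#' @return named list of `phylo` trees (genes with enough signal only)
#' @export
gene_trees <- function(msa, provirus_ref) {
  feats <- provirus_ref$features
  genes <- feats[feats$type == "gene", , drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(genes))) {
    cols <- genes$start[i]:genes$end[i]
    sub <- msa$matrix[, cols, drop = FALSE]
    D <- tryCatch(k2p_matrix(sub), error = function(e) NULL)
    if (is.null(D) || any(is.na(D))) next
    out[[genes$name[i]]] <- neighbor_joining(D)
  }
  out
}

#' Compare bipartitions between two trees
#'
#' @param tree_a,tree_b `phylo` trees over the same tips
#' @return list: `shared`, `only_a`, `only_b` (bipartition counts)
#' @export
compare_bipartitions <- function(tree_a, tree_b) {
  pa <- ape::prop.part(tree_a)
  pb <- ape::prop.part(tree_b)
  key <- function(pp, tr) {
    labs <- attr(pp, "labels")
    vapply(pp, function(idx) paste(sort(labs[idx]), collapse = "|"), "")
  }
  ka <- key(pa, tree_a); kb <- key(pb, tree_b)
  list(shared = length(intersect(ka, kb)),
       only_a = length(setdiff(ka, kb)),
       only_b = length(setdiff(kb, ka)))
}

#' Write a tree as Newick
#' @param tree a `phylo`
#' @param path output path
#' @return the path, invisibly
#' @export
write_tree_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}
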