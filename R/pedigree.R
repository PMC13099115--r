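#' Build the host pedigree/species tree for the simulator
#'
#' Constructs a rooted tree of simulated individuals with branch durations
#' in million years (My). The default topology mirrors a small *Felis*-like
#' pedigree: a jungle-cat-like lineage splitting first (oldest split,
#' default 2.0 My), a black-footed-cat-like lineage next, and several
#' domestic-cat-like individuals diverging recently. An optional
#' introgression edge transfers ERV copies from a donor branch to a
#' recipient branch at a given time.
#'
#' @param config a [sim_config()]; `config$tree` holds the tree description:
#'   either `topology = "felis"` with split times `chaus_split`,
#'   `nigripes_split`, `catus_split` (My) and `n_catus`, or
#'   `topology = "single"` with `duration` (My) for a one-tip tree.
#'   `introgression`, if given, is `list(donor, recipient, time_mya)` naming
#'   branches by their child node.
#' @return a `host_tree`: list with `branches` (data.frame: `child`,
#'   `parent`, `t_old`, `t_young` in My before present), `tips`, and the
#'   validated `introgression` edge (or `NULL`)
#' @export
build_host_pedigree <- function(config) {
  ts <- config$tree %||% default_tree_spec()
  if (identical(ts$topology, "single")) {
    dur <- ts$duration %||% 1
    if (dur < 0) stop("branch durations must be non-negative")
    branches <- data.frame(child = "tip_1", parent = "root",
                           t_old = dur, t_young = 0)
    tips <- "tip_1"
  } else {
    if (ts$nigripes_split >= ts$chaus_split ||
        ts$catus_split >= ts$nigripes_split) {
      stop("split times must be nested: chaus > nigripes > catus")
    }
    n_cat <- ts$n_catus %||% 3
    catus <- paste0("catus_", seq_len(n_cat))
    branches <- rbind(
      data.frame(child = "chaus", parent = "root",
                 t_old = ts$chaus_split, t_young = 0),
      data.frame(child = "anc_nigripes_catus", parent = "root",
                 t_old = ts$chaus_split, t_young = ts$nigripes_split),
      data.frame(child = "nigripes", parent = "anc_nigripes_catus",
                 t_old = ts$nigripes_split, t_young = 0),
      data.frame(child = "anc_catus", parent = "anc_nigripes_catus",
                 t_old = ts$nigripes_split, t_young = ts$catus_split),
      data.frame(child = catus, parent = "anc_catus",
                 t_old = ts$catus_split, t_young = 0)
    )
    tips <- c("chaus", "nigripes", catus)
  }
  if (any(branches$t_old < branches$t_young)) {
    stop("branch durations must be non-negative")
  }
  tree <- structure(list(branches = branches, tips = tips,
                         introgression = NULL), class = "host_tree")
  if (!is.null(ts$introgression)) {
    ie <- ts$introgression
    for (b in c(ie$donor, ie$recipient)) {
      if (!b %in% branches$child) stop("unknown branch in introgression: ", b)
    }
    within <- function(b, t) {
      row <- branches[branches$child == b, ]
      t <= row$t_old && t >= row$t_young
    }
    if (!within(ie$donor, ie$time_mya) || !within(ie$recipient, ie$time_mya)) {
      stop("introgression time lies outside a branch interval")
    }
    tree$introgression <- ie
  }
  tree
}

#' @export
print.host_tree <- function(x, ...) {
  cat(sprintf("host_tree: %d tips (%s), %d branches\n", length(x$tips),
              paste(x$tips, collapse = ", "), nrow(x$branches)))
  invisible(x)
}

# Tips descending from (and including) the given node.
descendant_tips <- function(tree, node) {
  br <- tree$branches
  out <- character(0)
  frontier <- node
  while (length(frontier)) {
    nxt <- character(0)
    for (n in frontier) {
      if (n %in% tree$tips) out <- c(out, n)
      nxt <- c(nxt, br$child[br$parent == n])
    }
    frontier <- nxt
  }
  unique(out)
}

# Chain of branches (child names) from the given branch up to the root.
ancestor_branches <- function(tree, branch) {
  br <- tree$branches
  out <- branch
  cur <- branch
  repeat {
    parent <- br$parent[br$child == cur]
    if (!length(parent) || !parent %in% br$child) break
    out <- c(out, parent)
    cur <- parent
  }
  out
}
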