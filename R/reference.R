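#' Provirus reference objects
#'
#' A `provirus_reference` bundles the query/annotation provirus sequence with
#' its feature table: the LTR, the three retroviral genes (*gag*, *pol*,
#' *env*) and their constituent peptides. Features use 1-based inclusive
#' coordinates on the provirus; gene and peptide features are in frame with
#' their own start (frame 0 at `start`).
#'
#' @param seq character scalar, the full provirus sequence (5' LTR .. 3' LTR)
#' @param features data.frame with columns `name`, `type`
#'   (`"ltr"`/`"gene"`/`"peptide"`), `start`, `end`, `parent` (gene name for
#'   peptides, `NA` otherwise)
#' @return an object of class `provirus_reference`
#' @export
provirus_reference <- function(seq, features) {
  stopifnot(is.character(seq), length(seq) == 1, nchar(seq) > 0)
  needed <- c("name", "type", "start", "end", "parent")
  if (!all(needed %in% names(features))) {
    stop("feature table must have columns: ", paste(needed, collapse = ", "))
  }
  if (any(features$start < 1 | features$end > nchar(seq) |
            features$start > features$end)) {
    stop("feature intervals must lie within the provirus sequence")
  }
  if (sum(features$type == "ltr") < 1) stop("feature table must contain an LTR")
  structure(list(seq = seq, features = features, length = nchar(seq)),
            class = "provirus_reference")
}

#' @export
print.provirus_reference <- function(x, ...) {
  cat(sprintf("provirus_reference: %d bp, %d features (%d genes, %d peptides)\n",
              x$length, nrow(x$features), sum(x$features$type == "gene"),
              sum(x$features$type == "peptide")))
  invisible(x)
}

#' Extract a feature's sequence from a provirus reference
#' @param ref a `provirus_reference`
#' @param name feature name (e.g. `"LTR"`, `"gag"`, `"reverse transcriptase"`)
#' @return character scalar
#' @export
reference_feature_seq <- function(ref, name) {
  row <- ref$features[ref$features$name == name, , drop = FALSE]
  if (nrow(row) == 0) stop("no such feature: ", name)
  substr(ref$seq, row$start[1], row$end[1])
}

ltr_length <- function(ref) {
  row <- ref$features[ref$features$type == "ltr", , drop = FALSE][1, ]
  row$end - row$start + 1
}

# Random codons avoiding stop codons, used to guarantee intact reading frames
# in the synthetic reference genes.
random_orf <- function(n_nt) {
  stopifnot(n_nt %% 3 == 0)
  codons <- apply(expand.grid(BASES, BASES, BASES), 1, paste, collapse = "")
  codons <- setdiff(codons, c("TAA", "TAG", "TGA"))
  paste(sample(codons, n_nt / 3, replace = TRUE), collapse = "")
}

#' Build a synthetic gammaretrovirus-like provirus reference
#'
#' Generates a provirus with the canonical 5'LTR--leader--gag--pol--env--
#' 3'UTR--3'LTR architecture, identical terminal LTRs, stop-free reading
#' frames in all three genes, and a peptide sub-feature table (matrix p15,
#' p12, capsid, nucleocapsid in *gag*; protease, reverse transcriptase,
#' integrase in *pol*; SU, TM in *env*). Gene lengths mirror typical
#' gammaretroviral proportions.
#'
#' @param seed integer seed for the sequence draw
#' @param ltr_len LTR length in bp (default 600)
#' @return a `provirus_reference`
#' @export
synthetic_provirus <- function(seed = 1, ltr_len = 600) {
  set.seed(substream_seed(seed, "reference"))
  leader_len <- 300; utr_len <- 150
  gag_len <- 1392; pol_len <- 1866; env_len <- 1821
  ltr <- random_dna(ltr_len)
  leader <- random_dna(leader_len)
  gag <- random_orf(gag_len)
  pol <- random_orf(pol_len)
  env <- random_orf(env_len)
  utr <- random_dna(utr_len)
  seq <- paste0(ltr, leader, gag, pol, env, utr, ltr)

  at <- ltr_len + leader_len
  gag_s <- at + 1; gag_e <- at + gag_len
  pol_s <- gag_e + 1; pol_e <- gag_e + pol_len
  env_s <- pol_e + 1; env_e <- pol_e + env_len
  total <- nchar(seq)
  pep <- function(name, parent, off_s, off_e, gs) {
    data.frame(name = name, type = "peptide", start = gs + off_s - 1,
               end = gs + off_e - 1, parent = parent)
  }
  features <- rbind(
    data.frame(name = "LTR", type = "ltr", start = 1, end = ltr_len, parent = NA),
    data.frame(name = "LTR", type = "ltr", start = total - ltr_len + 1,
               end = total, parent = NA),
    data.frame(name = "gag", type = "gene", start = gag_s, end = gag_e, parent = NA),
    data.frame(name = "pol", type = "gene", start = pol_s, end = pol_e, parent = NA),
    data.frame(name = "env", type = "gene", start = env_s, end = env_e, parent = NA),
    pep("matrix p15", "gag", 1, 360, gag_s),
    pep("p12", "gag", 361, 660, gag_s),
    pep("capsid", "gag", 661, 1230, gag_s),
    pep("nucleocapsid", "gag", 1231, 1392, gag_s),
    pep("protease", "pol", 1, 300, pol_s),
    pep("reverse transcriptase", "pol", 301, 1266, pol_s),
    pep("integrase", "pol", 1267, 1866, pol_s),
    pep("SU", "env", 1, 1200, env_s),
    pep("TM", "env", 1201, 1821, env_s)
  )
  provirus_reference(seq, features)
}
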