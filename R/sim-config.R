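#' Simulation configuration
#'
#' Builds and validates the configuration object driving the provirus
#' insertion simulator. Defaults describe the study conditions emulated
#' throughout the package: a small *Felis*-like host pedigree, neutral
#' per-site substitution at `r` = 2.3e-9 substitutions/site/year,
#' insertions within the last ~3.5 million years, 4-nt target-site
#' duplications, solo-LTR collapse, occasional large internal deletions and
#' internal duplications, and rare inter-copy recombination.
#'
#' @param seed integer master seed; all randomness in a run derives from it
#' @param background_length bp of background sequence per scaffold
#' @param n_scaffolds scaffolds per individual
#' @param r substitution rate, substitutions/site/year
#' @param kappa transition/transversion rate ratio of the substitution model
#' @param endogenization_rate insertion events per branch per My
#' @param max_insertion_age_years insertions older than this are not drawn
#' @param solo_collapse_hazard per-copy per-My probability of LTR-LTR
#'   ejection of the internal region
#' @param paired_solo_frac fraction of ejection events that retain both LTRs
#'   (paired solo LTR) instead of one
#' @param deletion_prob per-copy probability of one internal deletion
#' @param deletion_size_range bp range internal deletion sizes are drawn
#'   from (log-uniform); must allow sizes > 1000 nt
#' @param duplication_prob per-copy probability of an internal duplication
#'   (atypical architecture: repeated internal region around an LTR-like
#'   spacer)
#' @param recombination_prob per-copy probability of being replaced by a
#'   mosaic of two other copies
#' @param host_background_divergence pairwise substitutions/site between
#'   individuals' background sequence
#' @param tsd_length target-site duplication length; fixed at 4
#' @param gc background GC content
#' @param min_copy_spacing minimum bp between implant positions on one
#'   scaffold (overlapping draws are redrawn)
#' @param end_margin implant positions keep this distance from scaffold ends
#'   unless end-truncation is being simulated
#' @param tree host pedigree description, see [build_host_pedigree()]
#' @return a validated list of class `sim_config`
#' @export
sim_config <- function(seed = 1,
                       background_length = 1e6,
                       n_scaffolds = 1,
                       r = 2.3e-9,
                       kappa = 2,
                       endogenization_rate = 2,
                       max_insertion_age_years = 3.5e6,
                       solo_collapse_hazard = 0.3,
                       paired_solo_frac = 0.1,
                       deletion_prob = 0.3,
                       deletion_size_range = c(50, 3000),
                       duplication_prob = 0.03,
                       recombination_prob = 0.05,
                       host_background_divergence = 0.005,
                       tsd_length = 4,
                       gc = 0.42,
                       min_copy_spacing = 20000,
                       end_margin = 1000,
                       tree = NULL) {
  cfg <- as.list(environment())
  for (nm in c("solo_collapse_hazard", "paired_solo_frac", "deletion_prob",
               "duplication_prob", "recombination_prob")) {
    stopifnot_scalar_prob(cfg[[nm]], nm)
  }
  if (r < 0 || endogenization_rate < 0 || host_background_divergence < 0) {
    stop("rates must be >= 0")
  }
  if (tsd_length != 4) stop("tsd_length is fixed at 4")
  if (background_length < 1) stop("background_length must be positive")
  if (deletion_size_range[2] <= 1000) {
    stop("deletion_size_range must include sizes > 1000 nt")
  }
  if (is.null(cfg$tree)) cfg$tree <- default_tree_spec()
  class(cfg) <- "sim_config"
  cfg
}

default_tree_spec <- function() {
  list(topology = "felis", chaus_split = 2.0, nigripes_split = 1.5,
       catus_split = 0.1, n_catus = 3, introgression = NULL)
}
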