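#' @useDynLib ervmine, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
NULL

BASES <- c("A", "C", "G", "T")

# transition partner of each base; transversion partners are the other two
TS_MAP <- c(A = "G", G = "A", C = "T", T = "C")
TV_MAP <- list(A = c("C", "T"), G = c("C", "T"), C = c("A", "G"), T = c("A", "G"))

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Reverse complement of a DNA string
#' @param x character scalar over A/C/G/T/N
#' @return reverse-complemented character scalar
#' @keywords internal
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

chars_seq <- function(x) paste(x, collapse = "")

random_dna <- function(n, gc = 0.42) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  chars_seq(sample(BASES, n, replace = TRUE, prob = p))
}

#' Kimura two-parameter (K80) substitution probabilities after time t
#'
#' Closed-form transition probabilities of the K80 chain with total
#' instantaneous substitution rate `r` per site per year and
#' transition/transversion rate ratio `kappa`.
#'
#' @param t_years elapsed time in years
#' @param r substitutions/site/year
#' @param kappa transition/transversion rate ratio (alpha/beta)
#' @return list with `p_ts` (probability of a transition) and `p_tv`
#'   (probability of each of the two transversions)
#' @keywords internal
k80_site_probs <- function(t_years, r, kappa) {
  beta <- r / (kappa + 2)
  alpha <- kappa * beta
  e1 <- exp(-4 * beta * t_years)
  e2 <- exp(-2 * (alpha + beta) * t_years)
  p_ts <- 0.25 + 0.25 * e1 - 0.5 * e2
  p_tv_total <- 0.5 - 0.5 * e1
  list(p_ts = p_ts, p_tv = p_tv_total / 2)
}

# Apply K80 substitutions site-wise for t years. Vectorized over sites.
evolve_chars <- function(chars, t_years, r, kappa = 2) {
  if (t_years <= 0 || r <= 0 || length(chars) == 0) return(chars)
  pr <- k80_site_probs(t_years, r, kappa)
  n <- length(chars)
  u <- stats::runif(n)
  ts_hit <- u < pr$p_ts
  tv1_hit <- !ts_hit & u < pr$p_ts + pr$p_tv
  tv2_hit <- !ts_hit & !tv1_hit & u < pr$p_ts + 2 * pr$p_tv
  out <- chars
  if (any(ts_hit)) out[ts_hit] <- TS_MAP[chars[ts_hit]]
  if (any(tv1_hit)) {
    out[tv1_hit] <- vapply(chars[tv1_hit], function(b) TV_MAP[[b]][1], "")
  }
  if (any(tv2_hit)) {
    out[tv2_hit] <- vapply(chars[tv2_hit], function(b) TV_MAP[[b]][2], "")
  }
  out
}

evolve_seq <- function(seq, t_years, r, kappa = 2) {
  chars_seq(evolve_chars(seq_chars(seq), t_years, r, kappa))
}

# Apply a fixed expected number of substitutions/site (divergence d), by
# running the K80 chain for the time that yields total rate d at r = 1/yr.
diverge_seq <- function(seq, d, kappa = 2) {
  if (d <= 0) return(seq)
  evolve_seq(seq, t_years = d, r = 1, kappa = kappa)
}

# Deterministic seed fan-out: one named substream per pipeline stage.
substream_seed <- function(seed, stage) {
  offsets <- c(
    reference = 101L, pedigree = 211L, endogenization = 307L,
    evolve = 401L, emit = 503L, mining = 601L, recomb = 701L,
    phylo = 809L, misc = 907L
  )
  off <- offsets[[stage]] %||% 997L
  (as.integer(seed) * 1000L + off) %% .Machine$integer.max
}

stopifnot_scalar_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x > 1) {
    stop(sprintf("`%s` must be a probability in [0, 1]", name), call. = FALSE)
  }
}
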