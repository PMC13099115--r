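# Shared fixtures: built in code, no data files.

# a truth table row in the shape simulate_endogenization() produces
make_truth <- function(copy_id = "copy_001", scaffold = "scaffold_1",
                       pos = 50000, age = 0, tsd = "GGAG", strand = "+",
                       carriers = "tip_1", events = list(),
                       class_truth = "typical", trunc_cut = 0L) {
  df <- data.frame(copy_id = copy_id, branch = carriers[1],
                   scaffold = scaffold, insertion_position = pos,
                   age_years = age, tsd = tsd, strand = strand,
                   class_truth = class_truth,
                   carriers = paste(carriers, collapse = ","),
                   parent_copy_ids = "", trunc_cut = trunc_cut)
  df$events <- list(events)
  df
}

single_tip_config <- function(seed = 1, background_length = 100000, ...) {
  sim_config(seed = seed, background_length = background_length,
             tree = list(topology = "single", duration = 1),
             host_background_divergence = 0, ...)
}

# independent K2P oracle: enumerate site patterns via table(), then apply
# the estimator to the pattern counts
k2p_oracle <- function(a, b) {
  x <- strsplit(a, "")[[1]]
  y <- strsplit(b, "")[[1]]
  bases <- c("A", "C", "G", "T")
  ok <- x %in% bases & y %in% bases
  pat <- table(paste0(x[ok], y[ok]))
  n <- sum(pat)
  ts <- sum(pat[intersect(names(pat), c("AG", "GA", "CT", "TC"))])
  tv_names <- c("AC", "CA", "AT", "TA", "CG", "GC", "GT", "TG")
  tv <- sum(pat[intersect(names(pat), tv_names)])
  P <- ts / n; Q <- tv / n
  if (1 - 2 * P - Q <= 0 || 1 - 2 * Q <= 0) return(NA_real_)
  0.5 * log(1 / (1 - 2 * P - Q)) + 0.25 * log(1 / (1 - 2 * Q))
}

# brute-force two-sided Fisher p for fixed margins, via log-binomials
fisher_bruteforce <- function(t22) {
  m <- sum(t22[1, ]); n <- sum(t22[2, ]); k <- sum(t22[, 1])
  if (m + n == 0 || k == 0 || k == m + n) return(1)
  lo <- max(0, k - n); hi <- min(k, m)
  xs <- lo:hi
  logp <- lchoose(m, xs) + lchoose(n, k - xs) - lchoose(m + n, k)
  pr <- exp(logp)
  p_obs <- pr[match(t22[1, 1], xs)]
  sum(pr[pr <= p_obs * (1 + 1e-7)])
}

random_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
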