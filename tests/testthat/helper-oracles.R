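# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: the selection oracle enumerates genotype
# classes and allele bookkeeping explicitly, and the bootstrap oracle
# enumerates every possible resample.

# Allele frequency after one generation of viability selection, by direct
# enumeration: Hardy-Weinberg genotype proportions are weighted by fitness
# and each surviving genotype contributes its allele dose.
oracle_advance <- function(p, w_ss, w_rs, w_rr) {
  q <- 1 - p
  geno <- data.frame(
    freq = c(q^2, 2 * p * q, p^2),
    w = c(w_ss, w_rs, w_rr),
    r_dose = c(0, 1, 2) / 2
  )
  surv <- geno$freq * geno$w
  sum(surv * geno$r_dose) / sum(surv)
}

# Exact resampling distribution of the mean for small n: every one of the
# n^n equally likely resamples is enumerated.
oracle_bootstrap_quantiles <- function(values, probs = c(0.025, 0.975)) {
  n <- length(values)
  stopifnot(n <= 4)
  idx <- expand.grid(rep(list(seq_len(n)), n))
  means <- apply(idx, 1, function(i) mean(values[i]))
  list(
    quantiles = quantile(means, probs = probs, names = FALSE),
    step = min(diff(sort(unique(means))))
  )
}

# Fixed-point of the selection recursion by long iteration, used to check
# the closed-form overdominance equilibrium.
oracle_equilibrium_by_iteration <- function(w, p0 = 0.5, n_iter = 20000) {
  p <- p0
  for (i in seq_len(n_iter)) {
    q <- 1 - p
    wbar <- p^2 * w[3] + 2 * p * q * w[2] + q^2 * w[1]
    p <- p * (p * w[3] + q * w[2]) / wbar
  }
  p
}

# Default empirical fitness triples used in many tests.
paper_fitness <- function() fitness_table()

bt_fitness_triple <- function() habitat_fitness(paper_fitness(), 0)
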