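# Shared fixtures: small deterministic cohorts and hand-built matrices.

# small three-lineage cohort with one inversion; fast enough for unit tests
small_sim_config <- function(seed = 42, n = 20, n_bg = 1200, n_inv = 200,
                             q = c(A = 0, B = 0.5, C = 1),
                             missing_rate = 0, rad_sample_fraction = 0,
                             inversions = NULL, ...) {
  if (is.null(inversions))
    inversions <- list(inversion_spec("chr1", c(10e6, 15e6), n_sites = n_inv,
                                      inverted_freq = q))
  sim_config(
    n_per_lineage = stats::setNames(rep(n, 3), names(q)),
    chromosomes = data.frame(name = c("chr1", "chr2"),
                             length = c(25e6, 25e6)),
    n_background_snps = n_bg,
    background_F = stats::setNames(c(0.15, 0.08, 0.08), names(q)),
    inversions = inversions,
    missing_rate = missing_rate, rad_sample_fraction = rad_sample_fraction,
    seed = seed, ...)
}

# bare genotype matrix from a dosage matrix, sites 1 kb apart on one chrom
toy_geno <- function(dosage, chrom = "chr1", spacing = 1000) {
  dosage <- as.matrix(dosage)
  geno_matrix(dosage,
              samples = sprintf("s%02d", seq_len(nrow(dosage))),
              sites = data.frame(chrom = chrom,
                                 pos = spacing * seq_len(ncol(dosage)),
                                 ref = "A", alt = "T"))
}

# two-sided Fisher exact p by direct hypergeometric summation (oracle,
# independent of stats::fisher.test): sum the probabilities of all tables
# with the observed margins no more probable than the observed one.
fisher_p_oracle <- function(a, b, c_, d) {
  m <- a + c_      # total with term
  n <- b + d       # total without
  k <- a + b       # region genes
  lo <- max(0, k - n); hi <- min(k, m)
  x <- lo:hi
  pr <- stats::dhyper(x, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  sum(pr[pr <= p_obs * (1 + 1e-7)])
}

# Weir-Cockerham two-population theta from haploid allele counts, written
# out term by term (oracle for the vectorized implementation)
wc_oracle <- function(x1, n1, x2, n2) {
  p1 <- x1 / n1; p2 <- x2 / n2
  nbar <- (n1 + n2) / 2
  nc <- (n1 + n2) - (n1^2 + n2^2) / (n1 + n2)
  pbar <- (x1 + x2) / (n1 + n2)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / nbar
  a <- (nbar / nc) * (s2 - (pbar * (1 - pbar) - s2 / 2) / (nbar - 1))
  b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - s2 / 2)
  a / (a + b)
}

# rank-k covariance approximation of a window, materialized (oracle)
rank_k_approx <- function(wp) {
  A <- matrix(0, wp$n_samples, wp$n_samples)
  for (i in seq_len(wp$k))
    A <- A + wp$values[i] * tcrossprod(wp$vectors[, i])
  A / wp$total_norm
}
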