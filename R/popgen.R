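#' Principal component analysis of a genotype matrix
#'
#' Missing dosages are mean-imputed per site, sites are centred by their mean
#' dosage (no variance scaling by default, i.e. a covariance PCA on dosages),
#' and the eigendecomposition of the sample covariance gives scores and
#' loadings. Loading columns are unit-norm with a fixed sign convention: the
#' largest-magnitude entry of each column is positive.
#'
#' @param m a [geno_matrix()].
#' @param k number of components, at most `min(n_samples, n_sites)`.
#' @param scale if `TRUE`, additionally scale sites to unit variance.
#' @return An object of class `geno_pca`: list with `scores` (samples x k),
#'   `loadings` (sites x k), `explained_variance_fraction` (length k), and
#'   `site_index` (columns of `m` used).
#' @export
geno_pca <- function(m, k = 2, scale = FALSE) {
  stopifnot(n_samples(m) >= 2, k >= 1)
  k <- min(k, n_samples(m), n_sites(m))
  X <- impute_site_means(m$dosage)
  v <- apply(X, 2, stats::var)
  if (all(v < .Machine$double.eps))
    stop("geno_pca: all sites are monomorphic (zero total variance)")
  use <- if (scale) which(v > 0) else seq_len(ncol(X))
  pr <- stats::prcomp(X[, use, drop = FALSE], center = TRUE, scale. = scale)
  k <- min(k, ncol(pr$rotation))
  scores <- pr$x[, seq_len(k), drop = FALSE]
  loadings <- pr$rotation[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i_max <- which.max(abs(loadings[, j]))
    if (loadings[i_max, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  evf <- (pr$sdev^2 / sum(pr$sdev^2))[seq_len(k)]
  structure(
    list(scores = scores, loadings = loadings,
         explained_variance_fraction = evf,
         site_index = use, samples = m$samples),
    class = "geno_pca")
}

#' @export
print.geno_pca <- function(x, ...) {
  cat(sprintf("geno_pca: %d samples, %d components (%s%% of variance)\n",
              nrow(x$scores), ncol(x$scores),
              paste(sprintf("%.2f", 100 * x$explained_variance_fraction),
                    collapse = ", ")))
  invisible(x)
}

impute_site_means <- function(dos) {
  mu <- colMeans(dos, na.rm = TRUE)
  mu[is.nan(mu)] <- 0
  na_idx <- which(is.na(dos))
  if (length(na_idx))
    dos[na_idx] <- mu[((na_idx - 1) %/% nrow(dos)) + 1]
  dos
}

#' Per-individual heterozygosity
#'
#' The raw fraction of heterozygous calls: for each sample, the number of
#' dosage-1 sites over the number of non-missing sites in the subset. A
#' sample with no non-missing site gets `NA`.
#'
#' @param m a [geno_matrix()].
#' @param site_subset site column indices (default: all sites).
#' @return Named numeric vector, one value per sample.
#' @export
individual_heterozygosity <- function(m, site_subset = seq_len(n_sites(m))) {
  if (!length(site_subset)) stop("empty site subset")
  dos <- m$dosage[, site_subset, drop = FALSE]
  n_called <- rowSums(!is.na(dos))
  h <- rowSums(dos == 1, na.rm = TRUE) / n_called
  h[n_called == 0] <- NA_real_
  stats::setNames(h, m$samples)
}

#' Pairwise linkage disequilibrium (r-squared) between sites
#'
#' r-squared is the squared Pearson correlation of dosage vectors over the
#' samples non-missing at both sites (a genotypic r2). Pairs with fewer than
#' `min_shared` jointly called samples, a zero-variance member, or r-squared
#' below `r2_report_min` are omitted.
#'
#' @param m a [geno_matrix()].
#' @param site_indices site columns to consider (default: all).
#' @param r2_report_min report threshold (mirrors an LD-window r2 cutoff).
#' @param min_shared minimum jointly non-missing sample count per pair.
#' @return data.frame `(site_a, site_b, chrom_a, pos_a, chrom_b, pos_b,
#'   r_squared)` with `site_a < site_b` in matrix column order.
#' @export
pairwise_r2 <- function(m, site_indices = seq_len(n_sites(m)),
                        r2_report_min = 0.3, min_shared = 10) {
  stopifnot(length(site_indices) >= 2)
  dos <- m$dosage[, site_indices, drop = FALSE]
  r2 <- suppressWarnings(stats::cor(dos, use = "pairwise.complete.obs"))^2
  shared <- crossprod(!is.na(dos))
  ut <- upper.tri(r2)
  ok <- ut & !is.na(r2) & shared >= min_shared & r2 >= r2_report_min
  idx <- which(ok, arr.ind = TRUE)
  a <- site_indices[idx[, 1]]
  b <- site_indices[idx[, 2]]
  swap <- a > b
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  out <- data.frame(
    site_a = a, site_b = b,
    chrom_a = m$sites$chrom[a], pos_a = m$sites$pos[a],
    chrom_b = m$sites$chrom[b], pos_b = m$sites$pos[b],
    r_squared = r2[idx])
  out[order(out$site_a, out$site_b), , drop = FALSE]
}

#' Write an LD pair table
#' @param pairs data.frame from [pairwise_r2()]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_ld_pairs <- function(pairs, path) {
  utils::write.table(
    pairs[, c("chrom_a", "pos_a", "chrom_b", "pos_b", "r_squared")],
    path, sep = "\t", quote = FALSE, row.names = FALSE,
    col.names = c("CHR_A", "POS_A", "CHR_B", "POS_B", "R2"))
  invisible(path)
}

#' Per-site Weir-Cockerham FST between two groups
#'
#' The two-population Weir-Cockerham (1984) estimator in its haploid-count
#' formulation: each group's 2n observed alleles (from dosages over
#' non-missing genotypes) are treated as the allele sample. Estimates can be
#' slightly negative; they are reported as-is. Sites monomorphic across both
#' groups, or with a group entirely missing, yield `NA`.
#'
#' @param m a [geno_matrix()].
#' @param group_a,group_b disjoint sample id or index vectors, each of at
#'   least 2 samples.
#' @param site_subset site columns to scan (default: all).
#' @return data.frame `(chrom, pos, fst)` of class `fst_scan`.
#' @export
fst_scan <- function(m, group_a, group_b,
                     site_subset = seq_len(n_sites(m))) {
  ia <- if (is.character(group_a)) match(group_a, m$samples) else group_a
  ib <- if (is.character(group_b)) match(group_b, m$samples) else group_b
  if (anyNA(ia) || anyNA(ib)) stop("unknown sample id in group")
  if (length(intersect(ia, ib))) stop("groups must be disjoint")
  if (length(ia) < 2 || length(ib) < 2) stop("each group needs >= 2 samples")
  da <- m$dosage[ia, site_subset, drop = FALSE]
  db <- m$dosage[ib, site_subset, drop = FALSE]
  n1 <- 2 * colSums(!is.na(da))
  n2 <- 2 * colSums(!is.na(db))
  x1 <- colSums(da, na.rm = TRUE)
  x2 <- colSums(db, na.rm = TRUE)
  fst <- wc_fst_haploid(x1, n1, x2, n2)
  out <- data.frame(chrom = m$sites$chrom[site_subset],
                    pos = m$sites$pos[site_subset], fst = fst)
  class(out) <- c("fst_scan", "data.frame")
  out
}

# Weir-Cockerham (1984) theta-hat for r = 2 populations from haploid allele
# counts: x_i alternate alleles out of n_i sampled alleles.
wc_fst_haploid <- function(x1, n1, x2, n2) {
  ok <- n1 > 0 & n2 > 0
  p1 <- ifelse(ok, x1 / n1, NA_real_)
  p2 <- ifelse(ok, x2 / n2, NA_real_)
  nbar <- (n1 + n2) / 2
  nc <- (n1 + n2) - (n1^2 + n2^2) / (n1 + n2)   # r - 1 = 1
  pbar <- ifelse(ok, (x1 + x2) / (n1 + n2), NA_real_)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / nbar
  a <- (nbar / nc) * (s2 - (pbar * (1 - pbar) - s2 / 2) / (nbar - 1))
  b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - s2 / 2)
  fst <- a / (a + b)
  fst[!ok | (pbar %in% c(0, 1))] <- NA_real_   # monomorphic across groups
  fst
}

#' Write an FST scan table
#' @param scan data.frame from [fst_scan()]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_fst_scan <- function(scan, path) {
  utils::write.table(scan, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = c("CHR", "POS", "FST"))
  invisible(path)
}
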