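#' Split sites into non-sliding SNP windows
#'
#' Consecutive, non-overlapping blocks of exactly `window_snps` sites per
#' chromosome; a trailing remainder shorter than a full window is discarded,
#' and windows never span chromosome boundaries.
#'
#' @param m a [geno_matrix()].
#' @param window_snps sites per window (>= 2).
#' @return data.frame with one row per window: `window`, `chrom`,
#'   `first_site`, `last_site` (column indices into `m`), `start_bp`,
#'   `end_bp`.
#' @export
make_windows <- function(m, window_snps = 50) {
  stopifnot(window_snps >= 2)
  rows <- list()
  for (chrom in unique(m$sites$chrom)) {
    idx <- which(m$sites$chrom == chrom)
    n_win <- length(idx) %/% window_snps
    if (n_win == 0) {
      message("make_windows: ", chrom, " has fewer than ", window_snps,
              " sites; no windows")
      next
    }
    for (w in seq_len(n_win)) {
      span <- idx[((w - 1) * window_snps + 1):(w * window_snps)]
      rows[[length(rows) + 1]] <- data.frame(
        chrom = chrom, first_site = span[1], last_site = span[length(span)],
        start_bp = m$sites$pos[span[1]], end_bp = m$sites$pos[span[length(span)]],
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(window = integer(0), chrom = character(0),
                      first_site = integer(0), last_site = integer(0),
                      start_bp = integer(0), end_bp = integer(0)))
  out <- do.call(rbind, rows)
  cbind(window = seq_len(nrow(out)), out)
}

#' Rank-k spectral summary of one window
#'
#' Missing dosages are mean-imputed within the window, sites are centred, and
#' the n_samples x n_samples covariance of the windowed dosage matrix is
#' eigendecomposed. The summary keeps the top-k eigenpairs plus the Frobenius
#' norm of the full covariance, which is what window-to-window distances are
#' normalized by.
#'
#' @param m a [geno_matrix()].
#' @param window one row of [make_windows()] output (or a list with
#'   `first_site`/`last_site`).
#' @param k number of eigenpairs to keep.
#' @return An object of class `window_pca`: `values` (top-k eigenvalues,
#'   non-negative non-increasing), `vectors` (n_samples x k, unit columns),
#'   `total_norm` (Frobenius norm of the covariance), `monomorphic` flag.
#' @export
window_pca <- function(m, window, k = 2) {
  idx <- window$first_site:window$last_site
  X <- impute_site_means(m$dosage[, idx, drop = FALSE])
  X <- sweep(X, 2, colMeans(X))
  C <- tcrossprod(X) / (ncol(X) - 1)
  total_norm <- sqrt(sum(C^2))
  mono <- total_norm < .Machine$double.eps
  e <- eigen(C, symmetric = TRUE)
  kk <- min(k, length(e$values))
  structure(
    list(values = pmax(e$values[seq_len(kk)], 0),
         vectors = e$vectors[, seq_len(kk), drop = FALSE],
         total_norm = total_norm, k = kk,
         n_samples = nrow(C), monomorphic = mono),
    class = "window_pca")
}

#' Distance between two window spectral summaries
#'
#' The Frobenius norm of the difference between the two rank-k covariance
#' approximations (sum of lambda_i v_i v_i'), each normalized by its window's
#' total covariance norm. Computed from the eigenpairs without forming the
#' n x n matrices:
#' ||A1 - A2||_F^2 = sum(l1^2) + sum(l2^2) - 2 * sum_ij l1_i l2_j (v1_i . v2_j)^2.
#'
#' @param a,b `window_pca` objects with equal k and sample count.
#' @return A non-negative scalar; 0 for identical windows.
#' @export
window_distance <- function(a, b) {
  if (a$n_samples != b$n_samples) stop("mismatched sample counts")
  if (a$k != b$k) stop("mismatched k")
  l1 <- a$values / a$total_norm
  l2 <- b$values / b$total_norm
  cross <- crossprod(a$vectors, b$vectors)^2
  d2 <- sum(l1^2) + sum(l2^2) - 2 * sum(outer(l1, l2) * cross)
  sqrt(max(d2, 0))
}

#' All pairwise window distances
#'
#' @param wpcas list of `window_pca` objects; windows flagged monomorphic are
#'   excluded.
#' @return list with `D` (symmetric distance matrix over retained windows)
#'   and `retained` (indices into `wpcas`).
#' @export
window_distance_matrix <- function(wpcas) {
  retained <- which(!vapply(wpcas, `[[`, logical(1), "monomorphic"))
  n <- length(retained)
  D <- matrix(0, n, n)
  if (n >= 2) {
    for (i in 1:(n - 1)) {
      for (j in (i + 1):n) {
        d <- window_distance(wpcas[[retained[i]]], wpcas[[retained[j]]])
        D[i, j] <- d
        D[j, i] <- d
      }
    }
  }
  list(D = D, retained = retained)
}

#' Classical (Torgerson) multidimensional scaling
#'
#' Double-centres -D^2/2, eigendecomposes, and scales eigenvectors by the
#' square roots of the positive eigenvalues. Axes are ordered by eigenvalue
#' with the sign fixed so each axis's largest-magnitude coordinate is
#' positive. A warning is raised when a negative eigenvalue exceeds half the
#' largest in magnitude (strongly non-Euclidean input).
#'
#' @param D square symmetric distance matrix with zero diagonal.
#' @param n_axes number of axes to retain (default 3).
#' @return An object of class `mds_result`: `points` (windows x n_axes,
#'   zero-padded if the positive spectrum is smaller) and `eig` (all
#'   eigenvalues).
#' @export
classical_mds <- function(D, n_axes = 3) {
  D <- as.matrix(D)
  if (nrow(D) != ncol(D) || max(abs(D - t(D))) > 1e-8 ||
      max(abs(diag(D))) > 1e-12)
    stop("D must be square, symmetric with zero diagonal")
  n <- nrow(D)
  n_axes <- min(n_axes, n - 1)
  if (max(D) == 0)   # all points coincide: zero embedding, zero spectrum
    return(structure(list(points = matrix(0, n, n_axes,
                                          dimnames = list(NULL,
                                            paste0("MDS", seq_len(n_axes)))),
                          eig = rep(0, n)),
                     class = "mds_result"))
  # cmdscale warns when fewer than n_axes eigenvalues are positive; the
  # zero-padding below handles that case
  fit <- suppressWarnings(stats::cmdscale(D, k = n_axes, eig = TRUE))
  if (min(fit$eig) < -0.5 * max(abs(fit$eig)))
    warning("classical_mds: strongly non-Euclidean distances")
  pts <- fit$points
  if (is.null(dim(pts)) || ncol(pts) < n_axes) {
    pad <- matrix(0, n, n_axes)
    if (!is.null(pts) && length(pts)) pad[, seq_len(ncol(pts))] <- pts
    pts <- pad
  }
  for (j in seq_len(ncol(pts))) {
    i_max <- which.max(abs(pts[, j]))
    if (pts[i_max, j] < 0) pts[, j] <- -pts[, j]
  }
  colnames(pts) <- paste0("MDS", seq_len(ncol(pts)))
  structure(list(points = pts, eig = fit$eig), class = "mds_result")
}

#' Tukey-fence outlier windows along one MDS axis
#'
#' Uses `boxplot.stats` (Tukey hinges, 1.5 x IQR fences): a window is an
#' outlier when its coordinate falls outside
#' [Q1 - 1.5 IQR, Q3 + 1.5 IQR].
#'
#' @param mds an `mds_result` from [classical_mds()].
#' @param axis axis number (column of `mds$points`).
#' @return An object of class `outlier_set`: `axis`, `outliers` (row indices
#'   of `mds$points`), `fences` (lower, upper).
#' @export
detect_outlier_windows <- function(mds, axis = 1) {
  x <- mds$points[, axis]
  if (length(x) < 5) stop("need at least 5 windows")
  bs <- grDevices::boxplot.stats(x)
  iqr <- bs$stats[4] - bs$stats[2]
  fences <- c(lower = bs$stats[2] - 1.5 * iqr, upper = bs$stats[4] + 1.5 * iqr)
  structure(
    list(axis = axis, outliers = which(x < fences[1] | x > fences[2]),
         fences = fences),
    class = "outlier_set")
}

#' Summarize outlier windows by chromosome
#'
#' For each chromosome carrying at least one outlier window: the count and
#' its percentage of the axis's outliers, formatted to one decimal as in
#' figure-legend style summaries ("36.0%").
#'
#' @param outliers an `outlier_set` from [detect_outlier_windows()], whose
#'   indices refer to rows of `windows`.
#' @param windows the window table the MDS was computed over (rows aligned
#'   with the distance matrix / MDS points).
#' @return data.frame `(chrom, n_outliers, pct, pct_label)` sorted by
#'   decreasing count; zero rows when there are no outliers.
#' @export
summarize_outliers <- function(outliers, windows) {
  if (!length(outliers$outliers))
    return(data.frame(chrom = character(0), n_outliers = integer(0),
                      pct = numeric(0), pct_label = character(0)))
  tab <- table(windows$chrom[outliers$outliers])
  total <- sum(tab)
  out <- data.frame(chrom = names(tab), n_outliers = as.integer(tab),
                    pct = round(100 * as.integer(tab) / total, 1),
                    stringsAsFactors = FALSE)
  out$pct_label <- sprintf("%.1f%%", out$pct)
  out[order(-out$n_outliers, out$chrom), , drop = FALSE]
}

#' Run the full local-PCA / MDS outlier stage
#'
#' Windows the (unpruned) matrix, computes per-window rank-k summaries,
#' the window distance matrix, a classical MDS embedding, and Tukey outliers
#' along each retained axis.
#'
#' @param m a [geno_matrix()].
#' @param window_snps sites per window.
#' @param k eigenpairs kept per window.
#' @param n_axes MDS axes retained.
#' @return list with `windows` (retained windows only), `mds`, `outliers`
#'   (list of `outlier_set`, one per axis), `summaries` (per-axis
#'   [summarize_outliers()] tables).
#' @export
local_pca_scan <- function(m, window_snps = 50, k = 2, n_axes = 3) {
  win <- make_windows(m, window_snps)
  if (nrow(win) < 5) stop("too few windows for MDS outlier detection")
  wpcas <- lapply(seq_len(nrow(win)), function(i)
    window_pca(m, win[i, ], k = k))
  dm <- window_distance_matrix(wpcas)
  win_ret <- win[dm$retained, , drop = FALSE]
  mds <- classical_mds(dm$D, n_axes = n_axes)
  axes <- seq_len(ncol(mds$points))
  outliers <- lapply(axes, function(a) detect_outlier_windows(mds, a))
  summaries <- lapply(outliers, function(o) summarize_outliers(o, win_ret))
  names(outliers) <- names(summaries) <- paste0("MDS", axes)
  list(windows = win_ret, mds = mds, outliers = outliers,
       summaries = summaries)
}
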