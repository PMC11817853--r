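test_that("windows are exact, non-overlapping and chromosome-bounded", {
  m <- toy_geno(matrix(rbinom(5 * 120, 2, 0.5), 5, 120))
  w <- make_windows(m, 50)
  expect_equal(nrow(w), 2L)   # 120 %/% 50, trailing 20 discarded
  expect_equal(w$first_site, c(1L, 51L))
  expect_equal(w$last_site, c(50L, 100L))
  w1 <- make_windows(toy_geno(matrix(rbinom(5 * 50, 2, 0.5), 5, 50)), 50)
  expect_equal(nrow(w1), 1L)
  # two chromosomes of 60 sites each: one window per chromosome, no crossing
  dos <- matrix(rbinom(5 * 120, 2, 0.5), 5, 120)
  m2 <- geno_matrix(dos, sprintf("s%d", 1:5),
                    data.frame(chrom = rep(c("chr1", "chr2"), each = 60),
                               pos = rep(1000 * (1:60), 2)))
  w2 <- make_windows(m2, 50)
  expect_equal(nrow(w2), 2L)
  expect_equal(w2$chrom, c("chr1", "chr2"))
  expect_message(make_windows(toy_geno(matrix(1, 5, 10)), 50), "fewer than")
})

test_that("window PCA matches a dense eigendecomposition oracle", {
  set.seed(7)
  m <- toy_geno(matrix(rbinom(30 * 50, 2, 0.4), 30, 50))
  m$dosage[sample(length(m$dosage), 50)] <- NA
  w <- make_windows(m, 50)
  wp <- window_pca(m, w[1, ], k = 2)
  wp2 <- window_pca(m, w[1, ], k = 2)
  expect_identical(wp, wp2)   # deterministic
  # oracle: impute, centre, full covariance, dense eigen
  X <- m$dosage
  mu <- colMeans(X, na.rm = TRUE)
  for (j in seq_len(ncol(X))) X[is.na(X[, j]), j] <- mu[j]
  X <- sweep(X, 2, colMeans(X))
  C <- X %*% t(X) / (ncol(X) - 1)
  e <- eigen(C, symmetric = TRUE)
  expect_equal(wp$values, e$values[1:2], tolerance = 1e-8)
  expect_equal(abs(diag(crossprod(wp$vectors, e$vectors[, 1:2]))), c(1, 1),
               tolerance = 1e-8)
  expect_equal(wp$total_norm, sqrt(sum(C^2)), tolerance = 1e-8)
  # rank-1 window: all sites identical
  m1 <- toy_geno(matrix(rep(rbinom(20, 2, 0.5), 10), 20, 10))
  wp1 <- window_pca(m1, list(first_site = 1, last_site = 10), k = 3)
  expect_lt(wp1$values[2] / wp1$values[1], 1e-10)
})

test_that("window distance equals the brute-force matrix construction", {
  set.seed(8)
  m <- toy_geno(matrix(rbinom(25 * 300, 2, 0.45), 25, 300))
  w <- make_windows(m, 50)
  wp <- lapply(seq_len(nrow(w)), function(i) window_pca(m, w[i, ], k = 2))
  expect_equal(window_distance(wp[[1]], wp[[1]]), 0)
  for (i in 1:5) for (j in (i + 1):6) {
    d <- window_distance(wp[[i]], wp[[j]])
    expect_equal(d, window_distance(wp[[j]], wp[[i]]))   # symmetric
    oracle <- sqrt(sum((rank_k_approx(wp[[i]]) - rank_k_approx(wp[[j]]))^2))
    expect_equal(d, oracle, tolerance = 1e-8)
  }
  # distance matrix: non-negative, symmetric, zero diagonal, triangle inequality
  D <- window_distance_matrix(wp)$D
  expect_true(all(D >= 0))
  expect_equal(D, t(D))
  expect_equal(diag(D), rep(0, nrow(D)))
  for (tri in list(c(1, 2, 3), c(2, 4, 6), c(1, 3, 5)))
    expect_lte(D[tri[1], tri[3]],
               D[tri[1], tri[2]] + D[tri[2], tri[3]] + 1e-8)
})

test_that("classical MDS embeds Euclidean distances exactly", {
  # three collinear points with distances 1, 1, 2 -> a 1-D embedding
  D <- matrix(c(0, 1, 2, 1, 0, 1, 2, 1, 0), 3)
  fit <- classical_mds(D, n_axes = 2)
  expect_equal(as.matrix(dist(fit$points[, 1])), unname(D), tolerance = 1e-10,
               ignore_attr = TRUE)
  # all-zero distances -> all coordinates zero
  fit0 <- classical_mds(matrix(0, 4, 4), n_axes = 3)
  expect_true(all(fit0$points == 0))
  # round-trip of a random Euclidean cloud
  set.seed(10)
  pts <- matrix(rnorm(20 * 3), 20, 3)
  De <- as.matrix(dist(pts))
  fit3 <- classical_mds(De, n_axes = 3)
  expect_equal(as.matrix(dist(fit3$points)), De, tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_error(classical_mds(matrix(1:9, 3)), "symmetric")
})

test_that("MDS rows permute with window order (up to sign)", {
  set.seed(12)
  pts <- matrix(rnorm(15 * 2), 15, 2)
  D <- as.matrix(dist(pts))
  perm <- sample(15)
  f1 <- classical_mds(D, 2)
  f2 <- classical_mds(D[perm, perm], 2)
  for (j in 1:2)
    expect_equal(abs(f2$points[, j]), abs(f1$points[perm, j]),
                 tolerance = 1e-8)
})

test_that("Tukey-fence outliers match hinge arithmetic", {
  mk <- function(v) structure(list(points = matrix(v, ncol = 1)),
                              class = "mds_result")
  o <- detect_outlier_windows(mk(c(1:9, 100)), 1)
  expect_equal(o$outliers, 10L)   # hinges 3 and 7.5, upper fence 14.25
  expect_true(all(c(1:9, 100)[o$outliers] > o$fences["upper"]))
  expect_equal(detect_outlier_windows(mk(c(-3, -2, -1, 0, 1, 2, 3)), 1)$outliers,
               integer(0))
  expect_equal(detect_outlier_windows(mk(rep(2, 8)), 1)$outliers, integer(0))
  expect_error(detect_outlier_windows(mk(1:4), 1), "at least 5")
})

test_that("outlier summaries report per-chromosome counts and percentages", {
  win <- data.frame(chrom = c(rep("Lca05", 9), rep("other", 16)))
  o <- structure(list(axis = 1, outliers = 1:25), class = "outlier_set")
  s <- summarize_outliers(o, win)
  expect_equal(s$n_outliers[s$chrom == "Lca05"], 9L)
  expect_equal(s$pct_label[s$chrom == "Lca05"], "36.0%")
  empty <- structure(list(axis = 1, outliers = integer(0)),
                     class = "outlier_set")
  expect_equal(nrow(summarize_outliers(empty, win)), 0L)
})

test_that("windows overlapping a simulated inversion become MDS outliers", {
  sim <- simulate_cohort(small_sim_config(seed = 17, n = 25, n_bg = 2500,
                                          n_inv = 300))
  f <- filter_sites(sim$geno)
  lp <- local_pca_scan(f)
  ts <- sim$truth$spans
  w <- lp$windows
  ov <- which(w$chrom == ts$chrom & w$end_bp >= ts$start & w$start_bp <= ts$end)
  flagged <- unique(unlist(lapply(lp$outliers, `[[`, "outliers")))
  expect_gte(mean(ov %in% flagged), 0.8)
})
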