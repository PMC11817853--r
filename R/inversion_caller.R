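#' Detect extended high-LD blocks on one chromosome
#'
#' Each site pair with r-squared above `r2_min` is projected onto its bp
#' interval; intervals separated by gaps of at most `max_gap_bp` are merged,
#' and merged spans of at least `min_span_bp` are reported, largest first.
#'
#' @param pairs data.frame from [pairwise_r2()], all from one chromosome.
#' @param r2_min minimum r-squared for a pair to contribute (default 0.8).
#' @param min_span_bp minimum reported block span.
#' @param max_gap_bp maximum gap bridged when merging intervals.
#' @return data.frame `(chrom, start, end, span_bp, n_pairs)` of class
#'   `candidate_regions`; zero rows if nothing qualifies.
#' @export
detect_ld_blocks <- function(pairs, r2_min = 0.8, min_span_bp = 1e6,
                             max_gap_bp = 5e5) {
  if (nrow(pairs) && length(unique(c(pairs$chrom_a, pairs$chrom_b))) > 1)
    stop("detect_ld_blocks expects pairs from a single chromosome")
  empty <- data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), span_bp = numeric(0),
                      n_pairs = integer(0))
  class(empty) <- c("candidate_regions", "data.frame")
  hi <- pairs[pairs$r_squared > r2_min, , drop = FALSE]
  if (!nrow(hi)) return(empty)
  iv <- data.frame(start = pmin(hi$pos_a, hi$pos_b),
                   end = pmax(hi$pos_a, hi$pos_b))
  iv <- iv[order(iv$start, iv$end), , drop = FALSE]
  merged <- list()
  cur <- c(iv$start[1], iv$end[1]); cur_n <- 1L
  if (nrow(iv) > 1) {
    for (i in 2:nrow(iv)) {
      if (iv$start[i] - cur[2] <= max_gap_bp) {
        cur[2] <- max(cur[2], iv$end[i]); cur_n <- cur_n + 1L
      } else {
        merged[[length(merged) + 1]] <- c(cur, cur_n)
        cur <- c(iv$start[i], iv$end[i]); cur_n <- 1L
      }
    }
  }
  merged[[length(merged) + 1]] <- c(cur, cur_n)
  res <- do.call(rbind, merged)
  out <- data.frame(chrom = hi$chrom_a[1], start = res[, 1], end = res[, 2],
                    span_bp = res[, 2] - res[, 1] + 1, n_pairs = res[, 3])
  out <- out[out$span_bp >= min_span_bp, , drop = FALSE]
  out <- out[order(-out$span_bp), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("candidate_regions", "data.frame")
  out
}

# deterministic 1-D Lloyd k-means; init centers supplied. Ties and empty
# clusters are resolved by keeping the previous center (flagged degenerate).
lloyd_1d <- function(x, centers, max_iter = 100) {
  k <- length(centers)
  assign_old <- rep(0L, length(x))
  for (it in seq_len(max_iter)) {
    d <- abs(outer(x, centers, "-"))
    grp <- max.col(-d, ties.method = "first")
    if (identical(grp, assign_old)) break
    assign_old <- grp
    for (j in seq_len(k))
      if (any(grp == j)) centers[j] <- mean(x[grp == j])
  }
  list(cluster = grp, centers = centers,
       degenerate = !all(seq_len(k) %in% grp))
}

#' Provisional three-cluster karyotypes from PC1 of a candidate region
#'
#' PCA over the region's sites, then deterministic 1-D k-means (k = 3,
#' centers initialized at the minimum, median and maximum PC1 score).
#' Clusters are ordered along PC1 and labelled provisionally
#' `c("low", "mid", "high")`, the middle cluster being the putative
#' heterokaryotypes. A region where one karyotype is absent yields an empty
#' (degenerate) cluster, flagged rather than raised as an error.
#'
#' @param m a [geno_matrix()].
#' @param region one-row data.frame with `chrom`, `start`, `end`.
#' @param min_sites minimum polymorphic sites required in the region.
#' @return list with `pca` (a [geno_pca()] over region sites), `cluster`
#'   (1 = low PC1, 2 = mid, 3 = high, per sample), `degenerate` flag,
#'   `site_index` (region site columns in `m`).
#' @export
karyotype_by_pc1 <- function(m, region, min_sites = 20) {
  idx <- sites_in_span(m, region$chrom, region$start, region$end)
  dos <- m$dosage[, idx, drop = FALSE]
  poly <- apply(dos, 2, function(v) {
    v <- v[!is.na(v)]; length(v) > 0 && stats::var(v) > 0
  })
  if (sum(poly) < min_sites)
    stop("region has fewer than ", min_sites, " polymorphic sites")
  sub <- subset_geno(m, sites = idx)
  pca <- geno_pca(sub, k = 2)
  pc1 <- pca$scores[, 1]
  if (length(unique(pc1)) < 3) stop("fewer than 3 distinct PC1 values")
  init <- c(min(pc1), stats::median(pc1), max(pc1))
  if (anyDuplicated(init))
    init <- init + c(0, .Machine$double.eps^0.5, 0) * diff(range(pc1))
  km <- lloyd_1d(pc1, init)
  ord <- order(km$centers)
  cluster <- match(km$cluster, ord)
  # degenerate when a cluster is empty or two centers nearly coincide
  # relative to the widest gap (a missing karyotype class split in two)
  gaps <- diff(sort(km$centers))
  degenerate <- km$degenerate || min(gaps) < 0.25 * max(gaps)
  list(pca = pca, cluster = stats::setNames(cluster, m$samples),
       degenerate = degenerate, site_index = idx)
}

#' Select diagnostic SNPs from PC1 loadings
#'
#' Sites ranked by absolute PC1 loading, descending; the top
#' `ceiling(top_fraction * n_sites)` are returned. Ties at the cutoff are
#' broken by genomic position, ascending.
#'
#' @param pca a [geno_pca()] over the region's sites.
#' @param m the [geno_matrix()] the PCA was computed from (for positions).
#' @param site_index region site columns in `m` that `pca` covers.
#' @param top_fraction fraction of sites to keep (default 0.05).
#' @return Integer vector of site column indices into `m`.
#' @export
select_diagnostic_snps <- function(pca, m, site_index,
                                   top_fraction = 0.05) {
  stopifnot(top_fraction > 0, top_fraction <= 1)
  load1 <- abs(pca$loadings[, 1])
  region_sites <- site_index[pca$site_index]
  n_take <- ceiling(top_fraction * length(load1))
  ord <- order(-load1, m$sites$pos[region_sites])
  sort(region_sites[ord[seq_len(n_take)]])
}

#' Call inversion karyotypes from diagnostic SNPs
#'
#' Each diagnostic site is polarized so the anchor group's major allele is
#' the ancestral allele (dosage counts inverted-arrangement alleles after
#' polarization). Per sample, the mean polarized dosage over non-missing
#' diagnostics is thresholded: AHom below 0.5, Het in `[0.5, 1.5]`, RHom
#' above 1.5. Samples observing fewer than `min_diagnostics` diagnostic
#' sites are left unassigned.
#'
#' @param m a [geno_matrix()].
#' @param diagnostics diagnostic site column indices.
#' @param anchor_group sample ids/indices assumed enriched for the ancestral
#'   arrangement (polarity anchor).
#' @param min_diagnostics minimum observed diagnostics for a call (default 5).
#' @return An object of class `karyotype_call`: data.frame `(sample,
#'   genotype, mean_dosage, n_diagnostics)` plus attributes `diagnostics`
#'   and `flipped` (which sites were polarity-flipped).
#' @export
call_karyotypes <- function(m, diagnostics, anchor_group,
                            min_diagnostics = 5) {
  if (!length(diagnostics)) stop("no diagnostic sites supplied")
  ia <- if (is.character(anchor_group)) match(anchor_group, m$samples)
        else anchor_group
  if (!length(ia) || anyNA(ia)) stop("invalid anchor group")
  dos <- m$dosage[, diagnostics, drop = FALSE]
  anchor_mean <- colMeans(dos[ia, , drop = FALSE], na.rm = TRUE)
  if (all(is.nan(anchor_mean)))
    stop("anchor group entirely missing at all diagnostic sites")
  flip <- !is.nan(anchor_mean) & anchor_mean > 1
  dos[, flip] <- 2 - dos[, flip]
  n_obs <- rowSums(!is.na(dos))
  mean_dos <- rowMeans(dos, na.rm = TRUE)
  genotype <- ifelse(mean_dos < 0.5, "AHom",
                     ifelse(mean_dos <= 1.5, "Het", "RHom"))
  genotype[n_obs < min_diagnostics] <- "unassigned"
  genotype[n_obs == 0] <- "unassigned"
  out <- data.frame(sample = m$samples, genotype = genotype,
                    mean_dosage = ifelse(n_obs == 0, NA_real_, mean_dos),
                    n_diagnostics = n_obs, stringsAsFactors = FALSE)
  attr(out, "diagnostics") <- diagnostics
  attr(out, "flipped") <- which(flip)
  class(out) <- c("karyotype_call", "data.frame")
  out
}

#' Heterozygosity summaries per karyotype class
#'
#' Median and quartiles of per-individual heterozygosity over the region's
#' sites, split by called karyotype. Real inversions show the signature
#' ordering Het > AHom > RHom (heterokaryotypes carry both arrangements;
#' the inverted arrangement has reduced diversity).
#'
#' @param m a [geno_matrix()].
#' @param call a `karyotype_call`.
#' @param site_index region site columns.
#' @return data.frame `(genotype, n, q1, median, q3)`, one row per class
#'   with at least one sample.
#' @export
heterozygosity_by_karyotype <- function(m, call, site_index) {
  het <- individual_heterozygosity(m, site_index)
  cls <- call$genotype[match(m$samples, call$sample)]
  keep <- cls %in% c("AHom", "Het", "RHom") & !is.na(het)
  if (!any(keep)) stop("no called samples with observed heterozygosity")
  agg <- lapply(split(het[keep], cls[keep]), function(v) {
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(n = length(v), q1 = q[1], median = q[2], q3 = q[3])
  })
  out <- cbind(genotype = names(agg), do.call(rbind, agg))
  rownames(out) <- NULL
  out
}

#' Confirm an inversion with a homokaryotype FST scan
#'
#' Scans per-site Weir-Cockerham FST between AHom and RHom samples across the
#' region plus flanks, then refines boundaries as the outermost positions at
#' which a rolling-median FST exceeds `run_factor` times the flank median
#' (floored at `flank_floor`, since the flank median of a null Weir-Cockerham
#' scan straddles zero and a multiple of it alone is not a usable threshold).
#' The region is flagged `fst_elevated` when mean FST inside the input region
#' is at least `elevated_min`.
#'
#' @param m a [geno_matrix()] (typically restricted to one lineage with both
#'   homokaryotypes, mirroring the case-control design).
#' @param call a `karyotype_call`.
#' @param region one-row data.frame `(chrom, start, end)`.
#' @param flank_bp flank width on each side (default 5e6).
#' @param roll_snps rolling-median window in SNPs (default 25).
#' @param run_factor multiple of the flank median defining the elevated run.
#' @param flank_floor lower floor for the flank median (default 1e-3).
#' @param elevated_min mean inside-region FST needed for the evidence flag.
#' @return list with `scan` (the [fst_scan()] table over region + flanks),
#'   `boundaries` (named start/end, `NA` if no run), `fst_elevated`,
#'   `inside_mean`, `flank_mean`, `flank_median`; or `NULL` (with a warning)
#'   when fewer than 2 samples of either homokaryotype are available.
#' @export
fst_confirm <- function(m, call, region, flank_bp = 5e6, roll_snps = 25,
                        run_factor = 5, flank_floor = 0.01,
                        elevated_min = 0.25) {
  ah <- call$sample[call$genotype == "AHom"]
  rh <- call$sample[call$genotype == "RHom"]
  ah <- intersect(ah, m$samples); rh <- intersect(rh, m$samples)
  if (length(ah) < 2 || length(rh) < 2) {
    warning("fst_confirm: fewer than 2 samples in a homokaryotype class; ",
            "skipping FST confirmation")
    return(NULL)
  }
  lo <- max(1, region$start - flank_bp)
  hi <- region$end + flank_bp
  idx <- sites_in_span(m, region$chrom, lo, hi)
  scan <- fst_scan(m, ah, rh, site_subset = idx)
  ok <- !is.na(scan$fst)
  pos <- scan$pos[ok]; fst <- scan$fst[ok]
  inside <- pos >= region$start & pos <= region$end
  inside_mean <- mean(fst[inside])
  flank_mean <- if (any(!inside)) mean(fst[!inside]) else NA_real_
  flank_median <- if (any(!inside)) stats::median(fst[!inside]) else NA_real_
  thr <- run_factor * max(flank_median, flank_floor, na.rm = TRUE)
  rmed <- rolling_median(fst, roll_snps)
  elev <- rmed > thr
  boundaries <- c(start = NA_real_, end = NA_real_)
  if (any(elev, na.rm = TRUE)) {
    # outermost extent of the elevated stretch: the rolling median already
    # smooths over interspersed low-FST sites
    hits <- which(elev)
    boundaries <- c(start = pos[min(hits)], end = pos[max(hits)])
  }
  list(scan = scan, boundaries = boundaries,
       fst_elevated = is.finite(inside_mean) && inside_mean >= elevated_min,
       inside_mean = inside_mean, flank_mean = flank_mean,
       flank_median = flank_median)
}

rolling_median <- function(x, w) {
  n <- length(x)
  if (n < w) return(rep(NA_real_, n))
  half <- w %/% 2
  vapply(seq_len(n), function(i) {
    lo <- max(1, i - half); hi <- min(n, i + half)
    stats::median(x[lo:hi])
  }, numeric(1))
}

#' Karyotype frequencies by sampling location
#'
#' Per location: class counts and the inverted-allele frequency
#' `(Het + 2 RHom) / (2 assigned)`. Locations with no assigned samples are
#' omitted.
#'
#' @param call a `karyotype_call`.
#' @param meta sample metadata with `sample` and `location` columns.
#' @return data.frame `(location, n_AHom, n_Het, n_RHom, n_assigned,
#'   inverted_freq)`.
#' @export
frequency_by_location <- function(call, meta) {
  md <- meta[match(call$sample, meta$sample), , drop = FALSE]
  keep <- call$genotype %in% c("AHom", "Het", "RHom")
  if (!any(keep))
    return(data.frame(location = character(0), n_AHom = integer(0),
                      n_Het = integer(0), n_RHom = integer(0),
                      n_assigned = integer(0), inverted_freq = numeric(0)))
  tab <- table(md$location[keep],
               factor(call$genotype[keep], c("AHom", "Het", "RHom")))
  out <- data.frame(location = rownames(tab),
                    n_AHom = as.integer(tab[, "AHom"]),
                    n_Het = as.integer(tab[, "Het"]),
                    n_RHom = as.integer(tab[, "RHom"]),
                    stringsAsFactors = FALSE)
  out$n_assigned <- out$n_AHom + out$n_Het + out$n_RHom
  out$inverted_freq <- (out$n_Het + 2 * out$n_RHom) / (2 * out$n_assigned)
  rownames(out) <- NULL
  out
}

#' Write candidate regions as BED
#'
#' Converts internal 1-based inclusive spans to BED's 0-based half-open.
#'
#' @param regions a `candidate_regions` data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_regions_bed <- function(regions, path) {
  bed <- data.frame(regions$chrom, as.integer(regions$start) - 1L,
                    as.integer(regions$end))
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
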