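#' Discover and genotype chromosomal inversions in a genotype matrix
#'
#' The central fitting function. Runs the full discovery chain on called
#' genotypes:
#' site filtering (call rate, MAF) and LD pruning for the genome-wide PCA;
#' windowed local PCA with window-covariance distances, classical MDS and
#' Tukey-fence outlier windows on the unpruned filtered matrix; per-site
#' LD on chromosomes carrying outlier windows and merging of high-r2 pairs
#' into candidate blocks; per-region PC1 three-cluster karyotyping with
#' diagnostic SNPs (top PC1 loadings); heterozygosity-by-karyotype
#' summaries; a homokaryotype Weir-Cockerham FST confirmation scan with
#' boundary refinement; and karyotype frequencies by sampling location.
#'
#' @param geno a [geno_matrix()] of called diploid genotypes.
#' @param meta sample metadata (`sample`, `location`, `lineage`,
#'   `data_type`), one row per sample.
#' @param window_snps local-PCA window size in SNPs (default 50).
#' @param k eigenpairs kept per window (default 2).
#' @param mds_axes MDS axes retained (default 3).
#' @param r2_block minimum r-squared defining a high-LD pair (default 0.8).
#' @param min_span_bp,max_gap_bp LD-block merge parameters.
#' @param top_loading_fraction fraction of region sites kept as diagnostic
#'   SNPs (default 0.05).
#' @param min_presence,min_maf site filters (defaults 0.90 and 0.05).
#' @param prune_r2,prune_window_bp LD-pruning parameters for the global PCA
#'   (defaults 0.20 and 10000).
#' @param anchor_lineage lineage assumed ancestral-arrangement-enriched;
#'   `NULL` picks the lineage with the lowest mean diagnostic dosage.
#' @param fst_lineage lineage for the homokaryotype FST scan; `NULL` picks
#'   the lineage with the most balanced homokaryotype counts.
#' @param flank_bp FST-scan flank width (default 5e6).
#' @param min_diagnostics minimum observed diagnostic SNPs for a karyotype
#'   call (default 5).
#' @return An object of class `inversion_scan`; see [summary.inversion_scan()].
#' @examples
#' sim <- simulate_cohort(sim_config(
#'   n_per_lineage = c(A = 20, B = 20, C = 20),
#'   n_background_snps = 1500,
#'   inversions = list(inversion_spec("chr1", c(10e6, 15e6), n_sites = 200,
#'     inverted_freq = c(A = 0, B = 0.5, C = 1))),
#'   missing_rate = 0, rad_sample_fraction = 0, seed = 7))
#' fit <- inversion_scan(sim$geno, sim$meta)
#' fit
#' @export
inversion_scan <- function(geno, meta,
                           window_snps = 50, k = 2, mds_axes = 3,
                           r2_block = 0.8, min_span_bp = 1e6,
                           max_gap_bp = 5e5,
                           top_loading_fraction = 0.05,
                           min_presence = 0.90, min_maf = 0.05,
                           prune_r2 = 0.20, prune_window_bp = 10000,
                           anchor_lineage = NULL, fst_lineage = NULL,
                           flank_bp = 5e6, min_diagnostics = 5) {
  meta <- check_metadata(geno, meta)
  params <- list(window_snps = window_snps, k = k, mds_axes = mds_axes,
                 r2_block = r2_block, min_span_bp = min_span_bp,
                 max_gap_bp = max_gap_bp,
                 top_loading_fraction = top_loading_fraction,
                 min_presence = min_presence, min_maf = min_maf,
                 prune_r2 = prune_r2, prune_window_bp = prune_window_bp,
                 flank_bp = flank_bp, min_diagnostics = min_diagnostics)

  filtered <- filter_sites(geno, min_presence, min_maf)
  attrition <- c(input_sites = n_sites(geno), filtered_sites = n_sites(filtered))
  pruned <- ld_prune(filtered, prune_r2, prune_window_bp)
  attrition["pruned_sites"] <- n_sites(pruned)
  global_pca <- geno_pca(pruned, k = 2)

  local <- local_pca_scan(filtered, window_snps = window_snps, k = k,
                          n_axes = mds_axes)
  outlier_windows <- sort(unique(unlist(
    lapply(local$outliers, `[[`, "outliers"))))

  # LD blocks on every chromosome (unpruned filtered matrix): long-range LD
  # is an independent inversion signature, and fence-based window outliers
  # can miss a region when site ascertainment leaves few windows, so block
  # detection is not gated on the MDS stage; overlap with outlier windows is
  # recorded per region in the mds_outlier flag instead
  regions <- list(); ld_blocks <- list()
  for (chrom in unique(filtered$sites$chrom)) {
    idx <- which(filtered$sites$chrom == chrom)
    if (length(idx) < 2) next
    pairs <- pairwise_r2(filtered, idx, r2_report_min = r2_block)
    blocks <- detect_ld_blocks(pairs, r2_min = r2_block,
                               min_span_bp = min_span_bp,
                               max_gap_bp = max_gap_bp)
    if (nrow(blocks)) ld_blocks[[chrom]] <- blocks
  }
  regions <- if (length(ld_blocks)) do.call(rbind, ld_blocks) else
    data.frame(chrom = character(0), start = numeric(0), end = numeric(0),
               span_bp = numeric(0), n_pairs = integer(0))
  rownames(regions) <- NULL

  region_results <- list()
  if (nrow(regions)) {
    for (i in seq_len(nrow(regions))) {
      region <- regions[i, ]
      rr <- analyze_region(filtered, meta, region,
                           top_loading_fraction = top_loading_fraction,
                           anchor_lineage = anchor_lineage,
                           fst_lineage = fst_lineage, flank_bp = flank_bp,
                           min_diagnostics = min_diagnostics)
      region_results[[sprintf("%s:%d-%d", region$chrom,
                              as.integer(region$start),
                              as.integer(region$end))]] <- rr
    }
    regions$mds_outlier <- vapply(seq_len(nrow(regions)), function(i) {
      w <- local$windows
      ov <- w$chrom == regions$chrom[i] &
        w$end_bp >= regions$start[i] & w$start_bp <= regions$end[i]
      any(which(ov) %in% outlier_windows)
    }, logical(1))
    regions$ld_block <- TRUE
    regions$fst_elevated <- vapply(region_results, function(rr)
      isTRUE(rr$fst$fst_elevated), logical(1))
  }

  structure(
    list(params = params, meta = meta, attrition = attrition,
         global_pca = global_pca, local = local, regions = regions,
         region_results = region_results, filtered = filtered),
    class = "inversion_scan")
}

# per-region karyotyping, diagnostics, heterozygosity, FST, frequencies
analyze_region <- function(m, meta, region, top_loading_fraction,
                           anchor_lineage, fst_lineage, flank_bp,
                           min_diagnostics) {
  kp <- karyotype_by_pc1(m, region)
  diagnostics <- select_diagnostic_snps(kp$pca, m, kp$site_index,
                                        top_fraction = top_loading_fraction)
  # anchor: supplied lineage, else the one with lowest mean diagnostic dosage
  if (is.null(anchor_lineage)) {
    lin_means <- vapply(split(seq_len(n_samples(m)), meta$lineage),
                        function(rows) mean(m$dosage[rows, diagnostics],
                                            na.rm = TRUE), numeric(1))
    anchor_lineage <- names(which.min(lin_means))
  }
  anchor <- m$samples[meta$lineage == anchor_lineage]
  call <- call_karyotypes(m, diagnostics, anchor,
                          min_diagnostics = min_diagnostics)
  het <- heterozygosity_by_karyotype(m, call, kp$site_index)

  # FST between homokaryotypes, within one lineage where possible
  # (mirrors the case-control design restricted to the best-sampled lineage)
  cls_by_lin <- table(meta$lineage,
                      factor(call$genotype, c("AHom", "Het", "RHom")))
  balance <- pmin(cls_by_lin[, "AHom"], cls_by_lin[, "RHom"])
  if (is.null(fst_lineage) && any(balance >= 2))
    fst_lineage <- rownames(cls_by_lin)[which.max(balance)]
  if (!is.null(fst_lineage) && balance[fst_lineage] >= 2) {
    rows <- which(meta$lineage == fst_lineage)
    fst <- fst_confirm(subset_geno(m, samples = rows), call, region,
                       flank_bp = flank_bp)
  } else {
    fst <- fst_confirm(m, call, region, flank_bp = flank_bp)
  }
  freq <- frequency_by_location(call, meta)
  list(region = region, cluster = kp$cluster, degenerate = kp$degenerate,
       pca = kp$pca, site_index = kp$site_index, diagnostics = diagnostics,
       anchor_lineage = anchor_lineage, fst_lineage = fst_lineage,
       call = call, het_by_karyotype = het, fst = fst,
       freq_by_location = freq)
}

#' @export
print.inversion_scan <- function(x, ...) {
  cat("inversion_scan\n")
  cat(sprintf("  samples: %d   sites: %d filtered (%d input, %d pruned)\n",
              n_samples(x$filtered), x$attrition[["filtered_sites"]],
              x$attrition[["input_sites"]], x$attrition[["pruned_sites"]]))
  cat(sprintf("  local PCA: %d windows of %d SNPs; %d MDS axes\n",
              nrow(x$local$windows), x$params$window_snps,
              ncol(x$local$mds$points)))
  n_out <- vapply(x$local$outliers, function(o) length(o$outliers),
                  integer(1))
  cat(sprintf("  outlier windows per axis: %s\n",
              paste(sprintf("%s=%d", names(n_out), n_out), collapse = ", ")))
  if (nrow(x$regions)) {
    cat(sprintf("  candidate regions: %d\n", nrow(x$regions)))
    for (i in seq_len(nrow(x$regions)))
      cat(sprintf("    %s:%.2f-%.2f Mb (%.1f Mb; mds_outlier=%s, fst_elevated=%s)\n",
                  x$regions$chrom[i], x$regions$start[i] / 1e6,
                  x$regions$end[i] / 1e6, x$regions$span_bp[i] / 1e6,
                  x$regions$mds_outlier[i], x$regions$fst_elevated[i]))
  } else cat("  candidate regions: none\n")
  invisible(x)
}

#' Summarize an inversion scan
#'
#' @param object an `inversion_scan`.
#' @param ... unused.
#' @return A list with the candidate-region table, per-region karyotype
#'   counts, heterozygosity-by-karyotype tables and frequency-by-location
#'   tables, printed in a readable layout.
#' @export
summary.inversion_scan <- function(object, ...) {
  karyo <- lapply(object$region_results, function(rr)
    table(factor(rr$call$genotype, c("AHom", "Het", "RHom", "unassigned"))))
  out <- list(regions = object$regions, karyotype_counts = karyo,
              heterozygosity = lapply(object$region_results,
                                      `[[`, "het_by_karyotype"),
              frequencies = lapply(object$region_results,
                                   `[[`, "freq_by_location"),
              global_variance = object$global_pca$explained_variance_fraction)
  class(out) <- "summary.inversion_scan"
  out
}

#' @export
print.summary.inversion_scan <- function(x, ...) {
  cat("Candidate regions:\n")
  print(x$regions)
  for (id in names(x$karyotype_counts)) {
    cat("\nRegion", id, "karyotype counts:\n")
    print(x$karyotype_counts[[id]])
    cat("Heterozygosity by karyotype:\n")
    print(x$heterozygosity[[id]])
    cat("Inverted-allele frequency by location:\n")
    print(x$frequencies[[id]])
  }
  invisible(x)
}

#' Plot an inversion scan
#'
#' `type = "mds"` draws the first two MDS axes of window space with outlier
#' windows highlighted; `type = "fst"` draws the per-site homokaryotype FST
#' scan for one region with the refined boundaries; `type = "pc1"` draws the
#' PC1 karyotype clusters for one region.
#'
#' @param x an `inversion_scan`.
#' @param type one of `"mds"`, `"fst"`, `"pc1"`.
#' @param region region id (name in `x$region_results`), default the first.
#' @param ... passed to the underlying plot call.
#' @return `x`, invisibly.
#' @export
plot.inversion_scan <- function(x, type = c("mds", "fst", "pc1"),
                                region = NULL, ...) {
  type <- match.arg(type)
  if (type == "mds") {
    pts <- x$local$mds$points
    chroms <- factor(x$local$windows$chrom)
    out_idx <- sort(unique(unlist(lapply(x$local$outliers, `[[`, "outliers"))))
    graphics::plot(pts[, 1], pts[, 2], col = as.integer(chroms),
                   pch = ifelse(seq_len(nrow(pts)) %in% out_idx, 19, 1),
                   xlab = "MDS1", ylab = "MDS2", ...)
    graphics::legend("topright", legend = levels(chroms),
                     col = seq_along(levels(chroms)), pch = 1, cex = 0.8)
  } else {
    if (is.null(region)) region <- names(x$region_results)[1]
    rr <- x$region_results[[region]]
    if (is.null(rr)) stop("no such region: ", region)
    if (type == "fst") {
      if (is.null(rr$fst)) stop("no FST scan available for ", region)
      s <- rr$fst$scan
      graphics::plot(s$pos / 1e6, s$fst, pch = ".", cex = 2,
                     xlab = "position (Mb)", ylab = "FST", ...)
      graphics::abline(v = rr$fst$boundaries / 1e6, col = 2, lty = 2)
    } else {
      pc1 <- rr$pca$scores[, 1]
      cls <- factor(rr$call$genotype, c("AHom", "Het", "RHom", "unassigned"))
      graphics::stripchart(split(pc1, cls), vertical = TRUE, pch = 19,
                           method = "jitter", ylab = "PC1", ...)
    }
  }
  invisible(x)
}

#' Aggregate a sample metadata table
#'
#' Totals by lineage and by data type plus the overall sample count; the
#' grouped form of a study's sample table.
#'
#' @param meta metadata data.frame with `lineage` and `data_type` columns;
#'   an optional `n` column of group sizes is summed (one row per group),
#'   otherwise each row counts one sample.
#' @return list with `total`, `by_lineage` (named vector), `by_data_type`
#'   (named vector).
#' @export
aggregate_metadata <- function(meta) {
  w <- if ("n" %in% names(meta)) meta$n else rep(1L, nrow(meta))
  list(total = sum(w),
       by_lineage = tapply(w, meta$lineage, sum),
       by_data_type = tapply(w, meta$data_type, sum))
}
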