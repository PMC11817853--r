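#' Read a VCF into a genotype matrix
#'
#' Parses GT fields into alternate-allele dosages. Multi-allelic records and
#' records whose REF/ALT are not single bases are skipped (a count is
#' reported via `message()`); half-missing genotypes (`./1`) are treated as
#' missing. Phased and unphased separators are accepted.
#'
#' @param path path to a VCF (v4.x, plain text or gzipped).
#' @return A [geno_matrix()].
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  if (ncol(v@gt) < 2) stop("VCF contains zero sample columns")
  fix <- v@fix
  alt <- fix[, "ALT"]
  ref <- fix[, "REF"]
  keep <- !is.na(alt) & !grepl(",", alt) &
    nchar(ref) == 1 & nchar(alt) == 1 &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  n_skip <- sum(!keep)
  if (n_skip > 0)
    message("read_vcf: skipped ", n_skip, " multi-allelic/non-SNP record(s)")
  gt <- vcfR::extract.gt(v, element = "GT")[keep, , drop = FALSE]
  gt_core <- sub(":.*$", "", gt)
  a1 <- substr(gt_core, 1, 1)
  a2 <- substr(gt_core, 3, 3)
  num <- function(a) {
    r <- rep(NA_integer_, length(a))
    r[a == "0"] <- 0L
    r[a == "1"] <- 1L
    r
  }
  dos <- matrix(num(a1) + num(a2), nrow = nrow(gt_core),
                dimnames = dimnames(gt_core))
  sites <- data.frame(chrom = fix[keep, "CHROM"],
                      pos = as.integer(fix[keep, "POS"]),
                      ref = ref[keep], alt = alt[keep],
                      stringsAsFactors = FALSE)
  geno_matrix(t(dos), colnames(gt_core), sites)
}

#' Write a genotype matrix as minimal VCF v4.2
#'
#' Emits CHROM, POS, ID, REF, ALT and a GT-only FORMAT column per sample;
#' missing genotypes are written `./.`. The output round-trips through
#' [read_vcf()].
#'
#' @param m a [geno_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(m, path) {
  gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", m$samples), collapse = "\t")), con)
  dos <- m$dosage
  gt <- matrix("./.", nrow = nrow(dos), ncol = ncol(dos))
  ok <- !is.na(dos)
  gt[ok] <- gt_code[as.character(dos[ok])]
  lines <- paste(m$sites$chrom, m$sites$pos, ".", m$sites$ref, m$sites$alt,
                 ".", "PASS", ".", "GT",
                 apply(gt, 2, paste, collapse = "\t"), sep = "\t")
  writeLines(lines, con)
  invisible(path)
}

#' Filter sites on call rate and minor allele frequency
#'
#' Retains sites whose non-missing fraction is at least `min_presence` and
#' whose minor-allele frequency, computed over observed allele counts among
#' non-missing genotypes, is at least `min_maf` (both bounds inclusive).
#' Samples are never removed or reordered.
#'
#' @param m a [geno_matrix()].
#' @param min_presence minimum fraction of samples with a called genotype.
#' @param min_maf minimum minor-allele frequency, in `[0, 0.5)`.
#' @return A filtered `geno_matrix` (empty, with a warning, if no site
#'   survives).
#' @export
filter_sites <- function(m, min_presence = 0.90, min_maf = 0.05) {
  stopifnot(min_presence > 0, min_presence <= 1,
            min_maf >= 0, min_maf < 0.5)
  called <- colSums(!is.na(m$dosage))
  presence <- called / n_samples(m)
  alt_freq <- colSums(m$dosage, na.rm = TRUE) / (2 * called)
  maf <- pmin(alt_freq, 1 - alt_freq)
  keep <- presence >= min_presence & !is.na(maf) & maf >= min_maf
  if (!any(keep)) warning("filter_sites: all sites removed")
  subset_geno(m, sites = which(keep))
}

#' Greedy window-based LD pruning
#'
#' Left-to-right scan per chromosome: a site is dropped when its squared
#' dosage correlation with any already-retained site at most `window_bp`
#' upstream exceeds `r2_max`. Keep-first tie handling makes the result
#' deterministic and idempotent.
#'
#' @param m a [geno_matrix()].
#' @param r2_max maximum tolerated r-squared, in `(0, 1]`.
#' @param window_bp upstream window width in bp.
#' @return A pruned `geno_matrix`.
#' @export
ld_prune <- function(m, r2_max = 0.20, window_bp = 10000) {
  stopifnot(r2_max > 0, r2_max <= 1, window_bp > 0)
  if (n_sites(m) == 0) return(m)
  keep <- logical(n_sites(m))
  for (chrom in unique(m$sites$chrom)) {
    idx <- which(m$sites$chrom == chrom)
    pos <- m$sites$pos[idx]
    kept <- integer(0)
    for (j in seq_along(idx)) {
      in_win <- kept[pos[j] - pos[kept] <= window_bp]
      drop <- FALSE
      if (length(in_win)) {
        r2 <- dosage_r2(m$dosage[, idx[j]],
                        m$dosage[, idx[in_win], drop = FALSE])
        drop <- any(r2 > r2_max, na.rm = TRUE)
      }
      if (!drop) kept <- c(kept, j)
    }
    keep[idx[kept]] <- TRUE
  }
  subset_geno(m, sites = which(keep))
}

# r^2 between one dosage vector and each column of a dosage matrix,
# over pairwise-complete samples; NA when either member has zero variance
dosage_r2 <- function(x, ymat) {
  suppressWarnings(as.vector(stats::cor(x, ymat,
                                        use = "pairwise.complete.obs"))^2)
}
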