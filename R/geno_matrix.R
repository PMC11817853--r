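#' Construct a genotype matrix
#'
#' The central data container: a samples x sites matrix of alternate-allele
#' dosages (0, 1, 2 or `NA` for missing) for biallelic SNPs, together with
#' site coordinates. Sites are kept sorted by (chromosome, position) and
#' duplicate positions are rejected, so downstream windowing and interval
#' logic can rely on coordinate order.
#'
#' @param dosage integer/numeric matrix, samples in rows, sites in columns;
#'   values in \{0, 1, 2, NA\}.
#' @param samples character vector of sample ids (row names of `dosage`).
#' @param sites data.frame with columns `chrom`, `pos` (1-based), `ref`, `alt`;
#'   one row per column of `dosage`.
#' @return An object of class `geno_matrix`.
#' @export
geno_matrix <- function(dosage, samples, sites) {
  dosage <- as.matrix(dosage)
  if (is.null(dim(dosage))) stop("'dosage' must be a matrix")
  if (length(samples) != nrow(dosage))
    stop("length(samples) must equal nrow(dosage)")
  if (nrow(sites) != ncol(dosage))
    stop("nrow(sites) must equal ncol(dosage)")
  required <- c("chrom", "pos")
  if (!all(required %in% names(sites)))
    stop("'sites' needs columns chrom and pos")
  if (is.null(sites$ref)) sites$ref <- "A"
  if (is.null(sites$alt)) sites$alt <- "T"
  bad <- !(dosage %in% c(0, 1, 2)) & !is.na(dosage)
  if (any(bad)) stop("dosages must be 0, 1, 2 or NA")
  sites$chrom <- as.character(sites$chrom)
  sites$pos <- as.integer(sites$pos)
  ord <- order(sites$chrom, sites$pos)
  sites <- sites[ord, , drop = FALSE]
  dosage <- dosage[, ord, drop = FALSE]
  if (anyDuplicated(sites[, c("chrom", "pos")]))
    stop("duplicate (chrom, pos) sites are not allowed")
  rownames(sites) <- NULL
  dimnames(dosage) <- list(as.character(samples), NULL)
  structure(
    list(dosage = dosage, samples = as.character(samples), sites = sites),
    class = "geno_matrix"
  )
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf(
    "geno_matrix: %d samples x %d sites on %d chromosome(s); %.1f%% missing\n",
    n_samples(x), n_sites(x), length(unique(x$sites$chrom)),
    100 * mean(is.na(x$dosage))
  ))
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$dosage)

#' Number of samples / sites in a genotype matrix
#' @param m a `geno_matrix`
#' @return integer count
#' @export
n_samples <- function(m) nrow(m$dosage)

#' @rdname n_samples
#' @export
n_sites <- function(m) ncol(m$dosage)

#' Subset a genotype matrix
#'
#' @param m a `geno_matrix`
#' @param samples sample indices, logical mask or ids (NULL keeps all)
#' @param sites site column indices or logical mask (NULL keeps all)
#' @return a `geno_matrix`
#' @export
subset_geno <- function(m, samples = NULL, sites = NULL) {
  si <- if (is.null(samples)) seq_len(n_samples(m)) else samples
  if (is.character(si)) si <- match(si, m$samples)
  vi <- if (is.null(sites)) seq_len(n_sites(m)) else sites
  geno_matrix(m$dosage[si, vi, drop = FALSE], m$samples[si],
              m$sites[vi, , drop = FALSE])
}

#' Site indices falling inside a genomic span
#'
#' @param m a `geno_matrix`
#' @param chrom chromosome name
#' @param start,end 1-based inclusive bp bounds
#' @return integer vector of site column indices
#' @export
sites_in_span <- function(m, chrom, start, end) {
  which(m$sites$chrom == chrom & m$sites$pos >= start & m$sites$pos <= end)
}

#' Read a sample metadata table
#'
#' Tab-separated with header `sample location lineage data_type`.
#'
#' @param path file path
#' @return data.frame with those four character columns
#' @export
read_metadata <- function(path) {
  md <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, colClasses = "character")
  need <- c("sample", "location", "lineage", "data_type")
  if (!all(need %in% names(md)))
    stop("metadata must have columns: ", paste(need, collapse = ", "))
  md[, need]
}

#' Write a sample metadata table
#' @param meta data.frame as returned by [read_metadata()]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_metadata <- function(meta, path) {
  utils::write.table(meta, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

check_metadata <- function(m, meta) {
  if (!setequal(meta$sample, m$samples) ||
      anyDuplicated(meta$sample) > 0)
    stop("metadata must have exactly one row per matrix sample")
  meta[match(m$samples, meta$sample), , drop = FALSE]
}
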