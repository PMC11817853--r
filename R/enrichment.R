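#' Read a gene annotation table
#'
#' Tab-separated with header `gene chrom start end`.
#'
#' @param path file path
#' @return data.frame with those columns (`start`/`end` numeric)
#' @export
read_gene_table <- function(path) {
  g <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  need <- c("gene", "chrom", "start", "end")
  if (!all(need %in% names(g)))
    stop("gene table must have columns: ", paste(need, collapse = ", "))
  if (any(g$start >= g$end)) stop("gene start must be < end")
  g[, need]
}

#' Read a gene-to-GO mapping
#'
#' Two-column tab-separated (`gene`, `term`), one term per row; terms must be
#' well-formed GO ids (`GO:` + 7 digits).
#'
#' @param path file path
#' @return data.frame `(gene, term)`
#' @export
read_gene2go <- function(path) {
  g <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  if (!all(c("gene", "term") %in% names(g)))
    stop("gene2go table must have columns gene, term")
  bad <- !grepl("^GO:[0-9]{7}$", g$term)
  if (any(bad))
    stop("malformed GO term id(s), e.g. ", g$term[which(bad)[1]])
  g[, c("gene", "term")]
}

#' Genes inside candidate regions (midpoint rule)
#'
#' A gene belongs to a region when its midpoint `(start + end) / 2` lies
#' within the region's 1-based inclusive span. Alternative membership rules
#' (`"any-overlap"`, `"full-containment"`) are exposed for sensitivity checks.
#'
#' @param genes gene table as from [read_gene_table()].
#' @param regions data.frame with `chrom`, `start`, `end` (non-overlapping
#'   per chromosome).
#' @param rule membership rule, default `"midpoint"`.
#' @return Named list of character vectors of gene ids, one per region
#'   (named `chrom:start-end`).
#' @export
genes_in_regions <- function(genes, regions,
                             rule = c("midpoint", "any-overlap",
                                      "full-containment")) {
  rule <- match.arg(rule)
  out <- lapply(seq_len(nrow(regions)), function(i) {
    r <- regions[i, ]
    same <- genes$chrom == r$chrom
    inside <- switch(rule,
      midpoint = {
        mid <- (genes$start + genes$end) / 2
        same & mid >= r$start & mid <= r$end
      },
      `any-overlap` = same & genes$end >= r$start & genes$start <= r$end,
      `full-containment` = same & genes$start >= r$start & genes$end <= r$end)
    genes$gene[inside]
  })
  names(out) <- sprintf("%s:%d-%d", regions$chrom,
                        as.integer(regions$start), as.integer(regions$end))
  out
}

#' Fisher exact GO-term enrichment of region genes
#'
#' For every term annotated to at least one gene, a 2x2 table compares genes
#' inside the region against all other annotated genes (the per-region
#' background). Two-sided Fisher exact p-values are Benjamini-Hochberg
#' adjusted across all terms tested within the region; reported terms must
#' satisfy both the adjusted-p cutoff and a minimum in-region gene count.
#'
#' @param region_genes character vector of gene ids inside one region.
#' @param genes full gene table (defines the annotated-gene universe).
#' @param gene2go data.frame `(gene, term)`.
#' @param min_genes minimum in-region genes carrying the term (default 10).
#' @param alpha BH-adjusted significance cutoff (default 0.05).
#' @param all_terms if `TRUE`, return every tested term, not only the
#'   significant ones.
#' @return data.frame `(term, in_with, in_without, bg_with, bg_without,
#'   direction, p, p_adj, significant)` ordered by `p_adj`.
#' @export
fisher_enrichment <- function(region_genes, genes, gene2go,
                              min_genes = 10, alpha = 0.05,
                              all_terms = FALSE) {
  stopifnot(min_genes >= 1, alpha > 0, alpha < 1)
  universe <- unique(genes$gene)
  region_genes <- intersect(region_genes, universe)
  background <- setdiff(universe, region_genes)
  g2g <- gene2go[gene2go$gene %in% universe, , drop = FALSE]
  terms <- unique(g2g$term)
  if (!length(terms) || !length(region_genes))
    return(data.frame(term = character(0), in_with = integer(0),
                      in_without = integer(0), bg_with = integer(0),
                      bg_without = integer(0), direction = character(0),
                      p = numeric(0), p_adj = numeric(0),
                      significant = logical(0)))
  by_term <- split(g2g$gene, g2g$term)
  n_in <- length(region_genes); n_bg <- length(background)
  rows <- lapply(terms, function(tm) {
    with_term <- unique(by_term[[tm]])
    a <- length(intersect(with_term, region_genes))
    c_ <- length(with_term) - a
    b <- n_in - a
    d <- n_bg - c_
    p <- stats::fisher.test(matrix(c(a, b, c_, d), 2))$p.value
    dir <- if (a / n_in > (a + c_) / (n_in + n_bg)) "over" else "under"
    data.frame(term = tm, in_with = a, in_without = b, bg_with = c_,
               bg_without = d, direction = dir, p = p,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$p_adj <- stats::p.adjust(res$p, method = "BH")
  res$significant <- res$p_adj <= alpha & res$in_with >= min_genes
  res <- res[order(res$p_adj, res$p, res$term), , drop = FALSE]
  rownames(res) <- NULL
  if (all_terms) res else res[res$significant, , drop = FALSE]
}
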