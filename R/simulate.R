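#' Specify a simulated inversion locus
#'
#' Describes one polymorphic inversion: its genomic span, how many SNPs it
#' carries, and how the two arrangement-specific allele pools differ. A
#' fraction `fixed_diff_fraction` of sites are fixed differences (frequency 0
#' in the ancestral pool, 1 in the inverted pool); the remainder diverge by a
#' Balding-Nichols drift of `arrangement_divergence`, with the inverted pool
#' drifted further by `inverted_pool_F` so inverted homokaryotypes show
#' reduced diversity. Haplotypes never recombine across pools, mimicking the
#' recombination suppression of a real inversion in heterokaryotypes.
#'
#' @param chromosome chromosome name the inversion sits on.
#' @param span numeric length-2, 1-based inclusive (start, end) in bp.
#' @param n_sites number of SNPs inside the span.
#' @param fixed_diff_fraction fraction of sites that are fixed differences
#'   between arrangements, in `[0, 1]`.
#' @param arrangement_divergence Balding-Nichols F for non-fixed sites between
#'   the two arrangement pools.
#' @param inverted_pool_F extra drift applied to the inverted pool (lowers
#'   inverted-homokaryotype heterozygosity).
#' @param inverted_freq named numeric: inverted-arrangement frequency per
#'   lineage, each in `[0, 1]`.
#' @return An object of class `inversion_spec`.
#' @export
inversion_spec <- function(chromosome, span, n_sites = 600,
                           fixed_diff_fraction = 0.3,
                           arrangement_divergence = 0.1,
                           inverted_pool_F = 0.3,
                           inverted_freq) {
  stopifnot(length(span) == 2, span[1] < span[2], n_sites >= 1,
            fixed_diff_fraction >= 0, fixed_diff_fraction <= 1,
            arrangement_divergence >= 0, arrangement_divergence < 1,
            inverted_pool_F >= 0, inverted_pool_F < 1)
  if (is.null(names(inverted_freq)))
    stop("'inverted_freq' must be named by lineage")
  if (any(inverted_freq < 0 | inverted_freq > 1))
    stop("inverted_freq values must lie in [0, 1]")
  structure(
    list(chromosome = as.character(chromosome),
         span = as.numeric(span), n_sites = as.integer(n_sites),
         fixed_diff_fraction = fixed_diff_fraction,
         arrangement_divergence = arrangement_divergence,
         inverted_pool_F = inverted_pool_F,
         inverted_freq = inverted_freq),
    class = "inversion_spec"
  )
}

#' Configure a synthetic cohort
#'
#' Defaults emulate a three-lineage species complex in which the first
#' lineage (IND) split earliest and the other two (SEA, AUS+NG) share a more
#' recent ancestor, carrying one 5-Mb polymorphic inversion that is absent in
#' IND, intermediate in SEA and fixed in AUS+NG, genotyped as a mix of dense
#' (WGS) and sparse shared-locus (RAD) samples with moderate missingness.
#'
#' @param n_per_lineage named integer vector of sample counts per lineage.
#' @param chromosomes data.frame with columns `name` and `length` (bp).
#' @param n_background_snps total neutral SNPs spread over the chromosomes.
#' @param background_F named numeric, Balding-Nichols drift per lineage.
#' @param inversions list of [inversion_spec()] objects, at most one per
#'   chromosome.
#' @param rad_site_fraction fraction of sites retained (as a shared subset)
#'   for RAD-labelled samples, in `(0, 1]`.
#' @param missing_rate additional independent genotype missingness in `[0, 1)`
#'   (1 is tolerated and yields an all-missing matrix).
#' @param rad_sample_fraction fraction of each lineage's samples labelled RAD.
#' @param n_locations_per_lineage sampling locations per lineage (samples are
#'   split evenly across them).
#' @param seed integer RNG seed; the whole cohort is deterministic given it.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_per_lineage = c(IND = 50, SEA = 50, `AUS+NG` = 50),
                       chromosomes = data.frame(
                         name = c("chr1", "chr2", "chr3"),
                         length = rep(25e6, 3)),
                       n_background_snps = 5000,
                       background_F = c(IND = 0.15, SEA = 0.08,
                                        `AUS+NG` = 0.08),
                       inversions = list(
                         inversion_spec("chr1", c(10e6, 15e6), n_sites = 600,
                                        inverted_freq = c(IND = 0, SEA = 0.5,
                                                          `AUS+NG` = 1))),
                       rad_site_fraction = 0.3,
                       missing_rate = 0.1,
                       rad_sample_fraction = 0.5,
                       n_locations_per_lineage = 1,
                       seed = 1) {
  if (is.null(names(n_per_lineage)))
    stop("'n_per_lineage' must be named by lineage")
  stopifnot(all(n_per_lineage >= 0), sum(n_per_lineage) >= 2,
            n_background_snps >= 0,
            rad_site_fraction > 0, rad_site_fraction <= 1,
            missing_rate >= 0, missing_rate <= 1,
            rad_sample_fraction >= 0, rad_sample_fraction <= 1)
  lineages <- names(n_per_lineage)
  if (!all(lineages %in% names(background_F)))
    stop("'background_F' must cover every lineage")
  if (any(background_F[lineages] <= 0 | background_F[lineages] >= 1))
    stop("background_F values must lie in (0, 1)")
  inv_chroms <- vapply(inversions, function(iv) iv$chromosome, character(1))
  if (anyDuplicated(inv_chroms))
    stop("at most one inversion per chromosome")
  for (iv in inversions) {
    j <- match(iv$chromosome, chromosomes$name)
    if (is.na(j)) stop("inversion on unknown chromosome: ", iv$chromosome)
    if (iv$span[2] > chromosomes$length[j])
      stop("inversion span exceeds chromosome length on ", iv$chromosome)
    miss <- setdiff(lineages, names(iv$inverted_freq))
    if (length(miss))
      stop("inverted_freq missing lineage(s): ", paste(miss, collapse = ", "))
  }
  structure(
    list(n_per_lineage = n_per_lineage, chromosomes = chromosomes,
         n_background_snps = as.integer(n_background_snps),
         background_F = background_F, inversions = inversions,
         rad_site_fraction = rad_site_fraction, missing_rate = missing_rate,
         rad_sample_fraction = rad_sample_fraction,
         n_locations_per_lineage = as.integer(n_locations_per_lineage),
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

# Balding-Nichols draw around ancestral frequency p with drift F;
# clamped away from 0/1 so no lineage frequency is exactly monomorphic.
bn_draw <- function(p, F) {
  if (F <= 0) return(p)
  q <- stats::rbeta(length(p), p * (1 - F) / F, (1 - p) * (1 - F) / F)
  pmin(pmax(q, 0.001), 0.999)
}

# distinct positions in 1..len avoiding `exclude`
sample_positions <- function(len, n, exclude = integer(0)) {
  pos <- unique(sample.int(len, min(len, n + length(exclude))))
  pos <- setdiff(pos, exclude)
  while (length(pos) < n) {
    extra <- sample.int(len, n - length(pos))
    pos <- unique(c(pos, setdiff(extra, exclude)))
  }
  sort(pos[seq_len(n)])
}

#' Simulate a genotype cohort with known inversions
#'
#' Background sites follow a two-level hierarchical Balding-Nichols model:
#' ancestral frequencies are Uniform(0.05, 0.95); the first lineage draws its
#' frequency directly from the root, while the remaining two draw from a
#' shared intermediate node so that their allele frequencies are correlated
#' (the (L1,(L2,L3)) topology). Inversion-locus genotypes are built from two
#' non-recombining arrangement-specific haplotype pools; each individual's
#' karyotype (count of inverted arrangements, 0/1/2) is Binomial(2, q) with
#' the lineage-specific inverted frequency q.
#'
#' @param config a [sim_config()].
#' @return A list with elements `geno` (a [geno_matrix()] over background and
#'   inversion sites), `meta` (sample metadata data.frame), and `truth`
#'   (class `sim_truth`: per-individual karyotypes, true spans, realized
#'   arrangement pool frequencies, and the config).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  lineages <- names(config$n_per_lineage)
  n_tot <- sum(config$n_per_lineage)
  lineage_of <- rep(lineages, config$n_per_lineage)
  samples <- unlist(lapply(lineages, function(l) {
    sprintf("%s_%03d", gsub("[^A-Za-z0-9]", "", l),
            seq_len(config$n_per_lineage[[l]]))
  }))

  # metadata: locations split evenly, RAD labels assigned deterministically
  meta <- do.call(rbind, lapply(lineages, function(l) {
    n <- config$n_per_lineage[[l]]
    if (n == 0) return(NULL)
    nl <- max(1L, config$n_locations_per_lineage)
    loc <- sprintf("%s_loc%d", gsub("[^A-Za-z0-9]", "", l),
                   rep_len(seq_len(nl), n))
    n_rad <- round(n * config$rad_sample_fraction)
    dt <- c(rep("WGS", n - n_rad), rep("RAD", n_rad))
    data.frame(location = sort(loc), lineage = l, data_type = dt,
               stringsAsFactors = FALSE)
  }))
  meta <- cbind(sample = samples, meta)
  rownames(meta) <- NULL

  # allocate background SNPs to chromosomes in proportion to length
  lens <- config$chromosomes$length
  n_bg <- floor(config$n_background_snps * lens / sum(lens))
  rem <- config$n_background_snps - sum(n_bg)
  if (rem > 0) n_bg[seq_len(rem)] <- n_bg[seq_len(rem)] + 1

  site_chrom <- character(0); site_pos <- integer(0)
  site_kind <- character(0)  # "bg" or inversion id
  dosage_cols <- list()

  # lineage topology: first lineage from the root, the rest via a shared node
  F_lin <- config$background_F[lineages]
  use_tree <- length(lineages) == 3
  if (use_tree) {
    F_node <- 0.5 * min(F_lin[2], F_lin[3])
    F_tip <- 1 - (1 - F_lin[2:3]) / (1 - F_node)
  }

  inv_ids <- if (length(config$inversions))
    sprintf("inv_%s", vapply(config$inversions, `[[`, character(1),
                             "chromosome")) else character(0)
  truth_karyo <- list()
  realized <- list()

  for (ci in seq_len(nrow(config$chromosomes))) {
    chrom <- config$chromosomes$name[ci]
    len <- lens[ci]
    iv_i <- which(vapply(config$inversions, function(iv)
      iv$chromosome == chrom, logical(1)))
    iv <- if (length(iv_i)) config$inversions[[iv_i]] else NULL

    inv_pos <- integer(0)
    if (!is.null(iv)) {
      lo <- as.integer(iv$span[1]); hi <- as.integer(iv$span[2])
      inv_pos <- lo - 1L + sample_positions(hi - lo + 1L, iv$n_sites)
    }
    bg_pos <- if (n_bg[ci] > 0)
      sample_positions(len, n_bg[ci], exclude = inv_pos) else integer(0)

    # background genotypes on this chromosome
    if (length(bg_pos)) {
      p_anc <- stats::runif(length(bg_pos), 0.05, 0.95)
      p_by_lin <- matrix(0, length(bg_pos), length(lineages),
                         dimnames = list(NULL, lineages))
      if (use_tree) {
        p_by_lin[, 1] <- bn_draw(p_anc, F_lin[[1]])
        p_node <- bn_draw(p_anc, F_node)
        p_by_lin[, 2] <- bn_draw(p_node, F_tip[[1]])
        p_by_lin[, 3] <- bn_draw(p_node, F_tip[[2]])
      } else {
        for (j in seq_along(lineages))
          p_by_lin[, j] <- bn_draw(p_anc, F_lin[[j]])
      }
      g <- matrix(NA_integer_, n_tot, length(bg_pos))
      for (j in seq_along(lineages)) {
        rows <- which(lineage_of == lineages[j])
        if (!length(rows)) next
        g[rows, ] <- matrix(
          stats::rbinom(length(rows) * length(bg_pos), 2,
                        rep(p_by_lin[, j], each = length(rows))),
          nrow = length(rows))
      }
      dosage_cols[[length(dosage_cols) + 1]] <- g
      site_chrom <- c(site_chrom, rep(chrom, length(bg_pos)))
      site_pos <- c(site_pos, bg_pos)
      site_kind <- c(site_kind, rep("bg", length(bg_pos)))
    }

    # inversion genotypes
    if (!is.null(iv)) {
      ns <- iv$n_sites
      n_fix <- round(iv$fixed_diff_fraction * ns)
      fixed <- logical(ns)
      if (n_fix > 0) fixed[sample.int(ns, n_fix)] <- TRUE
      p0 <- stats::runif(ns, 0.05, 0.95)
      freq_anc <- bn_draw(p0, iv$arrangement_divergence)
      freq_inv <- bn_draw(bn_draw(p0, iv$arrangement_divergence),
                          iv$inverted_pool_F)
      freq_anc[fixed] <- 0
      freq_inv[fixed] <- 1
      q <- iv$inverted_freq[lineage_of]
      K <- stats::rbinom(n_tot, 2, q)
      g <- matrix(NA_integer_, n_tot, ns)
      for (i in seq_len(n_tot)) {
        g[i, ] <- stats::rbinom(ns, 2L - K[i], freq_anc) +
          stats::rbinom(ns, K[i], freq_inv)
      }
      dosage_cols[[length(dosage_cols) + 1]] <- g
      site_chrom <- c(site_chrom, rep(chrom, ns))
      site_pos <- c(site_pos, inv_pos)
      site_kind <- c(site_kind, rep(inv_ids[iv_i], ns))
      truth_karyo[[inv_ids[iv_i]]] <- K
      realized[[inv_ids[iv_i]]] <- data.frame(
        chrom = chrom, pos = inv_pos, fixed_diff = fixed,
        freq_ancestral = freq_anc, freq_inverted = freq_inv)
    }
  }

  dosage <- do.call(cbind, dosage_cols)
  sites <- data.frame(chrom = site_chrom, pos = site_pos,
                      ref = "A", alt = "T", kind = site_kind,
                      stringsAsFactors = FALSE)
  ord <- order(sites$chrom, sites$pos)
  geno <- geno_matrix(dosage[, ord, drop = FALSE], samples,
                      sites[ord, c("chrom", "pos", "ref", "alt")])
  geno$sites$kind <- sites$kind[ord]

  karyotypes <- do.call(rbind, lapply(names(truth_karyo), function(id) {
    data.frame(sample = samples, inversion = id,
               karyotype = truth_karyo[[id]], lineage = lineage_of,
               stringsAsFactors = FALSE)
  }))
  spans <- do.call(rbind, lapply(seq_along(config$inversions), function(i) {
    iv <- config$inversions[[i]]
    data.frame(inversion = inv_ids[i], chrom = iv$chromosome,
               start = iv$span[1], end = iv$span[2],
               stringsAsFactors = FALSE)
  }))
  truth <- structure(
    list(karyotypes = karyotypes, spans = spans, realized = realized,
         config = config),
    class = "sim_truth")
  list(geno = geno, meta = meta, truth = truth)
}

#' Apply WGS/RAD ascertainment and missingness masks
#'
#' RAD-labelled samples keep genotypes only at a shared, seeded random subset
#' of `rad_site_fraction` of sites (locus-based ascertainment, as restriction
#' sites are shared across a RAD library); everything else becomes missing.
#' All samples are then masked independently at `missing_rate`. Site order is
#' preserved.
#'
#' @param m a [geno_matrix()].
#' @param config the [sim_config()] (supplies fractions and the seed).
#' @param meta metadata data.frame with a `data_type` column labelling each
#'   sample `WGS` or `RAD`.
#' @return A masked `geno_matrix`.
#' @export
apply_ascertainment <- function(m, config, meta) {
  meta <- check_metadata(m, meta)
  has_rad <- any(meta$data_type == "RAD")
  if (has_rad && config$rad_site_fraction <= 0)
    stop("rad_site_fraction must be > 0 when RAD samples are present")
  set.seed(config$seed + 777L)
  dos <- m$dosage
  if (has_rad && config$rad_site_fraction < 1) {
    keep <- sort(sample.int(n_sites(m),
                            round(config$rad_site_fraction * n_sites(m))))
    drop <- setdiff(seq_len(n_sites(m)), keep)
    dos[meta$data_type == "RAD", drop] <- NA_integer_
  }
  if (config$missing_rate > 0) {
    mask <- stats::runif(length(dos)) < config$missing_rate
    dos[mask] <- NA_integer_
  }
  out <- m
  out$dosage <- dos
  out
}

#' @export
print.sim_truth <- function(x, ...) {
  cat(sprintf("sim_truth: %d inversion(s), %d individuals\n",
              nrow(x$spans), length(unique(x$karyotypes$sample))))
  invisible(x)
}

#' Write a simulation truth table
#'
#' Tab-separated: one row per individual per inversion with the true
#' karyotype (count of inverted arrangements).
#'
#' @param truth a `sim_truth` from [simulate_cohort()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  utils::write.table(truth$karyotypes, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
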