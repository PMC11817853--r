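---
title: "Detecting chromosomal inversions from genotype matrices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting chromosomal inversions from genotype matrices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## Overview

Large polymorphic inversions suppress recombination in heterokaryotypes, so
the two arrangements accumulate divergent haplotypes that segregate as single
Mendelian units. In population genotype data this leaves three coupled
signatures:

1. **Local structure**: PCA restricted to windows inside the inversion
   separates samples into three clusters along PC1 — the two homokaryotypes
   at the extremes and heterokaryotypes in between — regardless of the
   genome-wide structure.
2. **Long-range LD**: allele dosages at sites megabases apart inside the
   inversion remain strongly correlated (r² near 1 at arrangement-diagnostic
   sites).
3. **Elevated differentiation and heterozygosity**: FST between the two
   homokaryotype groups is high inside the inversion and background
   elsewhere, and heterokaryotypes show elevated heterozygosity at
   diagnostic sites.

`karyoscan` implements a scan that works through these signatures in order:
windowed local PCA with an MDS embedding of window distances to find
candidate regions, long-range LD block detection to delimit them, PC1-based
karyotype assignment with diagnostic SNPs, and homokaryotype FST plus
heterozygosity profiles to confirm and refine boundaries. A
forward-in-time-free simulator with recorded truth supports validation of
every stage.

## Local PCA and window distances

Sites that pass presence and minor-allele-frequency filters are cut into
consecutive, non-overlapping windows of exactly `window_snps` sites (default
50; remainders are discarded and windows never span chromosomes). For window
$w$ with mean-imputed, site-centred dosage matrix $X_w$ (samples × sites),
the sample-by-sample covariance is

$$C_w = \frac{1}{m-1} X_w X_w^\top,$$

summarized by its top $k$ eigenpairs (default $k = 2$). The distance between
windows is the Frobenius norm of the difference of their rank-$k$
approximations, each normalized by the Frobenius norm of its full
covariance:

$$d(w_1, w_2) = \left\lVert \frac{\hat C_{w_1}}{\lVert C_{w_1} \rVert_F}
  - \frac{\hat C_{w_2}}{\lVert C_{w_2} \rVert_F} \right\rVert_F ,$$

computed from eigenpairs alone via
$\lVert A_1 - A_2 \rVert_F^2 = \sum_i \lambda_{1i}^2 + \sum_j \lambda_{2j}^2
- 2 \sum_{ij} \lambda_{1i}\lambda_{2j} (v_{1i} \cdot v_{2j})^2$,
avoiding the $n \times n$ matrices. Windows with zero covariance
(monomorphic after imputation) are dropped.

The distance matrix is embedded with classical (Torgerson) MDS: eigen­decompose
the double-centred matrix $-\tfrac12 J D^{(2)} J$, scale eigenvectors by the
square roots of the positive eigenvalues, keep `n_axes` axes (default 3).
Signs are fixed so each axis's largest-magnitude coordinate is positive,
making the embedding deterministic. On each axis, windows outside the Tukey
fences (quartiles ± 1.5 IQR, via `boxplot.stats`) are flagged as outliers;
an inversion appears as a run of outlier windows concentrated on one
chromosome.

## LD blocks

Within chromosomes carrying outlier windows, pairwise genotypic $r^2$
(squared Pearson correlation of dosages over pairwise-complete samples, with
at least 10 shared samples) is computed among filtered sites. Pairs with
$r^2 >$ `r2_block` (default 0.8) are projected onto the chromosome as
intervals; intervals closer than `max_gap_bp` (default 500 kb) are merged and
merged blocks shorter than `min_span_bp` (default 1 Mb) are discarded. The
1 Mb span floor is what separates inversion-scale LD from ordinary
short-range LD, which the default simulator's unlinked background cannot
produce and which real data produces only over kilobases after LD pruning.

## Karyotyping

PCA over the sites of a candidate region gives PC1 scores that are clustered
with a deterministic one-dimensional Lloyd k-means ($k = 3$, centres
initialized at the minimum, median and maximum score). The clustering is
flagged *degenerate* when a cluster empties or when the smaller gap between
sorted centres is less than a quarter of the larger gap — the pattern
produced when only two karyotypes are present and a true three-way split is
not supported.

Diagnostic SNPs are the top `top_loading_fraction` (default 5%) of region
sites by absolute PC1 loading. Dosages are polarized so that 0 is the major
allele of an anchor group (a lineage believed fixed for the standard
arrangement); each sample's mean polarized diagnostic dosage $\bar g$ assigns
its karyotype: AHom if $\bar g < 0.5$, Het if $0.5 \le \bar g \le 1.5$, RHom
if $\bar g > 1.5$, and unassigned when fewer than `min_diagnostics` (default
5) diagnostic sites are observed.

## FST confirmation and boundaries

Per-site FST between the two homokaryotype groups uses the Weir–Cockerham
(1984) two-population estimator on haploid allele counts
($\theta = a / (a + b)$ from the among- and within-population variance
components). Where a single lineage segregates for both homokaryotypes, the
scan restricts to that lineage so that lineage differentiation does not
masquerade as arrangement differentiation.

A rolling median over `roll_snps` sites (default 25) is compared with the
flank median (sites within `flank_bp`, default 5 Mb, either side of the
region). The region is *elevated* when the rolling median exceeds both
`run_factor` (default 5) times the flank median and an absolute floor
`elevated_min` (default 0.25). Two numerical guards matter here:

- the flank median is floored at `flank_floor` (default 0.01) before
  multiplying, because null Weir–Cockerham estimates straddle zero and a
  near-zero (or negative) flank median would make the multiplicative rule
  vacuous;
- boundaries are reported as the outermost positions whose rolling median
  exceeds the threshold. Background sites interleaved with
  arrangement-diagnostic sites break up contiguous runs, so the outermost
  exceedances — not the longest contiguous run — recover the full span.

## The simulator

`simulate_cohort()` draws a cohort from an explicit hierarchical model and
records complete truth (`sim_truth`): every sample's karyotype, the realized
inversion site table, and the configuration.

- **Background structure.** Lineage allele frequencies follow the
  Balding–Nichols model: ancestral frequency $p \sim U(0.05, 0.95)$, lineage
  frequency $\sim \mathrm{Beta}(p(1-F)/F,\ (1-p)(1-F)/F)$ clamped to
  $[0.001, 0.999]$, genotypes binomial. A two-level hierarchy places two of
  the three default lineages under a shared node whose $F$ is half the
  smaller of the two sister lineages' $F$, with tip-level residual drift
  from $1 - F_\text{tip} = (1 - F_\text{lineage}) / (1 - F_\text{node})$.
- **The inversion.** Two non-recombining arrangement pools with independent
  drift; a fraction of inversion sites (default 0.3) are fixed differences
  (frequency 0 in the standard pool, 1 in the inverted pool). Karyotypes are
  $K \sim \mathrm{Binomial}(2, q_\text{lineage})$ and the dosage at an
  inversion site is the sum of $2-K$ draws from the standard pool frequency
  and $K$ draws from the inverted pool frequency — so dosage equals $K$
  exactly at fixed differences.
- **Ascertainment.** `apply_ascertainment()` emulates a mixed
  WGS + reduced-representation cohort: a fixed fraction of sites
  (`rad_site_fraction`, default 0.3) is retained for RAD-labelled samples,
  and uniform genotype missingness (`missing_rate`, default 0.1) is added.

The simulator deliberately does **not** model recombination within
arrangements, gene conversion between arrangements, linked background LD,
selection, or sequencing error; it produces exactly the signal structure the
detector targets plus exchangeable noise, which is what validation against
recorded truth requires.

The default configuration — 3 lineages × 50 samples, one 5 Mb inversion with
600 sites on a 25 Mb chromosome, inverted-arrangement frequencies
$q = 0, 0.5, 1$ across lineages, 5,000 background SNPs over three
chromosomes — is the package's reference problem size: large enough that
windowed statistics stabilize, small enough that the full scan runs in
seconds.

One consequence of ascertainment worth knowing: with default masking the
site-presence filter leaves only a handful of 50-SNP windows genome-wide, too
few for fence-based outlier detection to flag reliably. Karyotyping, LD
blocks and FST confirmation are robust to this; window-level MDS recall is
best assessed on the unmasked cohort.

## Enrichment

Genes are assigned to candidate regions by midpoint (options: any-overlap,
full containment). Per region, each annotation term with at least
`min_genes` (default 10) in-region genes is tested with a two-sided Fisher
exact test against the genome-wide background, p-values are
Benjamini–Hochberg adjusted across terms within the region, and terms with
adjusted p below `alpha` (default 0.05) are reported with an over/under
direction.

## Limitations

- Windows are fixed-size in SNP count, so physical resolution tracks SNP
  density; boundary precision is limited by window and rolling-median width.
- The karyotype caller assumes exactly three clusters along PC1; regions
  where one homokaryotype is absent are flagged degenerate rather than
  genotyped with $k = 2$.
- The Weir–Cockerham confirmation needs at least two samples in each
  homokaryotype class; very skewed arrangement frequencies leave the FST
  flag unset even when other signatures are clear.
- Genotype dosages are treated as known; genotype likelihoods and imputation
  uncertainty are out of scope.
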