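#' Per-sample heterozygosity in windows
#'
#' Heterozygosity per window is the fraction of callable, non-missing sites at
#' which the sample is heterozygous. Windows without any usable site get `NA`
#' (flagged, not zero).
#'
#' @param x A [variant_matrix()].
#' @param sample Sample id.
#' @param frame A [make_windows()] frame built on `x`.
#' @return Data frame `chrom`, `start`, `end`, `n_callable`, `n_het`, `het`.
#' @export
heterozygosity_windows <- function(x, sample, frame) {
  g <- genotypes_of(x, sample)
  use <- x$sites$callable & !is.na(g)
  nw <- n_windows(frame)
  n_call <- .window_sum(as.numeric(use), frame$site_window, nw)
  n_het <- .window_sum(as.numeric(use & g == 1L), frame$site_window, nw)
  out <- frame$windows[, c("chrom", "start", "end")]
  out$n_callable <- n_call
  out$n_het <- n_het
  out$het <- ifelse(n_call > 0, n_het / n_call, NA_real_)
  out
}

#' Pairwise diversity profile (pi1, pi2, pi12) for two diploids
#'
#' For each window and genome-wide, computes the two within-individual
#' heterozygosities `pi1`, `pi2` (fraction of included sites heterozygous in
#' each sample) and the cross-individual divergence `pi12`, the probability
#' that an allele drawn at random from sample 1 differs from an allele drawn
#' at random from sample 2. Per site, with allele dosages `a = g1/2`,
#' `b = g2/2`, the contribution to `pi12` is `a(1-b) + b(1-a)`. Sites missing
#' or non-callable in either sample are excluded from all three statistics, so
#' they share one inclusion set.
#'
#' @param x A [variant_matrix()].
#' @param s1,s2 Sample ids.
#' @param frame A [make_windows()] frame built on `x`.
#' @return A `pair_diversity` object: `windows` data frame (`chrom`, `start`,
#'   `end`, `n_sites`, `pi1`, `pi2`, `pi12`) plus genome-wide sums in
#'   `totals` and the pair labels.
#' @export
pair_pi <- function(x, s1, s2, frame) {
  g1 <- genotypes_of(x, s1)
  g2 <- genotypes_of(x, s2)
  use <- x$sites$callable & !is.na(g1) & !is.na(g2)
  a <- g1 / 2; b <- g2 / 2
  c12 <- a + b - 2 * a * b    # = a(1-b) + b(1-a)
  nw <- n_windows(frame)
  n_inc <- .window_sum(as.numeric(use), frame$site_window, nw)
  h1 <- .window_sum(as.numeric(use & g1 == 1L), frame$site_window, nw)
  h2 <- .window_sum(as.numeric(use & g2 == 1L), frame$site_window, nw)
  s12 <- .window_sum(ifelse(use, c12, NA_real_), frame$site_window, nw)
  win <- frame$windows[, c("chrom", "start", "end")]
  win$n_sites <- n_inc
  win$pi1 <- ifelse(n_inc > 0, h1 / n_inc, NA_real_)
  win$pi2 <- ifelse(n_inc > 0, h2 / n_inc, NA_real_)
  win$pi12 <- ifelse(n_inc > 0, s12 / n_inc, NA_real_)
  structure(list(
    windows = win, s1 = s1, s2 = s2,
    totals = c(n_sites = sum(use), het1 = sum(g1[use] == 1L),
               het2 = sum(g2[use] == 1L), sum12 = sum(c12[use]))
  ), class = "pair_diversity")
}

#' Genomic distance D from a pairwise diversity profile
#'
#' Computes `D = 1 - (pi1 + pi2) / (4 pi12)` per window and genome-wide. The
#' genome-wide value aggregates the pi sums over all included sites before
#' forming the ratio (it is not the mean of window D values). D is 0 for
#' clones, 0.5 for two unrelated individuals from a panmictic population, and
#' approaches 1 for deeply divergent species; related pairs can push the raw
#' value below 0, so a `[0, 1]`-clamped companion column is also returned.
#' Windows with `pi12 = 0` are flagged undefined (`NA`) rather than given a
#' number.
#'
#' @param pd A [pair_pi()] result.
#' @return A `pair_distance` object: the window table gains `D` and
#'   `D_clamped`; `D_genome` and `D_genome_clamped` hold the genome-wide
#'   aggregates.
#' @export
genomic_distance <- function(pd) {
  .assert(inherits(pd, "pair_diversity"), "pd must come from pair_pi()")
  win <- pd$windows
  defined <- !is.na(win$pi12) & win$pi12 > 0
  win$D <- ifelse(defined, 1 - (win$pi1 + win$pi2) / (4 * win$pi12), NA_real_)
  win$D_clamped <- pmin(pmax(win$D, 0), 1)
  tot <- pd$totals
  D_genome <- if (tot[["sum12"]] > 0) {
    1 - (tot[["het1"]] + tot[["het2"]]) / (4 * tot[["sum12"]])
  } else NA_real_
  structure(list(windows = win, s1 = pd$s1, s2 = pd$s2, totals = tot,
                 D_genome = D_genome,
                 D_genome_clamped = min(max(D_genome, 0), 1)),
            class = "pair_distance")
}

#' @exportS3Method base::print
print.pair_distance <- function(x, ...) {
  cat(sprintf("pair_distance %s vs %s: genome-wide D = %.4f over %d sites\n",
              x$s1, x$s2, x$D_genome, x$totals[["n_sites"]]))
  invisible(x)
}

## ---- Weir-Cockerham Fst ---------------------------------------------------

# Variance components of the Weir & Cockerham (1984) two-level estimator for
# one biallelic site. n_i = diploids genotyped, p_i = alt frequency,
# h_i = observed het proportion, per group.
#' @noRd
.wc_site_components <- function(n, p, h) {
  r <- length(n)
  nbar <- mean(n)
  if (nbar <= 1) return(c(a = 0, b = 0, c = 0))
  nc <- (r * nbar - sum(n^2) / (r * nbar)) / (r - 1)
  pbar <- sum(n * p) / (r * nbar)
  s2 <- sum(n * (p - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n * h) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  c(a = a, b = b, c = hbar / 2)
}

#' Weir-Cockerham Fst between two groups of diploids
#'
#' Two-level variance-components estimator for biallelic sites, aggregated as
#' a ratio of sums across sites (vcftools-compatible weighting):
#' `Fst = sum(a) / sum(a + b + c)`. Missing genotypes are excluded per site;
#' sites monomorphic across both groups contribute nothing.
#'
#' @param x A [variant_matrix()].
#' @param samplesA,samplesB Character vectors of sample ids (disjoint groups;
#'   at least two diploids per group recommended).
#' @return List with `fst` (genome-wide estimate; `NA` if no usable site) and
#'   `per_site` (data frame of per-site `a`, `b`, `c` components).
#' @export
fst_wc <- function(x, samplesA, samplesB) {
  .assert(length(intersect(samplesA, samplesB)) == 0, "groups must be disjoint")
  gA <- x$geno[, samplesA, drop = FALSE]
  gB <- x$geno[, samplesB, drop = FALSE]
  nA <- rowSums(!is.na(gA)); nB <- rowSums(!is.na(gB))
  pA <- rowSums(gA, na.rm = TRUE) / (2 * nA)
  pB <- rowSums(gB, na.rm = TRUE) / (2 * nB)
  hA <- rowSums(gA == 1L, na.rm = TRUE) / nA
  hB <- rowSums(gB == 1L, na.rm = TRUE) / nB
  use <- which(x$sites$callable & nA > 0 & nB > 0 & (nA + nB) > 2)
  comp <- matrix(0, nrow = length(use), ncol = 3,
                 dimnames = list(NULL, c("a", "b", "c")))
  for (k in seq_along(use)) {
    i <- use[k]
    comp[k, ] <- .wc_site_components(c(nA[i], nB[i]), c(pA[i], pB[i]),
                                     c(hA[i], hB[i]))
  }
  denom <- sum(comp)
  fst <- if (length(use) && denom != 0) sum(comp[, "a"]) / denom else NA_real_
  list(fst = fst,
       per_site = data.frame(site = use, a = comp[, "a"], b = comp[, "b"],
                             c = comp[, "c"]))
}

#' Build pseudo-diploids from extracted haplotypes
#'
#' Pairs haplotype columns into artificial diploids (genotype = sum of the two
#' haplotype alleles per site), enabling diploid-based estimators such as
#' [fst_wc()] on haplotype subsets (e.g. species-specific haplotypes extracted
#' from hybrids by [interspecific_phase()]). Sites unresolved (`NA`) in either
#' haplotype become missing.
#'
#' @param haps Sites x haplotypes matrix of 0/1/NA alleles.
#' @param sites Site table matching the haplotypes (from the source matrix).
#' @param pairs Two-column matrix/data frame of haplotype column indices or
#'   names, one row per pseudo-diploid.
#' @param ids Optional ids for the pseudo-diploids.
#' @return A [variant_matrix()] of the pseudo-diploids.
#' @export
pseudo_diploid <- function(haps, sites, pairs, ids = NULL) {
  pairs <- as.matrix(pairs)
  .assert(ncol(pairs) == 2, "pairs must have two columns")
  geno <- vapply(seq_len(nrow(pairs)), function(i) {
    h1 <- haps[, pairs[i, 1]]
    h2 <- haps[, pairs[i, 2]]
    .assert(length(h1) == length(h2) && length(h1) == nrow(sites),
            "haplotype length mismatch")
    as.integer(h1 + h2)
  }, integer(nrow(sites)))
  ids <- ids %||% paste0("pd", seq_len(nrow(pairs)))
  variant_matrix(sites, geno, data.frame(id = ids, stringsAsFactors = FALSE))
}

## ---- folded allele-frequency spectrum -------------------------------------

#' Folded allele-frequency spectrum
#'
#' Per site, counts the minor allele over the `2n` haplotypes of the selected
#' samples; bins `k` and `2n - k` are pooled (folded spectrum, indexed
#' `0..n`). Sites with any missing genotype among the samples are excluded, as
#' are sites inside `exclude` intervals (e.g. admixed segments) and
#' non-callable sites.
#'
#' @param x A [variant_matrix()].
#' @param samples Character vector of sample ids (>= 2).
#' @param exclude Optional interval table (`chrom`, `start`, `end`, 0-based
#'   half-open) of regions to drop.
#' @return An `afs` object: `spectrum` (named counts for minor-allele count
#'   0..n), `n_hap`, `n_sites_used`.
#' @export
folded_afs <- function(x, samples, exclude = NULL) {
  .assert(length(samples) >= 2, "need at least two samples")
  g <- x$geno[, samples, drop = FALSE]
  use <- x$sites$callable & rowSums(is.na(g)) == 0L &
    !.pos_in_intervals(x$sites$chrom, x$sites$pos, exclude)
  .assert(any(use), "all sites excluded")
  n_hap <- 2L * length(samples)
  ac <- rowSums(g[use, , drop = FALSE])
  minor <- pmin(ac, n_hap - ac)
  spectrum <- tabulate(minor + 1L, nbins = n_hap %/% 2L + 1L)
  names(spectrum) <- 0:(n_hap %/% 2L)
  structure(list(spectrum = spectrum, n_hap = n_hap, n_sites_used = sum(use)),
            class = "afs")
}

#' @exportS3Method base::print
print.afs <- function(x, ...) {
  cat(sprintf("folded AFS over %d haplotypes, %d sites\n", x$n_hap, x$n_sites_used))
  print(x$spectrum)
  invisible(x)
}
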