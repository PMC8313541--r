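#' Identity-by-state counts per window for a sample pair
#'
#' `IBS2` counts shared heterozygous sites (joint genotype AB|AB) and `IBS0`
#' counts homozygous differences (AA|BB) in each window, over sites callable
#' and non-missing in both samples. Zero counts are legitimate (e.g. a window
#' in which both samples are homozygous identical everywhere).
#'
#' @param x A [variant_matrix()].
#' @param s1,s2 Sample ids.
#' @param frame A [make_windows()] frame built on `x`.
#' @return Data frame `chrom`, `start`, `end`, `n_informative` (jointly
#'   non-missing callable sites), `ibs2`, `ibs0`.
#' @export
ibs_counts <- function(x, s1, s2, frame) {
  g1 <- genotypes_of(x, s1)
  g2 <- genotypes_of(x, s2)
  use <- x$sites$callable & !is.na(g1) & !is.na(g2)
  nw <- n_windows(frame)
  out <- frame$windows[, c("chrom", "start", "end")]
  out$n_informative <- .window_sum(as.numeric(use), frame$site_window, nw)
  out$ibs2 <- .window_sum(as.numeric(use & g1 == 1L & g2 == 1L),
                          frame$site_window, nw)
  out$ibs0 <- .window_sum(as.numeric(use & ((g1 == 0L & g2 == 2L) |
                                              (g1 == 2L & g2 == 0L))),
                          frame$site_window, nw)
  out
}

#' Identity-by-state ratio IBSR = IBS2 / (IBS2 + IBS0)
#'
#' For individuals of one population IBSR is independent of allele frequencies
#' and has mean 2/3 for two unrelated individuals under panmixia; if the pair
#' shares a haplotype across a window then IBS0 = 0 and IBSR = 1. Undefined
#' (`NA`) when both counts are zero.
#'
#' @param ibs2,ibs0 Numeric vectors of window counts.
#' @return Numeric vector of ratios in `[0, 1]`, `NA` where undefined.
#' @export
ibsr <- function(ibs2, ibs0) {
  tot <- ibs2 + ibs0
  ifelse(tot > 0, ibs2 / tot, NA_real_)
}

#' Classify the IBD state of a window from IBSR and D
#'
#' Applies the threshold rule: IBSR < 0.95 gives IBD0; IBSR >= 0.95 with
#' D < 0.05 gives IBD2; IBSR >= 0.95 with D > 0.05 gives IBD1. The boundary
#' D exactly 0.05 (left open by the rule as quoted) is assigned IBD1,
#' the conservative choice that avoids inflating clone calls. Windows with an
#' undefined statistic are `"undetermined"`.
#'
#' @param ibsr_value,window_D Numeric vectors (recycled).
#' @param ibsr_threshold,d_threshold The two decision thresholds.
#' @return Character vector in `{"IBD0", "IBD1", "IBD2", "undetermined"}`.
#' @export
classify_ibd <- function(ibsr_value, window_D,
                         ibsr_threshold = 0.95, d_threshold = 0.05) {
  n <- max(length(ibsr_value), length(window_D))
  ibsr_value <- rep_len(ibsr_value, n)
  window_D <- rep_len(window_D, n)
  out <- rep("undetermined", n)
  ok <- !is.na(ibsr_value) & !is.na(window_D)
  out[ok & ibsr_value < ibsr_threshold] <- "IBD0"
  out[ok & ibsr_value >= ibsr_threshold & window_D < d_threshold] <- "IBD2"
  out[ok & ibsr_value >= ibsr_threshold & window_D >= d_threshold] <- "IBD1"
  out
}

#' Coefficient of relatedness from IBD fractions
#'
#' `r = IBD1/2 + IBD2`, with the fractions taken over classified windows.
#' Expected values: ~1 for clones, ~0.5 for parent-offspring or full sibs,
#' ~0.25 for half sibs, ~0 for unrelated pairs.
#'
#' @param ibd_fractions Named numeric vector with elements `IBD0`, `IBD1`,
#'   `IBD2` summing to 1.
#' @return The coefficient of relatedness.
#' @export
relatedness_r <- function(ibd_fractions) {
  .assert(all(c("IBD1", "IBD2") %in% names(ibd_fractions)),
          "ibd_fractions needs IBD1 and IBD2")
  unname(0.5 * ibd_fractions[["IBD1"]] + ibd_fractions[["IBD2"]])
}

#' Full pairwise IBD profile for two samples
#'
#' Combines [ibs_counts()], [pair_pi()]/[genomic_distance()] window D values,
#' [ibsr()] and [classify_ibd()] into one per-window profile, then aggregates
#' genome-wide IBD0/1/2 fractions over classified windows and the coefficient
#' of relatedness `r`. Windows with fewer than `min_informative` jointly
#' genotyped sites are left undetermined (too little information for a stable
#' IBSR).
#'
#' @param x A [variant_matrix()].
#' @param s1,s2 Sample ids.
#' @param frame A [make_windows()] frame (typically 200-kb bp windows).
#' @param min_informative Minimum jointly genotyped callable sites per window.
#' @param ibsr_threshold,d_threshold Passed to [classify_ibd()].
#' @return A `pair_ibd` object: `windows` (per-window `ibs2`, `ibs0`, `ibsr`,
#'   `D`, `ibd`), `fractions` (IBD0/1/2 over classified windows), `r`,
#'   `n_classified`, and the genome-wide `D_genome`.
#' @export
pair_ibd <- function(x, s1, s2, frame, min_informative = 50,
                     ibsr_threshold = 0.95, d_threshold = 0.05) {
  ibs <- ibs_counts(x, s1, s2, frame)
  pdist <- genomic_distance(pair_pi(x, s1, s2, frame))
  win <- ibs
  win$ibsr <- ibsr(win$ibs2, win$ibs0)
  win$D <- pdist$windows$D
  win$ibd <- classify_ibd(win$ibsr, win$D, ibsr_threshold, d_threshold)
  win$ibd[win$n_informative < min_informative] <- "undetermined"
  classified <- win$ibd %in% c("IBD0", "IBD1", "IBD2")
  .assert(any(classified), "no window could be classified for this pair")
  fr <- table(factor(win$ibd[classified], levels = c("IBD0", "IBD1", "IBD2")))
  fractions <- as.numeric(fr) / sum(fr)
  names(fractions) <- names(fr)
  structure(list(windows = win, s1 = s1, s2 = s2, fractions = fractions,
                 r = relatedness_r(fractions), n_classified = sum(classified),
                 D_genome = pdist$D_genome),
            class = "pair_ibd")
}

#' @exportS3Method base::print
print.pair_ibd <- function(x, ...) {
  cat(sprintf("pair_ibd %s vs %s: IBD0/1/2 = %.3f/%.3f/%.3f, r = %.3f (D = %.3f)\n",
              x$s1, x$s2, x$fractions[["IBD0"]], x$fractions[["IBD1"]],
              x$fractions[["IBD2"]], x$r, x$D_genome))
  invisible(x)
}

## ---- interspecific phasing ------------------------------------------------

#' Phase a hybrid against two parental population panels
#'
#' At each heterozygous site of the hybrid, the two alleles are assigned to
#' the A- and B-derived haplotypes from the panel allele counts. Under the
#' default `"fixed"` rule a site phases only when it is diagnostic: one allele
#' absent from panel A (allele count at most `tolerance`) and fixed in panel
#' B, and vice versa for the other allele. The laxer `"present"` rule assigns
#' an allele to the panel where it occurs whenever it is absent from the other
#' panel; it resolves more sites at the cost of mis-phasing alleles that
#' segregate in both populations but were missed by one panel. Sites where
#' both alleles occur in both panels stay unresolved; homozygous sites
#' contribute their allele to both haplotypes.
#'
#' @param x A [variant_matrix()].
#' @param hybrid Sample id of the putative A x B hybrid.
#' @param panelA,panelB Non-empty character vectors of panel sample ids.
#' @param tolerance Maximum panel allele count still treated as "absent" (and
#'   slack allowed below fixation), to accommodate genotyping error.
#' @param rule `"fixed"` (default) or `"present"`, see above.
#' @return A `phased_pair`: `hapA`, `hapB` (0/1/NA vectors; the A-derived and
#'   B-derived haplotypes), `status` per site in
#'   `{"phased", "homozygous", "unresolved", "missing"}`.
#' @export
interspecific_phase <- function(x, hybrid, panelA, panelB, tolerance = 0,
                                rule = c("fixed", "present")) {
  .assert(length(panelA) >= 1 && length(panelB) >= 1, "panels must be non-empty")
  rule <- match.arg(rule)
  g <- genotypes_of(x, hybrid)
  nA <- rowSums(!is.na(x$geno[, panelA, drop = FALSE]))
  nB <- rowSums(!is.na(x$geno[, panelB, drop = FALSE]))
  altA <- rowSums(x$geno[, panelA, drop = FALSE], na.rm = TRUE)
  altB <- rowSums(x$geno[, panelB, drop = FALSE], na.rm = TRUE)
  refA <- 2 * nA - altA
  refB <- 2 * nB - altB
  M <- length(g)
  hapA <- rep(NA_integer_, M); hapB <- rep(NA_integer_, M)
  status <- rep("unresolved", M)
  status[is.na(g)] <- "missing"
  hom <- !is.na(g) & g != 1L
  hapA[hom] <- hapB[hom] <- as.integer(g[hom] / 2L)
  status[hom] <- "homozygous"
  het <- !is.na(g) & g == 1L & nA > 0 & nB > 0
  if (rule == "fixed") {
    # diagnostic configuration: panels fixed for opposite alleles
    alt_to_A <- het & refA <= tolerance & altB <= tolerance
    alt_to_B <- het & altA <= tolerance & refB <= tolerance
  } else {
    alt_to_B <- het & altA <= tolerance & altB > tolerance
    alt_to_A <- het & altB <= tolerance & altA > tolerance
    ref_to_B <- het & refA <= tolerance & refB > tolerance & !alt_to_A & !alt_to_B
    ref_to_A <- het & refB <= tolerance & refA > tolerance & !alt_to_A & !alt_to_B
    alt_to_A <- alt_to_A | ref_to_B
    alt_to_B <- alt_to_B | ref_to_A
  }
  hapA[alt_to_A] <- 1L; hapB[alt_to_A] <- 0L
  hapA[alt_to_B] <- 0L; hapB[alt_to_B] <- 1L
  status[alt_to_A | alt_to_B] <- "phased"
  structure(list(hapA = hapA, hapB = hapB, status = status, hybrid = hybrid,
                 panelA = panelA, panelB = panelB,
                 unresolved_fraction = mean(status == "unresolved")),
            class = "phased_pair")
}

#' @exportS3Method base::print
print.phased_pair <- function(x, ...) {
  cat(sprintf("phased_pair for %s: %.1f%% phased, %.1f%% homozygous, %.1f%% unresolved\n",
              x$hybrid, 100 * mean(x$status == "phased"),
              100 * mean(x$status == "homozygous"),
              100 * x$unresolved_fraction))
  invisible(x)
}

#' Haplotype identity calls between two haplotype vectors
#'
#' Per window, the mismatch rate is the number of allele disagreements over
#' the sites resolved (non-`NA`) in both haplotypes; two haplotypes are called
#' identical when the rate is below `threshold` (default `2e-4`, which
#' tolerates residual SNP-calling and phasing errors). Windows with no
#' compared site are undetermined.
#'
#' @param h1,h2 0/1/NA allele vectors on the same site list.
#' @param frame A [make_windows()] frame on that site list.
#' @param threshold Mismatch-rate threshold for identity.
#' @return List with `windows` (per-window `n_compared`, `n_mismatch`, `rate`,
#'   `identical`), `rate_genome`, `identical_genome`, and
#'   `fraction_identical` (identical windows / determined windows).
#' @export
haplotype_identity <- function(h1, h2, frame, threshold = 2e-4) {
  .assert(length(h1) == length(h2), "haplotypes must share one site list")
  use <- !is.na(h1) & !is.na(h2)
  mm <- use & h1 != h2
  nw <- n_windows(frame)
  out <- frame$windows[, c("chrom", "start", "end")]
  out$n_compared <- .window_sum(as.numeric(use), frame$site_window, nw)
  out$n_mismatch <- .window_sum(as.numeric(mm), frame$site_window, nw)
  out$rate <- ifelse(out$n_compared > 0, out$n_mismatch / out$n_compared, NA_real_)
  out$identical <- out$rate < threshold
  determined <- !is.na(out$identical)
  list(windows = out,
       rate_genome = sum(mm) / max(sum(use), 1L),
       identical_genome = sum(use) > 0 && sum(mm) / sum(use) < threshold,
       fraction_identical = if (any(determined)) {
         mean(out$identical[determined])
       } else NA_real_)
}

#' Haplotype sharing between a phased haplotype and a diploid genotype
#'
#' Tests whether `hap` could have been transmitted by `sample`: a site
#' mismatches when the haplotype allele is absent from the diploid genotype
#' (haplotype carries alt over a hom-ref genotype or ref over hom-alt).
#' Unlike [haplotype_identity()] this comparison is robust to crossovers in
#' the transmitted gamete, because the parent carries both of its haplotypes;
#' it is the natural test for parent-offspring haplotype sharing when the
#' candidate parent is unphased.
#'
#' @param hap 0/1/NA allele vector on the matrix's site list.
#' @param x A [variant_matrix()].
#' @param sample Candidate parent sample id.
#' @param frame A [make_windows()] frame on `x`.
#' @param threshold Mismatch-rate threshold for calling a window shared.
#' @return Same structure as [haplotype_identity()].
#' @export
haplotype_consistency <- function(hap, x, sample, frame, threshold = 2e-4) {
  g <- genotypes_of(x, sample)
  # het sites of the candidate carry both alleles: never a mismatch, but they
  # are still compared sites
  use <- !is.na(hap) & !is.na(g) & x$sites$callable
  mm <- use & ((hap == 1L & g == 0L) | (hap == 0L & g == 2L))
  nw <- n_windows(frame)
  out <- frame$windows[, c("chrom", "start", "end")]
  out$n_compared <- .window_sum(as.numeric(use), frame$site_window, nw)
  out$n_mismatch <- .window_sum(as.numeric(mm), frame$site_window, nw)
  out$rate <- ifelse(out$n_compared > 0, out$n_mismatch / out$n_compared, NA_real_)
  out$identical <- out$rate < threshold
  determined <- !is.na(out$identical)
  list(windows = out,
       rate_genome = sum(mm) / max(sum(use), 1L),
       identical_genome = sum(use) > 0 && sum(mm) / sum(use) < threshold,
       fraction_identical = if (any(determined)) {
         mean(out$identical[determined])
       } else NA_real_)
}
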