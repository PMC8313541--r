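#' Define a multi-population drift model for genotype simulation
#'
#' Describes a set of ancestral populations that diverged from a common
#' allele-frequency pool under pure drift, parameterized per population by a
#' Balding-Nichols drift coefficient `F` in (0, 1). All populations share one
#' site list (uniformly placed biallelic SNVs on `n_chrom` chromosomes).
#'
#' The default drift coefficients are calibrated so that realized pairwise
#' Weir-Cockerham Fst between simulated founder sets spans roughly 0.49-0.82,
#' matching the differentiation observed among the four ancestral citrus
#' populations (RK = *C. ryukyuensis*, MA = common mandarin, MS = mangshanyeju,
#' PU = pummelo): RK-MA about 0.67, RK-PU about 0.82, MS-MA about 0.49. For a
#' pair of populations drifted independently from the shared ancestral pool,
#' the expected estimate is approximately `(F_i + F_j)/2`.
#'
#' @param pops Character vector of population labels.
#' @param F Named numeric vector of per-population drift coefficients, each
#'   strictly in (0, 1); names must cover `pops`.
#' @param n_chrom Number of chromosomes (default 9, the citrus karyotype).
#' @param chrom_bp Chromosome length in bp (all chromosomes equal). The
#'   default genome is scaled down to 9 x 10 Mbp so that full cohorts build in
#'   seconds while windowed statistics keep realistic information content.
#' @param sites_per_chrom Number of segregating sites simulated per
#'   chromosome. The default density (4 sites per kb) puts ~800 genotyped
#'   sites and some tens of heterozygous sites into a 200-kb window,
#'   emulating the per-window information of deep whole-genome resequencing;
#'   window-level IBS/IBD classification degrades sharply below ~1 site/kb.
#' @param crossover_rate Expected number of crossovers per chromosome per
#'   meiosis (Poisson mean). Default 1.3 approximates a compact plant genetic
#'   map of ~130 cM per chromosome.
#' @param ancestral_shape Length-2 shape parameters of the Beta density from
#'   which ancestral allele frequencies are drawn. The default `c(0.5, 0.5)`
#'   is U-shaped, mimicking a neutral site-frequency spectrum ascertained in
#'   a diverged panel.
#' @return An object of class `population_model`.
#' @examples
#' m <- population_model(n_chrom = 2, sites_per_chrom = 500)
#' m$F
#' @export
population_model <- function(pops = c("RK", "MA", "MS", "PU"),
                             F = c(RK = 0.80, MA = 0.54, MS = 0.44, PU = 0.84),
                             n_chrom = 9,
                             chrom_bp = 10e6,
                             sites_per_chrom = 40000,
                             crossover_rate = 1.3,
                             ancestral_shape = c(0.5, 0.5)) {
  .assert(length(pops) >= 1 && !anyDuplicated(pops), "pops must be unique labels")
  .assert(all(pops %in% names(F)), "F must be named and cover every population")
  F <- F[pops]
  .assert(all(is.finite(F)) && all(F > 0) && all(F < 1),
          "drift parameter F must lie strictly in (0, 1)")
  .assert(n_chrom >= 1 && chrom_bp > 0 && sites_per_chrom >= 1,
          "genome dimensions must be positive")
  .assert(crossover_rate >= 0, "crossover_rate must be >= 0")
  .assert(length(ancestral_shape) == 2 && all(ancestral_shape > 0),
          "ancestral_shape must be two positive Beta shapes")
  structure(list(
    pops = pops, F = F, n_chrom = as.integer(n_chrom),
    chrom_bp = chrom_bp, sites_per_chrom = as.integer(sites_per_chrom),
    crossover_rate = crossover_rate, ancestral_shape = ancestral_shape,
    chroms = paste0("chr", seq_len(n_chrom))
  ), class = "population_model")
}

#' @exportS3Method base::print
print.population_model <- function(x, ...) {
  cat("population_model:", length(x$pops), "populations (",
      paste(x$pops, collapse = ", "), ")\n")
  cat("  F:", paste(sprintf("%s=%.2f", x$pops, x$F), collapse = ", "), "\n")
  cat(sprintf("  genome: %d chromosomes x %.0f bp, %d sites each; crossover rate %.2f\n",
              x$n_chrom, x$chrom_bp, x$sites_per_chrom, x$crossover_rate))
  invisible(x)
}

## ---- pedigree -------------------------------------------------------------

.ped_row <- function(id, role, pop = NA_character_, parentA = NA_character_,
                     parentB = NA_character_, source = NA_character_,
                     somatic_rate = NA_real_, donor_pop = NA_character_,
                     segments = list(NULL), depth = 30) {
  data.frame(id = id, role = role, pop = pop, parentA = parentA,
             parentB = parentB, source = source, somatic_rate = somatic_rate,
             donor_pop = donor_pop,
             segments = I(segments), depth = depth,
             stringsAsFactors = FALSE)
}

#' Pedigree member declarations
#'
#' Building blocks for [pedigree()]: founders drawn from a model population,
#' F1s and general crosses (including selfing/backcrosses) formed from
#' recombinant gametes of previously declared parents, somatic clones, and
#' founders carrying introgressed donor segments on one haplotype.
#'
#' @param id Sample identifier (unique within the pedigree).
#' @param pop,recipient,donor Population labels from the model.
#' @param parentA,parentB Ids of previously declared individuals.
#' @param source Id of the individual being cloned.
#' @param somatic_rate Per-site Bernoulli probability that a clone acquires a
#'   somatic mutation (one allele flipped at the site).
#' @param segments Data frame (`chrom`, `start`, `end`; 0-based half-open bp
#'   coordinates) of donor intervals placed on haplotype 1 of the recipient.
#' @param depth Sequencing-depth proxy carried into the sample metadata (used
#'   by clone-group representative selection).
#' @return One-row pedigree data frame.
#' @seealso [pedigree()], [build_cohort()]
#' @export
ped_founder <- function(id, pop, depth = 30) {
  .ped_row(id, "founder", pop = pop, depth = depth)
}

#' @rdname ped_founder
#' @export
ped_f1 <- function(id, parentA, parentB, depth = 30) {
  .ped_row(id, "f1", parentA = parentA, parentB = parentB, depth = depth)
}

#' @rdname ped_founder
#' @export
ped_cross <- function(id, parentA, parentB, depth = 30) {
  .ped_row(id, "cross", parentA = parentA, parentB = parentB, depth = depth)
}

#' @rdname ped_founder
#' @export
ped_clone <- function(id, source, somatic_rate = 0, depth = 30) {
  .assert(somatic_rate >= 0 && somatic_rate < 1, "somatic_rate must be in [0, 1)")
  .ped_row(id, "clone", source = source, somatic_rate = somatic_rate, depth = depth)
}

#' @rdname ped_founder
#' @export
ped_introgressed <- function(id, recipient, donor, segments, depth = 30) {
  .assert(is.data.frame(segments) &&
            all(c("chrom", "start", "end") %in% names(segments)),
          "segments must be a data frame with chrom, start, end")
  .assert(all(segments$end > segments$start), "segments must have end > start")
  .ped_row(id, "introgressed", pop = recipient, donor_pop = donor,
           segments = list(segments), depth = depth)
}

#' Assemble and validate a pedigree
#'
#' Combines member declarations into an ordered pedigree. Parents and clone
#' sources must be declared before the individuals that reference them;
#' introgressed donor segments must not overlap within a haplotype. Clones of
#' clones are permitted.
#'
#' @param ... One-row declarations from [ped_founder()], [ped_f1()],
#'   [ped_cross()], [ped_clone()], [ped_introgressed()], or data frames of such
#'   rows.
#' @return A `pedigree` data frame.
#' @examples
#' ped <- pedigree(
#'   ped_founder("A1", "RK"), ped_founder("B1", "MA"),
#'   ped_f1("H1", "A1", "B1"), ped_clone("H1c", "H1", somatic_rate = 1e-5)
#' )
#' @export
pedigree <- function(...) {
  ped <- do.call(rbind, list(...))
  .assert(nrow(ped) >= 1, "pedigree is empty")
  .assert(!anyDuplicated(ped$id), "duplicate individual ids in pedigree")
  seen <- character(0)
  for (i in seq_len(nrow(ped))) {
    row <- ped[i, ]
    refs <- stats::na.omit(c(row$parentA, row$parentB, row$source))
    missing <- setdiff(refs, seen)
    .assert(length(missing) == 0,
            paste0("individual '", row$id, "' references undeclared parent(s): ",
                   paste(missing, collapse = ", ")))
    seg <- row$segments[[1]]
    if (!is.null(seg) && nrow(seg) > 1) {
      seg <- seg[order(seg$chrom, seg$start), ]
      ovl <- seg$chrom[-1] == seg$chrom[-nrow(seg)] &
        seg$start[-1] < seg$end[-nrow(seg)]
      .assert(!any(ovl), paste0("overlapping donor segments for '", row$id, "'"))
    }
    seen <- c(seen, row$id)
  }
  class(ped) <- c("pedigree", class(ped))
  ped
}
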