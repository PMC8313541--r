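# Shared simulated fixtures, built once per test run (memoised). All seeds
# are fixed so every run sees the same cohorts.

.fixtures <- new.env(parent = emptyenv())

memo <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

# Compact genome for fast unit tests.
small_model <- function(n_chrom = 2, sites_per_chrom = 3000, ...) {
  population_model(n_chrom = n_chrom, sites_per_chrom = sites_per_chrom, ...)
}

# Standard-scale cohort mirroring the resolved family structure: exemplars
# for the four populations, a mandarin parent with six interspecific F1
# children by distinct RK mothers, clones, an intra-population
# parent-offspring trio and half-sib pair.
family_cohort <- function() memo("family", function() {
  m <- population_model()
  ped <- pedigree(
    ped_founder("PU1", "PU"), ped_founder("PU2", "PU"), ped_founder("PU3", "PU"),
    ped_founder("RK1", "RK"), ped_founder("RK2", "RK"), ped_founder("RK3", "RK"),
    ped_founder("MS1", "MS"), ped_founder("MS2", "MS"),
    ped_founder("MA1", "MA"), ped_founder("MA2", "MA"), ped_founder("MA3", "MA"),
    ped_founder("MA4", "MA"), ped_founder("MA5", "MA"), ped_founder("MA6", "MA"),
    ped_founder("PARENT", "MA", depth = 46),
    ped_founder("RKm1", "RK"), ped_founder("RKm2", "RK"), ped_founder("RKm3", "RK"),
    ped_founder("RKm4", "RK"), ped_founder("RKm5", "RK"), ped_founder("RKm6", "RK"),
    ped_f1("SH1", "PARENT", "RKm1"), ped_f1("SH2", "PARENT", "RKm2"),
    ped_f1("SH3", "PARENT", "RKm3"), ped_f1("SH4", "PARENT", "RKm4"),
    ped_f1("SH5", "PARENT", "RKm5"), ped_f1("SH6", "PARENT", "RKm6"),
    ped_clone("SH2c", "SH2", somatic_rate = 1e-5, depth = 35),
    # intra-population relationships
    ped_cross("PO1", "RK1", "RK2"),   # child of RK1 x RK2
    ped_cross("HS1", "RK1", "RK3"),   # half-sib of PO1 through RK1
    ped_clone("CL0", "RK2", somatic_rate = 0)
  )
  build_cohort(m, ped, seed = 20211)
})

# Phasing panels for the family cohort: every available founder of each
# parental population (mothers included), as one would use a full collection.
family_panels <- function() {
  list(A = c(paste0("RK", 1:3), paste0("RKm", 1:6)), B = paste0("MA", 1:6))
}

# Long-genome cohort for relatedness-coefficient recovery: realized
# half-sib sharing has high variance on a short genome, so this experiment
# uses 9 x 30 Mbp at the same marker density and averages several pairs.
relatedness_cohort <- function() memo("relatedness", function() {
  m <- population_model(chrom_bp = 30e6, sites_per_chrom = 120000)
  ped <- pedigree(
    ped_founder("RK1", "RK"), ped_founder("RK2", "RK"), ped_founder("RK3", "RK"),
    ped_founder("RKm1", "RK"), ped_founder("RKm2", "RK"),
    ped_founder("RKm3", "RK"), ped_founder("RKm4", "RK"),
    ped_cross("K1", "RK1", "RKm1"), ped_cross("K2", "RK1", "RKm2"),
    ped_cross("K3", "RK1", "RKm3"), ped_cross("K4", "RK1", "RKm4"),
    ped_clone("CL", "RK1", somatic_rate = 0)
  )
  build_cohort(m, ped, seed = 101)
})

relatedness_frame <- function() memo("relatedness_frame", function() {
  co <- relatedness_cohort()
  make_windows(co$matrix, "bp_span", 200000,
               chrom_lengths = stats::setNames(
                 rep(co$truth$model$chrom_bp, co$truth$model$n_chrom),
                 co$truth$model$chroms))
})

# Genome fraction over which two children's gametes from their shared parent
# carry the same parental haplotype (the truth value of IBD1 sharing).
truth_half_sib_sharing <- function(co, child_i, child_j) {
  m <- co$truth$model
  oi <- co$truth$transmission[[child_i]]$A
  oj <- co$truth$transmission[[child_j]]$A
  tot <- 0
  for (cc in m$chroms) {
    ci <- oi[oi$chrom == cc, ]; cj <- oj[oj$chrom == cc, ]
    cuts <- sort(unique(c(ci$start, ci$end, cj$start, cj$end)))
    for (b in seq_len(length(cuts) - 1)) {
      mid <- (cuts[b] + cuts[b + 1]) / 2
      hi <- ci$source_hap[ci$start <= mid & mid < ci$end]
      hj <- cj$source_hap[cj$start <= mid & mid < cj$end]
      if (hi == hj) tot <- tot + cuts[b + 1] - cuts[b]
    }
  }
  tot / (m$n_chrom * m$chrom_bp)
}

family_frame <- function() memo("family_frame", function() {
  co <- family_cohort()
  make_windows(co$matrix, "bp_span", 200000,
               chrom_lengths = stats::setNames(
                 rep(co$truth$model$chrom_bp, co$truth$model$n_chrom),
                 co$truth$model$chroms))
})

family_exemplars <- function() {
  list(PU = paste0("PU", 1:3), RK = paste0("RK", 1:3),
       MS = paste0("MS", 1:2), MA = paste0("MA", 1:3))
}

family_aims <- function() memo("family_aims", function() {
  derive_aims(family_cohort()$matrix, family_exemplars())
})

# Exemplar cohort carrying one individual with a single 2.4-Mbp introgressed
# pummelo segment in an otherwise pure mandarin genome.
introgression_cohort <- function() memo("intro", function() {
  m <- population_model()
  ped <- pedigree(
    ped_founder("PU1", "PU"), ped_founder("PU2", "PU"), ped_founder("PU3", "PU"),
    ped_founder("RK1", "RK"), ped_founder("RK2", "RK"), ped_founder("RK3", "RK"),
    ped_founder("MS1", "MS"), ped_founder("MS2", "MS"),
    ped_founder("MA1", "MA"), ped_founder("MA2", "MA"), ped_founder("MA3", "MA"),
    ped_introgressed("INTRO", "MA", "PU",
                     data.frame(chrom = "chr2", start = 4e6, end = 6.4e6))
  )
  build_cohort(m, ped, seed = 31)
})

# Tiny hand-built variant matrix from a genotype matrix (sites x samples).
toy_matrix <- function(geno, ids = NULL, chrom = "chr1", callable = TRUE) {
  geno <- as.matrix(geno)
  ids <- ids %||% paste0("s", seq_len(ncol(geno)))
  M <- nrow(geno)
  variant_matrix(
    data.frame(chrom = chrom, pos = seq_len(M) * 10L, ref = "A", alt = "C",
               callable = callable),
    geno, data.frame(id = ids, stringsAsFactors = FALSE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
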