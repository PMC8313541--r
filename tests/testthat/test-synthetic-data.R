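test_that("Balding-Nichols frequencies are reproducible, drift-limited and validated", {
  m <- small_model()
  s1 <- simulate_frequencies(m, seed = 3)
  s2 <- simulate_frequencies(m, seed = 3)
  expect_identical(s1, s2)
  expect_true(all(diff(s1$sites$pos[s1$sites$chrom == "chr1"]) > 0))
  expect_identical(colnames(s1$freq), m$pops)

  # zero-drift limit: population frequencies collapse onto the ancestral p
  m0 <- population_model(pops = "RK", F = c(RK = 1e-6), n_chrom = 1,
                         sites_per_chrom = 2000)
  s0 <- simulate_frequencies(m0, seed = 5)
  expect_lt(max(abs(s0$freq[, "RK"] - s0$ancestral)), 0.01)

  expect_error(population_model(pops = "RK", F = c(RK = 0)), "strictly")
  expect_error(population_model(pops = "RK", F = c(RK = 1)), "strictly")
})

test_that("realized differentiation between founder sets tracks the drift parameter", {
  fst_at <- function(Fval, seed) {
    m <- population_model(pops = c("A", "B"), F = c(A = Fval, B = Fval),
                          n_chrom = 1, sites_per_chrom = 20000)
    ped <- do.call(pedigree, c(
      lapply(1:4, function(i) ped_founder(paste0("a", i), "A")),
      lapply(1:4, function(i) ped_founder(paste0("b", i), "B"))))
    co <- build_cohort(m, ped, seed = seed)
    fst_wc(co$matrix, paste0("a", 1:4), paste0("b", 1:4))$fst
  }
  f <- vapply(c(0.2, 0.5, 0.8), fst_at, numeric(1), seed = 11)
  expect_true(all(diff(f) > 0))
  # the Weir-Cockerham estimate targets the drift coefficient itself
  expect_lt(abs(f[2] - 0.5), 0.05)
})

test_that("default drift coefficients realize the calibrated Fst targets", {
  co <- family_cohort()
  vm <- co$matrix
  rk <- c(paste0("RK", 1:3), paste0("RKm", 1:6))
  ma <- paste0("MA", 1:6)
  expect_lt(abs(fst_wc(vm, rk, ma)$fst - 0.67), 0.05)
  expect_lt(abs(fst_wc(vm, rk, paste0("PU", 1:3))$fst - 0.82), 0.05)
  expect_lt(abs(fst_wc(vm, c("MS1", "MS2"), ma)$fst - 0.49), 0.05)
})

test_that("founder genotypes follow Hardy-Weinberg proportions", {
  # near-degenerate Beta concentrates the ancestral density at p = 0.5
  m <- population_model(pops = "RK", F = c(RK = 0.5), n_chrom = 1,
                        sites_per_chrom = 100000,
                        ancestral_shape = c(5000, 5000))
  s <- simulate_frequencies(m, seed = 2)
  s$freq[1:5, "RK"] <- 0
  s$freq[6:10, "RK"] <- 1
  g <- sample_founder(s, "RK", seed = 4)
  expect_identical(g[1:5], rep(0L, 5))     # p = 0 -> hom-ref
  expect_identical(g[6:10], rep(2L, 5))    # p = 1 -> hom-alt
  # per-site heterozygosity at the realized frequencies: 2p(1-p) on average
  p <- s$freq[-(1:10), "RK"]
  expected <- mean(2 * p * (1 - p))
  se <- sqrt(expected * (1 - expected) / length(p))
  expect_lt(abs(mean(g[-(1:10)] == 1L) - expected), 3 * se)
})

test_that("gametes recombine at the Poisson rate and propagate parental alleles", {
  m <- small_model(n_chrom = 1, sites_per_chrom = 50)
  s <- simulate_frequencies(m, seed = 6)
  parent <- list(h = cbind(rep(0L, 50), rep(1L, 50)),
                 anc = list(data.frame(chrom = "chr1", start = 0, end = m$chrom_bp,
                                       pop = "RK"),
                            data.frame(chrom = "chr1", start = 0, end = m$chrom_bp,
                                       pop = "RK")))
  gam0 <- make_gamete(parent, s$sites, m$chrom_bp, rate = 0, seed = 9)
  expect_true(all(gam0$allele == 0L) || all(gam0$allele == 1L))
  expect_equal(gam0$n_crossover, 0)

  set.seed(10)
  ks <- replicate(10000, make_gamete(parent, s$sites, m$chrom_bp,
                                     rate = 1.5)$n_crossover)
  expect_lt(abs(mean(ks) - 1.5), 0.05)

  # allele at every site comes from the recorded source haplotype
  set.seed(12)
  parent2 <- list(h = cbind(stats::rbinom(50, 1, 0.5), stats::rbinom(50, 1, 0.5)),
                  anc = parent$anc)
  gam <- make_gamete(parent2, s$sites, m$chrom_bp, rate = 2)
  src <- gam$origin
  for (i in seq_len(50)) {
    hap <- src$source_hap[src$start < s$sites$pos[i] & s$sites$pos[i] <= src$end]
    expect_identical(gam$allele[i], parent2$h[i, hap])
  }
})

test_that("F1s combine one haplotype from each parental population", {
  m <- small_model()
  ped <- pedigree(ped_founder("A", "RK"), ped_founder("B", "MA"),
                  ped_f1("H", "A", "B"))
  co <- build_cohort(m, ped, seed = 13)
  th <- co$truth$haplotypes
  # each F1 haplotype is a mosaic of the corresponding parent's haplotypes
  expect_true(all(th[, "H_h1"] == th[, "A_h1"] | th[, "H_h1"] == th[, "A_h2"]))
  expect_true(all(th[, "H_h2"] == th[, "B_h1"] | th[, "H_h2"] == th[, "B_h2"]))
  # ancestry truth: haplotype 1 fully RK, haplotype 2 fully MA
  anc <- co$truth$ancestry
  h1 <- anc[anc$sample == "H" & anc$haplotype == 1, ]
  expect_true(all(h1$pop == "RK"))
  # F1 heterozygosity exceeds mean founder heterozygosity (differentiated parents)
  het <- function(s) mean(genotypes_of(co$matrix, s) == 1L)
  expect_gt(het("H"), mean(c(het("A"), het("B"))))
})

test_that("cohorts honor clone, introgression and tiling contracts", {
  m <- small_model()
  seg <- data.frame(chrom = "chr2", start = 5e6, end = 7.4e6)
  ped <- pedigree(ped_founder("A", "RK"), ped_founder("B", "MA"),
                  ped_clone("Ac", "A", somatic_rate = 0),
                  ped_introgressed("I", "MA", "PU", seg))
  co <- build_cohort(m, ped, seed = 17)
  expect_identical(genotypes_of(co$matrix, "A"), genotypes_of(co$matrix, "Ac"))

  anc <- co$truth$ancestry
  donor <- anc[anc$sample == "I" & anc$pop == "PU", ]
  expect_equal(nrow(donor), 1L)
  expect_equal(donor$haplotype, 1L)
  expect_equal(donor$start, 5e6)
  expect_equal(donor$end, 7.4e6)

  # ancestry segments tile each haplotype exactly once
  for (s in unique(anc$sample)) for (h in 1:2) for (cc in m$chroms) {
    seg_h <- anc[anc$sample == s & anc$haplotype == h & anc$chrom == cc, ]
    seg_h <- seg_h[order(seg_h$start), ]
    expect_equal(seg_h$start[1], 0)
    expect_equal(seg_h$end[nrow(seg_h)], m$chrom_bp)
    if (nrow(seg_h) > 1) {
      expect_equal(seg_h$start[-1], seg_h$end[-nrow(seg_h)])
    }
  }

  expect_error(pedigree(ped_f1("X", "nope", "A")), "undeclared")
  expect_error(build_cohort(m, pedigree(), seed = 1), "empty")
})

test_that("same configuration and seed give byte-identical emitted datasets", {
  m <- small_model(n_chrom = 1, sites_per_chrom = 500)
  ped <- pedigree(ped_founder("A", "RK"), ped_founder("B", "MA"),
                  ped_f1("H", "A", "B"))
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  emit_dataset(build_cohort(m, ped, seed = 23), d1)
  emit_dataset(build_cohort(m, ped, seed = 23), d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
})

test_that("half-sib children share the transmitted parental haplotype over half the genome", {
  co <- family_cohort()
  kids <- paste0("SH", 1:6)
  share <- c()
  for (i in 1:5) for (j in (i + 1):6) {
    share <- c(share, truth_half_sib_sharing(co, kids[i], kids[j]))
  }
  expect_lt(abs(mean(share) - 0.5), 0.08)
})

test_that("emitted datasets round-trip and truth intervals use BED conventions", {
  co <- family_cohort()
  dir <- withr::local_tempdir()
  paths <- emit_dataset(co, dir)
  back <- read_vcf(paths[["vcf"]])
  expect_identical(unname(back$geno), unname(co$matrix$geno))
  expect_identical(back$sites$pos, co$matrix$sites$pos)
  bed <- utils::read.delim(paths[["truth_bed"]], header = FALSE)
  expect_equal(min(bed$V2), 0)                       # 0-based starts
  expect_equal(max(bed$V3), co$truth$model$chrom_bp) # half-open ends
})
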