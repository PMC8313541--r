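test_that("per-site pi12 contributions match exhaustive allele-draw enumeration", {
  combos <- expand.grid(g1 = 0:2, g2 = 0:2)
  geno <- t(as.matrix(combos))  # 2 samples x 9 sites
  vm <- toy_matrix(t(geno), ids = c("x", "y"))
  fr <- make_windows(vm, "bp_span", 1000)
  pd <- pair_pi(vm, "x", "y", fr)
  # reconstruct per-site contributions from the genome-wide sum site by site
  for (i in seq_len(nrow(combos))) {
    single <- toy_matrix(matrix(as.integer(combos[i, ]), 1, 2), ids = c("x", "y"))
    fr1 <- make_windows(single, "bp_span", 1000)
    got <- pair_pi(single, "x", "y", fr1)$totals[["sum12"]]
    expect_equal(got, oracle_pi12_site(combos$g1[i], combos$g2[i]),
                 label = paste(combos[i, ], collapse = "|"))
  }
  expect_equal(pd$totals[["sum12"]],
               sum(mapply(oracle_pi12_site, combos$g1, combos$g2)))
})

test_that("identical diploids have pi12 = pi1/2, hence D = 0", {
  co <- family_cohort()
  vm <- co$matrix
  dup <- variant_matrix(vm$sites, cbind(vm$geno[, "RK1"], vm$geno[, "RK1"]),
                        data.frame(id = c("a", "b")))
  fr <- make_windows(dup, "bp_span", 200000)
  pd <- pair_pi(dup, "a", "b", fr)
  expect_equal(pd$totals[["sum12"]], pd$totals[["het1"]] / 2)
  expect_identical(genomic_distance(pd)$D_genome, 0)
})

test_that("genomic distance reproduces the closed-form anchor values", {
  # pi1 = pi2 = 0.002, pi12 = 0.004 over 1000 sites -> D = 0.75
  g1 <- rep(0L, 1000); g2 <- rep(0L, 1000)
  g1[1:2] <- 1L; g2[3:4] <- 1L          # four half-contributing sites
  g1[5:6] <- 0L; g2[5:6] <- 2L          # two full-contributing sites
  vm <- toy_matrix(cbind(g1, g2), ids = c("x", "y"))
  fr <- make_windows(vm, "bp_span", 20000)
  pd <- pair_pi(vm, "x", "y", fr)
  expect_equal(pd$totals[["sum12"]], 4)
  expect_equal(genomic_distance(pd)$D_genome, 0.75)

  # pi12 = 0 -> undefined, not a number
  hom <- toy_matrix(cbind(rep(0L, 10), rep(0L, 10)), ids = c("x", "y"))
  frh <- make_windows(hom, "bp_span", 1000)
  dh <- genomic_distance(pair_pi(hom, "x", "y", frh))
  expect_true(is.na(dh$D_genome))
  expect_true(all(is.na(dh$windows$D)))
})

test_that("genome-wide D behaves as the theory predicts on simulated cohorts", {
  co <- family_cohort()
  fr <- family_frame()
  # two unrelated founders from one panmictic population: D = 0.5 +/- 0.02
  d_unrel <- genomic_distance(pair_pi(co$matrix, "RK2", "RK3", fr))$D_genome
  expect_lt(abs(d_unrel - 0.5), 0.02)
  # founders of two differentiated species: D consistently above 0.5
  for (pr in list(c("RK1", "MA1"), c("RK1", "PU1"), c("MS1", "MA1"))) {
    expect_gt(genomic_distance(pair_pi(co$matrix, pr[1], pr[2], fr))$D_genome, 0.5)
  }
  # symmetry
  expect_equal(genomic_distance(pair_pi(co$matrix, "RK1", "MA1", fr))$D_genome,
               genomic_distance(pair_pi(co$matrix, "MA1", "RK1", fr))$D_genome)
})

test_that("between-species D increases with the drift parameter", {
  d_at <- function(Fval) {
    m <- population_model(pops = c("A", "B"), F = c(A = Fval, B = Fval),
                          n_chrom = 1, sites_per_chrom = 20000)
    co <- build_cohort(m, pedigree(ped_founder("a", "A"), ped_founder("b", "B")),
                       seed = 19)
    fr <- make_windows(co$matrix, "bp_span", 200000)
    genomic_distance(pair_pi(co$matrix, "a", "b", fr))$D_genome
  }
  ds <- vapply(c(0.2, 0.5, 0.8), d_at, numeric(1))
  expect_true(all(diff(ds) > 0))
})

test_that("the Weir-Cockerham estimator matches a literal per-site oracle", {
  m <- population_model(pops = c("A", "B"), F = c(A = 0.5, B = 0.5),
                        n_chrom = 1, sites_per_chrom = 20000)
  ped <- do.call(pedigree, c(
    lapply(1:5, function(i) ped_founder(paste0("a", i), "A")),
    lapply(1:5, function(i) ped_founder(paste0("b", i), "B"))))
  co <- build_cohort(m, ped, seed = 29)
  got <- fst_wc(co$matrix, paste0("a", 1:5), paste0("b", 1:5))$fst
  want <- oracle_wc_fst(co$matrix$geno, paste0("a", 1:5), paste0("b", 1:5))
  expect_lt(abs(got - want), 0.05)
  expect_equal(got, want, tolerance = 1e-10)  # same draws: should agree exactly
  # symmetry
  expect_equal(got, fst_wc(co$matrix, paste0("b", 1:5), paste0("a", 1:5))$fst)
})

test_that("Fst is near zero for split samples of one population and <= 0 per site for forced equality", {
  m <- population_model(pops = "A", F = c(A = 0.5), n_chrom = 1,
                        sites_per_chrom = 100000)
  ped <- do.call(pedigree,
                 lapply(1:8, function(i) ped_founder(paste0("a", i), "A")))
  co <- build_cohort(m, ped, seed = 37)
  null_fst <- fst_wc(co$matrix, paste0("a", 1:4), paste0("a", 5:8))$fst
  expect_lt(abs(null_fst), 0.02)

  # identical genotype columns across groups: per-site numerator never positive
  g <- co$matrix$geno[1:2000, 1:4]
  vm <- toy_matrix(cbind(g, g), ids = c(paste0("x", 1:4), paste0("y", 1:4)))
  comp <- fst_wc(vm, paste0("x", 1:4), paste0("y", 1:4))$per_site
  expect_true(all(comp$a <= 1e-12))
})

test_that("pseudo-diploids recover founder-set differentiation from extracted haplotypes", {
  # trivial algebra
  haps <- cbind(c(0L, 1L), c(1L, 1L))
  sites <- data.frame(chrom = "chr1", pos = c(10L, 20L), ref = "A", alt = "C")
  pd <- pseudo_diploid(haps, sites, rbind(c(1, 2)))
  expect_identical(unname(pd$geno[, 1]), c(1L, 2L))
  self <- pseudo_diploid(haps, sites, rbind(c(1, 1), c(2, 2)))
  expect_true(all(self$geno %in% c(0L, 2L)))
  expect_error(pseudo_diploid(haps[1, , drop = FALSE], sites, rbind(c(1, 2))),
               "mismatch")

  co <- family_cohort()
  th <- co$truth$haplotypes
  rk_h <- th[, paste0(rep(paste0("RK", 1:3), each = 2), "_h", 1:2)]
  ma_h <- th[, paste0(rep(paste0("MA", 1:3), each = 2), "_h", 1:2)]
  pdm <- pseudo_diploid(cbind(rk_h, ma_h), co$matrix$sites,
                        cbind(seq(1, 12, by = 2), seq(2, 12, by = 2)),
                        ids = c(paste0("rk", 1:3), paste0("ma", 1:3)))
  fst_pd <- fst_wc(pdm, paste0("rk", 1:3), paste0("ma", 1:3))$fst
  fst_founders <- fst_wc(co$matrix, paste0("RK", 1:3), paste0("MA", 1:3))$fst
  expect_lt(abs(fst_pd - fst_founders), 0.05)
})

test_that("the folded AFS matches a neutral-sampling oracle and its conventions", {
  # 4 samples all heterozygous at one site: minor count 4 of 8 -> bin 4
  vm <- toy_matrix(matrix(c(1L, 1L, 1L, 1L, 0L, 0L, 0L, 0L), nrow = 2,
                          byrow = TRUE))
  a <- folded_afs(vm, vm$samples$id)
  expect_equal(unname(a$spectrum[c("0", "4")]), c(1L, 1L))

  # missing data and excluded intervals drop sites
  vm$geno[1, 1] <- NA_integer_
  expect_equal(folded_afs(vm, vm$samples$id)$n_sites_used, 1L)
  expect_error(folded_afs(vm, vm$samples$id,
                          exclude = data.frame(chrom = "chr1", start = 0,
                                               end = 100)), "excluded")

  m <- population_model(pops = "A", F = c(A = 0.5), n_chrom = 1,
                        sites_per_chrom = 50000)
  ped <- do.call(pedigree,
                 lapply(1:8, function(i) ped_founder(paste0("a", i), "A")))
  co <- build_cohort(m, ped, seed = 41)
  afs <- folded_afs(co$matrix, paste0("a", 1:8))
  expect_equal(sum(afs$spectrum), afs$n_sites_used)
  want <- oracle_afs_expected(co$truth$freq[, "A"], 8)
  tv <- sum(abs(afs$spectrum / sum(afs$spectrum) - want / sum(want))) / 2
  expect_lt(tv, 0.02)
  # a drifted population still yields a spectrum that decays beyond the
  # monomorphic bin, the qualitative signature of sexual reproduction
  poly <- afs$spectrum[-1]
  expect_gt(poly[1], poly[length(poly)])
})

test_that("windowed heterozygosity counts callable non-missing sites only", {
  g <- rep(0L, 5000); g[1:250] <- 1L
  vm <- toy_matrix(cbind(g), ids = "s1")
  fr <- make_windows(vm, "callable_count", 5000)
  expect_equal(heterozygosity_windows(vm, "s1", fr)$het, 0.05)

  vm$geno[1:100, 1] <- NA_integer_   # missing excluded from both counts
  h <- heterozygosity_windows(vm, "s1", fr)
  expect_equal(h$n_callable, 4900)
  expect_equal(h$het, 150 / 4900)

  allhom <- toy_matrix(cbind(rep(0L, 100)))
  fr2 <- make_windows(allhom, "bp_span", 500)
  h2 <- heterozygosity_windows(allhom, "s1", fr2)
  expect_equal(h2$het[h2$n_callable > 0], rep(0, sum(h2$n_callable > 0)))
  expect_true(all(is.na(h2$het[h2$n_callable == 0])))

  # simulated founder at p ~ 0.5 everywhere (negligible drift): het ~ 0.5 (HWE)
  mm <- population_model(pops = "A", F = c(A = 1e-6), n_chrom = 1,
                         sites_per_chrom = 20000,
                         ancestral_shape = c(5000, 5000))
  cc <- build_cohort(mm, pedigree(ped_founder("a1", "A")), seed = 43)
  frc <- make_windows(cc$matrix, "callable_count", 2000)
  hw <- heterozygosity_windows(cc$matrix, "a1", frc)
  expect_lt(abs(mean(hw$het) - 0.5), 0.03)
})
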