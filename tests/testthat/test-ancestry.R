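test_that("the AIM rule accepts fixed diagnostic sites and rejects leaked alleles", {
  # columns: RK1 RK2 | MA1 MA2 | PU1
  geno <- rbind(
    c(2L, 2L, 0L, 0L, 0L),   # RK AIM (alt fixed in RK, absent elsewhere)
    c(2L, 2L, 0L, 1L, 0L),   # alt present once outside RK: not an AIM
    c(2L, 1L, 0L, 0L, 0L),   # not fixed in RK: not an AIM
    c(0L, 0L, 2L, 2L, 2L),   # RK AIM on the REF allele (all others fixed alt)
    c(2L, 2L, NA, 0L, 0L),   # missing exemplar genotype: skipped
    c(0L, 0L, 2L, 2L, 0L))   # MA AIM
  vm <- toy_matrix(geno, ids = c("RK1", "RK2", "MA1", "MA2", "PU1"))
  ex <- list(RK = c("RK1", "RK2"), MA = c("MA1", "MA2"), PU = "PU1")
  aims <- derive_aims(vm, ex, super = list())
  rk <- aims$aims[aims$aims$target == "RK", ]
  expect_setequal(rk$site, c(1L, 4L))
  expect_identical(rk$allele[match(c(1L, 4L), rk$site)], c(1L, 0L))
  expect_identical(aims$aims$site[aims$aims$target == "MA"], 6L)
  # exclusion intervals mask exemplar segments (site 1 falls in RK1's mask)
  aims2 <- derive_aims(vm, ex, exclude = data.frame(
    sample = "RK1", chrom = "chr1", start = 0, end = 15), super = list())
  expect_false(1L %in% aims2$aims$site)
  expect_error(derive_aims(vm, list(RK = character(0))), "no exemplars")
})

test_that("super-population markers are fixed in the union and disjoint from member AIMs", {
  geno <- rbind(
    c(0L, 0L, 2L, 2L, 2L, 2L),   # MM AIM: fixed in MA+MS, absent in RK/PU
    c(0L, 0L, 2L, 2L, 0L, 0L))   # MA AIM only
  vm <- toy_matrix(geno, ids = c("RK1", "PU1", "MA1", "MA2", "MS1", "MS2"))
  ex <- list(RK = "RK1", PU = "PU1", MA = c("MA1", "MA2"), MS = c("MS1", "MS2"))
  aims <- derive_aims(vm, ex)
  expect_identical(aims$aims$target[aims$aims$site == 1L], "MM")
  expect_identical(aims$aims$target[aims$aims$site == 2L], "MA")
  # disjointness per (site, allele) across all targets
  key <- paste(aims$aims$site, aims$aims$allele)
  expect_equal(anyDuplicated(key), 0L)
})

test_that("AIM derivation equals a brute-force exemplar scan on a simulated instance", {
  m <- population_model(n_chrom = 1, sites_per_chrom = 10000)
  ped <- pedigree(
    ped_founder("PU1", "PU"), ped_founder("PU2", "PU"), ped_founder("PU3", "PU"),
    ped_founder("RK1", "RK"), ped_founder("RK2", "RK"), ped_founder("RK3", "RK"),
    ped_founder("MS1", "MS"), ped_founder("MS2", "MS"),
    ped_founder("MA1", "MA"), ped_founder("MA2", "MA"), ped_founder("MA3", "MA"))
  co <- build_cohort(m, ped, seed = 53)
  ex <- family_exemplars()
  got <- derive_aims(co$matrix, ex)$aims
  want <- oracle_aim_scan(co$matrix, ex)
  got_key <- sort(paste(got$site, got$target, got$allele))
  want_key <- sort(paste(want$site, want$target, want$allele))
  expect_identical(got_key, want_key)
})

test_that("planted fixed differences are recovered exactly as AIMs", {
  set.seed(61)
  M <- 400
  base <- matrix(rbinom(M * 6, 2, 0.5), M, 6)
  planted <- sort(sample.int(M, 25))
  base[planted, ] <- 0L
  base[planted, 1:2] <- 2L   # fixed alt in pop A only
  vm <- toy_matrix(base, ids = c("A1", "A2", "B1", "B2", "C1", "C2"))
  aims <- derive_aims(vm, list(A = c("A1", "A2"), B = c("B1", "B2"),
                               C = c("C1", "C2")), super = list())
  got_planted <- aims$aims$site[aims$aims$target == "A" & aims$aims$allele == 1L]
  expect_true(all(planted %in% got_planted))
})

test_that("window likelihoods agree with an exhaustive scorer and apply the call rules", {
  co <- family_cohort()
  aims <- family_aims()
  tr <- window_ancestry(co$matrix, "SH1", aims)
  # exhaustive re-scoring of the first three windows
  frame <- make_windows(co$matrix, "marker_count", 500, subset = aims$aims$site)
  wid <- frame$site_window[aims$aims$site]
  g <- genotypes_of(co$matrix, "SH1")[aims$aims$site]
  dosage <- ifelse(aims$aims$allele == 1L, g, 2L - g)
  for (w in 1:3) {
    inw <- which(wid == w)
    want <- oracle_window_loglik(dosage[inw], aims$aims$target[inw],
                                 aims$pops, aims$super, epsilon = 0.01)
    best <- names(want)[which.max(want)]
    expect_identical(tr$windows$call[w], best)
    expect_equal(tr$windows$loglik[w], unname(max(want)), tolerance = 1e-10)
    expect_equal(tr$windows$margin[w],
                 unname(max(want) - sort(want, decreasing = TRUE)[2]),
                 tolerance = 1e-10)
  }
  expect_error(window_ancestry(co$matrix, "SH1", aims, epsilon = 0.7), "epsilon")
})

test_that("windows lacking five AIMs of every population become Unknown", {
  co <- family_cohort()
  aims <- family_aims()
  # thin the RK AIMs so no window can retain five of them
  a <- aims$aims
  thin <- aims
  rk_rows <- which(a$target == "RK")
  thin$aims <- a[-rk_rows[-seq_len(4)], ]
  tr <- window_ancestry(co$matrix, "SH1", thin)
  expect_true(all(tr$windows$call[tr$windows$n_RK < 5] == "Unknown"))
  expect_true(any(tr$windows$n_RK < 5))
})

test_that("F1s and pure founders receive the correct window calls and proportions", {
  co <- family_cohort()
  aims <- family_aims()
  tr <- window_ancestry(co$matrix, "SH1", aims)
  w <- tr$windows
  called <- w$call != "Unknown"
  expect_gte(mean(w$call[called] == "MA/RK"), 0.99)
  # 50:50 admixture within +/- 0.02 per parental population
  prop <- tr$proportions
  known <- 1 - prop[["Unknown"]]
  expect_lt(abs(prop[["RK"]] / known - 0.5), 0.02)
  expect_lt(abs(prop[["MA"]] / known - 0.5), 0.02)

  purity <- window_ancestry(co$matrix, "RKm1", aims)
  wp <- purity$windows
  calledp <- wp$call != "Unknown"
  het_pair <- grepl("/", wp$call[calledp]) &
    !wp$call[calledp] %in% c("RK/RK", "MA/MA", "MS/MS", "PU/PU")
  expect_lte(mean(het_pair), 0.01)
  expect_gte(purity$proportions[["RK"]] / (1 - purity$proportions[["Unknown"]]),
             0.98)
})

test_that("segment merging absorbs blips and reports bp coordinates", {
  fake <- structure(list(windows = data.frame(
    chrom = "chr1",
    start = seq(0, 800, by = 200), end = seq(200, 1000, by = 200),
    call = c("A/A", "A/A", "A/A", "B/B", "B/B"))), class = "ancestry_track")
  segs <- merge_segments(fake, min_windows = 1)
  expect_equal(segs$call, c("A/A", "B/B"))
  expect_equal(segs$n_windows, c(3L, 2L))
  expect_equal(segs$start, c(0, 600))

  blip <- fake
  blip$windows$call <- c("A/A", "B/B", "A/A", "A/A", "A/A")
  segs2 <- merge_segments(blip, min_windows = 2)
  expect_equal(segs2$call, "A/A")
  expect_equal(segs2$n_windows, 5L)

  isolated <- fake
  isolated$windows$call <- c("A/A", "A/A", "C/C", "B/B", "B/B")
  segs3 <- merge_segments(isolated, min_windows = 2)
  expect_identical(segs3$call, c("A/A", "B/B"))
})

test_that("a single planted multi-megabase introgression is detected", {
  co <- introgression_cohort()
  aims <- derive_aims(co$matrix, family_exemplars())
  tr <- window_ancestry(co$matrix, "INTRO", aims)
  segs <- merge_segments(tr)
  donor <- segs[segs$call == "MA/PU", ]
  expect_equal(nrow(donor), 1L)
  expect_identical(donor$chrom, "chr2")
  # boundaries within one window of the truth segment (4-6.4 Mbp)
  wwidth <- stats::median(tr$windows$end - tr$windows$start)
  expect_lt(abs(donor$start - 4e6), wwidth + 1)
  expect_lt(abs(donor$end - 6.4e6), wwidth + 1)
  # everything away from the segment is called pure mandarin
  expect_true(all(segs$call[segs$chrom == "chr1"] == "MA/MA"))
})
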