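# Independent oracle implementations used to cross-check the package. These
# deliberately share no code with R/: literal transcriptions and brute-force
# enumerations only.

# Weir & Cockerham (1984) theta-hat, written as an explicit per-site loop
# straight from the published variance-component formulas.
oracle_wc_fst <- function(geno, idxA, idxB) {
  num <- 0; den <- 0
  for (i in seq_len(nrow(geno))) {
    gA <- geno[i, idxA]; gA <- gA[!is.na(gA)]
    gB <- geno[i, idxB]; gB <- gB[!is.na(gB)]
    if (length(gA) == 0 || length(gB) == 0) next
    r <- 2
    n1 <- length(gA); n2 <- length(gB)
    if ((n1 + n2) <= 2) next
    p1 <- sum(gA) / (2 * n1); p2 <- sum(gB) / (2 * n2)
    h1 <- mean(gA == 1); h2 <- mean(gB == 1)
    nbar <- (n1 + n2) / 2
    if (nbar <= 1) next
    nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
    pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
    ssq <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
    hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
    a <- (nbar / nc) *
      (ssq - 1 / (nbar - 1) *
         (pbar * (1 - pbar) - (r - 1) / r * ssq - hbar / 4))
    b <- (nbar / (nbar - 1)) *
      (pbar * (1 - pbar) - (r - 1) / r * ssq -
         (2 * nbar - 1) / (4 * nbar) * hbar)
    cc <- hbar / 2
    num <- num + a
    den <- den + a + b + cc
  }
  num / den
}

# Probability that two alleles drawn at random, one from each diploid
# genotype, differ -- by exhaustive enumeration of the 2 x 2 draws.
oracle_pi12_site <- function(g1, g2) {
  alleles1 <- c(rep(0, 2 - g1), rep(1, g1))
  alleles2 <- c(rep(0, 2 - g2), rep(1, g2))
  mean(outer(alleles1, alleles2, `!=`))
}

# Expected folded AFS for n_dip diploids given true per-site frequencies:
# allele count ~ Binomial(2 n_dip, p), folded.
oracle_afs_expected <- function(pvec, n_dip) {
  n_hap <- 2 * n_dip
  ks <- 0:n_hap
  spec <- numeric(n_hap %/% 2 + 1)
  for (p in pvec) {
    pr <- stats::dbinom(ks, n_hap, p)
    folded <- pmin(ks, n_hap - ks)
    for (k in unique(folded)) {
      spec[k + 1] <- spec[k + 1] + sum(pr[folded == k])
    }
  }
  spec
}

# Brute-force AIM scan: per site, per target population, test the
# fixed-in-target / absent-in-others rule with explicit loops.
oracle_aim_scan <- function(vm, exemplars, super = list(MM = c("MA", "MS"))) {
  all_ex <- unique(unlist(exemplars))
  targets <- c(
    stats::setNames(lapply(names(exemplars), function(p) exemplars[[p]]),
                    names(exemplars)),
    stats::setNames(lapply(super, function(m) unlist(exemplars[m])),
                    names(super)))
  out <- list()
  for (i in seq_len(nrow(vm$sites))) {
    if (!vm$sites$callable[i]) next
    gx <- vm$geno[i, all_ex]
    if (any(is.na(gx))) next
    for (tg in names(targets)) {
      members <- targets[[tg]]
      others <- setdiff(all_ex, members)
      gm <- vm$geno[i, members]
      go <- vm$geno[i, others]
      for (allele in c(0L, 1L)) {
        hom <- if (allele == 1L) all(gm == 2L) else all(gm == 0L)
        cnt_o <- if (allele == 1L) sum(go) else sum(2L - go)
        if (hom && cnt_o == 0L) {
          out[[length(out) + 1L]] <- data.frame(
            site = i, target = tg, allele = allele)
        }
      }
    }
  }
  do.call(rbind, out)
}

# Exhaustive window-ancestry scorer: loops over every unordered population
# pair and every AIM in the window, summing binomial log-likelihoods.
oracle_window_loglik <- function(dosage, target, pops, super, epsilon) {
  prs <- list()
  for (i in seq_along(pops)) for (j in i:length(pops)) {
    prs[[length(prs) + 1L]] <- c(pops[i], pops[j])
  }
  res <- stats::setNames(numeric(length(prs)), vapply(prs, function(pr) {
    paste(sort(pr), collapse = "/")
  }, ""))
  for (k in seq_along(prs)) {
    tot <- 0
    for (a in seq_along(dosage)) {
      if (is.na(dosage[a])) next
      tg <- target[a]
      members <- if (tg %in% names(super)) super[[tg]] else tg
      mcount <- sum(prs[[k]] %in% members)
      q <- c(epsilon, 0.5, 1 - epsilon)[mcount + 1]
      tot <- tot + stats::dbinom(dosage[a], 2, q, log = TRUE)
    }
    res[k] <- tot
  }
  res
}

# Classical MDS by explicit Torgerson double-centering, as an independent
# check of the cmdscale-based implementation.
oracle_torgerson <- function(D, k) {
  n <- nrow(D)
  J <- diag(n) - matrix(1 / n, n, n)
  B <- -0.5 * J %*% (D^2) %*% J
  e <- eigen(B, symmetric = TRUE)
  keep <- seq_len(k)
  e$vectors[, keep, drop = FALSE] %*% diag(sqrt(pmax(e$values[keep], 0)), k)
}
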