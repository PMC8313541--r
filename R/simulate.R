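#' Simulate per-population allele frequencies under Balding-Nichols drift
#'
#' Draws a shared site list (uniform positions, sorted, deduplicated) and an
#' ancestral allele frequency `p` per site from the model's Beta density, then
#' for each population draws the population frequency from
#' `Beta(p(1-F)/F, (1-p)(1-F)/F)`, the Balding-Nichols model in which `F` is
#' the drift (coancestry) coefficient: `E[p_pop] = p`,
#' `Var[p_pop] = F p(1-p)`. As `F -> 0` all population frequencies collapse
#' onto `p`.
#'
#' @param model A [population_model()].
#' @param seed Integer seed; identical `(model, seed)` give identical tables.
#' @return A `pop_frequencies` list with elements `sites` (data frame `chrom`,
#'   `pos` (1-based), `ref`, `alt`, `callable`), `ancestral` (numeric vector),
#'   `freq` (sites x populations matrix), plus the model and seed echo.
#' @examples
#' sim <- simulate_frequencies(population_model(n_chrom = 1, sites_per_chrom = 100), seed = 1)
#' head(sim$freq)
#' @export
simulate_frequencies <- function(model, seed) {
  .assert(inherits(model, "population_model"), "model must be a population_model")
  set.seed(seed)
  M <- model$n_chrom * model$sites_per_chrom
  chrom <- rep(model$chroms, each = model$sites_per_chrom)
  pos <- unlist(lapply(seq_len(model$n_chrom), function(i) {
    sort(sample.int(model$chrom_bp, model$sites_per_chrom))
  }))
  bases <- c("A", "C", "G", "T")
  ref_i <- sample.int(4, M, replace = TRUE)
  alt_i <- (ref_i - 1L + sample.int(3, M, replace = TRUE)) %% 4L + 1L
  eps <- 1e-6
  p <- pmin(pmax(stats::rbeta(M, model$ancestral_shape[1], model$ancestral_shape[2]),
                 eps), 1 - eps)
  freq <- vapply(model$pops, function(pp) {
    Fp <- model$F[[pp]]
    stats::rbeta(M, p * (1 - Fp) / Fp, (1 - p) * (1 - Fp) / Fp)
  }, numeric(M))
  structure(list(
    sites = data.frame(chrom = chrom, pos = pos, ref = bases[ref_i],
                       alt = bases[alt_i], callable = TRUE,
                       stringsAsFactors = FALSE),
    ancestral = p, freq = freq, model = model, seed = seed
  ), class = "pop_frequencies")
}

# Two phased Bernoulli haplotypes for one founder (HWE by construction).
#' @noRd
.founder_haps <- function(pvec) {
  M <- length(pvec)
  cbind(stats::rbinom(M, 1L, pvec), stats::rbinom(M, 1L, pvec))
}

#' Draw one diploid founder genotype vector from population frequencies
#'
#' Genotypes are the sum of two independent Bernoulli haplotypes, so each site
#' is `Binomial(2, p_pop)` and Hardy-Weinberg proportions hold in expectation.
#'
#' @param freqs A `pop_frequencies` object from [simulate_frequencies()].
#' @param pop Population label to sample from.
#' @param seed Optional integer seed; if `NULL` the current RNG stream is used.
#' @return Integer vector of genotype codes (0 hom-ref, 1 het, 2 hom-alt).
#' @export
sample_founder <- function(freqs, pop, seed = NULL) {
  .assert(inherits(freqs, "pop_frequencies"), "freqs must come from simulate_frequencies()")
  .assert(pop %in% colnames(freqs$freq), paste0("unknown population '", pop, "'"))
  if (!is.null(seed)) set.seed(seed)
  h <- .founder_haps(freqs$freq[, pop])
  as.integer(h[, 1] + h[, 2])
}

# Internal representation of a simulated individual:
#   list(h = M x 2 0/1 matrix,
#        anc = list of two data frames (chrom, start, end, pop), 0-based half-open)

.founder_individual <- function(freqs, pop) {
  model <- freqs$model
  anc <- data.frame(chrom = model$chroms, start = 0, end = model$chrom_bp,
                    pop = pop, stringsAsFactors = FALSE)
  list(h = .founder_haps(freqs$freq[, pop]), anc = list(anc, anc))
}

#' Form a recombinant gamete from a phased parent
#'
#' Draws a Poisson number of crossovers per chromosome (uniform positions),
#' starts from a randomly chosen parental haplotype, and alternates parental
#' origin at each crossover. Ancestry labels carried by the parental
#' haplotypes propagate onto the gamete.
#'
#' @param parent A list with `h` (sites x 2 matrix of 0/1 alleles) and `anc`
#'   (list of two ancestry interval tables `chrom`, `start`, `end`, `pop`),
#'   e.g. an individual from [build_cohort()]'s truth set.
#' @param sites Site table (`chrom`, `pos`) the haplotypes are indexed by.
#' @param chrom_bp Chromosome length in bp.
#' @param rate Expected crossovers per chromosome (Poisson mean).
#' @param seed Optional integer seed.
#' @return List with `allele` (0/1 vector), `anc` (ancestry intervals of the
#'   gamete), `origin` (intervals `chrom`, `start`, `end`, `source_hap`
#'   recording which parental haplotype each block came from) and `n_crossover`.
#' @export
make_gamete <- function(parent, sites, chrom_bp, rate, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  chroms <- unique(sites$chrom)
  allele <- integer(nrow(sites))
  anc_out <- list(); origin_out <- list(); n_xo <- 0L
  for (cc in chroms) {
    idx <- which(sites$chrom == cc)
    pos <- sites$pos[idx]
    k <- stats::rpois(1L, rate)
    n_xo <- n_xo + k
    xo <- sort(stats::runif(k, 0, chrom_bp))
    first <- sample.int(2L, 1L)
    # origin haplotype for each site: alternates at each crossover
    ori_site <- (first - 1L + findInterval(pos - 0.5, xo)) %% 2L + 1L
    allele[idx] <- parent$h[idx, 1L] * (ori_site == 1L) +
      parent$h[idx, 2L] * (ori_site == 2L)
    bounds <- c(0, xo, chrom_bp)
    ori_iv <- (first - 1L + seq_len(length(bounds) - 1L) - 1L) %% 2L + 1L
    for (b in seq_along(ori_iv)) {
      lo <- bounds[b]; hi <- bounds[b + 1L]
      if (hi <= lo) next
      origin_out[[length(origin_out) + 1L]] <-
        data.frame(chrom = cc, start = lo, end = hi, source_hap = ori_iv[b],
                   stringsAsFactors = FALSE)
      seg <- .iv_clip(parent$anc[[ori_iv[b]]], cc, lo, hi)
      if (nrow(seg)) anc_out[[length(anc_out) + 1L]] <- seg
    }
  }
  anc <- .iv_merge(do.call(rbind, anc_out), "pop")
  origin <- .iv_merge(do.call(rbind, origin_out), "source_hap")
  rownames(anc) <- rownames(origin) <- NULL
  list(allele = as.integer(allele), anc = anc, origin = origin, n_crossover = n_xo)
}

#' Materialize a pedigree into genotypes plus ground truth
#'
#' Simulates allele frequencies, then walks the pedigree in declaration order:
#' founders get two Bernoulli haplotypes; `f1`/`cross` individuals get one
#' recombinant gamete from each parent; clones copy their source with somatic
#' mutations flipping one allele at Bernoulli-selected sites; introgressed
#' individuals are recipient-population founders whose haplotype 1 carries
#' donor-population alleles over the declared segments.
#'
#' @param model A [population_model()].
#' @param ped A [pedigree()].
#' @param seed Integer seed controlling frequencies and all meioses.
#' @return List with `matrix` (a [variant_matrix()]) and `truth` (a
#'   `truth_set`: ancestry intervals per haplotype, gamete transmission
#'   origins, phased haplotypes, pedigree, per-population frequencies, seed and
#'   model echo).
#' @examples
#' m <- population_model(n_chrom = 2, sites_per_chrom = 300)
#' ped <- pedigree(ped_founder("A1", "RK"), ped_founder("B1", "MA"),
#'                 ped_f1("H1", "A1", "B1"))
#' cohort <- build_cohort(m, ped, seed = 7)
#' cohort$matrix
#' @export
build_cohort <- function(model, ped, seed) {
  .assert(inherits(ped, "pedigree") || is.data.frame(ped), "ped must be a pedigree")
  .assert(nrow(ped) >= 1, "pedigree is empty: a cohort needs at least one individual")
  freqs <- simulate_frequencies(model, seed)
  sites <- freqs$sites
  M <- nrow(sites)
  inds <- list()
  trans <- list()
  for (i in seq_len(nrow(ped))) {
    row <- ped[i, ]
    ind <- switch(row$role,
      founder = .founder_individual(freqs, row$pop),
      f1 = ,
      cross = {
        gA <- make_gamete(inds[[row$parentA]], sites, model$chrom_bp, model$crossover_rate)
        gB <- make_gamete(inds[[row$parentB]], sites, model$chrom_bp, model$crossover_rate)
        trans[[row$id]] <- list(A = cbind(gA$origin, parent = row$parentA),
                                B = cbind(gB$origin, parent = row$parentB))
        list(h = cbind(gA$allele, gB$allele), anc = list(gA$anc, gB$anc))
      },
      clone = {
        src <- inds[[row$source]]
        h <- src$h
        if (row$somatic_rate > 0) {
          hit <- which(stats::runif(M) < row$somatic_rate)
          if (length(hit)) {
            which_hap <- sample.int(2L, length(hit), replace = TRUE)
            flip <- cbind(hit, which_hap)
            h[flip] <- 1L - h[flip]
          }
        }
        list(h = h, anc = src$anc)
      },
      introgressed = {
        ind <- .founder_individual(freqs, row$pop)
        donor_hap <- stats::rbinom(M, 1L, freqs$freq[, row$donor_pop])
        seg <- row$segments[[1]]
        in_seg <- .pos_in_intervals(sites$chrom, sites$pos, seg)
        ind$h[in_seg, 1L] <- donor_hap[in_seg]
        anc1 <- ind$anc[[1]]
        pieces <- list()
        for (cc in unique(anc1$chrom)) {
          segs_c <- seg[seg$chrom == cc, , drop = FALSE]
          cuts <- sort(unique(c(0, model$chrom_bp, segs_c$start, segs_c$end)))
          for (b in seq_len(length(cuts) - 1L)) {
            lo <- cuts[b]; hi <- cuts[b + 1L]
            is_donor <- nrow(segs_c) && any(segs_c$start <= lo & segs_c$end >= hi)
            pieces[[length(pieces) + 1L]] <- data.frame(
              chrom = cc, start = lo, end = hi,
              pop = if (is_donor) row$donor_pop else row$pop,
              stringsAsFactors = FALSE)
          }
        }
        ind$anc[[1]] <- .iv_merge(do.call(rbind, pieces), "pop")
        ind
      },
      stop("unknown pedigree role: ", row$role)
    )
    inds[[row$id]] <- ind
  }
  geno <- vapply(inds, function(x) as.integer(x$h[, 1] + x$h[, 2]), integer(M))
  colnames(geno) <- ped$id
  samples <- data.frame(id = ped$id, population = ped$pop, role = ped$role,
                        depth = ped$depth, stringsAsFactors = FALSE)
  vm <- variant_matrix(sites, geno, samples)
  anc_tab <- do.call(rbind, lapply(ped$id, function(id) {
    rbind(cbind(sample = id, haplotype = 1L, inds[[id]]$anc[[1]]),
          cbind(sample = id, haplotype = 2L, inds[[id]]$anc[[2]]))
  }))
  rownames(anc_tab) <- NULL
  haps <- do.call(cbind, lapply(inds, function(x) x$h))
  colnames(haps) <- paste0(rep(ped$id, each = 2), "_h", 1:2)
  truth <- structure(list(
    ancestry = anc_tab[, c("sample", "haplotype", "chrom", "start", "end", "pop")],
    transmission = trans, haplotypes = haps, pedigree = ped,
    freq = freqs$freq, ancestral = freqs$ancestral,
    seed = seed, model = model
  ), class = "truth_set")
  list(matrix = vm, truth = truth)
}

#' Write a simulated cohort to disk
#'
#' Emits a VCF v4.2 (GT only) via [write_matrix()], a tab-delimited sample
#' metadata table (`sample`, `population`, `role`, `depth_proxy`), the truth
#' ancestry intervals as a BED-like table (`chrom`, `start`, `end`, `sample`,
#' `haplotype`, `population`; 0-based half-open starts), the per-population
#' allele-frequency table, and a YAML echo of the model configuration and
#' seed. The VCF round-trips losslessly through [read_vcf()].
#'
#' @param cohort A list from [build_cohort()].
#' @param out_dir Output directory (created if absent).
#' @return Named character vector of the written file paths, invisibly.
#' @export
emit_dataset <- function(cohort, out_dir) {
  vm <- cohort$matrix; truth <- cohort$truth
  .assert(n_samples(vm) >= 1,
          "refusing to emit a VCF with zero samples: cohort/pedigree is empty")
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  model <- truth$model
  paths <- c(
    vcf = file.path(out_dir, "genotypes.vcf"),
    samples = file.path(out_dir, "samples.tsv"),
    truth_bed = file.path(out_dir, "truth_ancestry.bed"),
    freq = file.path(out_dir, "population_frequencies.tsv"),
    config = file.path(out_dir, "config.yaml")
  )
  write_matrix(vm, paths[["vcf"]], contig_lengths = stats::setNames(
    rep(model$chrom_bp, model$n_chrom), model$chroms))
  meta <- data.frame(sample = vm$samples$id, population = vm$samples$population,
                     role = vm$samples$role, depth_proxy = vm$samples$depth)
  utils::write.table(meta, paths[["samples"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  bed <- truth$ancestry[, c("chrom", "start", "end", "sample", "haplotype", "pop")]
  utils::write.table(format(bed, scientific = FALSE, trim = TRUE),
                     paths[["truth_bed"]], sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  utils::write.table(
    cbind(vm$sites[, c("chrom", "pos")], round(truth$freq, 6)),
    paths[["freq"]], sep = "\t", quote = FALSE, row.names = FALSE)
  yaml::write_yaml(list(
    seed = truth$seed,
    model = list(pops = model$pops, F = as.list(model$F),
                 n_chrom = model$n_chrom, chrom_bp = model$chrom_bp,
                 sites_per_chrom = model$sites_per_chrom,
                 crossover_rate = model$crossover_rate,
                 ancestral_shape = model$ancestral_shape)
  ), paths[["config"]])
  invisible(paths)
}
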