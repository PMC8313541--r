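#' Demonstration pipeline configuration
#'
#' Builds a complete [run_end_to_end()] configuration whose simulated cohort
#' mirrors the family structure resolved in Ryukyuan citrus: four ancestral
#' populations with exemplars, one mainland-mandarin-like parent carrying a
#' single 2.4-Mbp introgressed pummelo segment, six interspecific F1 children
#' by distinct RK mothers (a half-sib family sharing that one parent), a
#' somatic clone of one child, and a clone of the parent.
#'
#' @param n_chrom,sites_per_chrom,chrom_bp Genome scale knobs forwarded to
#'   [population_model()] (defaults are the package's standard desk scale).
#' @param seed Integer seed.
#' @return A config list for [run_end_to_end()].
#' @export
default_demo_config <- function(n_chrom = 9, sites_per_chrom = 40000,
                                chrom_bp = 10e6, seed = 2021) {
  intro_seg <- data.frame(chrom = "chr2", start = 4e6, end = 6.4e6)
  ped <- pedigree(
    ped_founder("PU1", "PU"), ped_founder("PU2", "PU"), ped_founder("PU3", "PU"),
    ped_founder("RK1", "RK"), ped_founder("RK2", "RK"), ped_founder("RK3x", "RK"),
    ped_founder("MS1", "MS"), ped_founder("MS2", "MS"),
    ped_founder("MA1", "MA"), ped_founder("MA2", "MA"), ped_founder("MA3", "MA"),
    ped_founder("MA4", "MA"), ped_founder("MA5", "MA"), ped_founder("MA6", "MA"),
    ped_introgressed("PARENT", "MA", "PU", intro_seg, depth = 46),
    ped_clone("PARENTc", "PARENT", somatic_rate = 1e-5, depth = 20),
    ped_founder("RKm1", "RK"), ped_founder("RKm2", "RK"), ped_founder("RKm3", "RK"),
    ped_founder("RKm4", "RK"), ped_founder("RKm5", "RK"), ped_founder("RKm6", "RK"),
    ped_f1("SH1", "PARENT", "RKm1"), ped_f1("SH2", "PARENT", "RKm2"),
    ped_f1("SH3", "PARENT", "RKm3"), ped_f1("SH4", "PARENT", "RKm4"),
    ped_f1("SH5", "PARENT", "RKm5"), ped_f1("SH6", "PARENT", "RKm6"),
    ped_clone("SH2c", "SH2", somatic_rate = 1e-5, depth = 35)
  )
  list(
    seed = seed,
    model = list(n_chrom = n_chrom, sites_per_chrom = sites_per_chrom,
                 chrom_bp = chrom_bp),
    pedigree = ped,
    windows = list(bp_span = 200000, het_sites = 2000, aims = 500,
                   min_aims_per_pop = 5),
    thresholds = list(ibsr = 0.95, d = 0.05, hap_mismatch = 2e-4,
                      clone_d = 0.02, epsilon = 0.01, margin = 2,
                      min_informative = 50),
    exemplars = list(PU = c("PU1", "PU2", "PU3"),
                     RK = c("RK1", "RK2", "RK3x"),
                     MS = c("MS1", "MS2"),
                     MA = c("MA1", "MA2", "MA3")),
    phase = list(hybrids = paste0("SH", 1:6),
                 panelA = c("RK1", "RK2", "RK3x", paste0("RKm", 1:6)),
                 panelB = paste0("MA", 1:6),
                 candidates = c("PARENT", "MA1", "MS1"))
  )
}

.config_keys <- c("seed", "model", "pedigree", "vcf", "samples", "windows",
                  "thresholds", "exemplars", "phase", "stages")

#' Validate a pipeline configuration
#'
#' Rejects unknown keys and checks stage prerequisites (a simulation block or
#' an input VCF; exemplars whenever the ancestry stage is enabled; a mandatory
#' seed when simulating) before any compute happens.
#'
#' @param config Config list (see [default_demo_config()]).
#' @return The config, with defaults filled in.
#' @export
validate_config <- function(config) {
  unknown <- setdiff(names(config), .config_keys)
  .assert(length(unknown) == 0,
          paste0("unknown config key(s): ", paste(unknown, collapse = ", ")))
  config$stages <- config$stages %||%
    c("divergence", "structure", "ancestry", "relatedness", "report")
  has_sim <- !is.null(config$pedigree) && !is.null(config$model)
  .assert(has_sim || !is.null(config$vcf),
          "config needs either a simulation block (model + pedigree) or an input vcf")
  if (has_sim) .assert(!is.null(config$seed), "simulation requires a seed")
  if ("ancestry" %in% config$stages) {
    .assert(!is.null(config$exemplars) && length(config$exemplars) > 0,
            "ancestry stage enabled but no exemplars configured")
  }
  config$windows <- utils::modifyList(
    list(bp_span = 200000, het_sites = 2000, aims = 500, min_aims_per_pop = 5),
    config$windows %||% list())
  config$thresholds <- utils::modifyList(
    list(ibsr = 0.95, d = 0.05, hap_mismatch = 2e-4, clone_d = 0.02,
         epsilon = 0.01, margin = 2, min_informative = 50),
    config$thresholds %||% list())
  config
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' Simulate (or ingest), then compute per-sample heterozygosity, the pairwise
#' D matrix, clone groups and MDS, ancestry-informative markers and per-sample
#' local ancestry, pairwise IBD/relatedness, interspecific phasing with
#' parentage calls, and a report. Every stage writes a tab-delimited table
#' under `out_dir`; a `manifest.json` records the seed, thresholds and md5 of
#' every output, so a rerun with the same config and seed reproduces identical
#' tables.
#'
#' @param config A config list (see [default_demo_config()]); validated by
#'   [validate_config()] before any compute.
#' @param out_dir Output directory.
#' @return Invisibly, a list with the key in-memory results (`matrix`,
#'   `truth`, `dmat`, `clones`, `mds`, `aims`, `tracks`, `relatedness`,
#'   `parentage`, `manifest`).
#' @export
run_end_to_end <- function(config, out_dir) {
  config <- validate_config(config)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  files <- character(0)
  t0 <- proc.time()[["elapsed"]]
  stage_msg <- function(name) {
    message(sprintf("[%6.1fs] stage: %s", proc.time()[["elapsed"]] - t0, name))
  }
  truth <- NULL
  if (!is.null(config$pedigree)) {
    stage_msg("simulate")
    model <- do.call(population_model, config$model %||% list())
    cohort <- build_cohort(model, config$pedigree, config$seed)
    files <- c(files, emit_dataset(cohort, out_dir))
    vm <- cohort$matrix
    truth <- cohort$truth
  } else {
    stage_msg("ingest")
    vm <- read_vcf(config$vcf)
    if (!is.null(config$samples)) {
      meta <- utils::read.delim(config$samples, stringsAsFactors = FALSE)
      vm$samples <- merge(vm$samples["id"], meta, by.x = "id",
                          by.y = names(meta)[1], all.x = TRUE, sort = FALSE)
    }
  }
  ids <- vm$samples$id
  chrom_len <- if (!is.null(truth)) {
    stats::setNames(rep(truth$model$chrom_bp, truth$model$n_chrom),
                    truth$model$chroms)
  } else NULL
  frame200 <- make_windows(vm, "bp_span", config$windows$bp_span,
                           chrom_lengths = chrom_len)
  res <- list(matrix = vm, truth = truth)

  if ("divergence" %in% config$stages) {
    stage_msg("divergence")
    hs <- min(config$windows$het_sites, max(sum(vm$sites$callable) %/% 4, 1))
    frame_het <- make_windows(vm, "callable_count", hs)
    het <- do.call(rbind, lapply(ids, function(s) {
      cbind(sample = s, heterozygosity_windows(vm, s, frame_het))
    }))
    files <- c(files, het = .write_tsv(het, file.path(out_dir, "het_windows.tsv")))
    dmat <- genome_distance_matrix(vm)
    files <- c(files, dmat = .write_tsv(
      data.frame(sample = rownames(dmat$D), round(dmat$D, 6),
                 check.names = FALSE),
      file.path(out_dir, "d_matrix.tsv")))
    res$dmat <- dmat
    res$het <- het
  }

  if ("structure" %in% config$stages) {
    stage_msg("structure")
    depth <- stats::setNames(vm$samples$depth %||% rep(0, length(ids)), ids)
    clones <- collapse_clones(res$dmat, depth, config$thresholds$clone_d)
    files <- c(files, clones = .write_tsv(clones, file.path(out_dir, "clone_groups.tsv")))
    reps <- attr(clones, "representatives")
    mds <- withCallingHandlers(
      classical_mds(structure(list(
        D_clamped = res$dmat$D_clamped[reps, reps, drop = FALSE]),
        class = "distance_matrix"), k = 3),
      warning = function(w) {
        message("structure: ", conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    mds_tab <- data.frame(sample = rownames(mds$coords),
                          round(mds$coords, 6), check.names = FALSE)
    names(mds_tab)[-1] <- paste0("dim", seq_len(ncol(mds$coords)))
    files <- c(files, mds = .write_tsv(mds_tab, file.path(out_dir, "mds_coords.tsv")))
    res$clones <- clones
    res$mds <- mds
  }

  if ("ancestry" %in% config$stages) {
    stage_msg("ancestry")
    aims <- derive_aims(vm, config$exemplars)
    files <- c(files, aims = .write_tsv(aims$aims, file.path(out_dir, "aims.tsv")))
    targets <- setdiff(ids, unlist(config$exemplars))
    tracks <- lapply(targets, function(s) {
      window_ancestry(vm, s, aims, config$windows$aims,
                      config$windows$min_aims_per_pop,
                      config$thresholds$epsilon, config$thresholds$margin)
    })
    names(tracks) <- targets
    prop <- do.call(rbind, lapply(tracks, function(tr) {
      data.frame(sample = tr$sample, t(round(tr$proportions, 4)),
                 check.names = FALSE)
    }))
    segs <- do.call(rbind, lapply(tracks, function(tr) {
      s <- merge_segments(tr)
      if (nrow(s)) cbind(sample = tr$sample, s) else NULL
    }))
    files <- c(files,
               admixture = .write_tsv(prop, file.path(out_dir, "admixture_proportions.tsv")),
               segments = .write_tsv(
                 segs %||% data.frame(),
                 file.path(out_dir, "ancestry_segments.tsv")))
    res$aims <- aims
    res$tracks <- tracks
    res$admixture <- prop
  }

  if ("relatedness" %in% config$stages) {
    stage_msg("relatedness")
    prs <- utils::combn(ids, 2)
    rel <- do.call(rbind, lapply(seq_len(ncol(prs)), function(k) {
      pi <- tryCatch(
        pair_ibd(vm, prs[1, k], prs[2, k], frame200,
                 config$thresholds$min_informative, config$thresholds$ibsr,
                 config$thresholds$d),
        error = function(e) NULL)
      if (is.null(pi)) return(NULL)
      data.frame(s1 = pi$s1, s2 = pi$s2,
                 IBD0 = pi$fractions[["IBD0"]], IBD1 = pi$fractions[["IBD1"]],
                 IBD2 = pi$fractions[["IBD2"]], r = pi$r, D = pi$D_genome)
    }))
    files <- c(files, relatedness = .write_tsv(
      within(rel, {IBD0 <- round(IBD0, 4); IBD1 <- round(IBD1, 4)
                   IBD2 <- round(IBD2, 4); r <- round(r, 4); D <- round(D, 4)}),
      file.path(out_dir, "relatedness.tsv")))
    res$relatedness <- rel
    if (!is.null(config$phase)) {
      ph <- config$phase
      parentage <- do.call(rbind, lapply(ph$hybrids, function(h) {
        phased <- interspecific_phase(vm, h, ph$panelA, ph$panelB)
        do.call(rbind, lapply(setdiff(ph$candidates, h), function(cand) {
          consA <- haplotype_consistency(phased$hapA, vm, cand, frame200,
                                         config$thresholds$hap_mismatch)
          consB <- haplotype_consistency(phased$hapB, vm, cand, frame200,
                                         config$thresholds$hap_mismatch)
          data.frame(hybrid = h, candidate = cand,
                     haplotype = c("A", "B"),
                     fraction_identical = round(c(consA$fraction_identical,
                                                  consB$fraction_identical), 4),
                     shared = c(consA$fraction_identical,
                                consB$fraction_identical) >= 0.99)
        }))
      }))
      files <- c(files, parentage = .write_tsv(
        parentage, file.path(out_dir, "parentage.tsv")))
      res$parentage <- parentage
    }
  }

  manifest <- list(
    package = "hybridscope",
    version = as.character(utils::packageVersion("hybridscope")),
    seed = config$seed,
    windows = config$windows,
    thresholds = config$thresholds,
    stages = config$stages,
    files = lapply(stats::setNames(as.list(files), basename(unlist(files))),
                   function(f) list(md5 = unname(tools::md5sum(f))))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  res$manifest <- manifest

  if ("report" %in% config$stages) {
    stage_msg("report")
    render_report(out_dir, res)
  }
  stage_msg("done")
  invisible(res)
}

#' Render figures and a text summary from pipeline outputs
#'
#' Produces an admixture stacked-bar figure, an MDS scatter and a windowed
#' heterozygosity violin (PNG), plus `summary.txt` with, per sample, the
#' population call, admixture proportions and top relatives by `r`, and any
#' parentage calls from haplotype sharing. Stages whose outputs are absent are
#' skipped with a notice in the summary.
#'
#' @param out_dir Pipeline output directory.
#' @param res Optional in-memory result list from [run_end_to_end()]; when
#'   `NULL` the tables are re-read from `out_dir`.
#' @return Paths of the written report files, invisibly.
#' @export
render_report <- function(out_dir, res = NULL) {
  read_if <- function(name) {
    p <- file.path(out_dir, name)
    if (file.exists(p)) utils::read.delim(p, check.names = FALSE) else NULL
  }
  admix <- read_if("admixture_proportions.tsv")
  mds_tab <- read_if("mds_coords.tsv")
  het <- read_if("het_windows.tsv")
  rel <- read_if("relatedness.tsv")
  parentage <- read_if("parentage.tsv")
  clones <- read_if("clone_groups.tsv")
  .assert(!is.null(rel) || !is.null(admix) || !is.null(mds_tab),
          paste0("no stage outputs found under ", out_dir))
  written <- character(0)
  if (!is.null(admix)) {
    long <- stats::reshape(admix, direction = "long",
                           varying = setdiff(names(admix), "sample"),
                           v.names = "fraction", timevar = "population",
                           times = setdiff(names(admix), "sample"))
    p <- ggplot2::ggplot(long, ggplot2::aes(x = sample, y = fraction,
                                            fill = population)) +
      ggplot2::geom_col() +
      ggplot2::labs(y = "genome fraction", x = NULL,
                    title = "Local-ancestry admixture proportions") +
      ggplot2::theme_minimal() +
      ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
    f <- file.path(out_dir, "admixture.png")
    ggplot2::ggsave(f, p, width = 8, height = 4, dpi = 120)
    written <- c(written, f)
  }
  if (!is.null(mds_tab) && nrow(mds_tab) > 2) {
    p <- ggplot2::ggplot(mds_tab, ggplot2::aes(x = dim1, y = dim2,
                                               label = sample)) +
      ggplot2::geom_point() +
      ggplot2::geom_text(vjust = -0.6, size = 2.5) +
      ggplot2::labs(title = "MDS of pairwise genomic distance D") +
      ggplot2::theme_minimal()
    f <- file.path(out_dir, "mds.png")
    ggplot2::ggsave(f, p, width = 6, height = 5, dpi = 120)
    written <- c(written, f)
  }
  if (!is.null(het)) {
    keep <- !is.na(het$het)
    p <- ggplot2::ggplot(het[keep, ], ggplot2::aes(x = sample, y = het)) +
      ggplot2::geom_violin(scale = "width", fill = "grey80") +
      ggplot2::labs(y = "heterozygous fraction per window", x = NULL,
                    title = "Windowed heterozygosity") +
      ggplot2::theme_minimal() +
      ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
    f <- file.path(out_dir, "heterozygosity.png")
    ggplot2::ggsave(f, p, width = 8, height = 4, dpi = 120)
    written <- c(written, f)
  }
  lines <- c("hybridscope pipeline summary", "===========================", "")
  samples <- unique(c(admix$sample, rel$s1, rel$s2))
  for (s in samples) {
    lines <- c(lines, sprintf("sample %s", s))
    if (!is.null(admix) && s %in% admix$sample) {
      row <- admix[admix$sample == s, -1, drop = FALSE]
      best <- names(row)[which.max(as.numeric(row))]
      lines <- c(lines,
                 sprintf("  ancestry call: %s (%s)", best,
                         paste(sprintf("%s=%.2f", names(row), as.numeric(row)),
                               collapse = ", ")))
    }
    if (!is.null(rel)) {
      mine <- rel[rel$s1 == s | rel$s2 == s, , drop = FALSE]
      if (nrow(mine)) {
        mine$other <- ifelse(mine$s1 == s, mine$s2, mine$s1)
        mine <- mine[order(-mine$r), ]
        top <- utils::head(mine, 3)
        lines <- c(lines, sprintf("  top relatives: %s",
                                  paste(sprintf("%s (r=%.2f)", top$other, top$r),
                                        collapse = ", ")))
      }
    }
    if (!is.null(clones) && s %in% clones$sample) {
      grp <- clones$group[clones$sample == s]
      mates <- setdiff(clones$sample[clones$group == grp], s)
      if (length(mates)) {
        lines <- c(lines, sprintf("  clone group with: %s",
                                  paste(mates, collapse = ", ")))
      }
    }
  }
  if (!is.null(parentage)) {
    shared <- parentage[parentage$shared, , drop = FALSE]
    lines <- c(lines, "", "parentage calls (haplotype sharing):")
    if (nrow(shared)) {
      lines <- c(lines, sprintf(
        "  %s haplotype %s is carried by %s (identical in %.1f%% of windows)",
        shared$hybrid, shared$haplotype, shared$candidate,
        100 * shared$fraction_identical))
    } else {
      lines <- c(lines, "  none")
    }
  } else {
    lines <- c(lines, "", "[phasing stage not run: parentage section omitted]")
  }
  f <- file.path(out_dir, "summary.txt")
  writeLines(lines, f)
  invisible(c(written, f))
}
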