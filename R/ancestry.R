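#' Derive ancestry-informative markers (AIMs) from population exemplars
#'
#' An AIM for target population T is a biallelic SNV whose diagnostic allele
#' is homozygous in every T exemplar but absent (allele count 0) from all
#' other populations' exemplars. A super-population (default `MM`, the union
#' of the two mandarin subspecies MA and MS) captures markers fixed in the
#' combined group relative to the remaining populations; such sites are by
#' construction not AIMs of the constituent populations, so targets stay
#' disjoint per (site, allele). Sites with a missing exemplar genotype are
#' skipped, as are sites falling in a sample's exclusion intervals (e.g.
#' admixed segments of an exemplar).
#'
#' @param x A [variant_matrix()].
#' @param exemplars Named list mapping population label to exemplar sample ids
#'   (each population needs at least one exemplar).
#' @param exclude Optional data frame (`sample`, `chrom`, `start`, `end`;
#'   0-based half-open) masking admixed exemplar segments.
#' @param super Named list of super-populations, each a character vector of
#'   member population labels; `list()` for none.
#' @return An `aim_set`: data frame `site` (row index in `x`), `chrom`, `pos`,
#'   `target`, `allele` (0 = ref diagnostic, 1 = alt diagnostic), with the
#'   exemplar map attached.
#' @export
derive_aims <- function(x, exemplars, exclude = NULL,
                        super = list(MM = c("MA", "MS"))) {
  .assert(is.list(exemplars) && length(names(exemplars)) == length(exemplars),
          "exemplars must be a named list")
  for (pp in names(exemplars)) {
    .assert(length(exemplars[[pp]]) >= 1,
            paste0("population '", pp, "' has no exemplars"))
  }
  pops <- names(exemplars)
  geno <- x$geno
  if (!is.null(exclude) && nrow(exclude)) {
    for (k in seq_len(nrow(exclude))) {
      hit <- x$sites$chrom == exclude$chrom[k] &
        x$sites$pos > exclude$start[k] & x$sites$pos <= exclude$end[k]
      geno[hit, exclude$sample[k]] <- NA_integer_
    }
  }
  super <- super[vapply(super, function(m) all(m %in% pops), logical(1))]
  targets <- c(as.list(stats::setNames(pops, pops)), super)
  all_ex <- unique(unlist(exemplars))
  any_missing <- rowSums(is.na(geno[, all_ex, drop = FALSE])) > 0L
  rows <- list()
  for (tg in names(targets)) {
    members <- unlist(exemplars[targets[[tg]]])
    others <- setdiff(all_ex, members)
    gm <- geno[, members, drop = FALSE]
    go <- geno[, others, drop = FALSE]
    alt_fixed_t <- rowSums(gm == 2L) == length(members)
    ref_fixed_t <- rowSums(gm == 0L) == length(members)
    alt_cnt_o <- rowSums(go)
    ref_cnt_o <- 2L * length(others) - alt_cnt_o
    ok <- x$sites$callable & !any_missing
    is_alt_aim <- ok & alt_fixed_t & alt_cnt_o == 0L
    is_ref_aim <- ok & ref_fixed_t & ref_cnt_o == 0L
    idx <- which(is_alt_aim | is_ref_aim)
    if (length(idx)) {
      rows[[tg]] <- data.frame(
        site = idx, chrom = x$sites$chrom[idx], pos = x$sites$pos[idx],
        target = tg, allele = as.integer(is_alt_aim[idx]),
        stringsAsFactors = FALSE)
    }
  }
  aims <- do.call(rbind, rows)
  if (is.null(aims)) {
    aims <- data.frame(site = integer(0), chrom = character(0), pos = integer(0),
                       target = character(0), allele = integer(0))
  }
  aims <- aims[order(match(aims$chrom, unique(x$sites$chrom)), aims$pos), ]
  rownames(aims) <- NULL
  structure(list(aims = aims, pops = pops, super = super,
                 exemplars = exemplars),
            class = "aim_set")
}

#' @exportS3Method base::print
print.aim_set <- function(x, ...) {
  cat("aim_set:", nrow(x$aims), "markers\n")
  print(table(x$aims$target))
  invisible(x)
}

# matrix of matches: does AIM target tg count population pp as "self"?
#' @noRd
.aim_matches <- function(target, pop, super) {
  target == pop | vapply(target, function(tg) {
    !is.null(super[[tg]]) && pop %in% super[[tg]]
  }, logical(1))
}

#' Likelihood-based local ancestry in AIM windows
#'
#' Scores every unordered pair of ancestral populations (including homozygous
#' pairs) for each window of `window_size` consecutive AIMs, using a binomial
#' dosage model with genotyping-error rate `epsilon`: at an AIM diagnostic for
#' population T, the expected diagnostic-allele frequency is `1 - epsilon` if
#' both haplotype ancestries match T, `1/2` if exactly one matches, and
#' `epsilon` if none; the observed diagnostic-allele dosage is
#' `Binomial(2, q)`. Super-population AIMs (e.g. MM) match any member
#' population. A window is called `Unknown` when any ancestral population has
#' fewer than `min_aims_per_pop` scored AIMs in it, or when the log-likelihood
#' margin between the best and second-best pair falls below `margin`.
#'
#' @param x A [variant_matrix()].
#' @param sample Sample id to call.
#' @param aimset An [derive_aims()] result.
#' @param window_size AIMs per window (windows are non-overlapping runs in
#'   genome order and never cross chromosomes).
#' @param min_aims_per_pop Minimum scored AIMs per ancestral population for a
#'   window to be callable.
#' @param epsilon Genotyping-error rate in (0, 0.5).
#' @param margin Minimum log-likelihood margin; ties go to `Unknown`.
#' @return An `ancestry_track`: `windows` (per-window AIM counts per
#'   population, `call` such as `"MA/RK"`, `loglik`, `margin`), `proportions`
#'   (per-population genome fractions plus `Unknown`, summing to 1), and the
#'   configuration echo.
#' @export
window_ancestry <- function(x, sample, aimset, window_size = 500,
                            min_aims_per_pop = 5, epsilon = 0.01, margin = 2) {
  .assert(epsilon > 0 && epsilon < 0.5, "epsilon must be in (0, 0.5)")
  aims <- aimset$aims
  .assert(nrow(aims) > 0, "empty AIM set")
  g <- genotypes_of(x, sample)[aims$site]
  dosage <- ifelse(aims$allele == 1L, g, 2L - g)
  scored <- !is.na(dosage)
  # windows of `window_size` AIMs per chromosome, genome order
  frame <- make_windows(x, "marker_count", window_size, subset = aims$site)
  wid <- frame$site_window[aims$site]
  nw <- n_windows(frame)
  pops <- aimset$pops
  pairs <- t(utils::combn(seq_along(pops), 2))
  pairs <- rbind(cbind(seq_along(pops), seq_along(pops)), pairs)
  pair_names <- apply(pairs, 1, function(pr) {
    paste(sort(pops[pr]), collapse = "/")
  })
  # per-AIM log-likelihood for 0, 1 or 2 matching haplotype ancestries
  ll <- cbind(stats::dbinom(dosage, 2, epsilon, log = TRUE),
              stats::dbinom(dosage, 2, 0.5, log = TRUE),
              stats::dbinom(dosage, 2, 1 - epsilon, log = TRUE))
  match_pop <- vapply(pops, function(pp) {
    .aim_matches(aims$target, pp, aimset$super)
  }, logical(nrow(aims)))
  win_ll <- matrix(NA_real_, nw, nrow(pairs), dimnames = list(NULL, pair_names))
  for (k in seq_len(nrow(pairs))) {
    m <- match_pop[, pairs[k, 1]] + match_pop[, pairs[k, 2]]
    lk <- ll[cbind(seq_len(nrow(aims)), m + 1L)]
    lk[!scored] <- NA_real_
    win_ll[, k] <- .window_sum(lk, wid, nw)
  }
  # AIM availability per base population (scored AIMs only; super-population
  # markers are not counted toward the per-population minimum)
  counts <- vapply(pops, function(pp) {
    .window_sum(as.numeric(scored & aims$target == pp), wid, nw)
  }, numeric(nw))
  colnames(counts) <- paste0("n_", pops)
  ord <- t(apply(win_ll, 1, order, decreasing = TRUE))
  best <- pair_names[ord[, 1]]
  loglik <- win_ll[cbind(seq_len(nw), ord[, 1])]
  second <- win_ll[cbind(seq_len(nw), ord[, 2])]
  marg <- loglik - second
  call <- best
  call[apply(counts < min_aims_per_pop, 1, any)] <- "Unknown"
  call[!is.na(marg) & marg < margin] <- "Unknown"
  call[is.na(loglik)] <- "Unknown"
  win <- cbind(frame$windows[, c("chrom", "start", "end", "n_sites")],
               as.data.frame(counts))
  win$call <- call
  win$loglik <- loglik
  win$margin <- marg
  # haplotype-weighted proportions: each called window contributes 1/2 per
  # member of its ancestry pair; Unknown reported as its own share
  prop <- stats::setNames(numeric(length(pops)), pops)
  known <- call != "Unknown"
  if (any(known)) {
    for (w in which(known)) {
      pr <- strsplit(call[w], "/", fixed = TRUE)[[1]]
      prop[pr[1]] <- prop[pr[1]] + 0.5
      prop[pr[2]] <- prop[pr[2]] + 0.5
    }
    prop <- prop / sum(known)
  }
  unk <- mean(!known)
  proportions <- c(prop * (1 - unk), Unknown = unk)
  structure(list(windows = win, sample = sample, proportions = proportions,
                 window_size = window_size, min_aims_per_pop = min_aims_per_pop,
                 epsilon = epsilon, margin = margin, pops = pops),
            class = "ancestry_track")
}

#' @exportS3Method base::print
print.ancestry_track <- function(x, ...) {
  cat(sprintf("ancestry_track for %s: %d windows\n", x$sample, nrow(x$windows)))
  print(round(x$proportions, 3))
  invisible(x)
}

#' Merge consecutive ancestry windows into segments
#'
#' Consecutive windows (within a chromosome) carrying the same ancestry call
#' are merged. Runs shorter than `min_windows` are absorbed into the flanking
#' call when both flanks agree, otherwise set to `Unknown`; `Unknown` windows
#' are excluded from the final segment table (they appear as gaps).
#'
#' @param track An [window_ancestry()] result.
#' @param min_windows Minimum run length (in windows) to stand on its own.
#' @return Data frame `chrom`, `start`, `end`, `call`, `n_windows`.
#' @export
merge_segments <- function(track, min_windows = 2) {
  win <- track$windows
  segs <- list()
  for (cc in unique(win$chrom)) {
    w <- win[win$chrom == cc, , drop = FALSE]
    call <- w$call
    # absorb short blips whose flanks agree
    repeat {
      rl <- rle(call)
      short <- which(rl$lengths < min_windows)
      changed <- FALSE
      for (b in short) {
        if (b > 1 && b < length(rl$lengths) &&
            rl$values[b - 1] == rl$values[b + 1] &&
            rl$values[b] != rl$values[b - 1]) {
          lo <- sum(rl$lengths[seq_len(b - 1)]) + 1L
          hi <- lo + rl$lengths[b] - 1L
          call[lo:hi] <- rl$values[b - 1]
          changed <- TRUE
          break
        }
      }
      if (!changed) break
    }
    # remaining short isolated runs (flanks disagree) become Unknown
    rl <- rle(call)
    pos0 <- cumsum(c(0, rl$lengths))
    for (b in which(rl$lengths < min_windows & rl$values != "Unknown")) {
      left <- if (b > 1) rl$values[b - 1] else NA
      right <- if (b < length(rl$values)) rl$values[b + 1] else NA
      if (!is.na(left) && !is.na(right) && left != right) {
        call[(pos0[b] + 1L):pos0[b + 1L]] <- "Unknown"
      }
    }
    rl <- rle(call)
    pos0 <- cumsum(c(0, rl$lengths))
    for (b in seq_along(rl$values)) {
      if (rl$values[b] == "Unknown") next
      i0 <- pos0[b] + 1L; i1 <- pos0[b + 1L]
      segs[[length(segs) + 1L]] <- data.frame(
        chrom = cc, start = w$start[i0], end = w$end[i1],
        call = rl$values[b], n_windows = i1 - i0 + 1L,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, segs) %||%
    data.frame(chrom = character(0), start = numeric(0), end = numeric(0),
               call = character(0), n_windows = integer(0))
  rownames(out) <- NULL
  out
}
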