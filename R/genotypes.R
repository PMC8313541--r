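#' Multi-sample diploid genotype matrix
#'
#' The central data container: biallelic SNVs on a shared coordinate system
#' with per-site callability flags and a genotype matrix coded 0 (hom-ref),
#' 1 (het), 2 (hom-alt), `NA` (missing, "./." in VCF). Positions are 1-based
#' within the site table (VCF convention); all windowing and BED output uses
#' 0-based half-open coordinates.
#'
#' @param sites Data frame with columns `chrom`, `pos` (1-based integer),
#'   `ref`, `alt`, and optionally `callable` (default `TRUE`). Positions must
#'   be strictly increasing within each chromosome.
#' @param geno Integer matrix, sites x samples, values in `{0, 1, 2, NA}`.
#' @param samples Data frame with column `id` and optional `population`,
#'   `clone_group`, `depth`.
#' @return A `variant_matrix` object.
#' @export
variant_matrix <- function(sites, geno, samples) {
  .assert(is.data.frame(sites) && all(c("chrom", "pos", "ref", "alt") %in% names(sites)),
          "sites must have chrom, pos, ref, alt")
  if (is.null(sites$callable)) sites$callable <- rep(TRUE, nrow(sites))
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  .assert(nrow(geno) == nrow(sites), "geno rows must match sites")
  if (is.character(samples)) samples <- data.frame(id = samples, stringsAsFactors = FALSE)
  .assert(is.data.frame(samples) && "id" %in% names(samples),
          "samples must be a data frame with an id column")
  .assert(ncol(geno) == nrow(samples), "geno columns must match samples")
  colnames(geno) <- samples$id
  ok <- geno %in% c(NA_integer_, 0L, 1L, 2L)
  .assert(all(ok), "genotype codes must be 0, 1, 2 or NA")
  for (cc in unique(sites$chrom)) {
    p <- sites$pos[sites$chrom == cc]
    .assert(all(diff(p) > 0),
            paste0("positions must be strictly increasing within ", cc))
  }
  structure(list(sites = sites, geno = geno, samples = samples),
            class = "variant_matrix")
}

#' @exportS3Method base::print
print.variant_matrix <- function(x, ...) {
  cat(sprintf("variant_matrix: %d sites x %d samples (%d callable sites, %.2f%% missing)\n",
              nrow(x$sites), ncol(x$geno), sum(x$sites$callable),
              100 * mean(is.na(x$geno))))
  invisible(x)
}

#' @rdname variant_matrix
#' @param x A `variant_matrix`.
#' @export
n_samples <- function(x) ncol(x$geno)

#' @rdname variant_matrix
#' @export
n_sites <- function(x) nrow(x$sites)

#' Extract one sample's genotype vector
#' @param x A `variant_matrix`.
#' @param sample Sample id.
#' @return Integer vector of genotype codes.
#' @export
genotypes_of <- function(x, sample) {
  .assert(sample %in% colnames(x$geno), paste0("unknown sample '", sample, "'"))
  x$geno[, sample]
}

## ---- VCF I/O --------------------------------------------------------------

#' Genotype filter configuration for [read_vcf()]
#'
#' Defaults follow standard GATK-hardened short-variant practice: biallelic
#' SNVs only (always enforced), site QUAL >= 30, per-sample depth >= 10, and
#' heterozygous allele balance within \[0.2, 0.8\] when AD is present. Filters
#' relying on absent VCF fields are skipped.
#'
#' @param min_qual Minimum site QUAL; failing sites are marked non-callable
#'   (`site_action = "mask"`) or removed (`"drop"`).
#' @param min_dp Minimum per-sample read depth; failing genotypes become `NA`.
#' @param ab_range Allowed alt-allele fraction for heterozygous calls.
#' @param site_action What to do with sites failing `min_qual`/FILTER.
#' @export
vcf_filters <- function(min_qual = 30, min_dp = 10, ab_range = c(0.2, 0.8),
                        site_action = c("mask", "drop")) {
  list(min_qual = min_qual, min_dp = min_dp, ab_range = ab_range,
       site_action = match.arg(site_action))
}

#' Read a multi-sample VCF into a variant matrix
#'
#' Parses GT (and, when present, QUAL, FILTER, DP, AD) via
#' \pkg{vcfR}. Multi-allelic and indel records are dropped and counted in a
#' message; site- and genotype-level filters follow `filter`.
#'
#' @param path Path to a VCF (optionally bgzipped).
#' @param filter A [vcf_filters()] list, or `NULL` to keep everything.
#' @param samples Optional sample metadata data frame (`id`, ...) to attach;
#'   default derives ids from the VCF header.
#' @return A [variant_matrix()]. The numbers of dropped multi-allelic/indel
#'   records are attached as attribute `"dropped"`.
#' @export
read_vcf <- function(path, filter = vcf_filters(), samples = NULL) {
  .assert(file.exists(path), paste0("VCF not found: ", path))
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  n_rec <- nrow(fix)
  if (n_rec == 0L) {
    ids <- colnames(v@gt)[-1] %||% character(0)
    return(variant_matrix(
      data.frame(chrom = character(0), pos = integer(0), ref = character(0),
                 alt = character(0), callable = logical(0)),
      matrix(integer(0), 0, length(ids)), data.frame(id = ids)))
  }
  alt <- fix[, "ALT"]
  ref <- fix[, "REF"]
  snv <- !is.na(alt) & !grepl(",", alt) & nchar(ref) == 1L & nchar(alt) == 1L
  n_multi <- sum(grepl(",", alt), na.rm = TRUE)
  n_indel <- sum(!snv) - n_multi
  if (any(!snv)) {
    message(sprintf("read_vcf: dropped %d multi-allelic and %d indel/other record(s)",
                    n_multi, n_indel))
  }
  keep <- which(snv)
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gsub("|", "/", gt[keep, , drop = FALSE], fixed = TRUE)
  geno <- matrix(NA_integer_, nrow = length(keep), ncol = ncol(gt))
  geno[gt == "0/0"] <- 0L
  geno[gt %in% c("0/1", "1/0")] <- 1L
  geno[gt == "1/1"] <- 2L
  colnames(geno) <- colnames(gt)
  qual <- suppressWarnings(as.numeric(fix[keep, "QUAL"]))
  filt_col <- fix[keep, "FILTER"]
  callable <- rep(TRUE, length(keep))
  if (!is.null(filter)) {
    fail_filt <- !is.na(filt_col) & !(filt_col %in% c("PASS", "."))
    fail_qual <- !is.na(qual) & qual < filter$min_qual
    bad_site <- fail_filt | fail_qual
    fmt <- if (nrow(v@gt)) {
      unique(unlist(strsplit(v@gt[, "FORMAT"], ":", fixed = TRUE)))
    } else character(0)
    if ("DP" %in% fmt) {
      dp <- suppressWarnings(apply(
        vcfR::extract.gt(v, element = "DP")[keep, , drop = FALSE], 2, as.numeric))
      dp <- matrix(dp, nrow = length(keep))
      geno[!is.na(dp) & dp < filter$min_dp] <- NA_integer_
    }
    if ("AD" %in% fmt) {
      ad <- vcfR::extract.gt(v, element = "AD")[keep, , drop = FALSE]
      ad2 <- strsplit(ad, ",", fixed = TRUE)
      refd <- suppressWarnings(as.numeric(vapply(ad2, `[`, "", 1L)))
      altd <- suppressWarnings(as.numeric(vapply(ad2, function(z) z[2] %||% NA_character_, "")))
      ab <- matrix(altd / (refd + altd), nrow = length(keep))
      bad_ab <- geno == 1L & !is.na(ab) &
        (ab < filter$ab_range[1] | ab > filter$ab_range[2])
      geno[bad_ab] <- NA_integer_
    }
    if (filter$site_action == "drop") {
      keep2 <- !bad_site
      keep <- keep[keep2]; geno <- geno[keep2, , drop = FALSE]
      qual <- qual[keep2]; callable <- callable[keep2]
    } else {
      callable <- !bad_site
    }
  }
  sites <- data.frame(
    chrom = fix[keep, "CHROM"], pos = as.integer(fix[keep, "POS"]),
    ref = fix[keep, "REF"], alt = fix[keep, "ALT"], callable = callable,
    stringsAsFactors = FALSE)
  smp <- samples %||% data.frame(id = colnames(geno), stringsAsFactors = FALSE)
  out <- variant_matrix(sites, geno, smp)
  attr(out, "dropped") <- c(multiallelic = n_multi, indel = n_indel)
  out
}

#' Write a variant matrix as plain-text VCF v4.2
#'
#' Lossless for genotype codes `{0, 1, 2, NA}` (NA becomes "./."); the
#' callable flag is encoded in FILTER (`PASS` vs `FAIL`). An empty site table
#' yields a header-only VCF.
#'
#' @param x A [variant_matrix()].
#' @param path Output file path.
#' @param contig_lengths Optional named vector of chromosome lengths for the
#'   header `##contig` lines.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(x, path, contig_lengths = NULL) {
  .assert(inherits(x, "variant_matrix"), "x must be a variant_matrix")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=hybridscope",
               '##FILTER=<ID=FAIL,Description="Site flagged non-callable">',
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">'), con)
  if (!is.null(contig_lengths)) {
    writeLines(sprintf("##contig=<ID=%s,length=%d>", names(contig_lengths),
                       as.integer(contig_lengths)), con)
  }
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", colnames(x$geno)), collapse = "\t"), con)
  if (nrow(x$sites)) {
    code <- c("0/0", "0/1", "1/1")
    gt <- matrix("./.", nrow(x$geno), ncol(x$geno))
    nz <- !is.na(x$geno)
    gt[nz] <- code[x$geno[nz] + 1L]
    body <- paste(x$sites$chrom, x$sites$pos, ".", x$sites$ref, x$sites$alt,
                  ".", ifelse(x$sites$callable, "PASS", "FAIL"), ".", "GT",
                  sep = "\t")
    if (ncol(gt)) {
      body <- paste(body, apply(gt, 1, paste, collapse = "\t"), sep = "\t")
    }
    writeLines(body, con)
  }
  invisible(path)
}

## ---- windowing ------------------------------------------------------------

#' Partition the genome into analysis windows
#'
#' Three windowing conventions are supported: fixed bp spans (e.g. 200-kb
#' windows for pairwise-distance and IBD profiles), fixed counts of callable
#' sites (e.g. heterozygosity in windows of a given number of callable sites),
#' and fixed counts of member markers from a supplied subset (e.g. windows of
#' 500 ancestry-informative markers). Windows are non-overlapping, never cross
#' chromosome boundaries, and the terminal window per chromosome may be
#' short. Coordinates are 0-based half-open.
#'
#' @param x A [variant_matrix()].
#' @param mode `"bp_span"`, `"callable_count"` or `"marker_count"`.
#' @param size Window size (bp for `bp_span`, site count otherwise); must be
#'   positive.
#' @param subset Integer site indices defining the marker set for
#'   `marker_count` mode.
#' @param chrom_lengths Optional named vector of chromosome lengths; defaults
#'   to the last observed position per chromosome.
#' @return A `window_frame`: list with `windows` (data frame `chrom`, `start`,
#'   `end`, `n_sites`), `site_window` (per-site window id, `NA` outside), and
#'   the mode/size echo.
#' @export
make_windows <- function(x, mode = c("bp_span", "callable_count", "marker_count"),
                         size, subset = NULL, chrom_lengths = NULL) {
  mode <- match.arg(mode)
  .assert(is.numeric(size) && length(size) == 1 && size > 0, "size must be > 0")
  .assert(n_sites(x) > 0, "variant matrix has no sites")
  sites <- x$sites
  site_window <- rep(NA_integer_, nrow(sites))
  rows <- list()
  wid <- 0L
  for (cc in unique(sites$chrom)) {
    idx <- which(sites$chrom == cc)
    if (mode == "bp_span") {
      L <- if (!is.null(chrom_lengths) && cc %in% names(chrom_lengths)) {
        chrom_lengths[[cc]]
      } else max(sites$pos[idx])
      starts <- (seq_len(ceiling(L / size)) - 1) * size
      ends <- pmin(starts + size, L)
      w_of <- findInterval(sites$pos[idx] - 0.5, starts)
      for (b in seq_along(starts)) {
        wid <- wid + 1L
        members <- idx[w_of == b]
        site_window[members] <- wid
        rows[[wid]] <- data.frame(chrom = cc, start = starts[b], end = ends[b],
                                  n_sites = length(members))
      }
    } else {
      members_all <- if (mode == "callable_count") {
        idx[sites$callable[idx]]
      } else {
        intersect(idx, subset %||% stop("marker_count mode needs `subset`"))
      }
      if (!length(members_all)) next
      cuts <- split(members_all, (seq_along(members_all) - 1L) %/% size)
      prev_end <- 0
      for (b in seq_along(cuts)) {
        wid <- wid + 1L
        members <- cuts[[b]]
        site_window[members] <- wid
        w_end <- sites$pos[members[length(members)]]
        rows[[wid]] <- data.frame(chrom = cc, start = prev_end, end = w_end,
                                  n_sites = length(members))
        prev_end <- w_end
      }
    }
  }
  windows <- do.call(rbind, rows)
  rownames(windows) <- NULL
  structure(list(windows = windows, site_window = site_window,
                 mode = mode, size = size),
            class = "window_frame")
}

#' @exportS3Method base::print
print.window_frame <- function(x, ...) {
  cat(sprintf("window_frame: %d windows (%s, size %g)\n",
              nrow(x$windows), x$mode, x$size))
  invisible(x)
}

#' @rdname make_windows
#' @param frame A `window_frame`.
#' @export
n_windows <- function(frame) nrow(frame$windows)
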