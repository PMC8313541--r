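#' Pairwise genome-wide distance matrix
#'
#' Computes the genome-wide genomic distance D ([genomic_distance()]) for all
#' sample pairs. Raw values (which can be negative for closely related pairs)
#' are kept alongside a `[0, 1]`-clamped matrix suitable for
#' [classical_mds()]; pairs with no shared polymorphism (`pi12 = 0`) are
#' masked as undefined.
#'
#' @param x A [variant_matrix()].
#' @param samples Sample ids (default all).
#' @return A `distance_matrix`: list with `D` (raw), `D_clamped`, and
#'   `defined` (logical mask), all square symmetric with zero diagonal.
#' @export
genome_distance_matrix <- function(x, samples = x$samples$id) {
  n <- length(samples)
  D <- matrix(0, n, n, dimnames = list(samples, samples))
  defined <- matrix(TRUE, n, n, dimnames = list(samples, samples))
  callable <- x$sites$callable
  g <- x$geno[, samples, drop = FALSE]
  het <- g == 1L
  for (i in seq_len(n - 1)) {
    gi <- g[, i]
    for (j in (i + 1):n) {
      gj <- g[, j]
      use <- callable & !is.na(gi) & !is.na(gj)
      # per-site a + b - 2ab with a = gi/2, b = gj/2
      s12 <- sum(gi[use] + gj[use] - gi[use] * gj[use]) / 2
      if (s12 <= 0) {
        defined[i, j] <- defined[j, i] <- FALSE
        D[i, j] <- D[j, i] <- NA_real_
      } else {
        d <- 1 - (sum(het[use, i]) + sum(het[use, j])) / (4 * s12)
        D[i, j] <- D[j, i] <- d
      }
    }
  }
  structure(list(D = D, D_clamped = pmin(pmax(D, 0), 1), defined = defined,
                 samples = samples),
            class = "distance_matrix")
}

#' Collapse clonal groups (D approximately 0)
#'
#' Single-linkage grouping of sample pairs whose genome-wide D falls below
#' `threshold` (clones differ only by somatic mutations and genotyping error,
#' so D is near 0). Each group is represented by its highest-depth member,
#' ties broken by sample-id order.
#'
#' @param dmat A [genome_distance_matrix()] result (or a plain square matrix).
#' @param depth Named numeric vector of sequencing-depth proxies per sample.
#' @param threshold Clone-calling threshold on D.
#' @return Data frame `sample`, `group`, `representative` (logical), plus the
#'   group representative lookup as attribute `"representatives"`.
#' @export
collapse_clones <- function(dmat, depth = NULL, threshold = 0.02) {
  D <- if (inherits(dmat, "distance_matrix")) dmat$D else as.matrix(dmat)
  ids <- rownames(D)
  n <- length(ids)
  depth <- depth %||% stats::setNames(rep(0, n), ids)
  # single linkage via union-find
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (n > 1) {
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      if (!is.na(D[i, j]) && D[i, j] < threshold) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[rj] <- ri
      }
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  group <- match(root, unique(root))
  rep_flag <- logical(n)
  for (gidx in unique(group)) {
    members <- which(group == gidx)
    d <- depth[ids[members]]
    d[is.na(d)] <- 0
    best <- members[order(-d, ids[members])][1]
    rep_flag[best] <- TRUE
  }
  out <- data.frame(sample = ids, group = group, representative = rep_flag,
                    stringsAsFactors = FALSE)
  attr(out, "representatives") <- out$sample[out$representative]
  out
}

#' Classical multidimensional scaling of a distance matrix
#'
#' Principal-coordinates analysis (Torgerson double-centering of the squared
#' distances followed by eigendecomposition, via `stats::cmdscale`) of the
#' clamped genome-wide D matrix. Negative eigenvalues (non-Euclidean input)
#' are dropped with a warning, matching `cmdscale`'s default behavior. Axis
#' signs are made deterministic by forcing the largest-magnitude loading of
#' each axis positive.
#'
#' @param dmat A [genome_distance_matrix()] result or square symmetric matrix.
#' @param k Number of coordinates to return (at most samples - 1).
#' @return An `mds_result`: `coords` (samples x k), `eig` (all eigenvalues,
#'   decreasing), `dispersion` (fraction of positive-eigenvalue dispersion per
#'   returned axis).
#' @export
classical_mds <- function(dmat, k = 3) {
  D <- if (inherits(dmat, "distance_matrix")) dmat$D_clamped else as.matrix(dmat)
  .assert(!anyNA(D), "distance matrix has undefined pairs; mask or impute first")
  .assert(isTRUE(all.equal(D, t(D))), "distance matrix must be symmetric")
  .assert(all(abs(diag(D)) < 1e-12), "distance matrix must have zero diagonal")
  n <- nrow(D)
  k <- min(k, n - 1)
  fit <- stats::cmdscale(stats::as.dist(D), k = k, eig = TRUE)
  .assert(any(fit$eig > 1e-12), "no positive eigenvalue: degenerate configuration")
  if (any(fit$eig < -1e-8)) {
    warning("classical_mds: dropped ", sum(fit$eig < -1e-8),
            " negative eigenvalue(s) (non-Euclidean distances)")
  }
  coords <- fit$points
  # cmdscale can return fewer than k columns when eigenvalues vanish
  k_eff <- ncol(coords)
  for (ax in seq_len(k_eff)) {
    s <- sign(coords[which.max(abs(coords[, ax])), ax])
    if (s < 0) coords[, ax] <- -coords[, ax]
  }
  pos <- fit$eig[fit$eig > 0]
  structure(list(coords = coords, eig = sort(fit$eig, decreasing = TRUE),
                 dispersion = fit$eig[seq_len(k_eff)] / sum(pos)),
            class = "mds_result")
}

#' @exportS3Method base::print
print.mds_result <- function(x, ...) {
  cat(sprintf("mds_result: %d samples x %d axes; dispersion %s\n",
              nrow(x$coords), ncol(x$coords),
              paste(sprintf("%.1f%%", 100 * x$dispersion), collapse = ", ")))
  invisible(x)
}
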