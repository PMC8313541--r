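# Internal helpers shared across modules. Intervals are 0-based half-open
# [start, end); site positions are 1-based (VCF convention), so a site at
# position p falls in [start, end) iff start < p <= end.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
.assert <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)

# Sum `values` per window given a site -> window-id map (NA = outside any
# window); returns a length-n_windows numeric vector, zeros where empty.
#' @noRd
.window_sum <- function(values, window_id, n_windows) {
  keep <- !is.na(window_id) & !is.na(values)
  out <- numeric(n_windows)
  if (!any(keep)) return(out)
  s <- rowsum(as.numeric(values[keep]), window_id[keep])
  out[as.integer(rownames(s))] <- s[, 1L]
  out
}

# Clip an interval table (chrom, start, end, ...) to [lo, hi) on one chromosome.
#' @noRd
.iv_clip <- function(iv, chrom, lo, hi) {
  iv <- iv[iv$chrom == chrom & iv$end > lo & iv$start < hi, , drop = FALSE]
  if (nrow(iv)) {
    iv$start <- pmax(iv$start, lo)
    iv$end <- pmin(iv$end, hi)
  }
  iv
}

# Merge adjacent/overlapping intervals sharing the same label column.
#' @noRd
.iv_merge <- function(iv, label = "pop") {
  if (nrow(iv) < 2L) return(iv)
  iv <- iv[order(iv$chrom, iv$start), , drop = FALSE]
  keep <- rep(TRUE, nrow(iv))
  for (i in 2:nrow(iv)) {
    j <- max(which(keep[1:(i - 1L)]))
    if (iv$chrom[i] == iv$chrom[j] && iv$start[i] <= iv$end[j] &&
        identical(iv[[label]][i], iv[[label]][j])) {
      iv$end[j] <- max(iv$end[j], iv$end[i])
      keep[i] <- FALSE
    }
  }
  out <- iv[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# TRUE where position p (1-based) lies in any interval of iv on its chromosome.
#' @noRd
.pos_in_intervals <- function(chrom, pos, iv) {
  hit <- logical(length(pos))
  if (is.null(iv) || nrow(iv) == 0L) return(hit)
  for (k in seq_len(nrow(iv))) {
    hit <- hit | (chrom == iv$chrom[k] & pos > iv$start[k] & pos <= iv$end[k])
  }
  hit
}
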