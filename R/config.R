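#' Build a pedigree from a declarative list (YAML-friendly)
#'
#' Converts a list of member declarations -- as read from a YAML config -- to
#' a [pedigree()]. Each entry is a list with `id`, `role` (`founder`, `f1`,
#' `cross`, `clone`, `introgressed`) and the role's fields: `pop`;
#' `parentA`/`parentB`; `source` and `somatic_rate`; `recipient`, `donor` and
#' `segments` (each `chrom`/`start`/`end`); optional `depth`.
#'
#' @param entries List of declarations.
#' @return A [pedigree()].
#' @export
pedigree_from_list <- function(entries) {
  rows <- lapply(entries, function(e) {
    depth <- e$depth %||% 30
    switch(e$role,
      founder = ped_founder(e$id, e$pop, depth),
      f1 = ped_f1(e$id, e$parentA, e$parentB, depth),
      cross = ped_cross(e$id, e$parentA, e$parentB, depth),
      clone = ped_clone(e$id, e$source, e$somatic_rate %||% 0, depth),
      introgressed = ped_introgressed(
        e$id, e$recipient, e$donor,
        do.call(rbind, lapply(e$segments, function(s) {
          data.frame(chrom = s$chrom, start = s$start, end = s$end)
        })), depth),
      stop("unknown pedigree role: ", e$role))
  })
  do.call(pedigree, rows)
}

#' Read a pipeline configuration from YAML
#'
#' Loads a [run_end_to_end()] configuration, coercing the YAML structures to
#' the types the pipeline expects (named drift vector, pedigree object).
#' Validation happens in [validate_config()].
#'
#' @param path Path to a YAML file.
#' @return A config list.
#' @export
config_from_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$model$F)) raw$model$F <- unlist(raw$model$F)
  if (!is.null(raw$model$pops)) raw$model$pops <- unlist(raw$model$pops)
  if (!is.null(raw$model$ancestral_shape)) {
    raw$model$ancestral_shape <- unlist(raw$model$ancestral_shape)
  }
  if (!is.null(raw$pedigree)) raw$pedigree <- pedigree_from_list(raw$pedigree)
  for (k in c("exemplars", "phase")) {
    if (!is.null(raw[[k]])) raw[[k]] <- lapply(raw[[k]], unlist)
  }
  raw
}
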