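#' Cytoarchitectonic group labels
#'
#' The seven permitted cytoarchitectonic groups: the five classical von
#' Economo cortical types plus the insula and the cingulate cortex as two
#' extra groups. Subcortical regions carry no group (`NA`) and are excluded
#' from cytoarchitecture analyses.
#'
#' @return Character vector of length 7.
#' @export
cyto_groups <- function() {
  c("type1", "type2", "type3", "type4", "type5", "insula", "cingulate")
}

#' Build a synthetic atlas map
#'
#' Generates a region table emulating a whole-brain parcellation: region ids,
#' hemisphere, lobe, and an arbitrary (documented, synthetic) assignment of
#' cortical regions to the seven cytoarchitectonic groups. The assignment is
#' deterministic in the region index; it carries no neuroanatomical meaning
#' and exists so that the cytoarchitecture analyses are runnable without a
#' user-supplied mapping.
#'
#' @param n_regions Number of regions (default 60; use 246 for full-scale
#'   parcellation emulation).
#' @param prop_subcortical Fraction of regions marked subcortical (no
#'   cytoarchitectonic group).
#' @return A tibble with columns `region_id`, `hemisphere`, `lobe`,
#'   `cyto_group`.
#' @export
synthetic_atlas <- function(n_regions = 60, prop_subcortical = 0.1) {
  stopifnot(n_regions >= 2)
  n_sub <- floor(n_regions * prop_subcortical)
  n_cort <- n_regions - n_sub
  lobes <- c("frontal", "parietal", "temporal", "occipital", "limbic")
  tibble::tibble(
    region_id = sprintf("R%03d", seq_len(n_regions)),
    hemisphere = rep_len(c("L", "R"), n_regions),
    lobe = c(rep_len(lobes, n_cort), rep("subcortical", n_sub)),
    cyto_group = c(rep_len(cyto_groups(), n_cort), rep(NA_character_, n_sub))
  )
}

validate_atlas <- function(atlas) {
  req <- c("region_id", "hemisphere", "lobe", "cyto_group")
  missing <- setdiff(req, names(atlas))
  if (length(missing) > 0) {
    abort(paste0("atlas is missing column(s): ", paste(missing, collapse = ", ")))
  }
  if (anyDuplicated(atlas$region_id)) {
    abort("atlas region_id values must be unique")
  }
  bad <- setdiff(stats::na.omit(unique(atlas$cyto_group)), cyto_groups())
  if (length(bad) > 0) {
    abort(paste0("unknown cyto_group label(s): ", paste(bad, collapse = ", ")))
  }
  invisible(atlas)
}

#' Read an atlas map from TSV
#'
#' @param path Tab-separated file with columns `region_id`, `hemisphere`,
#'   `lobe`, `cyto_group` (empty cell = unassigned/subcortical).
#' @return Validated atlas tibble.
#' @export
read_atlas <- function(path) {
  atlas <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  validate_atlas(atlas)
  atlas
}

#' Write an atlas map to TSV
#'
#' @param atlas Atlas tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_atlas <- function(atlas, path) {
  validate_atlas(atlas)
  readr::write_tsv(atlas, path, na = "")
  invisible(path)
}
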