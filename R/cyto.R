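# partition helper: named group vector for the labeled (cortical) regions
cyto_partition <- function(atlas) {
  validate_atlas(atlas)
  part <- setNames(atlas$cyto_group, atlas$region_id)
  n_drop <- sum(is.na(part))
  if (n_drop > 0) {
    inform(paste0(n_drop, " unassigned (subcortical) region(s) excluded ",
                  "from cytoarchitecture analyses"))
  }
  part[!is.na(part)]
}

#' Whole-brain versus intra-group global efficiency
#'
#' Computes global efficiency on the whole preprocessed network and on the
#' induced subgraph of each cytoarchitectonic group (so between-group edges
#' cannot leak into intra-group paths), averaging the per-group values.
#' Groups with fewer than 2 nodes are skipped with a warning; regions with
#' no group label (subcortical) are excluded.
#'
#' @param w Preprocessed `connectivity_matrix` with region-id dimnames.
#' @param atlas Atlas tibble carrying the `cyto_group` mapping.
#' @return One-row tibble `e_whole`, `e_intra` (mean over groups), plus a
#'   `per_group` attribute tibble.
#' @export
intra_group_efficiency <- function(w, atlas) {
  stopifnot(is.matrix(w), !is.null(rownames(w)))
  part <- cyto_partition(atlas)
  labeled <- names(part)
  missing <- setdiff(labeled, rownames(w))
  if (length(missing) > 0) abort("matrix lacks labeled regions from the atlas")
  unlabeled <- setdiff(rownames(w), c(labeled, atlas$region_id))
  if (length(unlabeled) > 0) {
    abort(paste0("unlabeled node '", unlabeled[1], "' not in the atlas"))
  }
  e_whole <- shortest_path_measures(w)$E_glob
  groups <- unique(part)
  per_group <- purrr::map(groups, function(g) {
    nodes <- names(part)[part == g]
    if (length(nodes) < 2) {
      warn(paste0("cyto group '", g, "' has < 2 nodes; skipped"))
      return(NULL)
    }
    sub <- w[nodes, nodes, drop = FALSE]
    tibble::tibble(cyto_group = g, n_nodes = length(nodes),
                   E_glob = shortest_path_measures(sub)$E_glob)
  })
  per_group <- dplyr::bind_rows(per_group)
  out <- tibble::tibble(e_whole = e_whole, e_intra = mean(per_group$E_glob))
  attr(out, "per_group") <- per_group
  out
}

#' Correlation of intra-group edge counts with age
#'
#' For each subject (matrices preprocessed at a common density) counts the
#' surviving edges within each cytoarchitectonic group and correlates the
#' count with age per group (Pearson). Groups with no surviving edge in any
#' subject get `NA`.
#'
#' @param networks Named list of preprocessed matrices (region-id dimnames),
#'   or tibble with `subject_id` and `network` columns.
#' @param ages Ages aligned with the networks.
#' @param atlas Atlas tibble with `cyto_group`.
#' @return Tibble `cyto_group`, `r`, `p`, `mean_edges`.
#' @export
edge_count_age_correlation <- function(networks, ages, atlas) {
  if (is.data.frame(networks)) networks <- setNames(networks$network,
                                                    networks$subject_id)
  stopifnot(length(networks) == length(ages))
  if (sd(ages) == 0) abort("constant age vector")
  part <- cyto_partition(atlas)
  groups <- unique(part)
  counts <- purrr::map(networks, function(w) {
    purrr::map_dbl(groups, function(g) {
      nodes <- intersect(names(part)[part == g], rownames(w))
      if (length(nodes) < 2) return(0)
      sub <- w[nodes, nodes, drop = FALSE]
      sum(sub[upper.tri(sub)] > 0)
    })
  })
  cnt <- do.call(rbind, counts)
  colnames(cnt) <- groups
  purrr::map_dfr(groups, function(g) {
    v <- cnt[, g]
    if (all(v == 0) || sd(v) == 0) {
      return(tibble::tibble(cyto_group = g, r = NA_real_, p = NA_real_,
                            mean_edges = mean(v)))
    }
    ct <- cor.test(v, ages)
    tibble::tibble(cyto_group = g, r = unname(ct$estimate), p = ct$p.value,
                   mean_edges = mean(v))
  })
}

#' Mean gray matter volume trajectories per cytoarchitectonic group
#'
#' Fits the lifespan trajectory of the mean regional volume for the whole
#' brain and for each group, reusing the smoothing-spline machinery with a
#' common smoothing parameter (GCV on the whole-brain curve, then frozen).
#' Empty groups are skipped with a warning.
#'
#' @param volumes A `volume_table`.
#' @param atlas Atlas tibble with `cyto_group`.
#' @param grid_step Age grid step (years).
#' @return Tibble `group`, `age`, `fitted`, `deriv` (group `"whole_brain"`
#'   included), with per-group mean slope in the `slopes` attribute.
#' @export
group_volume_trajectories <- function(volumes, atlas, grid_step = 0.5) {
  part <- cyto_partition(atlas)
  vols <- volume_matrix(volumes)
  ages <- volumes$age
  whole <- rowMeans(vols)
  fit_whole <- fit_trajectory(ages, whole, grid_step = grid_step,
                              metric = "mean_volume", modality = "whole_brain")
  lam <- fit_whole$lambda
  groups <- unique(part)
  fits <- purrr::map(groups, function(g) {
    nodes <- intersect(names(part)[part == g], colnames(vols))
    if (length(nodes) == 0) {
      warn(paste0("cyto group '", g, "' empty; skipped"))
      return(NULL)
    }
    fit_trajectory(ages, rowMeans(vols[, nodes, drop = FALSE]),
                   lambda = lam, grid_step = grid_step,
                   metric = "mean_volume", modality = g)
  })
  fits <- c(list(fit_whole), fits[!purrr::map_lgl(fits, is.null)])
  curves <- purrr::map_dfr(fits, function(f) {
    tibble::tibble(group = f$modality, age = f$grid, fitted = f$fitted,
                   deriv = f$deriv)
  })
  slopes <- curves |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(mean_slope = mean(.data$deriv), .groups = "drop")
  attr(curves, "slopes") <- slopes
  curves
}
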