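#' Preprocess a raw connectivity matrix
#'
#' Applies the standard connectome preprocessing chain: zero the diagonal,
#' optionally set negative weights to zero, keep the `k = floor(density *
#' n(n-1)/2)` largest upper-triangle weights (ties at the threshold broken by
#' (row, col) lexicographic order, so thresholded edge sets are nested across
#' densities), symmetrize, and divide the surviving weights by their maximum
#' so values lie in `[0, 1]`.
#'
#' @param m Square symmetric numeric matrix.
#' @param density Fraction of retained edges in (0, 1], default 0.30 (0.10
#'   and 0.50 are the standard robustness settings).
#' @param clip_negatives Set negative weights to zero before thresholding
#'   (the rule for correlation-valued and similarity networks).
#' @param modality Optional modality tag stored on the result.
#' @return A `connectivity_matrix`: the preprocessed matrix with attributes
#'   `density` and `modality`.
#' @export
preprocess_matrix <- function(m, density = 0.30, clip_negatives = TRUE,
                              modality = NA_character_) {
  stopifnot(is.matrix(m), nrow(m) == ncol(m))
  if (density <= 0 || density > 1) abort("density must be in (0, 1]")
  if (max(abs(m - t(m))) > 1e-8) abort("matrix must be symmetric")
  m <- (m + t(m)) / 2
  diag(m) <- 0
  if (clip_negatives) m[m < 0] <- 0
  n <- nrow(m)
  up <- which(upper.tri(m))
  w <- m[up]
  pos <- which(w > 0)
  if (length(pos) == 0) abort("empty graph: no positive weights after clipping")
  k <- floor(density * n * (n - 1) / 2)
  rows <- ((up - 1) %% n) + 1
  cols <- ((up - 1) %/% n) + 1
  ord <- order(-w[pos], rows[pos], cols[pos])
  keep <- pos[ord[seq_len(min(k, length(pos)))]]
  out <- matrix(0, n, n, dimnames = dimnames(m))
  out[up[keep]] <- w[keep]
  out <- out + t(out)
  out <- out / max(out)
  structure(out, density = density, modality = modality,
            class = c("connectivity_matrix", "matrix", "array"))
}

#' Weighted clustering coefficient (Onnela)
#'
#' Per-node clustering as the geometric mean of triangle weights
#' (weights normalized by the maximum): `c_i = (W^(1/3))^3_ii /
#' (k_i (k_i - 1))`, zero for nodes with degree < 2; the global value is the
#' mean over all nodes.
#'
#' @param w Preprocessed non-negative symmetric matrix.
#' @return Global clustering coefficient in `[0, 1]`.
#' @export
clustering_coefficient <- function(w) {
  stopifnot(is.matrix(w), nrow(w) == ncol(w), all(w >= 0))
  mx <- max(w)
  if (mx == 0) return(0)
  w13 <- (w / mx)^(1 / 3)
  tri <- diag(w13 %*% w13 %*% w13)
  k <- rowSums(w > 0)
  denom <- k * (k - 1)
  ci <- ifelse(denom > 0, tri / denom, 0)
  mean(ci)
}

#' Characteristic path length and global efficiency
#'
#' Edge length is the reciprocal weight `1/w`. `E_glob` is the mean of the
#' inverse shortest-path distances over ordered pairs (disconnected pairs
#' contribute 0); `L` is the mean distance over reachable pairs only. With a
#' fully disconnected node set `L` is `NA` and a `disconnected` flag is set.
#'
#' @param w Preprocessed non-negative symmetric matrix.
#' @return List with `L`, `E_glob`, `disconnected`.
#' @export
shortest_path_measures <- function(w) {
  stopifnot(is.matrix(w), nrow(w) == ncol(w), all(w >= 0))
  g <- igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  d <- igraph::distances(g, weights = 1 / igraph::E(g)$weight)
  off <- d[row(d) != col(d)]
  inv <- 1 / off
  inv[!is.finite(inv)] <- 0
  e_glob <- mean(inv)
  reach <- off[is.finite(off)]
  disconnected <- length(reach) < length(off)
  l <- if (length(reach) == 0) NA_real_ else mean(reach)
  if (length(reach) == 0) {
    warn("graph has no reachable pairs; path length undefined")
  }
  list(L = l, E_glob = e_glob, disconnected = disconnected)
}

#' Louvain modularity with restarts
#'
#' Runs Louvain community detection (resolution 1) on the weighted graph
#' `n_restarts` times with seeds `seed .. seed + n_restarts - 1` and returns
#' the partition with maximal Newman-Girvan weighted modularity.
#'
#' @param w Preprocessed non-negative symmetric matrix with >= 1 edge.
#' @param seed Base RNG seed.
#' @param n_restarts Number of restarts (default 10).
#' @return List with `Q` and `partition` (integer community labels).
#' @export
graph_modularity <- function(w, seed = 1, n_restarts = 10) {
  stopifnot(is.matrix(w), nrow(w) == ncol(w), all(w >= 0))
  if (all(w == 0)) abort("empty graph: modularity undefined")
  g <- igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  best_q <- -Inf
  best_part <- NULL
  for (r in seq_len(n_restarts)) {
    set.seed(seed + r - 1L)
    cl <- igraph::cluster_louvain(g, weights = igraph::E(g)$weight,
                                  resolution = 1)
    q <- igraph::modularity(g, igraph::membership(cl),
                            weights = igraph::E(g)$weight)
    if (q > best_q) {
      best_q <- q
      best_part <- as.integer(igraph::membership(cl))
    }
  }
  list(Q = best_q, partition = best_part)
}

#' All four global network measures
#'
#' Clustering coefficient, characteristic path length, global efficiency and
#' modularity of one preprocessed network; a subset can be requested to skip
#' unneeded computation.
#'
#' @param w Preprocessed non-negative symmetric matrix.
#' @param seed Seed for the Louvain restarts.
#' @param n_restarts Louvain restarts.
#' @param metrics Which of `c("C", "L", "E_glob", "Q")` to compute.
#' @return One-row tibble with the requested metric columns.
#' @export
global_metrics <- function(w, seed = 1, n_restarts = 10,
                           metrics = c("C", "L", "E_glob", "Q")) {
  metrics <- match.arg(metrics, several.ok = TRUE)
  out <- list()
  if ("C" %in% metrics) out$C <- clustering_coefficient(w)
  if (any(c("L", "E_glob") %in% metrics)) {
    sp <- shortest_path_measures(w)
    if ("L" %in% metrics) out$L <- sp$L
    if ("E_glob" %in% metrics) out$E_glob <- sp$E_glob
  }
  if ("Q" %in% metrics) out$Q <- graph_modularity(w, seed, n_restarts)$Q
  tibble::as_tibble(out)
}

#' Global metrics for a cohort of networks
#'
#' Preprocesses every network at a common density and computes the requested
#' global measures, returning a tidy per-subject table.
#'
#' @param networks Named list of raw square matrices, or a tibble with
#'   columns `subject_id` and `network` (as returned by
#'   [batch_individual_networks()]).
#' @param modality Modality tag for the output.
#' @param density Proportional threshold.
#' @param clip_negatives Passed to [preprocess_matrix()].
#' @param seed Base seed for Louvain (per-subject seeds are offset by the
#'   subject index for independence).
#' @param n_restarts Louvain restarts per subject.
#' @param metrics Which metrics to compute.
#' @return Tibble `subject_id`, `modality`, `density`, and one column per
#'   requested metric.
#' @export
cohort_metrics <- function(networks, modality = "similarity", density = 0.30,
                           clip_negatives = TRUE, seed = 1, n_restarts = 10,
                           metrics = c("C", "L", "E_glob", "Q")) {
  if (is.data.frame(networks)) {
    ids <- networks$subject_id
    mats <- networks$network
  } else {
    ids <- names(networks)
    mats <- networks
  }
  stopifnot(length(ids) == length(mats))
  rows <- purrr::map2(mats, seq_along(mats), function(m, i) {
    w <- preprocess_matrix(m, density = density,
                           clip_negatives = clip_negatives,
                           modality = modality)
    global_metrics(w, seed = seed + i, n_restarts = n_restarts,
                   metrics = metrics)
  })
  dplyr::bind_cols(
    tibble::tibble(subject_id = ids, modality = modality, density = density),
    dplyr::bind_rows(rows)
  )
}
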