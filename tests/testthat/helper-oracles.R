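# Independent brute-force oracles and tiny fixture builders. These stay
# deliberately naive (triple loops, exhaustive enumeration) so they cannot
# share a bug with the implementation they check.

# first-order closed form for a single covariate
oracle_partial_corr <- function(x, y, z) {
  rxy <- cor(x, y); rxz <- cor(x, z); ryz <- cor(y, z)
  (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
}

# Onnela weighted clustering via explicit triple loop
oracle_clustering <- function(w) {
  n <- nrow(w)
  wh <- w / max(w)
  ci <- numeric(n)
  for (i in seq_len(n)) {
    k <- sum(w[i, ] > 0)
    if (k < 2) next
    s <- 0
    for (j in seq_len(n)) for (h in seq_len(n)) {
      if (j != i && h != i && j != h) {
        s <- s + (wh[i, j] * wh[i, h] * wh[j, h])^(1 / 3)
      }
    }
    ci[i] <- s / (k * (k - 1))
  }
  mean(ci)
}

# all-pairs shortest paths by repeated edge relaxation (Bellman-Ford)
oracle_distances <- function(w) {
  n <- nrow(w)
  len <- ifelse(w > 0, 1 / w, Inf)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  for (src in seq_len(n)) {
    dist <- d[src, ]
    for (rep in seq_len(n)) {
      for (i in seq_len(n)) for (j in seq_len(n)) {
        if (is.finite(dist[i]) && is.finite(len[i, j]) &&
              dist[i] + len[i, j] < dist[j]) {
          dist[j] <- dist[i] + len[i, j]
        }
      }
    }
    d[src, ] <- dist
  }
  d
}

# weighted Newman-Girvan modularity of a given partition
oracle_q <- function(w, part) {
  m2 <- sum(w)
  k <- rowSums(w)
  same <- outer(part, part, "==")
  sum((w - outer(k, k) / m2) * same) / m2
}

# exhaustive search over all set partitions (n <= 8)
all_partitions <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in all_partitions(n - 1)) {
    for (g in seq_len(max(p) + 1L)) out[[length(out) + 1L]] <- c(p, g)
  }
  out
}

oracle_best_modularity <- function(w) {
  best <- -Inf
  for (p in all_partitions(nrow(w))) best <- max(best, oracle_q(w, p))
  best
}

# random symmetric weighted graph with given edge probability
random_graph <- function(n, p_edge = 0.5, seed = 1) {
  set.seed(seed)
  w <- matrix(0, n, n)
  up <- upper.tri(w)
  on <- up & matrix(runif(n * n) < p_edge, n, n)
  w[on] <- runif(sum(on), 0.1, 1)
  w <- w + t(w)
  dimnames(w) <- list(sprintf("R%03d", 1:n), sprintf("R%03d", 1:n))
  w
}

# hand-sized volume table: n subjects, p regions, optional planted structure
tiny_volume_table <- function(n = 5, p = 4, seed = 1) {
  set.seed(seed)
  vols <- matrix(runif(n * p, 5, 15), n, p)
  colnames(vols) <- sprintf("R%03d", seq_len(p))
  tab <- dplyr::bind_cols(
    tibble::tibble(subject_id = sprintf("S%04d", seq_len(n)),
                   age = runif(n, 20, 28), sex = rep_len(c("F", "M"), n),
                   education = rep(12, n), icv = runif(n, 1300, 1700)),
    tibble::as_tibble(vols))
  as_volume_table(tab, synthetic_atlas(p, prop_subcortical = 0))
}

# breakpoint OLS grid search: recover onset from mean-value-vs-age data
segmented_breakpoint <- function(ages, y, grid = seq(25, 80, by = 0.5)) {
  sse <- sapply(grid, function(b) {
    x <- pmax(0, ages - b)
    sum(resid(lm(y ~ x))^2)
  })
  grid[which.min(sse)]
}

# unit-weight two-triangle graph joined by a single bridge edge
two_triangles <- function() {
  w <- matrix(0, 6, 6)
  edges <- rbind(c(1, 2), c(1, 3), c(2, 3), c(4, 5), c(4, 6), c(5, 6), c(3, 4))
  w[edges] <- 1
  w <- w + t(w)
  dimnames(w) <- list(sprintf("R%03d", 1:6), sprintf("R%03d", 1:6))
  w
}
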