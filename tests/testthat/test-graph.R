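test_that("density thresholding keeps exactly the k largest edges, nested across densities", {
  w <- random_graph(5, 1, seed = 4)   # complete, distinct weights
  out <- preprocess_matrix(w, density = 0.4)
  up <- out[upper.tri(out)]
  expect_equal(sum(up > 0), 4)        # floor(0.4 * 10)
  kept <- sort(w[upper.tri(w)], decreasing = TRUE)[1:4]
  expect_setequal(round(up[up > 0] * max(kept), 12), round(kept, 12))
  expect_equal(max(out), 1)           # rescaled
  expect_equal(diag(out), setNames(rep(0, 5), rownames(w)))

  # nested edge sets across 0.1 < 0.3 < 0.5
  big <- random_graph(20, 0.9, seed = 6)
  sets <- lapply(c(0.1, 0.3, 0.5), function(d) {
    which(preprocess_matrix(big, d) > 0)
  })
  expect_true(all(sets[[1]] %in% sets[[2]]))
  expect_true(all(sets[[2]] %in% sets[[3]]))

  # deterministic lexicographic tie rule
  tied <- matrix(0.5, 4, 4)
  diag(tied) <- 0
  dimnames(tied) <- list(sprintf("R%03d", 1:4), sprintf("R%03d", 1:4))
  out_t <- preprocess_matrix(tied, density = 0.5)  # k = 3 of 6 equal edges
  # (row, col) lexicographic tie rule keeps (1,2), (1,3), (1,4)
  expect_equal(which(out_t > 0 & upper.tri(out_t), arr.ind = TRUE),
               cbind(row = c(1, 1, 1), col = c(2, 3, 4)),
               ignore_attr = TRUE)

  expect_error(preprocess_matrix(-random_graph(4, 1, seed = 1), 0.3),
               "empty graph")
  expect_error(preprocess_matrix(random_graph(4, 1, seed = 1), 1.5),
               "density")
})

test_that("negatives are clipped and zeros never become edges", {
  w <- random_graph(8, 0.6, seed = 9)
  w[1, 2] <- w[2, 1] <- -0.9
  out <- preprocess_matrix(w, density = 1)
  expect_equal(out[1, 2], 0)
  expect_true(all(out >= 0))
  # zeros stay zero even at density 1
  expect_equal(sum(out > 0), sum(w > 0))
})

test_that("weighted clustering matches the brute-force triangle oracle", {
  tri <- matrix(0, 3, 3)
  tri[upper.tri(tri)] <- 1
  tri <- tri + t(tri)
  expect_equal(clustering_coefficient(tri), 1)

  star <- matrix(0, 5, 5)
  star[1, 2:5] <- 1
  star <- star + t(star)
  expect_equal(clustering_coefficient(star), 0)

  for (s in 1:3) {
    w <- random_graph(10, 0.5, seed = 30 + s)
    expect_equal(clustering_coefficient(w), oracle_clustering(w),
                 tolerance = 1e-12)
  }
})

test_that("path length and efficiency match Bellman-Ford enumeration", {
  cg <- matrix(1, 4, 4); diag(cg) <- 0
  sp <- shortest_path_measures(cg)
  expect_equal(sp$L, 1)
  expect_equal(sp$E_glob, 1)

  # 3-node path, unit weights: pairs at distance 1, 1, 2
  pathg <- matrix(0, 3, 3)
  pathg[1, 2] <- pathg[2, 3] <- 1
  pathg <- pathg + t(pathg)
  expect_equal(shortest_path_measures(pathg)$E_glob, 5 / 6)

  for (s in 1:3) {
    w <- random_graph(12, 0.4, seed = 50 + s)
    d_or <- oracle_distances(w)
    off <- d_or[row(d_or) != col(d_or)]
    sp <- shortest_path_measures(w)
    expect_equal(sp$E_glob, mean(ifelse(is.finite(off), 1 / off, 0)),
                 tolerance = 1e-12)
    if (all(is.finite(off))) {
      expect_equal(sp$L, mean(off), tolerance = 1e-12)
    }
  }
})

test_that("Louvain attains the exhaustive-search modularity optimum", {
  w <- two_triangles()
  res <- graph_modularity(w, seed = 1)
  expect_equal(res$Q, 5 / 14, tolerance = 1e-12)
  expect_equal(res$Q, oracle_best_modularity(w), tolerance = 1e-12)
  # the partition is the two triangles
  expect_equal(length(unique(res$partition[1:3])), 1)
  expect_equal(length(unique(res$partition[4:6])), 1)
  expect_false(res$partition[1] == res$partition[4])

  # complete graph: no split beats the trivial partition (Q = 0)
  cg <- matrix(1, 5, 5); diag(cg) <- 0
  expect_gte(graph_modularity(cg, seed = 1)$Q, 0)
  expect_error(graph_modularity(matrix(0, 3, 3)), "empty")
})

test_that("planted blocks are recovered by the Louvain partition", {
  hits <- 0
  for (s in 1:10) {
    set.seed(s)
    n <- 40
    blocks <- rep(1:4, each = 10)
    w <- matrix(0.05, n, n)
    w[outer(blocks, blocks, "==")] <- 1
    diag(w) <- 0
    w <- w + matrix(rnorm(n * n, sd = 0.01), n, n)
    w <- pmax((w + t(w)) / 2, 0)
    part <- graph_modularity(w, seed = 100 + s, n_restarts = 5)$partition
    ok <- all(apply(table(blocks, part) > 0, 1, sum) == 1) &&
      length(unique(part)) == 4
    hits <- hits + ok
  }
  expect_gte(hits, 9)
})

test_that("global metrics are deterministic and permutation invariant", {
  w <- preprocess_matrix(random_graph(15, 0.7, seed = 77), 0.5)
  m1 <- global_metrics(w, seed = 3)
  m2 <- global_metrics(w, seed = 3)
  expect_equal(m1, m2)
  expect_true(m1$C >= 0 && m1$C <= 1)
  expect_true(m1$E_glob >= 0 && m1$E_glob <= 1)
  expect_true(m1$Q >= -0.5 && m1$Q <= 1)

  for (s in 1:5) {
    set.seed(200 + s)
    perm <- sample(15)
    wp <- unclass(w)[perm, perm]
    mp <- global_metrics(wp, seed = 3, metrics = c("C", "L", "E_glob"))
    expect_equal(mp$C, m1$C, tolerance = 1e-12)
    expect_equal(mp$L, m1$L, tolerance = 1e-12)
    expect_equal(mp$E_glob, m1$E_glob, tolerance = 1e-12)
  }

  # modularity is permutation invariant when the optimum is well separated
  wt <- two_triangles()
  q0 <- graph_modularity(wt, seed = 3)$Q
  for (s in 1:5) {
    set.seed(300 + s)
    perm <- sample(6)
    expect_equal(graph_modularity(wt[perm, perm], seed = 3)$Q, q0,
                 tolerance = 1e-12)
  }
})

test_that("efficiency is non-decreasing in density on the same raw matrix", {
  raw <- random_graph(20, 0.9, seed = 12)
  es <- sapply(c(0.1, 0.3, 0.5, 0.8),
               function(d) shortest_path_measures(preprocess_matrix(raw, d))$E_glob)
  expect_true(all(diff(es) >= 0))
})

test_that("cohort metrics produce the tidy contract", {
  mats <- list(A = random_graph(10, 0.6, seed = 1),
               B = random_graph(10, 0.6, seed = 2))
  tab <- cohort_metrics(mats, modality = "anatomical", density = 0.3,
                        n_restarts = 3)
  expect_named(tab, c("subject_id", "modality", "density",
                      "C", "L", "E_glob", "Q"))
  expect_equal(tab$subject_id, c("A", "B"))
  expect_equal(unique(tab$density), 0.3)
})
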