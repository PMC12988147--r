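# small deterministic graph fixtures
fixture_graphs <- function(n = 12, nn = 12, seed = 1, encode_age = TRUE) {
  set.seed(seed)
  ages <- runif(n, 20, 80)
  mats <- lapply(seq_len(n), function(i) {
    m <- matrix(runif(nn * nn, 0.2, 0.4), nn, nn)
    m <- (m + t(m)) / 2
    if (encode_age) m <- m * (1 + ages[i] / 50)
    keep <- matrix(runif(nn * nn) < 0.4, nn, nn)
    keep <- keep | t(keep)
    m[!keep] <- 0
    diag(m) <- 0
    dimnames(m) <- list(sprintf("R%03d", 1:nn), sprintf("R%03d", 1:nn))
    m
  })
  names(mats) <- sprintf("S%03d", seq_len(n))
  list(graphs = graphs_from_matrices(mats), ages = ages, mats = mats)
}

test_that("attention weights sum to one and the forward pass is permutation invariant", {
  fx <- fixture_graphs(6, 10, seed = 2)
  cfg <- gnn_config(seed = 3)
  model <- build_gnn(cfg, 1)
  for (g in fx$graphs) {
    fw <- persinet:::gnn_forward(model$params, g, cfg)
    expect_lt(abs(sum(fw$alpha) - 1), 1e-6)
  }

  # relabel nodes: same graph, same prediction
  m <- fx$mats[[1]]
  for (s in 1:3) {
    set.seed(400 + s)
    perm <- sample(nrow(m))
    gp <- graphs_from_matrices(list(a = m[perm, perm]))[[1]]
    f0 <- persinet:::gnn_forward(model$params, fx$graphs[[1]], cfg)
    fp <- persinet:::gnn_forward(model$params, gp, cfg)
    expect_lt(abs(f0$pred - fp$pred), 1e-5)
  }
})

test_that("analytic gradients match finite differences", {
  fx <- fixture_graphs(2, 8, seed = 5)
  cfg <- gnn_config(seed = 7)
  model <- build_gnn(cfg, 1)
  g <- fx$graphs[[1]]
  g$agg <- persinet:::aggregation_matrix(g, cfg$aggregation)
  target <- 0.3
  loss_at <- function(params) {
    fw <- persinet:::gnn_forward(params, g, cfg)
    (fw$raw - target)^2
  }
  fw <- persinet:::gnn_forward(model$params, g, cfg)
  grads <- persinet:::gnn_backward(model$params, g, fw$cache, fw$cz,
                                   2 * (fw$raw - target))
  eps <- 1e-6
  for (blk in c("edge", "node")) {
    w1 <- model$params[[blk]]$W[[1]]
    for (idx in c(1, length(w1))) {
      p2 <- model$params
      p2[[blk]]$W[[1]][idx] <- p2[[blk]]$W[[1]][idx] + eps
      num <- (loss_at(p2) - loss_at(model$params)) / eps
      expect_lt(abs(num - grads[[blk]]$W[[1]][idx]),
                1e-3 * max(1, abs(num)))
    }
  }
  p2 <- model$params
  p2$att$W[5] <- p2$att$W[5] + eps
  num <- (loss_at(p2) - loss_at(model$params)) / eps
  expect_lt(abs(num - grads$att$W[5]), 1e-3 * max(1, abs(num)))
  p2 <- model$params
  p2$head$W[3] <- p2$head$W[3] + eps
  num <- (loss_at(p2) - loss_at(model$params)) / eps
  expect_lt(abs(num - grads$head$W[3]), 1e-3 * max(1, abs(num)))
})

test_that("training is seed-reproducible and classification uses a sigmoid output", {
  fx <- fixture_graphs(10, 8, seed = 6)
  cfg <- gnn_config(epochs = 5, batch_size = 4, seed = 11)
  m1 <- train_gnn(build_gnn(cfg, 1), fx$graphs, fx$ages)
  m2 <- train_gnn(build_gnn(cfg, 1), fx$graphs, fx$ages)
  expect_equal(tail(m1$loss_trace, 1), tail(m2$loss_trace, 1),
               tolerance = 1e-6)

  cfgc <- gnn_config(task = "classification", epochs = 2, batch_size = 4,
                     seed = 11)
  labels <- as.numeric(fx$ages > 50)
  mc <- train_gnn(build_gnn(cfgc, 1), fx$graphs, labels)
  out <- predict_gnn(mc, fx$graphs)
  expect_true(all(out$pred > 0 & out$pred < 1))

  # channel mismatch is refused
  expect_error(train_gnn(build_gnn(cfg, 3), fx$graphs, fx$ages), "channel")
})

test_that("regression metrics match hand formulas", {
  expect_equal(regression_metrics(c(1, 2, 3), c(1, 2, 3)),
               tibble::tibble(R2 = 1, R = 1, MAE = 0, MSE = 0))
  m <- regression_metrics(c(30, 40, 50), c(32, 38, 52))
  expect_equal(m$MAE, 2.0)
  expect_equal(m$MSE, 4.0)
  expect_equal(m$R, cor(c(30, 40, 50), c(32, 38, 52)))
  expect_equal(m$R, 0.9744, tolerance = 1e-4)

  true <- c(30, 40, 50, 60)
  m2 <- regression_metrics(true, true + 5)
  expect_equal(m2$R, 1)
  expect_equal(m2$MAE, 5)
  expect_equal(m2$MSE, 25)
  expect_equal(m2$R2, 1 - 25 * 4 / sum((true - mean(true))^2))
  expect_error(regression_metrics(rep(5, 3), 1:3), "constant")
})

test_that("classification metrics match rank-pair enumeration", {
  perfect <- classification_metrics(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9))
  expect_equal(unlist(perfect), c(accuracy = 1, AUC = 1, sensitivity = 1,
                                  specificity = 1))
  # 3 of 4 cross pairs correctly ordered
  expect_equal(classification_metrics(c(0, 0, 1, 1),
                                      c(0.1, 0.6, 0.4, 0.9))$AUC, 0.75)
  expect_equal(classification_metrics(c(0, 1, 0, 1),
                                      rep(0.5, 4))$AUC, 0.5)
  expect_error(classification_metrics(c(1, 1, 1), c(0.2, 0.6, 0.9)),
               "both classes")
})

test_that("the CV protocol partitions subjects with balanced folds", {
  n <- 57
  for (r in 1:3) {
    folds <- persinet:::make_folds(n, 10, seed = r)
    sizes <- table(folds)
    expect_equal(length(sizes), 10)
    expect_lte(diff(range(sizes)), 1)
    expect_equal(sort(unique(folds)), 1:10)
  }
})

test_that("cross-validation produces out-of-fold predictions for every subject", {
  fx <- fixture_graphs(45, 8, seed = 9)
  cfg <- gnn_config(epochs = 2, batch_size = 16, seed = 21)
  expect_error(crossvalidate_gnn(fx$graphs, fx$ages, cfg), "at least 50")
  fx <- fixture_graphs(52, 8, seed = 9)
  run <- crossvalidate_gnn(fx$graphs, fx$ages, cfg, n_reps = 2)
  expect_s3_class(run, "age_prediction_run")
  pr <- run$predictions
  expect_equal(nrow(pr), 52 * 2)
  expect_true(all(!is.na(pr$predicted)))
  # each subject tested exactly once per repetition
  counts <- dplyr::count(pr, .data$subject_id, .data$rep)
  expect_true(all(counts$n == 1))
  expect_equal(nrow(run$metrics), 2)
  expect_named(run$metrics, c("rep", "R2", "R", "MAE", "MSE"))
  # 80/10/10: train folds = 8 of 10
  expect_equal(max(pr$fold), 10)

  # glance/tidy interface
  expect_equal(nrow(tidy(run)), 104)
  expect_true("mean_MAE" %in% names(glance(run)))
})

test_that("the MLP baseline overfits a linear volume-age relationship", {
  set.seed(10)
  n <- 60; p <- 15
  x <- matrix(runif(n * p, 5, 15), n, p,
              dimnames = list(sprintf("S%03d", 1:n), sprintf("R%03d", 1:p)))
  ages <- 20 + 3 * (rowSums(x) - min(rowSums(x))) /
    diff(range(rowSums(x))) * 20
  cfg <- mlp_config(epochs = 200, batch_size = 8, seed = 2)
  expect_equal(cfg$hidden, c(8, 16, 16, 8))
  fit <- persinet:::train_mlp_net(scale(x), (ages - mean(ages)) / sd(ages),
                                  cfg)
  pred <- drop(persinet:::mlp_forward(fit$params, scale(x))$out) *
    sd(ages) + mean(ages)
  expect_lt(mean(abs(pred - ages)), 2)

  f2 <- persinet:::train_mlp_net(scale(x), (ages - mean(ages)) / sd(ages),
                                 cfg)
  expect_equal(tail(fit$trace, 1), tail(f2$trace, 1), tolerance = 1e-8)
})

test_that("importance summaries follow the documented conventions", {
  # uniform attention -> equal nodal scores, tie rule keeps lowest indices
  e <- matrix(1, 10, 10); diag(e) <- 0
  nodal <- nodal_importance(e)
  expect_equal(length(unique(nodal)), 1)
  expect_equal(top_regions(nodal, 0.2), c(1, 2))
  expect_equal(length(top_regions(rnorm(246), 0.20)), 49)
  expect_error(top_regions(nodal, 0), "fraction")

  expect_equal(region_overlap(1:10, 1:10), 100)
  expect_equal(region_overlap(1:10, 11:20), 0)
  expect_equal(region_overlap(1:10, 6:15), 50)
  expect_error(region_overlap(1:3, 1:5), "equal size")
})

test_that("model comparison matches the textbook Welch formula", {
  expect_equal(compare_models(c(1, 2, 3), c(1, 2, 3)),
               tibble::tibble(t = 0, p = 1, mean_a = 2, mean_b = 2))
  res <- compare_models(c(1, 2, 3), c(11, 12, 13))
  expect_lt(res$p, 0.01)

  a <- c(2.1, 3.4, 2.9, 4.0)
  b <- c(5.5, 6.1, 5 - 0.2, 7.3)
  sa <- var(a) / 4; sb <- var(b) / 4
  t_hand <- (mean(a) - mean(b)) / sqrt(sa + sb)
  expect_equal(compare_models(a, b)$t, t_hand, tolerance = 1e-10)
  expect_equal(compare_models(rep(1, 3), rep(1, 4))$p, 1)
})

# age-informative graphs with an informative region block in one channel
planted_channel_graphs <- function(n, nn, ages, planted, informative, seed) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    m <- matrix(runif(nn * nn, 0.3, 0.5), nn, nn)
    m <- (m + t(m)) / 2
    if (informative) {
      m[planted, planted] <- 0.4 * (1 + (ages[i] - 50) / 40)
    }
    keep <- matrix(runif(nn * nn) < 0.5, nn, nn)
    keep <- keep | t(keep)
    keep[planted, planted] <- TRUE
    m[!keep] <- 0
    diag(m) <- 0
    dimnames(m) <- list(sprintf("R%03d", 1:nn), sprintf("R%03d", 1:nn))
    m
  })
}

attention_importance <- function(graphs, ages, cfg, nn) {
  fit <- fit_age_gnn(graphs, ages, cfg)
  out <- predict_age_gnn(fit, graphs)
  e <- matrix(0, nn, nn)
  for (k in seq_along(graphs)) {
    e[graphs[[k]]$edges] <- e[graphs[[k]]$edges] + out$attention[[k]]
  }
  (e + t(e)) / length(graphs)
}

test_that("attention importance concentrates on a planted informative block", {
  hits <- 0
  for (s in 1:6) {
    set.seed(300 + s)
    n <- 40; nn <- 16
    ages <- runif(n, 20, 80)
    planted <- 1:4
    mats <- planted_channel_graphs(n, nn, ages, planted, TRUE, 300 + s)
    names(mats) <- sprintf("S%03d", 1:n)
    gr <- graphs_from_matrices(mats)
    cfg <- gnn_config(epochs = 30, batch_size = 8, seed = s)
    nod <- nodal_importance(attention_importance(gr, ages, cfg, nn))
    hits <- hits + all(nod[planted] > median(nod[-planted]))
  }
  expect_gte(hits, 5)
})

test_that("multimodal importance elevates regions informative in one channel", {
  hits <- 0
  for (s in 1:4) {
    set.seed(400 + s)
    n <- 40; nn <- 14
    ages <- runif(n, 20, 80)
    planted <- 1:4
    chans <- lapply(1:3, function(ch) {
      planted_channel_graphs(n, nn, ages, planted, ch == 1, 400 + s * 7 + ch)
    })
    multi <- lapply(seq_len(n), function(i) {
      list(chans[[1]][[i]], chans[[2]][[i]], chans[[3]][[i]])
    })
    cfg <- gnn_config(epochs = 60, batch_size = 8, seed = s)
    gr <- graphs_from_matrices(multi)
    nod <- nodal_importance(attention_importance(gr, ages, cfg, nn))
    hits <- hits + all(nod[planted] > median(nod[-planted]))
  }
  expect_gte(hits, 3)
})
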