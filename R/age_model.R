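#' Regression performance metrics
#'
#' Coefficient of determination `R^2 = 1 - SS_res/SS_tot`, Pearson
#' correlation `R`, mean absolute error and mean square error between true
#' and predicted ages.
#'
#' @param true,predicted Equal-length numeric vectors (n >= 3).
#' @return One-row tibble `R2`, `R`, `MAE`, `MSE`.
#' @export
regression_metrics <- function(true, predicted) {
  stopifnot(length(true) == length(predicted))
  if (length(true) < 3) abort("need at least 3 observations")
  if (sd(true) == 0) abort("constant true vector: R undefined")
  res <- true - predicted
  tibble::tibble(
    R2 = 1 - sum(res^2) / sum((true - mean(true))^2),
    R = cor(true, predicted),
    MAE = mean(abs(res)),
    MSE = mean(res^2)
  )
}

#' Classification performance metrics
#'
#' Accuracy, sensitivity and specificity at a 0.5 score threshold, and AUC
#' by the Mann-Whitney rank formulation (ties get mean ranks).
#'
#' @param labels Binary 0/1 vector with both classes present.
#' @param scores Predicted scores in `[0, 1]`.
#' @param threshold Decision threshold (default 0.5).
#' @return One-row tibble `accuracy`, `AUC`, `sensitivity`, `specificity`.
#' @export
classification_metrics <- function(labels, scores, threshold = 0.5) {
  stopifnot(length(labels) == length(scores))
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2) abort("both classes must be present")
  pred <- as.integer(scores >= threshold)
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  rk <- rank(scores)
  auc <- (sum(rk[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  tibble::tibble(
    accuracy = mean(pred == labels),
    AUC = auc,
    sensitivity = sum(pred == 1 & labels == 1) / n1,
    specificity = sum(pred == 0 & labels == 0) / n0
  )
}

# fold labels for one repetition: sizes differ by at most one subject
make_folds <- function(n, n_folds, seed) {
  set.seed(seed)
  sample(rep(seq_len(n_folds), length.out = n))
}

#' Repeated k-fold cross-validation of the edge-attention GNN
#'
#' For each repetition a fresh random 10-fold split is drawn (repetition
#' `r` uses `seed + r` for both the fold assignment and the weight
#' initialisation); within each fold iteration one fold is the test set, the
#' next fold the validation set, and the remaining eight the training set
#' (80/10/10). Test-set predictions and edge-attention weights are
#' collected; per-repetition metrics are computed on the pooled test
#' predictions of that repetition. Ages are centred and scaled internally on
#' the training set and predictions mapped back to years.
#'
#' @param graphs Named list of graphs ([graphs_from_matrices()]).
#' @param targets Ages (regression) or 0/1 labels (classification),
#'   in `graphs` order.
#' @param config A `gnn_config`.
#' @param n_reps Repetitions (protocol default 100; scale down for
#'   exploratory runs).
#' @param n_folds Folds per repetition (default 10).
#' @return Object of class `age_prediction_run`: `predictions` tibble
#'   (`subject_id`, `rep`, `fold`, `true`, `predicted`), `metrics` tibble
#'   (one row per rep), mean edge-attention importance matrix `e_imp`, the
#'   config, and the model type.
#' @export
crossvalidate_gnn <- function(graphs, targets, config = gnn_config(),
                              n_reps = 5, n_folds = 10) {
  n <- length(graphs)
  if (n < 50) abort("need at least 50 subjects for the CV protocol")
  ids <- names(graphs) %||% as.character(seq_len(n))
  n_nodes <- graphs[[1]]$n_nodes
  n_chan <- ncol(graphs[[1]]$x)
  e_sum <- matrix(0, n_nodes, n_nodes)
  e_n <- 0
  preds <- list()
  metr <- list()
  for (r in seq_len(n_reps)) {
    seed_r <- config$seed + r
    folds <- make_folds(n, n_folds, seed_r)
    rep_pred <- rep(NA_real_, n)
    for (f in seq_len(n_folds)) {
      test <- which(folds == f)
      val <- which(folds == (f %% n_folds) + 1)
      train <- setdiff(seq_len(n), c(test, val))
      cfg <- config
      cfg$seed <- seed_r
      fit <- fit_scaled_gnn(cfg, n_chan, graphs[train], targets[train],
                            graphs[val], targets[val])
      out <- predict_scaled_gnn(fit, graphs[test])
      rep_pred[test] <- out$pred
      for (k in seq_along(test)) {
        g <- graphs[[test[k]]]
        alpha <- out$attention[[k]]
        e_sum[g$edges] <- e_sum[g$edges] + alpha
        e_n <- e_n + 1
      }
    }
    preds[[r]] <- tibble::tibble(subject_id = ids, rep = r, fold = folds,
                                 true = targets, predicted = rep_pred)
    metr[[r]] <- dplyr::bind_cols(
      tibble::tibble(rep = r),
      if (config$task == "regression") {
        regression_metrics(targets, rep_pred)
      } else {
        classification_metrics(targets, rep_pred)
      }
    )
  }
  e_imp <- e_sum / max(e_n, 1)
  e_imp <- e_imp + t(e_imp)
  structure(list(predictions = dplyr::bind_rows(preds),
                 metrics = dplyr::bind_rows(metr),
                 e_imp = e_imp, config = config, n_folds = n_folds,
                 model = "gnn"),
            class = "age_prediction_run")
}

# train a GNN on internally standardized targets (regression); returns the
# model plus the scaling so predictions come back in years
fit_scaled_gnn <- function(config, n_chan, graphs, targets,
                           val_graphs = NULL, val_targets = NULL) {
  if (config$task == "regression") {
    ctr <- mean(targets)
    scl <- max(sd(targets), 1e-8)
    y <- (targets - ctr) / scl
    vy <- if (is.null(val_targets)) NULL else (val_targets - ctr) / scl
  } else {
    ctr <- 0
    scl <- 1
    y <- targets
    vy <- val_targets
  }
  model <- build_gnn(config, n_chan)
  model <- train_gnn(model, graphs, y,
                     val_graphs = val_graphs, val_targets = vy)
  list(model = model, center = ctr, scale = scl)
}

predict_scaled_gnn <- function(fit, graphs) {
  out <- predict_gnn(fit$model, graphs)
  out$pred <- out$pred * fit$scale + fit$center
  out
}

#' MLP configuration for the volume baseline
#'
#' Four hidden layers with 8, 16, 16 and 8 nodes; optimizer settings as in
#' [gnn_config()].
#'
#' @inheritParams gnn_config
#' @param hidden Hidden layer widths.
#' @return Named list of class `mlp_config`.
#' @export
mlp_config <- function(hidden = c(8, 16, 16, 8),
                       task = c("regression", "classification"),
                       epochs = 200, batch_size = 64, learning_rate = 0.005,
                       seed = 1) {
  task <- match.arg(task)
  structure(list(hidden = hidden, task = task, epochs = epochs,
                 batch_size = batch_size, learning_rate = learning_rate,
                 seed = as.integer(seed)),
            class = "mlp_config")
}

# train the dense baseline on standardized features/targets
train_mlp_net <- function(x, y, config) {
  set.seed(config$seed)
  params <- mlp_init(c(ncol(x), config$hidden, 1))
  state <- adam_init(params)
  n <- nrow(x)
  trace <- numeric(config$epochs)
  for (ep in seq_len(config$epochs)) {
    set.seed(config$seed + 1000L + ep)
    ord <- sample.int(n)
    ep_loss <- 0
    for (start in seq(1, n, by = config$batch_size)) {
      batch <- ord[start:min(start + config$batch_size - 1, n)]
      fw <- mlp_forward(params, x[batch, , drop = FALSE])
      raw <- drop(fw$out)
      if (config$task == "classification") {
        p <- sigmoid(raw)
        loss <- -(y[batch] * log(p + 1e-12) +
                    (1 - y[batch]) * log(1 - p + 1e-12))
        d <- matrix((p - y[batch]) / length(batch), ncol = 1)
      } else {
        res <- raw - y[batch]
        loss <- abs(res)
        d <- matrix(sign(res) / length(batch), ncol = 1)
      }
      if (any(!is.finite(loss))) abort("NaN loss during training")
      ep_loss <- ep_loss + sum(loss)
      g <- mlp_backward(params, fw, d)
      upd <- adam_step(params, list(W = g$dW, b = g$db), state,
                       config$learning_rate)
      params <- upd$params
      state <- upd$state
    }
    trace[ep] <- ep_loss / n
  }
  list(params = params, trace = trace)
}

#' Cross-validated MLP baseline on regional volumes
#'
#' The non-graph comparison model: regional gray matter volume vectors are
#' fed to a dense network with hidden layers 8-16-16-8, trained under the
#' identical repeated k-fold protocol and scored with the same metrics as
#' the GNN. Features and targets are standardized on the training set.
#'
#' @param x Numeric matrix, subjects x regions (rownames = subject ids), or
#'   a `volume_table`.
#' @param targets Ages or 0/1 labels.
#' @param config An `mlp_config`.
#' @param n_reps,n_folds CV protocol.
#' @return An `age_prediction_run` (without attention importances).
#' @export
mlp_baseline <- function(x, targets, config = mlp_config(), n_reps = 5,
                         n_folds = 10) {
  if (inherits(x, "volume_table")) x <- volume_matrix(x)
  n <- nrow(x)
  if (n < 50) abort("need at least 50 subjects for the CV protocol")
  ids <- rownames(x) %||% as.character(seq_len(n))
  preds <- list()
  metr <- list()
  for (r in seq_len(n_reps)) {
    seed_r <- config$seed + r
    folds <- make_folds(n, n_folds, seed_r)
    rep_pred <- rep(NA_real_, n)
    for (f in seq_len(n_folds)) {
      test <- which(folds == f)
      val <- which(folds == (f %% n_folds) + 1)
      train <- setdiff(seq_len(n), c(test, val))
      mu <- colMeans(x[train, , drop = FALSE])
      sg <- apply(x[train, , drop = FALSE], 2, sd)
      sg[sg == 0] <- 1
      xs <- sweep(sweep(x, 2, mu), 2, sg, "/")
      if (config$task == "regression") {
        ctr <- mean(targets[train])
        scl <- max(sd(targets[train]), 1e-8)
        y <- (targets - ctr) / scl
      } else {
        ctr <- 0; scl <- 1; y <- targets
      }
      cfg <- config
      cfg$seed <- seed_r
      fit <- train_mlp_net(xs[train, , drop = FALSE], y[train], cfg)
      raw <- drop(mlp_forward(fit$params, xs[test, , drop = FALSE])$out)
      rep_pred[test] <- if (config$task == "classification") {
        sigmoid(raw)
      } else {
        raw * scl + ctr
      }
    }
    preds[[r]] <- tibble::tibble(subject_id = ids, rep = r, fold = folds,
                                 true = targets, predicted = rep_pred)
    metr[[r]] <- dplyr::bind_cols(
      tibble::tibble(rep = r),
      if (config$task == "regression") {
        regression_metrics(targets, rep_pred)
      } else {
        classification_metrics(targets, rep_pred)
      }
    )
  }
  structure(list(predictions = dplyr::bind_rows(preds),
                 metrics = dplyr::bind_rows(metr),
                 e_imp = NULL, config = config, n_folds = n_folds,
                 model = "mlp"),
            class = "age_prediction_run")
}

#' Fit one edge-attention age model on a full data set
#'
#' Trains a single GNN on all provided graphs (ages centred/scaled
#' internally for regression) — the deployable model, as opposed to the
#' cross-validation protocol of [crossvalidate_gnn()].
#'
#' @param graphs List of graphs ([graphs_from_matrices()]).
#' @param targets Ages or 0/1 labels.
#' @param config A `gnn_config`.
#' @return Object of class `age_gnn_fit`.
#' @export
fit_age_gnn <- function(graphs, targets, config = gnn_config()) {
  fit <- fit_scaled_gnn(config, ncol(graphs[[1]]$x), graphs, targets)
  structure(fit, class = "age_gnn_fit")
}

#' @rdname fit_age_gnn
#' @param fit A fitted `age_gnn_fit`.
#' @return `predict_age_gnn()`: tibble with `pred` (years or probability)
#'   and per-graph `attention` list-column.
#' @export
predict_age_gnn <- function(fit, graphs) {
  stopifnot(inherits(fit, "age_gnn_fit"))
  predict_scaled_gnn(fit, graphs)
}

#' Edge and nodal importance from attention weights
#'
#' Edge importance is the mean attention weight over test-set subjects and
#' repetitions; nodal importance sums the importances of a region's incident
#' edges.
#'
#' @param run An `age_prediction_run` from [crossvalidate_gnn()].
#' @return `edge_importance()`: symmetric n x n matrix.
#' @export
edge_importance <- function(run) {
  stopifnot(inherits(run, "age_prediction_run"))
  if (is.null(run$e_imp)) abort("run has no stored attention importances")
  run$e_imp
}

#' @rdname edge_importance
#' @param e_imp Edge importance matrix.
#' @return `nodal_importance()`: per-region score vector.
#' @export
nodal_importance <- function(e_imp) {
  stopifnot(is.matrix(e_imp), nrow(e_imp) == ncol(e_imp))
  rowSums(e_imp)
}

#' @rdname edge_importance
#' @param scores Per-region importance scores.
#' @param fraction Fraction of regions to keep (default 0.20, the top-20%
#'   rule; k = round(fraction * n), ties broken by region index).
#' @return `top_regions()`: integer indices of the top regions.
#' @export
top_regions <- function(scores, fraction = 0.20) {
  if (fraction <= 0 || fraction > 1) abort("fraction must be in (0, 1]")
  k <- round(fraction * length(scores))
  order(-scores, seq_along(scores))[seq_len(k)]
}

#' Percentage overlap between two equal-size region sets
#'
#' `100 * |A intersect B| / |A|`.
#'
#' @param set_a,set_b Equal-size vectors of region indices or ids.
#' @return Percentage in `[0, 100]`.
#' @export
region_overlap <- function(set_a, set_b) {
  if (length(set_a) != length(set_b)) abort("region sets must be equal size")
  100 * length(intersect(set_a, set_b)) / length(set_a)
}

#' Compare two model performance samples
#'
#' Two-sample t-test (Welch by default) on per-repetition metric samples.
#' Identical degenerate samples return t = 0, p = 1 by convention.
#'
#' @param a,b Numeric metric samples (>= 2 values each).
#' @param var_equal Use the pooled-variance test instead of Welch.
#' @return One-row tibble `t`, `p`, `mean_a`, `mean_b`.
#' @export
compare_models <- function(a, b, var_equal = FALSE) {
  stopifnot(length(a) >= 2, length(b) >= 2)
  if (sd(a) == 0 && sd(b) == 0) {
    if (mean(a) == mean(b)) {
      return(tibble::tibble(t = 0, p = 1, mean_a = mean(a), mean_b = mean(b)))
    }
    return(tibble::tibble(t = Inf * sign(mean(a) - mean(b)), p = 0,
                          mean_a = mean(a), mean_b = mean(b)))
  }
  tt <- t.test(a, b, var.equal = var_equal)
  tibble::tibble(t = unname(tt$statistic), p = tt$p.value,
                 mean_a = mean(a), mean_b = mean(b))
}
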