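#' Edge-attention GNN configuration
#'
#' Defaults follow the training protocol: encoder/decoder MLP hidden widths
#' 16 and 8 with a maintained latent dimension of 16, mean aggregation, ReLU
#' activation, 200 epochs, batch size 64, learning rate 0.005, Adam, MAE
#' loss for regression / binary cross-entropy for classification, density
#' 0.30 for single-modality inputs (0.10 for the three-channel multimodal
#' model).
#'
#' @param hidden Hidden widths of the edge/node MLPs.
#' @param latent Latent dimension of edge and node representations.
#' @param aggregation `"mean"` or `"sum"` aggregation of incident edges.
#' @param activation Hidden activation (`"relu"`).
#' @param task `"regression"` (linear output, MAE) or `"classification"`
#'   (sigmoid output, binary cross-entropy).
#' @param epochs,batch_size,learning_rate Optimizer settings.
#' @param density Proportional threshold the input graphs are built at.
#' @param seed Seed for weight initialisation and batching.
#' @return Named list of class `gnn_config`.
#' @export
gnn_config <- function(hidden = c(16, 8), latent = 16,
                       aggregation = c("mean", "sum"),
                       activation = "relu",
                       task = c("regression", "classification"),
                       epochs = 200, batch_size = 64, learning_rate = 0.005,
                       density = 0.30, seed = 1) {
  aggregation <- match.arg(aggregation)
  task <- match.arg(task)
  stopifnot(activation == "relu", epochs >= 1, batch_size >= 1,
            learning_rate > 0)
  structure(list(hidden = hidden, latent = latent, aggregation = aggregation,
                 activation = activation, task = task, epochs = epochs,
                 batch_size = batch_size, learning_rate = learning_rate,
                 density = density, seed = as.integer(seed)),
            class = "gnn_config")
}

#' Convert connectivity matrices to model input graphs
#'
#' Edges are the nonzero upper-triangle entries after preprocessing;
#' thresholded (absent) edges are excluded from message passing rather than
#' passed as zeros. For multimodal input, pass a list of matrices per
#' subject: the edge set is the union across channels and each edge carries
#' one weight per channel (zero where that channel lacks the edge).
#'
#' @param mats Named list: one matrix per subject (single modality) or one
#'   list of `n_channels` matrices per subject (multimodal).
#' @return Named list of graphs (`edges`, `x`, `n_nodes`, `agg` cache).
#' @export
graphs_from_matrices <- function(mats) {
  purrr::map(mats, function(m) {
    if (is.list(m)) {
      n <- nrow(m[[1]])
      nz <- Reduce("|", lapply(m, function(w) w != 0))
      idx <- which(upper.tri(nz) & nz)
      x <- do.call(cbind, lapply(m, function(w) w[idx]))
    } else {
      n <- nrow(m)
      idx <- which(upper.tri(m) & m != 0)
      x <- matrix(m[idx], ncol = 1)
    }
    edges <- cbind(((idx - 1) %% n) + 1, ((idx - 1) %/% n) + 1)
    list(edges = edges, x = x, n_nodes = n)
  })
}

# node-by-edge aggregation matrix (mean or sum over incident edges)
aggregation_matrix <- function(graph, aggregation) {
  n <- graph$n_nodes
  m <- nrow(graph$edges)
  a <- matrix(0, n, m)
  a[cbind(graph$edges[, 1], seq_len(m))] <- 1
  a[cbind(graph$edges[, 2], seq_len(m))] <- 1
  if (aggregation == "mean") {
    deg <- rowSums(a)
    deg[deg == 0] <- 1
    a <- a / deg
  }
  a
}

#' Build an edge-attention graph neural network
#'
#' Forward pass: an edge MLP encodes each edge's channel vector into a
#' latent edge state; incident edge states are aggregated
#' (mean/sum, permutation invariant) into node features, updated by a node
#' MLP; each edge's state is concatenated with its two endpoint node states
#' and scored by a linear attention layer; a softmax over the graph's edges
#' yields attention weights whose weighted sum of edge states is the global
#' embedding, decoded by a linear head (sigmoid for classification).
#'
#' @param config A `gnn_config`.
#' @param n_edge_channels 1 (single modality) or 3 (multimodal).
#' @return Object of class `gnn_model` (parameters + config).
#' @export
build_gnn <- function(config = gnn_config(), n_edge_channels = 1) {
  stopifnot(inherits(config, "gnn_config"))
  if (!n_edge_channels %in% c(1L, 3L)) {
    abort("n_edge_channels must be 1 (single modality) or 3 (multimodal)")
  }
  lat <- config$latent
  set.seed(config$seed)
  params <- list(
    edge = mlp_init(c(n_edge_channels, config$hidden, lat)),
    node = mlp_init(c(lat, config$hidden, lat)),
    att = list(W = glorot(2 * lat, 1), b = numeric(1)),
    head = list(W = glorot(lat, 1), b = numeric(1))
  )
  structure(list(params = params, config = config,
                 n_edge_channels = n_edge_channels,
                 loss_trace = numeric()),
            class = "gnn_model")
}

# full forward pass on one graph; returns prediction, attention and caches
gnn_forward <- function(params, graph, config) {
  if (is.null(graph$agg)) graph$agg <- aggregation_matrix(graph, config$aggregation)
  fe <- mlp_forward(params$edge, graph$x)
  ep <- fe$out                                   # m x latent edge states
  nfeat <- graph$agg %*% ep                      # n x latent
  fn <- mlp_forward(params$node, nfeat)
  np <- fn$out
  z <- cbind(ep, np[graph$edges[, 1], , drop = FALSE] +
               np[graph$edges[, 2], , drop = FALSE])
  s <- drop(z %*% params$att$W) + params$att$b
  s <- s - max(s)
  alpha <- exp(s) / sum(exp(s))
  cz <- drop(crossprod(ep, alpha))               # latent global embedding
  raw <- sum(cz * params$head$W) + params$head$b
  pred <- if (config$task == "classification") sigmoid(raw) else raw
  list(pred = pred, raw = raw, alpha = alpha, cz = cz,
       cache = list(fe = fe, fn = fn, ep = ep, np = np, z = z,
                    alpha = alpha, agg = graph$agg))
}

# gradient of the loss for one graph w.r.t. all parameters.
# d_raw: dL/d(raw output) (sign(res) for MAE; sigmoid(raw)-y for BCE)
gnn_backward <- function(params, graph, cache, cz, d_raw) {
  lat <- length(cz)
  ep <- cache$ep
  alpha <- cache$alpha
  d_head_W <- matrix(cz * d_raw, lat, 1)
  d_head_b <- d_raw
  d_cz <- drop(params$head$W) * d_raw
  d_alpha <- drop(ep %*% d_cz)
  d_ep <- alpha %*% t(d_cz)                      # from the weighted sum
  d_s <- alpha * (d_alpha - sum(alpha * d_alpha))
  d_att_W <- crossprod(cache$z, matrix(d_s, ncol = 1))
  d_att_b <- sum(d_s)
  d_z <- matrix(d_s, ncol = 1) %*% t(params$att$W)
  d_ep <- d_ep + d_z[, seq_len(lat), drop = FALSE]
  d_np <- matrix(0, graph$n_nodes, lat)
  i1 <- graph$edges[, 1]
  i2 <- graph$edges[, 2]
  d_pair <- d_z[, lat + seq_len(lat), drop = FALSE]
  for (col in seq_len(lat)) {
    d_np[, col] <- d_np[, col] +
      rowsum_by(d_pair[, col], i1, graph$n_nodes) +
      rowsum_by(d_pair[, col], i2, graph$n_nodes)
  }
  bn <- mlp_backward(params$node, cache$fn, d_np)
  d_ep <- d_ep + crossprod(cache$agg, bn$dX)
  be <- mlp_backward(params$edge, cache$fe, d_ep)
  list(edge = list(W = be$dW, b = be$db),
       node = list(W = bn$dW, b = bn$db),
       att = list(W = d_att_W, b = d_att_b),
       head = list(W = d_head_W, b = d_head_b))
}

rowsum_by <- function(x, idx, n) {
  out <- numeric(n)
  agg <- rowsum(x, idx)
  out[as.integer(rownames(agg))] <- agg
  out
}

loss_grad <- function(raw, target, task) {
  if (task == "classification") {
    p <- sigmoid(raw)
    list(loss = -(target * log(p + 1e-12) + (1 - target) * log(1 - p + 1e-12)),
         d_raw = p - target)
  } else {
    r <- raw - target
    list(loss = abs(r), d_raw = sign(r))
  }
}

#' Train an edge-attention GNN
#'
#' Mini-batch Adam on MAE (regression) or binary cross-entropy
#' (classification); fully deterministic given the config seed. A NaN loss
#' aborts with a diagnostic.
#'
#' When a validation set is supplied, the validation loss is evaluated after
#' every epoch and the parameters from the best-validation epoch are
#' restored at the end (epoch selection — the role of the validation fold
#' in the 80/10/10 protocol).
#'
#' @param model A `gnn_model` from [build_gnn()].
#' @param graphs List of graphs from [graphs_from_matrices()].
#' @param targets Numeric vector (ages, or 0/1 labels).
#' @param epochs,batch_size,learning_rate Optional overrides of the config.
#' @param val_graphs,val_targets Optional validation set for best-epoch
#'   selection.
#' @return The trained model with a per-epoch `loss_trace` (and
#'   `val_trace` when a validation set is given).
#' @export
train_gnn <- function(model, graphs, targets,
                      epochs = model$config$epochs,
                      batch_size = model$config$batch_size,
                      learning_rate = model$config$learning_rate,
                      val_graphs = NULL, val_targets = NULL) {
  stopifnot(inherits(model, "gnn_model"), length(graphs) == length(targets))
  config <- model$config
  graphs <- purrr::map(graphs, function(g) {
    if (ncol(g$x) != model$n_edge_channels) {
      abort("graph channel count does not match the model")
    }
    g$agg <- aggregation_matrix(g, config$aggregation)
    g
  })
  if (!is.null(val_graphs)) {
    val_graphs <- purrr::map(val_graphs, function(g) {
      g$agg <- aggregation_matrix(g, config$aggregation)
      g
    })
  }
  params <- model$params
  state <- adam_init(params)
  n <- length(graphs)
  trace <- numeric(epochs)
  val_trace <- numeric(epochs)
  best_val <- Inf
  best_params <- params
  for (ep in seq_len(epochs)) {
    set.seed(config$seed + 1000L + ep)
    ord <- sample.int(n)
    ep_loss <- 0
    for (start in seq(1, n, by = batch_size)) {
      batch <- ord[start:min(start + batch_size - 1, n)]
      grads <- NULL
      for (i in batch) {
        fw <- gnn_forward(params, graphs[[i]], config)
        lg <- loss_grad(fw$raw, targets[i], config$task)
        if (!is.finite(lg$loss)) abort("NaN loss during training")
        ep_loss <- ep_loss + lg$loss
        g <- gnn_backward(params, graphs[[i]], fw$cache, fw$cz, lg$d_raw)
        grads <- if (is.null(grads)) g else grad_add(grads, g)
      }
      grads <- grad_scale(grads, 1 / length(batch))
      upd <- adam_step(params, grads, state, learning_rate)
      params <- upd$params
      state <- upd$state
    }
    trace[ep] <- ep_loss / n
    if (!is.null(val_graphs)) {
      vl <- mean(vapply(seq_along(val_graphs), function(i) {
        fw <- gnn_forward(params, val_graphs[[i]], config)
        loss_grad(fw$raw, val_targets[i], config$task)$loss
      }, numeric(1)))
      val_trace[ep] <- vl
      if (vl < best_val) {
        best_val <- vl
        best_params <- params
      }
    }
  }
  if (!is.null(val_graphs)) {
    model$params <- best_params
    model$val_trace <- val_trace
  } else {
    model$params <- params
  }
  model$loss_trace <- c(model$loss_trace, trace)
  model
}

#' Predict from a trained GNN
#'
#' @param object A trained `gnn_model`.
#' @param graphs List of graphs.
#' @param ... Unused.
#' @return Tibble with `pred` and the per-graph attention weights
#'   (list-column `attention`, one weight per edge, summing to 1).
#' @export
predict_gnn <- function(object, graphs, ...) {
  out <- purrr::map(graphs, function(g) {
    fw <- gnn_forward(object$params, g, object$config)
    list(pred = fw$pred, alpha = fw$alpha)
  })
  tibble::tibble(pred = purrr::map_dbl(out, "pred"),
                 attention = purrr::map(out, "alpha"))
}
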