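# Single-response PLS (PLS1, NIPALS) on standardized predictors/response.
# Written in full rather than wrapped because the VIP statistic needs the
# per-component weights w_a, scores t_a and response loadings q_a exactly.

pls1_nipals <- function(x, y, n_comp) {
  n <- nrow(x)
  p <- ncol(x)
  w_mat <- matrix(0, p, n_comp)
  t_mat <- matrix(0, n, n_comp)
  p_mat <- matrix(0, p, n_comp)
  q_vec <- numeric(n_comp)
  xk <- x
  yk <- y
  for (a in seq_len(n_comp)) {
    w <- drop(crossprod(xk, yk))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) {
      return(list(W = w_mat[, seq_len(a - 1), drop = FALSE],
                  T = t_mat[, seq_len(a - 1), drop = FALSE],
                  P = p_mat[, seq_len(a - 1), drop = FALSE],
                  q = q_vec[seq_len(a - 1)], n_comp = a - 1L))
    }
    w <- w / nw
    tt <- drop(xk %*% w)
    tt2 <- sum(tt^2)
    pl <- drop(crossprod(xk, tt)) / tt2
    q <- sum(yk * tt) / tt2
    xk <- xk - tcrossprod(tt, pl)
    yk <- yk - q * tt
    w_mat[, a] <- w
    t_mat[, a] <- tt
    p_mat[, a] <- pl
    q_vec[a] <- q
  }
  list(W = w_mat, T = t_mat, P = p_mat, q = q_vec, n_comp = n_comp)
}

# regression coefficients (standardized scale) for the first a components
pls1_coef <- function(fit, a) {
  w <- fit$W[, seq_len(a), drop = FALSE]
  p <- fit$P[, seq_len(a), drop = FALSE]
  q <- fit$q[seq_len(a)]
  r <- w %*% solve(crossprod(p, w))
  drop(r %*% q)
}

#' Fit a single-response PLS regression with CV-selected components
#'
#' Predictors and response are standardized (z-scored); the model is fitted
#' by NIPALS and the number of latent variables `A` is chosen as the argmin
#' of the k-fold root-mean-square error of cross-validation over
#' `1..max_comp`. Deterministic given the fold seed.
#'
#' @param x Predictor matrix or data frame (complete cases, no zero-variance
#'   columns).
#' @param y Response vector.
#' @param max_comp Maximum number of latent variables tried (default
#'   `min(ncol(x), 10)`).
#' @param folds Number of CV folds (default 10; `n > folds` required).
#' @param seed Fold-assignment seed.
#' @return Object of class `pls_fit`: components (`W`, `T`, `P`, `q`),
#'   selected `A`, `rmsecv` curve, `vip` scores, fitted values and training
#'   `R2`, scaling info, `n`.
#' @export
fit_pls <- function(x, y, max_comp = NULL, folds = 10, seed = 1) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  stopifnot(nrow(x) == length(y))
  if (anyNA(x) || anyNA(y)) abort("complete cases required")
  n <- nrow(x)
  p <- ncol(x)
  if (n <= folds) abort("need n > folds")
  sds <- apply(x, 2, sd)
  if (any(sds == 0)) {
    abort(paste0("zero-variance predictor '",
                 colnames(x)[which(sds == 0)[1]], "'"))
  }
  if (sd(y) == 0) abort("zero-variance response")
  max_comp <- max_comp %||% min(p, 10)
  max_comp <- min(max_comp, p, n - 2)
  xs <- scale(x)
  ys <- drop(scale(y))
  fold_id <- make_folds(n, folds, seed)
  press <- numeric(max_comp)
  for (f in seq_len(folds)) {
    idx <- fold_id == f
    fit_f <- pls1_nipals(xs[!idx, , drop = FALSE], ys[!idx], max_comp)
    for (a in seq_len(max_comp)) {
      aa <- min(a, fit_f$n_comp)
      if (aa == 0) {
        press[a] <- press[a] + sum(ys[idx]^2)
      } else {
        pred <- drop(xs[idx, , drop = FALSE] %*% pls1_coef(fit_f, aa))
        press[a] <- press[a] + sum((ys[idx] - pred)^2)
      }
    }
  }
  rmsecv <- sqrt(press / n)
  a_opt <- which.min(rmsecv)
  fit <- pls1_nipals(xs, ys, a_opt)
  a_opt <- fit$n_comp
  if (a_opt < 1) abort("no usable latent variable (response orthogonal to predictors)")
  coefs <- pls1_coef(fit, a_opt)
  fitted_std <- drop(xs %*% coefs)
  r2 <- 1 - sum((ys - fitted_std)^2) / sum(ys^2)
  out <- structure(list(
    W = fit$W, T = fit$T, P = fit$P, q = fit$q, A = a_opt,
    coefficients = coefs, rmsecv = rmsecv, fitted = fitted_std,
    r2 = r2, n = n, p = p,
    predictors = colnames(x) %||% paste0("x", seq_len(p)),
    x_center = attr(xs, "scaled:center"), x_scale = attr(xs, "scaled:scale"),
    y_center = mean(y), y_scale = sd(y), folds = folds, seed = seed
  ), class = "pls_fit")
  out$vip <- vip(out)
  out
}

#' Variable importance in projection
#'
#' `VIP_j = sqrt( p * sum_a SS_a (w_ja / ||w_a||)^2 / sum_a SS_a )` with
#' `SS_a = q_a^2 t_a' t_a`; satisfies `sum_j VIP_j^2 = p`, so VIP > 1 marks
#' an above-average contribution.
#'
#' @param fit A `pls_fit`.
#' @return Named vector of VIP scores.
#' @export
vip <- function(fit) {
  stopifnot(inherits(fit, "pls_fit"))
  a <- fit$A
  w <- fit$W[, seq_len(a), drop = FALSE]
  tt <- fit$T[, seq_len(a), drop = FALSE]
  q <- fit$q[seq_len(a)]
  ss <- q^2 * colSums(tt^2)
  wn <- sweep(w, 2, sqrt(colSums(w^2)), "/")
  v <- sqrt(fit$p * drop(wn^2 %*% ss) / sum(ss))
  names(v) <- fit$predictors
  v
}

#' PLS cognition models across outcomes
#'
#' Fits one single-response PLS model per cognitive outcome with the
#' standard 15 predictors (age, sex, education, and the four global network
#' measures for each of the three modalities) and flags predictors with
#' VIP > 1 as significant. Complete cases per outcome; outcomes with fewer
#' than `min_n` complete cases are skipped with a warning. Sex is coded 0/1
#' and standardized like every other predictor.
#'
#' @param predictors Data frame with columns `age`, `sex`, `education` and
#'   the metric columns (e.g. `C_similarity`, ..., `Q_functional`), one row
#'   per subject.
#' @param outcomes Data frame of outcome columns aligned with `predictors`.
#' @param min_n Minimum complete cases per outcome (default 30).
#' @param ... Passed to [fit_pls()].
#' @return Tibble `outcome`, `predictor`, `VIP`, `significant`, `A`, `n`.
#' @export
cognition_models <- function(predictors, outcomes, min_n = 30, ...) {
  predictors <- tibble::as_tibble(predictors)
  outcomes <- tibble::as_tibble(outcomes)
  stopifnot(nrow(predictors) == nrow(outcomes))
  if ("sex" %in% names(predictors) && !is.numeric(predictors$sex)) {
    predictors$sex <- as.numeric(as.factor(predictors$sex)) - 1
  }
  x_all <- as.matrix(predictors)
  rows <- purrr::imap(outcomes, function(y, nm) {
    ok <- stats::complete.cases(x_all) & !is.na(y)
    if (sum(ok) < min_n) {
      warn(paste0("outcome '", nm, "' skipped: ", sum(ok),
                  " complete cases (< ", min_n, ")"))
      return(NULL)
    }
    fit <- fit_pls(x_all[ok, , drop = FALSE], y[ok], ...)
    tibble::tibble(outcome = nm, predictor = fit$predictors,
                   VIP = unname(fit$vip), significant = fit$vip > 1,
                   A = fit$A, n = fit$n)
  })
  dplyr::bind_rows(rows)
}
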