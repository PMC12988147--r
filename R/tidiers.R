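#' Tidy a fitted PLS model
#'
#' @param x A `pls_fit`.
#' @param ... Unused.
#' @return Tibble `predictor`, `VIP`, `coefficient` (standardized),
#'   `significant` (VIP > 1).
#' @method tidy pls_fit
#' @export
tidy.pls_fit <- function(x, ...) {
  tibble::tibble(predictor = x$predictors, VIP = unname(x$vip),
                 coefficient = unname(x$coefficients),
                 significant = unname(x$vip) > 1)
}

#' @rdname tidy.pls_fit
#' @return `glance()`: one-row tibble `A`, `r.squared`, `rmsecv`, `n`, `p`.
#' @method glance pls_fit
#' @export
glance.pls_fit <- function(x, ...) {
  tibble::tibble(A = x$A, r.squared = x$r2, rmsecv = x$rmsecv[x$A],
                 n = x$n, p = x$p)
}

#' Tidy an age-bias model
#'
#' @param x A `bias_model`.
#' @param ... Unused.
#' @return Tibble with terms `alpha` (slope) and `beta` (intercept).
#' @method tidy bias_model
#' @export
tidy.bias_model <- function(x, ...) {
  tibble::tibble(term = c("alpha", "beta"),
                 estimate = c(x$alpha, x$beta))
}

#' @rdname tidy.bias_model
#' @method glance bias_model
#' @export
glance.bias_model <- function(x, ...) {
  tibble::tibble(alpha = x$alpha, beta = x$beta, n = x$n)
}

#' Tidy an age prediction run
#'
#' @param x An `age_prediction_run`.
#' @param ... Unused.
#' @return The per-subject prediction tibble.
#' @method tidy age_prediction_run
#' @export
tidy.age_prediction_run <- function(x, ...) x$predictions

#' @rdname tidy.age_prediction_run
#' @return `glance()`: per-metric mean and sd over repetitions.
#' @method glance age_prediction_run
#' @export
glance.age_prediction_run <- function(x, ...) {
  x$metrics |>
    tidyr::pivot_longer(-"rep", names_to = "metric") |>
    dplyr::group_by(.data$metric) |>
    dplyr::summarise(mean = mean(.data$value), sd = sd(.data$value),
                     .groups = "drop") |>
    tidyr::pivot_wider(names_from = "metric",
                       values_from = c("mean", "sd"))
}

#' Tidy a trajectory fit
#'
#' @param x A `trajectory_fit`.
#' @param ... Unused.
#' @return Tibble `age`, `fitted`, `deriv`.
#' @method tidy trajectory_fit
#' @export
tidy.trajectory_fit <- function(x, ...) {
  tibble::tibble(age = x$grid, fitted = x$fitted, deriv = x$deriv)
}

#' @rdname tidy.trajectory_fit
#' @method glance trajectory_fit
#' @export
glance.trajectory_fit <- function(x, ...) {
  tibble::tibble(metric = x$metric, modality = x$modality,
                 lambda = x$lambda, n = x$n)
}

#' @export
print.reference_network <- function(x, ...) {
  cat("Young-reference similarity network\n")
  cat("  regions:", nrow(x$r_ref), " reference subjects:", x$n_ref,
      " (age <", x$cutoff, ")\n")
  invisible(x)
}

#' @export
print.individual_network <- function(x, ...) {
  cat("Individual similarity network for subject", x$subject_id, "\n")
  cat("  regions:", nrow(x$z),
      " mean |D|:", signif(mean(abs(x$d[upper.tri(x$d)])), 4), "\n")
  invisible(x)
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat("Synthetic cohort truth (seed", x$seed, ")\n")
  cat("  subjects:", x$n_subjects, " regions:", x$n_regions,
      " communities:", x$n_communities, "\n")
  cat("  planted onsets (years): volume/similarity",
      x$onsets[["volume"]], "| anatomical", x$onsets[["anatomical"]],
      "| functional", x$onsets[["functional"]], "\n")
  invisible(x)
}
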