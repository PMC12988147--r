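#' Fit the age-bias model
#'
#' Ordinary least squares of predicted age on chronological age,
#' `Y = alpha * Omega + beta`, capturing the regression-to-the-mean bias of
#' age prediction models.
#'
#' @param true Chronological ages (non-constant, n >= 3).
#' @param predicted Predicted ages.
#' @return Object of class `bias_model` with `alpha` (slope) and `beta`
#'   (intercept).
#' @export
fit_bias <- function(true, predicted) {
  stopifnot(length(true) == length(predicted))
  if (length(true) < 3) abort("need at least 3 observations")
  if (sd(true) == 0) abort("constant age vector")
  fit <- lm(predicted ~ true)
  structure(list(alpha = unname(coef(fit)[2]), beta = unname(coef(fit)[1]),
                 n = length(true)),
            class = "bias_model")
}

#' Apply the age-bias correction
#'
#' `corrected = predicted + (Omega - (alpha * Omega + beta))`. On the
#' fitting set this zeroes the OLS slope of the prediction error on age (a
#' consequence of least-squares residual orthogonality) and is idempotent
#' under refitting.
#'
#' @param predicted Predicted ages.
#' @param true Chronological ages.
#' @param bias A `bias_model`.
#' @return Corrected predicted ages.
#' @export
bias_correct <- function(predicted, true, bias) {
  stopifnot(inherits(bias, "bias_model"), length(predicted) == length(true))
  predicted + (true - (bias$alpha * true + bias$beta))
}

#' Correct an age prediction run per repetition
#'
#' Fits the bias model on each repetition's out-of-fold predictions and
#' corrects that repetition, appending a `corrected` column.
#'
#' @param run An `age_prediction_run` (regression task).
#' @return The run with `predictions$corrected` added.
#' @export
correct_run <- function(run) {
  stopifnot(inherits(run, "age_prediction_run"))
  run$predictions <- run$predictions |>
    dplyr::group_by(.data$rep) |>
    dplyr::group_modify(function(d, key) {
      b <- fit_bias(d$true, d$predicted)
      d$corrected <- bias_correct(d$predicted, d$true, b)
      d
    }) |>
    dplyr::ungroup()
  run
}

#' Phenotype failure analysis
#'
#' Correlates the bias-corrected prediction error with subject covariates:
#' Pearson correlation (with test) for continuous covariates, a two-sample
#' t-test for sex. Complete cases per covariate; covariates with fewer than
#' 10 complete cases are skipped with a warning. A Benjamini-Hochberg
#' adjusted p column is appended for transparency; the raw p values are the
#' primary report.
#'
#' @param errors Corrected prediction errors (corrected - true), one per
#'   subject.
#' @param covariates Data frame of per-subject covariates (numeric columns,
#'   plus optionally a `sex` factor/character column).
#' @return Tibble `covariate`, `type`, `statistic` (r or t), `p`, `p_bh`,
#'   `n`.
#' @export
phenotype_failure <- function(errors, covariates) {
  covariates <- tibble::as_tibble(covariates)
  if (ncol(covariates) == 0 || length(errors) == 0) {
    return(tibble::tibble(covariate = character(), type = character(),
                          statistic = numeric(), p = numeric(),
                          p_bh = numeric(), n = integer()))
  }
  stopifnot(nrow(covariates) == length(errors))
  rows <- purrr::imap(covariates, function(v, nm) {
    ok <- !is.na(v) & !is.na(errors)
    if (sum(ok) < 10) {
      warn(paste0("covariate '", nm, "' skipped: fewer than 10 complete cases"))
      return(NULL)
    }
    if (is.numeric(v)) {
      ct <- cor.test(errors[ok], v[ok])
      tibble::tibble(covariate = nm, type = "pearson",
                     statistic = unname(ct$estimate), p = ct$p.value,
                     n = sum(ok))
    } else {
      grp <- as.factor(v[ok])
      if (nlevels(grp) != 2) {
        warn(paste0("covariate '", nm, "' skipped: not two groups"))
        return(NULL)
      }
      tt <- t.test(errors[ok] ~ grp)
      tibble::tibble(covariate = nm, type = "t_test",
                     statistic = unname(tt$statistic), p = tt$p.value,
                     n = sum(ok))
    }
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) > 0) {
    out$p_bh <- p.adjust(out$p, method = "BH")
    out <- dplyr::relocate(out, "p_bh", .after = "p")
  } else {
    out <- tibble::tibble(covariate = character(), type = character(),
                          statistic = numeric(), p = numeric(),
                          p_bh = numeric(), n = integer())
  }
  out
}
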