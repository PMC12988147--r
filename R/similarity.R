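# residualize columns of x on covariates z (with intercept) via least squares
residualize <- function(x, z) {
  zmat <- cbind(1, as.matrix(z))
  fit <- lm.fit(zmat, as.matrix(x))
  as.matrix(fit$residuals)
}

#' Partial Pearson correlation of two vectors given a covariate
#'
#' Pearson correlation of the residuals of `x` and `y` after ordinary
#' least-squares regression (with intercept) on `z`. Used to control regional
#' volume correlations for total intracranial volume.
#'
#' @param x,y Numeric vectors (length >= 4, non-constant).
#' @param z Covariate vector (or matrix of covariates), non-constant.
#' @return Correlation in `[-1, 1]`.
#' @export
partial_corr <- function(x, y, z) {
  n <- length(x)
  if (length(y) != n || nrow(as.matrix(z)) != n) abort("input lengths differ")
  if (n < 4) abort("need at least 4 observations")
  for (v in list(x, y)) {
    if (sd(v) == 0) abort("zero variance input vector")
  }
  if (any(apply(as.matrix(z), 2, sd) == 0)) abort("zero variance covariate")
  r <- residualize(cbind(x, y), z)
  out <- cor(r[, 1], r[, 2])
  max(-1, min(1, out))
}

# full region x region partial-correlation matrix controlling for icv
partial_corr_matrix <- function(vols, icv) {
  res <- residualize(vols, icv)
  sds <- apply(res, 2, sd)
  if (any(sds == 0)) {
    abort(paste0("zero residual variance in region '",
                 colnames(vols)[which(sds == 0)[1]], "'"))
  }
  r <- cor(res)
  r[r > 1] <- 1
  r[r < -1] <- -1
  r
}

#' Build the young-reference structural covariance network
#'
#' Computes the reference similarity network: partial Pearson correlations
#' (controlling for ICV) between the gray matter volumes of every pair of
#' regions, over the subjects strictly younger than `cutoff`.
#'
#' @param volumes A `volume_table`.
#' @param cutoff Reference age cutoff in years (default 30; subjects with
#'   `age < cutoff` form the reference group).
#' @param min_ref Minimum reference group size (default 10; at least 4 is
#'   required for the partial correlations).
#' @return Object of class `reference_network`: list with the correlation
#'   matrix `r_ref`, the reference volumes/ICV, ids, `n_ref`, `cutoff`.
#' @export
build_reference <- function(volumes, cutoff = 30, min_ref = 10) {
  ref_rows <- volumes$age < cutoff
  n_ref <- sum(ref_rows)
  if (min_ref < 4) abort("min_ref must be >= 4")
  if (n_ref < min_ref) {
    abort(paste0("need >= ", min_ref, " reference subjects below cutoff ",
                 cutoff, "; found ", n_ref))
  }
  vols <- volume_matrix(volumes)[ref_rows, , drop = FALSE]
  icv <- volumes$icv[ref_rows]
  r_ref <- partial_corr_matrix(vols, icv)
  structure(list(r_ref = r_ref, volumes = vols, icv = icv,
                 subject_ids = volumes$subject_id[ref_rows],
                 n_ref = n_ref, cutoff = cutoff),
            class = "reference_network")
}

#' Perturbation-based individual similarity network
#'
#' Adds one subject to the reference group, recomputes the partial
#' correlation matrix over the `n_ref + 1` subjects (the subject's ICV enters
#' the covariate), takes the difference `D = P - R_ref`, and z-scores the
#' off-diagonal upper-triangle entries of `D` (sample sd, n-1 denominator),
#' mirroring to the lower triangle with zero diagonal.
#'
#' @param reference A `reference_network`.
#' @param subject One-row `volume_table` slice (must not be a reference
#'   subject).
#' @return Object of class `individual_network`: list with `z`, `d`, `p`
#'   matrices and `subject_id`.
#' @export
individual_network <- function(reference, subject) {
  stopifnot(inherits(reference, "reference_network"), nrow(subject) == 1)
  if (subject$subject_id %in% reference$subject_ids) {
    abort(paste0("subject '", subject$subject_id,
                 "' is in the reference set (leave-one-out is not supported)"))
  }
  svol <- volume_matrix(subject)
  if (!identical(colnames(svol), colnames(reference$volumes))) {
    abort("subject regions do not match the reference regions")
  }
  vols <- rbind(reference$volumes, svol)
  icv <- c(reference$icv, subject$icv)
  p <- partial_corr_matrix(vols, icv)
  d <- p - reference$r_ref
  up <- upper.tri(d)
  vals <- d[up]
  z <- (d - mean(vals)) / sd(vals)
  z[lower.tri(z)] <- t(z)[lower.tri(z)]
  diag(z) <- 0
  structure(list(z = z, d = d, p = p,
                 subject_id = subject$subject_id),
            class = "individual_network")
}

#' Individual similarity networks for every non-reference subject
#'
#' Applies [individual_network()] to every subject at or above the reference
#' cutoff and returns a tidy tibble with one row per subject and the z-scored
#' network as a list-column.
#'
#' @param volumes A `volume_table` for the whole cohort.
#' @param reference A `reference_network` built from the same cohort.
#' @return Tibble `subject_id`, `age`, `network` (list of z matrices).
#' @export
batch_individual_networks <- function(volumes, reference) {
  eligible <- volumes$age >= reference$cutoff
  if (!any(eligible)) {
    warn("no subjects at or above the reference cutoff; empty output")
    return(tibble::tibble(subject_id = character(), age = numeric(),
                          network = list()))
  }
  rows <- which(eligible)
  nets <- purrr::map(rows, function(i) {
    tryCatch(individual_network(reference, volumes[i, ]),
             error = function(e) {
               abort(paste0("subject '", volumes$subject_id[i], "': ",
                            conditionMessage(e)))
             })
  })
  out <- tibble::tibble(subject_id = volumes$subject_id[rows],
                        age = volumes$age[rows],
                        network = purrr::map(nets, "z"))
  dplyr::arrange(out, .data$subject_id)
}
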