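#' Ground-truth parameters for a synthetic cohort
#'
#' Defines everything needed to generate a reproducible synthetic cohort
#' emulating a lifespan structural/functional imaging study: ages uniform on
#' `age_range`, regions partitioned into communities, and modality-specific
#' age-related decline with planted onsets. Defaults plant the onsets
#' volume/similarity 32 < anatomical 43 < functional 62 years, so the
#' downstream trajectory analysis has a known ordering to recover.
#'
#' The gray-matter age effect enters three ways, all restricted to the
#' affected communities: a deterministic mean volume decline, a shrinking of
#' the community factor loadings, and — the component that drives the
#' similarity networks — an age-increasing prevalence of a fixed atrophy
#' pattern (each subject expresses it with probability growing linearly
#' after the volume onset, reducing affected-community volumes by
#' `atrophy_depth`). The prevalence mechanism gives the population mean
#' response a linear post-onset trend even though a single subject's effect
#' on the perturbed correlation matrix is quadratic in their offset, so the
#' planted onset is recoverable from the similarity-network trajectories.
#' The anatomical decline is likewise restricted to
#' within-affected-community edges: a globally uniform multiplicative
#' decline would cancel under max-rescaling during preprocessing and leave
#' no recoverable topological signature.
#'
#' @param n_subjects Number of subjects (>= 20).
#' @param n_regions Number of regions (60 for test-scale fixtures; 246 for
#'   full-scale emulation).
#' @param n_communities Number of region communities.
#' @param age_range Two ages (years), default `c(18, 88)`.
#' @param seed Integer seed; the truth object fully determines the cohort.
#' @param onset_volume,onset_anatomical,onset_functional Planted onset ages.
#' @param delta_volume Fractional mean-volume decline per year after onset in
#'   affected communities.
#' @param delta_loading Fractional factor-loading shrink per year after onset.
#' @param delta_anatomical Fractional decline per year of within-community
#'   anatomical edge weights after onset.
#' @param delta_functional Fractional decline per year of the cross-community
#'   functional coupling after onset.
#' @param icv_gamma Allometric ICV exponent.
#' @param lambda0 Base community factor loading (volume units).
#' @param sigma_volume Volume noise sd (volume units).
#' @param kappa0 Base cross-community functional coupling.
#' @param sigma_functional Functional observation noise sd.
#' @param sigma_anatomical Anatomical edge noise sd.
#' @param t_functional Length of the latent functional time series.
#' @param atrophy_rate Per-year increase (after the volume onset) in the
#'   probability that a subject expresses the fixed atrophy pattern.
#' @param atrophy_depth Fractional volume reduction in affected communities
#'   for subjects expressing the atrophy pattern.
#' @param cog_c0,cog_c1,cog_c2,sigma_cognition Cognition link: score =
#'   c0 - c1 max(0, age - 40) + c2 Q + noise, Q the subject's
#'   similarity-network modularity.
#' @return A list of class `synthetic_truth` (includes the drawn region base
#'   volumes, loadings, and anatomical template, so regeneration is exact).
#' @export
synthetic_truth <- function(n_subjects = 632, n_regions = 60,
                            n_communities = 6, age_range = c(18, 88),
                            seed = 1,
                            onset_volume = 32, onset_anatomical = 43,
                            onset_functional = 62,
                            delta_volume = 0, delta_loading = 0,
                            delta_anatomical = 0.006,
                            delta_functional = 0.015,
                            icv_gamma = 0.7, lambda0 = 1.0,
                            sigma_volume = 0.6, kappa0 = 0.7,
                            sigma_functional = 0.6, sigma_anatomical = 0.03,
                            t_functional = 200,
                            atrophy_rate = 0.02, atrophy_depth = 0.3,
                            cog_c0 = 100, cog_c1 = 0.3, cog_c2 = 12,
                            sigma_cognition = 0.6) {
  if (n_subjects < 20) abort("n_subjects must be >= 20")
  stopifnot(n_regions >= n_communities, length(age_range) == 2,
            age_range[1] < age_range[2])
  horizon <- age_range[2] - onset_volume
  if (delta_volume * horizon >= 1) {
    abort("delta_volume * (age_max - onset) >= 1: volumes would hit zero in expectation")
  }
  if (delta_anatomical * (age_range[2] - onset_anatomical) >= 1) {
    abort("delta_anatomical too large: weights would hit zero in expectation")
  }
  if (t_functional < 30) abort("t_functional < 30 gives unstable correlations")
  community <- rep(seq_len(n_communities), length.out = n_regions)
  community <- sort(community)
  affected <- seq_len(max(1L, floor(n_communities / 2)))
  set.seed(as.integer(seed))
  base_volumes <- runif(n_regions, 5, 15)
  loadings <- lambda0 * runif(n_regions, 0.6, 1.4)
  w0 <- anatomical_template(n_regions, community)
  structure(list(
    seed = as.integer(seed), n_subjects = n_subjects, n_regions = n_regions,
    n_communities = n_communities, age_range = age_range,
    community = community, affected_communities = affected,
    onsets = c(volume = onset_volume, anatomical = onset_anatomical,
               functional = onset_functional),
    delta_volume = delta_volume, delta_loading = delta_loading,
    atrophy_rate = atrophy_rate, atrophy_depth = atrophy_depth,
    delta_anatomical = delta_anatomical, delta_functional = delta_functional,
    icv_gamma = icv_gamma, lambda0 = lambda0, sigma_volume = sigma_volume,
    kappa0 = kappa0, sigma_functional = sigma_functional,
    sigma_anatomical = sigma_anatomical, t_functional = t_functional,
    cog_c0 = cog_c0, cog_c1 = cog_c1, cog_c2 = cog_c2,
    sigma_cognition = sigma_cognition,
    base_volumes = base_volumes, loadings = loadings, w0 = w0
  ), class = "synthetic_truth")
}

# modular weighted template: strong within-community, weak between; zero diagonal
anatomical_template <- function(n_regions, community) {
  w0 <- matrix(0, n_regions, n_regions)
  within <- outer(community, community, "==")
  up <- upper.tri(w0)
  w0[up & within] <- runif(sum(up & within), 0.5, 0.8)
  w0[up & !within] <- runif(sum(up & !within), 0.05, 0.25)
  w0 <- w0 + t(w0)
  diag(w0) <- 0
  w0
}

#' Subject-level draws of a synthetic truth
#'
#' Ages, sex, education and ICV implied by a `synthetic_truth`; every
#' generator uses exactly these draws (same seed offset), so volumes and
#' connectomes describe the same subjects.
#'
#' @param truth A `synthetic_truth`.
#' @return Tibble `subject_id`, `age`, `sex`, `education`, `icv`.
#' @export
cohort_subjects <- function(truth) {
  stopifnot(inherits(truth, "synthetic_truth"))
  draw_subjects(truth)
}

# subject-level draws shared by every generator (same seed offset ->
# identical ages/ICV across modalities)
draw_subjects <- function(truth) {
  set.seed(truth$seed + 100L)
  n <- truth$n_subjects
  tibble::tibble(
    subject_id = sprintf("S%04d", seq_len(n)),
    age = runif(n, truth$age_range[1], truth$age_range[2]),
    sex = sample(c("F", "M"), n, replace = TRUE),
    education = round(runif(n, 9, 25)),
    icv = rlnorm(n, log(1500), 0.08)
  )
}

#' Generate a synthetic gray-matter volume table
#'
#' Regional volume for subject s, region i:
#' `V = b_i (1 - delta_c max(0, age - a0)) (icv / mean icv)^gamma
#'    + Lambda_i(age) f_{s,c(i)} + eps`,
#' where `f` are per-subject community factors inducing within-community
#' covariance, `Lambda_i(age)` shrinks after the volume onset in affected
#' communities, and volumes are clipped at a small positive floor. A
#' WMH-like vascular burden phenotype increasing with age is included.
#'
#' @param truth A `synthetic_truth`.
#' @return A `volume_table` tibble (atlas order = region index order).
#' @export
generate_volumes <- function(truth) {
  stopifnot(inherits(truth, "synthetic_truth"))
  subjects <- draw_subjects(truth)
  set.seed(truth$seed + 200L)
  n <- truth$n_subjects
  p <- truth$n_regions
  comm <- truth$community
  aff <- comm %in% truth$affected_communities
  past <- pmax(0, subjects$age - truth$onsets[["volume"]])
  decline <- 1 - truth$delta_volume * outer(past, as.numeric(aff))
  icv_eff <- (subjects$icv / mean(subjects$icv))^truth$icv_gamma
  f <- matrix(rnorm(n * truth$n_communities), n, truth$n_communities)
  load_shrink <- 1 - truth$delta_loading * outer(past, as.numeric(aff))
  lam <- sweep(load_shrink, 2, truth$loadings, "*")
  eps <- matrix(rnorm(n * p, sd = truth$sigma_volume), n, p)
  vols <- sweep(decline, 2, truth$base_volumes, "*") * icv_eff +
    lam * f[, comm] + eps
  if (truth$atrophy_rate > 0 && truth$atrophy_depth > 0) {
    p_atrophy <- pmin(1, truth$atrophy_rate * past)
    expressed <- runif(n) < p_atrophy
    vols[expressed, aff] <- vols[expressed, aff] * (1 - truth$atrophy_depth)
  }
  vols <- pmax(vols, 0.1)
  colnames(vols) <- sprintf("R%03d", seq_len(p))
  wmh <- 0.05 * (subjects$age - truth$age_range[1]) +
    abs(rnorm(n, sd = 0.6))
  tab <- dplyr::bind_cols(subjects, tibble::as_tibble(vols),
                          tibble::tibble(wmh = wmh))
  atlas <- synthetic_atlas(p)
  as_volume_table(tab, atlas)
}

#' Generate synthetic anatomical (structural) connectomes
#'
#' Per subject: the modular template with within-affected-community weights
#' scaled by `1 - delta max(0, age - a0_anat)`, plus symmetric Gaussian edge
#' noise, clipped at zero.
#'
#' @param truth A `synthetic_truth`.
#' @param noise_sd Edge noise sd; set 0 for the noiseless construction.
#' @return Named list (subject_id) of symmetric non-negative matrices.
#' @export
generate_anatomical <- function(truth, noise_sd = truth$sigma_anatomical) {
  stopifnot(inherits(truth, "synthetic_truth"))
  subjects <- draw_subjects(truth)
  set.seed(truth$seed + 300L)
  p <- truth$n_regions
  comm <- truth$community
  within_aff <- outer(comm, comm, "==") &
    outer(comm %in% truth$affected_communities,
          comm %in% truth$affected_communities, "&")
  ids <- sprintf("R%03d", seq_len(p))
  out <- purrr::map(seq_len(truth$n_subjects), function(s) {
    fac <- 1 - truth$delta_anatomical *
      max(0, subjects$age[s] - truth$onsets[["anatomical"]])
    scale <- matrix(1, p, p)
    scale[within_aff] <- fac
    w <- truth$w0 * scale
    if (noise_sd > 0) {
      e <- matrix(rnorm(p * p, sd = noise_sd), p, p)
      e <- (e + t(e)) / 2
      w <- w + e
    }
    w <- pmax(w, 0)
    diag(w) <- 0
    dimnames(w) <- list(ids, ids)
    w
  })
  names(out) <- subjects$subject_id
  out
}

#' Generate synthetic functional connectomes
#'
#' Per subject, region time series = its community's latent signal + a
#' global signal scaled by the age-dependent coupling
#' `kappa(age) = kappa0 (1 - delta max(0, age - a0_func))` + observation
#' noise; the output is the region-by-region Pearson correlation matrix.
#' Cross-community coupling therefore declines after the functional onset.
#'
#' @param truth A `synthetic_truth`.
#' @param noise_sd Observation noise sd.
#' @param t_len Time series length (>= 30).
#' @return Named list of correlation matrices (diagonal 1, entries in
#'   `[-1, 1]`).
#' @export
generate_functional <- function(truth, noise_sd = truth$sigma_functional,
                                t_len = truth$t_functional) {
  stopifnot(inherits(truth, "synthetic_truth"))
  if (t_len < 30) abort("t_len < 30 gives unstable correlations")
  subjects <- draw_subjects(truth)
  set.seed(truth$seed + 400L)
  p <- truth$n_regions
  comm <- truth$community
  ids <- sprintf("R%03d", seq_len(p))
  out <- purrr::map(seq_len(truth$n_subjects), function(s) {
    kap <- truth$kappa0 * (1 - truth$delta_functional *
                             max(0, subjects$age[s] - truth$onsets[["functional"]]))
    sig <- matrix(rnorm(t_len * truth$n_communities), t_len,
                  truth$n_communities)
    g <- rnorm(t_len)
    x <- sig[, comm] + kap * g
    if (noise_sd > 0) x <- x + matrix(rnorm(t_len * p, sd = noise_sd), t_len, p)
    m <- stats::cor(x)
    dimnames(m) <- list(ids, ids)
    m
  })
  names(out) <- subjects$subject_id
  out
}

#' Generate synthetic cognition phenotypes linked to network topology
#'
#' `score = c0 - c1 max(0, age - 40) + c2 Q + noise`, with `Q` the subject's
#' similarity-network modularity. Three pure-noise phenotypes are appended as
#' negative controls.
#'
#' @param truth A `synthetic_truth`.
#' @param metrics Tibble with columns `subject_id`, `age`, `Q` (modularity of
#'   the subject's similarity network).
#' @return Tibble `subject_id`, `score`, `noise1`..`noise3`.
#' @export
generate_cognition <- function(truth, metrics) {
  stopifnot(inherits(truth, "synthetic_truth"),
            all(c("subject_id", "age", "Q") %in% names(metrics)))
  set.seed(truth$seed + 500L)
  n <- nrow(metrics)
  score <- truth$cog_c0 - truth$cog_c1 * pmax(0, metrics$age - 40) +
    truth$cog_c2 * metrics$Q + rnorm(n, sd = truth$sigma_cognition)
  tibble::tibble(subject_id = metrics$subject_id, score = score,
                 noise1 = rnorm(n), noise2 = rnorm(n), noise3 = rnorm(n))
}

#' Generate a full synthetic cohort (volumes + both connectome modalities)
#'
#' @param truth A `synthetic_truth`.
#' @return List with `truth`, `atlas`, `volumes`, `anatomical`, `functional`.
#' @export
simulate_cohort <- function(truth) {
  stopifnot(inherits(truth, "synthetic_truth"))
  list(truth = truth,
       atlas = synthetic_atlas(truth$n_regions),
       volumes = generate_volumes(truth),
       anatomical = generate_anatomical(truth),
       functional = generate_functional(truth))
}
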