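#' Run the similarity-network pipeline and collect global metrics
#'
#' Convenience orchestration over a simulated (or read-in) cohort: builds
#' the young-reference network, derives every eligible subject's individual
#' similarity network, preprocesses all three modalities at a common
#' density, and computes the requested global measures per subject and
#' modality.
#'
#' @param cohort List with `volumes`, `anatomical`, `functional` (as from
#'   [simulate_cohort()]).
#' @param cutoff Reference age cutoff (years).
#' @param density Proportional threshold.
#' @param seed Base seed for Louvain restarts.
#' @param n_restarts Louvain restarts per network.
#' @param metrics Which global measures to compute.
#' @param modalities Which modalities to process.
#' @return List with `reference`, `networks` (similarity tibble), `metrics`
#'   (tidy long table with `age`), and `metrics_wide` (one row per subject,
#'   `<metric>_<modality>` columns, ready for the PLS models).
#' @export
study_metrics <- function(cohort, cutoff = 30, density = 0.30, seed = 1,
                          n_restarts = 10,
                          metrics = c("C", "L", "E_glob", "Q"),
                          modalities = c("similarity", "anatomical",
                                         "functional")) {
  reference <- build_reference(cohort$volumes, cutoff = cutoff)
  nets <- batch_individual_networks(cohort$volumes, reference)
  ids <- nets$subject_id
  tabs <- list()
  if ("similarity" %in% modalities) {
    tabs$similarity <- cohort_metrics(nets, modality = "similarity",
                                      density = density, seed = seed,
                                      n_restarts = n_restarts,
                                      metrics = metrics)
  }
  if ("anatomical" %in% modalities) {
    tabs$anatomical <- cohort_metrics(cohort$anatomical[ids],
                                      modality = "anatomical",
                                      density = density, seed = seed + 10000L,
                                      n_restarts = n_restarts,
                                      metrics = metrics)
  }
  if ("functional" %in% modalities) {
    tabs$functional <- cohort_metrics(cohort$functional[ids],
                                      modality = "functional",
                                      density = density, seed = seed + 20000L,
                                      n_restarts = n_restarts,
                                      metrics = metrics)
  }
  long <- dplyr::bind_rows(tabs) |>
    dplyr::left_join(
      dplyr::select(tibble::as_tibble(cohort$volumes), "subject_id", "age"),
      by = "subject_id")
  wide <- long |>
    tidyr::pivot_wider(id_cols = c("subject_id", "age"),
                       names_from = "modality",
                       values_from = dplyr::all_of(metrics),
                       names_glue = "{.value}_{modality}")
  list(reference = reference, networks = nets, metrics = long,
       metrics_wide = wide)
}
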