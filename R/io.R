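# Column contract for volume tables. Region columns are exactly the atlas
# region ids; any other non-standard column must be a recognised (or declared)
# phenotype, otherwise it is treated as a misnamed region column and rejected.
standard_volume_cols <- c("subject_id", "age", "sex", "education", "icv")

known_phenotypes <- c("fluid_intelligence", "memory", "language", "emotion",
                      "motor", "executive", "anxiety", "depression", "sleep",
                      "wmh")

#' Read a subject-by-region gray matter volume table
#'
#' Reads a tab-separated table with one row per subject: `subject_id`, `age`,
#' `sex` (F/M), `education`, `icv`, one column per atlas region (non-negative
#' gray matter volume), and optional phenotype columns. Region columns are
#' reordered to the atlas order; missing phenotype cells are preserved as
#' `NA`, never imputed.
#'
#' @param path TSV file path.
#' @param atlas Atlas tibble (defines the region set and order).
#' @param extra_phenotypes Additional phenotype column names to accept beyond
#'   the standard ones.
#' @return A `volume_table` tibble.
#' @export
read_volume_table <- function(path, atlas, extra_phenotypes = character()) {
  validate_atlas(atlas)
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  as_volume_table(tab, atlas, extra_phenotypes)
}

#' Validate and order a data frame as a volume table
#'
#' @param tab Data frame with the volume-table column contract.
#' @inheritParams read_volume_table
#' @return A `volume_table` tibble with region columns in atlas order.
#' @export
as_volume_table <- function(tab, atlas, extra_phenotypes = character()) {
  validate_atlas(atlas)
  tab <- tibble::as_tibble(tab)
  missing_std <- setdiff(standard_volume_cols, names(tab))
  if (length(missing_std) > 0) {
    abort(paste0("volume table is missing column(s): ",
                 paste(missing_std, collapse = ", ")))
  }
  regions <- atlas$region_id
  missing_reg <- setdiff(regions, names(tab))
  if (length(missing_reg) > 0) {
    abort(paste0("volume table is missing region column(s): ",
                 paste(head(missing_reg, 5), collapse = ", ")))
  }
  other <- setdiff(names(tab), c(standard_volume_cols, regions))
  pheno_ok <- c(known_phenotypes, extra_phenotypes)
  unknown <- setdiff(other, pheno_ok)
  if (length(unknown) > 0) {
    abort(paste0("unknown region column '", unknown[[1]],
                 "' (not in atlas; declare phenotypes via extra_phenotypes)"))
  }
  for (rg in regions) {
    v <- tab[[rg]]
    if (!is.numeric(v)) {
      bad_row <- which(is.na(suppressWarnings(as.numeric(v))))[1]
      abort(paste0("non-numeric volume in region '", rg, "' at row ",
                   ifelse(is.na(bad_row), 1L, bad_row)))
    }
    if (anyNA(v)) abort(paste0("missing volume in region '", rg, "'"))
    if (any(v < 0)) abort(paste0("negative volume in region '", rg, "'"))
  }
  if (!is.numeric(tab$icv) || any(!is.finite(tab$icv)) || any(tab$icv <= 0)) {
    abort("icv must be positive and finite for every subject")
  }
  if (!is.numeric(tab$age) || any(!is.finite(tab$age))) {
    abort("age must be numeric and finite")
  }
  if (anyDuplicated(tab$subject_id)) abort("duplicate subject_id")
  phen <- intersect(pheno_ok, names(tab))
  out <- dplyr::select(tab, dplyr::all_of(c(standard_volume_cols, regions, phen)))
  structure(out, class = c("volume_table", class(out)),
            regions = regions, phenotypes = phen)
}

#' Extract the region-volume matrix of a volume table
#'
#' @param vt A `volume_table`.
#' @return Numeric matrix, subjects x regions, rownames = subject ids.
#' @export
volume_matrix <- function(vt) {
  regions <- attr(vt, "regions") %||% setdiff(
    names(vt), c(standard_volume_cols, known_phenotypes))
  m <- as.matrix(vt[, regions, drop = FALSE])
  rownames(m) <- vt$subject_id
  m
}

#' Write a volume table to TSV
#'
#' @param vt A `volume_table` (or compatible data frame).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_volume_table <- function(vt, path) {
  readr::write_tsv(tibble::as_tibble(vt), path, na = "")
  invisible(path)
}

#' Read a square region-by-region connectivity matrix
#'
#' Reads a dense TSV matrix with a region-id header row and a leading
#' region-id column. Rows/columns are reordered to atlas order. Asymmetries
#' beyond 1e-8 are resolved by symmetrization `(M + t(M)) / 2` with a
#' warning; `NaN` cells and non-square input are hard errors.
#'
#' @param path TSV file path.
#' @param atlas Atlas tibble.
#' @return Symmetric numeric matrix with region-id dimnames.
#' @export
read_matrix <- function(path, atlas) {
  validate_atlas(atlas)
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  ids <- as.character(tab[[1]])
  m <- as.matrix(tab[, -1, drop = FALSE])
  if (nrow(m) != ncol(m)) {
    abort(paste0("non-square matrix: ", nrow(m), " rows x ", ncol(m), " cols"))
  }
  rownames(m) <- ids
  if (!setequal(ids, atlas$region_id) || !setequal(colnames(m), atlas$region_id)) {
    abort("matrix region ids do not match the atlas")
  }
  m <- m[atlas$region_id, atlas$region_id]
  if (!is.numeric(m) || anyNA(m)) abort("matrix contains NaN/missing cells")
  asym <- max(abs(m - t(m)))
  if (asym > 1e-8) {
    warn(paste0("matrix asymmetric (max |M - t(M)| = ", signif(asym, 3),
                "); symmetrized as (M + t(M))/2"))
  }
  (m + t(m)) / 2
}

#' Write a connectivity matrix to TSV
#'
#' @param m Square matrix with region-id dimnames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(m, path) {
  stopifnot(is.matrix(m), nrow(m) == ncol(m), !is.null(rownames(m)))
  tab <- tibble::as_tibble(m, .name_repair = "minimal")
  tab <- dplyr::bind_cols(tibble::tibble(region_id = rownames(m)), tab)
  readr::write_tsv(tab, path)
  invisible(path)
}

#' Write a JSON run manifest
#'
#' Records the run configuration, seed, package and R versions, and md5
#' hashes of the input files, so that every CLI run is reproducible from its
#' manifest.
#'
#' @param path Output JSON path.
#' @param config A `run_config` (or plain named list).
#' @param inputs Character vector of input file paths to hash.
#' @param extra Optional named list merged into the manifest.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, config, inputs = character(), extra = list()) {
  hashes <- if (length(inputs)) as.list(tools::md5sum(inputs)) else list()
  manifest <- c(list(
    package = "persinet",
    package_version = as.character(utils::packageVersion("persinet")),
    r_version = R.version.string,
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = unclass(config),
    input_md5 = hashes
  ), extra)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
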