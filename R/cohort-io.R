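#' Write a cohort to a directory of delimited text files
#'
#' The manifest is one TSV row per patient; each modality's feature matrix
#' is a separate TSV whose first column is `id` and which contains only the
#' patients with that modality available. The simulation ground truth (if
#' present) and the generator configuration are stored alongside so a
#' written cohort is self-describing.
#'
#' @param cohort An `mm_cohort`.
#' @param dir Output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "mm_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest_path <- file.path(dir, "manifest.tsv")
  readr::write_tsv(cohort$manifest, manifest_path, progress = FALSE)
  for (m in names(cohort$features)) {
    readr::write_tsv(cohort$features[[m]],
                     file.path(dir, paste0("features_", m, ".tsv")),
                     progress = FALSE)
  }
  if (!is.null(cohort$truth)) {
    readr::write_tsv(cohort$truth, file.path(dir, "truth.tsv"), progress = FALSE)
  }
  if (!is.null(cohort$config)) {
    cfg <- cohort$config
    cfg$planted <- as.data.frame(cfg$planted)
    jsonlite::write_json(unclass(cfg), file.path(dir, "config.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(manifest_path)
}

#' Read a cohort written by [write_cohort()]
#'
#' Validates that patient ids are unique, that every feature-matrix id
#' appears in the manifest, and that availability flags agree with the
#' feature files.
#'
#' @param dir Directory containing `manifest.tsv` and `features_*.tsv`.
#' @return An `mm_cohort`.
#' @export
read_cohort <- function(dir) {
  manifest_path <- file.path(dir, "manifest.tsv")
  if (!file.exists(manifest_path)) abort(paste0("missing file: ", manifest_path))
  manifest <- readr::read_tsv(manifest_path, show_col_types = FALSE,
                              progress = FALSE)
  if (anyDuplicated(manifest$id)) {
    abort("duplicated patient ids in manifest")
  }
  if ("crs" %in% names(manifest)) manifest$crs <- as.integer(manifest$crs)

  modalities <- sub("^has_", "", grep("^has_", names(manifest), value = TRUE))
  features <- list()
  for (m in modalities) {
    path <- file.path(dir, paste0("features_", m, ".tsv"))
    if (!file.exists(path)) abort(paste0("missing file: ", path))
    fm <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
    if (names(fm)[1] != "id") abort(paste0("first column of ", path, " must be 'id'"))
    if (anyDuplicated(fm$id)) abort(paste0("duplicated patient ids in ", path))
    unknown <- setdiff(fm$id, manifest$id)
    if (length(unknown) > 0) {
      abort(sprintf("feature matrix '%s' has ids absent from manifest: %s",
                    m, paste(head(unknown, 3), collapse = ", ")))
    }
    flagged <- manifest$id[manifest[[paste0("has_", m)]]]
    if (!setequal(flagged, fm$id)) {
      abort(sprintf("availability flags for '%s' disagree with feature rows", m))
    }
    features[[m]] <- fm
  }

  truth_path <- file.path(dir, "truth.tsv")
  truth <- if (file.exists(truth_path)) {
    readr::read_tsv(truth_path, show_col_types = FALSE, progress = FALSE)
  }

  structure(
    list(manifest = manifest, features = features, truth = truth, config = NULL),
    class = "mm_cohort"
  )
}
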