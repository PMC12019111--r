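#' Write one scan (and its confounds) as TSV
#'
#' The scan matrix is written rows = frames, columns = ROIs; confounds (if
#' present) go to a sibling `*_confounds.tsv`, and the censor mask to
#' `*_censor.tsv` (one logical column `keep`).
#'
#' @param ts A [roi_timeseries()] scan.
#' @param path Output TSV path for the data matrix.
#' @return `path`, invisibly.
#' @export
write_scan_tsv <- function(ts, path) {
  readr::write_tsv(tibble::as_tibble(ts$data, .name_repair = "minimal"), path)
  stem <- sub("\\.tsv$", "", path)
  if (!is.null(ts$confounds)) {
    readr::write_tsv(tibble::as_tibble(ts$confounds), paste0(stem, "_confounds.tsv"))
  }
  readr::write_tsv(tibble::tibble(keep = ts$censor_mask),
                   paste0(stem, "_censor.tsv"))
  invisible(path)
}

#' Read a scan TSV (with optional confounds and censor mask) back
#'
#' @param path Data TSV written by [write_scan_tsv()].
#' @param tr_seconds Repetition time of the scan.
#' @param subject_id,condition Labels to attach.
#' @return A [roi_timeseries()] scan.
#' @export
read_scan_tsv <- function(path, tr_seconds, subject_id = NA_character_,
                          condition = NA_character_) {
  data <- as.matrix(readr::read_tsv(path, show_col_types = FALSE))
  stem <- sub("\\.tsv$", "", path)
  conf_path <- paste0(stem, "_confounds.tsv")
  cen_path <- paste0(stem, "_censor.tsv")
  confounds <- if (file.exists(conf_path)) {
    as.matrix(readr::read_tsv(conf_path, show_col_types = FALSE))
  }
  censor <- if (file.exists(cen_path)) {
    readr::read_tsv(cen_path, show_col_types = FALSE)$keep
  }
  roi_timeseries(data, tr_seconds = tr_seconds, subject_id = subject_id,
                 condition = condition, confounds = confounds,
                 censor_mask = censor)
}

#' Export a synthetic cohort to a directory of plain-text files
#'
#' Writes one TSV (+ confounds + censor TSVs) per scan, the ROI/network
#' templates and ground truth as JSON, and the subject table as TSV.
#'
#' @param cohort A `synthetic_cohort` generated with time series.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  assert_that(!is.null(cohort$scans),
              "cohort was generated without time series")
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (sid in names(cohort$scans)) {
    write_scan_tsv(cohort$scans[[sid]], file.path(dir, paste0(sid, ".tsv")))
  }
  readr::write_tsv(cohort$templates, file.path(dir, "templates.tsv"))
  readr::write_tsv(cohort$subjects, file.path(dir, "subjects.tsv"))
  jsonlite::write_json(
    list(sequences = cohort$truth$sequences,
         sensitivity = as.list(cohort$truth$sensitivity),
         ddwell_fpn = as.list(cohort$truth$ddwell_fpn)),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}
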