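#' Write and load subject recordings
#'
#' Recordings are exchanged as plain text: one TSV per subject (header =
#' ROI names, one row per frame), companion `<id>_csf.tsv` /
#' `<id>_wm.tsv` nuisance tables, and a JSON sidecar carrying group, TR,
#' motion summaries, parcel means and file pointers. The ground-truth
#' ledger of a simulated cohort is written as `ledger.json`.
#'
#' @param cohort result of [simulate_cohort()], or a plain list of
#'   `subject_recording` objects.
#' @param dir output directory (created if absent).
#' @return `write_recordings()`: invisibly, the sidecar paths.
#' @export
write_recordings <- function(cohort, dir) {
  recs <- if (!is.null(cohort$recordings)) cohort$recordings else cohort
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_tsv <- function(m, path) {
    if (is.null(colnames(m))) colnames(m) <- paste0("V", seq_len(ncol(m)))
    utils::write.table(m, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
  }
  paths <- vapply(recs, function(rec) {
    id <- rec$subject_id
    write_tsv(rec$roi_series, file.path(dir, paste0(id, ".tsv")))
    write_tsv(rec$csf_series, file.path(dir, paste0(id, "_csf.tsv")))
    write_tsv(rec$wm_series, file.path(dir, paste0(id, "_wm.tsv")))
    sidecar <- list(
      subject_id = id, group = rec$group, tr_seconds = rec$tr_seconds,
      motion_mm = rec$motion_mm, motion_deg = rec$motion_deg,
      parcel_means = as.list(rec$parcel_means),
      roi_file = paste0(id, ".tsv"),
      csf_file = paste0(id, "_csf.tsv"),
      wm_file = paste0(id, "_wm.tsv")
    )
    path <- file.path(dir, paste0(id, ".json"))
    jsonlite::write_json(sidecar, path, auto_unbox = TRUE, digits = NA)
    path
  }, character(1))
  if (!is.null(cohort$ledger)) {
    jsonlite::write_json(cohort$ledger, file.path(dir, "ledger.json"),
                         dataframe = "rows", digits = NA)
  }
  invisible(paths)
}

#' @rdname write_recordings
#' @param catalog an [roi_catalog()]; TSV headers must match its ROI
#'   names exactly (same set and order). Subjects failing validation are
#'   skipped with a per-subject diagnostic.
#' @return `load_dataset()`: list of `subject_recording` objects, with
#'   attribute `rejected` (named character vector of diagnostics).
#' @export
load_dataset <- function(dir, catalog = default_roi_catalog()) {
  sidecars <- sort(list.files(dir, pattern = "\\.json$", full.names = TRUE))
  sidecars <- sidecars[basename(sidecars) != "ledger.json"]
  if (!length(sidecars)) {
    warning("no subject sidecars found in ", dir)
    out <- list()
    attr(out, "rejected") <- character(0)
    return(out)
  }
  read_tsv_matrix <- function(path) {
    df <- utils::read.table(path, sep = "\t", header = TRUE,
                            check.names = FALSE, colClasses = "numeric")
    as.matrix(df)
  }
  recs <- list()
  rejected <- character(0)
  for (sc in sidecars) {
    id <- sub("\\.json$", "", basename(sc))
    res <- tryCatch({
      meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
      roi <- read_tsv_matrix(file.path(dir, meta$roi_file))
      if (!identical(colnames(roi), catalog$name)) {
        stop("ROI header mismatch: expected [",
             paste(catalog$name, collapse = ", "), "], found [",
             paste(colnames(roi), collapse = ", "), "]")
      }
      csf <- read_tsv_matrix(file.path(dir, meta$csf_file))
      wm <- read_tsv_matrix(file.path(dir, meta$wm_file))
      if (nrow(csf) != nrow(roi) || nrow(wm) != nrow(roi)) {
        stop("inconsistent frame counts across series")
      }
      if (anyNA(roi) || anyNA(csf) || anyNA(wm)) {
        stop("non-numeric or missing cells in time series")
      }
      structure(
        list(subject_id = meta$subject_id, group = meta$group,
             roi_series = roi,
             parcel_means = unlist(meta$parcel_means),
             csf_series = csf, wm_series = wm,
             motion_mm = meta$motion_mm, motion_deg = meta$motion_deg,
             tr_seconds = meta$tr_seconds,
             spike_frames = integer(0), dropout_rois = character(0),
             seed = NA_integer_),
        class = "subject_recording"
      )
    }, error = function(e) conditionMessage(e))
    if (is.character(res)) {
      rejected[id] <- res
      warning("subject ", id, " rejected: ", res)
    } else {
      recs[[length(recs) + 1L]] <- res
    }
  }
  attr(recs, "rejected") <- rejected
  recs
}
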