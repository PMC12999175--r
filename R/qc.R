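#' DVARS: frame-to-frame RMS intensity change
#'
#' DVARS at frame t (t >= 2) is the root mean square, across channels, of
#' the intensity difference between frames t and t-1. The first frame has
#' no predecessor and is set to 0 by convention (and is therefore never
#' flagged on its own). Computed on whatever channels are supplied (ROI
#' or parcel series); volume-level data are not needed at this stage.
#'
#' @param series numeric matrix, frames x channels, at least 2 frames.
#' @return numeric vector of length `nrow(series)`, nonnegative, first
#'   element 0.
#' @examples
#' compute_dvars(rbind(c(0, 0), c(3, 4), c(3, 4)))  # 0, sqrt(12.5), 0
#' @export
compute_dvars <- function(series) {
  series <- as_frames_matrix(series, "series")
  if (nrow(series) < 2L) stop("DVARS needs at least 2 frames")
  d <- diff(series)
  c(0, sqrt(rowMeans(d^2)))
}

#' Flag motion-outlier frames from a DVARS trace
#'
#' A frame is an outlier when its DVARS strictly exceeds
#' Q75 + 1.5 * (Q75 - Q25), with quantiles computed by linear
#' interpolation between order statistics (R type 7). The threshold is
#' computed per trace, i.e. per run per subject. An all-equal trace
#' yields zero flags.
#'
#' @param dvars nonnegative numeric vector from [compute_dvars()].
#' @param iqr_factor multiplier on the interquartile range (default 1.5).
#' @return logical vector of flags with attribute `threshold`.
#' @examples
#' flag_motion_outliers(c(1, 1, 1, 1, 10))
#' @export
flag_motion_outliers <- function(dvars, iqr_factor = 1.5) {
  if (!length(dvars)) stop("empty DVARS trace")
  if (anyNA(dvars)) stop("DVARS trace contains missing values")
  q <- stats::quantile(dvars, c(0.25, 0.75), names = FALSE, type = 7)
  threshold <- q[2] + iqr_factor * (q[2] - q[1])
  structure(dvars > threshold, threshold = threshold)
}

#' Best continuous window of frames
#'
#' Returns the contiguous window of exactly `window_length` frames that
#' minimizes the number of flagged frames; ties are broken by the
#' earliest start. Emulates keeping a continuous subset (e.g. 1600 of
#' 2300 frames) with a minimum number of motion outliers.
#'
#' @param outlier_mask logical vector of per-frame flags.
#' @param window_length window size, at most `length(outlier_mask)`.
#' @return list with `start` (1-based first frame), `end` (last frame,
#'   inclusive), and `n_outliers` inside the window.
#' @examples
#' select_continuous_window(c(FALSE, TRUE, FALSE, FALSE, FALSE, TRUE), 3)
#' @export
select_continuous_window <- function(outlier_mask, window_length) {
  t_len <- length(outlier_mask)
  if (window_length > t_len) {
    stop("window_length (", window_length, ") exceeds run length (",
         t_len, ")")
  }
  if (window_length < 1L) stop("window_length must be positive")
  counts <- cumsum(c(0, as.numeric(outlier_mask)))
  starts <- seq_len(t_len - window_length + 1L)
  in_window <- counts[starts + window_length] - counts[starts]
  best <- which.min(in_window)  # which.min returns the earliest minimum
  list(start = best, end = best + window_length - 1L,
       n_outliers = as.integer(in_window[best]))
}

#' Detect parcel-level signal dropout
#'
#' The mean and standard deviation of BOLD intensity are computed across
#' all cortical parcels of a subject; an ROI is listed as dropout when
#' its mean intensity lies strictly below mean - 3 SD. A zero SD (all
#' parcels equal) yields an empty list.
#'
#' @param parcel_means numeric vector of per-parcel mean intensities
#'   (>= 2 parcels).
#' @param roi_means named numeric vector of per-ROI mean intensities.
#' @param sd_cutoff number of SDs below the mean (default 3).
#' @return character vector of dropout ROI names (possibly empty).
#' @examples
#' detect_signal_dropout(seq(80, 120, length.out = 100), c(OC = 60))
#' @export
detect_signal_dropout <- function(parcel_means, roi_means, sd_cutoff = 3) {
  if (length(parcel_means) < 2L) stop("need at least 2 parcels")
  if (anyNA(parcel_means)) stop("parcel means contain missing values")
  if (!length(roi_means) || anyNA(roi_means)) {
    stop("ROI means missing or incomplete")
  }
  if (is.null(names(roi_means))) stop("roi_means must be named")
  mu <- mean(parcel_means)
  sig <- stats::sd(parcel_means)
  if (sig == 0) return(character(0))
  names(roi_means)[roi_means < mu - sd_cutoff * sig]
}

#' Apply group-specific exclusion rules
#'
#' Runs the full per-subject QC chain and returns the verdict. For
#' infants: DVARS outliers are flagged over the whole run, the best
#' continuous window (default 1600 frames) is selected, and the subject
#' is excluded when the outlier count inside that window strictly exceeds
#' `max_outliers` (default 160, i.e. 10% of the window). For adults:
#' excluded when maximum head movement strictly exceeds 2 mm or rotation
#' 2 degrees. Any group is excluded when signal dropout is detected in
#' any ROI.
#'
#' @param recording a `subject_recording` (or any list with the same
#'   fields).
#' @param group `"infant"`, `"sighted"`, or `"blind"`; defaults to the
#'   recording's own group.
#' @param window_length,max_outliers infant scrubbing parameters; when
#'   `window_length` is `NULL` it defaults to `min(1600, T)` and
#'   `max_outliers` to 10% of it.
#' @param iqr_factor DVARS threshold multiplier (default 1.5).
#' @param motion_mm_limit,motion_deg_limit adult motion-summary limits
#'   (default 2 each).
#' @param sd_cutoff dropout cutoff in SDs (default 3).
#' @return a `qc_report`: list with `subject_id`, `group`, `dvars`,
#'   `outlier_mask`, `threshold`, `retained_window` (`NULL` for adults:
#'   whole run), `n_outliers_in_window`, `dropout_rois`, `excluded`,
#'   `exclusion_reasons`.
#' @export
apply_exclusion_rules <- function(recording, group = NULL,
                                  window_length = NULL, max_outliers = NULL,
                                  iqr_factor = 1.5,
                                  motion_mm_limit = 2, motion_deg_limit = 2,
                                  sd_cutoff = 3) {
  group <- group %||% recording$group
  stopifnot(group %in% c("infant", "sighted", "blind"))
  series <- as_frames_matrix(recording$roi_series, "roi_series")
  tfr <- nrow(series)
  dvars <- compute_dvars(series)
  mask <- flag_motion_outliers(dvars, iqr_factor)
  threshold <- attr(mask, "threshold")

  rois <- colnames(series)
  roi_means <- recording$parcel_means[rois]
  names(roi_means) <- rois
  dropout <- detect_signal_dropout(recording$parcel_means, roi_means,
                                   sd_cutoff)

  reasons <- character(0)
  if (group == "infant") {
    if (is.null(window_length)) window_length <- min(1600L, tfr)
    if (is.null(max_outliers)) max_outliers <- floor(0.10 * window_length)
    win <- select_continuous_window(mask, window_length)
    n_out <- win$n_outliers
    if (n_out > max_outliers) reasons <- c(reasons, "motion")
  } else {
    win <- NULL
    n_out <- sum(mask)
    if (recording$motion_mm > motion_mm_limit ||
        recording$motion_deg > motion_deg_limit) {
      reasons <- c(reasons, "motion")
    }
  }
  if (length(dropout)) reasons <- c(reasons, "dropout")

  structure(
    list(subject_id = recording$subject_id, group = group,
         dvars = dvars, outlier_mask = as.logical(mask),
         threshold = threshold, retained_window = win,
         n_outliers_in_window = n_out, dropout_rois = dropout,
         excluded = length(reasons) > 0, exclusion_reasons = reasons),
    class = "qc_report"
  )
}

#' @export
print.qc_report <- function(x, ...) {
  cat("<qc_report>", x$subject_id, "(", x$group, "):",
      x$n_outliers_in_window, "outliers",
      if (!is.null(x$retained_window))
        paste0("in window [", x$retained_window$start, ", ",
               x$retained_window$end, "]"),
      "-", if (x$excluded)
        paste("EXCLUDED:", paste(x$exclusion_reasons, collapse = ", "))
      else "retained", "\n")
  invisible(x)
}
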