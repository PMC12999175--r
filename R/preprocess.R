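#' Linear detrending
#'
#' Removes, per channel, the least-squares fit on an intercept plus
#' linear time term. Residuals are orthogonal to both regressors.
#'
#' @param series numeric matrix, frames x channels, >= 3 frames.
#' @return detrended matrix, same shape.
#' @examples
#' max(abs(detrend_linear(cbind(3 + 2 * (1:50)))))  # ~0
#' @export
detrend_linear <- function(series) {
  series <- as_frames_matrix(series, "series")
  n <- nrow(series)
  if (n < 3L) stop("detrending needs at least 3 frames")
  x <- cbind(1, seq_len(n))
  out <- stats::lm.fit(x, series)$residuals
  out <- as.matrix(out)
  dimnames(out) <- dimnames(series)
  out
}

#' CompCor-style nuisance components
#'
#' Standardizes every CSF- and WM-like channel to zero mean and unit
#' variance, concatenates them, and extracts the first `k` principal
#' component time courses, ordered by explained variance. Zero-variance
#' channels are dropped with a warning. Components are mutually
#' orthogonal.
#'
#' @param csf_series,wm_series numeric matrices, frames x channels
#'   (either may be `NULL` if the other has enough channels).
#' @param k number of components (default 5).
#' @return frames x k matrix of component time courses with attribute
#'   `explained_variance` (eigenvalues, non-increasing).
#' @export
extract_compcor_components <- function(csf_series, wm_series, k = 5L) {
  pieces <- Filter(Negate(is.null), list(csf = csf_series, wm = wm_series))
  if (!length(pieces)) stop("no nuisance channels supplied")
  x <- do.call(cbind, lapply(names(pieces), function(nm) {
    as_frames_matrix(pieces[[nm]], nm)
  }))
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    warning(sum(sds == 0), " zero-variance nuisance channel(s) dropped")
    x <- x[, sds > 0, drop = FALSE]
    sds <- sds[sds > 0]
  }
  if (!ncol(x)) stop("all nuisance channels have zero variance")
  if (k > min(nrow(x), ncol(x))) {
    stop("k = ", k, " exceeds min(frames, channels) = ",
         min(nrow(x), ncol(x)))
  }
  x <- scale(x)
  sv <- svd(x, nu = k, nv = 0)
  comp <- sv$u[, seq_len(k), drop = FALSE] %*%
    diag(sv$d[seq_len(k)], k, k)
  colnames(comp) <- paste0("PC", seq_len(k))
  attr(comp, "explained_variance") <- sv$d^2 / (nrow(x) - 1)
  comp
}

#' Regress nuisance signals out of a series
#'
#' Per-channel least-squares residual after projecting on the given
#' regressors plus an intercept (always included). The design must be
#' full column rank.
#'
#' @param series numeric matrix, frames x channels.
#' @param regressors numeric matrix, frames x q (may have zero columns,
#'   in which case only the intercept is removed).
#' @return residual matrix, same shape as `series`.
#' @export
regress_nuisance <- function(series, regressors) {
  series <- as_frames_matrix(series, "series")
  if (is.null(regressors)) {
    regressors <- matrix(numeric(0), nrow(series), 0)
  }
  regressors <- as.matrix(regressors)
  if (nrow(regressors) != nrow(series)) {
    stop("regressors and series disagree on frame count")
  }
  # drop all-zero regressors (no information), then demand full rank
  nonzero <- apply(regressors, 2, function(c) any(c != 0))
  regressors <- regressors[, nonzero, drop = FALSE]
  x <- cbind(1, regressors)
  if (qr(x)$rank < ncol(x)) {
    stop("nuisance design is rank deficient (", ncol(x),
         " columns, rank ", qr(x)$rank, ")")
  }
  out <- as.matrix(stats::lm.fit(x, series)$residuals)
  dimnames(out) <- dimnames(series)
  out
}

#' Delete censored frames
#'
#' Removes flagged frames outright (no interpolation); downstream
#' correlations use the retained frames only.
#'
#' @param series numeric matrix, frames x channels.
#' @param outlier_mask logical vector, length = frame count; `TRUE`
#'   frames are dropped.
#' @param min_frames minimum retained frames for a usable series
#'   (default 10).
#' @return matrix of retained frames.
#' @export
censor_frames <- function(series, outlier_mask, min_frames = 10L) {
  series <- as_frames_matrix(series, "series")
  if (length(outlier_mask) != nrow(series)) {
    stop("mask length (", length(outlier_mask),
         ") does not match frame count (", nrow(series), ")")
  }
  kept <- series[!outlier_mask, , drop = FALSE]
  if (nrow(kept) < min_frames) {
    stop("only ", nrow(kept), " frames retained after censoring; ",
         "need at least ", min_frames)
  }
  kept
}

#' Denoise one subject's retained time series
#'
#' Runs the per-subject denoising chain on the retained window and
#' returns the cleaned series together with an ordered provenance record
#' of every step applied. Default order: linear detrend, CompCor
#' nuisance regression, zero-phase Butterworth temporal filter, frame
#' censoring. Censoring is applied last so the filter never runs across
#' deleted-frame gaps; set `censor_before_filter = TRUE` for the
#' alternate order (the change is recorded in the provenance, never
#' silent).
#'
#' @param recording a `subject_recording`.
#' @param qc_report matching `qc_report` from [apply_exclusion_rules()];
#'   supplies the retained window and the outlier mask.
#' @param lowpass_hz low-pass cutoff (default 0.08 Hz).
#' @param highpass_seconds optional high-pass period in seconds; the
#'   adult profile uses 150, infants `NULL` (their upstream denoising is
#'   emulated by the generator).
#' @param compcor_k CompCor components to remove; 0 disables (infants).
#' @param censor_before_filter logical flag for the alternate step order.
#' @return a `clean_series`: list with `matrix` (retained frames x ROIs),
#'   `provenance` (character), `tr_seconds`, `n_frames_used`.
#' @export
preprocess_subject <- function(recording, qc_report,
                               lowpass_hz = 0.08, highpass_seconds = NULL,
                               compcor_k = 5L,
                               censor_before_filter = FALSE) {
  series <- as_frames_matrix(recording$roi_series, "roi_series")
  mask <- qc_report$outlier_mask
  win <- qc_report$retained_window
  prov <- character(0)
  if (!is.null(win)) {
    idx <- win$start:win$end
    series <- series[idx, , drop = FALSE]
    mask <- mask[idx]
    csf <- recording$csf_series[idx, , drop = FALSE]
    wm <- recording$wm_series[idx, , drop = FALSE]
    prov <- c(prov, sprintf("window[%d,%d]", win$start, win$end))
  } else {
    csf <- recording$csf_series
    wm <- recording$wm_series
  }

  series <- detrend_linear(series)
  prov <- c(prov, "detrend_linear")

  if (compcor_k > 0 && (!is.null(csf) || !is.null(wm))) {
    comp <- extract_compcor_components(csf, wm, k = compcor_k)
    series <- regress_nuisance(series, comp)
    prov <- c(prov, sprintf("compcor_regress(k=%d)", compcor_k))
  }

  do_filter <- function(s) {
    temporal_filter(s, tr = recording$tr_seconds, lowpass_hz = lowpass_hz,
                    highpass_seconds = highpass_seconds)
  }
  filter_tag <- sprintf(
    "butterworth(low=%g Hz%s)", lowpass_hz,
    if (is.null(highpass_seconds)) ""
    else sprintf(", high=1/%g Hz", highpass_seconds))

  if (censor_before_filter) {
    series <- censor_frames(series, mask)
    prov <- c(prov, sprintf("censor(%d frames)", sum(mask)))
    series <- do_filter(series)
    prov <- c(prov, filter_tag)
  } else {
    series <- do_filter(series)
    prov <- c(prov, filter_tag)
    series <- censor_frames(series, mask)
    prov <- c(prov, sprintf("censor(%d frames)", sum(mask)))
  }

  structure(
    list(matrix = series, provenance = prov,
         tr_seconds = recording$tr_seconds,
         n_frames_used = nrow(series)),
    class = "clean_series"
  )
}
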