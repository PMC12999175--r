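#' Butterworth filter design (digital, via bilinear transform)
#'
#' Designs digital Butterworth low- or high-pass coefficients from the
#' analog prototype, pre-warping the cutoff for the bilinear transform.
#' Only the pieces needed for BOLD temporal filtering are implemented.
#'
#' @param order filter order (positive integer; default 4).
#' @param w normalized cutoff in (0, 1), as a fraction of the Nyquist
#'   frequency.
#' @param type `"low"` or `"high"`.
#' @return list with numerator `b` and denominator `a` coefficient vectors
#'   (length `order + 1`, `a[1] == 1`).
#' @keywords internal
butter_design <- function(order = 4L, w, type = c("low", "high")) {
  type <- match.arg(type)
  stopifnot(length(order) == 1L, order >= 1L, length(w) == 1L)
  if (!is.finite(w) || w <= 0 || w >= 1) {
    stop("normalized cutoff must lie strictly inside (0, 1); got ", w)
  }
  # analog prototype poles on the unit circle, left half-plane
  k <- seq_len(order)
  p <- exp(1i * pi * (2 * k + order - 1) / (2 * order))
  warped <- 4 * tan(pi * w / 2)  # fs = 2 convention, matches scipy
  if (type == "low") {
    p <- warped * p
    z <- complex(0)
    gain <- warped^order
  } else {
    z <- rep(0 + 0i, order)      # high-pass: zeros at s = 0
    gain <- 1
    p <- warped / p
  }
  # bilinear transform (fs = 2): s = 4 (z - 1) / (z + 1)
  fs2 <- 4
  zd <- (fs2 + z) / (fs2 - z)
  pd <- (fs2 + p) / (fs2 - p)
  gain <- gain * Re(prod(fs2 - z) / prod(fs2 - p))
  # high-pass gains zeros at z = -1 are already in zd (z = 0 maps to 1);
  # low-pass needs `order` zeros at z = -1 from the transform itself
  zd <- c(zd, rep(-1 + 0i, order - length(z)))
  b <- Re(gain * poly_from_roots(zd))
  a <- Re(poly_from_roots(pd))
  list(b = b, a = a)
}

# monic polynomial coefficients from roots, highest degree first
poly_from_roots <- function(r) {
  coefs <- 1 + 0i
  for (root in r) coefs <- c(coefs, 0) - c(0, coefs * root)
  coefs
}

# steady-state initial filter state for a unit-step input
# (solves (I - companion(a)') zi = b[-1] - a[-1] b[1])
lfilter_zi <- function(b, a) {
  n <- length(a)
  comp_t <- rbind(-a[-1] / a[1], diag(1, n - 2, n - 1))
  solve(diag(n - 1) - t(comp_t), b[-1] - a[-1] * b[1])
}

# direct-form-II-transposed IIR filter on a frames x channels matrix,
# with per-channel initial state zi ((n-1) x channels)
iir_filter <- function(b, a, x, zi = NULL) {
  nf <- nrow(x)
  nc <- ncol(x)
  n <- length(a)
  z <- if (is.null(zi)) matrix(0, n - 1, nc) else zi
  y <- matrix(0, nf, nc)
  for (m in seq_len(nf)) {
    xm <- x[m, ]
    ym <- b[1] * xm + z[1, ]
    if (n > 2) {
      for (i in seq_len(n - 2)) {
        z[i, ] <- b[i + 1] * xm + z[i + 1, ] - a[i + 1] * ym
      }
    }
    z[n - 1, ] <- b[n] * xm - a[n] * ym
    y[m, ] <- ym
  }
  y
}

#' Zero-phase forward-backward filtering
#'
#' Applies an IIR filter forward and backward so the net phase response is
#' zero, with odd-reflection edge padding and steady-state initial
#' conditions to suppress startup transients (the same convention as
#' SciPy's `filtfilt` default).
#'
#' @param b,a filter coefficients from [butter_design()].
#' @param x numeric matrix, frames x channels (a vector is treated as one
#'   channel).
#' @return filtered matrix, same shape as `x`.
#' @keywords internal
filtfilt <- function(b, a, x) {
  vec <- is.null(dim(x))
  if (vec) x <- matrix(x, ncol = 1)
  n <- nrow(x)
  padlen <- 3L * max(length(a), length(b))
  if (n <= padlen) {
    stop("series too short for zero-phase filtering: need more than ",
         padlen, " frames, got ", n)
  }
  head_pad <- 2 * rep(1, padlen) %o% x[1, ] - x[(padlen + 1):2, , drop = FALSE]
  tail_pad <- 2 * rep(1, padlen) %o% x[n, ] - x[(n - 1):(n - padlen), , drop = FALSE]
  ext <- rbind(head_pad, x, tail_pad)
  zi <- lfilter_zi(b, a)
  y <- iir_filter(b, a, ext, zi %o% ext[1, ])
  y <- y[nrow(y):1, , drop = FALSE]
  y <- iir_filter(b, a, y, zi %o% y[1, ])
  y <- y[nrow(y):1, , drop = FALSE]
  out <- y[(padlen + 1):(padlen + n), , drop = FALSE]
  if (vec) out[, 1] else out
}

#' Temporal filtering of ROI time series
#'
#' Zero-phase 4th-order Butterworth filtering of each column. A low-pass
#' cutoff (in Hz) is always applied; an optional high-pass (given as a
#' period in seconds, e.g. 150) adds a second zero-phase high-pass stage,
#' which together realize the band-pass used for adult recordings.
#'
#' @param series numeric matrix, frames x channels.
#' @param tr repetition time in seconds (sampling interval).
#' @param lowpass_hz low-pass cutoff in Hz (default 0.08).
#' @param highpass_seconds optional high-pass cutoff period in seconds
#'   (e.g. 150 for adult runs); `NULL` disables the high-pass stage.
#' @param order Butterworth order per stage (default 4).
#' @return filtered matrix with the same dimensions and column names.
#' @examples
#' x <- matrix(rnorm(400), 200, 2)
#' y <- temporal_filter(x, tr = 2, lowpass_hz = 0.08)
#' @export
temporal_filter <- function(series, tr, lowpass_hz = 0.08,
                            highpass_seconds = NULL, order = 4L) {
  series <- as_frames_matrix(series, "series")
  stopifnot(length(tr) == 1L, is.finite(tr), tr > 0)
  nyq <- 1 / (2 * tr)
  if (lowpass_hz >= nyq) {
    stop("low-pass cutoff ", lowpass_hz, " Hz is at or above Nyquist (",
         signif(nyq, 4), " Hz) for TR = ", tr, " s")
  }
  stages <- list(butter_design(order, lowpass_hz / nyq, "low"))
  if (!is.null(highpass_seconds)) {
    hp_hz <- 1 / highpass_seconds
    if (hp_hz >= nyq) {
      stop("high-pass cutoff ", signif(hp_hz, 4),
           " Hz is at or above Nyquist for TR = ", tr, " s")
    }
    if (hp_hz >= lowpass_hz) {
      stop("high-pass cutoff must lie below the low-pass cutoff")
    }
    stages <- c(stages, list(butter_design(order, hp_hz / nyq, "high")))
  }
  out <- series
  for (st in stages) {
    out <- filtfilt(st$b, st$a, out)
  }
  dimnames(out) <- dimnames(series)
  out
}
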