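#' ROI-to-ROI functional connectivity matrix
#'
#' Full pairwise Pearson correlation between ROI-averaged time series on
#' the retained frames.
#'
#' @param clean_series a `clean_series` from [preprocess_subject()], or a
#'   plain frames x ROIs matrix.
#' @return an `fc_matrix`: list with `matrix` (symmetric, unit diagonal,
#'   entries in \[-1, 1\]) and `n_frames_used`.
#' @examples
#' x <- matrix(rnorm(200), 50, 4, dimnames = list(NULL, letters[1:4]))
#' fc <- compute_fc_matrix(x)
#' isSymmetric(fc$matrix)
#' @export
compute_fc_matrix <- function(clean_series) {
  m <- if (inherits(clean_series, "clean_series")) clean_series$matrix
       else clean_series
  m <- as_frames_matrix(m, "clean_series")
  if (nrow(m) < 10L) {
    stop("need at least 10 retained frames; got ", nrow(m))
  }
  sds <- apply(m, 2, stats::sd)
  if (any(sds == 0)) {
    stop("zero-variance ROI(s): ",
         paste(colnames(m)[sds == 0] %||% which(sds == 0), collapse = ", "))
  }
  fc <- stats::cor(m)
  fc[fc > 1] <- 1
  fc[fc < -1] <- -1
  diag(fc) <- 1
  structure(list(matrix = fc, n_frames_used = nrow(m)),
            class = "fc_matrix")
}

fc_mat <- function(fc) if (inherits(fc, "fc_matrix")) fc$matrix else fc

#' Block-averaged connectivity
#'
#' Arithmetic mean of raw Pearson r over all seed x target ROI pairs
#' (both hemispheres unless the sets are restricted beforehand). Raw-r
#' averaging is the default because group summaries are reported as mean
#' r; Fisher-z averaging is available behind a flag.
#'
#' @param fc an `fc_matrix` or plain correlation matrix with dimnames.
#' @param seed_set,target_set character vectors of ROI names; non-empty
#'   and disjoint.
#' @param fisher average in Fisher-z space and back-transform
#'   (default `FALSE`).
#' @return mean correlation (scalar).
#' @export
average_block_fc <- function(fc, seed_set, target_set, fisher = FALSE) {
  m <- fc_mat(fc)
  if (!length(seed_set) || !length(target_set)) {
    stop("seed and target sets must be non-empty")
  }
  if (length(intersect(seed_set, target_set))) {
    stop("seed and target sets overlap: ",
         paste(intersect(seed_set, target_set), collapse = ", "))
  }
  missing <- setdiff(c(seed_set, target_set), rownames(m))
  if (length(missing)) {
    stop("ROIs absent from FC matrix: ", paste(missing, collapse = ", "))
  }
  block <- m[seed_set, target_set, drop = FALSE]
  if (fisher) tanh(mean(atanh(block))) else mean(block)
}

#' Within- vs between-hemisphere connectivity
#'
#' Splits the seed x target block into same-hemisphere and
#' opposite-hemisphere pairs and averages each.
#'
#' @inheritParams average_block_fc
#' @param catalog an [roi_catalog()] providing hemisphere labels.
#' @return list with `within` and `between` mean correlations.
#' @export
laterality_fc <- function(fc, seed_set, target_set, catalog) {
  m <- fc_mat(fc)
  hemi <- stats::setNames(catalog$hemisphere, catalog$name)
  for (set in list(seed_set, target_set)) {
    h <- hemi[set]
    if (anyNA(h)) stop("ROI(s) missing from catalog: ",
                       paste(set[is.na(h)], collapse = ", "))
    if (length(unique(h)) < 2L) {
      stop("each set needs ROIs in both hemispheres for laterality")
    }
  }
  same <- outer(hemi[seed_set], hemi[target_set], "==")
  block <- m[seed_set, target_set, drop = FALSE]
  list(within = mean(block[same]), between = mean(block[!same]))
}

#' Min-max normalization of a connectivity profile
#'
#' Rescales values to \[0, 1\] as (x - min) / (max - min), i.e. expresses
#' each value as a proportion of the profile's range. Invariant to
#' affine transforms of the input.
#'
#' @param values numeric vector, length >= 2, not all equal.
#' @return normalized vector (min 0, max 1).
#' @examples
#' minmax_normalize_profile(c(1, 2, 3))
#' @export
minmax_normalize_profile <- function(values) {
  if (length(values) < 2L) stop("need at least 2 values")
  if (anyNA(values)) stop("values contain NA")
  rng <- range(values)
  if (rng[1] == rng[2]) {
    stop("all values equal; min-max proportion undefined")
  }
  (values - rng[1]) / (rng[2] - rng[1])
}

#' Correlation between two group-mean connectivity matrices
#'
#' Pearson correlation between the vectorized unique off-diagonal cells
#' (strict lower triangle) of two group-mean FC submatrices over a
#' common ROI subset, in identical order.
#'
#' @param fc_a,fc_b `fc_matrix` objects or plain matrices with dimnames.
#' @param roi_subset character vector of >= 3 ROI names defining the
#'   submatrix (defaults to all shared ROIs, in `fc_a` order).
#' @return Pearson r between the two vectorized lower triangles.
#' @export
matrix_profile_correlation <- function(fc_a, fc_b, roi_subset = NULL) {
  a <- fc_mat(fc_a)
  b <- fc_mat(fc_b)
  roi_subset <- roi_subset %||% intersect(rownames(a), rownames(b))
  if (length(roi_subset) < 3L) {
    stop("need at least 3 ROIs (3 unique off-diagonal cells)")
  }
  missing <- c(setdiff(roi_subset, rownames(a)),
               setdiff(roi_subset, rownames(b)))
  if (length(missing)) {
    stop("ROIs absent from a matrix: ",
         paste(unique(missing), collapse = ", "))
  }
  av <- a[roi_subset, roi_subset][lower.tri(diag(length(roi_subset)))]
  bv <- b[roi_subset, roi_subset][lower.tri(diag(length(roi_subset)))]
  stats::cor(av, bv)
}

#' Split-half noise ceiling of an ROI's connectivity profile
#'
#' The time series is split into two contiguous halves (odd lengths give
#' the extra frame to the first half). For each half, the ROI's FC
#' profile is its vector of correlations to every other ROI; the noise
#' ceiling is the Pearson correlation between the two profiles. Bounds
#' the detectable effect size for that ROI and subject.
#'
#' @param clean_series `clean_series` or frames x ROIs matrix with >= 20
#'   frames and >= 3 ROIs.
#' @param roi ROI name (or column index) whose profile is evaluated;
#'   `NULL` returns a named vector of ceilings for every ROI.
#' @return noise ceiling(s) in \[-1, 1\].
#' @export
split_half_noise_ceiling <- function(clean_series, roi = NULL) {
  m <- if (inherits(clean_series, "clean_series")) clean_series$matrix
       else clean_series
  m <- as_frames_matrix(m, "clean_series")
  tfr <- nrow(m)
  if (tfr < 20L) stop("need at least 20 frames for a split-half ceiling")
  if (ncol(m) < 3L) {
    stop("need at least 3 ROIs so each profile has >= 2 entries")
  }
  half1 <- m[seq_len(ceiling(tfr / 2)), , drop = FALSE]
  half2 <- m[(ceiling(tfr / 2) + 1L):tfr, , drop = FALSE]
  fc1 <- stats::cor(half1)
  fc2 <- stats::cor(half2)
  ceiling_for <- function(j) {
    stats::cor(fc1[j, -j], fc2[j, -j])
  }
  cols <- colnames(m) %||% seq_len(ncol(m))
  if (is.null(roi)) {
    stats::setNames(vapply(seq_len(ncol(m)), ceiling_for, numeric(1)), cols)
  } else {
    j <- if (is.character(roi)) match(roi, cols) else roi
    if (is.na(j)) stop("ROI not found: ", roi)
    ceiling_for(j)
  }
}
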