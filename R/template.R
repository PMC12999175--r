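#' Build a group-specific ROI correlation template
#'
#' Constructs the target Pearson correlation matrix from which synthetic
#' BOLD series are drawn. Three named profiles encode the qualitative
#' group structure under study:
#'
#' * `blind_like` — occipital seeds (secondary visual and V1) couple more
#'   strongly with prefrontal targets than with non-visual sensory-motor
#'   targets (A1, S1/M1), by `effect_size`; seed-PFC coupling is strongly
#'   lateralized (within-hemisphere pairs exceed between-hemisphere pairs
#'   by `laterality`).
#' * `sighted_like` — the reverse dissociation: seed-sensorimotor exceeds
#'   seed-PFC by `effect_size`, with a weak laterality increment.
#' * `infant_like` — secondary-visual seeds are PFC-dominant like the
#'   blind profile, but V1 is balanced (PFC and sensorimotor coupling
#'   equal); laterality matches the sighted profile.
#'
#' All remaining ROI pairs sit at `baseline`. The raw block matrix is
#' repaired to the nearest correlation matrix if indefinite.
#'
#' @param profile_name one of `"sighted_like"`, `"blind_like"`,
#'   `"infant_like"`.
#' @param roi_catalog an [roi_catalog()]; must contain seed and target
#'   categories in both hemispheres.
#' @param effect_size planted block difference |mean(seed-PFC) -
#'   mean(seed-SM)| in correlation units (default 0.15).
#' @param baseline correlation assigned to unstructured pairs
#'   (default 0.2).
#' @param laterality within-minus-between hemisphere increment applied to
#'   seed-PFC pairs; defaults depend on profile (0.2 blind-like, 0.05
#'   sighted- and infant-like).
#' @return a `correlation_template`: list with `roi_names`, `matrix`
#'   (repaired), `raw_matrix` (before repair), `profile_name`, and the
#'   planted parameters.
#' @examples
#' tpl <- make_correlation_template("blind_like", default_roi_catalog())
#' range(tpl$matrix[upper.tri(tpl$matrix)])
#' @export
make_correlation_template <- function(profile_name = c("blind_like",
                                                       "sighted_like",
                                                       "infant_like"),
                                      roi_catalog = default_roi_catalog(),
                                      effect_size = 0.15,
                                      baseline = 0.2,
                                      laterality = NULL) {
  profile_name <- match.arg(profile_name)
  check_scalar(effect_size, "effect_size", lower = 0)
  if (is.null(laterality)) {
    laterality <- if (profile_name == "blind_like") 0.2 else 0.05
  }
  check_scalar(laterality, "laterality", lower = 0)
  cat <- roi_catalog
  required <- c(secondary_visual_categories(), "V1", pfc_categories(),
                sensorimotor_categories())
  missing <- setdiff(required, cat$category)
  if (length(missing)) {
    stop("catalog lacks required categories: ",
         paste(missing, collapse = ", "))
  }
  n <- nrow(cat)
  m <- matrix(baseline, n, n, dimnames = list(cat$name, cat$name))
  diag(m) <- 1

  sv <- cat$name[cat$category %in% secondary_visual_categories()]
  v1 <- cat$name[cat$category == "V1"]
  pfc <- cat$name[cat$category %in% pfc_categories()]
  sm <- cat$name[cat$category %in% sensorimotor_categories()]

  # per-profile signed block difference (PFC minus sensorimotor) per seed set
  delta <- switch(profile_name,
    blind_like   = c(sv = effect_size, v1 = effect_size),
    sighted_like = c(sv = -effect_size, v1 = -effect_size),
    infant_like  = c(sv = effect_size, v1 = 0)
  )
  set_block <- function(m, rows, cols, value) {
    m[rows, cols] <- value
    m[cols, rows] <- value
    m
  }
  for (seed_set in c("sv", "v1")) {
    seeds <- if (seed_set == "sv") sv else v1
    d <- delta[[seed_set]]
    m <- set_block(m, seeds, pfc, baseline + d / 2)
    m <- set_block(m, seeds, sm, baseline - d / 2)
    # laterality applies to the seed-PFC block: within-hemisphere pairs up,
    # between-hemisphere pairs down, preserving the block mean
    hemi <- stats::setNames(cat$hemisphere, cat$name)
    for (s in seeds) for (p in pfc) {
      shift <- if (hemi[s] == hemi[p]) laterality / 2 else -laterality / 2
      m[s, p] <- m[s, p] + shift
      m[p, s] <- m[s, p]
    }
  }
  off <- m[row(m) != col(m)]
  if (any(off <= -1 | off >= 1)) {
    stop("effect_size/laterality/baseline combination pushes correlations ",
         "outside (-1, 1); largest magnitude ", signif(max(abs(off)), 4))
  }
  repaired <- if (is_psd_correlation(m)) {
    structure(m, distance = 0, iterations = 0L)
  } else {
    nearest_correlation(m)
  }
  structure(
    list(roi_names = cat$name, matrix = repaired, raw_matrix = m,
         profile_name = profile_name, effect_size = effect_size,
         baseline = baseline, laterality = laterality),
    class = "correlation_template"
  )
}

#' @rdname make_correlation_template
#' @param mat symmetric matrix of target correlations with unit diagonal
#'   and dimnames (off-diagonal entries strictly inside (-1, 1));
#'   repaired to the nearest correlation matrix if indefinite.
#' @export
custom_correlation_template <- function(mat) {
  if (!is.matrix(mat) || nrow(mat) != ncol(mat) || is.null(rownames(mat))) {
    stop("`mat` must be a square matrix with ROI dimnames")
  }
  if (any(abs(diag(mat) - 1) > 1e-12)) stop("diagonal must be 1")
  off <- mat[row(mat) != col(mat)]
  if (any(off <= -1 | off >= 1)) {
    stop("off-diagonal entries must lie strictly inside (-1, 1)")
  }
  repaired <- if (is_psd_correlation(mat)) {
    structure(mat, distance = 0, iterations = 0L)
  } else {
    nearest_correlation(mat)
  }
  structure(
    list(roi_names = rownames(mat), matrix = repaired, raw_matrix = mat,
         profile_name = "custom", effect_size = NA_real_,
         baseline = NA_real_, laterality = NA_real_),
    class = "correlation_template"
  )
}

#' @export
print.correlation_template <- function(x, ...) {
  cat("<correlation_template>", x$profile_name, "-", length(x$roi_names),
      "ROIs, effect_size", x$effect_size, ", laterality", x$laterality,
      "\n  PSD repair distance:", format(attr(x$matrix, "distance")), "\n")
  invisible(x)
}
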