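#' ROI catalogs
#'
#' An ROI catalog lists the regions the pipeline analyses: name,
#' hemisphere, functional category, and role (seed or target). Seeds are
#' the occipital regions whose long-range connectivity is under study
#' (three secondary-visual regions defined by language, math, and
#' executive-function task responses, plus V1); targets are prefrontal
#' regions with the matching functional preferences and the non-visual
#' sensory-motor regions (A1, S1/M1).
#'
#' @param name character vector of unique ROI names.
#' @param hemisphere `"L"` or `"R"` per ROI.
#' @param category functional category per ROI; one of the values
#'   returned by [roi_categories()].
#' @param role `"seed"` or `"target"` per ROI.
#' @return a `roi_catalog`: a data.frame with columns `name`,
#'   `hemisphere`, `category`, `role`.
#' @examples
#' cat18 <- default_roi_catalog()
#' table(cat18$role)
#' @export
roi_catalog <- function(name, hemisphere, category, role) {
  df <- data.frame(
    name = as.character(name),
    hemisphere = as.character(hemisphere),
    category = as.character(category),
    role = as.character(role),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(df$name)) stop("ROI names must be unique")
  if (!all(df$hemisphere %in% c("L", "R"))) {
    stop("hemisphere must be 'L' or 'R'")
  }
  bad <- setdiff(df$category, roi_categories())
  if (length(bad)) stop("unknown ROI category: ", paste(bad, collapse = ", "))
  if (!all(df$role %in% c("seed", "target"))) {
    stop("role must be 'seed' or 'target'")
  }
  if (any(df$name[df$role == "seed"] %in% df$name[df$role == "target"])) {
    stop("seed and target sets must not overlap")
  }
  class(df) <- c("roi_catalog", "data.frame")
  df
}

#' @rdname roi_catalog
#' @export
roi_categories <- function() {
  c("secondary_visual_LG", "secondary_visual_MTH", "secondary_visual_EF",
    "V1", "PFC_LANG", "PFC_MATH", "PFC_EF", "A1", "S1M1")
}

#' @rdname roi_catalog
#' @export
default_roi_catalog <- function() {
  # 18 bilateral ROIs: 4 occipital seed categories, 5 target categories
  seeds <- c(OC_LANG = "secondary_visual_LG", OC_MATH = "secondary_visual_MTH",
             OC_EF = "secondary_visual_EF", V1 = "V1")
  targets <- c(PFC_LANG = "PFC_LANG", PFC_MATH = "PFC_MATH",
               PFC_EF = "PFC_EF", A1 = "A1", S1M1 = "S1M1")
  base <- c(seeds, targets)
  roi_catalog(
    name = paste0(rep(names(base), each = 2), "_", c("L", "R")),
    hemisphere = rep(c("L", "R"), length(base)),
    category = rep(unname(base), each = 2),
    role = rep(c("seed", "target"), times = c(2 * length(seeds),
                                              2 * length(targets)))
  )
}

# helper: ROI names belonging to any of the given categories
catalog_rois <- function(catalog, categories, hemisphere = NULL) {
  keep <- catalog$category %in% categories
  if (!is.null(hemisphere)) keep <- keep & catalog$hemisphere %in% hemisphere
  catalog$name[keep]
}

# category groupings used throughout the analyses
secondary_visual_categories <- function() {
  c("secondary_visual_LG", "secondary_visual_MTH", "secondary_visual_EF")
}
pfc_categories <- function() c("PFC_LANG", "PFC_MATH", "PFC_EF")
sensorimotor_categories <- function() c("A1", "S1M1")
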