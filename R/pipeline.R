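#' Pipeline configuration
#'
#' Declarative configuration for the end-to-end analysis. Defaults encode
#' the emulated study's processing choices: 1.5 x IQR DVARS threshold,
#' 1600-frame continuous window with a 160-outlier exclusion rule
#' (10%), -3 SD parcel dropout cutoff, 0.08 Hz low-pass for everyone,
#' 150 s high-pass and 5 CompCor components for adults. Infants receive
#' no high-pass; their upstream ICA-style denoising is emulated by
#' regressing the generator's nuisance compartments, so `compcor_k`
#' applies to all groups.
#'
#' @param catalog an [roi_catalog()].
#' @param iqr_factor DVARS outlier multiplier (default 1.5).
#' @param window_length infant continuous-window length; `NULL` =
#'   min(1600, run length).
#' @param max_outliers infant exclusion count; `NULL` = 10% of window.
#' @param dropout_sd parcel dropout cutoff in SDs (default 3).
#' @param motion_mm_limit,motion_deg_limit adult motion-summary limits.
#' @param lowpass_hz low-pass cutoff in Hz (default 0.08).
#' @param adult_highpass_seconds adult high-pass period (default 150 s).
#' @param compcor_k CompCor components removed per subject (default 5).
#' @param censor_before_filter alternate preprocessing order flag.
#' @param fisher_block_average average block FC in Fisher-z space.
#' @param verbose print per-stage progress.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(catalog = default_roi_catalog(),
                            iqr_factor = 1.5,
                            window_length = NULL, max_outliers = NULL,
                            dropout_sd = 3,
                            motion_mm_limit = 2, motion_deg_limit = 2,
                            lowpass_hz = 0.08,
                            adult_highpass_seconds = 150,
                            compcor_k = 5L,
                            censor_before_filter = FALSE,
                            fisher_block_average = FALSE,
                            verbose = FALSE) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' QC -> exclusion -> denoising -> connectivity -> group statistics, on a
#' list of recordings (simulated or loaded from disk). Every subject is
#' accounted for: `included + excluded = loaded`. Deterministic given
#' the recordings and configuration.
#'
#' Group statistics follow the study's analysis menu for each seed set
#' (secondary visual, V1): per-subject block-averaged FC to PFC and to
#' sensorimotor targets, the sighted-vs-blind group x target-category
#' mixed-ANOVA interaction, Bonferroni-corrected paired t per group with
#' Cohen's d, within- vs between-hemisphere laterality and its group
#' interaction, correlations between group-mean matrices (infant vs each
#' adult group) compared with the Pearson-Filon z, and a one-way ANOVA
#' on subject-mean noise ceilings across the three groups.
#'
#' @param recordings list of `subject_recording` objects (e.g.
#'   `simulate_cohort(...)$recordings` or [load_dataset()]).
#' @param config a [pipeline_config()].
#' @param out_dir optional directory; when given, tidy CSV report tables
#'   are written there.
#' @return list with `qc` (per-subject data.frame), `qc_reports`,
#'   `fc` (per-subject fc_matrix list), `noise_ceiling` (data.frame),
#'   `block_fc` (tidy data.frame), `laterality` (tidy data.frame),
#'   `matrix_correlation` (data.frame), `stats` (tidy data.frame),
#'   `included`, `excluded`.
#' @export
run_pipeline <- function(recordings, config = pipeline_config(),
                         out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  n_loaded <- length(recordings)
  if (!n_loaded) stop("no recordings supplied")
  say <- function(...) if (config$verbose) message(...)
  catalog <- config$catalog

  ## ---- QC ----
  say("QC: DVARS, scrubbing, dropout on ", n_loaded, " subjects")
  qc_reports <- lapply(recordings, function(rec) {
    apply_exclusion_rules(
      rec, window_length = config$window_length,
      max_outliers = config$max_outliers, iqr_factor = config$iqr_factor,
      motion_mm_limit = config$motion_mm_limit,
      motion_deg_limit = config$motion_deg_limit,
      sd_cutoff = config$dropout_sd)
  })
  qc_df <- do.call(rbind, lapply(qc_reports, function(q) {
    data.frame(subject_id = q$subject_id, group = q$group,
               n_outliers = q$n_outliers_in_window,
               window_start = q$retained_window$start %||% NA_integer_,
               dropout_rois = paste(q$dropout_rois, collapse = ";"),
               excluded = q$excluded,
               reasons = paste(q$exclusion_reasons, collapse = ";"),
               stringsAsFactors = FALSE)
  }))
  keep <- !qc_df$excluded

  ## ---- preprocessing + FC, with per-subject failure capture ----
  say("Denoising + FC on ", sum(keep), " retained subjects")
  fc_list <- list()
  ceil_rows <- list()
  failed <- character(0)
  for (i in which(keep)) {
    rec <- recordings[[i]]
    is_adult <- rec$group != "infant"
    res <- tryCatch({
      clean <- preprocess_subject(
        rec, qc_reports[[i]], lowpass_hz = config$lowpass_hz,
        highpass_seconds = if (is_adult) config$adult_highpass_seconds,
        compcor_k = config$compcor_k,
        censor_before_filter = config$censor_before_filter)
      list(fc = compute_fc_matrix(clean),
           ceiling = split_half_noise_ceiling(clean))
    }, error = function(e) conditionMessage(e))
    if (is.character(res)) {
      failed[rec$subject_id] <- res
      qc_df$excluded[i] <- TRUE
      qc_df$reasons[i] <- paste0("preprocessing_failed: ", res)
      keep[i] <- FALSE
    } else {
      fc_list[[rec$subject_id]] <- res$fc
      ceil_rows[[rec$subject_id]] <- data.frame(
        subject_id = rec$subject_id, group = rec$group,
        roi = names(res$ceiling), ceiling = unname(res$ceiling),
        stringsAsFactors = FALSE)
    }
  }
  ceiling_df <- do.call(rbind, c(ceil_rows, list(make.row.names = FALSE)))

  ## ---- per-subject connectivity summaries ----
  groups_kept <- vapply(recordings[keep], `[[`, "", "group")
  ids_kept <- vapply(recordings[keep], `[[`, "", "subject_id")
  pfc <- catalog_rois(catalog, pfc_categories())
  sm <- catalog_rois(catalog, sensorimotor_categories())
  seed_sets <- list(secondary_visual =
                      catalog_rois(catalog, secondary_visual_categories()),
                    V1 = catalog_rois(catalog, "V1"))

  block_rows <- list()
  lat_rows <- list()
  for (j in seq_along(ids_kept)) {
    fc <- fc_list[[ids_kept[j]]]
    for (sname in names(seed_sets)) {
      seeds <- seed_sets[[sname]]
      lat <- laterality_fc(fc, seeds, pfc, catalog)
      block_rows[[length(block_rows) + 1L]] <- data.frame(
        subject_id = ids_kept[j], group = groups_kept[j], seed = sname,
        r_pfc = average_block_fc(fc, seeds, pfc,
                                 fisher = config$fisher_block_average),
        r_sensorimotor = average_block_fc(fc, seeds, sm,
                                          fisher = config$fisher_block_average),
        stringsAsFactors = FALSE)
      lat_rows[[length(lat_rows) + 1L]] <- data.frame(
        subject_id = ids_kept[j], group = groups_kept[j], seed = sname,
        within = lat$within, between = lat$between,
        stringsAsFactors = FALSE)
    }
  }
  block_df <- do.call(rbind, block_rows)
  lat_df <- do.call(rbind, lat_rows)

  ## ---- group statistics ----
  say("Group statistics")
  stats_rows <- list()
  add_stat <- function(res, label, family = NA_character_) {
    stats_rows[[length(stats_rows) + 1L]] <<- data.frame(
      test = label, statistic = res$statistic,
      dof1 = res$dof[1], dof2 = if (length(res$dof) > 1) res$dof[2] else NA,
      p_raw = res$p, p_adj = res$p_adjusted,
      effect = res$effect_size, effect_name = res$effect_name,
      family = family, stringsAsFactors = FALSE)
  }
  have <- function(g) sum(groups_kept == g) >= 2
  mat_rows <- list()

  for (sname in names(seed_sets)) {
    bd <- block_df[block_df$seed == sname, ]
    ld <- lat_df[lat_df$seed == sname, ]
    # sighted-vs-blind group x target-category interaction
    if (have("sighted") && have("blind")) {
      ab <- bd[bd$group %in% c("sighted", "blind"), ]
      add_stat(mixed_anova_interaction(ab$r_pfc, ab$r_sensorimotor,
                                       ab$group),
               paste0(sname, ":group_x_target(sighted,blind)"))
      lb <- ld[ld$group %in% c("sighted", "blind"), ]
      add_stat(mixed_anova_interaction(lb$within, lb$between, lb$group),
               paste0(sname, ":group_x_laterality(sighted,blind)"))
    }
    # infant-vs-adult interactions
    for (adult in c("sighted", "blind")) {
      if (have("infant") && have(adult)) {
        ab <- bd[bd$group %in% c("infant", adult), ]
        add_stat(mixed_anova_interaction(ab$r_pfc, ab$r_sensorimotor,
                                         ab$group),
                 paste0(sname, ":group_x_target(infant,", adult, ")"))
        lb <- ld[ld$group %in% c("infant", adult), ]
        add_stat(mixed_anova_interaction(lb$within, lb$between, lb$group),
                 paste0(sname, ":group_x_laterality(infant,", adult, ")"))
      }
    }
    # per-group paired contrasts, Bonferroni over the groups tested
    grps <- intersect(c("sighted", "blind", "infant"), unique(bd$group))
    grps <- grps[vapply(grps, have, TRUE)]
    fam <- lapply(grps, function(g) {
      gd <- bd[bd$group == g, ]
      paired_ttest_cohend(gd$r_pfc, gd$r_sensorimotor)
    })
    p_adj <- bonferroni_adjust(vapply(fam, `[[`, 0, "p"), m = length(fam))
    for (k in seq_along(fam)) {
      res <- fam[[k]]
      res$correction <- "bonferroni"
      res$m_comparisons <- length(fam)
      res$p_adjusted <- p_adj[k]
      add_stat(res, paste0(sname, ":paired_pfc_vs_sm(", grps[k], ")"),
               family = paste0(sname, ":paired_pfc_vs_sm"))
    }
    # group-mean matrix correlations + Pearson-Filon comparison
    if (all(c("sighted", "blind", "infant") %in% groups_kept)) {
      subset_rois <- c(seed_sets[[sname]], pfc, sm)
      gmean <- function(g) {
        ms <- lapply(fc_list[ids_kept[groups_kept == g]], fc_mat)
        Reduce(`+`, ms) / length(ms)
      }
      mi <- gmean("infant"); mb <- gmean("blind"); ms <- gmean("sighted")
      r_ib <- matrix_profile_correlation(mi, mb, subset_rois)
      r_is <- matrix_profile_correlation(mi, ms, subset_rois)
      r_bs <- matrix_profile_correlation(mb, ms, subset_rois)
      n_cells <- length(subset_rois) * (length(subset_rois) - 1) / 2
      pf <- pearson_filon_z(r_ib, r_is, r_bs, n_cells)
      add_stat(pf, paste0(sname, ":pf_z(infant-blind vs infant-sighted)"))
      mat_rows[[length(mat_rows) + 1L]] <- data.frame(
        seed = sname, r_infant_blind = r_ib, r_infant_sighted = r_is,
        r_blind_sighted = r_bs, n_cells = n_cells,
        pf_z = pf$statistic, pf_p = pf$p, stringsAsFactors = FALSE)
    }
  }
  # noise-ceiling comparability across groups
  grp_ceil <- stats::aggregate(ceiling ~ subject_id + group, ceiling_df,
                               mean)
  grps <- intersect(c("sighted", "blind", "infant"), unique(grp_ceil$group))
  if (length(grps) >= 2 &&
      all(vapply(grps, function(g) sum(grp_ceil$group == g) >= 2, TRUE))) {
    add_stat(oneway_anova_eta(split(grp_ceil$ceiling, grp_ceil$group)),
             "noise_ceiling:oneway_anova(groups)")
  }

  out <- list(
    qc = qc_df, qc_reports = qc_reports, fc = fc_list,
    noise_ceiling = ceiling_df, block_fc = block_df, laterality = lat_df,
    matrix_correlation = do.call(rbind, mat_rows),
    stats = do.call(rbind, stats_rows),
    included = ids_kept, excluded = qc_df$subject_id[qc_df$excluded],
    failed = failed
  )
  stopifnot(length(out$included) + length(out$excluded) == n_loaded)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    wr <- function(df, name) {
      if (!is.null(df)) {
        utils::write.csv(df, file.path(out_dir, name), row.names = FALSE)
      }
    }
    wr(out$qc, "qc_report.csv")
    wr(out$block_fc, "block_fc.csv")
    wr(out$laterality, "laterality.csv")
    wr(out$noise_ceiling, "noise_ceiling.csv")
    wr(out$matrix_correlation, "matrix_correlation.csv")
    wr(out$stats, "stats.csv")
  }
  out
}
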