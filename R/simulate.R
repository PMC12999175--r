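#' Artifact and acquisition specifications
#'
#' `artifact_spec()` describes the artifacts planted in one simulated
#' recording: motion spikes (common-mode amplitude jumps that inflate
#' DVARS), linear drift, shared physiological nuisance injected into both
#' the ROI series and the CSF/WM channels, parcel-level signal dropout,
#' and summary head-motion values. `acquisition_spec()` describes the
#' sampling grid. Defaults mirror the emulated acquisitions: 2300 frames
#' at TR = 0.392 s for infant-like runs; adult-like runs default to 355
#' frames at TR = 2 s (the average total scan time of the emulated adult
#' sessions).
#'
#' @param n_motion_spikes number of spike frames (>= 0).
#' @param spike_amplitude spike height as a multiple of the baseline
#'   frame-to-frame RMS of the clean series (default 6).
#' @param drift_slope added linear trend, signal units per frame.
#' @param nuisance_weight fraction of ROI variance contributed by the
#'   shared nuisance sources, in `[0, 1)`.
#' @param dropout_rois ROI names whose parcels are forced to low mean
#'   intensity.
#' @param seed integer RNG seed; generation is deterministic given it.
#' @param ar_phi optional AR(1) coefficient for the latent signal
#'   (default 0: temporally white). Exposed for robustness checks only;
#'   no fidelity to real infant BOLD autocorrelation is claimed.
#' @param motion_mm,motion_deg maximum translation (mm) / rotation (deg)
#'   recorded in the subject's metadata.
#' @return a list of class `artifact_spec` / `acquisition_spec`.
#' @export
artifact_spec <- function(n_motion_spikes = 0L, spike_amplitude = 6,
                          drift_slope = 0, nuisance_weight = 0,
                          dropout_rois = character(), seed = 1L,
                          ar_phi = 0, motion_mm = 0.5, motion_deg = 0.5) {
  check_scalar(n_motion_spikes, "n_motion_spikes", lower = 0)
  check_scalar(spike_amplitude, "spike_amplitude", lower = 0)
  check_scalar(nuisance_weight, "nuisance_weight", lower = 0, upper = 1,
               strict_upper = TRUE)
  check_scalar(ar_phi, "ar_phi", lower = -1, upper = 1,
               strict_lower = TRUE, strict_upper = TRUE)
  structure(list(n_motion_spikes = as.integer(n_motion_spikes),
                 spike_amplitude = spike_amplitude,
                 drift_slope = drift_slope,
                 nuisance_weight = nuisance_weight,
                 dropout_rois = as.character(dropout_rois),
                 seed = as.integer(seed), ar_phi = ar_phi,
                 motion_mm = motion_mm, motion_deg = motion_deg),
            class = "artifact_spec")
}

#' @rdname artifact_spec
#' @param n_frames frame count T (>= 4).
#' @param tr_seconds repetition time in seconds (> 0).
#' @param cohort group label: `"sighted"`, `"blind"`, or `"infant"`.
#' @param n_parcels number of cortical parcels used for dropout QC
#'   (default 100).
#' @export
acquisition_spec <- function(n_frames = 2300L, tr_seconds = 0.392,
                             cohort = c("infant", "sighted", "blind"),
                             n_parcels = 100L) {
  cohort <- match.arg(cohort)
  check_scalar(n_frames, "n_frames", lower = 4)
  check_scalar(tr_seconds, "tr_seconds", lower = 0, strict_lower = TRUE)
  check_scalar(n_parcels, "n_parcels", lower = 2)
  structure(list(n_frames = as.integer(n_frames), tr_seconds = tr_seconds,
                 cohort = cohort, n_parcels = as.integer(n_parcels)),
            class = "acquisition_spec")
}

#' @rdname artifact_spec
#' @export
default_acquisition <- function(cohort) {
  switch(cohort,
    infant = acquisition_spec(2300L, 0.392, "infant"),
    sighted = acquisition_spec(355L, 2, "sighted"),
    blind = acquisition_spec(355L, 2, "blind"),
    stop("unknown cohort: ", cohort)
  )
}

# parcel intensity model: common level with tight spread so the -3 SD
# dropout rule cannot fire by chance, and a deep planted shift so it
# always fires on planted parcels
PARCEL_MEAN <- 1000
PARCEL_SD <- 20
PARCEL_CLAMP <- 2     # truncation of chance variation, in SD units
PARCEL_DROP <- 8      # planted dropout depth, in SD units

#' Simulate one subject's recording
#'
#' Draws a frames x ROIs series as correlated Gaussian noise with
#' population correlation equal to the template matrix, then layers the
#' requested artifacts: linear drift, shared nuisance sources (also
#' injected into the CSF- and WM-like channels), and motion spikes
#' (common-mode jumps added to every channel at the spiked frames, so
#' DVARS responds by construction). Parcel mean intensities are drawn
#' near a common level; parcels of `dropout_rois` are shifted far below.
#' Deterministic given `artifact$seed`.
#'
#' @param template a `correlation_template` from
#'   [make_correlation_template()].
#' @param acquisition an [acquisition_spec()].
#' @param artifact an [artifact_spec()].
#' @param subject_id identifier stored in the recording.
#' @return a `subject_recording`: list with `subject_id`, `group`,
#'   `roi_series` (T x R), `parcel_means`, `csf_series`, `wm_series`,
#'   `motion_mm`, `motion_deg`, `tr_seconds`, and ground truth
#'   `spike_frames`, `dropout_rois`.
#' @examples
#' tpl <- make_correlation_template("sighted_like")
#' rec <- simulate_subject(tpl, acquisition_spec(200, 2, "sighted"),
#'                         artifact_spec(seed = 7))
#' dim(rec$roi_series)
#' @export
simulate_subject <- function(template, acquisition, artifact,
                             subject_id = "sub-01") {
  stopifnot(inherits(template, "correlation_template"),
            inherits(acquisition, "acquisition_spec"),
            inherits(artifact, "artifact_spec"))
  tfr <- acquisition$n_frames
  rois <- template$roi_names
  r <- length(rois)
  if (r > acquisition$n_parcels) {
    stop("n_parcels must be at least the number of ROIs")
  }
  bad <- setdiff(artifact$dropout_rois, rois)
  if (length(bad)) {
    stop("dropout_rois not in template: ", paste(bad, collapse = ", "))
  }

  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  })
  set.seed(artifact$seed)

  # correlated Gaussian signal; optional AR(1) on the latent innovations
  z <- matrix(stats::rnorm(tfr * r), tfr, r)
  if (artifact$ar_phi != 0) {
    z <- apply(z, 2, function(col) {
      as.numeric(stats::filter(col, artifact$ar_phi, method = "recursive"))
    }) * sqrt(1 - artifact$ar_phi^2)
  }
  cf <- chol(template$matrix + diag(1e-10, r))
  signal <- z %*% cf

  w <- artifact$nuisance_weight
  n_sources <- 2L
  sources <- matrix(stats::rnorm(tfr * n_sources), tfr, n_sources)
  roi <- sqrt(1 - w) * signal
  if (w > 0) {
    mix <- matrix(stats::rnorm(n_sources * r), n_sources, r)
    mix <- sweep(mix, 2, sqrt(colSums(mix^2)), "/")
    roi <- roi + sqrt(w) * (sources %*% mix)
  }
  # CSF/WM channels: nuisance sources plus channel noise
  make_compartment <- function(n_chan) {
    load <- matrix(stats::rnorm(n_sources * n_chan), n_sources, n_chan)
    sources %*% load + 0.2 * matrix(stats::rnorm(tfr * n_chan), tfr, n_chan)
  }
  csf <- make_compartment(3L)
  colnames(csf) <- paste0("CSF", 1:3)
  wm <- make_compartment(3L)
  colnames(wm) <- paste0("WM", 1:3)

  drift <- artifact$drift_slope * seq_len(tfr)
  roi <- roi + drift

  spike_frames <- integer(0)
  if (artifact$n_motion_spikes > 0) {
    if (artifact$n_motion_spikes > tfr - 1L) {
      stop("more spikes requested than available frames")
    }
    spike_frames <- sort(sample(2:tfr, artifact$n_motion_spikes))
    baseline_rms <- sqrt(mean(diff(roi)^2))
    jump <- artifact$spike_amplitude * baseline_rms
    roi[spike_frames, ] <- roi[spike_frames, ] + jump
    csf[spike_frames, ] <- csf[spike_frames, ] + jump
    wm[spike_frames, ] <- wm[spike_frames, ] + jump
  }

  raw <- stats::rnorm(acquisition$n_parcels)
  parcel <- PARCEL_MEAN + PARCEL_SD * pmin(pmax(raw, -PARCEL_CLAMP),
                                           PARCEL_CLAMP)
  names(parcel) <- c(rois, if (acquisition$n_parcels > r)
    paste0("parcel_", seq_len(acquisition$n_parcels - r) + r))
  parcel[artifact$dropout_rois] <- PARCEL_MEAN - PARCEL_DROP * PARCEL_SD

  colnames(roi) <- rois
  structure(
    list(subject_id = subject_id, group = acquisition$cohort,
         roi_series = roi, parcel_means = parcel,
         csf_series = csf, wm_series = wm,
         motion_mm = artifact$motion_mm, motion_deg = artifact$motion_deg,
         tr_seconds = acquisition$tr_seconds,
         spike_frames = spike_frames,
         dropout_rois = artifact$dropout_rois,
         seed = artifact$seed),
    class = "subject_recording"
  )
}

#' @export
print.subject_recording <- function(x, ...) {
  cat("<subject_recording>", x$subject_id, "(", x$group, ")",
      nrow(x$roi_series), "frames x", ncol(x$roi_series),
      "ROIs, TR", x$tr_seconds, "s\n")
  invisible(x)
}

#' Cohort configuration and simulation
#'
#' `cohort_config()` collects everything needed to simulate the three
#' groups; `simulate_cohort()` executes it and returns the recordings
#' together with a ground-truth ledger of planted facts (spike counts,
#' dropout, motion, intended exclusion verdicts) for recovery tests.
#' Per-subject seeds are derived deterministically from `master_seed`, so
#' two cohorts built from the same configuration are identical.
#'
#' Planted exclusions: `n_high_motion` subjects per group receive a spike
#' fraction of `high_motion_spike_fraction` (default 12% of frames, well
#' above the 10% exclusion rule but low enough that the DVARS threshold
#' stays calibrated on clean frames); `n_dropout` subjects receive a
#' planted dropout ROI; `n_excess_motion` adult subjects receive
#' `motion_mm = 2.5`. All other subjects carry a light artifact load far
#' below every threshold.
#'
#' @param n_sighted,n_blind,n_infant group sizes (defaults 50 / 30 / 475,
#'   the emulated study cohorts).
#' @param effect_size,baseline,laterality passed to
#'   [make_correlation_template()]; `laterality = NULL` keeps the
#'   per-profile defaults.
#' @param catalog an [roi_catalog()].
#' @param n_frames named vector of frame counts per group; `NULL` uses
#'   the acquisition defaults (355 / 355 / 2300).
#' @param nuisance_weight,drift_slope,spike_fraction,spike_amplitude
#'   artifact load applied to every subject (spike count =
#'   `round(spike_fraction * n_frames)`).
#' @param n_high_motion,n_dropout,n_excess_motion named vectors of
#'   planted-exclusion counts per group (default none).
#' @param high_motion_spike_fraction spike fraction given to planted
#'   high-motion subjects (default 0.12).
#' @param master_seed integer master seed.
#' @return `cohort_config()`: a list of class `cohort_config`;
#'   `simulate_cohort()`: list with `recordings`, `ledger` (data.frame),
#'   `templates`, `config`.
#' @examples
#' cfg <- cohort_config(n_sighted = 3, n_blind = 3, n_infant = 4,
#'                      n_frames = c(sighted = 120, blind = 120, infant = 150))
#' coh <- simulate_cohort(cfg)
#' nrow(coh$ledger)
#' @export
cohort_config <- function(n_sighted = 50L, n_blind = 30L, n_infant = 475L,
                          effect_size = 0.15, baseline = 0.2,
                          laterality = NULL,
                          catalog = default_roi_catalog(),
                          n_frames = NULL,
                          nuisance_weight = 0.3, drift_slope = 0.001,
                          spike_fraction = 0.005, spike_amplitude = 6,
                          n_high_motion = c(sighted = 0, blind = 0, infant = 0),
                          n_dropout = c(sighted = 0, blind = 0, infant = 0),
                          n_excess_motion = c(sighted = 0, blind = 0, infant = 0),
                          high_motion_spike_fraction = 0.12,
                          master_seed = 1L) {
  ns <- c(sighted = n_sighted, blind = n_blind, infant = n_infant)
  if (any(ns <= 0)) stop("all group sizes must be positive")
  fill <- function(x) {
    out <- c(sighted = 0, blind = 0, infant = 0)
    out[names(x)] <- x
    out
  }
  structure(list(
    n = ns, effect_size = effect_size, baseline = baseline,
    laterality = laterality, catalog = catalog, n_frames = n_frames,
    nuisance_weight = nuisance_weight, drift_slope = drift_slope,
    spike_fraction = spike_fraction, spike_amplitude = spike_amplitude,
    n_high_motion = fill(n_high_motion), n_dropout = fill(n_dropout),
    n_excess_motion = fill(n_excess_motion),
    high_motion_spike_fraction = high_motion_spike_fraction,
    master_seed = as.integer(master_seed)
  ), class = "cohort_config")
}

#' @rdname cohort_config
#' @param config a `cohort_config`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  profiles <- c(sighted = "sighted_like", blind = "blind_like",
                infant = "infant_like")
  templates <- lapply(profiles, function(p) {
    make_correlation_template(p, config$catalog,
                              effect_size = config$effect_size,
                              baseline = config$baseline,
                              laterality = config$laterality)
  })

  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  })
  set.seed(config$master_seed)
  total <- sum(config$n)
  subject_seeds <- sample.int(.Machine$integer.max - 1L, total)

  recordings <- vector("list", total)
  rows <- vector("list", total)
  idx <- 0L
  for (grp in names(config$n)) {
    acq <- default_acquisition(grp)
    if (!is.null(config$n_frames) && grp %in% names(config$n_frames)) {
      acq$n_frames <- as.integer(config$n_frames[[grp]])
    }
    n_g <- config$n[[grp]]
    # planted-exclusion assignment: first n_high_motion subjects, then
    # n_dropout, then n_excess_motion (adults) -- disjoint by position
    kind <- rep("clean", n_g)
    pos <- 1L
    for (what in c("n_high_motion", "n_dropout", "n_excess_motion")) {
      k <- config[[what]][[grp]]
      if (k > 0) {
        if (pos + k - 1L > n_g) stop("more planted exclusions than subjects")
        kind[pos:(pos + k - 1L)] <- sub("^n_", "", what)
        pos <- pos + k
      }
    }
    first_seed_roi <- config$catalog$name[config$catalog$role == "seed"][1]
    for (i in seq_len(n_g)) {
      idx <- idx + 1L
      sid <- sprintf("%s-%03d", grp, i)
      frac <- if (kind[i] == "high_motion")
        config$high_motion_spike_fraction else config$spike_fraction
      dropout <- if (kind[i] == "dropout") first_seed_roi else character()
      motion <- if (kind[i] == "excess_motion") 2.5 else 0.5
      art <- artifact_spec(
        n_motion_spikes = round(frac * acq$n_frames),
        spike_amplitude = config$spike_amplitude,
        drift_slope = config$drift_slope,
        nuisance_weight = config$nuisance_weight,
        dropout_rois = dropout,
        seed = subject_seeds[idx],
        motion_mm = motion, motion_deg = 0.5
      )
      rec <- simulate_subject(templates[[grp]], acq, art, subject_id = sid)
      recordings[[idx]] <- rec
      reason <- c(
        if (grp == "infant" && frac > 0.10) "motion",
        if (length(dropout)) "dropout",
        if (grp != "infant" && motion > 2) "motion"
      )
      rows[[idx]] <- data.frame(
        subject_id = sid, group = grp, seed = subject_seeds[idx],
        n_frames = acq$n_frames, n_spikes = length(rec$spike_frames),
        spike_fraction = frac,
        dropout_rois = paste(dropout, collapse = ";"),
        motion_mm = motion, motion_deg = 0.5,
        intended_exclusion = length(reason) > 0,
        exclusion_reason = paste(reason, collapse = ";"),
        stringsAsFactors = FALSE
      )
    }
  }
  ledger <- do.call(rbind, rows)
  list(recordings = recordings, ledger = ledger, templates = templates,
       config = config)
}
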