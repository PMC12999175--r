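# shared fixtures: everything is generated in code at test time

# a fast recording: small T, no artifacts unless asked
quick_recording <- function(seed = 1, n_frames = 200, profile = "sighted_like",
                            ...) {
  tpl <- make_correlation_template(profile)
  cohort <- switch(profile, sighted_like = "sighted", blind_like = "blind",
                   infant_like = "infant")
  simulate_subject(tpl,
                   acquisition_spec(n_frames, 2, cohort),
                   artifact_spec(seed = seed, ...),
                   subject_id = sprintf("fix-%03d", seed))
}

# small fast cohort for pipeline-level tests
quick_cohort <- function(master_seed = 1, n = c(4, 4, 5), n_frames = 200,
                         ...) {
  cohort_config(n_sighted = n[1], n_blind = n[2], n_infant = n[3],
                n_frames = c(sighted = n_frames, blind = n_frames,
                             infant = n_frames),
                master_seed = master_seed, ...)
}

# independent textbook Pearson correlation (covariance normalization)
oracle_cor <- function(x, y) {
  xm <- x - mean(x); ym <- y - mean(y)
  sum(xm * ym) / sqrt(sum(xm^2) * sum(ym^2))
}

# independent quantile by linear interpolation between order statistics
oracle_quantile <- function(x, p) {
  s <- sort(x)
  h <- (length(s) - 1) * p + 1
  lo <- floor(h); hi <- ceiling(h)
  s[lo] + (h - lo) * (s[hi] - s[lo])
}
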