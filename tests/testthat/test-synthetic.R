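test_that("templates plant the advertised block structure", {
  cat18 <- default_roi_catalog()
  pfc <- cat18$name[cat18$category %in% pfc_categories()]
  sm <- cat18$name[cat18$category %in% sensorimotor_categories()]
  sv <- cat18$name[cat18$category %in% secondary_visual_categories()]
  v1 <- cat18$name[cat18$category == "V1"]
  block_diff <- function(m, seeds) {
    mean(m[seeds, pfc]) - mean(m[seeds, sm])
  }
  # planted differences live in the raw matrix, before PSD repair
  for (es in c(0, 0.1, 0.15, 0.3)) {
    blind <- make_correlation_template("blind_like", effect_size = es)
    sighted <- make_correlation_template("sighted_like", effect_size = es)
    infant <- make_correlation_template("infant_like", effect_size = es)
    expect_equal(block_diff(blind$raw_matrix, sv), es)
    expect_equal(block_diff(blind$raw_matrix, v1), es)
    expect_equal(block_diff(sighted$raw_matrix, sv), -es)
    expect_equal(block_diff(infant$raw_matrix, sv), es)
    expect_equal(block_diff(infant$raw_matrix, v1), 0)
  }
  # laterality: within-hemisphere seed-PFC exceeds between-hemisphere
  tpl <- make_correlation_template("blind_like")
  hemi <- setNames(cat18$hemisphere, cat18$name)
  same <- outer(hemi[sv], hemi[pfc], "==")
  blk <- tpl$raw_matrix[sv, pfc]
  expect_equal(mean(blk[same]) - mean(blk[!same]), tpl$laterality)
  s_tpl <- make_correlation_template("sighted_like")
  i_tpl <- make_correlation_template("infant_like")
  expect_lt(s_tpl$laterality, tpl$laterality)
  expect_identical(i_tpl$laterality, s_tpl$laterality)
})

test_that("template matrices are valid correlation matrices", {
  for (p in c("sighted_like", "blind_like", "infant_like")) {
    tpl <- make_correlation_template(p)
    m <- tpl$matrix
    expect_true(isSymmetric(m))
    expect_equal(unname(diag(m)), rep(1, nrow(m)))
    off <- m[row(m) != col(m)]
    expect_true(all(off > -1 & off < 1))
    ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
    expect_gt(min(ev), -1e-8)
  }
  expect_error(make_correlation_template("blind_like", effect_size = 2),
               "outside")
  expect_error(make_correlation_template("blind_like", effect_size = -1))
})

test_that("custom templates validate and repair their input", {
  m <- matrix(c(1, 0.9, -0.9,
                0.9, 1, 0.9,
                -0.9, 0.9, 1), 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tpl <- custom_correlation_template(m)   # indefinite: gets repaired
  expect_identical(tpl$profile_name, "custom")
  expect_gt(attr(tpl$matrix, "distance"), 0)
  ev <- eigen(tpl$matrix, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), -1e-8)
  ok <- diag(3); dimnames(ok) <- dimnames(m)
  expect_equal(attr(custom_correlation_template(ok)$matrix, "distance"), 0)
  expect_error(custom_correlation_template(matrix(1, 2, 2)), "dimnames")
  bad <- ok; bad[1, 2] <- bad[2, 1] <- 1
  expect_error(custom_correlation_template(bad), "inside")
})

test_that("PSD repair agrees with an independent oracle", {
  skip_if_not_installed("Matrix")
  # already-PSD input: repair is the identity
  tpl <- make_correlation_template("sighted_like", effect_size = 0.05)
  if (attr(tpl$matrix, "distance") == 0) {
    expect_equal(unclass(tpl$matrix), tpl$raw_matrix,
                 ignore_attr = TRUE, tolerance = 1e-12)
  }
  set.seed(11)
  for (i in 1:20) {
    n <- sample(4:8, 1)
    m <- matrix(runif(n * n, -0.9, 0.9), n)
    m <- (m + t(m)) / 2
    diag(m) <- 1
    ours <- nearest_correlation(m, tol = 1e-12)
    ref <- as.matrix(Matrix::nearPD(m, corr = TRUE, conv.tol = 1e-12,
                                    maxit = 500)$mat)
    expect_equal(unclass(ours), ref, ignore_attr = TRUE, tolerance = 1e-5)
    # invariants: unit diagonal exact, entry moves bounded by distance
    expect_equal(unname(diag(ours)), rep(1, n))
    expect_lte(max(abs(ours - m)), attr(ours, "distance") + 1e-12)
  }
})

test_that("simulated subjects honour the artifact spec and determinism", {
  rec1 <- quick_recording(seed = 5, n_motion_spikes = 3, drift_slope = 0.01,
                          nuisance_weight = 0.4,
                          dropout_rois = "V1_L")
  rec2 <- quick_recording(seed = 5, n_motion_spikes = 3, drift_slope = 0.01,
                          nuisance_weight = 0.4,
                          dropout_rois = "V1_L")
  expect_identical(rec1, rec2)             # bit-identical given the seed
  expect_length(rec1$spike_frames, 3)
  expect_false(anyNA(rec1$roi_series))
  expect_identical(colnames(rec1$roi_series),
                   default_roi_catalog()$name)
  expect_identical(nrow(rec1$roi_series), nrow(rec1$csf_series))
  # drift is present: regressing on time gives a positive slope everywhere
  slopes <- apply(rec1$roi_series, 2, function(y) {
    coef(lm.fit(cbind(1, seq_along(y)), y))[2]
  })
  expect_true(all(slopes > 0))
  # dropout parcel is far below the others
  expect_lt(rec1$parcel_means[["V1_L"]],
            mean(rec1$parcel_means) - 5 * sd(rec1$parcel_means))
  rec3 <- quick_recording(seed = 6)
  expect_false(identical(rec1$roi_series, rec3$roi_series))
  expect_error(simulate_subject(make_correlation_template("blind_like"),
                                acquisition_spec(50, 2, "blind"),
                                artifact_spec(dropout_rois = "nope")),
               "dropout_rois")
})

test_that("long artifact-free simulation converges to the template", {
  tpl <- make_correlation_template("blind_like")
  rec <- simulate_subject(tpl, acquisition_spec(20000, 2, "blind"),
                          artifact_spec(seed = 99))
  fc <- cor(rec$roi_series)
  expect_lt(max(abs(fc - tpl$matrix)), 0.05)
})

test_that("cohorts are deterministic and ledgers record planted facts", {
  cfg <- quick_cohort(master_seed = 7, n_frames = 60,
                      n_high_motion = c(infant = 2),
                      n_dropout = c(infant = 1),
                      n_excess_motion = c(sighted = 1))
  coh1 <- simulate_cohort(cfg)
  coh2 <- simulate_cohort(cfg)
  expect_identical(coh1$ledger, coh2$ledger)
  expect_identical(coh1$recordings[[3]]$roi_series,
                   coh2$recordings[[3]]$roi_series)
  expect_equal(nrow(coh1$ledger), 13)
  expect_equal(sum(coh1$ledger$intended_exclusion), 4)
  expect_setequal(
    coh1$ledger$exclusion_reason[coh1$ledger$intended_exclusion],
    c("motion", "motion", "dropout", "motion"))
  expect_error(cohort_config(n_sighted = 0), "positive")
})

test_that("AR(1) flag preserves the cross-ROI correlation target", {
  tpl <- make_correlation_template("sighted_like")
  rec <- simulate_subject(tpl, acquisition_spec(8000, 2, "sighted"),
                          artifact_spec(seed = 3, ar_phi = 0.4))
  fc <- cor(rec$roi_series)
  expect_lt(max(abs(fc - tpl$matrix)), 0.1)
  # lag-1 autocorrelation is present
  ac <- mean(apply(rec$roi_series, 2,
                   function(y) cor(y[-1], y[-length(y)])))
  expect_gt(ac, 0.25)
})
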