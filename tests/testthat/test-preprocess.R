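test_that("linear detrending removes trends and is orthogonal to them", {
  t <- 1:60
  expect_equal(max(abs(detrend_linear(cbind(3 + 2 * t)))), 0,
               tolerance = 1e-10)
  set.seed(5)
  x <- matrix(rnorm(300), 60, 5) + outer(t, runif(5), "*")
  r <- detrend_linear(x)
  expect_lt(max(abs(colMeans(r))), 1e-10)
  expect_lt(max(abs(crossprod(r, t))), 1e-7)   # orthogonality oracle
  expect_error(detrend_linear(matrix(1:4, 2, 2)), "3 frames")
})

test_that("temporal filter attenuates the stopband and passes the passband", {
  t <- (0:999) * 2                       # TR = 2 s
  tone <- function(f) sin(2 * pi * f * t)
  amp <- function(x) sqrt(mean(x[200:800]^2))  # steady-state section
  hi <- temporal_filter(cbind(tone(0.15)), tr = 2)
  expect_lt(amp(hi) / amp(tone(0.15)), 0.1)
  lo <- temporal_filter(cbind(tone(0.01)), tr = 2)
  expect_gt(amp(lo) / amp(tone(0.01)), 0.9)
  # adult band-pass: the 150 s high-pass kills very slow drift
  slow <- temporal_filter(cbind(tone(1 / 600)), tr = 2,
                          highpass_seconds = 150)
  expect_lt(amp(slow) / amp(tone(1 / 600)), 0.1)
  mid <- temporal_filter(cbind(tone(0.03)), tr = 2, highpass_seconds = 150)
  expect_gt(amp(mid) / amp(tone(0.03)), 0.9)
  # linearity: zero in, zero out
  expect_equal(temporal_filter(matrix(0, 100, 2), tr = 2),
               matrix(0, 100, 2))
  expect_error(temporal_filter(matrix(rnorm(100)), tr = 2, lowpass_hz = 0.3),
               "Nyquist")
  expect_error(temporal_filter(matrix(rnorm(100)), tr = 2,
                               highpass_seconds = 2), "Nyquist|below")
})

test_that("zero-phase filtering leaves no phase lag", {
  t <- (0:1999) * 0.5
  x <- sin(2 * pi * 0.02 * t)
  y <- temporal_filter(cbind(x), tr = 0.5)[, 1]
  mid <- 500:1500
  expect_gt(cor(x[mid], y[mid]), 0.999)  # in phase, not shifted
})

test_that("CompCor components behave like principal components", {
  set.seed(8)
  s <- rnorm(150)
  # rank-one case: every channel is a scaled copy of one source
  csf <- s %o% c(1, 2, 3)
  wm <- s %o% c(-1, 0.5, 2)
  comp <- extract_compcor_components(csf, wm, k = 1)
  expect_equal(abs(cor(comp[, 1], s)), 1)
  # orthogonality + ordered explained variance on random inputs
  csf <- matrix(rnorm(150 * 3), 150)
  wm <- matrix(rnorm(150 * 3), 150)
  comp <- extract_compcor_components(csf, wm, k = 5)
  g <- crossprod(comp)
  expect_lt(max(abs(g[row(g) != col(g)])), 1e-8)
  ev <- attr(comp, "explained_variance")
  expect_true(all(diff(ev) <= 1e-12))
  # eigendecomposition oracle: eigenvalues of the standardized covariance
  x <- scale(cbind(csf, wm))
  expect_equal(ev, eigen(cov(x), symmetric = TRUE)$values,
               tolerance = 1e-8)
  # zero-variance channel dropped with a warning
  expect_warning(extract_compcor_components(cbind(csf, 0), wm, k = 2),
                 "zero-variance")
  expect_error(extract_compcor_components(csf[1:3, ], wm[1:3, ], k = 5),
               "exceeds")
})

test_that("nuisance regression residuals are orthogonal to the design", {
  set.seed(9)
  reg <- matrix(rnorm(200), 100, 2)
  y <- cbind(2 * reg[, 1])               # exact fit
  expect_lt(max(abs(regress_nuisance(y, reg))), 1e-8)
  y <- matrix(rnorm(300), 100, 3)
  r <- regress_nuisance(y, reg)
  expect_lt(max(abs(crossprod(r, reg))), 1e-8)   # normal equations
  expect_lt(max(abs(colSums(r))), 1e-8)          # intercept included
  # zero regressors: just demeaning
  expect_equal(regress_nuisance(y, matrix(0, 100, 2)),
               scale(y, scale = FALSE), ignore_attr = TRUE)
  expect_error(regress_nuisance(y, cbind(reg, reg[, 1])), "rank deficient")
})

test_that("censoring deletes flagged frames and nothing else", {
  set.seed(10)
  x <- matrix(rnorm(500), 100, 5)
  expect_identical(censor_frames(x, rep(FALSE, 100)), x)
  mask <- seq_len(100) %in% sample(100, 7)
  out <- censor_frames(x, mask)
  expect_equal(nrow(out), 93)
  expect_identical(out, x[!mask, ])      # slicing oracle
  expect_equal(cor(out), cor(x[!mask, ]))
  expect_error(censor_frames(x, rep(TRUE, 100)), "retained")
  expect_error(censor_frames(x, mask[1:50]), "match")
})

test_that("the denoising chain records provenance and reduces nuisance", {
  rec <- quick_recording(seed = 12, n_frames = 600, nuisance_weight = 0.5,
                         drift_slope = 0.02, n_motion_spikes = 4)
  qc <- apply_exclusion_rules(rec)
  clean <- preprocess_subject(rec, qc, highpass_seconds = 150)
  expect_s3_class(clean, "clean_series")
  expect_equal(clean$n_frames_used, nrow(clean$matrix))
  expect_match(clean$provenance[1], "detrend")
  expect_match(paste(clean$provenance, collapse = " "), "compcor")
  expect_true(grep("censor", clean$provenance) >
                grep("butterworth", clean$provenance))
  # alternate order is visible in provenance, never silent
  clean2 <- preprocess_subject(rec, qc, highpass_seconds = 150,
                               censor_before_filter = TRUE)
  expect_true(grep("censor", clean2$provenance) <
                grep("butterworth", clean2$provenance))
  expect_false(identical(clean$provenance, clean2$provenance))
  # deterministic rerun
  expect_identical(clean$matrix,
                   preprocess_subject(rec, qc,
                                      highpass_seconds = 150)$matrix)
})

test_that("CompCor regression removes the planted shared nuisance", {
  # nuisance_weight 0.5: after regression, ROI residuals should share
  # almost no variance with the planted sources
  tpl <- make_correlation_template("infant_like")
  rec <- simulate_subject(tpl, acquisition_spec(2300, 0.392, "infant"),
                          artifact_spec(seed = 21, nuisance_weight = 0.5))
  # reconstruct the planted sources from the (noiseless-enough) channels
  comp <- extract_compcor_components(rec$csf_series, rec$wm_series, k = 5)
  resid <- regress_nuisance(detrend_linear(rec$roi_series), comp)
  src_proxy <- extract_compcor_components(rec$csf_series, rec$wm_series,
                                          k = 2)
  shared <- abs(cor(resid, src_proxy))
  expect_lt(mean(shared), 0.05)
  # before regression the shared variance is large
  before <- abs(cor(rec$roi_series, src_proxy))
  expect_gt(mean(before), 0.3)
})
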