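# Preprocessing stages: trimming, OD conversion, wavelet motion correction,
# PCA global-noise removal, band-pass, Beer-Lambert inversion, and the
# end-to-end recovery/robustness properties on synthetic data.

test_that("edge trimming removes exactly the stated samples", {
  x <- matrix(rnorm(2 * 12000), 2)
  y <- trim_edges(x, 15, 25)
  expect_equal(ncol(y), 12000 - 750)
  expect_equal(y, x[, 376:11625])
  expect_equal(trim_edges(x, 0, 25), x)
  expect_error(trim_edges(matrix(0, 2, 700), 15, 25), "too short")
})

test_that("optical density conversion follows -log(I/mean(I))", {
  mk_raw <- function(i1) {
    intensity <- array(0, dim = c(2, 1, length(i1)))
    intensity[1, 1, ] <- i1
    intensity[2, 1, ] <- i1
    structure(list(intensity = intensity, wavelengths_nm = c(690, 830),
                   sampling_rate_hz = 25, subject_id = "t", group = "control",
                   covariates = list()), class = "fnirs_raw")
  }
  od <- intensity_to_od(mk_raw(rep(2, 100)))
  expect_true(all(od$od == 0))
  # one sample at mean(I) * e^-1  ->  OD = 1 there
  i_dip <- 99 * exp(-1) / (100 - exp(-1))   # solves I = mean(I) * e^-1
  od <- intensity_to_od(mk_raw(c(rep(1, 99), i_dip)))
  expect_equal(od$od[1, 1, 100], 1, tolerance = 1e-12)
  # one sample at half the mean  ->  OD = ln 2
  od <- intensity_to_od(mk_raw(c(rep(1, 99), 99 / 199)))
  expect_equal(od$od[1, 1, 100], log(2), tolerance = 1e-12)
  bad <- mk_raw(c(rep(1, 99), -1))
  expect_error(intensity_to_od(bad), "channel")
})

test_that("wavelet correction passes clean signal and removes spikes", {
  N <- 4096
  x <- matrix(sin(2 * pi * (8 / N) * (0:(N - 1))), 1)   # ~0.049 Hz at 25 Hz
  y <- wavelet_motion_correct(x)
  expect_lt(max(abs(y - x)), 1e-6 * max(abs(x)))
  # single 10-SD spike: amplitude reduced >= 80%, sinusoid RMS kept within 5%
  spike <- numeric(N)
  spike[2000] <- 10 * sd(x)
  y2 <- wavelet_motion_correct(x + rbind(spike))
  expect_lt(abs(y2[2000] - x[1, 2000]) / spike[2000], 0.2)
  keep <- setdiff(seq_len(N), 1990:2010)
  expect_lt(abs(sd(y2[1, keep]) / sd(x[1, keep]) - 1), 0.05)
  expect_true(all(wavelet_motion_correct(matrix(0, 3, 512)) == 0))
})

test_that("wavelet fast path matches the reference R transform", {
  set.seed(21)
  x <- matrix(rnorm(5 * 1024), 5)
  xp <- fnirsnet:::reflect_pad(x, 2^6)
  dec <- fnirsnet:::dwt_periodic(xp, 6)
  # round trip with no thresholding is exact
  expect_lt(max(abs(fnirsnet:::idwt_periodic(dec) - xp)), 1e-10)
  # thresholded reconstruction agrees with the C++ path
  for (j in 1:6) {
    d <- dec$details[[j]]
    if (ncol(d) >= 32) {
      q <- apply(d, 1, quantile, probs = c(0.25, 0.75), names = FALSE)
      fence <- 1.5 * (q[2, ] - q[1, ])
      d[d < q[1, ] - fence | d > q[2, ] + fence] <- 0
    }
    dec$details[[j]] <- d
  }
  ref <- fnirsnet:::idwt_periodic(dec)
  cpp <- fnirsnet:::wavelet_correct_cpp(xp, 6L, 1.5, 32L)
  expect_lt(max(abs(ref - cpp)), 1e-12)
})

test_that("PCA removes global components per the cumulative-variance rule", {
  set.seed(4)
  # rank-1 common signal: the single component holds 100%, so it is removed
  common <- sin(2 * pi * 0.05 * (0:999) / 25)
  x <- outer(runif(8, 0.5, 1.5), common)
  res <- pca_global_denoise(x, 0.8)
  expect_lt(max(abs(res - rowMeans(x))), 1e-8)
  # 27 orthogonal equal-variance channels: k = 21 removed, 6/27 variance left
  N <- 2000
  t <- 0:(N - 1)
  x <- t(sapply(1:27, function(k) sqrt(2) * sin(2 * pi * k * t / N)))
  res <- pca_global_denoise(x, 0.8)
  ratio <- sum(res^2) / sum(x^2)
  expect_equal(ratio, 6 / 27, tolerance = 0.01)
  # disabled stage is the identity
  expect_identical(pca_global_denoise(x, NULL), x)
  expect_identical(pca_global_denoise(x, 0), x)
  expect_error(pca_global_denoise(x, 1.2), "variance_threshold")
  # "reach" mode removes one more component than "under" at a boundary
  k_under <- 21; k_reach <- 22
  res2 <- pca_global_denoise(x, 0.8, mode = "reach")
  expect_equal(sum(res2^2) / sum(x^2), (27 - k_reach) / 27, tolerance = 0.01)
})

test_that("band-pass gains match the design response", {
  fs <- 25
  N <- 60000
  tt <- 0:(N - 1)
  gain_at <- function(f_target) {
    k <- round(f_target * N / fs)
    x <- matrix(sin(2 * pi * k * tt / N), 1)
    y <- bandpass(x, 0.01, 0.08, sampling_rate_hz = fs)
    sd(y) / sd(x)
  }
  expect_gt(gain_at(0.04), 0.9)
  expect_lt(gain_at(0.04), 1.0)
  expect_lt(20 * log10(gain_at(1)), -20)      # cardiac
  expect_lt(20 * log10(gain_at(0.005)), -20)  # slow drift
  # DC offset removed
  y <- bandpass(matrix(5, 1, 2000), 0.01, 0.08, sampling_rate_hz = fs)
  expect_lt(max(abs(y)), 1e-8)
  expect_error(bandpass(matrix(0, 1, 100), 0.08, 0.01, sampling_rate_hz = fs),
               "low_hz")
  expect_error(bandpass(matrix(0, 1, 100), 0.01, 13, sampling_rate_hz = fs),
               "Nyquist")
})

test_that("Beer-Lambert inversion is exact and linear", {
  optics <- optics_defaults()
  m <- fnirsnet:::mbll_matrix(optics)
  set.seed(8)
  conc <- matrix(rnorm(2 * 50), 2)             # mM, arbitrary
  od_flat <- m %*% conc
  od <- array(0, dim = c(2, 1, 50))
  od[1, 1, ] <- od_flat[1, ]
  od[2, 1, ] <- od_flat[2, ]
  hemo <- od_to_hemoglobin(od, optics, sampling_rate_hz = 25)
  expect_equal(hemo$hbo[1, ], conc[1, ] * 1000, tolerance = 1e-10)
  expect_equal(hemo$hbr[1, ], conc[2, ] * 1000, tolerance = 1e-10)
  hemo2 <- od_to_hemoglobin(od * 2, optics, sampling_rate_hz = 25)
  expect_equal(hemo2$hbo, hemo$hbo * 2, tolerance = 1e-10)
  zero <- od_to_hemoglobin(array(0, dim = c(2, 3, 10)), optics,
                           sampling_rate_hz = 25)
  expect_true(all(zero$hbo == 0) && all(zero$hbr == 0))
})

test_that("the pipeline runs in the stated order and logs it", {
  cfg <- noiseless(small_sim_config(seed = 14))
  s <- simulate_cohort(cfg)$subjects[[1]]
  h <- preprocess(s$raw)
  steps <- vapply(h$processing_log, `[[`, character(1), "step")
  expect_equal(steps, c("trim", "optical_density", "wavelet", "pca",
                        "bandpass", "mbll"))
  h2 <- preprocess(s$raw, pca_threshold = NULL)
  expect_true(h2$processing_log[[4]]$skipped)
})

test_that("noiseless end-to-end recovery matches the ground truth", {
  cfg <- noiseless(simulation_config(n_subjects_per_group = 1, seed = 23))
  s <- simulate_cohort(cfg)$subjects[[1]]
  h <- preprocess(s$raw, pca_threshold = NULL)
  expect_lt(corr_rmsd(cor(t(h$hbo)), s$hemo_truth$target_corr), 0.05)
})

test_that("physiological noise barely moves the recovered connectivity", {
  cfg <- simulation_config(n_subjects_per_group = 1, seed = 24)
  s <- simulate_cohort(cfg)$subjects[[1]]
  s0 <- simulate_cohort(noiseless(cfg))$subjects[[1]]
  expect_identical(s$hemo_truth$clean_hbo, s0$hemo_truth$clean_hbo)
  cc0 <- cor(t(preprocess(s0$raw, pca_threshold = NULL)$hbo))
  cc1 <- cor(t(preprocess(s$raw, pca_threshold = NULL)$hbo))
  expect_lt(corr_rmsd(cc1, cc0), 0.1)
})
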