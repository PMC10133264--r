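test_that("detrending removes exactly the affine component", {
  expect_equal(detrend_trial(rep(5, 100)), rep(0, 100))
  expect_equal(detrend_trial(2 + 3 * seq_len(200)), rep(0, 200),
               tolerance = 1e-10)
  # sine + line: residual matches an independent normal-equations solve
  set.seed(21)
  t <- seq_len(500)
  y <- sin(2 * pi * t / 37) + 0.4 + 0.02 * t
  fit <- lm(y ~ t)
  expect_lt(max(abs(detrend_trial(y) - unname(residuals(fit)))), 1e-9)
})

test_that("feature-vector screen flags gross amplitude outliers and stays calibrated", {
  # gross outlier: one trial at x100 amplitude
  tt <- noise_tensor(n_leads = 1, n_trials = 24, n_samples = 1200, seed = 22)
  tt$data[1, 7, ] <- tt$data[1, 7, ] * 100
  m <- feature_vector_outliers(tt)
  expect_true(m[1, 7])

  # calibration: near-Gaussian features from white noise, 97.5th percentile
  set.seed(23)
  frac <- vapply(1:3, function(s) {
    sim <- simulate_dataset(n_leads = 1, n_trials_per_task = 1000,
                            tasks = "gender", pre_onset_s = 0.128,
                            post_onset_s = 0.128, seed = 100 + s)
    mean(feature_vector_outliers(sim$tensor))
  }, numeric(1))
  expect_lt(abs(mean(frac) - 0.025), 0.01)

  # leads with too few valid trials are skipped with a warning
  small <- noise_tensor(n_leads = 1, n_trials = 6, n_samples = 1200)
  expect_warning(m2 <- feature_vector_outliers(small), "skipped")
  expect_false(any(m2))
})

test_that("wavelet blob screen gates on centroid frequency and pooled intensity", {
  # an 80 Hz x10 burst among white-noise trials is flagged for that combination
  sim <- simulate_dataset(n_leads = 2, n_trials_per_task = 12,
                          tasks = "gender", post_onset_s = 0.2, seed = 24)
  inj <- inject_artifacts(
    sim$tensor,
    artifact_spec("gamma_blob", trial = 5, lead = 2, at_ms = 0,
                  center_freq_hz = 80, duration_ms = 200, factor = 10),
    seed = 1
  )
  m <- wavelet_blob_outliers(inj$tensor)
  expect_true(m[2, 5])

  # a large low-frequency event fails the centroid-frequency gate when the
  # cutoff sits above it (the scalogram floor is 10 Hz, so a 6 Hz event can
  # only leak into the lowest retained scales)
  inj2 <- sim
  tms <- time_ms(sim$tensor)
  env <- exp(-(tms - 50)^2 / (2 * 60^2))
  inj2$tensor$data[1, 3, ] <- inj2$tensor$data[1, 3, ] +
    20 * sin(2 * pi * 6 * tms / 1000) * env
  m2 <- wavelet_blob_outliers(inj2$tensor, low_cutoff_hz = 30)
  expect_false(m2[1, 3])

  # iid noise: clean-data false positives stay within the percentile screens
  m3 <- wavelet_blob_outliers(sim$tensor)
  expect_lte(mean(m3), 0.10)
})

test_that("earth-mover distance on histograms behaves as optimal transport", {
  expect_identical(emd_1d(c(3, 1, 0, 2), c(3, 1, 0, 2)), 0)
  # unit mass moved one bin = distance 1
  expect_equal(emd_1d(c(1, 0), c(0, 1)), 1)
  # moving mass two bins costs twice as much as one bin
  expect_equal(emd_1d(c(1, 0, 0), c(0, 0, 1)), 2)
  # symmetry
  p <- c(5, 2, 1, 0, 0); q <- c(0, 1, 2, 3, 2)
  expect_equal(emd_1d(p, q), emd_1d(q, p))
})

test_that("interictal detector isolates coherent-event trials and guards degeneracy", {
  sim <- simulate_dataset(n_leads = 5, n_trials_per_task = 20,
                          tasks = "gender", post_onset_s = 0.2, seed = 25)
  inj <- inject_artifacts(
    sim$tensor,
    dplyr::bind_rows(
      artifact_spec("interictal_coherent", trial = 4, at_ms = -500,
                    duration_ms = 300, factor = 8),
      artifact_spec("interictal_coherent", trial = 13, at_ms = 100,
                    duration_ms = 300, factor = 8)
    ),
    seed = 2
  )
  found <- interictal_trial_detector(inj$tensor)
  expect_setequal(found, c(4, 13))

  # statistically exchangeable trials: empty set (degenerate-clustering guard)
  for (s in c(26, 27)) {
    clean <- simulate_dataset(n_leads = 4, n_trials_per_task = 15,
                              tasks = "gender", post_onset_s = 0.2, seed = s)
    found0 <- suppressWarnings(interictal_trial_detector(clean$tensor))
    expect_length(found0, 0)
  }
})

test_that("trial-amplitude outliers follow the scaled-MAD rule", {
  # identical trials: zero dispersion, nothing flagged
  same <- trial_tensor(array(rep(sin(seq_len(1200) / 20), each = 2 * 5),
                             dim = c(2, 5, 1200)), fs = 1000,
                       onset_index = 1000)
  expect_length(trial_amplitude_outliers(same), 0)

  # statistic vector {1,1,1,1,20}: median 1, MAD 0, trial 5 flagged
  dat <- array(0, dim = c(2, 5, 1200))
  for (tr in 1:5) dat[1, tr, 600] <- c(1, 1, 1, 1, 20)[tr]
  tt <- trial_tensor(dat, fs = 1000, onset_index = 1000)
  expect_identical(trial_amplitude_outliers(tt), 5L)

  # one trial with a x10 peak among noise trials
  tt2 <- noise_tensor(n_leads = 2, n_trials = 12, n_samples = 1200, seed = 28)
  stat <- apply(abs(tt2$data), 2, max)
  tt2$data[1, 9, ] <- tt2$data[1, 9, ] * 10
  flagged <- trial_amplitude_outliers(tt2)
  # hand-computed rule on the statistic vector
  stat[9] <- max(abs(tt2$data[, 9, ]))
  expect_identical(flagged,
                   which(abs(stat - median(stat)) > 3 * mad(stat)))
  expect_true(9L %in% flagged)
})

test_that("glitch detector catches coherent jumps and ignores smooth signals", {
  tt <- noise_tensor(n_leads = 4, n_trials = 10, n_samples = 1500, seed = 29)
  step_at <- 1200
  tt$data[, 6, step_at:1500] <- tt$data[, 6, step_at:1500] + 50
  expect_identical(glitch_detector(tt), 6L)

  # smooth band-limited signals: empty set
  for (s in 1:3) {
    set.seed(30 + s)
    dat <- array(0, dim = c(3, 8, 1500))
    for (l in 1:3) for (tr in 1:8) {
      dat[l, tr, ] <- gcflow:::.fft_bandpass(rnorm(1500), 1000, 5, 40)
    }
    sm <- trial_tensor(dat, fs = 1000, onset_index = 1000)
    expect_length(glitch_detector(sm), 0)
  }

  # a step on 1 of 100 leads is diluted by the mean and passes
  big <- noise_tensor(n_leads = 100, n_trials = 8, n_samples = 1200, seed = 34)
  big$data[1, 3, 600:1200] <- big$data[1, 3, 600:1200] + 50
  expect_length(glitch_detector(big), 0)
})

test_that("flatness detector requires complete windows above the repeat gate", {
  cfg <- pipeline_config()
  wl <- cfg$flatness_winlen
  tt <- noise_tensor(n_leads = 2, n_trials = 4, n_samples = 1500, seed = 35)
  # constant segment of 3*winlen: flagged
  tt$data[1, 2, 301:(300 + 3 * wl)] <- 1.234
  m <- flatness_detector(tt)
  expect_true(m[1, 2])
  expect_identical(sum(m), 1L)
  # constant segment of winlen - 1: no complete window, not flagged
  tt2 <- noise_tensor(n_leads = 1, n_trials = 2, n_samples = 1500, seed = 36)
  tt2$data[1, 1, 301:(300 + wl - 1)] <- 0.5
  expect_false(any(flatness_detector(tt2)))
  # continuous noise: never flagged
  expect_false(any(flatness_detector(noise_tensor(seed = 37))))
})

test_that("combination logic applies the whole-trial gate and glitch override", {
  L <- 8; Tr <- 12
  fv <- matrix(FALSE, L, Tr); wb <- matrix(FALSE, L, Tr)
  fl <- matrix(FALSE, L, Tr)
  fv[1:6, 3] <- TRUE          # trial 3: 6 bivariate outlier leads
  fv[1:3, 5] <- TRUE          # trial 5: 3 bivariate outlier leads
  wb[2, 7] <- TRUE
  fl[4, 9] <- TRUE

  m <- combine_rejections(fv, wb, fl, interictal = c(3L, 5L),
                          amplitude = integer(), glitch = 11L,
                          lead_threshold = 5)
  # 6 > 5: removed; 3 <= 5: kept (only flagged combos masked); glitch always
  expect_setequal(m$removed_trials, c(3L, 11L))
  expect_true(all(m$combined[, 3]))
  expect_true(all(m$combined[, 11]))
  expect_identical(m$combined[, 5], fv[, 5])
  expect_true(m$combined[2, 7] && m$combined[4, 9])
  # union property: re-running any single criterion never unmasks
  expect_true(all(m$combined[fv | wb | fl]))
  expect_error(combine_rejections(fv, wb[1:4, ], fl), "mismatched")
})

test_that("rejection report counts the union once", {
  tt <- noise_tensor(n_leads = 4, n_trials = 8, n_samples = 1200)
  fv <- matrix(FALSE, 100, 128)
  fv[seq_len(1024)] <- TRUE
  m <- combine_rejections(fv, fv & FALSE, fv & FALSE)
  big <- list(data = array(0, dim = c(100, 128, 10)))
  rep1 <- rejection_report(m, structure(big, class = "trial_tensor"))
  expect_equal(rep1$fraction_rejected, 0.08)
  expect_equal(rep1$rejected_lead_trials, 1024)

  # no masking: fraction 0, median = min = n_trials
  m0 <- combine_rejections(matrix(FALSE, 4, 8), matrix(FALSE, 4, 8),
                           matrix(FALSE, 4, 8))
  rep0 <- rejection_report(m0, tt)
  expect_equal(rep0$fraction_rejected, 0)
  expect_equal(rep0$median_trials_per_lead, 8)
  expect_equal(rep0$min_trials_per_lead, 8)

  # overlap counted once: union <= sum of criteria
  fv2 <- matrix(FALSE, 4, 8); fv2[1, 1:4] <- TRUE
  wb2 <- matrix(FALSE, 4, 8); wb2[1, 3:6] <- TRUE
  m2 <- combine_rejections(fv2, wb2, matrix(FALSE, 4, 8))
  expect_lte(sum(m2$combined), sum(fv2) + sum(wb2))
  expect_identical(sum(m2$combined), sum(fv2 | wb2))
})

test_that("blob features report area, centroid, bounding box and intensities", {
  mag <- matrix(0, 20, 30)
  mag[5:8, 10:14] <- 10          # one rectangular blob
  mag[15, 25] <- 4               # single-pixel blob
  freqs <- seq(100, 5, length.out = 20)
  tms <- seq(0, 290, by = 10)
  fb <- blob_features(mag, freqs, tms, binarize_percentile = 80)
  fb <- fb[order(-fb$area), ]
  expect_equal(fb$area[1], 20)
  expect_equal(fb$centroid_freq_hz[1], mean(freqs[5:8]))
  expect_equal(fb$centroid_time_ms[1], mean(tms[10:14]))
  expect_equal(fb$max_intensity[1], 10)
  expect_equal(fb$bbox_time_lo[1], tms[10])
  # hole filling: a ring is one filled blob
  ring <- matrix(0, 15, 15)
  ring[5:9, 5:9] <- 10; ring[7, 7] <- 0
  fb2 <- blob_features(ring, seq(15, 1), seq_len(15), binarize_percentile = 80)
  expect_equal(nrow(fb2), 1L)
  expect_equal(fb2$area, 25)     # hole counted after filling
})
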