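test_that("gamma power scales with amplitude squared and respects the band", {
  n <- 2000; fs <- 1000
  mk <- function(a, f) {
    dat <- array(a * sin(2 * pi * f * seq_len(n) / fs), dim = c(1, 1, n))
    trial_tensor(dat, fs = fs, onset_index = 1000)
  }
  p1 <- gamma_power_timecourse(mk(1, 100))
  p2 <- gamma_power_timecourse(mk(2, 100))
  mid <- 30:60                                  # interior bins, no edge effects
  expect_equal(mean(p2$power[1, 1, mid]) / mean(p1$power[1, 1, mid]), 4,
               tolerance = 0.01)

  # 30 Hz sits outside the 50-150 Hz band: strong attenuation
  p30 <- gamma_power_timecourse(mk(1, 30))
  expect_lt(mean(p30$power[1, 1, mid]), 0.01 * mean(p1$power[1, 1, mid]))

  # zero signal: zero power; power is non-negative pre-z
  p0 <- gamma_power_timecourse(mk(0, 100))
  expect_true(all(p0$power == 0))
  expect_true(all(p1$power >= 0))
})

test_that("masked combinations propagate as NA through the power stage", {
  tt <- noise_tensor(n_leads = 2, n_trials = 4, n_samples = 1500, seed = 41)
  comb <- matrix(FALSE, 2, 4); comb[2, 3] <- TRUE
  tt <- mask_tensor(tt, comb)
  p <- gamma_power_timecourse(tt)
  expect_true(all(is.na(p$power[2, 3, ])))
  expect_false(anyNA(p$power[1, , ]))
})

test_that("baseline z-scoring normalizes the baseline and flags degenerate leads", {
  tt <- noise_tensor(n_leads = 2, n_trials = 24, n_samples = 2000, seed = 42)
  z <- zscore_vs_baseline(gamma_power_timecourse(tt))
  base <- z[z$time_ms < 0, ]
  for (l in unique(base$lead_id)) {
    zb <- base$z[base$lead_id == l]
    expect_equal(mean(zb), 0, tolerance = 1e-12)
    expect_equal(sd(zb), 1, tolerance = 1e-12)
  }
  # zero traces: zero power variance in the baseline is an error
  const <- trial_tensor(array(0, dim = c(1, 4, 1500)), fs = 1000,
                        onset_index = 1000)
  expect_error(zscore_vs_baseline(gamma_power_timecourse(const)),
               "zero baseline SD")
})

test_that("lead classification implements the responsive / selective rules", {
  mk_z <- function(lead, task, sep_peak, vep_peak = 0) {
    tms <- seq(-987.5, 1187.5, by = 25)
    z <- rep(0, length(tms))
    z[tms >= 75 & tms < 275] <- sep_peak
    z[tms >= 575 & tms < 1200] <- vep_peak
    tibble::tibble(lead_id = lead, task = task, time_ms = tms, z = z,
                   n_trials = 32)
  }
  z <- dplyr::bind_rows(
    mk_z("A", "gender", 4), mk_z("A", "action", 1),      # responsive+selective
    mk_z("B", "gender", 2), mk_z("B", "action", 0),      # not responsive
    mk_z("C", "gender", 4), mk_z("C", "action", 4),      # responsive only
    mk_z("D", "gender", 4, vep_peak = 4), mk_z("D", "action", 1) # epoch fail
  )
  cls <- classify_lead(z)
  expect_identical(cls$responsive[match(c("A", "B", "C", "D"), cls$lead_id)],
                   c(TRUE, FALSE, TRUE, TRUE))
  expect_identical(cls$selective[match(c("A", "B", "C", "D"), cls$lead_id)],
                   c(TRUE, FALSE, FALSE, FALSE))
  # selective implies responsive
  expect_true(all(!cls$selective | cls$responsive))

  # single-task input limits classification with a warning
  expect_warning(classify_lead(mk_z("A", "gender", 4)), "action task absent")
})

test_that("threshold-crossing latency/duration does exact linear geometry", {
  tms <- seq(-1000, 1000, by = 25)
  z <- rep(0, length(tms))
  ramp <- tms >= 100 & tms <= 200
  z[ramp] <- (tms[ramp] - 100) / 100 * 4        # 0 -> 4 over [100, 200]
  fall <- tms > 200 & tms <= 300
  z[fall] <- 4 - (tms[fall] - 200) / 100 * 4
  ld <- latency_duration(z, tms, threshold = 2)
  expect_equal(ld$latency_ms, 150)
  expect_equal(ld$duration_ms, 100)

  # never crosses: undefined, not an error
  ld2 <- latency_duration(z * 0.45, tms, threshold = 2)  # peak 1.8 < 2
  expect_true(is.na(ld2$latency_ms) && is.na(ld2$duration_ms))

  # time-shift equivariance
  shift_bins <- 8
  z_shift <- c(rep(0, shift_bins), z[seq_len(length(z) - shift_bins)])
  ld3 <- latency_duration(z_shift, tms, threshold = 2)
  expect_equal(ld3$latency_ms, ld$latency_ms + shift_bins * 25)
  expect_equal(ld3$duration_ms, ld$duration_ms)
})

test_that("classification recovers generator-responsive leads", {
  b <- burst_spec("L1", amplitude = 0.5)
  sim <- simulate_dataset(n_leads = 2, n_trials_per_task = 32, bursts = b,
                          post_onset_s = 0.8, seed = 43)
  z <- zscore_vs_baseline(gamma_power_timecourse(sim$tensor))
  cls <- classify_lead(z, video_epoch_ms = c(575, 800))
  expect_true(cls$responsive[cls$lead_id == "L1"])
  expect_true(cls$selective[cls$lead_id == "L1"])
  expect_false(cls$responsive[cls$lead_id == "L2"])
})

test_that("strength-power correlation distinguishes dependence from independence", {
  powers <- tibble::tibble(lead_id = paste0("L", 1:10),
                           peak_power = seq(1, 10))
  pairs <- tibble::tibble(source = paste0("L", 1:9),
                          target = paste0("L", 2:10))
  # C an exact linear function of source power: r = 1
  s1 <- dplyr::mutate(pairs, C = 2 * seq(1, 9) + 1)
  r1 <- gc_power_correlation(s1, powers)
  expect_equal(r1$r_source, 1)
  # constant C: zero variance -> NA
  s2 <- dplyr::mutate(pairs, C = 5)
  expect_true(is.na(gc_power_correlation(s2, powers)$r_source))
  # independent C and power, n = 100: |r| stays small in most seeds
  powers_big <- tibble::tibble(lead_id = paste0("L", 1:101),
                               peak_power = NA_real_)
  ok <- vapply(1:5, function(s) {
    set.seed(50 + s)
    powers_big$peak_power <- rexp(101)
    pr <- tibble::tibble(source = paste0("L", 1:100),
                         target = paste0("L", 2:101), C = rnorm(100))
    abs(gc_power_correlation(pr, powers_big)$r_source) < 0.3
  }, logical(1))
  expect_gte(sum(ok), 4)
  expect_error(gc_power_correlation(s1[1:2, ], powers), ">= 3 pairs")
})
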