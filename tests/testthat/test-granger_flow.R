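test_that("pair trial selection is per-pair set algebra with a minimum", {
  tt <- noise_tensor(n_leads = 3, n_trials = 20, n_samples = 1200, seed = 61)
  comb <- matrix(FALSE, 3, 20)
  comb[1, c(1, 2)] <- TRUE
  comb[2, c(2, 3)] <- TRUE
  tt <- mask_tensor(tt, comb)
  expect_setequal(select_pair_trials(tt, c("L1", "L2")), setdiff(1:20, 1:3))
  expect_setequal(select_pair_trials(tt, c("L1", "L3")), setdiff(1:20, 1:2))
  # no masking: all trials
  tt0 <- noise_tensor(n_leads = 2, n_trials = 15, n_samples = 1200)
  expect_identical(select_pair_trials(tt0, c("L1", "L2")), 1:15)
  # nearly disjoint valid sets: skip with warning
  comb2 <- matrix(FALSE, 3, 20); comb2[1, 1:15] <- TRUE; comb2[2, 10:20] <- TRUE
  tt2 <- mask_tensor(noise_tensor(n_leads = 3, n_trials = 20,
                                  n_samples = 1200), comb2)
  expect_warning(tr <- select_pair_trials(tt2, c("L1", "L2")), "skipped")
  expect_length(tr, 0)
})

test_that("window VAR estimates recover known coefficients", {
  set.seed(62)
  n_tr <- 120; n_s <- 100
  # bivariate VAR(1): x -> y with a = 0.5 (x self), c = 0.4
  A <- array(0, dim = c(2, n_tr, n_s))
  for (tr in seq_len(n_tr)) {
    x <- numeric(n_s); y <- numeric(n_s)
    for (t in 2:n_s) {
      x[t] <- 0.5 * x[t - 1] + rnorm(1)
      y[t] <- 0.3 * y[t - 1] + 0.4 * x[t - 1] + rnorm(1)
    }
    A[1, tr, ] <- x; A[2, tr, ] <- y
  }
  f <- fit_var_window(A, order = 1)
  expect_equal(f$coef[1, 1, 1], 0.5, tolerance = 0.05)
  expect_equal(f$coef[2, 1, 1], 0.4, tolerance = 0.05)
  expect_equal(f$coef[2, 2, 1], 0.3, tolerance = 0.05)
  # independent white-noise leads: cross-coefficients vanish
  set.seed(63)
  B <- array(rnorm(2 * 200 * 100), dim = c(2, 200, 100))
  f0 <- fit_var_window(B, order = 4)
  expect_lt(max(abs(f0$coef[1, 2, ])), 0.05)
  expect_lt(max(abs(f0$coef[2, 1, ])), 0.05)
  expect_error(fit_var_window(B, order = 0), "order")
})

test_that("tidiers expose the fitted VAR in broom style", {
  set.seed(64)
  A <- array(rnorm(2 * 50 * 100), dim = c(2, 50, 100))
  f <- fit_var_window(A, order = 3, ns_factor = 2)
  td <- tidy(f)
  expect_identical(nrow(td), 2L * 2L * 3L)
  expect_named(td, c("target", "source", "lag", "estimate"))
  expect_equal(td$estimate[td$target == 2 & td$source == 1 & td$lag == 2],
               f$coef[2, 1, 2])
  gl <- glance(f)
  expect_identical(gl$order, 3)
  expect_identical(gl$ns_factor, 2)
  expect_identical(gl$n_obs, 50L * (50L - 3L))
})

test_that("raw pairwise GC is non-negative and unbiased-null on uncoupled leads", {
  tt <- noise_tensor(n_leads = 2, n_trials = 48, n_samples = 1600, seed = 65)
  tr <- pairwise_ugc(tt, c("L1", "L2"))
  expect_true(all(tr$F >= -1e-10))
  # null mean close to the analytic small-sample bias p/N
  cfg <- pipeline_config()
  N <- 48 * (cfg$gc_window_samples - cfg$gc_lags)
  bias <- cfg$gc_lags / N
  expect_lt(mean(tr$F), 3 * bias)
  expect_gt(mean(tr$F), bias / 3)
})

test_that("directionality: forward F dominates and matches a long-run oracle", {
  set.seed(66)
  # stationary unidirectional coupling, fitted over a long realization
  n <- 3e5
  x <- numeric(n); y <- numeric(n)
  for (t in 2:n) {
    x[t] <- 0.5 * x[t - 1] + rnorm(1)
    y[t] <- 0.3 * y[t - 1] + 0.4 * x[t - 1] + rnorm(1)
  }
  n_tr <- 300; n_s <- 1000
  A <- array(0, dim = c(2, n_tr, n_s))
  A[1, , ] <- matrix(x, n_tr, byrow = TRUE)
  A[2, , ] <- matrix(y, n_tr, byrow = TRUE)
  f <- fit_var_window(A, order = 4)
  F_fw <- log(f$sigma_reduced[1, 2] / f$Sigma[2, 2])
  F_bw <- log(f$sigma_reduced[2, 1] / f$Sigma[1, 1])
  # oracle: two independent model fits (embed + lm.fit) on the same draw
  emb_y <- embed(y, 5)
  emb_x <- embed(x, 5)
  red <- lm.fit(cbind(1, emb_y[, 2:5]), emb_y[, 1])
  full <- lm.fit(cbind(1, emb_y[, 2:5], emb_x[, 2:5]), emb_y[, 1])
  F_oracle <- log(mean(red$residuals^2) / mean(full$residuals^2))
  expect_equal(F_fw, F_oracle, tolerance = 0.05 * F_oracle)
  expect_lt(F_bw, 0.1 * F_fw)
})

test_that("surrogate normalization is deterministic and centers the null", {
  cp <- coupling_spec("L1", "L2", lag_ms = 2, gain = 0.6,
                      window_s = c(0, 0.5))
  sim <- simulate_dataset(n_leads = 2, n_trials_per_task = 32,
                          tasks = "gender", post_onset_s = 0.6,
                          couplings = cp, seed = 67)
  s1 <- surrogate_normalize(sim$tensor, c("L1", "L2"), seed = 3)
  s2 <- surrogate_normalize(sim$tensor, c("L1", "L2"), seed = 3)
  expect_identical(s1$z_surr, s2$z_surr)
  # coupled direction exceeds 5 inside the gate
  fw <- s1[s1$source == "L1", ]
  expect_gt(max(fw$z_surr[fw$window_center_ms >= 100 &
                            fw$window_center_ms < 400]), 5)
  # baseline windows (no coupling): mostly |z| < 3
  base <- s1$z_surr[s1$window_end_ms <= 0]
  expect_lte(mean(abs(base) > 3, na.rm = TRUE), 0.05)
})

test_that("bootstrap variability brackets the point estimate", {
  tt <- noise_tensor(n_leads = 2, n_trials = 24, n_samples = 1300, seed = 68)
  bt <- bootstrap_gc(tt, c("L1", "L2"), n = 8, seed = 5)
  expect_true(all(bt$boot_sd >= 0))
  expect_true(all(is.finite(bt$boot_mean)))
  # same seed reproduces
  bt2 <- bootstrap_gc(tt, c("L1", "L2"), n = 8, seed = 5)
  expect_identical(bt$boot_mean, bt2$boot_mean)
})

test_that("baseline z-scoring of GC traces follows the definition", {
  base <- rep(c(0.1, 0.2), 30)                   # mean 0.15, sd ~0.0504
  resp <- 0.15 + 5 * sd(base)
  tr <- synthetic_gc_trace(base, resp)
  tz <- baseline_zscore_gc(tr)
  expect_equal(tz$z_base[nrow(tz)], 5, tolerance = 1e-10)
  # constant baseline: undefined marker
  tz2 <- baseline_zscore_gc(synthetic_gc_trace(rep(0.2, 30), 0.6))
  expect_true(all(is.na(tz2$z_base)))
})

test_that("the signed strength C reproduces the worked rules", {
  expect_identical(strength_rule(7, 1), 7)
  expect_identical(strength_rule(-1, -6), -6)
  expect_identical(strength_rule(2, -0.5), 0.75)
  expect_identical(strength_rule(6, -2), 6)
  # boundary: |max|-|min| difference exactly 3 takes the larger magnitude
  expect_identical(strength_rule(4, -1), 4)
})

test_that("connection typing reproduces the published taxonomy", {
  expect_identical(classify_connection(6, 2), "D")
  expect_identical(classify_connection(6, 7), "M")
  expect_identical(classify_connection(2, 6), "A")
  expect_identical(classify_connection(1, -6), "N")
  expect_identical(classify_connection(-6, 6), "opposite")
  expect_identical(classify_connection(6, -6), "opposite")
  expect_identical(classify_connection(2, 2), "weak")
  # ties at the threshold fall to the weaker category
  expect_identical(classify_connection(5, 2), "weak")
  expect_identical(classify_connection(5, 6), "A")
})

test_that("via-lead rule needs both strengths strong", {
  expect_true(via_lead_classification(6, 6))
  expect_false(via_lead_classification(6, 4))
  expect_false(via_lead_classification(4, 4))
  expect_identical(via_lead_classification(c(6, 6, 4), c(6, 4, 4)),
                   c(TRUE, FALSE, FALSE))
})

test_that("region averaging is the pointwise mean over traces", {
  tr1 <- synthetic_gc_trace(rep(0.1, 10), 2, target = "T1")
  tr2 <- synthetic_gc_trace(rep(0.1, 10), 4, target = "T2")
  avg <- region_average_gc(dplyr::bind_rows(tr1, tr2))
  expect_equal(avg$F[nrow(avg)], 3)
  # single trace: identity on the value columns
  one <- region_average_gc(tr1)
  expect_equal(one$F, tr1$F)
  expect_error(region_average_gc(tr1[0, ]), "no traces")
})

test_that("conditioned GC rejects conditioning on a pair member", {
  tt <- noise_tensor(n_leads = 3, n_trials = 16, n_samples = 1200, seed = 69)
  expect_error(conditioned_gc(tt, c("L1", "L2"), "L1"), "must not belong")
  expect_error(conditioned_gc(tt, c("L1", "L2"), "L2"), "must not belong")
})

test_that("spectral GC integrates to the time-domain statistic", {
  set.seed(70)
  n_tr <- 150; n_s <- 600
  A <- array(0, dim = c(2, n_tr, n_s))
  for (tr in seq_len(n_tr)) {
    x <- numeric(n_s); y <- numeric(n_s)
    for (t in 2:n_s) {
      x[t] <- 0.5 * x[t - 1] + rnorm(1)
      y[t] <- 0.3 * y[t - 1] + 0.4 * x[t - 1] + rnorm(1)
    }
    A[1, tr, ] <- x; A[2, tr, ] <- y
  }
  f <- fit_var_window(A, order = 4)
  F_fw <- log(f$sigma_reduced[1, 2] / f$Sigma[2, 2])
  sp <- spectral_gc(f, fs = 1000)
  expect_identical(nrow(sp), 2L * 101L)
  mean_fw <- mean(sp$f[sp$direction == "1->2"])
  expect_equal(mean_fw, F_fw, tolerance = 0.05 * F_fw)
  expect_lt(mean(sp$f[sp$direction == "2->1"]), 0.1 * mean_fw)
})

test_that("connection summary types a two-lag network end to end", {
  cp <- rbind(
    coupling_spec("L1", "L2", lag_ms = 2, gain = 0.6, window_s = c(0, 0.6)),
    coupling_spec("L3", "L4", lag_ms = 12, gain = 0.9, window_s = c(0, 0.6))
  )
  sim <- simulate_dataset(n_leads = 4, n_trials_per_task = 48,
                          tasks = "gender", post_onset_s = 0.8,
                          couplings = cp, seed = 71)
  cs <- connection_summary(sim$tensor,
                           rbind(c("L1", "L2"), c("L2", "L1"),
                                 c("L3", "L4")))
  expect_true(cs$type[cs$source == "L1" & cs$target == "L2"] %in% c("D", "M"))
  expect_identical(cs$type[cs$source == "L2" & cs$target == "L1"], "weak")
  expect_identical(cs$type[cs$source == "L3" & cs$target == "L4"], "A")
})
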