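#' Specify a directed cross-lead coupling
#'
#' A coupling is realized as a time-varying vector-autoregressive term:
#' inside the gated window of trials of the gated task,
#' `x[target, t] <- x[target, t] + gain * x[source, t - lag]`. Couplings are
#' applied recursively in time, so chains (A -> B -> C) propagate.
#'
#' @param source,target lead ids (or indices resolved at simulation time).
#' @param lag_ms positive delay of the causal influence in ms; must be an
#'   integer number of samples at the simulation rate.
#' @param gain unitless VAR coefficient.
#' @param task_gate task in which the coupling is active (`"gender"`,
#'   `"action"`, or `"all"`).
#' @param window_s interval relative to static onset during which the gain is
#'   applied; `NULL` means the whole trial (a tonic coupling).
#' @return tibble row describing the coupling.
#' @export
coupling_spec <- function(source, target, lag_ms, gain,
                          task_gate = "gender", window_s = c(0.1, 0.4)) {
  stopifnot(lag_ms > 0, is.finite(gain))
  tibble::tibble(source = source, target = target, lag_ms = lag_ms,
                 gain = gain, task_gate = task_gate,
                 window_start_s = if (is.null(window_s)) -Inf else window_s[1],
                 window_end_s = if (is.null(window_s)) Inf else window_s[2])
}

#' Specify a broadband-gamma burst response
#'
#' Bursts emulate the brief task-specific broadband (50-150 Hz) responses:
#' Gaussian noise band-passed to `band` and multiplied by a raised-cosine
#' envelope starting `onset_ms` after static onset and lasting `duration_ms`.
#'
#' @param lead lead id.
#' @param onset_ms,duration_ms burst timing relative to static onset; defaults
#'   170 ms and 110 ms, the typical observed response latency and duration.
#' @param amplitude burst RMS in units of the background-noise SD (default
#'   0.5, giving single-trial gamma z-scores of order 1 and a strongly
#'   significant trial-averaged response).
#' @param task_gate task in which the burst occurs (default `"gender"`).
#' @param band burst frequency band, default `c(50, 150)` Hz.
#' @return tibble row describing the burst.
#' @export
burst_spec <- function(lead, onset_ms = 170, duration_ms = 110,
                       amplitude = 0.5, task_gate = "gender",
                       band = c(50, 150)) {
  tibble::tibble(lead = lead, onset_ms = onset_ms, duration_ms = duration_ms,
                 amplitude = amplitude, task_gate = task_gate,
                 band_low = band[1], band_high = band[2])
}

#' Simulate a trial tensor with known ground truth
#'
#' Generates independent Gaussian background noise per lead (optionally with a
#' 1/f component), adds task-gated broadband-gamma bursts and directed VAR
#' couplings at known lags, and records everything injected in a
#' `ground_truth` object. Deterministic given `seed`.
#'
#' @param n_leads number of leads (default 4).
#' @param n_trials_per_task trials per task (default 128: 64 full + 64
#'   truncated, as in the recordings the pipeline was designed for).
#' @param tasks character vector of tasks (default `c("gender", "action")`).
#' @param fs sampling rate in Hz (default 1000).
#' @param pre_onset_s,post_onset_s trial extent around static onset (defaults
#'   1 and 1.2 s; the fixed post-onset duration stands in for the variable
#'   inter-trial gap of real sessions).
#' @param couplings tibble of [coupling_spec()] rows (may be `NULL`).
#' @param bursts tibble of [burst_spec()] rows (may be `NULL`).
#' @param noise_sd background noise SD in microvolts (default 1).
#' @param pink_fraction fraction of noise variance from a 1/f component
#'   (default 0: white, which keeps closed-form Granger oracles valid).
#' @param leads optional lead metadata table; defaults to `L1..Ln`,
#'   `gray-other`.
#' @param seed integer RNG seed (required for reproducibility).
#' @return list with elements `tensor` (a [trial_tensor()]) and `truth` (a
#'   `ground_truth` list: `couplings`, `bursts`, `artifacts`, `responses`,
#'   `rng_seed`).
#' @export
simulate_dataset <- function(n_leads = 4, n_trials_per_task = 128,
                             tasks = c("gender", "action"), fs = 1000,
                             pre_onset_s = 1, post_onset_s = 1.2,
                             couplings = NULL, bursts = NULL,
                             noise_sd = 1, pink_fraction = 0,
                             leads = NULL, seed = 1L) {
  stopifnot(n_leads >= 1, n_trials_per_task >= 1, fs > 0)
  n_trial <- n_trials_per_task * length(tasks)
  n_samp <- round((pre_onset_s + post_onset_s) * fs)
  onset_index <- round(pre_onset_s * fs)
  if (is.null(leads)) {
    leads <- tibble::tibble(lead_id = paste0("L", seq_len(n_leads)),
                            region = rep("gray-other", n_leads),
                            patient_id = "P1", in_ez = FALSE)
  }
  trial_labels <- tibble::tibble(
    task = rep(tasks, each = n_trials_per_task),
    truncation = rep(rep(c("full", "truncated"), length.out = n_trials_per_task),
                     times = length(tasks)),
    static_duration_ms = 575,
    response_time_ms = 830
  )

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)

  data <- array(stats::rnorm(n_leads * n_trial * n_samp, sd = noise_sd),
                dim = c(n_leads, n_trial, n_samp))
  if (pink_fraction > 0) {
    for (l in seq_len(n_leads)) for (tr in seq_len(n_trial)) {
      p <- .pink_noise(n_samp)
      data[l, tr, ] <- sqrt(1 - pink_fraction) * data[l, tr, ] +
        sqrt(pink_fraction) * noise_sd * p
    }
  }

  tms <- (seq_len(n_samp) - 1L - onset_index) / fs * 1000

  responses <- NULL
  if (!is.null(bursts) && nrow(bursts)) {
    for (b in seq_len(nrow(bursts))) {
      bs <- bursts[b, ]
      li <- .lead_index(bs$lead, leads)
      sel_tr <- which(bs$task_gate == "all" | trial_labels$task == bs$task_gate)
      env <- .raised_cosine(tms, bs$onset_ms, bs$duration_ms)
      for (tr in sel_tr) {
        carrier <- .fft_bandpass(stats::rnorm(n_samp), fs, bs$band_low, bs$band_high)
        carrier <- carrier / stats::sd(carrier)
        data[li, tr, ] <- data[li, tr, ] +
          bs$amplitude * noise_sd * carrier * env
      }
      responses <- dplyr::bind_rows(responses, tibble::tibble(
        lead = bs$lead, onset_ms = bs$onset_ms, duration_ms = bs$duration_ms,
        task = bs$task_gate))
    }
  }

  if (!is.null(couplings) && nrow(couplings)) {
    lag_samp <- couplings$lag_ms * fs / 1000
    if (any(abs(lag_samp - round(lag_samp)) > 1e-9)) {
      stop("coupling lag_ms must be an integer number of samples at fs = ",
           fs, " Hz", call. = FALSE)
    }
    lag_samp <- as.integer(round(lag_samp))
    src_i <- vapply(couplings$source, .lead_index, integer(1), leads = leads)
    tgt_i <- vapply(couplings$target, .lead_index, integer(1), leads = leads)
    gate_tr <- lapply(seq_len(nrow(couplings)), function(k) {
      couplings$task_gate[k] == "all" | trial_labels$task == couplings$task_gate[k]
    })
    gate_t <- lapply(seq_len(nrow(couplings)), function(k) {
      tms / 1000 >= couplings$window_start_s[k] &
        tms / 1000 < couplings$window_end_s[k]
    })
    for (t in seq_len(n_samp)) {
      for (k in seq_len(nrow(couplings))) {
        if (!gate_t[[k]][t] || t <= lag_samp[k]) next
        tr <- gate_tr[[k]]
        data[tgt_i[k], tr, t] <- data[tgt_i[k], tr, t] +
          couplings$gain[k] * data[src_i[k], tr, t - lag_samp[k]]
      }
    }
  }

  tensor <- trial_tensor(data, fs = fs, onset_index = onset_index,
                         trial_labels = trial_labels, leads = leads)
  truth <- structure(
    list(couplings = couplings %||% coupling_spec("x", "y", 1, 0)[0, ],
         bursts = bursts %||% burst_spec("x")[0, ],
         artifacts = tibble::tibble(), responses = responses,
         rng_seed = seed),
    class = "ground_truth"
  )
  list(tensor = tensor, truth = truth)
}

.lead_index <- function(lead, leads) {
  if (is.character(lead)) {
    i <- match(lead, leads$lead_id)
    if (is.na(i)) stop("unknown lead id in spec: ", lead, call. = FALSE)
    i
  } else as.integer(lead)
}

.raised_cosine <- function(tms, onset_ms, duration_ms, ramp_frac = 0.25) {
  u <- (tms - onset_ms) / duration_ms
  env <- numeric(length(tms))
  core <- u >= ramp_frac & u <= 1 - ramp_frac
  env[core] <- 1
  up <- u >= 0 & u < ramp_frac
  env[up] <- 0.5 - 0.5 * cos(pi * u[up] / ramp_frac)
  dn <- u > 1 - ramp_frac & u <= 1
  env[dn] <- 0.5 + 0.5 * cos(pi * (u[dn] - (1 - ramp_frac)) / ramp_frac)
  env
}

.pink_noise <- function(n) {
  f <- c(1, seq_len(n %/% 2))
  amp <- 1 / sqrt(f)
  ph <- stats::runif(length(amp), 0, 2 * pi)
  spec <- complex(modulus = amp, argument = ph)
  full <- complex(length.out = n)
  full[seq_along(spec)] <- spec
  x <- Re(stats::fft(full, inverse = TRUE))
  (x - mean(x)) / stats::sd(x)
}

#' Specify an injectable artifact
#'
#' One row per artifact instance. Kinds mirror the classes the rejection
#' pipeline targets: `amplitude_outlier` (trace scaled by `factor`),
#' `gamma_blob` (narrowband burst at `center_freq_hz` of `duration_ms`,
#' amplitude `factor` x trace SD), `interictal_coherent` (a smooth biphasic
#' transient shared, with equal sign, by `lead_fraction` of the leads, not
#' locked to onset), `glitch` (simultaneous step of `factor` x SD on all
#' leads at one sample), `flat_segment` (samples replaced by a constant for
#' `duration_ms`).
#'
#' @param kind artifact class (see above).
#' @param trial trial index (`NA` = draw at random at injection time).
#' @param lead lead index or id (`NA` = random; ignored by `glitch` and
#'   `interictal_coherent`).
#' @param at_ms placement time relative to static onset (`NA` = random).
#' @param factor amplitude factor (default 10).
#' @param center_freq_hz gamma-blob carrier (default 80).
#' @param duration_ms event duration (default 200; 500 is typical for flat
#'   segments).
#' @param lead_fraction fraction of leads carrying a coherent event (default
#'   0.8).
#' @return tibble row.
#' @export
artifact_spec <- function(kind, trial = NA, lead = NA, at_ms = NA,
                          factor = 10, center_freq_hz = 80, duration_ms = 200,
                          lead_fraction = 0.8) {
  kind <- match.arg(kind, c("amplitude_outlier", "gamma_blob",
                            "interictal_coherent", "glitch", "flat_segment"))
  tibble::tibble(kind = kind, trial = trial, lead = as.character(lead),
                 at_ms = at_ms, factor = factor,
                 center_freq_hz = center_freq_hz, duration_ms = duration_ms,
                 lead_fraction = lead_fraction)
}

#' Inject artifacts into a trial tensor
#'
#' Returns a modified copy of the tensor plus the exact placement record
#' (random placements resolved), for use as a recovery oracle when testing the
#' rejection pipeline. Flat segments and glitches may not overlap on the same
#' samples of a trial, to keep the artifact classes separable.
#'
#' @param tensor a [trial_tensor()].
#' @param specs tibble of [artifact_spec()] rows.
#' @param seed RNG seed for random placements.
#' @return list `tensor` (modified copy) and `truth` (`ground_truth` holding
#'   the placed artifact table).
#' @export
inject_artifacts <- function(tensor, specs, seed = 1L) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  d <- dim(tensor$data)
  fs <- tensor$fs
  tms <- time_ms(tensor)
  placed <- NULL
  flat_marks <- list()   # per trial: samples already flattened
  glitch_marks <- list()
  global_sd <- stats::sd(tensor$data)

  for (k in seq_len(nrow(specs))) {
    sp <- specs[k, ]
    trial <- if (is.na(sp$trial)) sample.int(d[2L], 1L) else as.integer(sp$trial)
    lead <- if (is.na(sp$lead) || sp$lead == "NA") sample.int(d[1L], 1L) else
      .lead_index(.maybe_numeric(sp$lead), tensor$leads)
    at_ms <- if (is.na(sp$at_ms)) {
      stats::runif(1, tms[1] + 100, tms[d[3L]] - sp$duration_ms - 100)
    } else sp$at_ms
    i0 <- which.min(abs(tms - at_ms))
    n_dur <- max(1L, round(sp$duration_ms / 1000 * fs))
    idx <- i0:min(d[3L], i0 + n_dur - 1L)

    switch(sp$kind,
      amplitude_outlier = {
        tensor$data[lead, trial, ] <- tensor$data[lead, trial, ] * sp$factor
      },
      gamma_blob = {
        tr_sd <- stats::sd(tensor$data[lead, trial, ])
        env <- .raised_cosine(tms, at_ms, sp$duration_ms)
        carrier <- sin(2 * pi * sp$center_freq_hz * (tms / 1000))
        tensor$data[lead, trial, ] <- tensor$data[lead, trial, ] +
          sp$factor * tr_sd * carrier * env
      },
      interictal_coherent = {
        n_aff <- max(2L, round(sp$lead_fraction * d[1L]))
        aff <- sort(sample.int(d[1L], n_aff))
        shape <- .biphasic(length(idx))
        tr_sd <- stats::sd(tensor$data[, trial, ])
        for (l in aff) {
          tensor$data[l, trial, idx] <- tensor$data[l, trial, idx] +
            sp$factor * tr_sd * shape
        }
        lead <- NA_integer_
      },
      glitch = {
        if (!is.null(flat_marks[[as.character(trial)]]) &&
            i0 %in% flat_marks[[as.character(trial)]]) {
          stop("glitch overlaps a flat segment on trial ", trial, call. = FALSE)
        }
        step <- sp$factor * global_sd
        tensor$data[, trial, i0:d[3L]] <- tensor$data[, trial, i0:d[3L]] + step
        glitch_marks[[as.character(trial)]] <- c(glitch_marks[[as.character(trial)]], i0)
        lead <- NA_integer_
      },
      flat_segment = {
        if (!is.null(glitch_marks[[as.character(trial)]]) &&
            any(glitch_marks[[as.character(trial)]] %in% idx)) {
          stop("flat segment overlaps a glitch on trial ", trial, call. = FALSE)
        }
        tensor$data[lead, trial, idx] <- tensor$data[lead, trial, idx[1L]]
        flat_marks[[as.character(trial)]] <- c(flat_marks[[as.character(trial)]], idx)
      }
    )
    placed <- dplyr::bind_rows(placed, tibble::tibble(
      kind = sp$kind, trial = trial, lead = lead, at_ms = at_ms,
      factor = sp$factor, duration_ms = sp$duration_ms,
      lead_fraction = sp$lead_fraction))
  }
  truth <- structure(list(couplings = NULL, bursts = NULL, artifacts = placed,
                          responses = NULL, rng_seed = seed),
                     class = "ground_truth")
  list(tensor = tensor, truth = truth)
}

.maybe_numeric <- function(x) {
  n <- suppressWarnings(as.numeric(x))
  if (!is.na(n)) n else x
}

# smooth biphasic transient (spike-and-wave-like), unit peak
.biphasic <- function(n) {
  u <- seq(0, 1, length.out = n)
  s <- sin(2 * pi * u) * exp(-3 * u)
  s / max(abs(s))
}

#' @export
print.ground_truth <- function(x, ...) {
  cat("<ground_truth> seed", x$rng_seed, "\n")
  if (!is.null(x$couplings) && nrow(x$couplings))
    cat("  couplings:", nrow(x$couplings), "\n")
  if (!is.null(x$bursts) && nrow(x$bursts))
    cat("  bursts:", nrow(x$bursts), "\n")
  if (!is.null(x$artifacts) && nrow(x$artifacts))
    cat("  artifacts:", nrow(x$artifacts), "\n")
  invisible(x)
}
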