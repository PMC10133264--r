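#' Broadband-gamma power time course
#'
#' Complex-wavelet power at the ten 10-Hz sub-band centers spanning the gamma
#' band (55, 65, ..., 145 Hz for the default 50-150 Hz band), averaged over
#' sub-bands and then within non-overlapping 25 ms bins. The wavelet family is
#' configurable (`config$power_wavelet`): analytic Morse (consistent with the
#' rejection stage, the default) or complex Morlet.
#'
#' @param tensor a [trial_tensor()].
#' @param config a [pipeline_config()].
#' @return a `power_tensor`: list with `power` (array `leads x trials x bins`
#'   of raw, pre-z gamma power; masked combinations are `NA`), `bin_ms`,
#'   `bin_center_ms` (bin centers relative to onset), `band`, `fs`,
#'   `onset_index`, `trial_labels`, `leads`.
#' @export
gamma_power_timecourse <- function(tensor, config = pipeline_config()) {
  d <- dim(tensor$data)
  band <- config$power_band
  centers <- seq(band[1] + 5, band[2] - 5, by = 10)
  bin_samp <- max(1L, round(config$power_bin_ms / 1000 * tensor$fs))
  n_bins <- d[3L] %/% bin_samp
  bin_id <- rep(seq_len(n_bins), each = bin_samp)
  valid <- valid_combinations(tensor)
  P <- array(NA_real_, dim = c(d[1L], d[2L], n_bins))
  for (l in seq_len(d[1L])) for (tr in seq_len(d[2L])) {
    if (!valid[l, tr]) next
    cw <- cwt_transform(tensor$data[l, tr, ], tensor$fs, freqs = centers,
                        wavelet = config$power_wavelet)
    pw <- colMeans(Mod(cw$coef)^2)          # average over the ten sub-bands
    P[l, tr, ] <- vapply(seq_len(n_bins), function(b) {
      mean(pw[bin_id == b])
    }, numeric(1))
  }
  first_center <- (bin_samp + 1) / 2
  bin_center_ms <- ((seq_len(n_bins) - 1L) * bin_samp + first_center - 1 -
                      tensor$onset_index) / tensor$fs * 1000
  structure(list(power = P, bin_ms = config$power_bin_ms,
                 bin_center_ms = bin_center_ms, band = band, fs = tensor$fs,
                 onset_index = tensor$onset_index,
                 trial_labels = tensor$trial_labels, leads = tensor$leads),
            class = "power_tensor")
}

#' @export
print.power_tensor <- function(x, ...) {
  d <- dim(x$power)
  cat("<power_tensor> ", d[1L], " leads x ", d[2L], " trials x ", d[3L],
      " bins of ", x$bin_ms, " ms; band ", x$band[1], "-", x$band[2],
      " Hz\n", sep = "")
  invisible(x)
}

#' Baseline z-scored, trial-averaged gamma power
#'
#' Averages the (unmasked) trials of each lead — optionally per task — and
#' z-scores the averaged time course against the mean and SD of its baseline
#' bins (default the 1 s before onset). Leads with zero baseline SD raise an
#' error.
#'
#' @param power a `power_tensor` from [gamma_power_timecourse()].
#' @param baseline_window_s baseline interval in s relative to onset (default
#'   `c(-1, 0)`, the 1 s pre-onset period).
#' @param by_task average separately per task label? (default TRUE)
#' @return tibble: `lead_id`, `task` (if `by_task`), `time_ms` (bin center),
#'   `z`, plus `n_trials` averaged.
#' @export
zscore_vs_baseline <- function(power, baseline_window_s = c(-1, 0),
                               by_task = TRUE) {
  stopifnot(inherits(power, "power_tensor"))
  lo <- baseline_window_s[1] * 1000
  hi <- baseline_window_s[2] * 1000
  base_sel <- power$bin_center_ms >= lo & power$bin_center_ms < hi
  if (!any(base_sel)) stop("baseline window holds no power bins", call. = FALSE)
  groups <- if (by_task) unique(power$trial_labels$task) else "all"
  purrr::map_dfr(seq_len(dim(power$power)[1L]), function(l) {
    purrr::map_dfr(groups, function(g) {
      trs <- if (by_task) which(power$trial_labels$task == g) else
        seq_len(dim(power$power)[2L])
      m <- power$power[l, trs, , drop = FALSE]
      keep <- !apply(matrix(is.na(m[1L, , ]), nrow = length(trs)), 1L, any)
      if (!any(keep)) return(NULL)
      avg <- colMeans(matrix(m[1L, keep, ], nrow = sum(keep)))
      mu <- mean(avg[base_sel]); sdv <- stats::sd(avg[base_sel])
      if (sdv == 0) {
        stop("zero baseline SD for lead ", power$leads$lead_id[l], call. = FALSE)
      }
      tibble::tibble(lead_id = power$leads$lead_id[l], task = g,
                     time_ms = power$bin_center_ms, z = (avg - mu) / sdv,
                     n_trials = sum(keep))
    })
  })
}

#' Classify leads as responsive / selective
#'
#' A lead is *responsive* when its gender-task z exceeds
#' `config$responsive_z` (default 3) in any bin of the static epoch (SEp, the
#' 200 ms window starting 75 ms after static onset). A responsive lead is
#' additionally *selective* when its action-task SEp z and its gender-task
#' video-epoch (VEp: static end to response) z never exceed the threshold.
#' When only one task is present, classification is limited to responsiveness,
#' with a warning.
#'
#' Latency and duration of the gender-task response are measured by
#' [latency_duration()] at threshold `config$responsive_z`.
#'
#' @param z tibble from [zscore_vs_baseline()] (`by_task = TRUE`).
#' @param static_epoch_ms SEp window, default `c(75, 275)` ms.
#' @param video_epoch_ms VEp window; default from the median static duration
#'   and response time in `trial_labels` is not available here, so supply
#'   `c(static_end, response)` in ms (default `c(575, 1200)`).
#' @param config a [pipeline_config()].
#' @return tibble: `lead_id`, `responsive`, `selective`, `latency_ms`,
#'   `duration_ms`, and the epoch peak z-scores (`sep_gender`, `sep_action`,
#'   `vep_gender`).
#' @export
classify_lead <- function(z, static_epoch_ms = c(75, 275),
                          video_epoch_ms = c(575, 1200),
                          config = pipeline_config()) {
  thr <- config$responsive_z
  have_action <- "action" %in% z$task
  if (!have_action) {
    warning("action task absent: classification limited to responsiveness")
  }
  peak_in <- function(d, w) {
    sel <- d$time_ms >= w[1] & d$time_ms < w[2]
    if (!any(sel)) NA_real_ else max(d$z[sel])
  }
  z |>
    dplyr::group_by(.data$lead_id) |>
    dplyr::group_modify(function(d, key) {
      g <- d[d$task == "gender", ]
      a <- d[d$task == "action", ]
      sep_g <- peak_in(g, static_epoch_ms)
      sep_a <- if (nrow(a)) peak_in(a, static_epoch_ms) else NA_real_
      vep_g <- peak_in(g, video_epoch_ms)
      responsive <- isTRUE(sep_g > thr)
      selective <- responsive && have_action &&
        isTRUE(sep_a <= thr) && isTRUE(vep_g <= thr)
      ld <- latency_duration(g$z, g$time_ms, threshold = thr)
      tibble::tibble(responsive = responsive, selective = selective,
                     latency_ms = ld$latency_ms, duration_ms = ld$duration_ms,
                     sep_gender = sep_g, sep_action = sep_a, vep_gender = vep_g)
    }) |>
    dplyr::ungroup()
}

#' Latency and duration by threshold crossing
#'
#' Latency is the first post-onset up-crossing of `threshold` by the trace
#' (linearly interpolated between bins); duration is the time from there to
#' the next down-crossing (interpolated; to the last bin if the trace never
#' comes back down). A trace that never crosses returns `NA` for both — an
#' undefined, not an error.
#'
#' @param z numeric trace (e.g. z-scored binned power).
#' @param time_ms bin centers in ms relative to onset.
#' @param threshold crossing threshold: 2 for averaged-trace latencies, 3 for
#'   the masking-style analysis (caller supplies).
#' @return one-row tibble: `latency_ms`, `duration_ms`.
#' @export
latency_duration <- function(z, time_ms, threshold = 3) {
  post <- which(time_ms >= 0)
  und <- tibble::tibble(latency_ms = NA_real_, duration_ms = NA_real_)
  if (length(post) < 2L) return(und)
  up <- NULL
  for (i in post[-length(post)]) {
    if (z[i] < threshold && z[i + 1L] >= threshold) {
      frac <- (threshold - z[i]) / (z[i + 1L] - z[i])
      up <- time_ms[i] + frac * (time_ms[i + 1L] - time_ms[i])
      i_up <- i + 1L
      break
    }
  }
  if (is.null(up)) {
    if (z[post[1L]] >= threshold) {        # already above at onset
      up <- time_ms[post[1L]]
      i_up <- post[1L]
    } else {
      return(und)
    }
  }
  dn <- time_ms[length(time_ms)]
  n <- length(z)
  if (i_up < n) for (i in i_up:(n - 1L)) {
    if (z[i] >= threshold && z[i + 1L] < threshold) {
      frac <- (z[i] - threshold) / (z[i] - z[i + 1L])
      dn <- time_ms[i] + frac * (time_ms[i + 1L] - time_ms[i])
      break
    }
  }
  tibble::tibble(latency_ms = up, duration_ms = dn - up)
}

#' Correlation of connection strength with response power
#'
#' Checks whether the Granger strengths are an independent measurement or
#' merely reflect the power of the connected leads: Pearson correlation of C
#' with the source lead's peak response power, the target lead's, and their
#' product. Zero-variance inputs return `NA` for the affected coefficient.
#'
#' @param strengths tibble with columns `source`, `target`, `C` (e.g. from
#'   [connection_strength()]).
#' @param powers tibble with columns `lead_id`, `peak_power` (per-lead peak
#'   response power, any consistent units).
#' @return one-row tibble: `r_source`, `r_target`, `r_product`, `n_pairs`.
#' @export
gc_power_correlation <- function(strengths, powers) {
  d <- strengths |>
    dplyr::inner_join(powers, by = c(source = "lead_id")) |>
    dplyr::rename(source_power = "peak_power") |>
    dplyr::inner_join(powers, by = c(target = "lead_id")) |>
    dplyr::rename(target_power = "peak_power")
  if (nrow(d) < 3L) stop("need >= 3 pairs", call. = FALSE)
  safe_cor <- function(x, y) {
    if (stats::sd(x) == 0 || stats::sd(y) == 0) NA_real_ else stats::cor(x, y)
  }
  tibble::tibble(
    r_source = safe_cor(d$C, d$source_power),
    r_target = safe_cor(d$C, d$target_power),
    r_product = safe_cor(d$C, d$source_power * d$target_power),
    n_pairs = nrow(d)
  )
}
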