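#' Pipeline configuration with published defaults
#'
#' Collects every tunable parameter of the pipeline in one list, each with the
#' default used in the original analysis where one is stated. The resolved
#' configuration is serialized alongside every stage output so a run can be
#' audited and reproduced.
#'
#' @param bivariate_reject_percentile percentile of the bivariate-Gaussian
#'   reference above which robust Mahalanobis distances flag a trial for a
#'   lead; ranged 90-99 in practice, default 97.5 (threshold 2.7162).
#' @param wavelet_low_cutoff_hz blobs with centroid frequency at or below this
#'   are ignored (default 10 Hz).
#' @param wavelet_blob_percentile pooled max-intensity percentile above which a
#'   largest-area blob flags its (trial, lead) (default 95).
#' @param trial_reject_lead_threshold a trial slated by the trial-based
#'   detectors is removed only if it holds more than this many bivariate
#'   feature outliers (range 5-10, default 5).
#' @param glitch_threshold_factor scaled-MAD multiple for glitch maxima
#'   (default 10; a per-dataset parameter in practice — a genuine glitch is a
#'   coherent jump far above the diff-noise maxima, and a high factor keeps
#'   the detector specific).
#' @param amplitude_threshold_factor scaled-MAD multiple for trial amplitude
#'   maxima (default 3).
#' @param flatness_winlen,flatness_winstep,flatness_replen flat-segment
#'   detector: window length and step (samples) over the flat-difference
#'   labels, and the count of all-flat windows above which a (trial, lead) is
#'   removed. Defaults 100, 50, 2.
#' @param interictal_winlen,interictal_winstep,interictal_maxlag,interictal_nbins
#'   coherent-event detector: sliding window length 400 samples, step 50,
#'   cross-correlation lags -150..150, 20 histogram bins.
#' @param gc_window_samples sliding Granger window length at the base rate
#'   (default 100 samples = 100 ms at 1 kHz).
#' @param gc_offset_samples window step (default 10 samples).
#' @param gc_lags model order (default 4 lags).
#' @param ns_factors sample-spacing settings; 1, 2, 4 give maximum modelled
#'   delays of 4, 8, 16 ms at 4 lags and 1 kHz.
#' @param n_bootstrap,n_surrogate number of bootstrap / trial-permutation
#'   surrogate recomputations (default 20 each).
#' @param strong_z,medium_z z thresholds for strong (5) and medium (3)
#'   connections.
#' @param strength_window_s response interval for the signed strength C,
#'   default `c(0.1, 0.4)` s after static onset.
#' @param baseline_window_s baseline interval for z-scoring, default
#'   `c(-0.9, 0)` s relative to onset.
#' @param min_common_trials minimum unmasked trials shared by a pair before it
#'   is analysed (default 12).
#' @param power_bin_ms gamma-power bin width (default 25 ms).
#' @param power_band gamma band limits, default `c(50, 150)` Hz averaged over
#'   ten 10-Hz sub-bands.
#' @param power_wavelet `"morse"` (default, consistent with the rejection
#'   stage) or `"morlet"`.
#' @param responsive_z threshold on the static-epoch z (default 3).
#' @param onset_search_window_s search window for the half-peak onset
#'   estimator, default `c(0.05, 0.5)` s (covers observed 165-201 ms response
#'   latencies with margin).
#' @param rng_seed integer seed recorded with every stochastic stage.
#'
#' @return a named list of class `pipeline_config`.
#' @export
pipeline_config <- function(bivariate_reject_percentile = 97.5,
                            wavelet_low_cutoff_hz = 10,
                            wavelet_blob_percentile = 95,
                            trial_reject_lead_threshold = 5,
                            glitch_threshold_factor = 10,
                            amplitude_threshold_factor = 3,
                            flatness_winlen = 100,
                            flatness_winstep = 50,
                            flatness_replen = 2,
                            interictal_winlen = 400,
                            interictal_winstep = 50,
                            interictal_maxlag = 150,
                            interictal_nbins = 20,
                            gc_window_samples = 100,
                            gc_offset_samples = 10,
                            gc_lags = 4,
                            ns_factors = c(1, 2, 4),
                            n_bootstrap = 20,
                            n_surrogate = 20,
                            strong_z = 5,
                            medium_z = 3,
                            strength_window_s = c(0.1, 0.4),
                            baseline_window_s = c(-0.9, 0),
                            min_common_trials = 12,
                            power_bin_ms = 25,
                            power_band = c(50, 150),
                            power_wavelet = c("morse", "morlet"),
                            responsive_z = 3,
                            onset_search_window_s = c(0.05, 0.5),
                            rng_seed = 1L) {
  power_wavelet <- match.arg(power_wavelet)
  cfg <- as.list(environment())
  validate_config(structure(cfg, class = "pipeline_config"))
}

validate_config <- function(cfg) {
  stopifnot(
    cfg$bivariate_reject_percentile > 0, cfg$bivariate_reject_percentile < 100,
    cfg$gc_window_samples > 0, cfg$gc_offset_samples > 0, cfg$gc_lags >= 1,
    all(cfg$ns_factors >= 1), cfg$n_bootstrap >= 2, cfg$n_surrogate >= 2,
    length(cfg$strength_window_s) == 2L,
    length(cfg$baseline_window_s) == 2L,
    cfg$strength_window_s[1] < cfg$strength_window_s[2],
    cfg$baseline_window_s[1] < cfg$baseline_window_s[2]
  )
  cfg
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("<pipeline_config>\n")
  for (nm in names(x)) {
    cat("  ", format(nm, width = 30), ": ",
        paste(format(x[[nm]]), collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Serialize / restore a pipeline configuration
#'
#' JSON round-trip used to embed the exact parameter set in every stage
#' output directory.
#'
#' @param config a [pipeline_config()].
#' @param path file path (`.json`).
#' @return `write_config` returns `path` invisibly; `read_config` returns the
#'   restored `pipeline_config`.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- pipeline_config()
  unknown <- setdiff(names(raw), names(cfg))
  if (length(unknown)) {
    stop("unknown config field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg[names(raw)] <- raw
  validate_config(structure(cfg, class = "pipeline_config"))
}
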