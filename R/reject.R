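#' Remove a linear trend from one trace
#'
#' Residual of the least-squares line fit; the output has (numerically) zero
#' mean and is orthogonal to both the constant and the linear regressor. A
#' constant or exactly linear trace detrends to all zeros.
#'
#' @param series numeric vector of length >= 2.
#' @return detrended numeric vector.
#' @export
detrend_trial <- function(series) {
  n <- length(series)
  stopifnot(n >= 2L)
  t <- seq_len(n) - (n + 1) / 2            # centered time regressor
  beta <- sum(t * series) / sum(t * t)
  series - mean(series) - beta * t
}

# detrend every valid (lead, trial) trace of a tensor
detrend_tensor <- function(tensor) {
  d <- dim(tensor$data)
  valid <- valid_combinations(tensor)
  for (l in seq_len(d[1L])) for (tr in seq_len(d[2L])) {
    if (valid[l, tr]) {
      tensor$data[l, tr, ] <- detrend_trial(tensor$data[l, tr, ])
    }
  }
  tensor
}

#' Mahalanobis threshold of the bivariate-Gaussian reference
#'
#' The distance below which `percentile`% of samples from a bivariate Gaussian
#' lie: `sqrt(qchisq(percentile/100, df = 2))`. At 97.5 this is 2.7162.
#'
#' @param percentile percentile in (0, 100).
#' @return scalar distance threshold.
#' @export
mahalanobis_threshold <- function(percentile = 97.5) {
  sqrt(stats::qchisq(percentile / 100, df = 2))
}

#' Bivariate feature-vector outliers (robust Mahalanobis screen)
#'
#' For each lead separately, each valid trial is summarized by a two-component
#' feature vector: log high-gamma (50-150 Hz) power (Welch estimate summed
#' over the band) and log SD over time. Components below `1e-42` are dropped
#' before taking logs. A robust center and covariance are estimated by the
#' minimum-covariance-determinant method and trials whose robust Mahalanobis
#' distance exceeds [mahalanobis_threshold()] at
#' `config$bivariate_reject_percentile` are flagged. Leads with fewer than 10
#' valid trials are skipped with a warning (robust covariance on 2 features
#' needs a margin over the parameter count).
#'
#' @param tensor a [trial_tensor()] (detrended traces expected; the pipeline
#'   wrapper [reject_artifacts()] detrends first).
#' @param percentile rejection percentile (default from `config`).
#' @param config a [pipeline_config()].
#' @return logical `leads x trials` matrix; `TRUE` = flagged.
#' @export
feature_vector_outliers <- function(tensor,
                                    percentile = config$bivariate_reject_percentile,
                                    config = pipeline_config()) {
  d <- dim(tensor$data)
  valid <- valid_combinations(tensor)
  out <- matrix(FALSE, d[1L], d[2L])
  thr <- mahalanobis_threshold(percentile)
  for (l in seq_len(d[1L])) {
    trs <- which(valid[l, ])
    if (length(trs) < 10L) {
      warning("feature_vector_outliers: lead ", l,
              " has < 10 valid trials; skipped")
      next
    }
    pw <- vapply(trs, function(tr) {
      band_power(tensor$data[l, tr, ], tensor$fs, band = config$power_band)
    }, numeric(1))
    sdv <- vapply(trs, function(tr) stats::sd(tensor$data[l, tr, ]), numeric(1))
    ok <- pw >= 1e-42 & sdv >= 1e-42
    X <- cbind(log(pw[ok]), log(sdv[ok]))
    if (nrow(X) < 10L) {
      warning("feature_vector_outliers: lead ", l,
              " has < 10 usable trials after the low-value screen; skipped")
      next
    }
    rob <- MASS::cov.rob(X, method = "mcd")
    # reweighting step of the standard MCD pipeline: classical estimate over
    # the points inside the 97.5% gate, corrected for truncation shrinkage
    d2 <- stats::mahalanobis(X, rob$center, rob$cov)
    gate <- stats::qchisq(0.975, df = 2)
    w <- d2 <= gate
    if (sum(w) >= 5L) {
      cfac <- stats::pchisq(gate, df = 4) / 0.975
      ctr <- colMeans(X[w, , drop = FALSE])
      cv <- stats::cov(X[w, , drop = FALSE]) / cfac
      d2 <- stats::mahalanobis(X, ctr, cv)
    }
    # finite-sample consistency: align the distance median with its
    # chi-square reference so the percentile gate is calibrated at any n
    med <- stats::median(d2)
    if (med > 0) d2 <- d2 * stats::qchisq(0.5, df = 2) / med
    out[l, trs[ok][sqrt(d2) > thr]] <- TRUE
  }
  out
}

#' Wavelet transient-blob outliers
#'
#' Per valid (trial, lead) trace: continuous wavelet transform (analytic
#' Morse, symmetry 3, time-bandwidth 60, 10 voices per octave), magnitude,
#' time downsampled by 10, scales restricted to > 10 Hz, binarized at the
#' image's 95th percentile, holes filled, 8-connected components labelled,
#' and the largest-area blob kept. Largest blobs are pooled across all
#' combinations ("global" pooling); a combination is flagged when its blob has
#' centroid frequency above `low_cutoff_hz` and max intensity strictly above
#' the pooled `blob_percentile` (ties at the boundary are not flagged).
#'
#' @inheritParams feature_vector_outliers
#' @param low_cutoff_hz centroid-frequency gate (default from `config`).
#' @param blob_percentile pooled intensity percentile (default from `config`).
#' @return logical `leads x trials` matrix.
#' @export
wavelet_blob_outliers <- function(tensor,
                                  low_cutoff_hz = config$wavelet_low_cutoff_hz,
                                  blob_percentile = config$wavelet_blob_percentile,
                                  config = pipeline_config()) {
  d <- dim(tensor$data)
  out <- matrix(FALSE, d[1L], d[2L])
  if (any(d == 0L)) return(out)
  valid <- valid_combinations(tensor)
  tms <- time_ms(tensor)
  blobs <- vector("list", d[1L] * d[2L])
  idx <- 0L
  for (l in seq_len(d[1L])) for (tr in seq_len(d[2L])) {
    if (!valid[l, tr]) next
    bb <- .largest_blob(tensor$data[l, tr, ], tensor$fs, tms)
    if (is.null(bb)) next
    idx <- idx + 1L
    bb$lead <- l; bb$trial <- tr
    blobs[[idx]] <- bb
  }
  if (idx == 0L) return(out)
  pool <- dplyr::bind_rows(blobs[seq_len(idx)])
  cut <- stats::quantile(pool$max_intensity, blob_percentile / 100, names = FALSE)
  hit <- pool$centroid_freq_hz > low_cutoff_hz & pool$max_intensity > cut
  out[cbind(pool$lead[hit], pool$trial[hit])] <- TRUE
  out
}

#' One-dimensional earth-mover's distance between histograms
#'
#' Optimal-transport distance with ground distance = bin-index distance; for
#' one-dimensional histograms this is the L1 distance between the cumulative
#' distributions. Histograms are normalized to unit mass first.
#'
#' @param p,q non-negative vectors of equal length (histogram counts).
#' @return scalar distance in bin units; 0 for identical histograms.
#' @export
emd_1d <- function(p, q) {
  stopifnot(length(p) == length(q), all(p >= 0), all(q >= 0))
  if (sum(p) == 0 || sum(q) == 0) return(0)
  sum(abs(cumsum(p / sum(p) - q / sum(q))))
}

#' Detect trials carrying coherent (putative interictal) events
#'
#' Per trial: each lead's trace is z-scored; over sliding windows
#' (`interictal_winlen` samples, step `interictal_winstep`) the maximum over
#' lags (+-`interictal_maxlag`) of the absolute normalized cross-correlation
#' is computed per lead pair, keeping the max across windows. The off-diagonal
#' entries of the resulting per-trial correlation matrix are histogrammed
#' (`interictal_nbins` bins, common edges across trials); pairwise
#' earth-mover's distances between trial histograms are clustered into two
#' fuzzy groups and the smaller group (in trial count) is returned as the
#' outlier candidates.
#'
#' A degeneracy guard handles statistically exchangeable trials, where no
#' coherent-event cluster exists: if both clusters' maximum membership is
#' below 0.6, or the smaller cluster holds more than 40% of trials, an empty
#' set is returned with a warning.
#'
#' @inheritParams feature_vector_outliers
#' @return integer vector of candidate trial indices (possibly empty).
#' @export
interictal_trial_detector <- function(tensor, config = pipeline_config()) {
  d <- dim(tensor$data)
  if (d[2L] < 3L || d[1L] < 2L) stop("need >= 3 trials and >= 2 leads", call. = FALSE)
  winlen <- config$interictal_winlen
  winstep <- config$interictal_winstep
  maxlag <- config$interictal_maxlag
  nbins <- config$interictal_nbins
  n <- d[3L]
  winlen <- min(winlen, n)
  starts <- seq(1L, max(1L, n - winlen + 1L), by = winstep)
  nfft <- stats::nextn(winlen + maxlag, 2)
  pairs <- utils::combn(d[1L], 2L)

  offdiag <- matrix(NA_real_, ncol(pairs), d[2L])
  for (tr in seq_len(d[2L])) {
    z <- matrix(tensor$data[, tr, ], nrow = d[1L])
    mu <- rowMeans(z)
    sdl <- apply(z, 1L, stats::sd)
    sdl[sdl == 0] <- 1                      # flat lead: leave as zeros
    z <- (z - mu) / sdl                     # z-score each lead over the trial
    best <- rep(-Inf, ncol(pairs))
    for (s in starts) {
      seg <- z[, s:(s + winlen - 1L), drop = FALSE]
      seg <- seg - rowMeans(seg)
      sds <- sqrt(rowSums(seg^2))
      F <- t(apply(seg, 1L, function(v) stats::fft(c(v, numeric(nfft - winlen)))))
      for (pp in seq_len(ncol(pairs))) {
        a <- pairs[1L, pp]; b <- pairs[2L, pp]
        if (sds[a] == 0 || sds[b] == 0) next
        cc <- Re(stats::fft(F[a, ] * Conj(F[b, ]), inverse = TRUE)) / nfft
        lags_pos <- cc[1:(maxlag + 1L)]
        lags_neg <- cc[(nfft - maxlag + 1L):nfft]
        m <- max(abs(c(lags_neg, lags_pos))) / (sds[a] * sds[b])
        if (m > best[pp]) best[pp] <- m
      }
    }
    offdiag[, tr] <- best
  }
  rng <- range(offdiag, finite = TRUE)
  if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5)
  edges <- seq(rng[1], rng[2], length.out = nbins + 1L)
  H <- apply(offdiag, 2L, function(v) {
    v <- v[is.finite(v)]
    graphics::hist(pmin(pmax(v, rng[1]), rng[2]), breaks = edges,
                   plot = FALSE)$counts
  })
  nt <- d[2L]
  D <- matrix(0, nt, nt)
  for (i in seq_len(nt - 1L)) for (j in (i + 1L):nt) {
    D[i, j] <- D[j, i] <- emd_1d(H[, i], H[, j])
  }
  # fuzzy c-means on the rows of the distance matrix (each trial's vector of
  # EMD distances to every other trial is its feature vector)
  memb <- tryCatch(.fuzzy_cmeans(D, k = 2L, seed = config$rng_seed),
                   error = function(e) NULL)
  if (is.null(memb)) {
    warning("interictal_trial_detector: clustering failed; no trials flagged")
    return(integer())
  }
  assign_cl <- max.col(memb)
  sizes <- tabulate(assign_cl, nbins = 2L)
  if (max(memb[, 1L]) < 0.6 && max(memb[, 2L]) < 0.6) {
    warning("interictal_trial_detector: degenerate clustering; no trials flagged")
    return(integer())
  }
  small <- which.min(sizes)
  if (sizes[small] > 0.4 * nt) {
    warning("interictal_trial_detector: no coherent-event cluster; ",
            "no trials flagged")
    return(integer())
  }
  # separation guard: a genuine coherent-event cluster sits far outside the
  # bulk (order-of-magnitude separation), while exchangeable trials split
  # with between/within distance ratios near 1
  in_small <- assign_cl == small
  d_within <- mean(D[!in_small, !in_small][upper.tri(diag(sum(!in_small)))])
  d_between <- mean(D[in_small, !in_small])
  eps <- 1e-12
  if ((d_between + eps) / (d_within + eps) <= 3) {
    warning("interictal_trial_detector: candidate cluster not separated; ",
            "no trials flagged")
    return(integer())
  }
  sort(which(in_small))
}

# standard fuzzy c-means (Bezdek, fuzzifier m) on rows of X; returns the
# n x k membership matrix. Deterministic given `seed` (centers initialized
# from sampled rows). No installed package provides the algorithm.
.fuzzy_cmeans <- function(X, k = 2L, m = 2, max_iter = 200L, tol = 1e-8,
                          seed = 1L) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < k) stop("fewer observations than clusters", call. = FALSE)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  centers <- X[sample.int(n, k), , drop = FALSE]
  U <- matrix(1 / k, n, k)
  for (it in seq_len(max_iter)) {
    d2 <- vapply(seq_len(k), function(j) {
      rowSums((X - matrix(centers[j, ], n, ncol(X), byrow = TRUE))^2)
    }, numeric(n))
    d2 <- pmax(d2, 1e-300)
    w <- d2^(-1 / (m - 1))
    U_new <- w / rowSums(w)
    Um <- U_new^m
    centers <- t(Um) %*% X / colSums(Um)
    if (max(abs(U_new - U)) < tol) { U <- U_new; break }
    U <- U_new
  }
  U
}

# median +- k * scaled-MAD dispersion outliers. Strict >, so a zero MAD
# (identical values) flags exactly the values that deviate from the median,
# matching the behaviour of the standard routine.
.mad_outliers <- function(x, k = 3) {
  med <- stats::median(x)
  smad <- stats::mad(x)                    # 1.4826 * median(|x - med|)
  abs(x - med) > k * smad
}

#' Trial amplitude outliers
#'
#' Per trial, the statistic is the maximum over leads and time of the absolute
#' value; trials are flagged by the median +- `k` scaled-MAD dispersion rule
#' (`k = config$amplitude_threshold_factor`, default 3 — the named routine's
#' default settings).
#'
#' @inheritParams feature_vector_outliers
#' @return integer vector of candidate trial indices.
#' @export
trial_amplitude_outliers <- function(tensor, config = pipeline_config()) {
  d <- dim(tensor$data)
  if (d[2L] < 3L) stop("need >= 3 trials", call. = FALSE)
  valid <- valid_combinations(tensor)
  stat <- vapply(seq_len(d[2L]), function(tr) {
    leads <- which(valid[, tr])
    if (!length(leads)) return(NA_real_)
    max(abs(tensor$data[leads, tr, ]))
  }, numeric(1))
  which(.mad_outliers(stat, k = config$amplitude_threshold_factor))
}

#' Glitch (coherent jump) detector
#'
#' Per trial the time series `m[t]` = mean over leads of the absolute
#' difference between consecutive samples is formed; its local maxima are
#' pooled across trials and dispersion outliers at
#' `config$glitch_threshold_factor` scaled-MADs are located. Trials owning an
#' outlier maximum are returned.
#'
#' The default factor is 10: a genuine glitch is a simultaneous step on all
#' leads, orders of magnitude above the diff-noise maxima, while a high factor
#' keeps smooth data from being flagged and lets single-lead steps (diluted by
#' the mean across many leads) pass — the factor is a per-dataset parameter in
#' practice.
#'
#' @inheritParams feature_vector_outliers
#' @param threshold_factor scaled-MAD multiple (default from `config`).
#' @return integer vector of flagged trial indices.
#' @export
glitch_detector <- function(tensor,
                            threshold_factor = config$glitch_threshold_factor,
                            config = pipeline_config()) {
  d <- dim(tensor$data)
  stopifnot(d[3L] >= 2L)
  vals <- list(); owner <- list()
  for (tr in seq_len(d[2L])) {
    x <- matrix(tensor$data[, tr, ], nrow = d[1L])
    m <- colMeans(abs(x[, -1L, drop = FALSE] - x[, -d[3L], drop = FALSE]))
    n <- length(m)
    is_max <- c(FALSE, m[2:(n - 1L)] > m[1:(n - 2L)] & m[2:(n - 1L)] >= m[3:n], FALSE)
    vals[[tr]] <- m[is_max]
    owner[[tr]] <- rep(tr, sum(is_max))
  }
  v <- unlist(vals); ow <- unlist(owner)
  if (!length(v)) return(integer())
  sort(unique(ow[.mad_outliers(v, k = threshold_factor)]))
}

#' Flat (out-of-range) segment detector
#'
#' Samples where the successive difference is below `1e-10` are labelled flat;
#' windows of `winlen` samples stepped by `winstep` that are entirely flat are
#' counted, and a (trial, lead) combination is flagged when the count exceeds
#' `replen`. Run on raw (not detrended) data, since detrending perturbs exact
#' constancy.
#'
#' @inheritParams feature_vector_outliers
#' @param winlen,winstep,replen detector parameters (defaults from `config`).
#' @return logical `leads x trials` matrix.
#' @export
flatness_detector <- function(tensor,
                              winlen = config$flatness_winlen,
                              winstep = config$flatness_winstep,
                              replen = config$flatness_replen,
                              config = pipeline_config()) {
  d <- dim(tensor$data)
  stopifnot(winlen <= d[3L])
  out <- matrix(FALSE, d[1L], d[2L])
  starts <- seq(1L, d[3L] - 1L - winlen + 1L, by = winstep)
  for (l in seq_len(d[1L])) for (tr in seq_len(d[2L])) {
    flat <- abs(diff(tensor$data[l, tr, ])) < 1e-10
    cs <- cumsum(c(0L, as.integer(flat)))
    n_full <- sum(cs[starts + winlen] - cs[starts] == winlen)
    if (n_full > replen) out[l, tr] <- TRUE
  }
  out
}

#' Combine the six rejection criteria into one mask
#'
#' Trial-based candidates (coherent-event union amplitude outliers) are
#' removed as whole trials only when the trial holds more than
#' `lead_threshold` bivariate feature-vector outlier leads; glitch trials are
#' removed unconditionally. The combined `(lead, trial)` mask is the union of
#' the removed trials (all leads) with the feature-vector, wavelet-blob and
#' flatness masks.
#'
#' @param feature_vector,wavelet,flatness logical `leads x trials` matrices.
#' @param interictal,amplitude,glitch integer vectors of candidate trials.
#' @param lead_threshold whole-trial removal gate (default from `config`).
#' @param config a [pipeline_config()].
#' @return a `rejection_mask`: list with `per_criterion` (named list of the
#'   inputs), `removed_trials` (integer vector), and `combined` (logical
#'   `leads x trials`).
#' @export
combine_rejections <- function(feature_vector, wavelet, flatness,
                               interictal = integer(), amplitude = integer(),
                               glitch = integer(),
                               lead_threshold = config$trial_reject_lead_threshold,
                               config = pipeline_config()) {
  d <- dim(feature_vector)
  if (!identical(dim(wavelet), d) || !identical(dim(flatness), d)) {
    stop("per-criterion masks have mismatched shapes", call. = FALSE)
  }
  candidates <- sort(unique(c(interictal, amplitude)))
  n_bivar <- colSums(feature_vector)
  removed <- candidates[n_bivar[candidates] > lead_threshold]
  removed <- sort(unique(c(removed, glitch)))
  combined <- feature_vector | wavelet | flatness
  combined[, removed] <- TRUE
  structure(
    list(per_criterion = list(feature_vector = feature_vector,
                              wavelet = wavelet, flatness = flatness,
                              interictal = interictal, amplitude = amplitude,
                              glitch = glitch),
         removed_trials = removed, combined = combined),
    class = "rejection_mask"
  )
}

#' @export
print.rejection_mask <- function(x, ...) {
  cat("<rejection_mask> ", sum(x$combined), "/", length(x$combined),
      " (lead, trial) combinations rejected; ",
      length(x$removed_trials), " whole trials removed\n", sep = "")
  invisible(x)
}

#' Summarize a rejection mask
#'
#' Per-dataset summary mirroring the published per-patient rejection table:
#' lead count, total lead-trials, rejected lead-trials (union, not double
#' counted), fraction rejected, and median / minimum remaining trials per
#' lead.
#'
#' @param mask a `rejection_mask` from [combine_rejections()].
#' @param tensor the tensor the mask was computed on.
#' @return one-row tibble.
#' @export
rejection_report <- function(mask, tensor) {
  d <- dim(tensor$data)
  rej <- sum(mask$combined)
  kept_per_lead <- rowSums(!mask$combined)
  tibble::tibble(
    n_leads = d[1L],
    total_lead_trials = d[1L] * d[2L],
    rejected_lead_trials = rej,
    fraction_rejected = rej / (d[1L] * d[2L]),
    median_trials_per_lead = stats::median(kept_per_lead),
    min_trials_per_lead = min(kept_per_lead)
  )
}

#' Run the full artifact-rejection pipeline
#'
#' Detrends every trace, computes all six criteria (flatness on the raw data,
#' the others on detrended data, with gender and action trials pooled),
#' combines them per the whole-trial gate, and applies the resulting mask to
#' the tensor.
#'
#' @param tensor a [trial_tensor()].
#' @param config a [pipeline_config()].
#' @return list with `tensor` (masked copy), `mask` (the `rejection_mask`),
#'   and `report` (the [rejection_report()] tibble).
#' @export
reject_artifacts <- function(tensor, config = pipeline_config()) {
  # the MCD estimator subsamples internally; pin the stream for reproducibility
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(config$rng_seed)
  det <- detrend_tensor(tensor)
  fv <- feature_vector_outliers(det, config = config)
  wb <- wavelet_blob_outliers(det, config = config)
  fl <- flatness_detector(tensor, config = config)   # raw data
  ii <- interictal_trial_detector(det, config = config)
  am <- trial_amplitude_outliers(det, config = config)
  gl <- glitch_detector(det, config = config)
  mask <- combine_rejections(fv, wb, fl, interictal = ii, amplitude = am,
                             glitch = gl, config = config)
  masked <- mask_tensor(tensor, mask$combined)
  list(tensor = masked, mask = mask, report = rejection_report(mask, tensor))
}
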