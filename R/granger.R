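#' Trials usable for a lead pair
#'
#' Trials unmasked in *both* leads of the pair ("greedy" per-pair selection:
#' every pair gets its own trial set rather than the global intersection
#' across all leads, which would discard too much data).
#'
#' @param tensor a [trial_tensor()].
#' @param pair two lead ids or indices, ordered `(source, target)`.
#' @param task optional task filter (`"gender"`/`"action"`); `NULL` = all.
#' @param config a [pipeline_config()]; supplies `min_common_trials` (default
#'   12) below which the pair is skipped with a warning and an empty set is
#'   returned.
#' @return integer vector of trial indices (possibly empty).
#' @export
select_pair_trials <- function(tensor, pair, task = NULL,
                               config = pipeline_config()) {
  li <- resolve_lead(tensor, pair)
  stopifnot(length(li) >= 2L)
  valid <- valid_combinations(tensor)
  common <- which(apply(valid[li, , drop = FALSE], 2L, all))
  if (!is.null(task)) {
    common <- intersect(common, which(tensor$trial_labels$task == task))
  }
  if (length(common) < config$min_common_trials) {
    warning("pair (", paste(pair, collapse = ", "), "): only ",
            length(common), " common trials (< ", config$min_common_trials,
            "); pair skipped")
    return(integer())
  }
  common
}

# sliding-window grid at the base sampling rate
.gc_windows <- function(tensor, config) {
  W <- config$gc_window_samples
  step <- config$gc_offset_samples
  n <- n_samples(tensor)
  starts <- seq(1L, n - W + 1L, by = step)
  t0 <- (starts - 1L - tensor$onset_index) / tensor$fs * 1000
  tibble::tibble(
    window = seq_along(starts), start = starts, end = starts + W,
    window_start_ms = t0,
    window_end_ms = t0 + W / tensor$fs * 1000,
    window_center_ms = t0 + W / tensor$fs * 500
  )
}

# pooled-trial least-squares VAR fit on a (possibly decimated) window.
# dat: list of L matrices (trials x samples). Returns coefficient matrices,
# full residual covariance, and reduced residual variances (target excluding
# one source).
.var_fit_core <- function(dat, p, ridge_rcond = 1e-10) {
  L <- length(dat); Tr <- nrow(dat[[1L]]); S <- ncol(dat[[1L]])
  if (S <= p + 1L) stop("window too short for ", p, " lags", call. = FALSE)
  rows <- (p + 1L):S
  nr <- length(rows); N <- Tr * nr
  # rows are ordered (trial within time); any consistent ordering is valid LS
  Y <- matrix(0, N, L)
  X <- matrix(0, N, L * p + 1L)
  X[, 1L] <- 1
  for (l in seq_len(L)) {
    Bl <- dat[[l]]
    Y[, l] <- Bl[, rows]
    for (j in seq_len(p)) {
      X[, 1L + (j - 1L) * L + l] <- Bl[, rows - j]
    }
  }
  XtX <- crossprod(X)
  XtY <- crossprod(X, Y)
  YtY <- crossprod(Y)
  if (rcond(XtX) < ridge_rcond) {
    XtX <- XtX + diag(1e-8 * sum(diag(XtX)) / ncol(XtX), ncol(XtX))
  }
  B <- solve(XtX, XtY)
  Sigma <- (YtY - crossprod(XtY, B) - crossprod(B, XtY) +
              crossprod(B, XtX %*% B)) / N
  # reduced models: for every (excluded source s, target t)
  red <- matrix(NA_real_, L, L)
  for (s in seq_len(L)) {
    keep <- c(1L, setdiff(seq_len(L * p) + 1L,
                          1L + (seq_len(p) - 1L) * L + s))
    XtXk <- XtX[keep, keep]
    for (t in seq_len(L)) {
      if (t == s) next
      b <- solve(XtXk, XtY[keep, t])
      rss <- YtY[t, t] - 2 * sum(b * XtY[keep, t]) +
        sum(b * (XtXk %*% b))
      red[s, t] <- rss / N
    }
  }
  list(B = B, Sigma = Sigma, sigma_reduced = red, n_obs = N, L = L, p = p)
}

#' Fit a pooled-trial VAR to one analysis window
#'
#' Ordinary least squares over pooled trial-wise regressor rows (each trial
#' contributes `samples - lags` rows after decimation by `ns_factor`). The
#' normal equations are ridge-regularized (`1e-8 * trace(X'X)/p` on the
#' diagonal) only when the reciprocal condition number falls below `1e-10`.
#'
#' @param window_data numeric array `leads x trials x samples` at the base
#'   sampling rate (two leads for pairwise, three for conditioned analysis).
#' @param order VAR model order (lags); must be >= 1.
#' @param ns_factor sample spacing: every `ns_factor`-th sample is kept before
#'   fitting (plain decimation, matching doubling/quadrupling the distance
#'   between samples; no anti-alias filter).
#' @return object of class `var_fit`: coefficient array `coef[target, source,
#'   lag]`, `intercept`, residual covariance `Sigma`, matrix `sigma_reduced`
#'   (`[s, t]` = residual variance of target `t` when source `s` is excluded),
#'   `n_obs`, `order`, `ns_factor`.
#' @export
fit_var_window <- function(window_data, order = 4, ns_factor = 1) {
  if (order < 1L) stop("`order` must be >= 1", call. = FALSE)
  stopifnot(is.array(window_data), length(dim(window_data)) == 3L)
  idx <- seq(1L, dim(window_data)[3L], by = ns_factor)
  dat <- lapply(seq_len(dim(window_data)[1L]), function(l) {
    matrix(window_data[l, , idx], nrow = dim(window_data)[2L])
  })
  f <- .var_fit_core(dat, order)
  L <- f$L
  coef <- array(0, dim = c(L, L, order))
  for (j in seq_len(order)) {
    # column block j of B (beyond intercept) holds lag-j coefficients
    coef[, , j] <- t(f$B[1L + (j - 1L) * L + seq_len(L), , drop = FALSE])
  }
  structure(list(coef = coef, intercept = f$B[1L, ], Sigma = f$Sigma,
                 sigma_reduced = f$sigma_reduced, n_obs = f$n_obs,
                 order = order, ns_factor = ns_factor),
            class = "var_fit")
}

#' @export
print.var_fit <- function(x, ...) {
  cat("<var_fit> ", nrow(x$Sigma), " leads, order ", x$order,
      ", ns ", x$ns_factor, ", ", x$n_obs, " pooled rows\n", sep = "")
  invisible(x)
}

# time-domain GC for ordered directions from a core fit:
# F(src -> tgt) = log(sigma2_reduced / Sigma[tgt, tgt])
.gc_from_fit <- function(f, directions) {
  vapply(seq_len(nrow(directions)), function(k) {
    s <- directions[k, 1L]; t <- directions[k, 2L]
    log(f$sigma_reduced[s, t] / f$Sigma[t, t])
  }, numeric(1))
}

# raw GC time course. leads_idx: lead indices entering the model (2 or 3);
# trials_mat: n x length(leads_idx) matrix of trial indices per lead;
# directions: matrix of (src, tgt) positions within leads_idx.
.gc_trace_raw <- function(tensor, leads_idx, trials_mat, ns, config,
                          directions) {
  wins <- .gc_windows(tensor, config)
  L <- length(leads_idx)
  dat <- lapply(seq_len(L), function(l) {
    matrix(tensor$data[leads_idx[l], trials_mat[, l], ],
           nrow = nrow(trials_mat))
  })
  Fm <- matrix(NA_real_, nrow(wins), nrow(directions))
  W <- config$gc_window_samples
  keep <- seq(1L, W, by = ns)
  for (w in seq_len(nrow(wins))) {
    cols <- (wins$start[w] - 1L) + keep
    dw <- lapply(dat, function(m) m[, cols, drop = FALSE])
    f <- .var_fit_core(dw, config$gc_lags)
    Fm[w, ] <- .gc_from_fit(f, directions)
  }
  Fm
}

#' Pairwise unconditioned Granger causality over sliding windows
#'
#' Fits a bivariate VAR (`config$gc_lags` lags) in every 100-sample window
#' stepped by 10 samples over the trial, pooling the pair's common trials, and
#' returns the time-domain Granger statistic
#' `F = ln(sigma2_reduced / sigma2_full)` for both directions. `ns_factor`
#' sets the sample spacing: 1, 2, 4 give maximum modelled delays of 4, 8,
#' 16 ms at 4 lags and a 1 kHz base rate (the NS1/NS2/NS4 settings).
#'
#' @inheritParams select_pair_trials
#' @param ns_factor sample-spacing setting (1, 2 or 4).
#' @param trials optional explicit trial set (defaults to
#'   [select_pair_trials()]).
#' @return a `gc_trace` tibble: `source`, `target`, `ns_factor`, `window`,
#'   `window_start_ms`, `window_center_ms`, `window_end_ms`, `F` (one row per
#'   window and direction). Empty when the pair is skipped.
#' @export
pairwise_ugc <- function(tensor, pair, ns_factor = 1,
                         config = pipeline_config(), task = NULL,
                         trials = NULL) {
  li <- resolve_lead(tensor, pair)
  if (is.null(trials)) {
    trials <- select_pair_trials(tensor, pair, task = task, config = config)
  }
  ids <- tensor$leads$lead_id[li]
  if (!length(trials)) return(.empty_gc_trace())
  dirs <- rbind(c(1L, 2L), c(2L, 1L))
  Fm <- .gc_trace_raw(tensor, li, cbind(trials, trials), ns_factor, config, dirs)
  wins <- .gc_windows(tensor, config)
  out <- dplyr::bind_rows(
    dplyr::mutate(wins, source = ids[1L], target = ids[2L], F = Fm[, 1L]),
    dplyr::mutate(wins, source = ids[2L], target = ids[1L], F = Fm[, 2L])
  )
  out$ns_factor <- ns_factor
  out <- dplyr::select(out, "source", "target", "ns_factor", "window",
                       "window_start_ms", "window_center_ms", "window_end_ms",
                       "F")
  class(out) <- c("gc_trace", class(out))
  out
}

.empty_gc_trace <- function() {
  out <- tibble::tibble(source = character(), target = character(),
                        ns_factor = numeric(), window = integer(),
                        window_start_ms = numeric(),
                        window_center_ms = numeric(),
                        window_end_ms = numeric(), F = numeric())
  class(out) <- c("gc_trace", class(out))
  out
}

#' Surrogate normalization of a pairwise GC trace
#'
#' Recomputes the pair's GC with the trials of each lead independently
#' permuted (`n` runs, breaking any trial-locked coupling while preserving
#' each lead's marginal statistics), and z-scores the observed trace against
#' the surrogate mean and SD per window and direction:
#' `z_surr = (F - mean_surr) / sd_surr`. Windows with zero surrogate SD get
#' `NA`.
#'
#' @inheritParams pairwise_ugc
#' @param n number of surrogate runs (default `config$n_surrogate` = 20).
#' @param seed RNG seed (default `config$rng_seed`); surrogate permutations
#'   consume a dedicated, recorded stream.
#' @return the `gc_trace` tibble with added columns `surr_mean`, `surr_sd`,
#'   `z_surr`.
#' @export
surrogate_normalize <- function(tensor, pair, ns_factor = 1,
                                config = pipeline_config(), task = NULL,
                                trials = NULL, n = config$n_surrogate,
                                seed = config$rng_seed) {
  stopifnot(n >= 2L)
  li <- resolve_lead(tensor, pair)
  if (is.null(trials)) {
    trials <- select_pair_trials(tensor, pair, task = task, config = config)
  }
  if (!length(trials)) return(.empty_gc_trace())
  raw <- pairwise_ugc(tensor, pair, ns_factor = ns_factor, config = config,
                      trials = trials)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  dirs <- rbind(c(1L, 2L), c(2L, 1L))
  nt <- length(trials)
  acc <- acc2 <- matrix(0, nrow(raw) / 2L, 2L)
  for (r in seq_len(n)) {
    tm <- cbind(trials[sample.int(nt)], trials[sample.int(nt)])
    Fs <- .gc_trace_raw(tensor, li, tm, ns_factor, config, dirs)
    acc <- acc + Fs
    acc2 <- acc2 + Fs^2
  }
  mu <- acc / n
  sdv <- sqrt(pmax(acc2 / n - mu^2, 0) * n / (n - 1))
  raw$surr_mean <- c(mu[, 1L], mu[, 2L])
  raw$surr_sd <- c(sdv[, 1L], sdv[, 2L])
  raw$z_surr <- ifelse(raw$surr_sd > 0, (raw$F - raw$surr_mean) / raw$surr_sd,
                       NA_real_)
  raw
}

#' Bootstrap variability of a pairwise GC trace
#'
#' Recomputes the GC on `n` trial resamples (with replacement, the same
#' resample applied to both leads) to estimate the statistical variability due
#' to the limited trial count.
#'
#' @inheritParams surrogate_normalize
#' @param n number of bootstrap runs (default `config$n_bootstrap` = 20).
#' @return the `gc_trace` tibble with added columns `boot_mean`, `boot_sd`.
#' @export
bootstrap_gc <- function(tensor, pair, ns_factor = 1,
                         config = pipeline_config(), task = NULL,
                         trials = NULL, n = config$n_bootstrap,
                         seed = config$rng_seed) {
  stopifnot(n >= 2L)
  li <- resolve_lead(tensor, pair)
  if (is.null(trials)) {
    trials <- select_pair_trials(tensor, pair, task = task, config = config)
  }
  if (!length(trials)) return(.empty_gc_trace())
  raw <- pairwise_ugc(tensor, pair, ns_factor = ns_factor, config = config,
                      trials = trials)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed + 1L)
  dirs <- rbind(c(1L, 2L), c(2L, 1L))
  nt <- length(trials)
  acc <- acc2 <- matrix(0, nrow(raw) / 2L, 2L)
  for (r in seq_len(n)) {
    bs <- trials[sample.int(nt, replace = TRUE)]
    Fs <- .gc_trace_raw(tensor, li, cbind(bs, bs), ns_factor, config, dirs)
    acc <- acc + Fs
    acc2 <- acc2 + Fs^2
  }
  mu <- acc / n
  sdv <- sqrt(pmax(acc2 / n - mu^2, 0) * n / (n - 1))
  raw$boot_mean <- c(mu[, 1L], mu[, 2L])
  raw$boot_sd <- c(sdv[, 1L], sdv[, 2L])
  raw
}

#' Baseline z-scoring of a GC trace
#'
#' Isolates the phasic component: per direction (and ns setting), the trace is
#' z-scored against the mean and SD of the windows lying wholly inside the
#' baseline period (default -900..0 ms relative to static onset). Applied to
#' the raw GC by default; more variable baselines therefore yield smaller
#' z-scores, and negative z marks task-related suppression of a causal
#' influence.
#'
#' @param trace a `gc_trace` tibble.
#' @param baseline_window_s baseline interval in s relative to onset.
#' @param value column to z-score (default `"F"`).
#' @return the tibble with added column `z_base` (`NA` where the baseline SD
#'   is zero).
#' @export
baseline_zscore_gc <- function(trace, baseline_window_s = c(-0.9, 0),
                               value = "F") {
  lo <- baseline_window_s[1] * 1000
  hi <- baseline_window_s[2] * 1000
  trace |>
    dplyr::group_by(.data$source, .data$target, .data$ns_factor) |>
    dplyr::mutate(
      z_base = {
        base <- .data[[value]][.data$window_start_ms >= lo &
                                 .data$window_end_ms <= hi]
        if (length(base) < 2L || stats::sd(base) == 0) {
          NA_real_
        } else {
          (.data[[value]] - mean(base)) / stats::sd(base)
        }
      }
    ) |>
    dplyr::ungroup()
}

#' Signed connection strength C
#'
#' Summarizes a baseline-z GC trace by the extreme value in the response
#' window (default 0.1-0.4 s after static onset). With `mx`/`mn` the maximum
#' and minimum z in the window: both positive gives `C = mx`; both negative
#' gives `C = mn`; mixed signs give the mean of the two when their absolute
#' values differ by less than 3, else whichever has the larger absolute value
#' (with its sign). The rule yields one signed strength even for bimodal
#' response profiles.
#'
#' @param trace a `gc_trace` tibble with a `z_base` column (see
#'   [baseline_zscore_gc()]).
#' @param response_window_s response interval in s (default `c(0.1, 0.4)`).
#' @param value column summarized (default `"z_base"`).
#' @return tibble with one row per (source, target, ns_factor): `C`, `z_max`,
#'   `z_min`.
#' @export
connection_strength <- function(trace, response_window_s = c(0.1, 0.4),
                                value = "z_base") {
  lo <- response_window_s[1] * 1000
  hi <- response_window_s[2] * 1000
  in_win <- trace$window_center_ms >= lo & trace$window_center_ms < hi
  if (!any(in_win)) stop("no GC windows inside the response window", call. = FALSE)
  trace[in_win, ] |>
    dplyr::group_by(.data$source, .data$target, .data$ns_factor) |>
    dplyr::summarise(
      z_max = max(.data[[value]], na.rm = TRUE),
      z_min = min(.data[[value]], na.rm = TRUE),
      C = strength_rule(z_max, z_min),
      .groups = "drop"
    )
}

#' @rdname connection_strength
#' @param mx,mn maximum and minimum z in the response window.
#' @export
strength_rule <- function(mx, mn) {
  if (mx >= 0 && mn >= 0) return(mx)
  if (mx <= 0 && mn <= 0) return(mn)
  if (abs(abs(mx) - abs(mn)) < 3) (mx + mn) / 2 else if (abs(mx) >= abs(mn)) mx else mn
}

#' Type a connection from its two-delay strengths
#'
#' Combines the signed strengths at the short (NS1, max 4 ms) and long (NS4,
#' max 16 ms) delay settings into the published types, with `strong_z = 5`
#' (strict `>`; ties at the threshold fall to the weaker category):
#' \describe{
#'   \item{D (disappear)}{strong only at the short delay.}
#'   \item{M (maintain)}{strong at both delays.}
#'   \item{A (appear)}{strong only at the long delay, short not strong of
#'     either sign.}
#'   \item{N (negative)}{strongly suppressed at the long delay, short below
#'     strong.}
#'   \item{opposite}{a strong value flipping sign between delays; excluded
#'     from downstream statistics.}
#'   \item{weak}{none of the above.}
#' }
#'
#' @param C_ns1,C_ns4 numeric vectors of signed strengths.
#' @param strong_z strong threshold (default 5).
#' @return character vector of types.
#' @export
classify_connection <- function(C_ns1, C_ns4, strong_z = 5) {
  stopifnot(length(C_ns1) == length(C_ns4))
  mapply(function(c1, c4) {
    sp1 <- c1 > strong_z; sn1 <- c1 < -strong_z
    sp4 <- c4 > strong_z; sn4 <- c4 < -strong_z
    if ((sp1 && sn4) || (sn1 && sp4)) return("opposite")
    if (sp1 && sp4) return("M")
    if (sp1) return("D")
    if (!sp1 && !sn1 && sp4) return("A")
    if (sn4 && c1 < strong_z) return("N")
    "weak"
  }, C_ns1, C_ns4, USE.NAMES = FALSE)
}

#' Two-delay connection summary for a set of ordered pairs
#'
#' Convenience wrapper: computes the baseline-z strength C at NS1 and NS4 for
#' each ordered pair and types the connection.
#'
#' @param tensor a [trial_tensor()].
#' @param pairs two-column matrix or data frame of ordered (source, target)
#'   lead ids.
#' @inheritParams select_pair_trials
#' @return tibble: `source`, `target`, `C_ns1`, `C_ns4`, `type`.
#' @export
connection_summary <- function(tensor, pairs, task = NULL,
                               config = pipeline_config()) {
  pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
  res <- purrr::map_dfr(seq_len(nrow(pairs)), function(k) {
    pr <- c(pairs[k, 1L], pairs[k, 2L])
    cs <- purrr::map_dfr(c(1, 4), function(ns) {
      tr <- pairwise_ugc(tensor, pr, ns_factor = ns, config = config,
                         task = task)
      if (!nrow(tr)) return(NULL)
      tr |>
        baseline_zscore_gc(config$baseline_window_s) |>
        connection_strength(config$strength_window_s)
    })
    cs[cs$source == pairs[k, 1L] & cs$target == pairs[k, 2L], ]
  })
  if (!nrow(res)) {
    return(tibble::tibble(source = character(), target = character(),
                          C_ns1 = numeric(), C_ns4 = numeric(),
                          type = character()))
  }
  res |>
    dplyr::mutate(ns = paste0("C_ns", .data$ns_factor)) |>
    dplyr::select("source", "target", "ns", "C") |>
    tidyr::pivot_wider(names_from = "ns", values_from = "C") |>
    dplyr::mutate(type = classify_connection(.data$C_ns1, .data$C_ns4,
                                             config$strong_z))
}

#' Conditioned Granger causality
#'
#' Fits a three-lead VAR (pair plus one conditioning lead) and returns the
#' conditional GC of the pair's two directions given the conditioning lead:
#' the reduced model for `source -> target | cond` keeps the target's and the
#' conditioning lead's past but drops the source's. Common-input confounds
#' that pairwise GC mistakes for coupling vanish under conditioning on the
#' true driver.
#'
#' @inheritParams pairwise_ugc
#' @param cond_lead conditioning lead id/index; must not belong to the pair.
#' @return `gc_trace` tibble with an added `cond_lead` column.
#' @export
conditioned_gc <- function(tensor, pair, cond_lead, ns_factor = 1,
                           config = pipeline_config(), task = NULL,
                           trials = NULL) {
  li <- resolve_lead(tensor, pair)
  ci <- resolve_lead(tensor, cond_lead)
  if (ci %in% li) stop("`cond_lead` must not belong to the pair", call. = FALSE)
  all_leads <- c(li, ci)
  if (is.null(trials)) {
    trials <- select_pair_trials(tensor, tensor$leads$lead_id[all_leads],
                                 task = task, config = config)
  }
  if (!length(trials)) {
    out <- .empty_gc_trace(); out$cond_lead <- character(); return(out)
  }
  dirs <- rbind(c(1L, 2L), c(2L, 1L))
  Fm <- .gc_trace_raw(tensor, all_leads, cbind(trials, trials, trials),
                      ns_factor, config, dirs)
  wins <- .gc_windows(tensor, config)
  ids <- tensor$leads$lead_id[li]
  out <- dplyr::bind_rows(
    dplyr::mutate(wins, source = ids[1L], target = ids[2L], F = Fm[, 1L]),
    dplyr::mutate(wins, source = ids[2L], target = ids[1L], F = Fm[, 2L])
  )
  out$ns_factor <- ns_factor
  out$cond_lead <- tensor$leads$lead_id[ci]
  out <- dplyr::select(out, "source", "target", "cond_lead", "ns_factor",
                       "window", "window_start_ms", "window_center_ms",
                       "window_end_ms", "F")
  class(out) <- c("gc_trace", class(out))
  out
}

#' Screen candidate leads for a conditioning effect
#'
#' Tries every candidate once as the conditioning lead of the pair and
#' returns, per candidate, the pair's peak baseline-z GC in the response
#' window before and after conditioning. Candidates that pull the peak below
#' `config$medium_z` (default 3) are the influential leads — the strongest
#' common inputs to the pair.
#'
#' @inheritParams conditioned_gc
#' @param candidates vector of candidate conditioning lead ids/indices
#'   (members of the pair are dropped).
#' @param direction `"forward"` analyses `pair[1] -> pair[2]` (default).
#' @return tibble: `source`, `target`, `cond_lead`, `peak_z_before`,
#'   `peak_z_after`, `influential`.
#' @export
conditioning_screen <- function(tensor, pair, candidates, ns_factor = 1,
                                config = pipeline_config(), task = NULL) {
  ids <- tensor$leads$lead_id[resolve_lead(tensor, pair)]
  candidates <- setdiff(tensor$leads$lead_id[resolve_lead(tensor, candidates)],
                        ids)
  peak_of <- function(tr) {
    tr <- baseline_zscore_gc(tr, config$baseline_window_s)
    lo <- config$strength_window_s[1] * 1000
    hi <- config$strength_window_s[2] * 1000
    sel <- tr$source == ids[1L] & tr$target == ids[2L] &
      tr$window_center_ms >= lo & tr$window_center_ms < hi
    max(tr$z_base[sel], na.rm = TRUE)
  }
  before <- peak_of(pairwise_ugc(tensor, ids, ns_factor = ns_factor,
                                 config = config, task = task))
  purrr::map_dfr(candidates, function(cl) {
    tr <- conditioned_gc(tensor, ids, cl, ns_factor = ns_factor,
                         config = config, task = task)
    pk <- if (nrow(tr)) peak_of(tr) else NA_real_
    tibble::tibble(source = ids[1L], target = ids[2L], cond_lead = cl,
                   peak_z_before = before, peak_z_after = pk,
                   influential = isTRUE(pk < config$medium_z))
  })
}

#' Is an outside lead a "via" lead for a pair?
#'
#' An outside lead routes a (source, target) connection when it is strongly
#' connected from the source and to the target: both
#' `C(source -> lead) > strong_z` and `C(lead -> target) > strong_z`.
#'
#' @param c_source_to_lead,c_lead_to_target signed strengths.
#' @param strong_z strong threshold (default 5).
#' @return logical vector.
#' @export
via_lead_classification <- function(c_source_to_lead, c_lead_to_target,
                                    strong_z = 5) {
  c_source_to_lead > strong_z & c_lead_to_target > strong_z
}

#' Pointwise average of GC traces
#'
#' Averages the value columns of several GC traces per window (used e.g. to
#' average an outside lead's connections over the target-region leads
#' available in a patient).
#'
#' @param traces a `gc_trace` tibble holding >= 1 trace (several source or
#'   target leads).
#' @return tibble averaged per (ns_factor, window); numeric GC columns (`F`,
#'   `z_surr`, `z_base`, ... whichever are present) are averaged.
#' @export
region_average_gc <- function(traces) {
  if (!nrow(traces)) stop("no traces to average", call. = FALSE)
  vals <- intersect(c("F", "surr_mean", "surr_sd", "z_surr", "boot_mean",
                      "boot_sd", "z_base"), names(traces))
  out <- traces |>
    dplyr::group_by(.data$ns_factor, .data$window, .data$window_start_ms,
                    .data$window_center_ms, .data$window_end_ms) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(vals), mean),
                     .groups = "drop")
  class(out) <- c("gc_trace", class(out))
  out
}

#' Parametric frequency-domain Granger causality
#'
#' Geweke's frequency decomposition computed from a fitted bivariate VAR's
#' transfer function, reported at `n_freqs` equally spaced frequencies from 0
#' to the Nyquist frequency of the (decimated) sampling rate. A diagnostic of
#' which bands carry a connection; typing always uses the time-domain
#' statistic.
#'
#' @param fit a two-lead `var_fit` from [fit_var_window()].
#' @param fs base sampling rate in Hz (the effective rate is
#'   `fs / fit$ns_factor`).
#' @param n_freqs number of frequency points (default 101).
#' @return tibble: `freq_hz`, `direction` (`"1->2"`, `"2->1"`), `f` (GC at
#'   that frequency).
#' @export
spectral_gc <- function(fit, fs, n_freqs = 101) {
  stopifnot(inherits(fit, "var_fit"), nrow(fit$Sigma) == 2L)
  fs_eff <- fs / fit$ns_factor
  freqs <- seq(0, fs_eff / 2, length.out = n_freqs)
  p <- fit$order
  Sg <- fit$Sigma
  one_dir <- function(src, tgt) {
    vapply(freqs, function(fr) {
      z <- exp(-2i * pi * fr / fs_eff * seq_len(p))
      Aw <- diag(2) - Reduce(`+`, lapply(seq_len(p), function(k) {
        fit$coef[, , k] * z[k]
      }))
      H <- solve(Aw)
      # remove the instantaneous correlation from the source channel
      Ht_tt <- H[tgt, tgt] + (Sg[src, tgt] / Sg[tgt, tgt]) * H[tgt, src]
      S_tt <- Re(H[tgt, tgt] * Sg[tgt, tgt] * Conj(H[tgt, tgt]) +
                   2 * Re(H[tgt, tgt] * Sg[tgt, src] * Conj(H[tgt, src])) +
                   H[tgt, src] * Sg[src, src] * Conj(H[tgt, src]))
      intrinsic <- Re(Ht_tt * Sg[tgt, tgt] * Conj(Ht_tt))
      log(max(S_tt, 1e-300) / max(intrinsic, 1e-300))
    }, numeric(1))
  }
  tibble::tibble(
    freq_hz = rep(freqs, 2L),
    direction = rep(c("1->2", "2->1"), each = n_freqs),
    f = c(one_dir(1L, 2L), one_dir(2L, 1L))
  )
}
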