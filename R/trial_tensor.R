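#' Trial tensor: trial-aligned multichannel recordings
#'
#' A `trial_tensor` holds a `leads x trials x samples` array of trial-aligned
#' intracranial recordings (microvolts), the sampling rate, the sample index of
#' static stimulus onset, a logical mask of invalid entries, per-trial
#' condition labels, and a lead metadata table. It is the common currency of
#' every stage of the pipeline: rejection masks entries, power and Granger
#' estimators skip masked `(trial, lead)` combinations.
#'
#' Time convention: sample 1 is the first recorded sample; latencies are
#' reported in ms relative to the onset sample; analysis windows are half-open
#' `[start, end)`.
#'
#' @param data numeric array, `leads x trials x samples`.
#' @param fs sampling rate in Hz (positive scalar).
#' @param onset_index number of pre-onset samples (equivalently, the 0-based
#'   index of the static-onset sample): the first `onset_index` samples are
#'   baseline, sample `onset_index + 1` is the first at/after onset. Must
#'   provide at least 900 ms of baseline at `fs`.
#' @param mask logical array of the same shape as `data`; `TRUE` marks invalid
#'   entries. Defaults to all-`FALSE`. After rejection the mask is
#'   all-or-nothing along the sample axis for any `(lead, trial)`.
#' @param trial_labels tibble with one row per trial. Columns `task`
#'   (`"gender"`/`"action"`), `truncation` (`"full"`/`"truncated"`),
#'   `static_duration_ms`, and optionally `response_time_ms` (end of the video
#'   epoch). A default all-gender/full frame is supplied when omitted.
#' @param leads tibble with one row per lead: `lead_id`, `region` (one of
#'   `r paste0('"', gcflow_regions(), '"', collapse = ", ")`), `patient_id`,
#'   `in_ez`. Defaults to anonymous leads tagged `gray-other`.
#'
#' @return an object of class `trial_tensor`.
#' @export
trial_tensor <- function(data, fs, onset_index, mask = NULL,
                         trial_labels = NULL, leads = NULL) {
  if (!is.array(data) || length(dim(data)) != 3L) {
    stop("`data` must be a 3-d array (leads x trials x samples)", call. = FALSE)
  }
  storage.mode(data) <- "double"
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0) {
    stop("`fs` must be a positive scalar sampling rate in Hz", call. = FALSE)
  }
  fs <- as.numeric(fs)
  if (!is.numeric(onset_index) || length(onset_index) != 1L ||
      onset_index != round(onset_index)) {
    stop("`onset_index` must be an integer sample index", call. = FALSE)
  }
  d <- dim(data)
  if (is.null(mask)) {
    mask <- array(FALSE, dim = d)
  }
  if (!identical(dim(mask), d)) stop("`mask` shape must match `data`", call. = FALSE)
  storage.mode(mask) <- "logical"
  n_lead <- d[1L]; n_trial <- d[2L]; n_samp <- d[3L]
  if (onset_index < 0L || onset_index >= n_samp) {
    stop("`onset_index` outside the recorded samples", call. = FALSE)
  }
  if (is.null(trial_labels)) {
    trial_labels <- tibble::tibble(
      task = rep("gender", n_trial),
      truncation = rep("full", n_trial),
      static_duration_ms = rep(575, n_trial)
    )
  }
  trial_labels <- tibble::as_tibble(trial_labels)
  if (nrow(trial_labels) != n_trial) {
    stop("`trial_labels` must have one row per trial", call. = FALSE)
  }
  if (is.null(leads)) {
    leads <- tibble::tibble(
      lead_id = paste0("L", seq_len(n_lead)),
      region = rep("gray-other", n_lead),
      patient_id = rep("P1", n_lead),
      in_ez = rep(FALSE, n_lead)
    )
  }
  leads <- validate_lead_table(leads)
  if (nrow(leads) != n_lead) stop("`leads` must have one row per lead", call. = FALSE)
  dimnames(data) <- list(leads$lead_id, NULL, NULL)
  x <- structure(
    list(data = data, fs = fs, onset_index = as.integer(onset_index),
         mask = mask, trial_labels = trial_labels, leads = leads),
    class = "trial_tensor"
  )
  x
}

#' Closed vocabulary of anatomical region tags
#'
#' Temporal-pole subregions (T tip, VL ventrolateral, Md medial, Ds dorsal)
#' plus tags for leads outside the temporal pole.
#' @return character vector of allowed region tags.
#' @export
gcflow_regions <- function() c("T", "VL", "Md", "Ds", "outside", "gray-other")

#' Validate a lead metadata table
#'
#' Checks the closed region vocabulary and per-patient uniqueness of lead ids.
#'
#' @param leads data frame with columns `lead_id`, `region`, `patient_id`,
#'   `in_ez`.
#' @return the validated table as a tibble.
#' @export
validate_lead_table <- function(leads) {
  leads <- tibble::as_tibble(leads)
  need <- c("lead_id", "region", "patient_id", "in_ez")
  miss <- setdiff(need, names(leads))
  if (length(miss)) {
    stop("lead table lacks column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  bad <- setdiff(unique(leads$region), gcflow_regions())
  if (length(bad)) {
    stop("unknown region tag(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  dup <- leads |>
    dplyr::count(.data$patient_id, .data$lead_id) |>
    dplyr::filter(.data$n > 1L)
  if (nrow(dup)) {
    stop("duplicated lead_id within patient: ",
         paste(dup$lead_id, collapse = ", "), call. = FALSE)
  }
  leads$in_ez <- as.logical(leads$in_ez)
  leads
}

#' @export
print.trial_tensor <- function(x, ...) {
  d <- dim(x$data)
  cat("<trial_tensor> ", d[1L], " leads x ", d[2L], " trials x ", d[3L],
      " samples @ ", x$fs, " Hz\n", sep = "")
  cat("  onset after ", x$onset_index, " baseline samples (",
      round(x$onset_index / x$fs * 1000), " ms); ",
      sum(x$mask[, , 1L]), "/", d[1L] * d[2L],
      " (lead, trial) combinations masked\n", sep = "")
  tasks <- table(x$trial_labels$task)
  cat("  trials: ", paste(names(tasks), tasks, sep = "=", collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' @export
dim.trial_tensor <- function(x) dim(x$data)

#' Number of leads / trials / samples of a trial tensor
#' @param tensor a [trial_tensor()].
#' @return integer count.
#' @export
n_leads <- function(tensor) dim(tensor$data)[1L]

#' @rdname n_leads
#' @export
n_trials <- function(tensor) dim(tensor$data)[2L]

#' @rdname n_leads
#' @export
n_samples <- function(tensor) dim(tensor$data)[3L]

#' Does the tensor provide the required pre-onset baseline?
#'
#' The baseline period used throughout the pipeline starts 900 ms before
#' static stimulus onset; a tensor is usable only if the onset index leaves at
#' least that much recorded signal before it.
#'
#' @param tensor a [trial_tensor()].
#' @param min_baseline_s minimum pre-onset duration in seconds (default 0.9).
#' @return `TRUE` iff at least `min_baseline_s` of pre-onset samples exist
#'   (`onset_index >= fs * min_baseline_s`).
#' @export
validate_baseline <- function(tensor, min_baseline_s = 0.9) {
  tensor$onset_index >= tensor$fs * min_baseline_s
}

#' Sample times in ms relative to static onset
#' @param tensor a [trial_tensor()].
#' @return numeric vector, one entry per sample.
#' @export
time_ms <- function(tensor) {
  (seq_len(n_samples(tensor)) - 1L - tensor$onset_index) / tensor$fs * 1000
}

#' Which (lead, trial) combinations are valid (unmasked)?
#'
#' @param tensor a [trial_tensor()].
#' @return logical `leads x trials` matrix; `TRUE` = usable. A combination is
#'   usable when none of its samples are masked.
#' @export
valid_combinations <- function(tensor) {
  !apply(tensor$mask, c(1L, 2L), any)
}

#' Apply a rejection mask to a trial tensor
#'
#' Marks whole `(lead, trial)` combinations invalid (the all-or-nothing mask
#' contract: a rejected combination is wholly invalid).
#'
#' @param tensor a [trial_tensor()].
#' @param combined logical `leads x trials` matrix (`TRUE` = reject), e.g. the
#'   `combined` element of [combine_rejections()].
#' @return the tensor with its mask extended (never reduced).
#' @export
mask_tensor <- function(tensor, combined) {
  stopifnot(identical(dim(combined), dim(tensor$data)[1:2]))
  add <- array(rep(as.logical(combined), n_samples(tensor)), dim = dim(tensor$data))
  tensor$mask <- tensor$mask | add
  tensor
}

#' Extract one (lead, trial) trace
#' @param tensor a [trial_tensor()].
#' @param lead lead index or lead id.
#' @param trial trial index.
#' @return numeric vector of samples (NA-free; masked traces error).
#' @export
get_trace <- function(tensor, lead, trial) {
  lead <- resolve_lead(tensor, lead)
  tensor$data[lead, trial, ]
}

resolve_lead <- function(tensor, lead) {
  if (is.character(lead)) {
    idx <- match(lead, tensor$leads$lead_id)
    if (anyNA(idx)) stop("unknown lead id: ", lead[is.na(idx)][1L], call. = FALSE)
    idx
  } else {
    as.integer(lead)
  }
}

#' Convert a trial tensor to a long tibble
#'
#' Mostly for plotting and small-scale inspection; the array form is the
#' computational representation.
#'
#' @param x a [trial_tensor()].
#' @param ... unused.
#' @return tibble with columns `lead_id`, `trial`, `time_ms`, `value`,
#'   `masked`.
#' @export
as_tibble.trial_tensor <- function(x, ...) {
  d <- dim(x$data)
  tibble::tibble(
    lead_id = rep(x$leads$lead_id, times = d[2L] * d[3L]),
    trial = rep(rep(seq_len(d[2L]), each = d[1L]), times = d[3L]),
    time_ms = rep(time_ms(x), each = d[1L] * d[2L]),
    value = as.vector(x$data),
    masked = as.vector(x$mask)
  )
}
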