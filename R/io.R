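#' Read / write a trial-tensor container
#'
#' The container is a directory of plain-text files, inspectable and
#' language-portable:
#' \describe{
#'   \item{meta.json}{dimensions, `fs`, `onset_index`.}
#'   \item{data.tsv}{one row per (lead, trial) in lead-major order, one column
#'     per sample, printed with 17 significant digits so IEEE-754 doubles
#'     round-trip bit-exactly.}
#'   \item{mask.tsv}{same layout, 0/1; present only when any entry is masked.}
#'   \item{trials.tsv}{per-trial condition labels.}
#'   \item{leads.tsv}{lead metadata table.}
#' }
#'
#' @param tensor a [trial_tensor()].
#' @param path directory path for the container.
#' @return `write_trial_tensor` returns `path` invisibly; `read_trial_tensor`
#'   returns the restored [trial_tensor()]. The round trip is the identity on
#'   all fields and bit-exact on the data array.
#' @export
write_trial_tensor <- function(tensor, path) {
  stopifnot(inherits(tensor, "trial_tensor"))
  if (!dir.exists(path)) dir.create(path, recursive = TRUE)
  d <- dim(tensor$data)
  meta <- list(n_leads = d[1L], n_trials = d[2L], n_samples = d[3L],
               fs = tensor$fs, onset_index = tensor$onset_index)
  jsonlite::write_json(meta, file.path(path, "meta.json"), auto_unbox = TRUE,
                       digits = NA)
  writeLines(.format_rows(tensor$data), file.path(path, "data.tsv"))
  mask_file <- file.path(path, "mask.tsv")
  if (any(tensor$mask)) {
    m <- array(as.integer(tensor$mask), dim = d)
    writeLines(.format_rows(m, fmt = "%d"), mask_file)
  } else if (file.exists(mask_file)) {
    unlink(mask_file)
  }
  utils::write.table(tensor$trial_labels, file.path(path, "trials.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(tensor$leads, file.path(path, "leads.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

# rows of the (lead, trial) x sample matrix, lead-major, full precision
.format_rows <- function(a, fmt = "%.17g") {
  d <- dim(a)
  m <- matrix(aperm(a, c(3L, 1L, 2L)), nrow = d[3L])  # samples x (lead-major rows)
  apply(m, 2L, function(v) paste(sprintf(fmt, v), collapse = "\t"))
}

#' @rdname write_trial_tensor
#' @export
read_trial_tensor <- function(path) {
  meta_file <- file.path(path, "meta.json")
  if (!file.exists(meta_file)) {
    stop("not a trial-tensor container (missing meta.json): ", path, call. = FALSE)
  }
  meta <- jsonlite::read_json(meta_file, simplifyVector = TRUE)
  need <- c("n_leads", "n_trials", "n_samples", "fs", "onset_index")
  miss <- setdiff(need, names(meta))
  if (length(miss)) {
    stop("container metadata lacks field(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (meta$fs <= 0) stop("invalid sampling rate in container: fs <= 0", call. = FALSE)
  d <- c(meta$n_leads, meta$n_trials, meta$n_samples)
  data <- .read_rows(file.path(path, "data.tsv"), d)
  mask_file <- file.path(path, "mask.tsv")
  mask <- if (file.exists(mask_file)) {
    array(.read_rows(mask_file, d) != 0, dim = d)
  } else NULL
  trials <- utils::read.table(file.path(path, "trials.tsv"), sep = "\t",
                              header = TRUE, stringsAsFactors = FALSE)
  leads <- utils::read.table(file.path(path, "leads.tsv"), sep = "\t",
                             header = TRUE, stringsAsFactors = FALSE)
  trial_tensor(data, fs = meta$fs, onset_index = meta$onset_index, mask = mask,
               trial_labels = tibble::as_tibble(trials),
               leads = tibble::as_tibble(leads))
}

.read_rows <- function(file, d) {
  v <- scan(file, what = double(), sep = "\t", quiet = TRUE)
  if (length(v) != prod(d)) {
    stop("container data size does not match metadata dimensions", call. = FALSE)
  }
  aperm(array(v, dim = d[c(3L, 1L, 2L)]), c(2L, 3L, 1L))
}

#' Read / write a lead metadata table
#'
#' Tab-separated text with header `lead_id`, `region`, `patient_id`, `in_ez`.
#'
#' @param leads lead table (validated on write and read).
#' @param path TSV file path.
#' @return `read_lead_table` returns a validated tibble.
#' @export
write_lead_table <- function(leads, path) {
  leads <- validate_lead_table(leads)
  utils::write.table(leads, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_lead_table
#' @export
read_lead_table <- function(path) {
  validate_lead_table(utils::read.table(path, sep = "\t", header = TRUE,
                                        stringsAsFactors = FALSE))
}
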