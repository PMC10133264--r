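# Minimal binary-image morphology for wavelet scalograms: binarization, hole
# filling, 8-connected component labelling and region properties. Hand-rolled
# because no image-analysis package is available in the supported stack; the
# images involved are small (tens of scales x a few hundred time pixels).

# flood fill (4-connectivity) of FALSE background reachable from the border;
# unreached background pixels are holes
.fill_holes <- function(bw) {
  nr <- nrow(bw); nc <- ncol(bw)
  reached <- matrix(FALSE, nr, nc)
  stack <- integer(2L * (nr + nc) + 8L)
  top <- 0L
  push <- function(i) {
    top <<- top + 1L
    if (top > length(stack)) stack <<- c(stack, integer(length(stack)))
    stack[top] <<- i
  }
  for (r in seq_len(nr)) for (cc in c(1L, nc)) {
    i <- r + (cc - 1L) * nr
    if (!bw[i] && !reached[i]) { reached[i] <- TRUE; push(i) }
  }
  for (cc in seq_len(nc)) for (r in c(1L, nr)) {
    i <- r + (cc - 1L) * nr
    if (!bw[i] && !reached[i]) { reached[i] <- TRUE; push(i) }
  }
  while (top > 0L) {
    i <- stack[top]; top <- top - 1L
    r <- ((i - 1L) %% nr) + 1L
    cc <- ((i - 1L) %/% nr) + 1L
    if (r > 1L) { j <- i - 1L; if (!bw[j] && !reached[j]) { reached[j] <- TRUE; push(j) } }
    if (r < nr) { j <- i + 1L; if (!bw[j] && !reached[j]) { reached[j] <- TRUE; push(j) } }
    if (cc > 1L) { j <- i - nr; if (!bw[j] && !reached[j]) { reached[j] <- TRUE; push(j) } }
    if (cc < nc) { j <- i + nr; if (!bw[j] && !reached[j]) { reached[j] <- TRUE; push(j) } }
  }
  bw | (!bw & !reached)
}

# 8-connected component labelling by iterative flood fill
.label_components <- function(bw) {
  nr <- nrow(bw); nc <- ncol(bw)
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  idx_all <- which(bw)
  for (seed in idx_all) {
    if (lab[seed] != 0L) next
    cur <- cur + 1L
    stack <- seed
    lab[seed] <- cur
    while (length(stack)) {
      i <- stack[length(stack)]
      stack <- stack[-length(stack)]
      r <- ((i - 1L) %% nr) + 1L
      cc <- ((i - 1L) %/% nr) + 1L
      for (dr in -1L:1L) for (dc in -1L:1L) {
        if (dr == 0L && dc == 0L) next
        r2 <- r + dr; c2 <- cc + dc
        if (r2 < 1L || r2 > nr || c2 < 1L || c2 > nc) next
        j <- r2 + (c2 - 1L) * nr
        if (bw[j] && lab[j] == 0L) {
          lab[j] <- cur
          stack <- c(stack, j)
        }
      }
    }
  }
  list(labels = lab, n = cur)
}

#' Transient-event blobs in a wavelet scalogram
#'
#' Binarizes a magnitude scalogram at its `binarize_percentile`-th percentile,
#' fills holes, labels 8-connected components and returns their region
#' properties. The blob with the largest area summarizes a trace's dominant
#' transient oscillatory event.
#'
#' @param mag magnitude matrix, scales (rows, mapped by `freqs`) x time
#'   pixels.
#' @param freqs center frequency (Hz) of each row.
#' @param time_ms time (ms) of each column.
#' @param binarize_percentile percentile of `mag` used as the binarization
#'   threshold (default 95).
#' @return tibble with one row per blob: `area` (pixels), `centroid_freq_hz`,
#'   `centroid_time_ms`, bounding box (`bbox_*`), `mean_intensity`,
#'   `max_intensity`.
#' @export
blob_features <- function(mag, freqs, time_ms, binarize_percentile = 95) {
  stopifnot(nrow(mag) == length(freqs), ncol(mag) == length(time_ms))
  thr <- stats::quantile(mag, binarize_percentile / 100, names = FALSE)
  bw <- mag > thr
  if (!any(bw)) {
    return(tibble::tibble(area = integer(), centroid_freq_hz = numeric(),
                          centroid_time_ms = numeric(), bbox_freq_lo = numeric(),
                          bbox_freq_hi = numeric(), bbox_time_lo = numeric(),
                          bbox_time_hi = numeric(), mean_intensity = numeric(),
                          max_intensity = numeric()))
  }
  bw <- .fill_holes(bw)
  lb <- .label_components(bw)
  purrr::map_dfr(seq_len(lb$n), function(k) {
    px <- which(lb$labels == k)
    r <- ((px - 1L) %% nrow(mag)) + 1L
    cc <- ((px - 1L) %/% nrow(mag)) + 1L
    tibble::tibble(
      area = length(px),
      centroid_freq_hz = mean(freqs[r]),
      centroid_time_ms = mean(time_ms[cc]),
      bbox_freq_lo = min(freqs[r]), bbox_freq_hi = max(freqs[r]),
      bbox_time_lo = min(time_ms[cc]), bbox_time_hi = max(time_ms[cc]),
      mean_intensity = mean(mag[px]),
      max_intensity = max(mag[px])
    )
  })
}

# largest-area blob of one trace (NULL when the scalogram is empty/degenerate)
.largest_blob <- function(x, fs, tms, low_freq = 10, downsample = 10L,
                          binarize_percentile = 95) {
  cw <- cwt_transform(x, fs)
  keep_t <- seq(1L, length(x), by = downsample)
  keep_f <- cw$freqs > low_freq
  mag <- Mod(cw$coef[keep_f, keep_t, drop = FALSE])
  if (all(mag == mag[1L])) return(NULL)
  fb <- blob_features(mag, cw$freqs[keep_f], tms[keep_t],
                      binarize_percentile = binarize_percentile)
  if (!nrow(fb)) return(NULL)
  fb[which.max(fb$area), ]
}
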