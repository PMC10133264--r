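#' Continuous wavelet transform with analytic Morse or Morlet wavelets
#'
#' FFT-domain implementation of the analytic continuous wavelet transform.
#' The default is the generalized Morse wavelet with symmetry parameter
#' `gamma = 3` and time-bandwidth product `beta * gamma = 60` (so
#' `beta = 20`), the settings used throughout the rejection stage; a complex
#' Morlet (carrier `omega0 = 6`) is available for the power stage. Filters are
#' normalized to peak gain 2, so a unit-amplitude sinusoid at a filter's
#' center frequency yields coefficients of magnitude ~1 (power ~1).
#'
#' @param x numeric vector, one trace.
#' @param fs sampling rate (Hz).
#' @param freqs center frequencies in Hz. If `NULL`, a dyadic grid with
#'   `voices` voices per octave from `fmin` to `fmax` is used (descending, as
#'   conventional for scalograms).
#' @param voices voices per octave for the automatic grid (default 10).
#' @param fmin,fmax automatic grid limits; defaults 4 Hz and `0.4 * fs`.
#' @param wavelet `"morse"` or `"morlet"`.
#' @param gamma,tbp Morse symmetry and time-bandwidth product (defaults 3, 60).
#' @param omega0 Morlet carrier (default 6).
#' @return list with `coef` (complex matrix, `length(freqs) x length(x)`) and
#'   `freqs` (Hz).
#' @export
cwt_transform <- function(x, fs, freqs = NULL, voices = 10,
                          fmin = 4, fmax = 0.4 * fs,
                          wavelet = c("morse", "morlet"),
                          gamma = 3, tbp = 60, omega0 = 6) {
  wavelet <- match.arg(wavelet)
  n <- length(x)
  if (is.null(freqs)) {
    n_oct <- log2(fmax / fmin)
    freqs <- fmax * 2^(-seq(0, n_oct, by = 1 / voices))
  }
  xf <- stats::fft(x)
  w <- 2 * pi * (seq_len(n) - 1L) / n          # DFT angular frequencies [0, 2pi)
  w <- ifelse(w > pi, w - 2 * pi, w) * fs      # physical rad/s per sample -> rad/sample*fs? keep rad/s
  coef <- matrix(0 + 0i, nrow = length(freqs), ncol = n)
  for (k in seq_along(freqs)) {
    H <- switch(wavelet,
      morse = .morse_filter(w, 2 * pi * freqs[k], gamma = gamma, beta = tbp / gamma),
      morlet = .morlet_filter(w, 2 * pi * freqs[k], omega0 = omega0)
    )
    coef[k, ] <- stats::fft(xf * H, inverse = TRUE) / n
  }
  list(coef = coef, freqs = freqs)
}

# analytic generalized Morse filter, peak gain 2 at omega_c (rad/s), zero for
# omega <= 0
.morse_filter <- function(w, wc, gamma, beta) {
  wp <- (beta / gamma)^(1 / gamma)            # dimensionless peak frequency
  u <- w / wc * wp
  H <- numeric(length(w))
  pos <- u > 0
  # log-domain for numerical stability; normalized so H(wc) = 2
  H[pos] <- 2 * exp(beta * log(u[pos] / wp) - u[pos]^gamma + wp^gamma)
  H
}

# analytic Morlet filter, peak gain 2 at omega_c, zero for omega <= 0
.morlet_filter <- function(w, wc, omega0) {
  s <- omega0 / wc
  H <- numeric(length(w))
  pos <- w > 0
  H[pos] <- 2 * exp(-0.5 * (s * w[pos] - omega0)^2)
  H
}

#' Welch power spectral density
#'
#' Segment-averaged periodogram with a Hann window and 50% overlap; used for
#' the high-gamma power statistic of the bivariate feature vector and for the
#' window-based power estimates that accompany the Granger windows.
#'
#' @param x numeric vector.
#' @param fs sampling rate (Hz).
#' @param nseg segment length in samples (default `min(256, length(x))`).
#' @return tibble with columns `freq` (Hz) and `psd` (power per Hz).
#' @export
welch_psd <- function(x, fs, nseg = min(256L, length(x))) {
  n <- length(x)
  nseg <- min(nseg, n)
  step <- max(1L, nseg %/% 2L)
  starts <- seq(1L, n - nseg + 1L, by = step)
  win <- 0.5 - 0.5 * cos(2 * pi * seq_len(nseg) / (nseg + 1))  # Hann
  u <- sum(win^2)
  nf <- nseg %/% 2L + 1L
  acc <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + nseg - 1L)]
    seg <- (seg - mean(seg)) * win
    p <- Mod(stats::fft(seg))^2 / (u * fs)
    acc <- acc + p[seq_len(nf)]
  }
  psd <- acc / length(starts)
  # one-sided: double everything except DC and (for even nseg) Nyquist
  if (nf > 2L) {
    last <- if (nseg %% 2L == 0L) nf - 1L else nf
    psd[2L:last] <- 2 * psd[2L:last]
  }
  tibble::tibble(freq = (seq_len(nf) - 1L) * fs / nseg, psd = psd)
}

#' Band power from a Welch spectrum
#' @param x numeric vector.
#' @param fs sampling rate.
#' @param band `c(low, high)` in Hz (half-open `[low, high)`).
#' @param nseg Welch segment length.
#' @return scalar band power (integral of the PSD over the band).
#' @export
band_power <- function(x, fs, band = c(50, 150), nseg = min(256L, length(x))) {
  s <- welch_psd(x, fs, nseg = nseg)
  sel <- s$freq >= band[1] & s$freq < band[2]
  df <- fs / (min(nseg, length(x)))
  sum(s$psd[sel]) * df
}

# zero-phase FFT band-pass with raised-cosine edges; synthesis utility for the
# generator (no filter-design package in the stack)
.fft_bandpass <- function(x, fs, low, high, edge = 4) {
  n <- length(x)
  f <- (seq_len(n) - 1L) / n * fs
  f <- ifelse(f > fs / 2, fs - f, f)          # folded |frequency|
  g <- numeric(n)
  g[f >= low & f <= high] <- 1
  rise <- f >= low - edge & f < low
  g[rise] <- 0.5 - 0.5 * cos(pi * (f[rise] - (low - edge)) / edge)
  fall <- f > high & f <= high + edge
  g[fall] <- 0.5 + 0.5 * cos(pi * (f[fall] - high) / edge)
  Re(stats::fft(stats::fft(x) * g, inverse = TRUE) / n)
}
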