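#' painhfa: intracranial HFA analysis of tonic pain psychophysics
#'
#' End-to-end tools for sliding-window mixed-effects analysis of broadband
#' high-frequency activity (HFA, 70-150 Hz) against binary and graded pain
#' reports, plus a synthetic-data module emulating the thermal pain task and
#' stereo-EEG recordings.
#'
#' @keywords internal
#' @aliases painhfa-package
#' @useDynLib painhfa, .registration = TRUE
#' @importFrom Rcpp evalCpp
"_PACKAGE"

logistic <- function(x) 1 / (1 + exp(-x))

#' Analytic-signal amplitude (Hilbert envelope)
#'
#' Magnitude of the analytic signal, computed by zeroing the negative
#' frequencies of the discrete Fourier transform.
#'
#' @param x numeric vector.
#' @return numeric vector of the same length; the instantaneous amplitude.
#' @keywords internal
hilbert_amplitude <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  Mod(stats::fft(X * h, inverse = TRUE) / n)
}

#' Welch power spectral density estimate
#'
#' Averaged modified periodogram with Hann-windowed segments. Returned on the
#' one-sided density scale (input units squared per Hz), so a pure sinusoid of
#' amplitude a concentrates a^2/2 of power across the window's equivalent
#' noise bandwidth.
#'
#' @param x numeric vector.
#' @param fs sampling rate in Hz.
#' @param seg_len segment length in samples (default 1 s worth).
#' @param overlap fractional overlap between segments.
#' @return list with `freq` (Hz) and `psd` (density) vectors.
#' @keywords internal
welch_psd <- function(x, fs, seg_len = fs, overlap = 0.5) {
  n <- length(x)
  seg_len <- min(seg_len, n)
  step <- max(1L, floor(seg_len * (1 - overlap)))
  starts <- seq(1L, n - seg_len + 1L, by = step)
  w <- 0.5 * (1 - cos(2 * pi * seq_len(seg_len) / (seg_len + 1)))
  scale <- fs * sum(w^2)
  nfreq <- seg_len %/% 2 + 1L
  segs <- vapply(starts, function(s) x[s:(s + seg_len - 1L)] * w,
                 numeric(seg_len))
  P <- Mod(stats::mvfft(segs))^2 / scale
  psd <- rowMeans(P[seq_len(nfreq), , drop = FALSE])
  # one-sided: double everything except DC (and Nyquist when present)
  if (seg_len %% 2 == 0) {
    psd[2:(nfreq - 1L)] <- 2 * psd[2:(nfreq - 1L)]
  } else {
    psd[2:nfreq] <- 2 * psd[2:nfreq]
  }
  list(freq = seq(0, by = fs / seg_len, length.out = nfreq), psd = psd)
}

#' Centered moving average with shrinking edges
#'
#' Interior samples are averaged over the full window; near the edges the
#' window shrinks to the available samples, so the output has no NA padding
#' and a constant input is reproduced exactly everywhere.
#'
#' @param x numeric vector.
#' @param w window length in samples.
#' @return numeric vector, same length as `x`.
#' @keywords internal
moving_average <- function(x, w) {
  n <- length(x)
  if (w <= 1L) return(x)
  half_lo <- (w - 1L) %/% 2L
  half_hi <- w - 1L - half_lo
  cs <- cumsum(c(0, x))
  i <- seq_len(n)
  lo <- pmax(i - half_lo, 1L)
  hi <- pmin(i + half_hi, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Zero-phase IIR magnitude response on the DFT grid
#'
#' Squared magnitude response |H(f)|^2 of a designed filter, evaluated at the
#' DFT bin frequencies for signals of length `n`: the response of the
#' forward-backward (zero-phase) application of the filter. Multiplying a
#' signal's DFT by this and inverting applies the same linear operator as
#' forward-backward filtering, with periodic instead of reflective boundary
#' handling; epochs are extracted with generous margins and their outer edges
#' excluded from statistics, so the boundary choice is immaterial and the
#' spectral form lets one response vector serve every epoch of a given
#' length.
#'
#' @param flt filter object with `b`/`a` coefficients (from
#'   [signal::butter()]).
#' @param n signal length in samples.
#' @param fs sampling rate (Hz).
#' @return numeric vector of length `n`.
#' @keywords internal
zero_phase_mag2 <- function(flt, n, fs) {
  f <- (seq_len(n) - 1L) / n * fs
  w <- 2 * pi * pmin(f, fs - f) / fs      # fold to [0, pi]
  z <- exp(-1i * w)
  H <- signal::polyval(rev(flt$b), z) / signal::polyval(rev(flt$a), z)
  Mod(H)^2
}

# apply a precomputed zero-phase response (vector over DFT bins)
spectral_filter <- function(x, H2) {
  Re(stats::fft(stats::fft(x) * H2, inverse = TRUE)) / length(x)
}

# median of each column of a channels-by-time matrix, via one radix sort
# (orders of magnitude faster than per-column median calls)
col_medians <- function(X) {
  r <- nrow(X); m <- ncol(X)
  o <- order(col(X), X, method = "radix")
  S <- matrix(X[o], r, m)
  if (r %% 2 == 1) S[(r + 1) %/% 2, ] else (S[r %/% 2, ] + S[r %/% 2 + 1, ]) / 2
}

ms_to_samples <- function(ms, fs) as.integer(round(ms / 1000 * fs))

`%||%` <- function(a, b) if (is.null(a)) b else a
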