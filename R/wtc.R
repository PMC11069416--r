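# Morlet continuous wavelet transform and wavelet transform coherence.
#
# The transform follows the standard analytic-Morlet formulation (centre
# frequency w0 = 6) evaluated in the frequency domain over dyadic scales,
# and coherence uses scale-dependent smoothing of the cross- and
# auto-spectra: a Gaussian window in time with SD equal to the scale, and a
# 0.6-octave boxcar across scales. Both smoothing kernels are non-negative,
# which guarantees squared coherence in [0, 1] by the Cauchy-Schwarz
# inequality. Plans (wavelet filters and smoothing operators) depend only on
# the series length and sampling step and are cached across calls.

wtc_cache <- new.env(parent = emptyenv())

wtc_plan <- function(n, dt, dj = 1/12, s0 = 2 * dt, w0 = 6) {
  key <- paste(n, signif(dt, 12), signif(dj, 12), signif(s0, 12), w0, sep = "|")
  hit <- wtc_cache[[key]]
  if (!is.null(hit)) return(hit)
  nfft <- stats::nextn(n, 2)
  J <- floor(log2(n * dt / s0) / dj)
  scales <- s0 * 2^((0:J) * dj)
  S <- length(scales)
  omega <- 2 * pi * (0:(nfft - 1)) / (nfft * dt)
  omega[omega > pi / dt] <- omega[omega > pi / dt] - 2 * pi / dt
  pos <- omega > 0
  PSI <- matrix(0, nfft, S)
  PSI[pos, ] <- exp(-(outer(omega[pos], scales) - w0)^2 / 2)
  PSI <- sweep(PSI, 2, pi^(-1 / 4) * sqrt(2 * pi * scales / dt), "*")
  om <- 2 * pi * (0:(nfft - 1)) / nfft
  om[om > pi] <- om[om > pi] - 2 * pi
  G <- exp(-0.5 * outer(om, scales / dt)^2)  # FFT of the time-smoothing kernel
  nsw <- 0.6 / dj
  k <- floor((nsw - 1) / 2)
  wts <- c((nsw - (2 * k + 1)) / 2, rep(1, 2 * k + 1), (nsw - (2 * k + 1)) / 2)
  K <- matrix(0, S, S)
  for (i in seq_len(S)) {
    idx <- (i - k - 1):(i + k + 1)
    ok <- idx >= 1 & idx <= S
    K[idx[ok], i] <- wts[ok] / sum(wts[ok])
  }
  fourier_factor <- 4 * pi / (w0 + sqrt(2 + w0^2))
  plan <- list(n = n, nfft = nfft, dt = dt, dj = dj, w0 = w0,
               scales = scales, freqs = 1 / (fourier_factor * scales),
               fourier_factor = fourier_factor, PSI = PSI, G = G, K = K)
  wtc_cache[[key]] <- plan
  plan
}

# CWT of x under a plan: n x S complex matrix (time x scale)
wtc_cwt <- function(x, plan) {
  xh <- fft(c(x - mean(x), rep(0, plan$nfft - plan$n)))
  mvfft(plan$PSI * xh, inverse = TRUE)[seq_len(plan$n), , drop = FALSE] / plan$nfft
}

# scale-dependent smoothing (time Gaussian then scale boxcar) of an n x S field
wtc_smooth <- function(M, plan) {
  Mp <- rbind(M, matrix(0, plan$nfft - plan$n, ncol(M)))
  Ts <- mvfft(mvfft(Mp) * plan$G, inverse = TRUE)[seq_len(plan$n), , drop = FALSE] / plan$nfft
  Ts %*% plan$K
}

# smoothed auto-spectrum |W|^2 / s (real n x S)
wtc_autospec <- function(W, plan) {
  Re(wtc_smooth(sweep(abs(W)^2, 2, plan$scales, "/"), plan))
}

# per-time cone-of-influence boundary frequency (Hz): estimates at
# frequencies below this are affected by the series edges (e-folding time
# of the Morlet at scale s is sqrt(2) * s)
wtc_coi <- function(n, dt, fourier_factor) {
  d <- pmax(dt * pmin(seq_len(n) - 1, n - seq_len(n)), .Machine$double.eps)
  sqrt(2) / (fourier_factor * d)
}

new_coherence_spectrogram <- function(r2, freqs, times, coi, plan) {
  structure(list(r2 = r2, freqs = freqs, times = times, coi = coi,
                 scales = plan$scales, dt = plan$dt, w0 = plan$w0),
            class = "coherence_spectrogram")
}

#' Wavelet transform coherence between two signals
#'
#' Computes time-frequency squared coherence between two equally sampled
#' series using the analytic Morlet wavelet (centre frequency `w0 = 6`)
#' over dyadic scales (12 voices per octave from `2/fs` seconds up to the
#' series duration), with scale-dependent Gaussian smoothing in time and a
#' 0.6-octave boxcar across scales applied to the cross- and auto-spectra.
#' Without this smoothing, squared coherence would be identically 1; the
#' smoothing is what makes coherence estimable.
#'
#' @param x,y Numeric vectors of equal length (at least 64 samples).
#' @param fs Sampling rate in Hz.
#' @param dj Scale resolution (octave fraction per voice); default 1/12.
#' @param s0 Smallest scale in seconds; default `2/fs`.
#' @param w0 Morlet centre frequency; default 6.
#' @return A `"coherence_spectrogram"`: `r2` (frequency x time matrix of
#'   squared coherence), `freqs` (Hz, descending, one per scale), `times`
#'   (s), and `coi` (per-time boundary frequency in Hz below which
#'   estimates are edge-affected).
#' @examples
#' t <- seq(0, 120, by = 1 / 8.33)
#' x <- sin(2 * pi * 0.05 * t) + rnorm(length(t), sd = 0.5)
#' y <- sin(2 * pi * 0.05 * t) + rnorm(length(t), sd = 0.5)
#' sp <- wtc(x, y, fs = 8.33)
#' range(sp$r2)
#' @export
wtc <- function(x, y, fs, dj = 1 / 12, s0 = 2 / fs, w0 = 6) {
  if (length(x) != length(y)) abort("`x` and `y` must have equal length")
  n <- length(x)
  if (n < 64) abort("series must have at least 64 samples")
  if (!all(is.finite(x)) || !all(is.finite(y))) abort("inputs must be finite")
  assert_scalar_num(fs, "fs", lo = 1e-9)
  plan <- wtc_plan(n, 1 / fs, dj = dj, s0 = s0, w0 = w0)
  Wx <- wtc_cwt(x, plan)
  Wy <- wtc_cwt(y, plan)
  Sx <- wtc_autospec(Wx, plan)
  Sy <- wtc_autospec(Wy, plan)
  Sxy <- wtc_smooth(sweep(Wx * Conj(Wy), 2, plan$scales, "/"), plan)
  r2 <- Mod(Sxy)^2 / (Sx * Sy)
  r2 <- pmin(pmax(r2, 0), 1)
  new_coherence_spectrogram(t(r2), plan$freqs, (seq_len(n) - 1) / fs,
                            wtc_coi(n, 1 / fs, plan$fourier_factor), plan)
}

#' @export
print.coherence_spectrogram <- function(x, ...) {
  cat(sprintf("<coherence_spectrogram> %d frequencies (%.3g-%.3g Hz) x %d times (%.4g s)\n",
              length(x$freqs), min(x$freqs), max(x$freqs), length(x$times),
              max(x$times) + x$dt))
  invisible(x)
}

#' Band-averaged coherence
#'
#' Averages squared coherence over all time-frequency cells whose frequency
#' lies in `[lo, hi)` of the requested band, optionally restricted to cells
#' above the cone-of-influence boundary (edge-unaffected cells). The
#' fraction of in-band cells excluded by the cone is reported; for the low
#' band on a two-minute trial most of the plane is edge-affected and the
#' excluded fraction is necessarily large.
#'
#' @param spec A `"coherence_spectrogram"` from [wtc()].
#' @param band A band name (`"high"`, `"medium"`, `"low"`), or a one-row
#'   data frame with `band`, `lo_hz`, `hi_hz` as in [frequency_bands()].
#' @param exclude_coi Drop edge-affected cells (default `TRUE`).
#' @return A one-row tibble: `band`, `value` (mean squared coherence in
#'   `[0, 1]`), `n_cells`, `coi_excluded_fraction`.
#' @export
band_average <- function(spec, band, exclude_coi = TRUE) {
  stopifnot(inherits(spec, "coherence_spectrogram"))
  if (is.character(band)) {
    bands <- frequency_bands()
    if (!band %in% bands$band)
      abort(sprintf("unknown band '%s' (available: %s)", band,
                    paste(bands$band, collapse = ", ")))
    band <- bands[bands$band == band, ]
  }
  in_band <- spec$freqs >= band$lo_hz & spec$freqs < band$hi_hz
  if (!any(in_band))
    abort(sprintf("band [%g, %g) Hz lies outside the resolved frequency range",
                  band$lo_hz, band$hi_hz))
  sub <- spec$r2[in_band, , drop = FALSE]
  total <- length(sub)
  if (exclude_coi) {
    keep <- outer(spec$freqs[in_band], spec$coi, ">=")
    excluded <- 1 - sum(keep) / total
    if (!any(keep))
      abort(sprintf("no cells in band [%g, %g) Hz survive the cone of influence for this trial length",
                    band$lo_hz, band$hi_hz))
    value <- mean(sub[keep])
    n_cells <- sum(keep)
  } else {
    excluded <- 0
    value <- mean(sub)
    n_cells <- total
  }
  tibble::tibble(band = band$band, value = value, n_cells = n_cells,
                 coi_excluded_fraction = excluded)
}
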