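#' Raw intensity container
#'
#' Wraps a block of raw optical intensities as recorded by a continuous-wave
#' NIRS machine: one series per channel and wavelength, strictly positive,
#' in arbitrary machine units.
#'
#' @param values Numeric array of dimension `channels x time x 3`
#'   (wavelengths in the order of `wavelengths`).
#' @param fs Sampling rate in Hz.
#' @param wavelengths Wavelengths in nm; default `c(780, 805, 830)`.
#' @param channels Optional tibble of channel metadata (ids, source/detector
#'   pairs); defaults to sequential ids.
#' @return An object of class `"ib_raw"`.
#' @export
raw_intensity <- function(values, fs, wavelengths = c(780, 805, 830),
                          channels = NULL) {
  if (length(dim(values)) != 3 || dim(values)[3] != length(wavelengths))
    abort("`values` must be a channels x time x wavelength array")
  if (length(wavelengths) != 3)
    abort("exactly 3 wavelengths are required")
  assert_scalar_num(fs, "fs", lo = 1e-9)
  bad <- which(values <= 0 | !is.finite(values), arr.ind = TRUE)
  if (nrow(bad) > 0)
    abort(sprintf("non-positive intensity at channel %d, sample %d, wavelength %d",
                  bad[1, 1], bad[1, 2], bad[1, 3]))
  if (is.null(channels))
    channels <- tibble::tibble(channel = seq_len(dim(values)[1]))
  structure(list(values = values, fs = fs, wavelengths = wavelengths,
                 channels = channels), class = "ib_raw")
}

#' @export
print.ib_raw <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<ib_raw> %d channels x %d samples x %d wavelengths @ %.3g Hz\n",
              d[1], d[2], d[3], x$fs))
  invisible(x)
}

new_od <- function(values, fs, wavelengths, channels) {
  structure(list(values = values, fs = fs, wavelengths = wavelengths,
                 channels = channels), class = "ib_od")
}

#' @export
print.ib_od <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<ib_od> %d channels x %d samples x %d wavelengths @ %.3g Hz\n",
              d[1], d[2], d[3], x$fs))
  invisible(x)
}

#' Convert raw intensity to optical-density change
#'
#' `OD(t) = -ln(I(t) / mean(I))` per channel and wavelength, with the
#' temporal mean of each series as its reference level, so a series equal
#' to its mean everywhere has zero optical density.
#'
#' @param raw An [raw_intensity()] object.
#' @return An `"ib_od"` object with the same dimensions.
#' @export
intensity_to_od <- function(raw) {
  stopifnot(inherits(raw, "ib_raw"))
  v <- raw$values
  od <- v
  for (w in seq_len(dim(v)[3])) {
    m <- rowMeans(v[, , w, drop = FALSE][, , 1, drop = FALSE])
    od[, , w] <- -log(v[, , w] / m)
  }
  new_od(od, raw$fs, raw$wavelengths, raw$channels)
}

#' Wavelet-based motion-artifact correction
#'
#' Decomposes each optical-density series with a Daubechies-5 discrete
#' wavelet transform to its maximum dyadic depth, zeroes detail
#' coefficients lying outside `[Q1 - iqr_factor*IQR, Q3 + iqr_factor*IQR]`
#' of their level's coefficient distribution, and reconstructs. Spikes and
#' step shifts load onto outlying detail coefficients and are suppressed
#' while the slow hemodynamic content is preserved.
#'
#' @param od An `"ib_od"` object.
#' @param iqr_factor Fence width in IQR units; default 1.5.
#' @return An `"ib_od"` object of identical shape.
#' @export
motion_correct_wavelet <- function(od, iqr_factor = 1.5) {
  stopifnot(inherits(od, "ib_od"))
  assert_scalar_num(iqr_factor, "iqr_factor", lo = 1e-9)
  v <- od$values
  n <- dim(v)[2]
  if (n < 2 * length(DB5_LO)) {
    warn("series too short for wavelet decomposition; motion correction skipped")
    return(od)
  }
  for (ch in seq_len(dim(v)[1])) for (w in seq_len(dim(v)[3]))
    v[ch, , w] <- dwt_despike(v[ch, , w], iqr_factor)
  new_od(v, od$fs, od$wavelengths, od$channels)
}

#' Zero-phase Butterworth band-pass filter
#'
#' Applies a Butterworth band-pass (default 0.01-0.4 Hz, order 5) to every
#' channel/wavelength series, forward and backward (`signal::filtfilt`) so
#' that no phase distortion is introduced. The series is demeaned and
#' mirror-padded before filtering to suppress start-up transients.
#'
#' @param od An `"ib_od"` object.
#' @param lo,hi Band edges in Hz.
#' @param order Filter order (of each prototype; applied twice by the
#'   forward-backward pass).
#' @return An `"ib_od"` object of identical shape.
#' @export
bandpass_filter <- function(od, lo = 0.01, hi = 0.4, order = 5) {
  stopifnot(inherits(od, "ib_od"))
  assert_scalar_num(lo, "lo", lo = 1e-9)
  assert_scalar_num(hi, "hi", lo = lo + 1e-12)
  if (hi >= od$fs / 2)
    abort(sprintf("`hi` (%g Hz) must be below the Nyquist frequency (%g Hz)", hi, od$fs / 2))
  bf <- signal::butter(order, c(lo, hi) / (od$fs / 2), type = "pass")
  v <- od$values
  n <- dim(v)[2]
  pad <- min(n - 1, ceiling(3 * od$fs / lo))
  for (ch in seq_len(dim(v)[1])) for (w in seq_len(dim(v)[3])) {
    x <- v[ch, , w]
    x <- x - mean(x)
    xp <- c(rev(x[seq_len(pad) + 1]), x, rev(x[n - seq_len(pad)]))
    y <- signal::filtfilt(bf, xp)
    v[ch, , w] <- y[pad + seq_len(n)]
  }
  new_od(v, od$fs, od$wavelengths, od$channels)
}

#' Extinction coefficients for HbO and HbR
#'
#' Molar extinction coefficients (in 1/(mM cm)) of oxygenated and
#' deoxygenated hemoglobin at the three acquisition wavelengths, compiled
#' from the standard Gratzer/Kollias tabulation of hemoglobin spectra. The
#' absolute concentration scale inherits any uncertainty in these values,
#' but coherence is amplitude-invariant so downstream results do not.
#'
#' @return A tibble with columns `wavelength_nm`, `eps_hbo`, `eps_hbr`.
#' @export
extinction_coefficients <- function() {
  tibble::tribble(
    ~wavelength_nm, ~eps_hbo, ~eps_hbr,
    780,            0.7360,   1.1050,
    805,            0.8770,   0.7904,
    830,            0.9740,   0.6930
  )
}

#' Optical density to hemoglobin concentration (modified Beer-Lambert law)
#'
#' Solves, per channel and sample, the three-wavelength system
#' `dOD(lambda) = (eps_HbO(lambda) dHbO + eps_HbR(lambda) dHbR) * d * DPF(lambda)`
#' for the two chromophore concentration changes by least squares.
#'
#' @param od An `"ib_od"` object.
#' @param source_detector_distance Optode separation in cm; default 3.
#' @param dpf Differential pathlength factor per wavelength; default
#'   `c(6, 6, 6)`.
#' @return An `"ib_conc"` object with `hbo` and `hbr` matrices
#'   (channels x time, micromolar).
#' @export
od_to_concentration <- function(od, source_detector_distance = 3,
                                dpf = c(6, 6, 6)) {
  stopifnot(inherits(od, "ib_od"))
  assert_scalar_num(source_detector_distance, "source_detector_distance", lo = 1e-9)
  if (length(dpf) != 3 || any(dpf <= 0)) abort("`dpf` must be 3 positive values")
  ext <- extinction_coefficients()
  if (!isTRUE(all.equal(ext$wavelength_nm, od$wavelengths)))
    abort("extinction table does not match the data's wavelengths")
  A <- diag(source_detector_distance * dpf) %*% as.matrix(ext[, c("eps_hbo", "eps_hbr")])
  if (abs(det(crossprod(A))) < 1e-12) abort("extinction system is singular")
  pinv <- solve(crossprod(A), t(A))  # 2 x 3
  nch <- dim(od$values)[1]; nt <- dim(od$values)[2]
  hbo <- matrix(0, nch, nt); hbr <- matrix(0, nch, nt)
  for (ch in seq_len(nch)) {
    sol <- pinv %*% t(od$values[ch, , ])  # 2 x nt, mM
    hbo[ch, ] <- sol[1, ] * 1000          # -> uM
    hbr[ch, ] <- sol[2, ] * 1000
  }
  structure(list(hbo = hbo, hbr = hbr, fs = od$fs, dpf = dpf,
                 channels = od$channels), class = "ib_conc")
}

#' @export
print.ib_conc <- function(x, ...) {
  cat(sprintf("<ib_conc> %d channels x %d samples @ %.3g Hz (uM)\n",
              nrow(x$hbo), ncol(x$hbo), x$fs))
  invisible(x)
}

#' Correlation-based signal improvement (CBSI) activation signal
#'
#' Combines HbO and HbR into a single activation series per channel,
#' `x = (HbO - alpha * HbR) / 2` with `alpha = sd(HbO) / sd(HbR)`,
#' exploiting the physiological anti-correlation of the two chromophores.
#' Channels with zero HbR variance are flagged degenerate and carry an
#' all-NA activation series.
#'
#' @param conc An `"ib_conc"` object.
#' @return An `"ib_activation"` object with fields `values`
#'   (channels x time), `alpha` and `degenerate` (logical per channel).
#' @export
cbsi <- function(conc) {
  stopifnot(inherits(conc, "ib_conc"))
  sdo <- apply(conc$hbo, 1, sd); sdr <- apply(conc$hbr, 1, sd)
  degenerate <- sdr <= 0 | !is.finite(sdr) | !is.finite(sdo)
  alpha <- ifelse(degenerate, NA_real_, sdo / sdr)
  x <- (conc$hbo - ifelse(is.na(alpha), 0, alpha) * conc$hbr) / 2
  x[degenerate, ] <- NA_real_
  structure(list(values = x, alpha = alpha, degenerate = degenerate,
                 fs = conc$fs, channels = conc$channels),
            class = "ib_activation")
}

#' @export
print.ib_activation <- function(x, ...) {
  cat(sprintf("<ib_activation> %d channels x %d samples @ %.3g Hz (%d degenerate)\n",
              nrow(x$values), ncol(x$values), x$fs, sum(x$degenerate)))
  invisible(x)
}

#' Automated channel-quality report
#'
#' Replaces visual channel screening with three deterministic gates on the
#' raw intensities: a heartbeat gate (spectral peak in the cardiac band must
#' exceed the neighbouring-band floor by `snr_threshold_db`), a saturation
#' gate (any sample at/above `rail`, or a flat-line of constant values
#' longer than 2 s), and a motion gate (count of first-difference jumps
#' beyond `jump_factor` IQRs, excluded when above `max_jumps`).
#'
#' @param raw An [raw_intensity()] object (at least 60 s of data).
#' @param heartbeat_band Cardiac frequency interval in Hz.
#' @param snr_threshold_db Minimum heartbeat SNR in dB; default 18. The
#'   peak-over-neighbour-median statistic has a noise floor around 10-12 dB
#'   even without any cardiac component (the maximum over many periodogram
#'   bins), while channels with a real heartbeat sit above 30 dB, so the
#'   gate is placed between the two regimes.
#' @param rail Saturation rail in intensity units; default `Inf` (flat-line
#'   detection only).
#' @param jump_factor First-difference outlier fence in IQR units.
#' @param max_jumps Maximum tolerated jump count.
#' @return A tibble with one row per channel: `channel`, `heartbeat_snr_db`,
#'   `saturation_flag`, `motion_jump_count`, `included`.
#' @export
channel_quality <- function(raw, heartbeat_band = c(0.5, 2.0),
                            snr_threshold_db = 18, rail = Inf,
                            jump_factor = 5, max_jumps = 20) {
  stopifnot(inherits(raw, "ib_raw"))
  nt <- dim(raw$values)[2]
  if (nt < 60 * raw$fs) abort("channel_quality requires at least 60 s of data")
  hb_hi <- min(heartbeat_band[2], raw$fs / 2 * 0.98)
  rows <- lapply(seq_len(dim(raw$values)[1]), function(ch) {
    # use the middle wavelength's series for the spectral gate
    x <- raw$values[ch, , 2]
    xc <- x - mean(x)
    win <- 0.5 * (1 - cos(2 * pi * (seq_len(nt) - 1) / (nt - 1)))  # Hann
    spec <- Mod(fft(xc * win))^2
    freqs <- (seq_len(nt) - 1) * raw$fs / nt
    in_hb <- freqs >= heartbeat_band[1] & freqs <= hb_hi
    nb <- (freqs >= heartbeat_band[1] / 2 & freqs < heartbeat_band[1]) |
      (freqs > hb_hi & freqs <= min(1.5 * hb_hi, raw$fs / 2))
    snr <- 10 * log10(max(spec[in_hb]) / max(median(spec[nb]), .Machine$double.xmin))
    flat <- max(rle(round(x, 12))$lengths)
    sat <- any(raw$values[ch, , ] >= rail) || flat > 2 * raw$fs
    d <- abs(diff(x))
    fence <- quantile(d, 0.75) + jump_factor * IQR(d)
    jumps <- sum(d > fence & d > .Machine$double.eps * 100)
    tibble::tibble(channel = ch, heartbeat_snr_db = snr,
                   saturation_flag = sat, motion_jump_count = jumps,
                   included = !sat & snr >= snr_threshold_db & jumps <= max_jumps)
  })
  dplyr::bind_rows(rows)
}

#' Full preprocessing chain for one participant
#'
#' Runs the fixed stage order: optical density, wavelet motion correction,
#' band-pass filter, modified Beer-Lambert law, CBSI. The returned object
#' records the stages and their parameters as provenance.
#'
#' @param raw An [raw_intensity()] object.
#' @param iqr_factor,lo,hi,order,source_detector_distance,dpf Stage
#'   parameters; see the individual stage functions.
#' @return An `"ib_activation"` object with a `provenance` attribute
#'   (list of stage names and parameters, in execution order).
#' @export
preprocess_session <- function(raw, iqr_factor = 1.5, lo = 0.01, hi = 0.4,
                               order = 5, source_detector_distance = 3,
                               dpf = c(6, 6, 6)) {
  act <- raw |>
    intensity_to_od() |>
    motion_correct_wavelet(iqr_factor = iqr_factor) |>
    bandpass_filter(lo = lo, hi = hi, order = order) |>
    od_to_concentration(source_detector_distance = source_detector_distance,
                        dpf = dpf) |>
    cbsi()
  attr(act, "provenance") <- list(
    stages = c("intensity_to_od", "motion_correct_wavelet", "bandpass_filter",
               "od_to_concentration", "cbsi"),
    parameters = list(iqr_factor = iqr_factor, band = c(lo, hi), order = order,
                      source_detector_distance = source_detector_distance,
                      dpf = dpf))
  act
}
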