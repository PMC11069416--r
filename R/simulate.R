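#' Simulation configuration
#'
#' Assembles and validates the configuration of the synthetic dyadic fNIRS
#' generator. Defaults reproduce the acquisition conditions the pipeline is
#' designed for: 27 dyads, 8.33 Hz sampling, three phases of 120 s (first
#' co-watching), 1200 s (conversation) and 120 s (second co-watching),
#' 19 channels per hemisphere, a ~1.1 Hz cardiac oscillation, slow drift
#' and motion artifacts. Inter-brain coupling defaults to zero everywhere
#' (a fully null cohort); use [coupling_spec()] to inject band-limited
#' coupling into chosen phases, bands and ROIs.
#'
#' @param n_dyads Number of real dyads; default 27.
#' @param fs Sampling rate in Hz; default 8.33.
#' @param phase_durations Seconds per phase, named or in order
#'   video1/conversation/video2; default `c(120, 1200, 120)`.
#' @param n_channels_per_hemisphere Channels per hemisphere (see
#'   [reference_montage()]); default 19.
#' @param coupling Dyad-level coupling table from [coupling_spec()] (phase,
#'   band, roi, coupling in `[0, 1]`), recycled to every real dyad. Default
#'   `NULL` = no coupling.
#' @param stimulus_coupling Coupling of every participant to a
#'   stimulus-locked latent during the two video phases, shared by all
#'   participants with the same episode order (this is what gives pseudo
#'   dyads non-trivial coherence); default 0.
#' @param artifact_rate Motion events per minute per channel; default 0.5.
#' @param heartbeat_freq Cardiac frequency in Hz; default 1.1.
#' @param heartbeat_amp Cardiac oscillation amplitude in OD units; default
#'   0.02.
#' @param noise_sd Relative white measurement noise on intensities; default
#'   0.005.
#' @param drift_sd Slow drift amplitude in OD units; default 0.01.
#' @param signal_amplitude_um Peak-to-SD scale of the hemodynamic latents
#'   in micromolar; default 0.5.
#' @param mni_jitter_sd,mni_jitter_max Per-optode MNI registration jitter:
#'   isotropic Gaussian SD (mm) truncated at a maximum displacement (mm);
#'   defaults 8 and 15.
#' @param real_jitter_sd Real-space digitiser noise SD in cm; default 0.05.
#' @param counterbalance Alternate episode order across dyads; default TRUE.
#' @param seed Integer master seed; every random draw in the generator is
#'   derived from it, so equal configurations give bit-identical cohorts.
#' @return A validated list of class `"sim_config"`.
#' @export
sim_config <- function(n_dyads = 27, fs = 8.33,
                       phase_durations = c(video1 = 120, conversation = 1200,
                                           video2 = 120),
                       n_channels_per_hemisphere = 19,
                       coupling = NULL, stimulus_coupling = 0,
                       artifact_rate = 0.5, heartbeat_freq = 1.1,
                       heartbeat_amp = 0.02, noise_sd = 0.005,
                       drift_sd = 0.01, signal_amplitude_um = 0.5,
                       mni_jitter_sd = 8, mni_jitter_max = 15,
                       real_jitter_sd = 0.05, counterbalance = TRUE,
                       seed = 1L) {
  assert_scalar_num(n_dyads, "n_dyads", lo = 1)
  assert_scalar_num(fs, "fs", lo = 1e-6)
  if (length(phase_durations) != 3 || any(phase_durations <= 0))
    abort("`phase_durations` must be 3 positive durations (video1, conversation, video2)")
  phase_durations <- stats::setNames(as.numeric(phase_durations), phase_names())
  assert_scalar_num(stimulus_coupling, "stimulus_coupling", lo = 0, hi = 1)
  assert_scalar_num(artifact_rate, "artifact_rate", lo = 0)
  assert_scalar_num(heartbeat_freq, "heartbeat_freq", lo = 0)
  assert_scalar_num(seed, "seed", lo = 0, hi = 2^31 - 1)
  coupling <- validate_coupling(coupling)
  montage <- reference_montage(n_channels_per_hemisphere)
  structure(list(
    n_dyads = as.integer(n_dyads), fs = fs, phase_durations = phase_durations,
    n_channels_per_hemisphere = as.integer(n_channels_per_hemisphere),
    coupling = coupling, stimulus_coupling = stimulus_coupling,
    artifact_rate = artifact_rate, heartbeat_freq = heartbeat_freq,
    heartbeat_amp = heartbeat_amp, noise_sd = noise_sd, drift_sd = drift_sd,
    signal_amplitude_um = signal_amplitude_um,
    mni_jitter_sd = mni_jitter_sd, mni_jitter_max = mni_jitter_max,
    real_jitter_sd = real_jitter_sd, counterbalance = isTRUE(counterbalance),
    seed = as.integer(seed), montage = montage), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("<sim_config> %d dyads @ %.3g Hz, phases %s s, %d ch/hemisphere, seed %d\n",
              x$n_dyads, x$fs, paste(x$phase_durations, collapse = "/"),
              x$n_channels_per_hemisphere, x$seed))
  if (nrow(x$coupling) > 0) {
    cat("  coupling:\n")
    print(x$coupling)
  } else cat("  coupling: none (null cohort)\n")
  invisible(x)
}

#' Declare injected inter-brain coupling
#'
#' Builds the coupling table consumed by [sim_config()]: each row sets the
#' coupling coefficient (in `[0, 1]`) between the two members of every real
#' dyad for one phase, frequency band and ROI. The coefficient `c` mixes a
#' shared and a private band-limited latent as
#' `x = c * shared + sqrt(1 - c^2) * private`, so expected band coherence
#' increases monotonically with `c` (and equals 1 when `c = 1` with all
#' noise sources disabled).
#'
#' @param phase Phase name(s): `"video1"`, `"conversation"`, `"video2"`.
#' @param band Band name(s): `"high"`, `"medium"`, `"low"`.
#' @param roi ROI name(s) as in [roi_table()], or `"all"`.
#' @param coupling Coefficient(s) in `[0, 1]`.
#' @return A tibble `phase`, `band`, `roi`, `coupling`.
#' @examples
#' coupling_spec(phase = "video2", band = "high", roi = "TPJ_R", coupling = 0.8)
#' @export
coupling_spec <- function(phase, band, roi = "all", coupling) {
  grid <- tidyr::expand_grid(phase = phase, band = band, roi = roi)
  grid$coupling <- rep_len(coupling, nrow(grid))
  if (any(grid$roi == "all")) {
    allr <- grid[grid$roi == "all", ]
    grid <- dplyr::bind_rows(
      grid[grid$roi != "all", ],
      tidyr::expand_grid(dplyr::select(allr, -"roi"), roi = roi_table()$roi))
  }
  validate_coupling(grid[, c("phase", "band", "roi", "coupling")])
}

validate_coupling <- function(coupling) {
  if (is.null(coupling))
    return(tibble::tibble(phase = character(), band = character(),
                          roi = character(), coupling = numeric()))
  stopifnot(all(c("phase", "band", "roi", "coupling") %in% names(coupling)))
  bad_band <- setdiff(coupling$band, band_names())
  if (length(bad_band) > 0)
    abort(sprintf("unknown frequency band '%s' in coupling map (valid: %s)",
                  bad_band[1], paste(band_names(), collapse = ", ")))
  bad_phase <- setdiff(coupling$phase, phase_names())
  if (length(bad_phase) > 0)
    abort(sprintf("unknown phase '%s' in coupling map (valid: %s)",
                  bad_phase[1], paste(phase_names(), collapse = ", ")))
  bad_roi <- setdiff(coupling$roi, roi_table()$roi)
  if (length(bad_roi) > 0)
    abort(sprintf("unknown ROI '%s' in coupling map (valid: %s)",
                  bad_roi[1], paste(roi_table()$roi, collapse = ", ")))
  if (any(coupling$coupling < 0 | coupling$coupling > 1))
    abort("coupling coefficients must lie in [0, 1]")
  if (anyDuplicated(coupling[, c("phase", "band", "roi")]))
    abort("duplicate (phase, band, roi) entries in coupling map")
  tibble::as_tibble(coupling)
}

# band-limited unit-variance Gaussian noise: white noise shaped in the
# frequency domain by a steep Butterworth magnitude response (circular,
# hence exactly stationary; high order keeps injected coupling confined to
# its analysis band)
bl_noise <- function(n, fs, lo, hi, order = 16) {
  # work at a power-of-two length (fast FFT); truncating a circularly
  # stationary series keeps it stationary and band-limited
  n2 <- stats::nextn(n, 2)
  x <- rnorm(n2)
  f <- (seq_len(n2) - 1) / n2 * fs
  f <- pmin(f, fs - f)  # fold to [0, fs/2]
  H <- 1 / sqrt(1 + (f / hi)^(2 * order))
  H <- H / sqrt(1 + ifelse(f > 0, (lo / f)^(2 * order), Inf))
  y <- Re(fft(fft(x) * H, inverse = TRUE))[seq_len(n)] / n2
  s <- sd(y)
  if (s == 0) return(y)
  y / s
}

# per-sample phase label vector for a config
phase_index <- function(config) {
  ns <- round(config$phase_durations * config$fs)
  rep(phase_names(), times = ns)
}

events_table <- function(config) {
  d <- config$phase_durations
  tibble::tibble(onset_s = c(0, cumsum(d))[1:3], duration_s = as.numeric(d),
                 phase_label = phase_names())
}

# full coupling grid (phase x band x roi) with configured values filled in
coupling_grid <- function(config) {
  grid <- tidyr::expand_grid(phase = phase_names(), band = band_names(),
                             roi = roi_table()$roi)
  grid <- dplyr::left_join(grid, config$coupling,
                           by = c("phase", "band", "roi"))
  grid$coupling[is.na(grid$coupling)] <- 0
  grid
}

#' Simulate one dyadic session
#'
#' Generates the raw recording of one dyad under the forward model: per-ROI
#' band-limited hemodynamic latents (a dyad-shared component weighted by
#' the coupling coefficient, a stimulus-locked component shared by all
#' dyads with the same episode order, and a private remainder) drive HbO in
#' the montage's designated ROI channels; HbR is generated anti-correlated
#' with HbO; both are pushed through the extinction-coefficient forward
#' model to optical density and then to intensities with baseline, cardiac
#' oscillation, slow drift, white noise and injected motion artifacts.
#'
#' @param config A [sim_config()].
#' @param dyad_index Dyad number (1-based); determines the episode-order
#'   label under counterbalancing and seeds all dyad-level randomness.
#' @return An `"ib_session"`: participants `A`/`B` as [raw_intensity()]
#'   objects, `events`, per-participant `geometry`, dyad `meta` and the
#'   ground `truth` (coupling grid, artifact event lists, designated
#'   channel map, seeds).
#' @export
simulate_session <- function(config, dyad_index) {
  stopifnot(inherits(config, "sim_config"))
  assert_scalar_num(dyad_index, "dyad_index", lo = 1)
  video_order <- if (config$counterbalance && dyad_index %% 2 == 0)
    "order_BA" else "order_AB"
  mont <- config$montage
  fs <- config$fs
  ph <- phase_index(config)
  n <- length(ph)
  bands <- frequency_bands()
  rois <- roi_table()$roi
  grid <- coupling_grid(config)

  # dyad-shared and stimulus-shared latents per (roi, band)
  shared <- list(); stim <- list()
  for (r in rois) for (b in bands$band) {
    lo <- bands$lo_hz[bands$band == b]; hi <- bands$hi_hz[bands$band == b]
    shared[[paste(r, b)]] <- with_seed(
      derive_seed(config$seed, 11, dyad_index, match(r, rois), match(b, bands$band)),
      bl_noise(n, fs, lo, hi))
    stim[[paste(r, b)]] <- with_seed(
      derive_seed(config$seed, 13, match(video_order, c("order_AB", "order_BA")),
                  match(r, rois), match(b, bands$band)),
      bl_noise(n, fs, lo, hi))
  }
  cs <- ifelse(ph %in% c("video1", "video2"), config$stimulus_coupling, 0)

  ext <- extinction_coefficients()
  d_cm <- 3; dpf <- c(6, 6, 6)
  artifacts <- list()

  participants <- lapply(c(A = 1, B = 2), function(role) {
    pseed <- derive_seed(config$seed, 17, dyad_index, role)
    nch <- nrow(mont$channels)
    hbo <- matrix(0, nch, n)
    with_seed(pseed, {
      for (ci in seq_len(nch)) {
        droi <- mont$channels$designated_roi[ci]
        if (!is.na(droi)) {
          acc <- numeric(n)
          for (b in bands$band) {
            lo <- bands$lo_hz[bands$band == b]; hi <- bands$hi_hz[bands$band == b]
            cd <- numeric(n)
            for (p in phase_names()) {
              cc <- grid$coupling[grid$phase == p & grid$band == b & grid$roi == droi]
              cd[ph == p] <- cc
            }
            priv <- bl_noise(n, fs, lo, hi)
            resid <- sqrt(pmax(1 - cd^2 - cs^2, 0))
            acc <- acc + cd * shared[[paste(droi, b)]] +
              cs * stim[[paste(droi, b)]] + resid * priv
          }
          hbo[ci, ] <- config$signal_amplitude_um * acc / sqrt(nrow(bands))
        } else {
          hbo[ci, ] <- config$signal_amplitude_um * bl_noise(n, fs, 0.01, 0.2)
        }
      }
      hbr_noise <- matrix(0, nch, n)
      for (ci in seq_len(nch)) hbr_noise[ci, ] <- bl_noise(n, fs, 0.01, 0.2)
      hbr <- -0.3 * hbo + 0.1 * config$signal_amplitude_um * hbr_noise
      # forward modified Beer-Lambert law: uM -> OD per wavelength
      values <- array(0, dim = c(nch, n, 3))
      for (w in 1:3) {
        od_sig <- (ext$eps_hbo[w] * hbo / 1000 + ext$eps_hbr[w] * hbr / 1000) *
          d_cm * dpf[w]
        values[, , w] <- od_sig
      }
      # shared nuisance components per channel (identical across wavelengths)
      tsec <- (seq_len(n) - 1) / fs
      hb_f <- config$heartbeat_freq * runif(1, 0.97, 1.03)
      ev_list <- vector("list", nch)
      for (ci in seq_len(nch)) {
        hbph <- runif(1, 0, 2 * pi)
        heart <- config$heartbeat_amp * sin(2 * pi * hb_f * tsec + hbph)
        drift <- if (config$drift_sd > 0) {
          dr <- bl_noise(n, fs, 1e-4, 0.005, order = 2)
          config$drift_sd * dr
        } else numeric(n)
        i0 <- 1000 * runif(1, 0.8, 1.2)
        for (w in 1:3) {
          I <- i0 * exp(-(values[ci, , w] + heart + drift))
          if (config$noise_sd > 0)
            I <- I * (1 + rnorm(n, sd = config$noise_sd))
          values[ci, , w] <- pmax(I, i0 * 1e-6)
        }
        if (config$artifact_rate > 0) {
          inj <- inject_motion_artifacts(values[ci, , 2], fs,
                                         rate_per_min = config$artifact_rate,
                                         seed = derive_seed(pseed, 23, ci))
          ev_list[[ci]] <- inj$events
          for (w in 1:3)
            values[ci, , w] <- pmax(apply_artifact_events(values[ci, , w],
                                                          inj$events, fs),
                                    i0 * 1e-6)
        } else {
          ev_list[[ci]] <- tibble::tibble(sample = integer(), time_s = numeric(),
                                          type = character(), amplitude = numeric(),
                                          width_s = numeric())
        }
      }
      ev <- dplyr::bind_rows(ev_list, .id = "channel")
      ev$channel <- as.integer(ev$channel)
      list(raw = raw_intensity(values, fs, channels = mont$channels[, c("channel", "source", "detector", "hemisphere")]),
           artifact_events = ev, seed = pseed, hbo = hbo, hbr = hbr)
    })
  })

  geometry <- lapply(c(A = "A", B = "B"), function(role) {
    gseed <- derive_seed(config$seed, 29, dyad_index, match(role, c("A", "B")))
    with_seed(gseed, {
      g <- mont$optodes
      g$x_cm <- g$x_cm + rnorm(nrow(g), sd = config$real_jitter_sd)
      g$y_cm <- g$y_cm + rnorm(nrow(g), sd = config$real_jitter_sd)
      g$z_cm <- g$z_cm + rnorm(nrow(g), sd = config$real_jitter_sd)
      if (config$mni_jitter_sd > 0) {
        jit <- matrix(rnorm(3 * nrow(g), sd = config$mni_jitter_sd), ncol = 3)
        nrm <- sqrt(rowSums(jit^2))
        over <- nrm > config$mni_jitter_max
        jit[over, ] <- jit[over, ] * (config$mni_jitter_max / nrm[over])
        g$mni_x <- g$mni_x + jit[, 1]
        g$mni_y <- g$mni_y + jit[, 2]
        g$mni_z <- g$mni_z + jit[, 3]
      }
      g$participant <- paste0("d", sprintf("%02d", dyad_index), role)
      g
    })
  })

  meta <- tibble::tibble(
    dyad = sprintf("d%02d", dyad_index), video_order = video_order,
    participant_a = sprintf("d%02dA", dyad_index),
    participant_b = sprintf("d%02dB", dyad_index), is_real = TRUE)

  truth <- list(
    coupling = grid, stimulus_coupling = config$stimulus_coupling,
    designated_channels = mont$channels[!is.na(mont$channels$designated_roi),
                                        c("channel", "designated_roi")],
    artifact_events = list(A = participants$A$artifact_events,
                           B = participants$B$artifact_events),
    latents = list(A = list(hbo = participants$A$hbo, hbr = participants$A$hbr),
                   B = list(hbo = participants$B$hbo, hbr = participants$B$hbr)),
    seeds = list(A = participants$A$seed, B = participants$B$seed),
    video_order = video_order)

  structure(list(
    dyad = meta$dyad, meta = meta, events = events_table(config),
    participants = list(A = participants$A$raw, B = participants$B$raw),
    geometry = geometry, truth = truth, fs = fs), class = "ib_session")
}

#' @export
print.ib_session <- function(x, ...) {
  cat(sprintf("<ib_session> dyad %s (%s), %d channels, %d samples @ %.3g Hz\n",
              x$dyad, x$meta$video_order, dim(x$participants$A$values)[1],
              dim(x$participants$A$values)[2], x$fs))
  invisible(x)
}

#' Simulate a cohort of dyads
#'
#' Generates `n_dyads` sessions under a common configuration. With
#' counterbalancing on, episode order alternates across dyads so the two
#' order groups differ in size by at most one.
#'
#' @param config A [sim_config()].
#' @return An `"ib_cohort"`: `sessions` (list of [simulate_session()]
#'   results), `meta` (one row per dyad) and the `config`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_dyads < 2) abort("a cohort needs at least 2 dyads")
  sessions <- lapply(seq_len(config$n_dyads),
                     function(i) simulate_session(config, i))
  meta <- dplyr::bind_rows(lapply(sessions, function(s) s$meta))
  structure(list(sessions = sessions, meta = meta, config = config),
            class = "ib_cohort")
}

#' @export
print.ib_cohort <- function(x, ...) {
  cat(sprintf("<ib_cohort> %d dyads (%s)\n", nrow(x$meta),
              paste(table(x$meta$video_order), collapse = "/")))
  invisible(x)
}

#' Inject synthetic motion artifacts
#'
#' Adds motion events at Poisson-distributed times: half are spikes
#' (Gaussian bumps of amplitude 5-8 times the series SD and width under
#' 2 s), half are step shifts (level changes of 2-5 SD persisting to the
#' end). The ground-truth event list is returned alongside the corrupted
#' series; with `rate_per_min = 0` the input is returned untouched.
#'
#' @param x Numeric series.
#' @param fs Sampling rate in Hz.
#' @param rate_per_min Expected events per minute.
#' @param seed Integer seed for the event draw.
#' @return A list: `values` (corrupted series) and `events` (tibble
#'   `sample`, `time_s`, `type`, `amplitude`, `width_s`).
#' @export
inject_motion_artifacts <- function(x, fs, rate_per_min, seed = 1L) {
  assert_scalar_num(rate_per_min, "rate_per_min", lo = 0)
  empty <- tibble::tibble(sample = integer(), time_s = numeric(),
                          type = character(), amplitude = numeric(),
                          width_s = numeric())
  if (rate_per_min == 0)
    return(list(values = x, events = empty))
  n <- length(x)
  minutes <- n / fs / 60
  events <- with_seed(seed, {
    k <- rpois(1, rate_per_min * minutes)
    if (k == 0) empty else {
      s <- sd(x)
      ev <- tibble::tibble(
        sample = sort(sample.int(n, k, replace = TRUE)),
        type = sample(c("spike", "shift"), k, replace = TRUE),
        amplitude = runif(k, 5, 8) * s * sample(c(-1, 1), k, replace = TRUE),
        width_s = runif(k, 0.2, 1.5))
      # step shifts are drawn at 2-5 SD (0.4-0.65 of the spike range)
      shifts <- ev$type == "shift"
      ev$amplitude[shifts] <- ev$amplitude[shifts] * runif(sum(shifts), 0.4, 0.65)
      ev
    }
  })
  if (nrow(events) > 0) {
    events$time_s <- (events$sample - 1) / fs
    events <- events[, c("sample", "time_s", "type", "amplitude", "width_s")]
  }
  list(values = apply_artifact_events(x, events, fs), events = events)
}

#' Apply a known artifact event list to a series
#'
#' Deterministic counterpart of [inject_motion_artifacts()], used to apply
#' one channel's event draw identically to all three wavelengths.
#'
#' @param x Numeric series.
#' @param events Event tibble as returned by [inject_motion_artifacts()].
#' @param fs Sampling rate in Hz.
#' @return The corrupted series.
#' @export
apply_artifact_events <- function(x, events, fs) {
  if (is.null(events) || nrow(events) == 0) return(x)
  n <- length(x)
  for (i in seq_len(nrow(events))) {
    k <- events$sample[i]
    if (events$type[i] == "spike") {
      half <- events$width_s[i] * fs / 2
      idx <- max(1, floor(k - 3 * half)):min(n, ceiling(k + 3 * half))
      x[idx] <- x[idx] + events$amplitude[i] * exp(-((idx - k)^2) / (2 * half^2))
    } else {
      x[k:n] <- x[k:n] + events$amplitude[i]
    }
  }
  x
}
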