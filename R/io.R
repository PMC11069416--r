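# Plain-text serialisation of sessions and results.
#
# Intensities: one TSV per participant, one column per channel x wavelength
# ("ch01_w780" ...), one row per sample. Events: 3-column TSV. Geometry:
# one TSV per participant with real-space (cm) and MNI (mm) coordinates.
# Ground truth: JSON. Intensities are written at 9 significant digits
# (instrument noise makes more meaningless); readers reconstruct the
# in-memory objects to that precision.

#' Write one session to a directory
#'
#' @param session An `"ib_session"` from [simulate_session()].
#' @param dir Target directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
write_session_tsv <- function(session, dir) {
  stopifnot(inherits(session, "ib_session"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  for (role in c("A", "B")) {
    raw <- session$participants[[role]]
    d <- dim(raw$values)
    cols <- list()
    for (ci in seq_len(d[1])) for (w in seq_len(d[3]))
      cols[[sprintf("ch%02d_w%d", ci, raw$wavelengths[w])]] <- signif(raw$values[ci, , w], 9)
    p <- file.path(dir, sprintf("%s_intensity.tsv", session$meta[[paste0("participant_", tolower(role))]]))
    readr::write_tsv(tibble::as_tibble(cols), p)
    paths <- c(paths, p)
    g <- session$geometry[[role]]
    pg <- file.path(dir, sprintf("%s_geometry.tsv", g$participant[1]))
    readr::write_tsv(g[, c("optode", "kind", "hemisphere", "x_cm", "y_cm",
                           "z_cm", "mni_x", "mni_y", "mni_z", "participant")], pg)
    paths <- c(paths, pg)
  }
  pe <- file.path(dir, "events.tsv")
  readr::write_tsv(session$events, pe)
  pt <- file.path(dir, "truth.json")
  jsonlite::write_json(list(
    dyad = session$dyad, video_order = session$truth$video_order,
    fs = session$fs, coupling = session$truth$coupling,
    stimulus_coupling = session$truth$stimulus_coupling,
    designated_channels = session$truth$designated_channels,
    artifact_events = session$truth$artifact_events,
    seeds = session$truth$seeds),
    pt, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, pe, pt))
}

#' Read a participant's intensity TSV
#'
#' @param path Path to an `*_intensity.tsv` written by
#'   [write_session_tsv()].
#' @param fs Sampling rate in Hz (not stored in the TSV).
#' @return An [raw_intensity()] object.
#' @export
read_intensity_tsv <- function(path, fs) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  parts <- regmatches(names(tbl), regexec("^ch(\\d+)_w(\\d+)$", names(tbl)))
  ch <- as.integer(vapply(parts, `[`, character(1), 2))
  wl <- as.integer(vapply(parts, `[`, character(1), 3))
  wavelengths <- sort(unique(wl))
  nch <- max(ch); nt <- nrow(tbl)
  values <- array(NA_real_, c(nch, nt, length(wavelengths)))
  for (k in seq_along(ch))
    values[ch[k], , match(wl[k], wavelengths)] <- tbl[[k]]
  raw_intensity(values, fs, wavelengths = wavelengths)
}

#' Read an events TSV
#' @param path Path to `events.tsv`.
#' @return Event tibble (`onset_s`, `duration_s`, `phase_label`).
#' @export
read_events_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                  col_types = "ddc")
}

#' Read a geometry TSV
#' @param path Path to a `*_geometry.tsv`.
#' @return Optode tibble as consumed by [validate_optode_distances()].
#' @export
read_geometry_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}

#' Write the results of a run
#'
#' Writes the two permutation grids in the standard reporting layout
#' (frequency band, region, real mean (sd), pseudo mean (sd), observed
#' difference, p-value, effect size, CI bounds), the tidy band-coherence
#' values, quality report, and the run manifest.
#'
#' @param run An `"ib_run"` from [run_full()].
#' @param dir Output directory.
#' @return Invisibly, the manifest (with file checksums filled in).
#' @export
write_run <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  for (m in names(run$results)) {
    g <- run$results[[m]]
    out <- tibble::tibble(
      frequency_band = g$band, region = g$roi,
      real_mean = g$real_mean, real_sd = g$real_sd,
      pseudo_mean = g$pseudo_mean, pseudo_sd = g$pseudo_sd,
      observed_diff = g$observed_diff, p_value = g$p,
      effect_size = g$effect_size, ci_low = g$ci_low, ci_high = g$ci_high)
    p <- file.path(dir, sprintf("results_%s.csv", m))
    readr::write_csv(out, p)
    paths <- c(paths, p)
  }
  p <- file.path(dir, "band_values.csv")
  readr::write_csv(run$band_values, p); paths <- c(paths, p)
  p <- file.path(dir, "quality.csv")
  readr::write_csv(run$quality, p); paths <- c(paths, p)
  alloc <- dplyr::bind_rows(run$allocations, .id = "participant")
  p <- file.path(dir, "allocations.csv")
  readr::write_csv(alloc, p); paths <- c(paths, p)
  manifest <- run$manifest
  manifest$files <- lapply(stats::setNames(paths, basename(paths)),
                           function(f) unname(tools::md5sum(f)))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Generate a miniature packaged cohort
#'
#' Writes a 4-dyad cohort (reduced 13-channel cap, 30/15/30 s phases) as
#' plain TSV/JSON under `dir`. Regeneration with the same seed is
#' byte-identical; the test suite relies on this instead of shipping
#' binary fixtures.
#'
#' @param seed Master seed; default 20.
#' @param dir Target directory.
#' @return The cohort object, invisibly; files are written under `dir`.
#' @export
make_fixtures <- function(seed = 20L, dir = tempfile("ib_fixtures_")) {
  config <- sim_config(n_dyads = 4, phase_durations = c(30, 15, 30),
                       n_channels_per_hemisphere = 13, seed = seed)
  cohort <- simulate_cohort(config)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (s in cohort$sessions)
    write_session_tsv(s, file.path(dir, s$dyad))
  readr::write_tsv(cohort$meta, file.path(dir, "dyads.tsv"))
  invisible(cohort)
}
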