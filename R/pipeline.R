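#' Pipeline configuration
#'
#' Bundles every tunable of the full analysis into one serialisable list.
#' Defaults equal the acquisition and analysis settings the pipeline is
#' built around: 0.01-0.4 Hz 5th-order band-pass, wavelet motion correction
#' with IQR factor 1.5, DPF 6 at all wavelengths, 3 cm optode separation,
#' 2 cm ROI radius, cone-of-influence exclusion on, 10,000 permutations.
#'
#' @param sim A [sim_config()] describing the cohort to simulate (or NULL
#'   when running on data read from disk).
#' @param iqr_factor,band_lo,band_hi,filter_order,source_detector_distance,dpf
#'   Preprocessing parameters.
#' @param snr_threshold_db,jump_factor Channel-quality gates.
#' @param exclude_coi Cone-of-influence policy for band averages.
#' @param n_perm,seed Inference settings.
#' @param statistic Test statistic (`"pooled"` or `"welch"`).
#' @return A list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(sim = sim_config(), iqr_factor = 1.5,
                            band_lo = 0.01, band_hi = 0.4, filter_order = 5,
                            source_detector_distance = 3, dpf = c(6, 6, 6),
                            snr_threshold_db = 18, jump_factor = 5,
                            exclude_coi = TRUE, n_perm = 10000, seed = 1L,
                            statistic = "pooled") {
  structure(list(sim = sim, iqr_factor = iqr_factor, band_lo = band_lo,
                 band_hi = band_hi, filter_order = filter_order,
                 source_detector_distance = source_detector_distance,
                 dpf = dpf, snr_threshold_db = snr_threshold_db,
                 jump_factor = jump_factor, exclude_coi = exclude_coi,
                 n_perm = n_perm, seed = as.integer(seed),
                 statistic = statistic), class = "pipeline_config")
}

#' Preprocess every participant of a cohort
#'
#' Runs the quality gates and the fixed preprocessing chain on each
#' participant of each session.
#'
#' @param cohort An `"ib_cohort"` from [simulate_cohort()].
#' @param config A [pipeline_config()].
#' @param channels Optional named list (participant id -> channel ids)
#'   restricting the correction chain to the channels whose activation is
#'   actually consumed downstream; others return NA rows. Quality gates
#'   always run on every channel.
#' @return A list: `activations` (named by participant id), `quality`
#'   (tibble over all participants).
#' @export
preprocess_cohort <- function(cohort, config = pipeline_config(),
                              channels = NULL) {
  activations <- list(); quality <- list()
  for (s in cohort$sessions) {
    for (role in c("A", "B")) {
      pid <- if (role == "A") s$meta$participant_a else s$meta$participant_b
      raw <- s$participants[[role]]
      q <- channel_quality(raw, snr_threshold_db = config$snr_threshold_db,
                           jump_factor = config$jump_factor)
      q$participant <- pid
      quality[[pid]] <- q
      sel <- if (is.null(channels)) NULL else channels[[pid]]
      activations[[pid]] <- preprocess_participant(raw, config, sel)
    }
  }
  list(activations = activations, quality = dplyr::bind_rows(quality))
}

# run the preprocessing chain, optionally restricted to a channel subset
# (channels whose activation is never consumed are returned as NA rows)
preprocess_participant <- function(raw, config, channels = NULL) {
  nch <- dim(raw$values)[1]
  sel <- if (is.null(channels)) seq_len(nch) else sort(unique(channels))
  sub <- raw_intensity(raw$values[sel, , , drop = FALSE], raw$fs,
                       raw$wavelengths)
  act_sub <- preprocess_session(
    sub, iqr_factor = config$iqr_factor, lo = config$band_lo,
    hi = config$band_hi, order = config$filter_order,
    source_detector_distance = config$source_detector_distance,
    dpf = config$dpf)
  if (length(sel) == nch) {
    act_sub$channels <- raw$channels
    return(act_sub)
  }
  values <- matrix(NA_real_, nch, ncol(act_sub$values))
  alpha <- rep(NA_real_, nch)
  degenerate <- rep(TRUE, nch)
  values[sel, ] <- act_sub$values
  alpha[sel] <- act_sub$alpha
  degenerate[sel] <- act_sub$degenerate
  out <- act_sub
  out$values <- values; out$alpha <- alpha; out$degenerate <- degenerate
  out$channels <- raw$channels
  out
}

#' Allocate every participant's channels to ROIs
#'
#' Validates optode registrations, derives channel MNI positions (with
#' cohort-mean fallback), and runs the mutual-nearest ROI assignment for
#' each participant.
#'
#' @param cohort An `"ib_cohort"`.
#' @return A list: `allocations` (named by participant id),
#'   `positions` (named list of channel-position tibbles), `cohort_means`.
#' @export
allocate_cohort <- function(cohort) {
  mont <- cohort$config$montage
  geoms <- list()
  for (s in cohort$sessions) for (role in c("A", "B")) {
    g <- s$geometry[[role]]
    geoms[[g$participant[1]]] <- validate_optode_distances(g, mont)
  }
  first_pass <- lapply(geoms, function(g) {
    tryCatch(channel_positions(g, mont), error = function(e) NULL)
  })
  means <- cohort_mean_positions(Filter(Negate(is.null), first_pass))
  positions <- lapply(geoms, function(g)
    channel_positions(g, mont, cohort_positions = means))
  allocations <- lapply(positions, assign_channels_to_rois)
  list(allocations = allocations, positions = positions, cohort_means = means)
}

# ROI-by-time activation matrix for one participant (NA rows for ROIs with
# no usable channel)
roi_signals <- function(act, allocation, quality = NULL) {
  nt <- ncol(act$values)
  out <- matrix(NA_real_, nrow(allocation), nt,
                dimnames = list(allocation$roi, NULL))
  for (i in seq_len(nrow(allocation))) {
    ch <- allocation$channel[i]
    if (is.na(ch)) next
    if (!is.null(quality) && !quality$included[quality$channel == ch]) next
    if (act$degenerate[ch]) next
    out[i, ] <- act$values[ch, ]
  }
  attr(out, "fs") <- act$fs
  out
}

#' Band coherence for every dyad, ROI and trial
#'
#' The coherence engine: for each (ROI, trial) it computes the Morlet CWT
#' of every participant's ROI activation signal once, then forms the
#' smoothed cross-spectra for every real and pseudo pairing, and averages
#' squared coherence over the three frequency bands.
#'
#' @param roi_mats Named list (participant id -> ROI x time matrix from the
#'   allocation stage) for the full session.
#' @param events Event tibble shared by the cohort (or a named list per
#'   participant).
#' @param pairs Tibble of dyad pairings: `dyad`, `participant_a`,
#'   `participant_b`, `is_real`.
#' @param exclude_coi Cone-of-influence policy for the band means.
#' @param trials Trials to process; default both co-watching phases.
#' @return A tibble: `dyad`, `is_real`, `roi`, `band`, `trial`, `value`,
#'   `coi_excluded_fraction`.
#' @export
cohort_band_coherence <- function(roi_mats, events, pairs,
                                  exclude_coi = TRUE,
                                  trials = c("video1", "video2")) {
  fs <- attr(roi_mats[[1]], "fs")
  rois <- rownames(roi_mats[[1]])
  bands <- frequency_bands()
  per_events <- function(pid) if (is.data.frame(events)) events else events[[pid]]
  out <- list()
  for (trial in trials) {
    segs <- lapply(stats::setNames(names(roi_mats), names(roi_mats)), function(pid)
      extract_trial(roi_mats[[pid]], per_events(pid), trial))
    n <- ncol(segs[[1]])
    plan <- wtc_plan(n, 1 / fs)
    coi <- wtc_coi(n, 1 / fs, plan$fourier_factor)
    in_band <- lapply(seq_len(nrow(bands)), function(bi)
      plan$freqs >= bands$lo_hz[bi] & plan$freqs < bands$hi_hz[bi])
    keep <- lapply(seq_len(nrow(bands)), function(bi)
      outer(coi, plan$freqs[in_band[[bi]]], "<="))  # time x freq eligibility
    for (r in rois) {
      cwts <- list()
      for (pid in names(segs)) {
        x <- segs[[pid]][r, ]
        if (anyNA(x)) { cwts[[pid]] <- NULL; next }
        W <- wtc_cwt(x, plan)
        cwts[[pid]] <- list(W = W, S = wtc_autospec(W, plan))
      }
      for (k in seq_len(nrow(pairs))) {
        a <- cwts[[pairs$participant_a[k]]]
        b <- cwts[[pairs$participant_b[k]]]
        if (is.null(a) || is.null(b)) {
          vals <- rep(NA_real_, nrow(bands)); fracs <- rep(NA_real_, nrow(bands))
        } else {
          Sxy <- wtc_smooth(sweep(a$W * Conj(b$W), 2, plan$scales, "/"), plan)
          r2 <- pmin(pmax(Mod(Sxy)^2 / (a$S * b$S), 0), 1)  # time x scale
          vals <- numeric(nrow(bands)); fracs <- numeric(nrow(bands))
          for (bi in seq_len(nrow(bands))) {
            sub <- r2[, in_band[[bi]], drop = FALSE]
            if (exclude_coi) {
              kp <- keep[[bi]]
              vals[bi] <- if (any(kp)) mean(sub[kp]) else NA_real_
              fracs[bi] <- 1 - sum(kp) / length(sub)
            } else {
              vals[bi] <- mean(sub); fracs[bi] <- 0
            }
          }
        }
        out[[length(out) + 1L]] <- tibble::tibble(
          dyad = pairs$dyad[k], is_real = pairs$is_real[k], roi = r,
          band = bands$band, trial = trial, value = vals,
          coi_excluded_fraction = fracs)
      }
    }
  }
  dplyr::bind_rows(out)
}

#' Dyad measures from band coherence values
#'
#' Pivots per-trial band coherence into the two inference measures
#' (`cowatch1`, `change`) plus the supplementary across-video `mean`.
#'
#' @param band_values Output of [cohort_band_coherence()].
#' @return A tibble: `dyad`, `is_real`, `roi`, `band`, `cowatch1`,
#'   `change`, `mean`.
#' @export
coherence_measures <- function(band_values) {
  wide <- tidyr::pivot_wider(
    band_values[, c("dyad", "is_real", "roi", "band", "trial", "value")],
    names_from = "trial", values_from = "value")
  tibble::tibble(
    dyad = wide$dyad, is_real = wide$is_real, roi = wide$roi,
    band = wide$band, cowatch1 = wide$video1,
    change = wide$video2 - wide$video1,
    mean = (wide$video1 + wide$video2) / 2)
}

#' Run the full pipeline
#'
#' Executes every stage on a simulated cohort: simulate, preprocess,
#' allocate, pseudo-dyad construction, band coherence, and the two
#' permutation grids (co-watching video 1, and conversation-induced
#' change). Optionally writes the result tables, a run manifest with
#' config hash and file checksums, and per-stage provenance to `out_dir`.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional output directory.
#' @return A list of class `"ib_run"`: `results` (named list of
#'   [permutation_grid()] tibbles for `cowatch1` and `change`), `measures`,
#'   `band_values`, `quality`, `allocations`, `meta` (real + pseudo),
#'   `manifest`.
#' @export
run_full <- function(config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(config$sim)) abort("run_full currently requires a simulation config")
  cohort <- simulate_cohort(config$sim)
  al <- allocate_cohort(cohort)
  # only channels allocated to an ROI feed coherence; the heavy per-channel
  # correction chain is restricted to those (quality runs on every channel)
  used <- lapply(al$allocations, function(a) a$channel[!is.na(a$channel)])
  pp <- preprocess_cohort(cohort, config, channels = used)
  qual <- split(pp$quality, pp$quality$participant)
  roi_mats <- lapply(stats::setNames(names(pp$activations), names(pp$activations)),
                     function(pid) roi_signals(pp$activations[[pid]],
                                               al$allocations[[pid]],
                                               qual[[pid]]))
  pseudo <- build_pseudo_dyads(cohort$meta)
  pairs <- dplyr::bind_rows(
    cohort$meta[, c("dyad", "participant_a", "participant_b", "is_real")],
    pseudo[, c("dyad", "participant_a", "participant_b", "is_real")])
  band_values <- cohort_band_coherence(roi_mats, cohort$sessions[[1]]$events,
                                       pairs, exclude_coi = config$exclude_coi)
  measures <- coherence_measures(band_values)
  results <- list(
    cowatch1 = permutation_grid(measures, "cowatch1", n_perm = config$n_perm,
                                seed = derive_seed(config$seed, 41),
                                statistic = config$statistic),
    change = permutation_grid(measures, "change", n_perm = config$n_perm,
                              seed = derive_seed(config$seed, 43),
                              statistic = config$statistic))
  manifest <- list(
    package_version = as.character(utils::packageVersion("interbrain")),
    r_version = R.version.string,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = config$seed, n_perm = config$n_perm,
    config_hash = config_hash(config),
    n_dyads = nrow(cohort$meta), n_pseudo_dyads = nrow(pseudo),
    permutation_draws = vapply(results, attr, numeric(1), "draws"))
  run <- structure(list(results = results, measures = measures,
                        band_values = band_values, quality = pp$quality,
                        allocations = al$allocations,
                        meta = dplyr::bind_rows(cohort$meta, pseudo),
                        manifest = manifest, config = config),
                   class = "ib_run")
  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

#' @export
print.ib_run <- function(x, ...) {
  cat(sprintf("<ib_run> %d real + %d pseudo dyads, %d permutations per cell\n",
              sum(x$meta$is_real), sum(!x$meta$is_real), x$config$n_perm))
  for (m in names(x$results)) {
    top <- x$results[[m]][which.min(x$results[[m]]$p), ]
    cat(sprintf("  %s: min p = %.4g at %s/%s\n", m, top$p, top$roi, top$band))
  }
  invisible(x)
}

# canonical JSON hash of a config (montage omitted: derived from its size)
config_hash <- function(config) {
  x <- config
  if (!is.null(x$sim)) x$sim$montage <- NULL
  json <- jsonlite::toJSON(unclass_rec(x), auto_unbox = TRUE, digits = NA)
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(json, f)
  unname(tools::md5sum(f))
}

unclass_rec <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_rec) else x
}
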