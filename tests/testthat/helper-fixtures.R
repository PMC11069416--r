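# shared test helpers: small deterministic objects built in code

# raw-intensity object from a channels x time x 3 array of OD-scale signals
raw_from_od <- function(od, fs = 8.33, i0 = 1000) {
  raw_intensity(i0 * exp(-od), fs = fs)
}

# single-channel raw object from one series per wavelength (recycled)
raw_one_channel <- function(x, fs = 8.33) {
  arr <- array(rep(x, 3), dim = c(1, length(x), 3))
  raw_intensity(arr, fs = fs)
}

# subset a raw recording to chosen channels (stages operate per channel)
sub_raw <- function(raw, ch) {
  raw_intensity(raw$values[ch, , , drop = FALSE], raw$fs, raw$wavelengths)
}

# small session config used across tests: short conversation phase and the
# reduced 13-channel cap keep runtimes down while exercising every stage
test_config <- function(seed = 1, ...) {
  sim_config(n_dyads = 4, phase_durations = c(120, 30, 120),
             n_channels_per_hemisphere = 13, seed = seed, ...)
}

# designated channel id for an ROI in a config's montage
designated_channel <- function(config, roi) {
  ch <- config$montage$channels
  ch$channel[!is.na(ch$designated_roi) & ch$designated_roi == roi]
}

# brute-force stable-allocation oracle: enumerate all injective
# within-radius assignments and return the one with no blocking pair
# (a channel and ROI that are mutually closer than their current matches)
allocation_oracle <- function(positions, rois) {
  P <- as.matrix(positions[, c("mni_x", "mni_y", "mni_z")])
  R <- as.matrix(rois[, c("x", "y", "z")])
  D <- as.matrix(stats::dist(rbind(P, R)))[seq_len(nrow(P)),
                                           nrow(P) + seq_len(nrow(R)), drop = FALSE]
  radius <- rois$radius_mm
  nC <- nrow(P); nR <- nrow(R)
  # candidate assignments: channel -> roi or 0
  choices <- lapply(seq_len(nC), function(i) c(0, which(D[i, ] <= radius)))
  grids <- expand.grid(choices)
  best <- NULL
  for (k in seq_len(nrow(grids))) {
    a <- as.integer(grids[k, ])
    used <- a[a > 0]
    if (anyDuplicated(used)) next
    # maximality: an unmatched channel and unmatched in-radius roi is a
    # blocking pair too
    blocking <- FALSE
    for (i in seq_len(nC)) for (r in seq_len(nR)) {
      if (D[i, r] > radius[r]) next
      cur_i <- a[i]
      holder <- which(a == r)
      i_prefers <- cur_i == 0 || D[i, r] < D[i, cur_i]
      r_prefers <- length(holder) == 0 || D[i, r] < D[holder, r]
      if (i_prefers && r_prefers) { blocking <- TRUE; break }
    }
    if (!blocking) { best <- a; break }
  }
  best
}
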