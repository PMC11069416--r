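#' Region-of-interest table
#'
#' The eight cortical regions of interest used throughout the package, given
#' as MNI centre coordinates with the channel-assignment radius. Four regions
#' are defined per hemisphere: dorso-lateral prefrontal cortex (DLPF),
#' ventral premotor cortex (vPM), temporo-parietal junction (TPJ) and
#' superior parietal lobe (SPL). A channel can only be allocated to a region
#' if its MNI position lies within `radius_mm` of the centre.
#'
#' @param radius_mm Assignment radius around each centre, in millimetres.
#'   Default 20 mm.
#' @return A tibble with one row per ROI: `roi` (e.g. `"TPJ_R"`), `region`,
#'   `laterality` (`"L"`/`"R"`), `x`, `y`, `z` (MNI mm) and `radius_mm`.
#' @examples
#' roi_table()
#' @export
roi_table <- function(radius_mm = 20) {
  stopifnot(is.numeric(radius_mm), radius_mm > 0)
  tbl <- tibble::tribble(
    ~region, ~laterality, ~x,  ~y,  ~z,
    "DLPF",  "R",          44,  34,  28,
    "DLPF",  "L",         -46,  30,  30,
    "vPM",   "R",          64,  -4,  20,
    "vPM",   "L",         -58,  -8,  28,
    "TPJ",   "R",          58, -56,  18,
    "TPJ",   "L",         -54, -56,  22,
    "SPL",   "R",          37, -63,  59,
    "SPL",   "L",         -40, -64,  53
  )
  tbl$roi <- paste(tbl$region, tbl$laterality, sep = "_")
  tbl$radius_mm <- radius_mm
  tbl[, c("roi", "region", "laterality", "x", "y", "z", "radius_mm")]
}

#' Frequency bands of interest
#'
#' The three period ranges over which wavelet coherence is summarised:
#' high (0.1-0.2 Hz, 5-10 s periods), medium (0.03-0.1 Hz, 10-30 s) and
#' low (0.02-0.03 Hz, 30-60 s). Bands are half-open intervals
#' `[lo, hi)` so that the three bands tile 0.02-0.2 Hz without overlap.
#' Frequencies below 0.02 Hz are dominated by slow noise and frequencies
#' above 0.2 Hz are too fast to be of hemodynamic origin, so neither is
#' ever summarised.
#'
#' @return A tibble with columns `band` (`"high"`, `"medium"`, `"low"`),
#'   `lo_hz`, `hi_hz`.
#' @examples
#' frequency_bands()
#' @export
frequency_bands <- function() {
  tibble::tribble(
    ~band,     ~lo_hz, ~hi_hz,
    "high",     0.10,   0.20,
    "medium",   0.03,   0.10,
    "low",      0.02,   0.03
  )
}

band_names <- function() frequency_bands()$band

phase_names <- function() c("video1", "conversation", "video2")
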