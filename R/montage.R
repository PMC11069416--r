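#' Reference optode montage
#'
#' Builds the cap layout used by the synthetic-data generator and by the
#' geometry checks: per hemisphere a 2-row grid of alternating sources and
#' detectors at 3 cm nominal spacing (7 sources and 7 detectors per
#' hemisphere in the default layout), forming 19 channels per hemisphere
#' from adjacent source-detector pairs. Channel ids run 1-19 on the right
#' hemisphere and 20-38 on the left.
#'
#' Nominal MNI coordinates are constructed so that, per hemisphere, four of
#' the vertical (between-row) channels sit exactly on the four ROI centres
#' of [roi_table()], with the remaining channels strung along the arc
#' between them. These designated channels are the ones into which the
#' generator injects ROI-level hemodynamics.
#'
#' @param n_channels_per_hemisphere Channels per hemisphere; must satisfy
#'   `n = 3 * ncol - 2` for an integer number of grid columns `ncol >= 5`
#'   (19 gives the default 7-column cap; 13 gives a reduced 5-column cap).
#' @return A list with class `"ib_montage"`:
#'   * `optodes`: tibble of optode id, kind (`source`/`detector`),
#'     hemisphere, grid row/column, nominal real-space x/y/z (cm) and
#'     nominal MNI x/y/z (mm);
#'   * `channels`: tibble of channel id, source/detector optode ids,
#'     hemisphere, nominal MNI midpoint and `designated_roi` (NA for
#'     channels that carry no ROI signal in the generator);
#'   * `neighbors`: tibble of optode-id pairs adjacent on the grid (the
#'     graph over which inter-optode distances are validated).
#' @examples
#' m <- reference_montage()
#' nrow(m$channels)   # 38
#' @export
reference_montage <- function(n_channels_per_hemisphere = 19) {
  ncol_grid <- (n_channels_per_hemisphere + 2) / 3
  if (ncol_grid != round(ncol_grid) || ncol_grid < 5)
    abort("`n_channels_per_hemisphere` must equal 3*ncol - 2 for integer ncol >= 5 (e.g. 13, 19)")
  ncol_grid <- as.integer(ncol_grid)

  rois <- roi_table()
  build_hemi <- function(hemi) {
    centers <- rois[rois$laterality == hemi, c("x", "y", "z")]
    centers <- as.matrix(centers)  # DLPF, vPM, TPJ, SPL order
    rownames(centers) <- rois$roi[rois$laterality == hemi]
    # column midpoints along the DLPF -> vPM -> TPJ -> SPL arc; designated
    # columns land exactly on the centres
    if (ncol_grid == 7) {
      mids <- rbind(
        centers[1, ] + 0.6 * (centers[1, ] - centers[2, ]),
        centers[1, ],
        (centers[1, ] + centers[2, ]) / 2,
        centers[2, ],
        (centers[2, ] + centers[3, ]) / 2,
        centers[3, ],
        centers[4, ])
      designated <- c(NA, 1L, NA, 2L, NA, 3L, 4L)
    } else {
      extra <- ncol_grid - 4L
      lead <- lapply(rev(seq_len(extra)), function(i)
        centers[1, ] + 0.5 * i * (centers[1, ] - centers[2, ]))
      mids <- rbind(do.call(rbind, lead), centers)
      designated <- c(rep(NA, extra), 1L, 2L, 3L, 4L)
    }
    offset <- c(0, 0, 15)  # mm, splits each column midpoint into two optodes
    list(mids = mids, designated = designated, offset = offset)
  }

  optodes <- list(); channels <- list(); neighbors <- list()
  oid <- 0L
  for (hemi in c("R", "L")) {
    hspec <- build_hemi(hemi)
    x0 <- if (hemi == "R") 0 else 30  # real-space cm offset between caps
    # optode grid: row 1 (top), row 2 (bottom); sources at odd columns in
    # row 1 and even columns in row 2
    ids <- matrix(NA_integer_, 2, ncol_grid)
    for (r in 1:2) for (c in seq_len(ncol_grid)) {
      oid <- oid + 1L
      ids[r, c] <- oid
      is_source <- if (r == 1) (c %% 2 == 1) else (c %% 2 == 0)
      mni <- unname(hspec$mids[c, ] + (if (r == 1) 1 else -1) * hspec$offset)
      optodes[[oid]] <- tibble::tibble(
        optode = oid, kind = if (is_source) "source" else "detector",
        hemisphere = hemi, row = r, col = c,
        x_cm = x0 + 3 * (c - 1), y_cm = 3 * (2 - r), z_cm = 0,
        mni_x = mni[1], mni_y = mni[2], mni_z = mni[3])
    }
    roi_by_col <- rep(NA_character_, ncol_grid)
    roi_by_col[!is.na(hspec$designated)] <-
      rois$roi[rois$laterality == hemi][hspec$designated[!is.na(hspec$designated)]]
    ch_local <- list()
    for (r in 1:2) for (c in seq_len(ncol_grid - 1)) {
      ch_local[[length(ch_local) + 1L]] <- list(
        src = ids[r, c], det = ids[r, c + 1], roi = NA_character_)
    }
    for (c in seq_len(ncol_grid)) {
      ch_local[[length(ch_local) + 1L]] <- list(
        src = ids[1, c], det = ids[2, c], roi = roi_by_col[c])
    }
    for (ch in ch_local) {
      # orient so src is the source optode
      k1 <- optodes[[ch$src]]$kind
      src <- if (k1 == "source") ch$src else ch$det
      det <- if (k1 == "source") ch$det else ch$src
      channels[[length(channels) + 1L]] <- tibble::tibble(
        channel = length(channels) + 1L, source = src, detector = det,
        hemisphere = hemi, designated_roi = ch$roi)
    }
    for (r in 1:2) for (c in seq_len(ncol_grid - 1))
      neighbors[[length(neighbors) + 1L]] <- c(ids[r, c], ids[r, c + 1])
    for (c in seq_len(ncol_grid))
      neighbors[[length(neighbors) + 1L]] <- c(ids[1, c], ids[2, c])
  }
  optodes <- dplyr::bind_rows(optodes)
  channels <- dplyr::bind_rows(channels)
  omni <- as.matrix(optodes[, c("mni_x", "mni_y", "mni_z")])
  mid <- (omni[channels$source, ] + omni[channels$detector, ]) / 2
  channels$mni_x <- mid[, 1]; channels$mni_y <- mid[, 2]; channels$mni_z <- mid[, 3]
  neighbors <- tibble::tibble(
    a = vapply(neighbors, `[`, integer(1), 1),
    b = vapply(neighbors, `[`, integer(1), 2))
  structure(list(optodes = optodes, channels = channels, neighbors = neighbors,
                 n_channels_per_hemisphere = as.integer(n_channels_per_hemisphere)),
            class = "ib_montage")
}

#' @export
print.ib_montage <- function(x, ...) {
  cat(sprintf("<ib_montage> %d optodes, %d channels (%d per hemisphere)\n",
              nrow(x$optodes), nrow(x$channels), x$n_channels_per_hemisphere))
  invisible(x)
}
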