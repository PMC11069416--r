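#' Validate optode registrations against the cap geometry
#'
#' An optode is accepted as correctly digitised when its real-space distance
#' to every neighbouring optode on the cap lies between 2.5 and 3.5 cm
#' (inclusive at both bounds), the tolerance band around the 3 cm nominal
#' spacing. Neighbours are the grid-adjacent optode pairs of the montage.
#'
#' @param optodes Tibble of one participant's optodes with columns `optode`,
#'   `x_cm`, `y_cm`, `z_cm` (real-space digitiser coordinates).
#' @param montage An [reference_montage()] object supplying the neighbour
#'   graph.
#' @param bounds Acceptance interval in cm; default `c(2.5, 3.5)`.
#' @return The input tibble with a logical `valid` column.
#' @export
validate_optode_distances <- function(optodes, montage = reference_montage(),
                                      bounds = c(2.5, 3.5)) {
  stopifnot(inherits(montage, "ib_montage"))
  nb <- montage$neighbors
  missing_nb <- setdiff(optodes$optode, c(nb$a, nb$b))
  if (length(missing_nb) > 0)
    abort(sprintf("optode(s) %s have no neighbours in the montage",
                  paste(missing_nb, collapse = ", ")))
  pos <- as.matrix(optodes[, c("x_cm", "y_cm", "z_cm")])
  rownames(pos) <- optodes$optode
  valid <- rep(TRUE, nrow(optodes))
  names(valid) <- optodes$optode
  for (i in seq_len(nrow(nb))) {
    a <- as.character(nb$a[i]); b <- as.character(nb$b[i])
    if (!(a %in% rownames(pos)) || !(b %in% rownames(pos))) next
    d <- euclid(pos[a, ], pos[b, ])
    if (d < bounds[1] || d > bounds[2]) {
      valid[a] <- FALSE
      valid[b] <- FALSE
    }
  }
  optodes$valid <- unname(valid[as.character(optodes$optode)])
  optodes
}

#' Channel MNI positions with fallback provenance
#'
#' Computes each channel's MNI position as the midpoint of its two forming
#' optodes when both are validly registered (`measured-midpoint`). Channels
#' formed by a mis-located optode take the cohort's mean position for that
#' channel (`partial-fallback`). When more than half of a participant's
#' optodes are mis-located, or MNI registration is absent altogether, every
#' channel takes the cohort mean (`group-mean`).
#'
#' @param optodes Tibble of one participant's optodes with `valid` flags
#'   (see [validate_optode_distances()]) and `mni_x/y/z` columns (may be NA
#'   when registration failed).
#' @param montage The montage defining channel-forming optode pairs.
#' @param cohort_positions Optional tibble `channel`, `mni_x`, `mni_y`,
#'   `mni_z` of cohort mean positions, required as soon as any fallback is
#'   needed (see [cohort_mean_positions()]).
#' @return A tibble `channel`, `mni_x`, `mni_y`, `mni_z`, `provenance`.
#' @export
channel_positions <- function(optodes, montage = reference_montage(),
                              cohort_positions = NULL) {
  stopifnot(inherits(montage, "ib_montage"))
  ch <- montage$channels
  if (!"valid" %in% names(optodes))
    abort("run validate_optode_distances() first (no `valid` column)")
  pos <- as.matrix(optodes[, c("mni_x", "mni_y", "mni_z")])
  rownames(pos) <- optodes$optode
  valid <- stats::setNames(optodes$valid, optodes$optode)
  registration_absent <- all(is.na(pos))
  whole_group <- registration_absent || mean(!valid) > 0.5
  rows <- lapply(seq_len(nrow(ch)), function(i) {
    s <- as.character(ch$source[i]); d <- as.character(ch$detector[i])
    if (!whole_group && isTRUE(valid[s]) && isTRUE(valid[d]) &&
        all(is.finite(pos[s, ])) && all(is.finite(pos[d, ]))) {
      mid <- unname((pos[s, ] + pos[d, ]) / 2)
      tibble::tibble(channel = ch$channel[i], mni_x = mid[1], mni_y = mid[2],
                     mni_z = mid[3], provenance = "measured-midpoint")
    } else {
      tibble::tibble(channel = ch$channel[i], mni_x = NA_real_,
                     mni_y = NA_real_, mni_z = NA_real_,
                     provenance = if (whole_group) "group-mean" else "partial-fallback")
    }
  })
  out <- dplyr::bind_rows(rows)
  needs <- out$provenance != "measured-midpoint"
  if (any(needs)) {
    if (is.null(cohort_positions))
      abort(sprintf("cohort mean positions required for channel(s) %s but not supplied",
                    paste(out$channel[needs], collapse = ", ")))
    m <- match(out$channel[needs], cohort_positions$channel)
    if (anyNA(m))
      abort("cohort_positions does not cover all fallback channels")
    out$mni_x[needs] <- cohort_positions$mni_x[m]
    out$mni_y[needs] <- cohort_positions$mni_y[m]
    out$mni_z[needs] <- cohort_positions$mni_z[m]
  }
  out
}

#' Cohort mean channel positions
#'
#' Per-channel arithmetic mean of MNI positions over the participants whose
#' position for that channel was directly measured (`measured-midpoint`
#' provenance only), used as the fallback location for participants with
#' mis-located optodes or failed registration.
#'
#' @param position_list List of per-participant tibbles from
#'   [channel_positions()] (computed without fallback, i.e. participants
#'   whose channels are all measured), or with fallback channels present
#'   (they are ignored).
#' @return A tibble `channel`, `mni_x`, `mni_y`, `mni_z`, `n_participants`.
#' @export
cohort_mean_positions <- function(position_list) {
  all_pos <- dplyr::bind_rows(position_list)
  all_pos <- all_pos[all_pos$provenance == "measured-midpoint", ]
  if (nrow(all_pos) == 0) abort("no measured channel positions in cohort")
  dplyr::summarise(
    dplyr::group_by(all_pos, .data$channel),
    mni_x = mean(.data$mni_x), mni_y = mean(.data$mni_y),
    mni_z = mean(.data$mni_z), n_participants = dplyr::n(),
    .groups = "drop")
}

#' Allocate channels to regions of interest
#'
#' Assigns channels to ROIs under the mutual-nearest rule: each channel's
#' candidate is its nearest ROI within the assignment radius; when two
#' channels compete for one ROI the nearer channel wins and the loser moves
#' to its next-nearest ROI with a free slot, iterating to a fixed point
#' (deferred acceptance with a common distance ranking). The result is
#' injective both ways: at most one channel per ROI and one ROI per
#' channel. Ties are broken by lower channel id, then by ROI table order.
#'
#' @param positions Tibble of channel MNI positions (from
#'   [channel_positions()]).
#' @param rois ROI table; default [roi_table()].
#' @return A tibble with one row per ROI: `roi`, `channel` (NA when the ROI
#'   receives no channel), `distance_mm`, plus an `unassigned` attribute
#'   listing channels allocated to no ROI.
#' @export
assign_channels_to_rois <- function(positions, rois = roi_table()) {
  stopifnot(all(c("channel", "mni_x", "mni_y", "mni_z") %in% names(positions)))
  P <- as.matrix(positions[, c("mni_x", "mni_y", "mni_z")])
  if (!all(is.finite(P))) abort("channel positions must be finite")
  R <- as.matrix(rois[, c("x", "y", "z")])
  D <- outer(rowSums(P^2), rep(1, nrow(R))) +
    outer(rep(1, nrow(P)), rowSums(R^2)) - 2 * P %*% t(R)
  D <- sqrt(pmax(D, 0))  # channels x rois, mm
  radius <- rois$radius_mm
  # preference lists: eligible ROIs per channel, nearest first (ties: ROI order)
  prefs <- lapply(seq_len(nrow(P)), function(i) {
    elig <- which(D[i, ] <= radius)
    elig[order(D[i, elig], elig)]
  })
  cursor <- rep(1L, nrow(P))
  holder <- rep(NA_integer_, nrow(R))   # channel row index held by each ROI
  free <- order(positions$channel)      # proposal queue, lowest channel id first
  while (length(free) > 0) {
    i <- free[1]
    free <- free[-1]
    if (cursor[i] > length(prefs[[i]])) next  # exhausted: stays unassigned
    r <- prefs[[i]][cursor[i]]
    cursor[i] <- cursor[i] + 1L
    j <- holder[r]
    if (is.na(j)) {
      holder[r] <- i
    } else if (D[i, r] < D[j, r] ||
               (D[i, r] == D[j, r] && positions$channel[i] < positions$channel[j])) {
      holder[r] <- i
      free <- c(free, j)
    } else {
      free <- c(free, i)
    }
  }
  out <- tibble::tibble(
    roi = rois$roi,
    channel = ifelse(is.na(holder), NA_integer_, positions$channel[holder]),
    distance_mm = ifelse(is.na(holder), NA_real_,
                         D[cbind(holder, seq_len(nrow(R)))]))
  attr(out, "unassigned") <-
    setdiff(positions$channel, out$channel[!is.na(out$channel)])
  out
}

#' Cohort-level ROI data-sufficiency screen
#'
#' Flags ROIs that received channels from too few participants to be
#' analysed. The default threshold is the cohort's mean number of
#' contributing participants per ROI, mirroring the logic of screening ROIs
#' against the average data availability of the sample.
#'
#' @param allocations List (or bind) of per-participant allocation tibbles
#'   from [assign_channels_to_rois()].
#' @param min_participants Minimum contributing participants; default the
#'   cohort mean across ROIs.
#' @return A tibble `roi`, `n_participants`, `retained`.
#' @export
screen_rois <- function(allocations, min_participants = NULL) {
  tbl <- dplyr::bind_rows(allocations)
  counts <- dplyr::summarise(
    dplyr::group_by(tbl, .data$roi),
    n_participants = sum(!is.na(.data$channel)), .groups = "drop")
  thr <- min_participants %||% mean(counts$n_participants)
  counts$retained <- counts$n_participants >= thr
  counts
}
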