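#' Extract a trial window from an activation signal
#'
#' Selects the samples of one experimental phase using the session's event
#' table. The window is half-open: samples `[round(onset * fs),
#' round((onset + duration) * fs))`, zero-based, so adjacent phases share no
#' sample.
#'
#' @param act An `"ib_activation"` object (or a channels x time matrix with
#'   an `fs` attribute).
#' @param events Event tibble with columns `onset_s`, `duration_s`,
#'   `phase_label`.
#' @param phase Phase label to extract (e.g. `"video1"`).
#' @return An object of the same type as `act`, restricted to the trial
#'   samples.
#' @export
extract_trial <- function(act, events, phase) {
  stopifnot(all(c("onset_s", "duration_s", "phase_label") %in% names(events)))
  row <- events[events$phase_label == phase, ]
  if (nrow(row) == 0)
    abort(sprintf("phase '%s' not present; available phases: %s", phase,
                  paste(unique(events$phase_label), collapse = ", ")))
  row <- row[1, ]
  fs <- if (inherits(act, "ib_activation")) act$fs else attr(act, "fs")
  if (is.null(fs)) abort("`act` carries no sampling rate")
  from <- round(row$onset_s * fs)           # zero-based, inclusive
  to <- round((row$onset_s + row$duration_s) * fs)  # zero-based, exclusive
  idx <- seq.int(from + 1, length.out = max(to - from, 0))
  if (inherits(act, "ib_activation")) {
    out <- act
    out$values <- act$values[, idx, drop = FALSE]
    out
  } else {
    out <- act[, idx, drop = FALSE]
    attr(out, "fs") <- fs
    out
  }
}

#' Dyad-level coherence measures
#'
#' Combines the band coherence of the two co-watching trials into the two
#' measures carried to inference: coherence while co-watching the first
#' video (`cowatch1`) and the conversation-induced change (`change`, second
#' video minus first). The across-video mean is retained as a supplementary
#' summary only.
#'
#' @param v1,v2 Band coherence for the first and second video trial: either
#'   numeric scalars or one-row tibbles as returned by [band_average()]
#'   augmented with `dyad`/`roi`/`band` keys (keys must match between the
#'   two).
#' @return A one-row tibble with `cowatch1`, `change`, `mean` (plus any
#'   matched key columns).
#' @export
dyad_measures <- function(v1, v2) {
  if (is.numeric(v1) && is.numeric(v2)) {
    stopifnot(length(v1) == 1, length(v2) == 1)
    return(tibble::tibble(cowatch1 = v1, change = v2 - v1, mean = (v1 + v2) / 2))
  }
  keys <- intersect(c("dyad", "roi", "band"), intersect(names(v1), names(v2)))
  for (k in keys)
    if (!identical(v1[[k]], v2[[k]]))
      abort(sprintf("trial values disagree on key '%s' (%s vs %s)",
                    k, v1[[k]], v2[[k]]))
  out <- dyad_measures(v1$value, v2$value)
  if (length(keys) > 0) out <- dplyr::bind_cols(v1[, keys], out)
  out
}
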