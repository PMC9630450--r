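#' @include distance.R
NULL

#' Per-frame on/off-vessel classification of a track
#'
#' Labels each frame "on" when the cell position is fused with the vessel
#' signal: with `contactToleranceUm = 0` (the default) a frame is on iff its
#' position falls inside the mask occupancy; with a positive tolerance a
#' frame is on iff inside or within that distance of the vessel surface.
#' Contiguous on-periods are returned as a run-length segmentation.
#'
#' @param tr a [Track-class].
#' @param masks a single [VesselMask-class] (static vasculature) or a list
#'   with one mask per frame.
#' @param config an [AnalysisConfig-class].
#' @return list with `labels` (data.frame `frame, t_h, on`) and `runs`
#'   (data.frame `start_frame, end_frame, t_start, t_end, duration_h, on`).
#' @export
classifyTrackContacts <- function(tr, masks, config = analysisConfig()) {
  stopifnot(is(tr, "Track"))
  s <- samples(tr)
  n <- nrow(s)
  maskFor <- function(k) {
    if (is(masks, "VesselMask")) masks
    else {
      if (length(masks) < n)
        stop("a mask is required for each frame", call. = FALSE)
      masks[[k]]
    }
  }
  pts <- as.matrix(s[, c("x_um", "y_um", "z_um")])
  if (is(masks, "VesselMask")) {
    on <- insideOccupancy(pts, masks)
    if (config@contactToleranceUm > 0 && nrow(masks@surface)) {
      d <- minSurfaceDistance(pts, masks@surface, voxelSize(masks))
      on <- on | d <= config@contactToleranceUm
    }
  } else {
    on <- vapply(seq_len(n), function(k) {
      m <- maskFor(k)
      inside <- insideOccupancy(pts[k, , drop = FALSE], m)
      if (!inside && config@contactToleranceUm > 0 && nrow(m@surface))
        inside <- minSurfaceDistance(pts[k, , drop = FALSE], m@surface,
                                     voxelSize(m)) <= config@contactToleranceUm
      inside
    }, logical(1))
  }
  r <- rle(on)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- data.frame(start_frame = starts, end_frame = ends,
                     t_start = s$t_h[starts], t_end = s$t_h[ends],
                     duration_h = s$t_h[ends] - s$t_h[starts], on = r$values)
  list(labels = data.frame(frame = seq_len(n), t_h = s$t_h, on = on),
       runs = runs)
}

#' Maximum migration distance of persistently vessel-associated cells
#'
#' Implements the on-vessel persistence selection: a track qualifies when it
#' has some contiguous on-vessel period lasting at least `minOnVesselH`
#' hours; for qualifying tracks the maximum Euclidean distance from the
#' start position over the whole observation is returned, otherwise `NA`
#' (track not selected).
#'
#' @param tr a [Track-class].
#' @param contacts result of [classifyTrackContacts()] for `tr`.
#' @param config an [AnalysisConfig-class].
#' @return maximum distance in um, or `NA_real_` when not selected.
#' @export
onVesselPersistence <- function(tr, contacts, config = analysisConfig()) {
  runs <- contacts$runs
  if (!any(runs$on & runs$duration_h >= config@minOnVesselH))
    return(NA_real_)
  s <- samples(tr)
  max(sqrt((s$x_um - s$x_um[1])^2 + (s$y_um - s$y_um[1])^2 +
             (s$z_um - s$z_um[1])^2))
}

#' Per-field off/on migration ratio
#'
#' For each objective field, counts tracks migrating off versus on the
#' vessel/endothelial structure and reports their ratio. Only tracks
#' traceable for at least `traceabilityMinH` hours are counted; a track is
#' called "on" when the majority of its labelled frames are on (ties count
#' as off). A field with zero on-tracks gets an `NA` ratio with a flag,
#' never infinity.
#'
#' @param tracks list of [Track-class].
#' @param contactsList list of [classifyTrackContacts()] results, parallel
#'   to `tracks`.
#' @param fieldIds character/factor vector assigning each track to a field.
#' @param config an [AnalysisConfig-class].
#' @return data.frame with `field, n_on, n_off, n_excluded, ratio, flagged`.
#' @export
offOnRatio <- function(tracks, contactsList, fieldIds,
                       config = analysisConfig()) {
  stopifnot(length(tracks) == length(contactsList),
            length(tracks) == length(fieldIds))
  traceable <- vapply(tracks, function(tr) {
    t <- samples(tr)$t_h
    (max(t) - min(t)) >= config@traceabilityMinH
  }, logical(1))
  onTrack <- vapply(contactsList, function(ct) mean(ct$labels$on) > 0.5,
                    logical(1))
  fields <- unique(as.character(fieldIds))
  rows <- lapply(fields, function(f) {
    inF <- as.character(fieldIds) == f
    nOn <- sum(inF & traceable & onTrack)
    nOff <- sum(inF & traceable & !onTrack)
    data.frame(field = f, n_on = nOn, n_off = nOff,
               n_excluded = sum(inF & !traceable),
               ratio = if (nOn > 0) nOff / nOn else NA_real_,
               flagged = nOn == 0)
  })
  do.call(rbind, rows)
}
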