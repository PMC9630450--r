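#' @include AllClasses.R
NULL

## Signed in-plane angle helpers ---------------------------------------------
##
## Directions are measured in the slice plane (x, y) from +x,
## counter-clockwise positive, because the emulated acquisition merges ~10
## focal planes (~50 um) before tracing. Speeds use the full 3D displacement;
## the 2D in-plane speed is reported alongside.

hemisphereSign <- function(hemi) if (identical(hemi, "left")) -1 else 1

#' Per-frame motion steps of a track
#'
#' One step per consecutive sample pair: midpoint time, 3D and in-plane
#' displacement, speed (`displacement / dt`, exactly), in-plane direction
#' (degrees from +x, counter-clockwise; `NA` when the in-plane displacement
#' is zero) and the speed gate (`TRUE` iff the speed strictly exceeds
#' `speedGateUmh`; frames at exactly the gate are not gated).
#'
#' @param tr a [Track-class] (at least two samples, strictly increasing
#'   times; duplicate timestamps are rejected naming the offending index).
#' @param config an [AnalysisConfig-class].
#' @return data.frame with columns `track_id, t_mid, dt_h, displacement_um,
#'   displacement2d_um, speed_umh, speed2d_umh, direction_deg, gated`.
#' @examples
#' tr <- track("a", data.frame(t_h = c(0, 0.5), x_um = c(0, 5), y_um = 0,
#'                             z_um = 0))
#' frameSteps(tr)$speed_umh  # 10 um/h, not gated (strict inequality)
#' @export
frameSteps <- function(tr, config = analysisConfig()) {
  stopifnot(is(tr, "Track"), is(config, "AnalysisConfig"))
  s <- samples(tr)
  bad <- which(diff(s$t_h) <= 0)
  if (length(bad))
    stop(sprintf("duplicate or non-increasing timestamp at sample index %d",
                 bad[1] + 1L), call. = FALSE)
  n <- nrow(s)
  dt <- diff(s$t_h)
  dx <- diff(s$x_um); dy <- diff(s$y_um); dz <- diff(s$z_um)
  d2 <- sqrt(dx^2 + dy^2)
  d3 <- sqrt(dx^2 + dy^2 + dz^2)
  dir <- ifelse(d2 > 0, atan2(dy, dx) * 180 / pi, NA_real_)
  data.frame(track_id = trackId(tr),
             t_mid = (s$t_h[-n] + s$t_h[-1]) / 2,
             dt_h = dt,
             displacement_um = d3,
             displacement2d_um = d2,
             speed_umh = d3 / dt,
             speed2d_umh = d2 / dt,
             direction_deg = dir,
             gated = d3 / dt > config@speedGateUmh)
}

## gated steps with a defined direction, in order
gatedDirections <- function(tr, config) {
  st <- frameSteps(tr, config)
  st$direction_deg[st$gated & !is.na(st$direction_deg)]
}

#' Signed directional changes between consecutive gated steps
#'
#' The direction difference of two consecutive gated frames, wrapped to
#' (-180, 180]. Sub-gate frames are skipped (not interpolated), and steps
#' with zero in-plane displacement carry no direction and are excluded. For
#' the left hemisphere the sign is negated, so positive values always carry
#' the same anatomical meaning (the rightward-in-right / leftward-in-left
#' turn convention); the hemisphere flip is an exact sign involution.
#'
#' @param tr a [Track-class] (>= 3 samples for a non-empty result).
#' @param config an [AnalysisConfig-class].
#' @return numeric vector of signed degrees in (-180, 180]; empty when fewer
#'   than two gated directed steps exist.
#' @export
directionalChanges <- function(tr, config = analysisConfig()) {
  dirs <- gatedDirections(tr, config)
  if (length(dirs) < 2L) return(numeric())
  hemisphereSign(hemisphere(tr)) * wrapAngle(diff(dirs))
}

#' Signed angles between gated steps and the radial axis
#'
#' Per gated step, the signed angle between the step direction and the
#' radial axis (the direction from the ventricular zone toward the pial
#' surface), in (-180, 180]. Lateral deviations are positive and medial
#' negative, resolved via the hemisphere tag of the cortical frame: lateral
#' is +x in the right hemisphere and -x in the left, so a purely lateral
#' step maps to +90 degrees in both hemispheres.
#'
#' @param tr a [Track-class].
#' @param frame a [CorticalFrame-class]; its (unit) radial axis defines the
#'   0-degree direction.
#' @param config an [AnalysisConfig-class].
#' @return numeric vector of signed degrees in (-180, 180], one per gated
#'   directed step.
#' @export
anglesToRadial <- function(tr, frame, config = analysisConfig()) {
  stopifnot(is(frame, "CorticalFrame"))
  dirs <- gatedDirections(tr, config)
  if (!length(dirs)) return(numeric())
  ax <- radialAxis(frame)
  axisDir <- atan2(ax[2], ax[1]) * 180 / pi
  s <- -hemisphereSign(hemisphere(frame))
  s * wrapAngle(dirs - axisDir)
}

#' Net displacement polar summary of a track
#'
#' Straight-line in-plane distance and signed radial-axis-referenced
#' direction from the first to the last sample (the polar-plot convention:
#' 0 degrees is the radial direction toward the pia, lateral positive).
#'
#' @param tr a [Track-class].
#' @param frame a [CorticalFrame-class].
#' @return list with `netDistanceUm`, `netDirectionDeg` (`NA` when
#'   degenerate) and `degenerate` (TRUE when the net displacement is zero so
#'   the direction is undefined).
#' @export
polarSummary <- function(tr, frame) {
  stopifnot(is(tr, "Track"), is(frame, "CorticalFrame"))
  s <- samples(tr)
  n <- nrow(s)
  dx <- s$x_um[n] - s$x_um[1]
  dy <- s$y_um[n] - s$y_um[1]
  dist <- sqrt(dx^2 + dy^2)
  if (dist == 0)
    return(list(netDistanceUm = 0, netDirectionDeg = NA_real_,
                degenerate = TRUE))
  ax <- radialAxis(frame)
  axisDir <- atan2(ax[2], ax[1]) * 180 / pi
  sgn <- -hemisphereSign(hemisphere(frame))
  list(netDistanceUm = dist,
       netDirectionDeg = sgn * wrapAngle(atan2(dy, dx) * 180 / pi - axisDir),
       degenerate = FALSE)
}

#' Partition tracks into motile and stationary
#'
#' A track is motile iff its maximum in-plane displacement from the first
#' position, within the first `motilityWindowH` hours of its observation,
#' strictly exceeds `motilityDisplacementUm` (default: over 20 um within the
#' first 24 h).
#'
#' @param tracks list of [Track-class].
#' @param config an [AnalysisConfig-class].
#' @return list with elements `motile` and `stationary` (lists of tracks)
#'   and `isMotile` (named logical vector in input order).
#' @export
motileFilter <- function(tracks, config = analysisConfig()) {
  stopifnot(is(config, "AnalysisConfig"))
  isMotile <- vapply(tracks, function(tr) {
    s <- samples(tr)
    w <- s$t_h - s$t_h[1] <= config@motilityWindowH
    disp <- sqrt((s$x_um[w] - s$x_um[1])^2 + (s$y_um[w] - s$y_um[1])^2)
    max(disp) > config@motilityDisplacementUm
  }, logical(1))
  names(isMotile) <- vapply(tracks, trackId, "")
  list(motile = tracks[isMotile], stationary = tracks[!isMotile],
       isMotile = isMotile)
}

#' Welch comparison of two gated frame-speed distributions
#'
#' The per-frame speed comparison between migration modes: a Welch two-sample
#' t test on gated frame speeds, with descriptive group summaries following
#' the box-plot convention (whiskers at 1.5 x IQR beyond the quartiles).
#'
#' @param groupA,groupB data.frames of frame steps (from [frameSteps()],
#'   possibly row-bound over tracks). Only gated frames are compared; each
#'   group needs at least two of them.
#' @param labels character(2) group labels for the report.
#' @return a [TestReport-class] (unit: frame).
#' @export
compareSpeedDistributions <- function(groupA, groupB,
                                      labels = c("groupA", "groupB")) {
  a <- groupA$speed_umh[groupA$gated]
  b <- groupB$speed_umh[groupB$gated]
  if (length(a) < 2L || length(b) < 2L)
    stop("each group needs at least two gated frames", call. = FALSE)
  g <- list(a, b); names(g) <- labels
  runTest(g, method = "welch_t", unit = "frame")
}
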