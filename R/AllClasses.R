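#' @include AllGenerics.R
NULL

## ---------------------------------------------------------------------------
## SimulationConfig
## ---------------------------------------------------------------------------

#' Simulation configuration for the synthetic imaging world
#'
#' Holds every tunable parameter of the synthetic-data generator: acquisition
#' geometry (a ~250 um organotypic slice imaged as a merged ~50 um projection,
#' frames every 10--30 min over 24 h), the three trajectory classes (erratic,
#' radial, vessel-guided), the radially biased vessel network, the nuclei
#' reference cloud and the rasterization settings. Construct with
#' [simulationConfig()].
#'
#' @slot seed integer; master RNG seed, every generator derives its own
#'   sub-stream from it.
#' @slot durationH,frameIntervalH observation duration and frame interval in
#'   hours.
#' @slot fieldSizeUm numeric(3); field extents (X, Y, Z) in micrometres.
#' @slot nCellsPerMode integer; tracks generated per migration mode.
#' @slot erraticSpeedMeanUmh,erraticSpeedSd lognormal frame-speed moments for
#'   erratic walkers, um/h.
#' @slot erraticTurnSdDeg wrapped-normal turning-angle SD for erratic walkers.
#' @slot erraticDriftUmh constant surface-ward (+y) drift velocity, um/h.
#' @slot radialSpeedMeanUmh,radialSpeedSd,radialTurnSdDeg radial-mode analogs.
#' @slot vesselGuidedSpeedUmh crawling speed along a vessel axis, um/h.
#' @slot attachProbPerFrame,detachProbPerFrame per-frame attach/detach
#'   probabilities for vessel-guided agents.
#' @slot captureRadiusUm distance from a vessel surface within which an
#'   unattached agent may attach (default 5, the association threshold).
#' @slot vesselNSegments,vesselRadiusUm,vesselSegmentLengthUm network size,
#'   capillary radius and mean segment length.
#' @slot vesselRadialBias probability that a segment is oriented within 30
#'   degrees of the radial (+y) axis.
#' @slot nNuclei size of the uniform nuclei reference cloud.
#' @slot voxelSizeUm numeric(3); rasterization voxel size (z, y, x) in um.
#' @slot cellBlobVolumeUm3 half-maximum isosurface volume of a rendered cell
#'   blob, um^3.
#' @slot noiseSd additive Gaussian intensity noise SD for rasterization.
#' @export
setClass("SimulationConfig", representation(
  seed = "integer",
  durationH = "numeric",
  frameIntervalH = "numeric",
  fieldSizeUm = "numeric",
  nCellsPerMode = "integer",
  erraticSpeedMeanUmh = "numeric",
  erraticSpeedSd = "numeric",
  erraticTurnSdDeg = "numeric",
  erraticDriftUmh = "numeric",
  radialSpeedMeanUmh = "numeric",
  radialSpeedSd = "numeric",
  radialTurnSdDeg = "numeric",
  vesselGuidedSpeedUmh = "numeric",
  attachProbPerFrame = "numeric",
  detachProbPerFrame = "numeric",
  captureRadiusUm = "numeric",
  vesselNSegments = "integer",
  vesselRadiusUm = "numeric",
  vesselSegmentLengthUm = "numeric",
  vesselRadialBias = "numeric",
  nNuclei = "integer",
  voxelSizeUm = "numeric",
  cellBlobVolumeUm3 = "numeric",
  noiseSd = "numeric"
))

setValidity("SimulationConfig", function(object) {
  msg <- character()
  probs <- c(attachProbPerFrame = object@attachProbPerFrame,
             detachProbPerFrame = object@detachProbPerFrame,
             vesselRadialBias = object@vesselRadialBias)
  if (any(probs < 0 | probs > 1))
    msg <- c(msg, "probabilities must lie in [0, 1]")
  pos <- c(object@durationH, object@frameIntervalH, object@fieldSizeUm,
           object@erraticSpeedMeanUmh, object@radialSpeedMeanUmh,
           object@vesselGuidedSpeedUmh, object@vesselRadiusUm,
           object@vesselSegmentLengthUm, object@voxelSizeUm,
           object@cellBlobVolumeUm3, object@captureRadiusUm)
  if (any(!is.finite(pos)) || any(pos <= 0))
    msg <- c(msg, "durations, extents, speeds, radii and voxel sizes must be strictly positive")
  if (object@erraticSpeedSd < 0 || object@radialSpeedSd < 0 ||
      object@erraticTurnSdDeg < 0 || object@radialTurnSdDeg < 0 ||
      object@noiseSd < 0 || object@erraticDriftUmh < 0)
    msg <- c(msg, "spread, noise and drift parameters must be non-negative")
  if (length(object@fieldSizeUm) != 3L)
    msg <- c(msg, "fieldSizeUm must have length 3 (X, Y, Z)")
  if (length(object@voxelSizeUm) != 3L)
    msg <- c(msg, "voxelSizeUm must have length 3 (z, y, x)")
  if (object@nCellsPerMode < 0L || object@vesselNSegments < 0L || object@nNuclei < 0L)
    msg <- c(msg, "counts must be non-negative")
  if (length(msg)) msg else TRUE
})

#' Construct a SimulationConfig
#'
#' Defaults encode the acquisition regime the generator emulates: 24 h of
#' observation at 15-min frames (within the 10--30 min acquisition range), a
#' 256 x 256 x 64 um field at 1 um isotropic voxels, erratic walkers faster
#' (30 +/- 12 um/h) than radial migrators (12 +/- 5 um/h) with a surface-ward
#' drift, and a sparse (~1% volume fraction) radially biased capillary
#' network.
#'
#' @param seed master RNG seed (integer).
#' @param durationH,frameIntervalH hours. A frame interval outside
#'   [10/60, 30/60] h is accepted with a warning (it leaves the emulated
#'   acquisition regime).
#' @param fieldSizeUm numeric(3) field extents (X, Y, Z), um.
#' @param nCellsPerMode tracks per migration mode.
#' @param erraticSpeedMeanUmh,erraticSpeedSd,erraticTurnSdDeg,erraticDriftUmh
#'   erratic-mode parameters.
#' @param radialSpeedMeanUmh,radialSpeedSd,radialTurnSdDeg radial-mode
#'   parameters.
#' @param vesselGuidedSpeedUmh,attachProbPerFrame,detachProbPerFrame,captureRadiusUm
#'   vessel-guided-mode parameters.
#' @param vesselNSegments,vesselRadiusUm,vesselSegmentLengthUm,vesselRadialBias
#'   vessel-network parameters.
#' @param nNuclei nuclei-cloud size.
#' @param voxelSizeUm numeric(3) voxel size (z, y, x), um.
#' @param cellBlobVolumeUm3 rendered cell-blob half-max volume, um^3.
#' @param noiseSd rasterization noise SD.
#' @return a validated `SimulationConfig`.
#' @examples
#' cfg <- simulationConfig(seed = 1, nCellsPerMode = 5)
#' cfg
#' @export
simulationConfig <- function(seed = 1L,
                             durationH = 24,
                             frameIntervalH = 0.25,
                             fieldSizeUm = c(256, 256, 64),
                             nCellsPerMode = 20L,
                             erraticSpeedMeanUmh = 30,
                             erraticSpeedSd = 12,
                             erraticTurnSdDeg = 60,
                             erraticDriftUmh = 5,
                             radialSpeedMeanUmh = 12,
                             radialSpeedSd = 5,
                             radialTurnSdDeg = 10,
                             vesselGuidedSpeedUmh = 20,
                             attachProbPerFrame = 0.5,
                             detachProbPerFrame = 0.02,
                             captureRadiusUm = 5,
                             vesselNSegments = 70L,
                             vesselRadiusUm = 2,
                             vesselSegmentLengthUm = 40,
                             vesselRadialBias = 0.7,
                             nNuclei = 1000L,
                             voxelSizeUm = c(1, 1, 1),
                             cellBlobVolumeUm3 = 8000,
                             noiseSd = 1) {
  if (frameIntervalH < 10 / 60 || frameIntervalH > 30 / 60)
    warning("frameIntervalH outside the emulated 10-30 min acquisition range",
            call. = FALSE)
  new("SimulationConfig",
      seed = as.integer(seed), durationH = durationH,
      frameIntervalH = frameIntervalH, fieldSizeUm = as.numeric(fieldSizeUm),
      nCellsPerMode = as.integer(nCellsPerMode),
      erraticSpeedMeanUmh = erraticSpeedMeanUmh,
      erraticSpeedSd = erraticSpeedSd, erraticTurnSdDeg = erraticTurnSdDeg,
      erraticDriftUmh = erraticDriftUmh,
      radialSpeedMeanUmh = radialSpeedMeanUmh, radialSpeedSd = radialSpeedSd,
      radialTurnSdDeg = radialTurnSdDeg,
      vesselGuidedSpeedUmh = vesselGuidedSpeedUmh,
      attachProbPerFrame = attachProbPerFrame,
      detachProbPerFrame = detachProbPerFrame,
      captureRadiusUm = captureRadiusUm,
      vesselNSegments = as.integer(vesselNSegments),
      vesselRadiusUm = vesselRadiusUm,
      vesselSegmentLengthUm = vesselSegmentLengthUm,
      vesselRadialBias = vesselRadialBias, nNuclei = as.integer(nNuclei),
      voxelSizeUm = as.numeric(voxelSizeUm),
      cellBlobVolumeUm3 = cellBlobVolumeUm3, noiseSd = noiseSd)
}

## ---------------------------------------------------------------------------
## AnalysisConfig
## ---------------------------------------------------------------------------

#' Analysis configuration: the numeric thresholds of the migration analyses
#'
#' Houses every gate and margin the quantitative analyses use: the 10 um/h
#' per-frame speed gate, the 20 um / 24 h motility displacement filter, the
#' 5 h minimum continuous on-vessel period, the 10 h traceability filter for
#' off/on ratios, the 5 um vessel-association threshold, the 15 um Z and
#' 20 um XY edge exclusions, the 6000 um^3 detection size filter and the
#' four-bin cortical depth histogram. All comparisons against these
#' thresholds are strict ("more than", "over", "larger than").
#'
#' @slot speedGateUmh per-frame speed gate, um/h.
#' @slot motilityDisplacementUm,motilityWindowH motility filter: displacement
#'   (um) that must be exceeded within the first window (h).
#' @slot minOnVesselH minimum continuous on-vessel period (h) for persistence
#'   analysis.
#' @slot traceabilityMinH minimum traceable duration (h) for off/on ratios.
#' @slot associationThresholdUm distance (um) below which a cell counts as
#'   vessel-associated.
#' @slot zExclusionUm,xyMarginUm edge-exclusion margins, um.
#' @slot sizeFilterUm3 minimum detection volume, um^3 (strict).
#' @slot nBins number of cortical depth bins.
#' @slot contactToleranceUm distance tolerance for per-frame on-vessel calls
#'   (0 = mask overlap).
#' @slot histBinWidthUm association histogram bin width, um.
#' @slot minComponentVoxels small-object removal threshold for vessel masks.
#' @export
setClass("AnalysisConfig", representation(
  speedGateUmh = "numeric",
  motilityDisplacementUm = "numeric",
  motilityWindowH = "numeric",
  minOnVesselH = "numeric",
  traceabilityMinH = "numeric",
  associationThresholdUm = "numeric",
  zExclusionUm = "numeric",
  xyMarginUm = "numeric",
  sizeFilterUm3 = "numeric",
  nBins = "integer",
  contactToleranceUm = "numeric",
  histBinWidthUm = "numeric",
  minComponentVoxels = "integer"
))

setValidity("AnalysisConfig", function(object) {
  msg <- character()
  thr <- c(object@speedGateUmh, object@motilityDisplacementUm,
           object@motilityWindowH, object@minOnVesselH, object@traceabilityMinH,
           object@associationThresholdUm, object@zExclusionUm,
           object@xyMarginUm, object@sizeFilterUm3, object@contactToleranceUm,
           object@histBinWidthUm)
  if (any(!is.finite(thr)) || any(thr < 0))
    msg <- c(msg, "all thresholds must be finite and non-negative")
  if (object@nBins < 1L) msg <- c(msg, "nBins must be >= 1")
  if (object@minComponentVoxels < 1L)
    msg <- c(msg, "minComponentVoxels must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Construct an AnalysisConfig
#'
#' @param speedGateUmh speed gate, um/h (default 10).
#' @param motilityDisplacementUm motility displacement, um (default 20).
#' @param motilityWindowH motility window, h (default 24).
#' @param minOnVesselH minimum continuous on-vessel period, h (default 5).
#' @param traceabilityMinH traceability filter, h (default 10).
#' @param associationThresholdUm association threshold, um (default 5).
#' @param zExclusionUm Z edge exclusion, um (default 15).
#' @param xyMarginUm XY edge margin, um (default 20).
#' @param sizeFilterUm3 detection size filter, um^3 (default 6000).
#' @param nBins depth bins (default 4).
#' @param contactToleranceUm on-vessel call tolerance, um (default 0).
#' @param histBinWidthUm association histogram bin width, um (default 2.5).
#' @param minComponentVoxels vessel-mask small-object threshold (default 1,
#'   i.e. no removal).
#' @return a validated `AnalysisConfig`.
#' @examples
#' analysisConfig()
#' @export
analysisConfig <- function(speedGateUmh = 10,
                           motilityDisplacementUm = 20,
                           motilityWindowH = 24,
                           minOnVesselH = 5,
                           traceabilityMinH = 10,
                           associationThresholdUm = 5,
                           zExclusionUm = 15,
                           xyMarginUm = 20,
                           sizeFilterUm3 = 6000,
                           nBins = 4L,
                           contactToleranceUm = 0,
                           histBinWidthUm = 2.5,
                           minComponentVoxels = 1L) {
  new("AnalysisConfig",
      speedGateUmh = speedGateUmh,
      motilityDisplacementUm = motilityDisplacementUm,
      motilityWindowH = motilityWindowH, minOnVesselH = minOnVesselH,
      traceabilityMinH = traceabilityMinH,
      associationThresholdUm = associationThresholdUm,
      zExclusionUm = zExclusionUm, xyMarginUm = xyMarginUm,
      sizeFilterUm3 = sizeFilterUm3, nBins = as.integer(nBins),
      contactToleranceUm = contactToleranceUm,
      histBinWidthUm = histBinWidthUm,
      minComponentVoxels = as.integer(minComponentVoxels))
}

## ---------------------------------------------------------------------------
## VesselNetwork
## ---------------------------------------------------------------------------

#' Tubular vessel-segment geometry
#'
#' A set of capsule segments (two endpoints plus a radius, all in um) standing
#' in for the cortical microvasculature (the DsRed endothelial channel of the
#' emulated slices). Rasterizable to a binary mask; the union-of-capsules
#' volume fraction is computable with [vesselVolumeFraction()].
#'
#' @slot segments data.frame with columns `segment_id, x0, y0, z0, x1, y1,
#'   z1, radius_um`.
#' @slot fieldSizeUm numeric(3) field extents (X, Y, Z), um.
#' @export
setClass("VesselNetwork", representation(
  segments = "data.frame",
  fieldSizeUm = "numeric"
))

setValidity("VesselNetwork", function(object) {
  seg <- object@segments
  need <- c("segment_id", "x0", "y0", "z0", "x1", "y1", "z1", "radius_um")
  if (!all(need %in% names(seg)))
    return(sprintf("segments must have columns %s", paste(need, collapse = ", ")))
  if (nrow(seg)) {
    if (any(seg$radius_um <= 0)) return("all radii must be strictly positive")
    f <- object@fieldSizeUm
    pts <- rbind(as.matrix(seg[, c("x0", "y0", "z0")]),
                 as.matrix(seg[, c("x1", "y1", "z1")]))
    if (any(pts < 0) || any(sweep(pts, 2, f) > 1e-9))
      return("all segment endpoints must lie inside the field bounds")
  }
  TRUE
})

#' Construct a VesselNetwork
#'
#' @param segments data.frame of segments (`x0..z1`, `radius_um`; a
#'   `segment_id` column is added when absent).
#' @param fieldSizeUm numeric(3) field extents (X, Y, Z), um.
#' @return a validated `VesselNetwork`.
#' @examples
#' vesselNetwork(data.frame(x0 = 10, y0 = 10, z0 = 10, x1 = 60, y1 = 60,
#'                          z1 = 10, radius_um = 2), fieldSizeUm = c(100, 100, 50))
#' @export
vesselNetwork <- function(segments, fieldSizeUm) {
  segments <- as.data.frame(segments)
  if (!nrow(segments)) {
    segments <- data.frame(segment_id = integer(), x0 = numeric(),
                           y0 = numeric(), z0 = numeric(), x1 = numeric(),
                           y1 = numeric(), z1 = numeric(),
                           radius_um = numeric())
  } else if (is.null(segments$segment_id)) {
    segments$segment_id <- seq_len(nrow(segments))
  }
  cols <- c("segment_id", "x0", "y0", "z0", "x1", "y1", "z1", "radius_um")
  new("VesselNetwork", segments = segments[, cols, drop = FALSE],
      fieldSizeUm = as.numeric(fieldSizeUm))
}

#' @describeIn VesselNetwork segment table accessor.
#' @param x,object a `VesselNetwork`.
#' @param ... unused.
#' @export
setMethod("segments", "VesselNetwork", function(x, ...) x@segments)

#' @describeIn VesselNetwork number of segments.
#' @export
setMethod("nSegments", "VesselNetwork", function(x) nrow(x@segments))

#' @describeIn VesselNetwork field extents (X, Y, Z) in um.
#' @export
setMethod("fieldSize", "VesselNetwork", function(x) x@fieldSizeUm)

setMethod("show", "VesselNetwork", function(object) {
  cat(sprintf("VesselNetwork: %d segment(s) in a %g x %g x %g um field\n",
              nSegments(object), object@fieldSizeUm[1], object@fieldSizeUm[2],
              object@fieldSizeUm[3]))
  if (nSegments(object))
    cat(sprintf("  radius range: %g - %g um\n",
                min(object@segments$radius_um), max(object@segments$radius_um)))
})

## ---------------------------------------------------------------------------
## Track
## ---------------------------------------------------------------------------

#' A single cell trajectory
#'
#' One cell's time-stamped 3D positions in physical units, with a hemisphere
#' tag (needed for the signed turn conventions), an optional ground-truth
#' migration-mode label and optional per-sample vessel-contact flags (both
#' synthetic-only).
#'
#' @slot trackId character identifier.
#' @slot hemisphere `"left"` or `"right"`.
#' @slot samples data.frame with columns `t_h, x_um, y_um, z_um`; `t_h`
#'   strictly increasing, at least two rows.
#' @slot trueMode `"erratic"`, `"radial"`, `"vessel_guided"` or `NA`.
#' @slot contact logical vector (per-sample ground-truth vessel contact) or
#'   length-zero when absent.
#' @export
setClass("Track", representation(
  trackId = "character",
  hemisphere = "character",
  samples = "data.frame",
  trueMode = "character",
  contact = "logical"
))

setValidity("Track", function(object) {
  s <- object@samples
  if (!all(c("t_h", "x_um", "y_um", "z_um") %in% names(s)))
    return("samples must have columns t_h, x_um, y_um, z_um")
  if (nrow(s) < 2L) return("a track needs at least two samples")
  if (any(diff(s$t_h) <= 0)) return("t_h must be strictly increasing")
  if (!object@hemisphere %in% c("left", "right"))
    return("hemisphere must be 'left' or 'right'")
  if (length(object@contact) && length(object@contact) != nrow(s))
    return("contact flags must match the number of samples")
  TRUE
})

#' Construct a Track
#'
#' @param trackId identifier.
#' @param samples data.frame with `t_h, x_um, y_um, z_um` (a missing `z_um`
#'   column is filled with 0).
#' @param hemisphere `"left"` or `"right"` (default `"right"`).
#' @param trueMode optional ground-truth mode label.
#' @param contact optional per-sample logical contact flags.
#' @return a validated `Track`.
#' @examples
#' track("t1", data.frame(t_h = c(0, 1), x_um = c(0, 5), y_um = c(0, 5),
#'                        z_um = 0))
#' @export
track <- function(trackId, samples, hemisphere = "right",
                  trueMode = NA_character_, contact = logical()) {
  samples <- as.data.frame(samples)
  if (is.null(samples$z_um)) samples$z_um <- 0
  new("Track", trackId = as.character(trackId), hemisphere = hemisphere,
      samples = samples[, c("t_h", "x_um", "y_um", "z_um")],
      trueMode = as.character(trueMode), contact = as.logical(contact))
}

#' @describeIn Track identifier accessor.
#' @param x,object a `Track`.
#' @export
setMethod("trackId", "Track", function(x) x@trackId)

#' @describeIn Track hemisphere accessor.
#' @export
setMethod("hemisphere", "Track", function(x) x@hemisphere)

#' @describeIn Track sample table accessor.
#' @export
setMethod("samples", "Track", function(x) x@samples)

#' @describeIn Track ground-truth mode accessor.
#' @export
setMethod("trueMode", "Track", function(x) x@trueMode)

#' @describeIn Track ground-truth contact flags (length zero when absent).
#' @export
setMethod("contactFlags", "Track", function(x) x@contact)

setMethod("show", "Track", function(object) {
  s <- object@samples
  cat(sprintf("Track '%s' (%s hemisphere%s): %d samples, %g - %g h\n",
              object@trackId, object@hemisphere,
              if (is.na(object@trueMode)) "" else
                paste0(", mode ", object@trueMode),
              nrow(s), min(s$t_h), max(s$t_h)))
})

## ---------------------------------------------------------------------------
## VolumeStack
## ---------------------------------------------------------------------------

#' Multi-channel 3D intensity volume
#'
#' Named 3D intensity arrays in (Z, Y, X) order with per-axis voxel sizes in
#' um, standing in for confocal two-channel stacks (~50 optical sections at
#' 1 um spacing). Physical coordinates map to indices per the package
#' convention: voxel `i` covers `[(i-1)*v, i*v)` and is centred at
#' `(i-0.5)*v`, so the mapping round-trips within half a voxel.
#'
#' @slot channels named list of numeric 3D arrays, identical dimensions.
#' @slot voxelSizeUm numeric(3), voxel size (z, y, x) in um.
#' @export
setClass("VolumeStack", representation(
  channels = "list",
  voxelSizeUm = "numeric"
))

setValidity("VolumeStack", function(object) {
  ch <- object@channels
  if (!length(ch)) return("at least one channel is required")
  if (is.null(names(ch)) || any(!nzchar(names(ch))))
    return("channels must be named")
  dims <- lapply(ch, dim)
  if (any(vapply(dims, length, 1L) != 3L))
    return("channels must be 3D arrays (Z, Y, X)")
  if (length(unique(vapply(dims, paste, "", collapse = "x"))) != 1L)
    return("all channels must share the same dimensions")
  if (length(object@voxelSizeUm) != 3L || any(object@voxelSizeUm <= 0))
    return("voxelSizeUm must be three strictly positive values (z, y, x)")
  TRUE
})

#' Construct a VolumeStack
#'
#' @param channels named list of 3D arrays in (Z, Y, X) order.
#' @param voxelSizeUm numeric(3) voxel size (z, y, x), um.
#' @return a validated `VolumeStack`.
#' @examples
#' volumeStack(list(gfp = array(0, c(4, 8, 8))), voxelSizeUm = c(1, 1, 1))
#' @export
volumeStack <- function(channels, voxelSizeUm) {
  new("VolumeStack", channels = channels, voxelSizeUm = as.numeric(voxelSizeUm))
}

#' @describeIn VolumeStack channel names.
#' @param x,object a `VolumeStack`.
#' @export
setMethod("channelNames", "VolumeStack", function(x) names(x@channels))

#' @describeIn VolumeStack extract one channel array by name.
#' @param name channel name.
#' @export
setMethod("getChannel", "VolumeStack", function(x, name) {
  if (!name %in% names(x@channels))
    stop(sprintf("no channel named '%s'", name), call. = FALSE)
  x@channels[[name]]
})

#' @describeIn VolumeStack voxel size (z, y, x) in um.
#' @export
setMethod("voxelSize", "VolumeStack", function(x) x@voxelSizeUm)

setMethod("show", "VolumeStack", function(object) {
  d <- dim(object@channels[[1]])
  cat(sprintf("VolumeStack: %d channel(s) [%s], %d x %d x %d (Z,Y,X), voxel %g x %g x %g um\n",
              length(object@channels),
              paste(names(object@channels), collapse = ", "),
              d[1], d[2], d[3], object@voxelSizeUm[1], object@voxelSizeUm[2],
              object@voxelSizeUm[3]))
})

## ---------------------------------------------------------------------------
## VesselMask
## ---------------------------------------------------------------------------

#' Voxelized vessel reconstruction
#'
#' A binary occupancy volume with its medial-axis skeleton and its
#' 6-connectivity surface (occupied voxels with at least one empty
#' 6-neighbour). Built from an intensity channel with [buildVesselMask()].
#'
#' @slot occupancy logical 3D array (Z, Y, X).
#' @slot voxelSizeUm numeric(3), voxel size (z, y, x) in um.
#' @slot skeleton integer matrix of skeleton voxel indices (iz, iy, ix).
#' @slot surface integer matrix of surface voxel indices (iz, iy, ix).
#' @slot emptyForeground logical; TRUE when thresholding produced no
#'   foreground (the mask is valid but degenerate).
#' @export
setClass("VesselMask", representation(
  occupancy = "array",
  voxelSizeUm = "numeric",
  skeleton = "matrix",
  surface = "matrix",
  emptyForeground = "logical"
))

setValidity("VesselMask", function(object) {
  occ <- object@occupancy
  if (length(dim(occ)) != 3L) return("occupancy must be a 3D array")
  if (!is.logical(occ)) return("occupancy must be logical")
  ok <- function(m) !nrow(m) || all(occ[m])
  if (!ok(object@skeleton)) return("skeleton must be a subset of occupancy")
  if (!ok(object@surface)) return("surface must be a subset of occupancy")
  TRUE
})

#' @describeIn VesselMask occupancy array accessor.
#' @param x,object a `VesselMask`.
#' @export
setMethod("occupancy", "VesselMask", function(x) x@occupancy)

#' @describeIn VesselMask skeleton voxel indices (iz, iy, ix).
#' @export
setMethod("skeleton", "VesselMask", function(x) x@skeleton)

#' @describeIn VesselMask surface voxel indices (iz, iy, ix).
#' @export
setMethod("surfaceVoxels", "VesselMask", function(x) x@surface)

#' @describeIn VesselMask voxel size (z, y, x) in um.
#' @export
setMethod("voxelSize", "VesselMask", function(x) x@voxelSizeUm)

setMethod("show", "VesselMask", function(object) {
  d <- dim(object@occupancy)
  cat(sprintf("VesselMask: %d x %d x %d (Z,Y,X), %d occupied, %d surface, %d skeleton voxel(s)%s\n",
              d[1], d[2], d[3], sum(object@occupancy), nrow(object@surface),
              nrow(object@skeleton),
              if (isTRUE(object@emptyForeground)) " [empty foreground]" else ""))
})

## ---------------------------------------------------------------------------
## CorticalFrame
## ---------------------------------------------------------------------------

#' Geometric reference frame for cortical depth analysis
#'
#' The radial axis direction (a unit 2-vector in the slice plane pointing
#' toward the pial surface) together with the positions of the upper
#' (pial-side) and lower cortical-plate borders measured as depth coordinates
#' along the inward normal, and the hemisphere tag that resolves the
#' lateral/medial sign convention.
#'
#' @slot radialAxis numeric(2), unit vector (x, y) toward the pia.
#' @slot upperBorderUm,lowerBorderUm border depth coordinates along the
#'   inward axis; upper < lower.
#' @slot hemisphere `"left"` or `"right"`.
#' @export
setClass("CorticalFrame", representation(
  radialAxis = "numeric",
  upperBorderUm = "numeric",
  lowerBorderUm = "numeric",
  hemisphere = "character"
))

setValidity("CorticalFrame", function(object) {
  if (length(object@radialAxis) != 2L) return("radialAxis must have length 2")
  n <- sqrt(sum(object@radialAxis^2))
  if (!is.finite(n) || n == 0) return("radialAxis must be non-degenerate")
  if (abs(n - 1) > 1e-8) return("radialAxis must be a unit vector")
  if (!(object@upperBorderUm < object@lowerBorderUm))
    return("upperBorderUm must be smaller than lowerBorderUm along the depth axis")
  if (!object@hemisphere %in% c("left", "right"))
    return("hemisphere must be 'left' or 'right'")
  TRUE
})

#' Construct a CorticalFrame
#'
#' @param radialAxis numeric(2) in-plane direction toward the pial surface
#'   (normalized internally; default `c(0, 1)`, the package +y convention).
#' @param upperBorderUm,lowerBorderUm border positions as depth coordinates
#'   along the inward normal (depth increases away from the pia);
#'   upper < lower.
#' @param hemisphere `"left"` or `"right"`.
#' @return a validated `CorticalFrame`.
#' @examples
#' corticalFrame(upperBorderUm = -250, lowerBorderUm = -50)
#' @export
corticalFrame <- function(radialAxis = c(0, 1), upperBorderUm,
                          lowerBorderUm, hemisphere = "right") {
  n <- sqrt(sum(radialAxis^2))
  if (!is.finite(n) || n == 0)
    stop("radialAxis must be a non-zero in-plane vector", call. = FALSE)
  new("CorticalFrame", radialAxis = as.numeric(radialAxis) / n,
      upperBorderUm = upperBorderUm, lowerBorderUm = lowerBorderUm,
      hemisphere = hemisphere)
}

#' @describeIn CorticalFrame radial axis accessor.
#' @param x,object a `CorticalFrame`.
#' @export
setMethod("radialAxis", "CorticalFrame", function(x) x@radialAxis)

#' @describeIn CorticalFrame hemisphere accessor.
#' @export
setMethod("hemisphere", "CorticalFrame", function(x) x@hemisphere)

setMethod("show", "CorticalFrame", function(object) {
  cat(sprintf("CorticalFrame: axis (%.3f, %.3f), borders %g (upper) / %g (lower) um, %s hemisphere\n",
              object@radialAxis[1], object@radialAxis[2], object@upperBorderUm,
              object@lowerBorderUm, object@hemisphere))
})

## ---------------------------------------------------------------------------
## TestReport
## ---------------------------------------------------------------------------

#' Statistical test report
#'
#' Uniform container returned by the statistical layer: test name, statistic,
#' degrees of freedom (when defined), two-sided p-value, per-comparison
#' adjusted p-values (for multiple-comparison procedures) and per-group
#' descriptive summaries following the box-plot convention (whiskers at
#' exactly 1.5 x IQR below/above the first/third quartiles).
#'
#' @slot testName character.
#' @slot statistic,df,pTwoSided numeric (NA where undefined).
#' @slot comparisons data.frame of pairwise comparisons with `p` and
#'   `p_adjusted` (zero rows for two-sample tests).
#' @slot groupSummaries data.frame with `group, n, mean, sd, sem, median, q1,
#'   q3, whisker_lo, whisker_hi`.
#' @slot unit character; the unit of analysis (e.g. "frame", "cell", "brain",
#'   "field").
#' @slot details list of method details (e.g. adjustment method).
#' @export
setClass("TestReport", representation(
  testName = "character",
  statistic = "numeric",
  df = "numeric",
  pTwoSided = "numeric",
  comparisons = "data.frame",
  groupSummaries = "data.frame",
  unit = "character",
  details = "list"
))

setMethod("show", "TestReport", function(object) {
  cat(sprintf("TestReport: %s (unit: %s)\n", object@testName, object@unit))
  if (!is.na(object@statistic))
    cat(sprintf("  statistic = %.6g%s, p (two-sided) = %.4g %s\n",
                object@statistic,
                if (is.na(object@df)) "" else sprintf(", df = %.4g", object@df),
                object@pTwoSided, significanceStars(object@pTwoSided)))
  if (nrow(object@comparisons)) {
    cat("  comparisons:\n")
    print(object@comparisons, row.names = FALSE)
  }
})
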