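#' @include vesselmask.R
NULL

## min distance from each point (n x 3 physical x,y,z) to any surface-voxel
## centre, anisotropy-aware, chunked to bound memory
minSurfaceDistance <- function(points, surface, voxelSizeUm) {
  pts <- rbind(points)
  sc <- indexToPhys(surface, voxelSizeUm)
  n <- nrow(pts)
  out <- numeric(n)
  chunk <- max(1L, floor(2e7 / nrow(sc)))
  for (s in seq(1, n, by = chunk)) {
    e <- min(n, s + chunk - 1L)
    block <- pts[s:e, , drop = FALSE]
    d2 <- outer(block[, 1], sc[, 1], "-")^2 +
      outer(block[, 2], sc[, 2], "-")^2 +
      outer(block[, 3], sc[, 3], "-")^2
    out[s:e] <- sqrt(apply(d2, 1, min))
  }
  out
}

## TRUE for points whose containing voxel is occupied
insideOccupancy <- function(points, mask) {
  occ <- occupancy(mask)
  idx <- physToIndex(points, voxelSize(mask), dim(occ))
  inside <- rep(FALSE, nrow(idx))
  ok <- !is.na(idx[, 1])
  if (any(ok)) inside[ok] <- occ[idx[ok, , drop = FALSE]]
  inside
}

#' Centroid-to-nearest-vessel-surface distances
#'
#' Euclidean distance in physical micrometres from each cell centroid to the
#' nearest vessel surface-voxel centre (the center-to-surface convention of a
#' voxelized reconstruction; no sub-voxel interpolation). Centroids whose
#' containing voxel is inside the occupancy get distance 0. Anisotropic voxel
#' sizes are honoured.
#'
#' @param centroids n x 3 matrix (x, y, z in um) or data.frame with those
#'   columns.
#' @param mask a non-degenerate [VesselMask-class].
#' @param cellIds optional identifiers (default `cell_1..n`).
#' @return data.frame of distance records: `cell_id, x, y, z, distance_um,
#'   included, exclusion_reason` (all records included, reason "none";
#'   apply [applyEdgeExclusion()] afterwards).
#' @export
nearestVesselDistance <- function(centroids, mask, cellIds = NULL) {
  stopifnot(is(mask, "VesselMask"))
  if (isTRUE(mask@emptyForeground) || nrow(mask@surface) == 0L)
    stop("vessel mask is empty: distances are undefined", call. = FALSE)
  pts <- as.matrix(as.data.frame(centroids)[, 1:3])
  colnames(pts) <- c("x", "y", "z")
  if (is.null(cellIds)) cellIds <- sprintf("cell_%d", seq_len(nrow(pts)))
  d <- minSurfaceDistance(pts, mask@surface, voxelSize(mask))
  d[insideOccupancy(pts, mask)] <- 0
  data.frame(cell_id = cellIds, x = pts[, 1], y = pts[, 2], z = pts[, 3],
             distance_um = d, included = TRUE, exclusion_reason = "none",
             stringsAsFactors = FALSE)
}

#' Flag records near the imaged-volume edges as excluded
#'
#' Cells near the axial faces or the lateral borders of the imaged volume are
#' excluded from distance statistics because their true nearest vessel may
#' have been cut off: within `zExclusionUm` of either Z face (reason
#' `z_limit`), or within `xyMarginUm` of any XY border (reason `xy_margin`;
#' the Z rule takes precedence when both apply). No record is deleted - the
#' output has exactly the input rows with `included` / `exclusion_reason`
#' updated.
#'
#' @param records data.frame from [nearestVesselDistance()].
#' @param fieldBounds numeric(3) upper extents (X, Y, Z) in um, or a list
#'   with `lower` and `upper` numeric(3) vectors.
#' @param config an [AnalysisConfig-class].
#' @return the records with exclusion flags set.
#' @export
applyEdgeExclusion <- function(records, fieldBounds, config = analysisConfig()) {
  if (!is.list(fieldBounds))
    fieldBounds <- list(lower = c(0, 0, 0), upper = as.numeric(fieldBounds))
  lo <- fieldBounds$lower; hi <- fieldBounds$upper
  if (any(records$x < lo[1] | records$x > hi[1] |
          records$y < lo[2] | records$y > hi[2] |
          records$z < lo[3] | records$z > hi[3]))
    stop("fieldBounds must enclose all centroids", call. = FALSE)
  zBad <- records$z < lo[3] + config@zExclusionUm |
    records$z > hi[3] - config@zExclusionUm
  xyBad <- records$x < lo[1] + config@xyMarginUm |
    records$x > hi[1] - config@xyMarginUm |
    records$y < lo[2] + config@xyMarginUm |
    records$y > hi[2] - config@xyMarginUm
  records$exclusion_reason <- ifelse(zBad, "z_limit",
                                     ifelse(xyBad, "xy_margin", "none"))
  records$included <- !zBad & !xyBad
  records
}

#' Vessel-association fraction and distance histogram
#'
#' The fraction of included cells lying strictly closer than
#' `associationThresholdUm` (default 5 um) to the nearest vessel surface,
#' with a fixed-width distance histogram for peak inspection.
#'
#' @param records data.frame of distance records (after edge exclusion).
#' @param config an [AnalysisConfig-class].
#' @return list with `fraction`, `nIncluded`, and `histogram` (data.frame
#'   `bin_start, bin_end, count`; bins `[a, b)` of width `histBinWidthUm`).
#' @export
associationFraction <- function(records, config = analysisConfig()) {
  d <- records$distance_um[records$included]
  if (!length(d))
    stop("no included records: association fraction undefined", call. = FALSE)
  bw <- config@histBinWidthUm
  breaks <- seq(0, (floor(max(d) / bw) + 1) * bw, by = bw)
  counts <- vapply(seq_len(length(breaks) - 1L), function(i)
    sum(d >= breaks[i] & d < breaks[i + 1L]), 0L)
  list(fraction = mean(d < config@associationThresholdUm),
       nIncluded = length(d),
       histogram = data.frame(bin_start = breaks[-length(breaks)],
                              bin_end = breaks[-1], count = counts))
}
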