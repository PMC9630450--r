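#' @include simulate.R
NULL

## Default rendered intensity amplitude for both channels.
.rasterAmplitude <- 100

#' Gaussian blob sigma for a requested half-maximum volume
#'
#' Cells are rendered as isotropic Gaussian blobs whose half-maximum
#' isosurface encloses the requested volume: the half-max radius is
#' `(3V / 4 pi)^(1/3)` and `sigma = r_halfmax / sqrt(2 ln 2)`. This makes the
#' 6000 um^3 detection size filter analytically testable.
#'
#' @param volumeUm3 requested half-maximum volume, um^3.
#' @return sigma in um.
#' @export
gaussianBlobSigma <- function(volumeUm3) {
  (3 * volumeUm3 / (4 * pi))^(1 / 3) / sqrt(2 * log(2))
}

## linear index into a (Z, Y, X) array from integer triples
linearIndex <- function(idx, d) {
  idx[, 1] + (idx[, 2] - 1L) * d[1] + (idx[, 3] - 1L) * d[1] * d[2]
}

## integer index ranges covering a physical bbox (clamped to the array)
indexRange <- function(lo, hi, v, n) {
  i0 <- max(1L, floor(lo / v) + 1L)
  i1 <- min(n, floor(hi / v) + 1L)
  if (i0 > i1) return(integer())
  i0:i1
}

## voxel-centre grid (n x 3 physical x,y,z + index triples) for index ranges
voxelGrid <- function(zr, yr, xr, voxelSize) {
  g <- expand.grid(iz = zr, iy = yr, ix = xr)
  list(idx = as.matrix(g),
       phys = cbind((g$ix - 0.5) * voxelSize[3], (g$iy - 0.5) * voxelSize[2],
                    (g$iz - 0.5) * voxelSize[1]))
}

#' Add Gaussian cell blobs to a (Z, Y, X) array
#'
#' @param vol numeric 3D array (modified copy returned).
#' @param voxelSizeUm numeric(3) voxel size (z, y, x), um.
#' @param centers n x 3 matrix of blob centres (x, y, z), um.
#' @param volumesUm3 half-maximum volumes per blob (recycled), um^3.
#' @param amplitude peak intensity per blob (recycled).
#' @return the array with blobs added.
#' @export
renderGaussianBlobs <- function(vol, voxelSizeUm, centers, volumesUm3,
                                amplitude = .rasterAmplitude) {
  centers <- rbind(centers)
  if (!nrow(centers)) return(vol)
  volumesUm3 <- rep_len(volumesUm3, nrow(centers))
  amplitude <- rep_len(amplitude, nrow(centers))
  d <- dim(vol)
  for (i in seq_len(nrow(centers))) {
    s <- gaussianBlobSigma(volumesUm3[i])
    c3 <- centers[i, ]
    ext <- 4 * s
    zr <- indexRange(c3[3] - ext, c3[3] + ext, voxelSizeUm[1], d[1])
    yr <- indexRange(c3[2] - ext, c3[2] + ext, voxelSizeUm[2], d[2])
    xr <- indexRange(c3[1] - ext, c3[1] + ext, voxelSizeUm[3], d[3])
    if (!length(zr) || !length(yr) || !length(xr)) next
    g <- voxelGrid(zr, yr, xr, voxelSizeUm)
    r2 <- rowSums(sweep(g$phys, 2, c3)^2)
    li <- linearIndex(g$idx, d)
    vol[li] <- vol[li] + amplitude[i] * exp(-r2 / (2 * s^2))
  }
  vol
}

#' Rasterize a synthetic frame to a two-channel volume
#'
#' Produces the `VolumeStack` the downstream analyses consume, emulating a
#' two-channel confocal stack: the `vessel` channel is the union of capsules
#' (voxel centres inside any capsule get the full amplitude), the `cell`
#' channel is the sum of isotropic Gaussian blobs at the tracked cell
#' positions of the requested frame, and both channels receive additive
#' Gaussian noise of SD `noiseSd`. Arrays are (Z, Y, X).
#'
#' @param vessels a [VesselNetwork-class].
#' @param tracks list of [Track-class]; tracks without the requested frame
#'   are omitted.
#' @param frameIndex 1-based frame number (sample row within each track).
#' @param config a [SimulationConfig-class] (voxel size, field, blob volume,
#'   noise, seed).
#' @return a [VolumeStack-class] with channels `vessel` and `cell`.
#' @export
rasterizeFrame <- function(vessels, tracks, frameIndex, config) {
  stopifnot(is(config, "SimulationConfig"))
  f <- config@fieldSizeUm
  v <- config@voxelSizeUm
  d <- c(ceiling(f[3] / v[1]), ceiling(f[2] / v[2]), ceiling(f[1] / v[3]))
  if (prod(d) > 1.5e8)
    stop(sprintf("field of %g x %g x %g um at this voxel size needs %g voxels; exceeds the size limit",
                 f[1], f[2], f[3], prod(d)), call. = FALSE)
  vol <- array(0, d)
  seg <- segments(vessels)
  pad <- sqrt(sum(v^2))
  for (i in seq_len(nrow(seg))) {
    s <- seg[i, ]
    lo <- pmin(c(s$x0, s$y0, s$z0), c(s$x1, s$y1, s$z1)) - s$radius_um - pad
    hi <- pmax(c(s$x0, s$y0, s$z0), c(s$x1, s$y1, s$z1)) + s$radius_um + pad
    zr <- indexRange(lo[3], hi[3], v[1], d[1])
    yr <- indexRange(lo[2], hi[2], v[2], d[2])
    xr <- indexRange(lo[1], hi[1], v[3], d[3])
    if (!length(zr) || !length(yr) || !length(xr)) next
    g <- voxelGrid(zr, yr, xr, v)
    inside <- pointSegmentAxisDistance(g$phys, s) <= s$radius_um
    if (any(inside))
      vol[linearIndex(g$idx[inside, , drop = FALSE], d)] <- .rasterAmplitude
  }
  centers <- do.call(rbind, lapply(tracks, function(tr) {
    s <- samples(tr)
    if (frameIndex >= 1 && frameIndex <= nrow(s))
      c(s$x_um[frameIndex], s$y_um[frameIndex], s$z_um[frameIndex])
    else NULL
  }))
  cells <- array(0, d)
  if (!is.null(centers))
    cells <- renderGaussianBlobs(cells, v, centers, config@cellBlobVolumeUm3)
  if (config@noiseSd > 0) {
    withSeed(subSeed(config@seed, 4L + frameIndex), {
      vol <- vol + array(stats::rnorm(prod(d), 0, config@noiseSd), d)
      cells <- cells + array(stats::rnorm(prod(d), 0, config@noiseSd), d)
    })
  }
  volumeStack(list(vessel = vol, cell = cells), v)
}
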