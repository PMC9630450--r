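## Internal geometry / angle / RNG helpers shared across modules.
##
## Coordinate convention (fixed, package-wide): right-handed physical
## coordinates in micrometres; +y is the radial direction toward the pial
## surface, x the mediolateral in-slice axis, z the imaging depth. Arrays are
## indexed (Z, Y, X); voxel i (1-based) covers the half-open physical interval
## [(i-1)*v, i*v) along its axis and has its centre at (i-0.5)*v.

#' Wrap angles into (-180, 180]
#'
#' Reduces angles in degrees modulo 360 to the signed interval (-180, 180].
#' Idempotent: `wrapAngle(wrapAngle(x))` equals `wrapAngle(x)`.
#'
#' @param deg numeric vector of angles in degrees.
#' @return numeric vector of the same length with values in (-180, 180].
#' @examples
#' wrapAngle(c(190, -340, 180, -180))
#' @export
wrapAngle <- function(deg) {
  w <- deg - 360 * floor((deg + 180) / 360)
  # floor maps +180 to -180; the convention keeps +180
  w[w <= -180] <- w[w <= -180] + 360
  w
}

## Evaluate expr with a temporarily fixed RNG state, restoring the caller's
## stream afterwards. `seed` must be a single finite number.
withSeed <- function(seed, expr) {
  seed <- as.integer(seed %% .Machine$integer.max)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

## Sub-seed derivation: generators consume disjoint streams from one config
## seed. Kept below 2^31 - 1.
subSeed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1009 + offset) %% (.Machine$integer.max - 1L))
}

## points: n x 3 matrix (x, y, z); segments: data.frame with x0..z1, radius_um.
## Returns n-vector of Euclidean distances to the nearest segment AXIS.
pointSegmentAxisDistance <- function(points, segments) {
  points <- rbind(points)
  n <- nrow(points)
  if (nrow(segments) == 0L) return(rep(Inf, n))
  best <- rep(Inf, n)
  for (i in seq_len(nrow(segments))) {
    p0 <- c(segments$x0[i], segments$y0[i], segments$z0[i])
    p1 <- c(segments$x1[i], segments$y1[i], segments$z1[i])
    d <- p1 - p0
    len2 <- sum(d * d)
    rel <- sweep(points, 2, p0)
    tt <- if (len2 == 0) rep(0, n) else pmin(1, pmax(0, rel %*% d / len2))
    foot <- outer(drop(tt), d)
    diff <- rel - foot
    best <- pmin(best, sqrt(rowSums(diff * diff)))
  }
  best
}

## Signed distance to the capsule SURFACE (negative inside). Used for
## analytic association geometry on synthetic networks.
pointCapsuleSurfaceDistance <- function(points, segments) {
  if (nrow(segments) == 0L) return(rep(Inf, nrow(rbind(points))))
  points <- rbind(points)
  best <- rep(Inf, nrow(points))
  for (i in seq_len(nrow(segments))) {
    seg <- segments[i, , drop = FALSE]
    best <- pmin(best, pointSegmentAxisDistance(points, seg) - seg$radius_um)
  }
  best
}

## Physical (x, y, z) in um -> 1-based array index (iz, iy, ix).
## voxelSize is (z, y, x); dim is array dim (Z, Y, X). Points outside the
## array get NA rows.
physToIndex <- function(points, voxelSize, dim) {
  points <- rbind(points)
  ix <- floor(points[, 1] / voxelSize[3]) + 1
  iy <- floor(points[, 2] / voxelSize[2]) + 1
  iz <- floor(points[, 3] / voxelSize[1]) + 1
  idx <- cbind(iz = iz, iy = iy, ix = ix)
  bad <- iz < 1 | iz > dim[1] | iy < 1 | iy > dim[2] | ix < 1 | ix > dim[3]
  idx[bad, ] <- NA_real_
  storage.mode(idx) <- "integer"
  idx
}

## 1-based (iz, iy, ix) index rows -> voxel-centre physical (x, y, z) in um.
indexToPhys <- function(idx, voxelSize) {
  idx <- rbind(idx)
  cbind(x = (idx[, 3] - 0.5) * voxelSize[3],
        y = (idx[, 2] - 0.5) * voxelSize[2],
        z = (idx[, 1] - 0.5) * voxelSize[1])
}

## Uniform direction on the unit sphere.
runifSphere <- function(n) {
  z <- stats::runif(n, -1, 1)
  phi <- stats::runif(n, 0, 2 * pi)
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

stopifnotScalar <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("'%s' must be strictly positive", name), call. = FALSE)
  if (nonneg && x < 0)
    stop(sprintf("'%s' must be non-negative", name), call. = FALSE)
  invisible(TRUE)
}
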